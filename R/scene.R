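#' Synthetic scene specification
#'
#' Describes a synthetic histology-like patch: rotated elliptical "nuclei"
#' with class-dependent hue on a noisy light background. The default class
#' distribution is strongly skewed to emulate the class imbalance of real
#' nuclei datasets.
#'
#' @param height,width canvas size in pixels (each at least 64).
#' @param n_nuclei number of nuclei to attempt to place.
#' @param radius_range numeric length 2, min/max ellipse semi-axis (pixels).
#' @param class_probabilities length-K simplex vector of type frequencies.
#' @param allow_touching if `FALSE`, nuclei are placed with a 2-pixel
#'   clearance; if `TRUE`, later nuclei may abut earlier ones but never
#'   overwrite their pixels (first-come ownership).
#' @param seed integer seed; identical specs give bit-identical scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_nuclei = 10L,
                       radius_range = c(6, 12),
                       class_probabilities = c(0.70, 0.15, 0.10, 0.05),
                       allow_touching = FALSE, seed = 1L) {
  stopifnot(
    height >= 64L, width >= 64L, n_nuclei >= 0L,
    length(radius_range) == 2L, radius_range[1] > 0,
    radius_range[1] <= radius_range[2],
    all(class_probabilities >= 0),
    abs(sum(class_probabilities) - 1) <= 1e-9
  )
  if (radius_range[2] >= min(height, width) / 2) {
    stop("radius_range[2] must be smaller than half the canvas")
  }
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      n_nuclei = as.integer(n_nuclei), radius_range = as.numeric(radius_range),
      class_probabilities = as.numeric(class_probabilities),
      allow_touching = isTRUE(allow_touching), seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

scene_class_colors <- function(k) {
  # dark blue-purple palette reminiscent of hematoxylin-stained chromatin
  hues <- (0.62 + 0.55 * (seq_len(k) - 1) / max(k, 1)) %% 1
  t(grDevices::col2rgb(grDevices::hsv(hues, s = 0.55, v = 0.52)))
}

#' Generate a synthetic scene
#'
#' Renders shaded rotated ellipses (class-dependent hue, light Gaussian
#' noise) on a pale background and returns the image together with
#' consistent instance and class label maps. Placement rejects candidate
#' positions that violate the touching policy, so the number of placed
#' nuclei can be smaller than requested on crowded canvases.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3, values 0-255), `instances`
#'   (H x W integer map, 0 = background, ids 1..n), `classes` (H x W
#'   integer map of types in 0..K).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height
  W <- spec$width
  K <- length(spec$class_probabilities)
  cols <- scene_class_colors(K)
  with_seed_local(spec$seed, {
    inst <- matrix(0L, H, W)
    cls <- matrix(0L, H, W)
    shade <- matrix(0, H, W) # normalized elliptical radius at nucleus pixels
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * max(spec$n_nuclei, 1L)
    while (placed < spec$n_nuclei && tries < max_tries) {
      tries <- tries + 1L
      a <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      th <- stats::runif(1, 0, pi)
      k <- sample.int(K, 1L, prob = spec$class_probabilities)
      margin <- ceiling(max(a, b)) + 3L
      if (2L * margin + 2L >= min(H, W)) {
        stop("radius_range cannot fit the canvas")
      }
      cy <- stats::runif(1, margin + 1, H - margin)
      cx <- stats::runif(1, margin + 1, W - margin)
      r0 <- max(1L, floor(cy - margin)); r1 <- min(H, ceiling(cy + margin))
      c0 <- max(1L, floor(cx - margin)); c1 <- min(W, ceiling(cx + margin))
      rr <- r0:r1
      cc <- c0:c1
      Y <- matrix(rr, length(rr), length(cc)) - cy
      X <- matrix(cc, length(rr), length(cc), byrow = TRUE) - cx
      u <- X * cos(th) + Y * sin(th)
      v <- -X * sin(th) + Y * cos(th)
      e <- (u / a)^2 + (v / b)^2
      mask <- e <= 1
      if (!any(mask)) next
      occ <- inst[rr, cc]
      if (!spec$allow_touching) {
        guard <- (u / (a + 2))^2 + (v / (b + 2))^2 <= 1
        if (any(occ[guard] > 0L)) next
        free <- mask
      } else {
        free <- mask & occ == 0L
        if (sum(free) < 0.5 * sum(mask)) next # mostly occluded, retry
      }
      placed <- placed + 1L
      occ[free] <- placed
      inst[rr, cc] <- occ
      ck <- cls[rr, cc]
      ck[free] <- k
      cls[rr, cc] <- ck
      sh <- shade[rr, cc]
      sh[free] <- sqrt(pmax(e[free], 0))
      shade[rr, cc] <- sh
    }
    bg <- c(235, 214, 223)
    img <- array(0, c(H, W, 3L))
    fg <- inst > 0L
    for (ch in 1:3) {
      plane <- matrix(bg[ch], H, W)
      if (any(fg)) {
        base <- cols[cls[fg], ch]
        plane[fg] <- base * (1.15 - 0.35 * shade[fg])
      }
      img[, , ch] <- plane
    }
    img <- img + array(stats::rnorm(H * W * 3, sd = 4), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, instances = inst, classes = cls)
  })
}

#' Canonicalize an instance label map
#'
#' Relabels the positive ids to 1..N (ascending original id) while
#' preserving the pixel partition; background stays 0. Idempotent.
#'
#' @param m H x W integer matrix of non-negative instance ids.
#' @return relabelled integer matrix.
#' @export
canonicalize_instances <- function(m) {
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("instance ids must be non-negative")
  pos <- m > 0L
  if (!any(pos)) return(m)
  u <- sort(unique(m[pos]))
  m[pos] <- match(m[pos], u)
  m
}

#' Read / write a scene specification (YAML or JSON)
#'
#' @param spec a [scene_spec()].
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scene_spec` returns a validated [scene_spec()].
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(spec), path)
  }
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  v <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  do.call(scene_spec, v)
}

# Validate a paired instance/class map (one class per instance, classes
# only on instance pixels). Used by tests and the training loop.
check_scene_pair <- function(instances, classes) {
  if (any((classes > 0L) & (instances == 0L))) {
    stop("class labels present on background pixels")
  }
  if (any((classes == 0L) & (instances > 0L))) {
    stop("instance pixels missing a class label")
  }
  ids <- sort(unique(instances[instances > 0L]))
  for (id in ids) {
    cl <- unique(classes[instances == id])
    if (length(cl) != 1L) stop("instance ", id, " carries multiple classes")
  }
  invisible(TRUE)
}
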