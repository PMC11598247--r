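#' Post-processing configuration
#'
#' Thresholds and hygiene parameters of the watershed-based instance
#' extraction: `h` binarizes the nuclear probability map, `k` binarizes the
#' Sobel boundary-energy map, components smaller than `min_instance_px`
#' are discarded, and `sobel_ksize` sets the Sobel aperture (odd; larger
#' kernels smooth spurious ridges on noisy predictions).
#'
#' @param h probability threshold in (0, 1).
#' @param k energy threshold in (0, 1).
#' @param min_instance_px minimum instance size in pixels.
#' @param sobel_ksize odd Sobel kernel size.
#' @return a `postproc_config` list.
#' @export
postproc_config <- function(h = 0.5, k = 0.4, min_instance_px = 10L,
                            sobel_ksize = 5L) {
  stopifnot(
    h > 0, h < 1, k > 0, k < 1, min_instance_px >= 1L,
    sobel_ksize >= 3L, sobel_ksize %% 2L == 1L
  )
  structure(
    list(
      h = h, k = k, min_instance_px = as.integer(min_instance_px),
      sobel_ksize = as.integer(sobel_ksize)
    ),
    class = "postproc_config"
  )
}

# Sobel kernels of odd size: outer product of a binomial smoothing vector
# and a derivative vector (ksize 3 gives the classic [-1 0 1] x [1 2 1]).
sobel_kernels <- function(ksize) {
  smooth <- c(1, 2, 1)
  deriv <- c(-1, 0, 1)
  while (length(smooth) < ksize) {
    smooth <- stats::convolve(smooth, rev(c(1, 2, 1)), type = "open")
    deriv <- stats::convolve(deriv, rev(c(1, 2, 1)), type = "open")
  }
  # Kx responds positively to gradients increasing along columns (x), Ky
  # along rows (y); the sign flip compensates for filter2's convolution
  # (kernel-flipping) semantics so the result is a correlation.
  list(kx = -outer(smooth, deriv), ky = -outer(deriv, smooth))
}

# Correlation of a matrix with a kernel, replicate borders.
filter_replicate <- function(x, kern) {
  r <- EBImage::filter2(x, kern, boundary = "replicate")
  matrix(r, nrow(x), ncol(x))
}

#' Sobel boundary energy of a predicted distance map
#'
#' Applies the horizontal Sobel component to the horizontal channel and the
#' vertical component to the vertical channel, rescales each response map
#' so the strongest boundary response (the steep negative transition
#' between adjacent nuclei) maps to 1, and takes the pixelwise maximum.
#' Constant channels contribute 0 everywhere (degenerate rescale).
#'
#' @param pred_hv H x W x 2 distance map.
#' @param ksize odd Sobel kernel size.
#' @return H x W energy matrix in `[0, 1]`.
#' @export
sobel_energy <- function(pred_hv, ksize = 5L) {
  kerns <- sobel_kernels(ksize)
  comp <- function(g) {
    rng <- range(g)
    if (rng[2] - rng[1] < 1e-12) {
      matrix(0, nrow(g), ncol(g))
    } else {
      1 - (g - rng[1]) / (rng[2] - rng[1])
    }
  }
  gx <- filter_replicate(pred_hv[, , 1], kerns$kx)
  gy <- filter_replicate(pred_hv[, , 2], kerns$ky)
  pmax(comp(gx), comp(gy))
}

#' Threshold function
#'
#' Elementwise `1` where `a > b`, else `0` (strict inequality).
#'
#' @param a numeric array/matrix.
#' @param b scalar threshold.
#' @return 0/1 array of the same shape.
#' @export
threshold <- function(a, b) {
  out <- (a > b) * 1
  dim(out) <- dim(a)
  out
}

#' Markers and energy landscape for the watershed
#'
#' Markers are the positive part of `tau(q, h) - tau(Sm, k)`, labelled with
#' 8-connectivity and cleaned of components smaller than
#' `min_instance_px`; the energy is `1 - tau(Sm, k) * tau(q, h)` restricted
#' to the thresholded foreground (energy 1 outside it).
#'
#' @param q H x W foreground probability map in `[0, 1]`.
#' @param Sm H x W Sobel energy from [sobel_energy()].
#' @param cfg a [postproc_config()].
#' @return list with `markers` (labelled H x W integer map) and `energy`.
#' @export
markers_and_energy <- function(q, Sm, cfg = postproc_config()) {
  tq <- threshold(q, cfg$h)
  ts <- threshold(Sm, cfg$k)
  m0 <- pmax(tq - ts, 0) > 0
  lab <- cc_label8_cpp(m0)
  lab <- drop_small_instances(lab, cfg$min_instance_px)
  energy <- 1 - ts * tq
  energy[tq == 0] <- 1
  list(markers = lab, energy = energy)
}

drop_small_instances <- function(lab, min_px) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  lab[!(lab %in% keep)] <- 0L
  canonicalize_instances(lab)
}

#' Instance segmentation by marker-controlled watershed
#'
#' Full post-processing of predicted probability and distance maps:
#' Sobel boundary energy, marker extraction, priority-flood watershed of
#' the energy landscape seeded by the markers and confined to the
#' thresholded foreground, small-instance removal and canonicalization.
#'
#' @param q H x W foreground probability map.
#' @param pred_hv H x W x 2 predicted distance map.
#' @param cfg a [postproc_config()].
#' @return H x W integer instance label map.
#' @export
watershed_instances <- function(q, pred_hv, cfg = postproc_config()) {
  stopifnot(identical(dim(q), dim(pred_hv)[1:2]))
  Sm <- sobel_energy(pred_hv, cfg$sobel_ksize)
  me <- markers_and_energy(q, Sm, cfg)
  mask <- matrix(q > cfg$h, nrow(q), ncol(q))
  if (max(me$markers) == 0L) {
    return(matrix(0L, nrow(q), ncol(q)))
  }
  lab <- watershed_flood_cpp(me$energy, me$markers, mask)
  drop_small_instances(lab, cfg$min_instance_px)
}

#' Assign a nucleus type to each instance by majority vote
#'
#' Each instance's type is the majority argmax class over its pixels,
#' excluding background votes; ties are broken by the highest summed
#' probability among the tied types, and instances whose pixels all vote
#' background fall back to the type with the highest summed non-background
#' probability.
#'
#' @param instances H x W integer instance map.
#' @param class_probs H x W x (K+1) per-pixel class probabilities
#'   (channel 1 = background, channels 2..K+1 = types 1..K).
#' @return list with `types` (data.frame of `instance`, `type`) and
#'   `class_map` (H x W integer map painted with the per-instance types).
#' @export
assign_types <- function(instances, class_probs) {
  d <- dim(class_probs)
  stopifnot(identical(dim(instances), d[1:2]))
  K <- d[3] - 1L
  pm <- matrix(class_probs, ncol = d[3])
  amax <- max.col(pm, ties.method = "first") - 1L # 0 = background
  ids <- sort(unique(instances[instances > 0L]))
  class_map <- matrix(0L, d[1], d[2])
  types <- integer(length(ids))
  for (i in seq_along(ids)) {
    idx <- which(instances == ids[i])
    votes <- tabulate(amax[idx], nbins = K) # background votes excluded
    if (all(votes == 0L)) {
      sums <- colSums(pm[idx, -1L, drop = FALSE])
      types[i] <- which.max(sums)
    } else {
      best <- which(votes == max(votes))
      if (length(best) > 1L) {
        sums <- colSums(pm[idx, best + 1L, drop = FALSE])
        best <- best[which.max(sums)]
      }
      types[i] <- best
    }
    class_map[idx] <- types[i]
  }
  list(types = data.frame(instance = ids, type = types), class_map = class_map)
}
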