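#' Horizontal-vertical distance target encoding
#'
#' Encodes an instance label map into the two-channel regression target of
#' the distance branch: for every nucleus pixel, the signed horizontal
#' (channel 1) and vertical (channel 2) offset to the instance's center of
#' mass, scaled per instance and per side so the extreme left/top maps to
#' -1 and the extreme right/bottom to +1 (the center of mass maps to 0 even
#' for asymmetric instances). Background pixels are exactly 0.
#'
#' @param m H x W integer instance map (0 = background).
#' @return H x W x 2 numeric array with values in `[-1, 1]`.
#' @export
compute_hv_map <- function(m) {
  H <- nrow(m)
  W <- ncol(m)
  hv <- array(0, c(H, W, 2L))
  ids <- unique(m[m > 0L])
  scale_side <- function(d) {
    out <- numeric(length(d))
    mx <- max(d)
    mn <- min(d)
    pos <- d > 0
    neg <- d < 0
    if (mx > 0) out[pos] <- d[pos] / mx
    if (mn < 0) out[neg] <- -d[neg] / mn
    out
  }
  for (id in ids) {
    idx <- which(m == id)
    r <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    dx <- cc - mean(cc)
    dy <- r - mean(r)
    hv[idx] <- scale_side(dx) # channel 1 occupies the first H*W block
    hv[idx + H * W] <- scale_side(dy)
  }
  hv
}

grad2d_h <- function(m) {
  x <- array(m, c(1L, nrow(m), ncol(m), 1L))
  matrix(fd_h(x), nrow(m), ncol(m))
}

grad2d_v <- function(m) {
  x <- array(m, c(1L, nrow(m), ncol(m), 1L))
  matrix(fd_v(x), nrow(m), ncol(m))
}

#' Gradient targets of a horizontal-vertical distance map
#'
#' Returns the horizontal finite-difference gradient of channel 1 and the
#' vertical gradient of channel 2 (central differences in the interior,
#' one-sided at the borders). These are the quantities compared by the
#' gradient mean-squared-error loss.
#'
#' @param hv H x W x 2 distance map.
#' @return H x W x 2 array of gradients.
#' @export
hv_gradient_targets <- function(hv) {
  stopifnot(length(dim(hv)) == 3L, dim(hv)[3] == 2L)
  out <- array(0, dim(hv))
  out[, , 1] <- grad2d_h(hv[, , 1])
  out[, , 2] <- grad2d_v(hv[, , 2])
  out
}
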