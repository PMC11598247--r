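#' Loss weights
#'
#' Weights of the composite objective `L = alpha * L1 + L2`, where `L1` is
#' computed from the coarse predictions and `L2` from the refined ones.
#' Each `Li` sums the three branch losses: probability branch
#' `beta3 * CE + beta4 * Dice`, distance branch `beta1 * MSE + beta2 *
#' gradient MSE`, classification branch `beta5 * CE + beta6 * generalized
#' Dice`. All weights default to 1; `beta2 = 2` is the setting used for
#' crowded colorectal data.
#'
#' @param alpha auxiliary (coarse) loss weight.
#' @param beta1,beta2,beta3,beta4,beta5,beta6 per-term weights.
#' @param epsilon Dice smoothing constant.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta1 = 1, beta2 = 1, beta3 = 1,
                         beta4 = 1, beta5 = 1, beta6 = 1, epsilon = 0.001) {
  w <- list(
    alpha = alpha, beta1 = beta1, beta2 = beta2, beta3 = beta3,
    beta4 = beta4, beta5 = beta5, beta6 = beta6, epsilon = epsilon
  )
  stopifnot(all(unlist(w) >= 0), epsilon > 0)
  structure(w, class = "loss_weights")
}

CE_LOG_FLOOR <- 1e-8

# ---- exported single-map losses ------------------------------------------

#' Mean squared error of a distance map
#'
#' Mean over all pixels and both channels of the squared difference.
#'
#' @param pred_hv,true_hv H x W x 2 arrays.
#' @return scalar loss.
#' @export
mse_loss <- function(pred_hv, true_hv) {
  stopifnot(identical(dim(pred_hv), dim(true_hv)))
  mean((pred_hv - true_hv)^2)
}

#' Gradient mean squared error of a distance map
#'
#' Compares the horizontal gradient of channel 1 and the vertical gradient
#' of channel 2 (see [hv_gradient_targets()]) over the nuclear pixel set
#' only: the mean over the mask of the squared horizontal-gradient error
#' plus the mean of the squared vertical-gradient error.
#'
#' @param pred_hv,true_hv H x W x 2 arrays.
#' @param nuclear_mask H x W logical/0-1 matrix marking nucleus pixels.
#' @return scalar loss; 0 (with a warning) when the mask is empty.
#' @export
msge_loss <- function(pred_hv, true_hv, nuclear_mask) {
  stopifnot(identical(dim(pred_hv), dim(true_hv)))
  msk <- nuclear_mask > 0
  m <- sum(msk)
  if (m == 0L) {
    warning("empty nuclear mask; gradient MSE undefined, returning 0")
    return(0)
  }
  gp <- hv_gradient_targets(pred_hv)
  gt <- hv_gradient_targets(true_hv)
  dh <- (gp[, , 1] - gt[, , 1])[msk]
  dv <- (gp[, , 2] - gt[, , 2])[msk]
  sum(dh^2) / m + sum(dv^2) / m
}

#' Dice loss of a foreground probability map
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`.
#'
#' @param pred_prob foreground probabilities in `[0, 1]`.
#' @param true_mask binary ground truth of the same shape.
#' @param epsilon smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_prob, true_mask, epsilon = 0.001) {
  stopifnot(identical(dim(pred_prob), dim(true_mask)))
  p <- as.numeric(pred_prob)
  t <- as.numeric(true_mask)
  1 - (2 * sum(p * t) + epsilon) / (sum(p) + sum(t) + epsilon)
}

#' Cross-entropy loss over per-pixel class distributions
#'
#' `-(1/N) * sum_i sum_m t[i,m] * log(p[i,m])` where `N` is the number of
#' pixels and the log is floored at 1e-8. Inputs are either H x W x M
#' arrays or N x M matrices.
#'
#' @param pred_probs predicted per-pixel distributions.
#' @param true_onehot one-hot ground truth of the same shape.
#' @return scalar loss.
#' @export
ce_loss <- function(pred_probs, true_onehot) {
  stopifnot(identical(dim(pred_probs), dim(true_onehot)))
  d <- dim(pred_probs)
  n_pix <- if (length(d) == 3L) d[1] * d[2] else d[1]
  -sum(true_onehot * log(pmax(pred_probs, CE_LOG_FLOOR))) / n_pix
}

#' Generalized Dice loss
#'
#' Multi-class Dice with per-class weights inverse to the squared class
#' volume, `w_l = 1 / (sum_n r_ln)^2`, which up-weights rare classes:
#' `1 - 2 * sum_l w_l sum_n r_ln p_ln / sum_l w_l sum_n (r_ln + p_ln)`.
#' Classes absent from the ground truth are skipped (weight 0).
#'
#' @param pred_probs H x W x K (or N x K) predicted class probabilities
#'   (background channel included).
#' @param true_onehot one-hot ground truth of the same shape.
#' @return scalar loss in `[0, 1]`.
#' @export
generalized_dice_loss <- function(pred_probs, true_onehot) {
  stopifnot(identical(dim(pred_probs), dim(true_onehot)))
  d <- dim(pred_probs)
  K <- d[length(d)]
  p <- matrix(pred_probs, ncol = K)
  r <- matrix(true_onehot, ncol = K)
  vol <- colSums(r)
  w <- ifelse(vol > 0, 1 / vol^2, 0)
  num <- sum(w * colSums(r * p))
  den <- sum(w * (vol + colSums(p)))
  if (den == 0) return(1)
  1 - 2 * num / den
}

#' Composite branch losses
#'
#' Evaluates the full objective `L = alpha * L1 + L2` on one sample.
#' `L1` uses the coarse maps and `L2` the refined maps; each is the sum of
#' the probability-branch loss (`beta3 * CE + beta4 * Dice`), the
#' distance-branch loss (`beta1 * MSE + beta2 * gradient MSE`) and the
#' classification-branch loss (`beta5 * CE + beta6 * generalized Dice`).
#'
#' @param outputs list with `prob_coarse`, `prob_refined` (H x W x 2
#'   probability distributions), `hv_coarse`, `hv_refined` (H x W x 2),
#'   `class_coarse`, `class_refined` (H x W x (K+1) distributions).
#' @param targets list with `prob_mask` (H x W binary foreground), `hv`
#'   (H x W x 2) and `class_onehot` (H x W x (K+1)).
#' @param w a [loss_weights()].
#' @return list with `total`, `L1`, `L2` and the six per-term values for
#'   each of the coarse/refined passes.
#' @export
branch_losses <- function(outputs, targets, w = loss_weights()) {
  fg <- targets$prob_mask > 0
  prob_onehot <- array(c(1 - fg, as.numeric(fg)), c(dim(fg), 2L))
  part <- function(prob, hv, cls) {
    terms <- c(
      ce_prob = ce_loss(prob, prob_onehot),
      dice = dice_loss(prob[, , 2], fg * 1, w$epsilon),
      mse = mse_loss(hv, targets$hv),
      msge = msge_loss(hv, targets$hv, fg),
      ce_class = ce_loss(cls, targets$class_onehot),
      gdl = generalized_dice_loss(cls, targets$class_onehot)
    )
    total <- w$beta3 * terms[["ce_prob"]] + w$beta4 * terms[["dice"]] +
      w$beta1 * terms[["mse"]] + w$beta2 * terms[["msge"]] +
      w$beta5 * terms[["ce_class"]] + w$beta6 * terms[["gdl"]]
    list(total = total, terms = terms)
  }
  l1 <- part(outputs$prob_coarse, outputs$hv_coarse, outputs$class_coarse)
  l2 <- part(outputs$prob_refined, outputs$hv_refined, outputs$class_refined)
  list(
    total = w$alpha * l1$total + l2$total,
    L1 = l1$total, L2 = l2$total,
    terms_coarse = l1$terms, terms_refined = l2$terms
  )
}

# ---- differentiable batch losses (training path) -------------------------
# All operate on (C, H, W, N) values; targets are plain arrays.

op_mse_b <- function(pred, target) {
  pv <- ag_value(pred)
  diff <- pv - target
  n <- length(pv)
  ag_node(sum(diff^2) / n, backward = function(node) {
    ag_accum(pred, node$grad * 2 * diff / n)
  })
}

# mask: (H, W, N) logical array of nuclear pixels.
op_msge_b <- function(pred, target, mask) {
  pv <- ag_value(pred)
  d <- dim(pv)
  N <- d[4]
  ph <- fd_h(pv[1, , , , drop = FALSE])
  pv_v <- fd_v(pv[2, , , , drop = FALSE])
  th <- fd_h(target[1, , , , drop = FALSE])
  tv <- fd_v(target[2, , , , drop = FALSE])
  dh <- ph - th
  dv <- pv_v - tv
  mk <- array(mask, c(1L, d[2], d[3], N))
  mcount <- apply(mk, 4, sum)
  per <- numeric(N)
  inv_m <- ifelse(mcount > 0, 1 / mcount, 0)
  for (n in seq_len(N)) {
    per[n] <- inv_m[n] * (sum((dh[, , , n] * mk[, , , n])^2) +
      sum((dv[, , , n] * mk[, , , n])^2))
  }
  ag_node(mean(per), backward = function(node) {
    g <- node$grad / N
    wh <- dh * mk
    wv <- dv * mk
    for (n in seq_len(N)) {
      wh[, , , n] <- wh[, , , n] * (2 * inv_m[n])
      wv[, , , n] <- wv[, , , n] * (2 * inv_m[n])
    }
    gh <- fd_h_adj(wh)
    gv <- fd_v_adj(wv)
    dp <- array(0, d)
    dp[1, , , ] <- gh * g
    dp[2, , , ] <- gv * g
    ag_accum(pred, dp)
  })
}

# pred: (1, H, W, N) foreground probabilities; target same shape binary.
op_dice_b <- function(pred, target, epsilon) {
  pv <- ag_value(pred)
  d <- dim(pv)
  N <- d[4]
  HW <- d[2] * d[3]
  pm <- matrix(pv, HW, N)
  tm <- matrix(target, HW, N)
  inter <- colSums(pm * tm)
  sp <- colSums(pm)
  st <- colSums(tm)
  den <- sp + st + epsilon
  dice <- 1 - (2 * inter + epsilon) / den
  ag_node(mean(dice), backward = function(node) {
    g <- node$grad / N
    dpm <- matrix(0, HW, N)
    for (n in seq_len(N)) {
      dpm[, n] <- -g * (2 * tm[, n] * den[n] - (2 * inter[n] + epsilon)) / den[n]^2
    }
    dim(dpm) <- d
    ag_accum(pred, dpm)
  })
}

# probs: (C, H, W, N) distributions; onehot same shape. N_pix normalization
# counts pixels (not pixels x channels), averaged over the batch.
op_ce_b <- function(probs, onehot) {
  pv <- ag_value(probs)
  d <- dim(pv)
  n_pix <- d[2] * d[3]
  N <- d[4]
  pc <- pmax(pv, CE_LOG_FLOOR)
  val <- -sum(onehot * log(pc)) / (n_pix * N)
  ag_node(val, backward = function(node) {
    dp <- -(onehot / pc) * (pv >= CE_LOG_FLOOR) / (n_pix * N)
    ag_accum(probs, node$grad * dp)
  })
}

op_gdl_b <- function(probs, onehot) {
  pv <- ag_value(probs)
  d <- dim(pv)
  C <- d[1]
  HW <- d[2] * d[3]
  N <- d[4]
  dim(pv) <- c(C, HW, N)
  oh <- onehot
  dim(oh) <- c(C, HW, N)
  vals <- numeric(N)
  ws <- matrix(0, C, N)
  nums <- numeric(N)
  dens <- numeric(N)
  for (n in seq_len(N)) {
    r <- oh[, , n]
    p <- pv[, , n]
    vol <- rowSums(r)
    w <- ifelse(vol > 0, 1 / vol^2, 0)
    num <- sum(w * rowSums(r * p))
    den <- sum(w * (vol + rowSums(p)))
    ws[, n] <- w
    nums[n] <- num
    dens[n] <- den
    vals[n] <- if (den == 0) 1 else 1 - 2 * num / den
  }
  ag_node(mean(vals), backward = function(node) {
    g <- node$grad / N
    dp <- array(0, c(C, HW, N))
    for (n in seq_len(N)) {
      if (dens[n] == 0) next
      # d/dp of (1 - 2A/B): -2 (dA * B - A * dB) / B^2
      dA <- ws[, n] * oh[, , n]
      dB <- ws[, n]
      dp[, , n] <- -2 * g * (dA * dens[n] - nums[n] * dB) / dens[n]^2
    }
    dim(dp) <- d
    ag_accum(probs, dp)
  })
}

# Full differentiable objective on a batch. outputs: node list from
# model_forward(training = TRUE); targets: list with prob_onehot
# (2, H, W, N), hv (2, H, W, N), class_onehot (K+1, H, W, N),
# fg_mask (H, W, N).
batch_objective <- function(outputs, targets, w = loss_weights()) {
  part <- function(prob_logits, hv, class_logits) {
    p <- op_softmax_ch(prob_logits)
    cl <- op_softmax_ch(class_logits)
    pfg <- op_crop_channel(p, 2L)
    terms <- list(
      ce_prob = op_ce_b(p, targets$prob_onehot),
      dice = op_dice_b(pfg, targets$fg_arr, w$epsilon),
      mse = op_mse_b(hv, targets$hv),
      msge = op_msge_b(hv, targets$hv, targets$fg_mask),
      ce_class = op_ce_b(cl, targets$class_onehot),
      gdl = op_gdl_b(cl, targets$class_onehot)
    )
    total <- op_add(
      op_add(
        op_add(op_scale(terms$ce_prob, w$beta3), op_scale(terms$dice, w$beta4)),
        op_add(op_scale(terms$mse, w$beta1), op_scale(terms$msge, w$beta2))
      ),
      op_add(op_scale(terms$ce_class, w$beta5), op_scale(terms$gdl, w$beta6))
    )
    list(total = total, terms = vapply(terms, ag_value, numeric(1)))
  }
  l1 <- part(outputs$prob_coarse, outputs$hv_coarse, outputs$class_coarse)
  l2 <- part(outputs$prob_refined, outputs$hv_refined, outputs$class_refined)
  total <- op_add(op_scale(l1$total, w$alpha), l2$total)
  list(
    loss = total,
    log = c(
      total = ag_value(total), L1 = ag_value(l1$total), L2 = ag_value(l2$total),
      stats::setNames(l1$terms, paste0("coarse_", names(l1$terms))),
      stats::setNames(l2$terms, paste0("refined_", names(l2$terms)))
    )
  )
}

# Select one channel, keeping dims: (C,H,W,N) -> (1,H,W,N).
op_crop_channel <- function(x, ch) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[ch, , , , drop = FALSE]
  ag_node(y, backward = function(node) {
    dx <- array(0, d)
    dx[ch, , , ] <- node$grad
    ag_accum(x, dx)
  })
}
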