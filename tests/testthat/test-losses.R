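test_that("mean squared error matches the per-pixel oracle", {
  hv <- array(0, c(4, 4, 2))
  expect_identical(mse_loss(hv, hv), 0)
  expect_equal(mse_loss(hv + 0.5, hv), 0.25)
  withr::with_seed(1, {
    p <- array(rnorm(32), c(4, 4, 2))
    t <- array(rnorm(32), c(4, 4, 2))
  })
  oracle <- 0
  for (i in seq_along(p)) oracle <- oracle + (p[i] - t[i])^2
  expect_equal(mse_loss(p, t), oracle / length(p))
})

test_that("gradient MSE kills constants but not scalings", {
  m <- matrix(0L, 12, 12)
  m[4:9, 4:9] <- 1L
  hv <- compute_hv_map(m)
  msk <- m > 0
  expect_identical(msge_loss(hv, hv, msk), 0)
  expect_equal(msge_loss(hv + 0.7, hv, msk), 0, tolerance = 1e-12)
  expect_gt(mse_loss(hv + 0.7, hv), 0)
  # doubling a ramp doubles its gradient: error = (slope)^2 summed per mask px
  gt <- hv_gradient_targets(hv)
  d <- (hv_gradient_targets(2 * hv) - gt)
  oracle <- sum(d[, , 1][msk]^2) / sum(msk) + sum(d[, , 2][msk]^2) / sum(msk)
  expect_equal(msge_loss(2 * hv, hv, msk), oracle)
  expect_warning(v <- msge_loss(hv, hv, matrix(0, 12, 12)), "empty")
  expect_identical(v, 0)
})

test_that("dice loss follows the smoothed overlap formula", {
  ones <- matrix(1, 10, 10)
  expect_equal(dice_loss(ones, ones), 0, tolerance = 1e-5)
  expect_equal(dice_loss(ones * 0, ones), 1 - 0.001 / (100 + 0.001))
  expect_identical(dice_loss(ones * 0, ones * 0), 0)
})

test_that("cross-entropy matches closed forms and a brute-force loop", {
  onehot <- array(0, c(2, 2, 2))
  onehot[, , 1] <- 1
  expect_equal(ce_loss(onehot, onehot), 0, tolerance = 1e-7)
  uni <- array(0.5, c(2, 2, 2))
  expect_equal(ce_loss(uni, onehot), log(2))
  withr::with_seed(2, {
    z <- array(runif(12), c(2, 2, 3))
    z <- z / array(rep(apply(z, c(1, 2), sum), 3), dim(z))
    cls <- matrix(sample(1:3, 4, TRUE), 2, 2)
  })
  oh <- array(0, c(2, 2, 3))
  for (i in 1:2) for (j in 1:2) oh[i, j, cls[i, j]] <- 1
  oracle <- 0
  for (i in 1:2) for (j in 1:2) for (k in 1:3) {
    oracle <- oracle - oh[i, j, k] * log(max(z[i, j, k], 1e-8))
  }
  expect_equal(ce_loss(z, oh), oracle / 4)
})

test_that("generalized dice weights classes by inverse squared volume", {
  # 90/10 two-class fixture, prediction perfect on the large class only
  n <- 100
  r <- cbind(c(rep(1, 90), rep(0, 10)), c(rep(0, 90), rep(1, 10)))
  p <- cbind(rep(1, n), rep(0, n))
  w <- c(1 / 90^2, 1 / 10^2)
  num <- sum(w * colSums(r * p))
  den <- sum(w * (colSums(r) + colSums(p)))
  expect_equal(generalized_dice_loss(p, r), 1 - 2 * num / den)
  expect_equal(generalized_dice_loss(r, r), 0, tolerance = 1e-12)
  # disjoint supports
  expect_equal(generalized_dice_loss(1 - r, r), 1)
  # absent class is skipped (weight 0): no NaN
  r0 <- cbind(rep(1, n), rep(0, n))
  expect_true(is.finite(generalized_dice_loss(p, r0)))
})

test_that("equal class volumes reduce generalized dice to plain multiclass dice", {
  withr::with_seed(3, {
    r <- cbind(c(rep(1, 50), rep(0, 50)), c(rep(0, 50), rep(1, 50)))
    p <- matrix(runif(200), 100, 2)
    p <- p / rowSums(p)
  })
  plain <- 1 - 2 * sum(r * p) / sum(r + p)
  expect_equal(generalized_dice_loss(p, r), plain)
})

test_that("the composite objective satisfies its algebraic identities", {
  withr::with_seed(4, {
    H <- 8L
    m <- matrix(0L, H, H)
    m[3:6, 3:6] <- 1L
    hv <- compute_hv_map(m)
    K <- 2L
    cls_oh <- array(0, c(H, H, K + 1L))
    cls_oh[, , 1] <- m == 0
    cls_oh[, , 2] <- m == 1
    mk_probs <- function(C) {
      z <- array(runif(H * H * C), c(H, H, C))
      z / array(rep(apply(z, c(1, 2), sum), C), dim(z))
    }
    targets <- list(prob_mask = m, hv = hv, class_onehot = cls_oh)
    coarse <- list(
      prob = mk_probs(2L), hv = hv + array(rnorm(H * H * 2, sd = .1), dim(hv)),
      cls = mk_probs(K + 1L)
    )
    refined <- list(
      prob = mk_probs(2L), hv = hv + array(rnorm(H * H * 2, sd = .05), dim(hv)),
      cls = mk_probs(K + 1L)
    )
  })
  outs <- list(
    prob_coarse = coarse$prob, prob_refined = refined$prob,
    hv_coarse = coarse$hv, hv_refined = refined$hv,
    class_coarse = coarse$cls, class_refined = refined$cls
  )
  same <- outs
  same$prob_refined <- same$prob_coarse
  same$hv_refined <- same$hv_coarse
  same$class_refined <- same$class_coarse

  for (alpha in c(0, 0.4, 1)) {
    w <- loss_weights(alpha = alpha, beta2 = 2)
    r <- branch_losses(outs, targets, w)
    expect_equal(r$total, alpha * r$L1 + r$L2, tolerance = 1e-14)
    rs <- branch_losses(same, targets, w)
    expect_equal(rs$total, (1 + alpha) * rs$L1, tolerance = 1e-14)
  }
  w <- loss_weights()
  r0 <- branch_losses(outs, targets, loss_weights(alpha = 0))
  expect_equal(r0$total, r0$L2)
  # perfect predictions give (almost exactly) zero
  perfect <- list(
    prob = array(c(1 - m, m), c(H, H, 2L)), hv = hv,
    cls = cls_oh
  )
  pouts <- list(
    prob_coarse = perfect$prob, prob_refined = perfect$prob,
    hv_coarse = perfect$hv, hv_refined = perfect$hv,
    class_coarse = perfect$cls, class_refined = perfect$cls
  )
  expect_equal(branch_losses(pouts, targets, w)$total, 0, tolerance = 1e-4)
  # every term is non-negative, dice and GDL within [0, 1]
  terms <- branch_losses(outs, targets, w)$terms_coarse
  expect_true(all(terms >= 0))
  expect_lte(terms[["dice"]], 1)
  expect_lte(terms[["gdl"]], 1)
})

test_that("the differentiable batch losses agree with the single-map API", {
  withr::with_seed(6, {
    m <- matrix(0L, 8, 8)
    m[2:5, 3:7] <- 1L
    hv <- compute_hv_map(m)
    pred <- hv + array(rnorm(128, sd = 0.2), dim(hv))
    p <- matrix(runif(64), 8, 8)
  })
  b <- aernet:::ag_no_grad(aernet:::ag_value(
    aernet:::op_mse_b(aernet:::as_ag(aernet:::to_chw(pred)), aernet:::to_chw(hv))
  ))
  expect_equal(b, mse_loss(pred, hv))
  bm <- aernet:::ag_no_grad(aernet:::ag_value(aernet:::op_msge_b(
    aernet:::as_ag(aernet:::to_chw(pred)), aernet:::to_chw(hv),
    array(m > 0, c(8, 8, 1))
  )))
  expect_equal(bm, msge_loss(pred, hv, m > 0))
  bd <- aernet:::ag_no_grad(aernet:::ag_value(aernet:::op_dice_b(
    aernet:::as_ag(array(p, c(1, 8, 8, 1))), array(m, c(1, 8, 8, 1)), 0.001
  )))
  expect_equal(bd, dice_loss(p, (m > 0) * 1))
})
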