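test_that("matching pairs instances above IoU 0.5 with the documented arithmetic", {
  m <- matrix(0L, 20, 20)
  m[2:11, 2:11] <- 1L # 100 px
  p <- matrix(0L, 20, 20)
  p[4:11, 2:11] <- 1L # 80 px, fully inside: union 100
  r <- match_instances(m, p)
  expect_equal(r$tp_pairs$iou, 0.8)
  # constructed 80-overlap / 120-union pair
  p2 <- matrix(0L, 20, 20)
  p2[4:13, 2:11] <- 1L # 100 px, overlap 80, union 120
  r2 <- match_instances(m, p2)
  expect_equal(r2$tp_pairs$iou, 80 / 120)
  # identity and empty predictions
  ri <- match_instances(m, m)
  expect_equal(ri$tp_pairs$iou, 1)
  re <- match_instances(m, matrix(0L, 20, 20))
  expect_identical(nrow(re$tp_pairs), 0L)
  expect_identical(re$fn_ids, 1L)
})

test_that("greedy IoU>0.5 matching equals the optimal-assignment oracle", {
  brute_force_best <- function(gt, pred) {
    # maximum-cardinality matching over IoU>0.5 candidate pairs, found by
    # exhaustive recursion (valid for small instance counts)
    mr <- list()
    gids <- sort(unique(gt[gt > 0]))
    pids <- sort(unique(pred[pred > 0]))
    iou <- matrix(0, length(gids), length(pids))
    for (gi in seq_along(gids)) {
      for (pi in seq_along(pids)) {
        a <- gt == gids[gi]
        b <- pred == pids[pi]
        inter <- sum(a & b)
        if (inter > 0) iou[gi, pi] <- inter / sum(a | b)
      }
    }
    cand <- which(iou > 0.5, arr.ind = TRUE)
    best <- 0
    rec <- function(i, used_g, used_p, n) {
      if (i > nrow(cand)) {
        best <<- max(best, n)
        return()
      }
      rec(i + 1, used_g, used_p, n)
      if (!(cand[i, 1] %in% used_g) && !(cand[i, 2] %in% used_p)) {
        rec(i + 1, c(used_g, cand[i, 1]), c(used_p, cand[i, 2]), n + 1)
      }
    }
    rec(1, integer(0), integer(0), 0)
    best
  }
  for (seed in 1:20) {
    gt <- random_rect_map(30, 30, sample(2:6, 1), seed)
    pred <- random_rect_map(30, 30, sample(2:6, 1), seed + 500)
    m <- match_instances(gt, pred)
    expect_identical(nrow(m$tp_pairs), as.integer(brute_force_best(gt, pred)))
    # uniqueness: no id appears twice
    expect_false(any(duplicated(m$tp_pairs$gt_id)))
    expect_false(any(duplicated(m$tp_pairs$pred_id)))
    expect_true(all(m$tp_pairs$iou > 0.5))
  }
})

test_that("panoptic quality composes detection and segmentation quality", {
  m <- matrix(0L, 20, 20)
  m[2:11, 2:11] <- 1L
  p <- matrix(0L, 20, 20)
  p[4:13, 2:11] <- 1L
  pq <- panoptic_quality(match_instances(m, p))
  expect_equal(pq$DQ, 1)
  expect_equal(pq$SQ, 80 / 120)
  expect_equal(pq$PQ, 80 / 120)
  # 1 TP at IoU 0.8 plus 1 FP and 1 FN: DQ = 1/2, PQ = 0.4
  m2 <- m
  m2[14:16, 14:16] <- 2L # unmatched GT
  p2 <- matrix(0L, 20, 20)
  p2[4:11, 2:11] <- 1L # IoU 0.8 with gt 1
  p2[17:19, 1:3] <- 2L # unmatched prediction
  pq2 <- panoptic_quality(match_instances(m2, p2))
  expect_equal(pq2$DQ, 0.5)
  expect_equal(pq2$PQ, 0.4)
  perfect <- panoptic_quality(match_instances(m2, m2))
  expect_equal(perfect$PQ, 1)
  # PQ = DQ * SQ and bounds on random maps
  for (seed in 30:35) {
    gt <- random_rect_map(25, 25, 4, seed)
    pr <- random_rect_map(25, 25, 4, seed + 99)
    q <- panoptic_quality(match_instances(gt, pr))
    expect_equal(q$PQ, q$DQ * q$SQ, tolerance = 1e-15)
    expect_true(q$PQ >= 0 && q$PQ <= 1)
  }
})

test_that("detection F-score follows 2TP/(2TP+FP+FN)", {
  fake <- structure(
    list(
      tp_pairs = data.frame(gt_id = 1:8, pred_id = 1:8, iou = rep(0.9, 8)),
      fp_ids = 1:2 + 100L, fn_ids = 1:2 + 200L, n_gt = 10L, n_pred = 10L
    ),
    class = "match_result"
  )
  expect_equal(detection_f1(fake), 16 / 20)
  m <- matrix(0L, 10, 10)
  m[2:5, 2:5] <- 1L
  expect_equal(detection_f1(match_instances(m, matrix(0L, 10, 10))), 0)
  expect_equal(detection_f1(match_instances(m, m)), 1)
  empty <- matrix(0L, 10, 10)
  expect_equal(detection_f1(match_instances(empty, empty)), 1)
})

test_that("classification F-score combines typing and detection errors", {
  # 3 TP pairs typed (t,t), (t,u), (u,u); 1 FPd, 0 FNd; for t: 2(1+1)/(4+0+2+1)
  fake <- structure(
    list(
      tp_pairs = data.frame(gt_id = 1:3, pred_id = 1:3, iou = rep(0.8, 3)),
      fp_ids = 9L, fn_ids = integer(0), n_gt = 3L, n_pred = 4L
    ),
    class = "match_result"
  )
  gt_types <- data.frame(instance = 1:3, type = c(1L, 1L, 2L))
  pred_types <- data.frame(instance = c(1:3, 9L), type = c(1L, 2L, 2L, 1L))
  expect_equal(classification_f1(fake, gt_types, pred_types, 1L), 4 / 7)
  # perfect typing over 10 TPs gives 1 for every type
  fake2 <- structure(
    list(
      tp_pairs = data.frame(gt_id = 1:10, pred_id = 1:10, iou = rep(1, 10)),
      fp_ids = integer(0), fn_ids = integer(0), n_gt = 10L, n_pred = 10L
    ),
    class = "match_result"
  )
  ty <- data.frame(instance = 1:10, type = rep(c(1L, 2L), c(4, 6)))
  expect_equal(classification_f1(fake2, ty, ty, 1L), 1)
  expect_equal(classification_f1(fake2, ty, ty, 2L), 1)
  expect_error(classification_f1(fake2, ty[1:5, ], ty, 1L), "unknown instance")
})

test_that("detection score is invariant to relabeling and joint translation", {
  gt <- random_rect_map(30, 30, 5, 77)
  pred <- random_rect_map(30, 30, 5, 177)
  f0 <- detection_f1(match_instances(gt, pred))
  # relabel
  perm <- sample(max(gt))
  gt_r <- gt
  gt_r[gt > 0] <- perm[gt[gt > 0]]
  expect_equal(detection_f1(match_instances(gt_r, pred)), f0)
  # translate both maps by (3, 4)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <- m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(detection_f1(match_instances(shift(gt, 3, 4), shift(pred, 3, 4))), f0)
})

test_that("multi-image evaluation pools raw counts before forming ratios", {
  m1 <- matrix(0L, 15, 15)
  m1[2:7, 2:7] <- 1L
  m2 <- matrix(0L, 15, 15)
  m2[3:8, 3:8] <- 1L
  m2[10:13, 10:13] <- 2L
  # predictions: image 1 perfect; image 2 misses instance 2
  p2 <- m2
  p2[m2 == 2L] <- 0L
  res <- evaluate_maps(list(m1, m2), list(m1, p2))
  expect_equal(res$DQ, 2 / (2 + 0.5)) # 2 TP, 1 FN pooled
  expect_equal(res$SQ, 1)
  expect_equal(res$Fd, 4 / 5)
})
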