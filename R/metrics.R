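#' Match predicted and ground-truth instances at IoU > 0.5
#'
#' Pairs every ground-truth instance with the prediction whose
#' intersection-over-union exceeds 0.5. Such pairs are mathematically
#' unique (no two segments can both exceed 0.5 IoU with the same segment),
#' so the greedy pairing equals the optimal assignment. Unmatched
#' predictions are false positives, unmatched ground-truth instances false
#' negatives.
#'
#' @param gt,pred H x W integer instance label maps of the same size.
#' @return a `match_result` list with `tp_pairs` (data.frame `gt_id`,
#'   `pred_id`, `iou`), `fp_ids`, `fn_ids`, `n_gt`, `n_pred`.
#' @export
match_instances <- function(gt, pred) {
  stopifnot(identical(dim(gt), dim(pred)))
  gt_ids <- sort(unique(gt[gt > 0L]))
  pred_ids <- sort(unique(pred[pred > 0L]))
  area_g <- tabulate(gt[gt > 0L], nbins = max(gt, 0L))
  area_p <- tabulate(pred[pred > 0L], nbins = max(pred, 0L))
  tp <- data.frame(gt_id = integer(0), pred_id = integer(0), iou = numeric(0))
  sel <- gt > 0L & pred > 0L
  if (any(sel)) {
    pairs <- paste(gt[sel], pred[sel])
    tab <- table(pairs)
    ids <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    g <- as.integer(ids[, 1])
    p <- as.integer(ids[, 2])
    inter <- as.numeric(tab)
    iou <- inter / (area_g[g] + area_p[p] - inter)
    keep <- iou > 0.5
    tp <- data.frame(gt_id = g[keep], pred_id = p[keep], iou = iou[keep])
    tp <- tp[order(tp$gt_id), , drop = FALSE]
    rownames(tp) <- NULL
  }
  structure(
    list(
      tp_pairs = tp,
      fp_ids = setdiff(pred_ids, tp$pred_id),
      fn_ids = setdiff(gt_ids, tp$gt_id),
      n_gt = length(gt_ids), n_pred = length(pred_ids)
    ),
    class = "match_result"
  )
}

#' Panoptic Quality
#'
#' `DQ = TP / (TP + FP/2 + FN/2)` (detection quality), `SQ` = mean IoU over
#' matched pairs (0 when there are none), `PQ = DQ * SQ`. When both maps
#' are empty all three are 1 by convention.
#'
#' @param match a `match_result` from [match_instances()].
#' @return list with `DQ`, `SQ`, `PQ`.
#' @export
panoptic_quality <- function(match) {
  tp <- nrow(match$tp_pairs)
  fp <- length(match$fp_ids)
  fn <- length(match$fn_ids)
  if (tp + fp + fn == 0L) {
    return(list(DQ = 1, SQ = 1, PQ = 1))
  }
  dq <- tp / (tp + 0.5 * fp + 0.5 * fn)
  sq <- if (tp > 0L) mean(match$tp_pairs$iou) else 0
  list(DQ = dq, SQ = sq, PQ = dq * sq)
}

#' Detection F-score
#'
#' `Fd = 2 TP / (2 TP + FP + FN)` over the IoU > 0.5 matching; 1 when both
#' maps are empty.
#'
#' @param match a `match_result`.
#' @return scalar in `[0, 1]`.
#' @export
detection_f1 <- function(match) {
  tp <- nrow(match$tp_pairs)
  fp <- length(match$fp_ids)
  fn <- length(match$fn_ids)
  den <- 2 * tp + fp + fn
  if (den == 0) return(1)
  2 * tp / den
}

type_of <- function(types, ids) {
  if (is.data.frame(types)) {
    out <- types$type[match(ids, types$instance)]
  } else {
    out <- unname(types[as.character(ids)])
  }
  if (any(is.na(out))) stop("unknown instance id in type table")
  out
}

#' Per-type classification F-score
#'
#' Splits the matched pairs by type `t`: correctly classified type-t pairs
#' (TPt), correctly classified non-t pairs (TNt), predictions of type t
#' whose ground truth is non-t (FPt) and vice versa (FNt); detection errors
#' enter as FPd/FNd:
#' `Ft = 2(TPt + TNt) / (2(TPt + TNt) + 2 FPt + 2 FNt + FPd + FNd)`.
#'
#' @param match a `match_result`.
#' @param gt_types,pred_types type tables: a data.frame with columns
#'   `instance` and `type`, or a vector named by instance id.
#' @param t the type evaluated.
#' @return scalar in `[0, 1]`; 1 when there is nothing to evaluate.
#' @export
classification_f1 <- function(match, gt_types, pred_types, t) {
  fpd <- length(match$fp_ids)
  fnd <- length(match$fn_ids)
  tpd <- nrow(match$tp_pairs)
  if (tpd > 0) {
    gtt <- type_of(gt_types, match$tp_pairs$gt_id)
    prt <- type_of(pred_types, match$tp_pairs$pred_id)
    tpt <- sum(gtt == t & prt == t)
    tnt <- sum(gtt != t & prt != t)
    fpt <- sum(prt == t & gtt != t)
    fnt <- sum(gtt == t & prt != t)
  } else {
    tpt <- tnt <- fpt <- fnt <- 0L
  }
  den <- 2 * (tpt + tnt) + 2 * fpt + 2 * fnt + fpd + fnd
  if (den == 0) {
    return(if (match$n_gt == 0L && match$n_pred == 0L) 1 else 0)
  }
  2 * (tpt + tnt) / den
}

#' Evaluate segmentation and classification over a set of images
#'
#' Aggregates raw counts (TP/FP/FN and IoU sums, and the per-type
#' classification counts) across images before forming the ratios, the
#' stable convention for small test sets.
#'
#' @param gt_maps,pred_maps lists of instance label maps.
#' @param gt_types,pred_types optional lists of per-image type tables
#'   (as in [classification_f1()]).
#' @param types integer vector of types to report `Ft` for.
#' @return list with `DQ`, `SQ`, `PQ`, `Fd` and, when types are given,
#'   `Ft` (named numeric vector).
#' @export
evaluate_maps <- function(gt_maps, pred_maps, gt_types = NULL,
                          pred_types = NULL, types = NULL) {
  stopifnot(length(gt_maps) == length(pred_maps))
  tp <- fp <- fn <- 0L
  iou_sum <- 0
  n_gt_tot <- n_pred_tot <- 0L
  K <- if (is.null(types)) integer(0) else types
  cls_counts <- matrix(0, length(K), 4,
    dimnames = list(as.character(K), c("tpt", "tnt", "fpt", "fnt"))
  )
  for (i in seq_along(gt_maps)) {
    m <- match_instances(gt_maps[[i]], pred_maps[[i]])
    tp <- tp + nrow(m$tp_pairs)
    fp <- fp + length(m$fp_ids)
    fn <- fn + length(m$fn_ids)
    iou_sum <- iou_sum + sum(m$tp_pairs$iou)
    n_gt_tot <- n_gt_tot + m$n_gt
    n_pred_tot <- n_pred_tot + m$n_pred
    if (length(K) && nrow(m$tp_pairs) > 0) {
      gtt <- type_of(gt_types[[i]], m$tp_pairs$gt_id)
      prt <- type_of(pred_types[[i]], m$tp_pairs$pred_id)
      for (j in seq_along(K)) {
        t <- K[j]
        cls_counts[j, ] <- cls_counts[j, ] + c(
          sum(gtt == t & prt == t), sum(gtt != t & prt != t),
          sum(prt == t & gtt != t), sum(gtt == t & prt != t)
        )
      }
    }
  }
  dq <- if (tp + fp + fn == 0L) 1 else tp / (tp + 0.5 * fp + 0.5 * fn)
  sq <- if (tp > 0L) iou_sum / tp else if (tp + fp + fn == 0L) 1 else 0
  fd <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  out <- list(DQ = dq, SQ = sq, PQ = dq * sq, Fd = fd)
  if (length(K)) {
    ft <- numeric(length(K))
    for (j in seq_along(K)) {
      cc <- cls_counts[j, ]
      den <- 2 * (cc["tpt"] + cc["tnt"]) + 2 * cc["fpt"] + 2 * cc["fnt"] + fp + fn
      ft[j] <- if (den == 0) {
        if (n_gt_tot == 0L && n_pred_tot == 0L) 1 else 0
      } else {
        unname(2 * (cc["tpt"] + cc["tnt"]) / den)
      }
    }
    out$Ft <- stats::setNames(ft, paste0("F", K))
  }
  out
}
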