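#' Intersection over union of two boxes
#'
#' @param a,b \code{box} objects (half-open pixel coordinates).
#' @return IoU in \code{[0, 1]}.
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  iw <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  ih <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

# IoU of one box against a list of boxes, vectorized.
iou_many <- function(b, boxes) {
  if (length(boxes) == 0L) return(numeric(0))
  m <- boxes_to_matrix(boxes)
  iw <- pmin(b[["x_max"]], m[, "x_max"]) - pmax(b[["x_min"]], m[, "x_min"])
  ih <- pmin(b[["y_max"]], m[, "y_max"]) - pmax(b[["y_min"]], m[, "y_min"])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areas <- (m[, "x_max"] - m[, "x_min"]) * (m[, "y_max"] - m[, "y_min"])
  unname(inter / (box_area(b) + areas - inter))
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in order of decreasing confidence (ties broken by
#' input order); a detection is suppressed iff its IoU with an already-kept
#' detection exceeds \code{iou_threshold} (strict inequality). Kept
#' detections are returned in decreasing-confidence order.
#'
#' @param detections List of detections, each a list with elements
#'   \code{box} (a \code{box}) and \code{conf} (numeric confidence).
#' @param iou_threshold Suppression threshold in \code{(0, 1)}.
#' @return The retained subset of \code{detections}.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  n <- length(detections)
  if (n <= 1L) return(detections)
  confs <- vapply(detections, function(d) d$conf, numeric(1))
  ord <- order(-confs)  # stable: ties keep input order
  kept <- list()
  for (i in ord) {
    sup <- FALSE
    for (k in kept) {
      if (iou(detections[[i]]$box, detections[[k]]$box) > iou_threshold) {
        sup <- TRUE
        break
      }
    }
    if (!sup) kept <- c(kept, i)
  }
  detections[unlist(kept)]
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class \code{"confusion_counts"}.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cc <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cc < 0) || any(cc != round(cc))) {
    abort_input("confusion counts must be non-negative integers")
  }
  structure(as.list(cc), class = "confusion_counts")
}

# Counts of the decision rule score >= tau against binary labels.
counts_at_threshold <- function(scores, labels, tau) {
  pred <- scores >= tau
  confusion_counts(sum(pred & labels == 1), sum(pred & labels == 0),
                   sum(!pred & labels == 1), sum(!pred & labels == 0))
}

#' Classification metrics from confusion counts
#'
#' Any 0/0 ratio is defined as 0 and flagged via the \code{"degenerate"}
#' attribute of the result.
#'
#' @param counts A \code{confusion_counts} object.
#' @return Named list with \code{precision}, \code{recall}, \code{f1},
#'   \code{specificity}, \code{accuracy}.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  flags <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      return(0)
    }
    num / den
  }
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn, "f1")
  specificity <- safe_div(tn, tn + fp, "specificity")
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn, "accuracy")
  out <- list(precision = precision, recall = recall, f1 = f1,
              specificity = specificity, accuracy = accuracy)
  attr(out, "degenerate") <- flags
  out
}

# F1 of the rule score >= tau.
f1_at_threshold <- function(scores, labels, tau) {
  classification_metrics(counts_at_threshold(scores, labels, tau))$f1
}

#' ROC-AUC (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels, need_both = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (all-points interpolation)
#'
#' Area under the precision-recall step curve with the precision envelope
#' made monotone non-increasing before integration. Ties in score are broken
#' by input order.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); at least one positive required.
#' @param n_positives Optional total number of positives for the recall
#'   denominator (used by detection-level AP where unmatched ground truth
#'   counts as missed); defaults to \code{sum(labels == 1)}.
#' @return AP in \code{[0, 1]}.
#' @export
average_precision <- function(scores, labels, n_positives = NULL) {
  check_scores_labels(scores, labels, need_both = FALSE)
  npos <- n_positives %||% sum(labels == 1)
  if (npos < 1) abort_input("average_precision needs at least one positive")
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  # envelope: running max from the right
  env <- rev(cummax(rev(precision)))
  d_recall <- diff(c(0, recall))
  sum(d_recall * env)
}

#' Single-class mean average precision at an IoU threshold
#'
#' Detections are pooled across images and sorted by decreasing confidence.
#' Each detection is greedily matched to the highest-IoU not-yet-matched
#' ground-truth box of its image; it is a true positive iff that IoU is at
#' least \code{iou_threshold}. Unmatched ground truth counts as a miss. With
#' a single foreground class the mean over classes reduces to the AP itself.
#'
#' @param detections_per_image List (one element per image) of detection
#'   lists, each detection a list with \code{box} and \code{conf}.
#' @param gt_boxes_per_image List (same length) of lists of ground-truth
#'   \code{box}es.
#' @param iou_threshold Match threshold in \code{(0, 1)}.
#' @return mAP in \code{[0, 1]}.
#' @export
map_at_iou <- function(detections_per_image, gt_boxes_per_image,
                       iou_threshold = 0.5) {
  stopifnot(length(detections_per_image) == length(gt_boxes_per_image))
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    abort_input("iou_threshold must be in (0, 1)")
  }
  n_gt <- sum(vapply(gt_boxes_per_image, length, integer(1)))
  if (n_gt == 0) abort_input("no ground-truth boxes")
  img <- integer(0); confs <- numeric(0); dets <- list()
  for (i in seq_along(detections_per_image)) {
    for (d in detections_per_image[[i]]) {
      img <- c(img, i); confs <- c(confs, d$conf); dets <- c(dets, list(d))
    }
  }
  if (length(dets) == 0L) return(0)
  ord <- order(-confs)
  matched <- lapply(gt_boxes_per_image, function(g) rep(FALSE, length(g)))
  is_tp <- logical(length(dets))
  for (j in ord) {
    i <- img[j]
    gts <- gt_boxes_per_image[[i]]
    if (length(gts) == 0L) next
    ious <- iou_many(dets[[j]]$box, gts)
    ious[matched[[i]]] <- -1
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      is_tp[j] <- TRUE
      matched[[i]][best] <- TRUE
    }
  }
  average_precision(confs, as.integer(is_tp), n_positives = n_gt)
}

check_scores_labels <- function(scores, labels, need_both = FALSE) {
  if (length(scores) != length(labels)) {
    abort_input("scores and labels must have the same length")
  }
  if (length(scores) == 0L) abort_input("empty input")
  if (!all(labels %in% c(0, 1))) abort_input("labels must be binary 0/1")
  if (need_both && (all(labels == 1) || all(labels == 0))) {
    abort_input("both label classes must be present")
  }
  invisible(TRUE)
}
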