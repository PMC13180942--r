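test_that("iou matches hand-computed overlaps and is symmetric", {
  a <- box(0, 0, 10, 10)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box(20, 20, 30, 30)), 0)
  expect_equal(iou(a, box(5, 0, 15, 10)), 1 / 3)
  withr::with_seed(4, {
    for (i in 1:25) {
      b1 <- random_box(); b2 <- random_box()
      expect_equal(iou(b1, b2), iou(b2, b1), tolerance = 1e-12)
      expect_lte(iou(b1, b2),
                 min(box_area(b1), box_area(b2)) /
                   max(box_area(b1), box_area(b2)) + 1e-12)
    }
  })
})

test_that("greedy NMS equals a brute-force reference on random boxes", {
  brute_nms <- function(dets, thr) {
    confs <- vapply(dets, function(d) d$conf, numeric(1))
    ord <- order(-confs)
    keep <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (k in keep) {
        if (iou(dets[[i]]$box, dets[[k]]$box) > thr) ok <- FALSE
      }
      if (ok) keep <- c(keep, i)
    }
    dets[keep]
  }
  withr::with_seed(17, {
    for (rep in 1:6) {
      dets <- lapply(1:50, function(i)
        list(box = random_box(30, 60), conf = runif(1)))
      expect_identical(nms(dets, 0.4), brute_nms(dets, 0.4))
      expect_identical(nms(dets, 0.7), brute_nms(dets, 0.7))
    }
  })
  # duplicate boxes: only the higher confidence survives
  d2 <- list(list(box = box(0, 0, 5, 5), conf = 0.8),
             list(box = box(0, 0, 5, 5), conf = 0.9))
  kept <- nms(d2, 0.5)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$conf, 0.9)
  expect_length(nms(d2[1], 0.5), 1)
})

test_that("classification metrics follow the standard formulas", {
  m <- classification_metrics(confusion_counts(2, 1, 1, 6))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 6 / 7)

  perfect <- classification_metrics(confusion_counts(5, 0, 0, 5))
  expect_true(all(unlist(perfect) == 1))

  degen <- classification_metrics(confusion_counts(0, 0, 3, 7))
  expect_equal(degen$precision, 0)
  expect_true("precision" %in% attr(degen, "degenerate"))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("roc_auc agrees with an independent reference implementation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 300
      labels <- rbinom(n, 1, 0.4)
      scores <- round(runif(n) + 0.3 * labels, 2)  # include ties
      ref <- suppressMessages(
        as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
      expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-9)
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both label classes")
})

test_that("average precision uses all-points interpolation", {
  expect_equal(average_precision(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  # hand-enumerated 3-point PR curve
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # rank-sum oracle: AP = mean over positives of precision at their rank,
  # with the envelope applied
  ap_oracle <- function(scores, labels) {
    ord <- order(-scores)
    y <- labels[ord]
    prec <- cumsum(y) / seq_along(y)
    for (i in rev(seq_along(prec))[-1]) prec[i] <- max(prec[i], prec[i + 1])
    mean(prec[y == 1])
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- 40
      labels <- rbinom(n, 1, 0.5)
      if (sum(labels) == 0) labels[1] <- 1
      scores <- runif(n)
      expect_equal(average_precision(scores, labels),
                   ap_oracle(scores, labels), tolerance = 1e-9)
      # invariance under strictly monotone transforms
      expect_equal(average_precision(plogis(3 * scores - 1), labels),
                   average_precision(scores, labels), tolerance = 1e-12)
    }
  })
  expect_error(average_precision(c(0.4, 0.2), c(0, 0)), "positive")
})

test_that("map_at_iou matches an exhaustive-matching oracle on toy cases", {
  gt <- list(list(box(0, 0, 10, 10), box(20, 20, 30, 30)))
  # detections identical to GT -> perfect
  dets <- list(list(list(box = box(0, 0, 10, 10), conf = 0.3),
                    list(box = box(20, 20, 30, 30), conf = 0.9)))
  expect_equal(map_at_iou(dets, gt, 0.5), 1)
  # no detections -> 0
  expect_equal(map_at_iou(list(list()), gt, 0.5), 0)

  # duplicate detection of one GT counts as FP: ranks (TP, TP, FP)
  dets2 <- list(list(list(box = box(0, 0, 10, 10), conf = 0.9),
                     list(box = box(1, 0, 11, 10), conf = 0.7),
                     list(box = box(20, 20, 30, 30), conf = 0.8)))
  # by hand: conf order 0.9 (TP), 0.8 (TP), 0.7 (duplicate -> FP)
  # PR points: (0.5, 1), (1, 1), (1, 2/3) -> AP = 1
  expect_equal(map_at_iou(dets2, gt, 0.5), 1)
  # same but duplicate outranks the second GT's detection
  dets3 <- list(list(list(box = box(0, 0, 10, 10), conf = 0.9),
                     list(box = box(1, 0, 11, 10), conf = 0.8),
                     list(box = box(20, 20, 30, 30), conf = 0.7)))
  # ranks: TP, FP (dup), TP -> envelope precisions 1, 2/3 at the recalls
  expect_equal(map_at_iou(dets3, gt, 0.5), 0.5 * 1 + 0.5 * (2 / 3))
  expect_error(map_at_iou(list(list()), list(list()), 0.5), "ground-truth")
})
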