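# Confidence fusion, operating-point selection, calibration diagnostics,
# and the statistical machinery used on evaluation reports.

#' Convex confidence fusion
#'
#' Fuses the adjudicator probability with the detector confidence:
#' \code{S = alpha * y_hat + (1 - alpha) * s}. At \code{alpha = 0} the
#' decision falls back to the detector; at \code{alpha = 1} it is the
#' adjudicator alone. Vectorized over \code{y_hat} and \code{s}.
#'
#' @param y_hat Adjudicator probabilities in \code{[0, 1]}.
#' @param s Detector confidences in \code{[0, 1]}.
#' @param alpha Convex weight in \code{[0, 1]} (default 0.6).
#' @return Fused scores in \code{[0, 1]}.
#' @export
fuse_scores <- function(y_hat, s, alpha = 0.6) {
  if (length(alpha) != 1L || !is_prob(alpha)) {
    abort_input("alpha must be a single value in [0, 1]")
  }
  if (!is_prob(y_hat) || !is_prob(s)) {
    abort_input("y_hat and s must lie in [0, 1]")
  }
  alpha * y_hat + (1 - alpha) * s
}

#' Select the decision threshold maximizing F1
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores, plus 0 and 1. The decision rule is \code{S >= tau}
#' positive. Ties in F1 are broken toward the smallest threshold (favoring
#' recall).
#'
#' @param scores Numeric scores in \code{[0, 1]}.
#' @param labels Binary labels. At least one positive is required (with no
#'   positives F1 is identically zero and no threshold is meaningful); an
#'   all-positive input is allowed and yields \code{tau = 0}.
#' @return List with \code{tau} and \code{f1}.
#' @export
select_threshold <- function(scores, labels) {
  check_scores_labels(scores, labels)
  if (all(labels == 0)) abort_input("threshold selection needs a positive")
  ss <- sort(unique(scores))
  cands <- c(0, if (length(ss) > 1L) (ss[-1] + ss[-length(ss)]) / 2, 1)
  best_tau <- cands[1]
  best_f1 <- -Inf
  for (tau in cands) {
    f1 <- f1_at_threshold(scores, labels, tau)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1
      best_tau <- tau
    }
  }
  list(tau = best_tau, f1 = best_f1)
}

#' Select the fusion weight and threshold on validation data
#'
#' Scans \code{alpha} over a uniform grid; for each candidate the F1-optimal
#' threshold is selected via \code{\link{select_threshold}}. Among the
#' maximal-F1 candidates, ties prefer \code{alpha = 0.6} (the reference
#' default) and then the smallest \code{alpha}.
#'
#' @param y_hat,s,labels Aligned validation vectors.
#' @param grid_step Grid spacing in \code{(0, 0.5]} (default 0.05, giving
#'   21 candidates).
#' @return List with \code{alpha}, \code{tau}, \code{f1}.
#' @export
select_alpha <- function(y_hat, s, labels, grid_step = 0.05) {
  if (grid_step <= 0 || grid_step > 0.5) {
    abort_input("grid_step must be in (0, 0.5]")
  }
  stopifnot(length(y_hat) == length(s), length(s) == length(labels))
  grid <- unique(c(seq(0, 1, by = grid_step), 1))
  res <- lapply(grid, function(a) {
    sel <- select_threshold(fuse_scores(y_hat, s, a), labels)
    list(alpha = a, tau = sel$tau, f1 = sel$f1)
  })
  f1s <- vapply(res, function(r) r$f1, numeric(1))
  top <- which(f1s >= max(f1s) - 1e-12)
  alphas <- vapply(res[top], function(r) r$alpha, numeric(1))
  pick <- if (any(abs(alphas - 0.6) < 1e-12)) {
    top[which(abs(alphas - 0.6) < 1e-12)[1]]
  } else {
    top[which.min(alphas)]
  }
  res[[pick]]
}

#' Reliability bins
#'
#' Partition of \code{[0, 1]} into \code{n_bins} equal-width intervals
#' (last bin right-closed): per-bin count, mean confidence and empirical
#' positive rate — the data behind a reliability diagram.
#'
#' @param scores Scores in \code{[0, 1]}.
#' @param labels Binary labels.
#' @param n_bins Number of bins (default 10).
#' @return Data frame with columns \code{bin_lo, bin_hi, count,
#'   mean_confidence, positive_rate} (NA rates for empty bins).
#' @export
reliability_bins <- function(scores, labels, n_bins = 10L) {
  check_scores_labels(scores, labels)
  if (!is_prob(scores)) abort_input("scores must lie in [0, 1]")
  if (n_bins < 1) abort_input("n_bins must be at least 1")
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1) / n_bins,
                    bin_hi = seq_len(n_bins) / n_bins,
                    count = 0L, mean_confidence = NA_real_,
                    positive_rate = NA_real_)
  for (b in seq_len(n_bins)) {
    in_b <- bin == b
    out$count[b] <- sum(in_b)
    if (any(in_b)) {
      out$mean_confidence[b] <- mean(scores[in_b])
      out$positive_rate[b] <- mean(labels[in_b])
    }
  }
  out
}

#' Expected calibration error
#'
#' Count-weighted mean absolute gap between per-bin mean confidence and
#' empirical positive rate over non-empty equal-width bins.
#'
#' @inheritParams reliability_bins
#' @return ECE in \code{[0, 1]}.
#' @export
ece <- function(scores, labels, n_bins = 10L) {
  bins <- reliability_bins(scores, labels, n_bins)
  keep <- bins$count > 0
  sum(bins$count[keep] / length(scores) *
        abs(bins$mean_confidence[keep] - bins$positive_rate[keep]))
}

#' Brier score
#'
#' Mean squared error between predicted probability and binary outcome.
#'
#' @param scores Scores in \code{[0, 1]}.
#' @param labels Binary labels.
#' @return Brier score in \code{[0, 1]}.
#' @export
brier <- function(scores, labels) {
  check_scores_labels(scores, labels)
  if (!is_prob(scores)) abort_input("scores must lie in [0, 1]")
  mean((scores - labels)^2)
}

#' Calibration report
#'
#' @inheritParams reliability_bins
#' @return A \code{calibration_report}: list with \code{ece}, \code{brier}
#'   and the \code{bins} data frame.
#' @export
calibration_report <- function(scores, labels, n_bins = 10L) {
  structure(list(ece = ece(scores, labels, n_bins),
                 brier = brier(scores, labels),
                 bins = reliability_bins(scores, labels, n_bins)),
            class = "calibration_report")
}

#' Bootstrap percentile confidence interval for a metric
#'
#' Seeded resampling with replacement at full sample size. Resamples on
#' which the metric is undefined (e.g. a single-label resample for F1 or
#' AUC) are redrawn; the number of redraws is reported.
#'
#' @param metric_fn \code{function(scores, labels)} returning a scalar.
#' @param scores,labels The evaluation sample.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return List with \code{lower}, \code{upper}, \code{estimate},
#'   \code{level}, \code{n_boot}, \code{redraws} and the replicate vector
#'   \code{replicates}.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  if (n_boot < 100) abort_input("n_boot must be at least 100")
  n <- length(scores)
  stopifnot(length(labels) == n, n > 0)
  redraws <- 0L
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric_fn(scores[idx], labels[idx]),
                        error = function(e) NA_real_)
        if (!is.na(val)) return(val)
        redraws <<- redraws + 1L
        if (redraws > 100L * n_boot) {
          stop("metric undefined on almost all resamples", call. = FALSE)
        }
      }
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2],
       estimate = metric_fn(scores, labels),
       level = level, n_boot = n_boot, redraws = redraws,
       replicates = reps)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired samples; zero differences are
#' dropped (an error if all differences are zero). The exact distribution
#' is used for up to 25 non-zero untied differences, otherwise the normal
#' approximation with tie correction.
#'
#' @param metric_a,metric_b Equal-length paired samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_paired <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_a - metric_b
  d <- d[d != 0]
  if (length(d) == 0L) {
    abort_input("all paired differences are zero: test undefined")
  }
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                       exact = exact, correct = FALSE))
  unname(res$p.value)
}
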