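test_that("convex fusion evaluates its closed forms and limits", {
  expect_equal(fuse_scores(1.0, 0.5, 0.6), 0.8)
  expect_equal(fuse_scores(0.3, 0.9, 0), 0.9)
  expect_equal(fuse_scores(0.3, 0.9, 1), 0.3)
  expect_error(fuse_scores(0.5, 0.5, 1.2), "alpha")
  expect_error(fuse_scores(1.5, 0.5, 0.5), "\\[0, 1\\]")
  # monotone non-decreasing in both arguments, bounded in [0, 1]
  withr::with_seed(2, {
    y <- runif(50); s <- runif(50)
    S <- fuse_scores(y, s, 0.6)
    expect_true(all(S >= 0 & S <= 1))
    expect_true(all(fuse_scores(pmin(y + 0.1, 1), s, 0.6) >= S))
    expect_true(all(fuse_scores(y, pmin(s + 0.1, 1), 0.6) >= S))
  })
})

test_that("threshold selection maximizes F1 with recall-favoring ties", {
  sel <- select_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(sel$tau, 0.5)
  expect_equal(sel$f1, 1)
  # all-positive labels: accept everything at tau = 0
  sel1 <- select_threshold(c(0.2, 0.7), c(1, 1))
  expect_equal(sel1$tau, 0)
  expect_equal(sel1$f1, 1)
  expect_error(select_threshold(c(0.2, 0.7), c(0, 0)), "positive")

  # dense-grid oracle
  grid_best <- function(scores, labels, step = 1e-4) {
    taus <- seq(0, 1, by = step)
    max(vapply(taus, function(t) f1_at_threshold(scores, labels, t),
               numeric(1)))
  }
  withr::with_seed(7, {
    for (rep in 1:60) {
      n <- 30
      labels <- rbinom(n, 1, 0.5)
      if (all(labels == 0)) labels[1] <- 1
      scores <- round(runif(n), 3)
      sel <- select_threshold(scores, labels)
      expect_equal(sel$f1, grid_best(scores, labels), tolerance = 1e-12)
      expect_equal(f1_at_threshold(scores, labels, sel$tau), sel$f1,
                   tolerance = 1e-12)
    }
  })
})

test_that("alpha selection scans the grid with the documented tie rules", {
  withr::with_seed(9, {
    n <- 80
    labels <- rbinom(n, 1, 0.5)
    labels[1] <- 1; labels[2] <- 0
    # adjudicator perfectly predictive, detector pure noise
    y_hat <- labels * 0.9 + 0.05
    s <- runif(n)
    sel <- select_alpha(y_hat, s, labels)
    expect_equal(sel$f1, 1)
    # at the selected (alpha, tau) the separation really is perfect
    expect_equal(f1_at_threshold(fuse_scores(y_hat, s, sel$alpha), labels,
                                 sel$tau), 1)
    # identical inputs: every alpha ties, preference returns 0.6
    sel_tie <- select_alpha(s, s, labels)
    expect_equal(sel_tie$alpha, 0.6)
  })
  expect_error(select_alpha(0.5, 0.5, 1, grid_step = 0.6), "grid_step")
})

test_that("reliability bins partition the sample and drive ECE", {
  expect_equal(ece(rep(1, 10), rep(1, 10)), 0)
  expect_equal(ece(rep(1, 10), rep(0, 10)), 1)
  # single occupied bin, confidence equal to positive rate
  expect_equal(ece(rep(0.7, 10), c(rep(1, 7), rep(0, 3))), 0,
               tolerance = 1e-12)
  withr::with_seed(14, {
    scores <- runif(200)
    labels <- rbinom(200, 1, scores)
    bins <- reliability_bins(scores, labels, 10)
    expect_equal(sum(bins$count), 200)
    expect_equal(nrow(bins), 10)
    # hand-recomputed ECE from the bins
    keep <- bins$count > 0
    want <- sum(bins$count[keep] / 200 *
                  abs(bins$mean_confidence[keep] - bins$positive_rate[keep]))
    expect_equal(ece(scores, labels, 10), want, tolerance = 1e-12)
    expect_gte(ece(scores, labels), 0)
    expect_lte(ece(scores, labels), 1)
  })
  expect_error(ece(numeric(0), numeric(0)), "empty")
})

test_that("the Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier(c(1, 0), c(0, 1)), 1)
  rep <- calibration_report(c(0.2, 0.8), c(0, 1))
  expect_named(rep, c("ece", "brier", "bins"))
})

test_that("bootstrap intervals are seeded, degenerate-safe and calibrated", {
  # identical records -> zero-width interval
  ci0 <- bootstrap_ci(function(s, l) mean(s), rep(0.4, 30), rep(1, 30),
                      n_boot = 100, seed = 1)
  expect_equal(ci0$lower, ci0$upper)
  # same seed -> identical interval; different seed -> generally not
  scores <- withr::with_seed(5, runif(40))
  labels <- withr::with_seed(6, rbinom(40, 1, 0.5))
  ci1 <- bootstrap_ci(brier, scores, labels, n_boot = 150, seed = 9)
  ci2 <- bootstrap_ci(brier, scores, labels, n_boot = 150, seed = 9)
  expect_identical(ci1$replicates, ci2$replicates)
  # undefined resamples (single-label draws for AUC) are redrawn
  ci3 <- bootstrap_ci(roc_auc, c(0.9, 0.4, 0.8, 0.1),
                      c(1, 0, 1, 0), n_boot = 100, seed = 3)
  expect_gte(ci3$redraws, 1)
  expect_true(ci3$lower >= 0 && ci3$upper <= 1)
  expect_error(bootstrap_ci(brier, 1:3 / 4, c(1, 0, 1), n_boot = 10), "100")
})

test_that("bootstrap coverage approximates the nominal level", {
  # known-parameter Bernoulli simulation: scores are the true positive
  # probabilities, F1 measured at threshold 0.5
  n <- 500
  true_p <- 0.7
  metric <- function(s, l) mean(l)  # positive rate, true value known
  withr::with_seed(33, {
    hits <- 0L
    reps <- 120L
    for (i in seq_len(reps)) {
      l <- rbinom(n, 1, true_p)
      ci <- bootstrap_ci(metric, rep(0.5, n), l, n_boot = 200,
                         level = 0.95, seed = i)
      if (ci$lower <= true_p && true_p <= ci$upper) hits <- hits + 1L
    }
    expect_gte(hits / reps, 0.90)
    expect_lte(hits / reps, 0.99)
  })
})

test_that("paired Wilcoxon p-values match the exact distribution", {
  # n = 6, all differences positive: two-sided exact p = 2/2^6
  expect_equal(wilcoxon_paired(1:6, rep(0, 6)), 2 / 64)
  # constant positive shift is detected
  withr::with_seed(21, {
    b <- rnorm(20)
    expect_lt(wilcoxon_paired(b + 1, b), 0.05)
    # symmetry of the two-sided test
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(wilcoxon_paired(x, y), wilcoxon_paired(y, x))
  })
  expect_error(wilcoxon_paired(1:4, 1:4), "zero")
})
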