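# Hand-built model with constant backbone output: zero conv weights and a
# known bias in the last stage give a constant feature map, so the head
# can be evaluated with pencil and paper.
constant_feature_model <- function(f_const = 2, channels = c(2L, 3L)) {
  m <- adjudicator_model(patch_size = 8L, channels = channels,
                         hidden = 2L, seed = 1L)
  for (l in seq_along(channels)) {
    m$params[[paste0("Wc", l)]][] <- 0
    m$params[[paste0("bc", l)]][] <- 0
  }
  nl <- length(channels)
  m$params[[paste0("bc", nl)]][] <- f_const
  m
}

test_that("embeddings are L2-normalized with degenerate inputs rejected", {
  m <- separable_fit()$model
  withr::with_seed(3, {
    for (i in 1:10) {
      psi <- embed(m, matrix(runif(64), 8, 8))
      expect_equal(sqrt(sum(psi^2)), 1, tolerance = 1e-6)
    }
  })
  # already-unit feature vector: constant maps give f = (c, c, c)
  mc <- constant_feature_model(f_const = 1, channels = c(2L, 1L))
  expect_equal(embed(mc, matrix(0.5, 8, 8)), 1)
  # zero feature vector errors
  mz <- constant_feature_model(f_const = 0)
  expect_error(embed(mz, matrix(0.5, 8, 8)), "degenerate embedding")
})

test_that("adjudicate matches a pencil-and-paper forward pass", {
  # constant feature maps: f = (2, 2, 2), psi = 1/sqrt(3) * (1, 1, 1)
  m <- constant_feature_model(f_const = 2, channels = c(2L, 3L))
  # zero head -> sigma(0) = 0.5
  m0 <- m
  m0$params$W1[] <- 0; m0$params$b1[] <- 0
  m0$params$W2[] <- 0; m0$params$b2 <- 0
  expect_equal(adjudicate(m0, matrix(0.1, 8, 8), 0.7), 0.5)
  # saturating bias -> probability ~ 1
  m1 <- m0
  m1$params$b2 <- 30
  expect_gt(adjudicate(m1, matrix(0.1, 8, 8), 0.7), 1 - 1e-9)

  # 2-unit head with hand-picked weights
  mh <- m
  mh$params$W1 <- matrix(c(1, -1, 0.5, 0.25, -0.5, 1, 0.2, -0.2),
                         nrow = 2)  # 2 x 4 (d = 3 plus confidence)
  mh$params$b1 <- c(0.1, -0.2)
  mh$params$W2 <- matrix(c(2, -1), 1)
  mh$params$b2 <- 0.3
  s <- 0.6
  z <- c(rep(1 / sqrt(3), 3), s)
  h <- pmax(mh$params$W1 %*% z + mh$params$b1, 0)
  want <- 1 / (1 + exp(-(mh$params$W2 %*% h + 0.3)))
  expect_equal(adjudicate(mh, matrix(0.1, 8, 8), s), as.numeric(want),
               tolerance = 1e-12)
  expect_error(adjudicate(mh, matrix(0.1, 8, 8), 1.4), "\\[0, 1\\]")
})

test_that("focal loss evaluates its closed forms and limits", {
  expect_equal(focal_loss(0.5, 1, gamma = 0), log(2), tolerance = 1e-12)
  expect_equal(focal_loss(0.5, 1, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
  # gamma = 0 reduces to mean binary cross-entropy
  withr::with_seed(5, {
    p <- runif(200, 0.01, 0.99)
    y <- rbinom(200, 1, 0.5)
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(focal_loss(p, y, 0), bce, tolerance = 1e-10)
  })
  # modulating factor shrinks easy-example loss
  expect_lt(focal_loss(0.99, 1, 2), focal_loss(0.99, 1, 0))
  # monotone in y_hat on a grid
  grid <- seq(0.01, 0.99, by = 0.01)
  l1 <- vapply(grid, function(p) focal_loss(p, 1, 2), numeric(1))
  l0 <- vapply(grid, function(p) focal_loss(p, 0, 2), numeric(1))
  expect_true(all(diff(l1) < 0))
  expect_true(all(diff(l0) > 0))
  # extreme probabilities are clamped, not infinite
  expect_true(is.finite(focal_loss(c(0, 1), c(1, 0), 2)))
  expect_error(focal_loss(0.5, 1, gamma = -1), "non-negative")
})

test_that("focal gradient matches a finite-difference derivative", {
  eps <- 1e-6
  for (y in c(0, 1)) {
    for (p in c(0.2, 0.5, 0.9)) {
      z <- qlogis(p)
      num <- (focal_loss(plogis(z + eps), y, 2) -
                focal_loss(plogis(z - eps), y, 2)) / (2 * eps)
      expect_equal(focal_grad_logit(p, y, 2), num, tolerance = 1e-6)
    }
  }
})

test_that("training reaches perfect validation F1 on a separable fixture", {
  fit <- separable_fit()
  expect_equal(max(fit$history$val_f1), 1)
  # best-epoch restoration: returned model reproduces the best F1
  yv <- vapply(fit$val, function(r) r$y, numeric(1))
  f1 <- f1_at_threshold(predict_records(fit$model, fit$val), yv, 0.5)
  expect_equal(f1, max(fit$history$val_f1))
})

test_that("training bookkeeping: no-op mining keeps pools constant", {
  fit <- separable_fit()
  expect_true(all(fit$history$n_Nh == 0))
  expect_true(all(diff(fit$history$n_P) == 0))
  expect_lte(nrow(fit$history), 8)
  sel <- attr(fit$history, "selected_epoch")
  expect_equal(fit$history$val_f1[sel], max(fit$history$val_f1))
})

test_that("training is reproducible and guards its preconditions", {
  recs <- make_separable_records(10, 10, seed = 2)
  pids <- vapply(recs, function(r) r$patient_id, character(1))
  tr <- recs[pids %in% sprintf("P%02d", 1:4)]
  va <- recs[pids %in% sprintf("P%02d", 5:6)]
  cfg <- train_config(max_epochs = 2L, learning_rate = 3e-3, seed = 4L)
  model <- adjudicator_model(8L, c(4L), hidden = 8L, seed = 9L)
  f1 <- train_adjudicator(model, tr, va, cfg)
  f2 <- train_adjudicator(model, tr, va, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)

  expect_error(train_adjudicator(model, list(), va, cfg), "empty training")
  expect_error(train_adjudicator(model, recs, va, cfg), "leakage")
  expect_error(train_config(gamma = -0.1), "non-negative")
  expect_error(train_config(learning_rate = 0), "positive")
})

test_that("mining hook output grows the training pool during training", {
  recs <- make_separable_records(16, 16, seed = 6)
  pids <- vapply(recs, function(r) r$patient_id, character(1))
  tr <- recs[pids %in% sprintf("P%02d", 1:4)]
  va <- recs[pids %in% sprintf("P%02d", 5:6)]
  extra <- make_separable_records(0, 4, seed = 8)
  extra <- lapply(extra, function(r) {
    r$patient_id <- "P01"
    r$provenance <- "mined_neg"
    r$scene_index <- r$scene_index + 1000L
    r
  })
  hook <- function(model, epoch) if (epoch == 1L) extra else list()
  model <- adjudicator_model(8L, c(4L), hidden = 8L, seed = 2L)
  fit <- train_adjudicator(model, tr, va,
                           train_config(max_epochs = 3L,
                                        learning_rate = 1e-3, seed = 3L),
                           mining_hook = hook)
  expect_equal(fit$history$n_Nh, c(4, 4, 4))
  expect_true(all(diff(fit$history$n_Nh) >= 0))
})
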