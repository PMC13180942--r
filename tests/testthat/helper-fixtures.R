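# Shared fixtures: lightweight ROI record stubs (no images) for split /
# mining / bookkeeping tests, and a tiny separable patch set for training
# tests.

# n_per_patient ROI stubs for each of n_patients patients.
make_record_stubs <- function(n_patients, n_per_patient, seed = 1L,
                              pos_rate = 0.6) {
  withr::with_seed(seed, {
    recs <- list()
    k <- 0L
    for (p in seq_len(n_patients)) {
      for (i in seq_len(n_per_patient)) {
        k <- k + 1L
        y <- as.integer(stats::runif(1) < pos_rate)
        recs[[k]] <- list(
          patch = NULL,
          box = box(k %% 50, (k * 3) %% 50, k %% 50 + 10, (k * 3) %% 50 + 10),
          s = stats::runif(1), y = y,
          patient_id = sprintf("P%04d", p),
          provenance = if (y == 1) "orig_pos" else "orig_neg",
          scene_index = k)
      }
    }
    recs
  })
}

# Tiny patches where the class signal is a bright square in the center:
# linearly separable in pixel space, so a few epochs suffice.
make_separable_records <- function(n_pos, n_neg, patch_size = 8L,
                                   n_patients = 6L, seed = 1L) {
  withr::with_seed(seed, {
    recs <- list()
    for (k in seq_len(n_pos + n_neg)) {
      y <- as.integer(k <= n_pos)
      base <- matrix(stats::runif(patch_size^2, 0, 0.2),
                     patch_size, patch_size)
      if (y == 1) {
        c0 <- patch_size %/% 2
        base[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)] <-
          base[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)] + 0.7
      }
      recs[[k]] <- list(
        patch = pmin(base, 1),
        box = box(0, 0, patch_size, patch_size),
        s = if (y == 1) stats::runif(1, 0.6, 0.95) else stats::runif(1, 0.3, 0.7),
        y = y,
        patient_id = sprintf("P%02d", 1L + (k %% n_patients)),
        provenance = if (y == 1) "orig_pos" else "orig_neg",
        scene_index = k)
    }
    recs
  })
}

# A small trained model on the separable fixture, cached per test run.
separable_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- make_separable_records(40, 40, seed = 3)
      pids <- vapply(recs, function(r) r$patient_id, character(1))
      tr <- recs[pids %in% sprintf("P%02d", 1:4)]
      va <- recs[pids %in% sprintf("P%02d", 5:6)]
      model <- adjudicator_model(patch_size = 8L, channels = c(6L, 12L),
                                 hidden = 16L, seed = 5L)
      cache <<- c(train_adjudicator(model, tr, va,
                                    train_config(max_epochs = 8L,
                                                 learning_rate = 3e-3,
                                                 patience = 8L, seed = 7L)),
                  list(train = tr, val = va))
    }
    cache
  }
})

random_box <- function(max_side = 40, lim = 100) {
  x0 <- stats::runif(1, 0, lim - 2)
  y0 <- stats::runif(1, 0, lim - 2)
  box(x0, y0, x0 + stats::runif(1, 1, max_side),
      y0 + stats::runif(1, 1, max_side))
}
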