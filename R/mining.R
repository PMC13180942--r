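# Iterative hard-negative mining: select convincing false positives
# (fused score above a mining threshold but labeled negative) and fold
# them into the training pool.

#' Mining configuration
#'
#' @param tau_mine Mining threshold in \code{(0, 1)}; in the pipeline it is
#'   selected on the validation split (see \code{\link{select_tau_mine}}).
#' @param cadence_epochs Mine every K epochs (default 1: after each epoch).
#' @param allow_duplicates If \code{TRUE}, a record may appear both as an
#'   original negative and as a mined negative; off by default.
#' @param max_pool_growth Optional cap on the total number of mined
#'   negatives.
#' @return A \code{mining_config} list.
#' @export
mining_config <- function(tau_mine = 0.5, cadence_epochs = 1L,
                          allow_duplicates = FALSE,
                          max_pool_growth = Inf) {
  if (tau_mine <= 0 || tau_mine >= 1) abort_input("tau_mine must be in (0, 1)")
  structure(list(tau_mine = tau_mine,
                 cadence_epochs = as.integer(cadence_epochs),
                 allow_duplicates = isTRUE(allow_duplicates),
                 max_pool_growth = max_pool_growth),
            class = "mining_config")
}

# De-duplication key: source image id plus box coordinates rounded to
# integer pixels.
record_key <- function(r) {
  paste(r$scene_index %||% r$patient_id,
        paste(round(unclass(r$box)), collapse = ","), sep = "|")
}

#' Select hard negatives from scored records
#'
#' Returns exactly the records with fused score strictly above
#' \code{tau_mine} and label 0, with provenance set to \code{mined_neg} and
#' de-duplicated by (image, integer-rounded box) key.
#'
#' @param records List of ROI records.
#' @param fused_scores Numeric vector aligned with \code{records}.
#' @param tau_mine Mining threshold.
#' @return List of mined records.
#' @export
mine_hard_negatives <- function(records, fused_scores, tau_mine) {
  if (length(records) != length(fused_scores)) {
    abort_input("records and fused_scores must be aligned")
  }
  y <- vapply(records, function(r) r$y, numeric(1))
  sel <- which(fused_scores > tau_mine & y == 0)
  mined <- lapply(records[sel], function(r) {
    r$provenance <- "mined_neg"
    r
  })
  if (length(mined) > 1L) {
    mined <- mined[!duplicated(vapply(mined, record_key, character(1)))]
  }
  mined
}

#' Create or update a mining pool
#'
#' A mining pool tracks the original positives P, original negatives N0,
#' and the accumulated mined hard negatives N_h; the training multiset is
#' their union D' with \code{|D'| = |P| + |N0| + |N_h|}.
#'
#' @param positives,negatives Lists of ROI records seeding P and N0.
#' @param config A \code{\link{mining_config}}.
#' @return A \code{mining_pool} object.
#' @export
mining_pool <- function(positives, negatives, config = mining_config()) {
  if (any(vapply(positives, function(r) r$y, numeric(1)) != 1)) {
    abort_input("all records in P must have y = 1")
  }
  if (any(vapply(negatives, function(r) r$y, numeric(1)) != 0)) {
    abort_input("all records in N0 must have y = 0")
  }
  structure(list(P = positives, N0 = negatives, N_h = list(),
                 config = config), class = "mining_pool")
}

#' @rdname mining_pool
#' @param pool A \code{mining_pool}.
#' @param new_negatives Records to merge into N_h (all must have y = 0);
#'   records already present in the pool (by de-duplication key, unless
#'   duplicates are enabled) are ignored, so merging is idempotent.
#' @export
merge_pool <- function(pool, new_negatives) {
  stopifnot(inherits(pool, "mining_pool"))
  if (length(new_negatives) == 0L) return(pool)
  if (any(vapply(new_negatives, function(r) r$y, numeric(1)) != 0)) {
    abort_input("mined records must have y = 0")
  }
  if (!pool$config$allow_duplicates) {
    have <- vapply(c(pool$N0, pool$N_h), record_key, character(1))
    keys <- vapply(new_negatives, record_key, character(1))
    new_negatives <- new_negatives[!(keys %in% have)]
    if (length(new_negatives) > 1L) {
      new_negatives <- new_negatives[
        !duplicated(vapply(new_negatives, record_key, character(1)))]
    }
  } else {
    have_h <- vapply(pool$N_h, record_key, character(1))
    keys <- vapply(new_negatives, record_key, character(1))
    new_negatives <- new_negatives[!(keys %in% have_h)]
  }
  room <- pool$config$max_pool_growth - length(pool$N_h)
  if (is.finite(room)) {
    new_negatives <- utils::head(new_negatives, max(room, 0))
  }
  pool$N_h <- c(pool$N_h, lapply(new_negatives, function(r) {
    r$provenance <- "mined_neg"
    r
  }))
  pool
}

#' @rdname mining_pool
#' @return \code{pool_records} returns the training multiset D' = P, N0,
#'   N_h concatenated; \code{pool_counts} its bookkeeping sizes.
#' @export
pool_records <- function(pool) c(pool$P, pool$N0, pool$N_h)

#' @rdname mining_pool
#' @export
pool_counts <- function(pool) {
  c(P = length(pool$P), N0 = length(pool$N0), Nh = length(pool$N_h),
    D_prime = length(pool$P) + length(pool$N0) + length(pool$N_h))
}

#' Select the mining threshold on a validation set
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' fused scores) and returns the smallest one whose mined set — items with
#' fused score strictly above the threshold — is contaminated by true
#' positives at a rate of at most \code{1 - precision_floor}; i.e. the
#' fraction of truly-negative items among those exceeding the threshold is
#' at least \code{precision_floor}. If no candidate qualifies the median
#' fused score is returned with a warning.
#'
#' @param val_records Validation ROI records (both labels present).
#' @param val_fused_scores Aligned fused scores.
#' @param precision_floor Required fraction of true negatives among mined
#'   items, in \code{[0, 1]}.
#' @return Threshold in \code{(0, 1)}.
#' @export
select_tau_mine <- function(val_records, val_fused_scores,
                            precision_floor = 0.8) {
  y <- vapply(val_records, function(r) r$y, numeric(1))
  check_scores_labels(val_fused_scores, y, need_both = TRUE)
  ss <- sort(unique(val_fused_scores))
  cands <- if (length(ss) > 1L) (ss[-1] + ss[-length(ss)]) / 2 else numeric(0)
  for (tau in cands) {
    over <- val_fused_scores > tau
    # empty mined set is vacuously uncontaminated
    if (!any(over) || mean(y[over] == 0) >= precision_floor) return(tau)
  }
  warning("no mining threshold met the precision floor; using median score")
  stats::median(val_fused_scores)
}
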