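# End-to-end orchestration: simulate -> detect -> label -> train with
# mining -> fuse / calibrate -> evaluate -> explain, plus the ablation
# ladder. One global seed deterministically derives every module seed.

#' Experiment configuration
#'
#' Desk-scale defaults (256 x 256 scenes, 64 x 64 patches, compact
#' backbone, 10 epochs) run the full pipeline in minutes on one CPU; the
#' fidelity profile switches to 224 x 224 patches, a deeper backbone and
#' the reference 50-epoch recipe.
#'
#' @param seed Global run seed; all stage seeds are derived from it.
#' @param n_patients,scenes_per_patient Cohort size.
#' @param scene A \code{\link{scene_config}} (its seed is overridden by a
#'   derived seed).
#' @param detector A \code{\link{detector_config}} (seed likewise derived).
#' @param ratios Train/validation/test split fractions.
#' @param patch_size,context_pad ROI extraction parameters.
#' @param channels,hidden Backbone and head sizes.
#' @param train A \code{\link{train_config}}.
#' @param mining A \code{\link{mining_config}}.
#' @param neg_keep Fraction of training-split negatives placed in the
#'   initial pool N0; the remainder forms the reservoir that hard-negative
#'   mining can draw from. Ignored when mining is off (the model then
#'   trains on P and N0 only).
#' @param precision_floor Validation precision floor for
#'   \code{\link{select_tau_mine}}.
#' @param alpha_grid_step Grid step for \code{\link{select_alpha}}.
#' @param use_adjudicator,use_mining,use_fusion Ablation flags.
#' @param augment_train \code{NULL} or an \code{\link{aug_config}}.
#' @param n_boot Bootstrap replicates for test-metric confidence intervals.
#' @param target_recall Matched-recall operating point used in the
#'   confounder false-positive analysis.
#' @param out_dir Optional output directory; when set, manifests, training
#'   history and the evaluation report are persisted there.
#' @param profile \code{"desk"} or \code{"fidelity"}.
#' @return An \code{experiment_config} list.
#' @export
experiment_config <- function(seed = 1L,
                              n_patients = 100L, scenes_per_patient = 1L,
                              scene = scene_config(),
                              detector = detector_config(),
                              ratios = c(0.8, 0.1, 0.1),
                              patch_size = 64L, context_pad = 0.5,
                              channels = c(8L, 16L, 32L, 64L), hidden = 64L,
                              train = train_config(max_epochs = 18L,
                                                   learning_rate = 3e-3,
                                                   patience = 12L),
                              mining = mining_config(),
                              neg_keep = 0.5, precision_floor = 0.8,
                              alpha_grid_step = 0.05,
                              use_adjudicator = TRUE, use_mining = TRUE,
                              use_fusion = TRUE,
                              augment_train = aug_config(),
                              n_boot = 200L, target_recall = 0.9,
                              out_dir = NULL, profile = c("desk", "fidelity")) {
  profile <- match.arg(profile)
  if (profile == "fidelity") {
    patch_size <- 224L
    channels <- c(16L, 24L, 40L, 80L)
    train <- train_config(max_epochs = 50L, learning_rate = 1e-4,
                          patience = 10L)
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 scenes_per_patient = as.integer(scenes_per_patient),
                 scene = scene, detector = detector, ratios = ratios,
                 patch_size = as.integer(patch_size),
                 context_pad = context_pad, channels = channels,
                 hidden = hidden, train = train, mining = mining,
                 neg_keep = neg_keep, precision_floor = precision_floor,
                 alpha_grid_step = alpha_grid_step,
                 use_adjudicator = isTRUE(use_adjudicator),
                 use_mining = isTRUE(use_mining),
                 use_fusion = isTRUE(use_fusion),
                 augment_train = augment_train,
                 n_boot = as.integer(n_boot), target_recall = target_recall,
                 out_dir = out_dir, profile = profile),
            class = "experiment_config")
}

# Stage seeds, all derived from the run seed.
stage_seeds <- function(seed) {
  list(scene = derive_seed(seed, 1), detector = derive_seed(seed, 2),
       split = derive_seed(seed, 3), model = derive_seed(seed, 4),
       train = derive_seed(seed, 5), pool = derive_seed(seed, 6),
       boot = derive_seed(seed, 7))
}

# Simulate the cohort, run the mock detector, build labeled ROI records
# and the patient-disjoint splits. Shared by run_pipeline / run_ablation.
prepare_benchmark <- function(config) {
  seeds <- stage_seeds(config$seed)
  scn <- config$scene
  scn$seed <- seeds$scene
  scenes <- generate_cohort(scn, config$n_patients, config$scenes_per_patient)
  det <- config$detector
  det$seed <- seeds$detector
  detections <- lapply(scenes, mock_detect, config = det)
  records <- build_roi_records(scenes, detections, config$patch_size,
                               context_pad = config$context_pad)
  splits <- split_by_patient(records, split_spec(config$ratios, seeds$split))
  list(scenes = scenes, detections = detections, records = records,
       splits = splits, seeds = seeds)
}

# Train an adjudicator on the prepared benchmark. With mining, the initial
# negative pool N0 is a seeded random fraction (neg_keep) of the
# training-split negatives; the remainder forms a reservoir from which the
# per-epoch hook mines records whose provisional fused score (default
# alpha 0.6) exceeds a validation-selected mining threshold.
fit_adjudicator <- function(config, bench, use_confidence = TRUE,
                            use_mining = config$use_mining) {
  seeds <- bench$seeds
  train_recs <- bench$splits$train
  val_recs <- bench$splits$val
  y_tr <- vapply(train_recs, function(r) r$y, numeric(1))
  model <- adjudicator_model(config$patch_size, config$channels,
                             hidden = config$hidden,
                             use_confidence = use_confidence,
                             seed = seeds$model)
  hook <- NULL
  if (use_mining) {
    pos <- train_recs[y_tr == 1]
    neg <- train_recs[y_tr == 0]
    ord <- with_seed(seeds$pool, sample(length(neg)))
    n_keep <- ceiling(config$neg_keep * length(neg))
    pool <- mining_pool(pos, neg[ord[seq_len(n_keep)]], config$mining)
    reservoir <- neg[ord[-seq_len(n_keep)]]
    env <- environment()
    hook <- function(model, epoch) {
      if (epoch %% config$mining$cadence_epochs != 0L) return(list())
      if (length(env$reservoir) == 0L) return(list())
      yh_val <- predict_records(model, val_recs)
      s_val <- vapply(val_recs, function(r) r$s, numeric(1))
      fused_val <- fuse_scores(yh_val, s_val, 0.6)
      tau_mine <- tryCatch(
        suppressWarnings(select_tau_mine(val_recs, fused_val,
                                         config$precision_floor)),
        error = function(e) config$mining$tau_mine)
      yh_res <- predict_records(model, env$reservoir)
      s_res <- vapply(env$reservoir, function(r) r$s, numeric(1))
      fused_res <- fuse_scores(yh_res, s_res, 0.6)
      mined <- mine_hard_negatives(env$reservoir, fused_res, tau_mine)
      mined <- lapply(mined, function(r) {
        r$epoch_mined <- epoch
        r
      })
      env$pool <- merge_pool(env$pool, mined)
      if (length(mined) > 0L) {
        mined_keys <- vapply(mined, record_key, character(1))
        res_keys <- vapply(env$reservoir, record_key, character(1))
        env$reservoir <- env$reservoir[!(res_keys %in% mined_keys)]
      }
      mined
    }
    train_start <- pool_records(pool)
  } else {
    train_start <- train_recs
  }
  cfg <- config$train
  cfg$seed <- seeds$train
  fit <- train_adjudicator(model, train_start, val_recs, cfg,
                           mining_hook = hook,
                           augmentation = config$augment_train)
  fit
}

# Decision scores for a record set under the chosen configuration.
decision_scores <- function(records, model = NULL, alpha = NULL) {
  s <- vapply(records, function(r) r$s, numeric(1))
  if (is.null(model)) return(s)
  yh <- predict_records(model, records)
  if (is.null(alpha)) return(yh)
  fuse_scores(yh, s, alpha)
}

# Count confounder-sited false positives at the matched-recall operating
# point: the threshold is the smallest score among the top
# ceil(target_recall * n_pos) positives, so recall >= target_recall.
count_confounder_fps <- function(scores, labels, on_confounder,
                                 target_recall = 0.9) {
  pos_scores <- sort(scores[labels == 1], decreasing = TRUE)
  if (length(pos_scores) == 0L) return(NA_integer_)
  k <- ceiling(target_recall * length(pos_scores))
  tau <- pos_scores[k]
  sum(scores >= tau & labels == 0 & on_confounder)
}

# Detection-level mAP@0.5 on a set of scenes with ROI scores replacing the
# raw detector confidences.
rescored_map <- function(records, scores, scenes, iou_threshold = 0.5) {
  scene_idx <- vapply(records, function(r) r$scene_index, numeric(1))
  used <- sort(unique(scene_idx))
  dets <- lapply(used, function(i) {
    sel <- which(scene_idx == i)
    lapply(sel, function(j) list(box = records[[j]]$box, conf = scores[j]))
  })
  gts <- lapply(used, function(i) scenes[[i]]$fracture_boxes)
  if (sum(vapply(gts, length, integer(1))) == 0L) return(NA_real_)
  map_at_iou(dets, gts, iou_threshold)
}

# Grad-CAM localization over the true-positive test records.
saliency_eval <- function(model, records) {
  pos <- Filter(function(r) r$y == 1 && !is.null(r$gt_patch_box), records)
  if (length(pos) == 0L) {
    return(list(n = 0L, pointing_accuracy = NA_real_, chance_rate = NA_real_,
                mean_mask_iou = NA_real_, mean_dice = NA_real_))
  }
  hits <- numeric(0); ious <- numeric(0); dices <- numeric(0)
  chance <- numeric(0)
  psz <- model$patch_size
  for (r in pos) {
    sal <- gradcam(model, r$patch, r$s)
    msk <- heatmap_to_mask(sal$heatmap, 0.5)
    sc <- localization_scores(sal$heatmap, msk, r$gt_patch_box)
    hits <- c(hits, sc$pointing_hit)
    ious <- c(ious, sc$mask_iou)
    dices <- c(dices, sc$dice)
    chance <- c(chance, box_area(r$gt_patch_box) / (psz * psz))
  }
  list(n = length(pos), pointing_accuracy = mean(hits),
       chance_rate = mean(chance), mean_mask_iou = mean(ious),
       mean_dice = mean(dices))
}

#' Run the full adjudication pipeline
#'
#' Executes every stage on patient-disjoint splits: cohort simulation, mock
#' detection, ROI labeling, adjudicator training with per-epoch
#' hard-negative mining, fusion-weight and threshold selection on the
#' validation split only, and test-split evaluation with bootstrap
#' confidence intervals, calibration diagnostics and Grad-CAM localization
#' scores. All randomness derives from \code{config$seed}.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return An \code{eval_report} list; see Details. When
#'   \code{config$out_dir} is set, manifests, the training history and the
#'   report JSON are written there.
#' @export
run_pipeline <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  bench <- prepare_benchmark(config)
  tr <- bench$splits$train; va <- bench$splits$val; te <- bench$splits$test
  y_val <- vapply(va, function(r) r$y, numeric(1))
  y_test <- vapply(te, function(r) r$y, numeric(1))
  s_test <- vapply(te, function(r) r$s, numeric(1))
  on_conf <- vapply(te, function(r) isTRUE(r$on_confounder), logical(1))

  model <- NULL; history <- NULL; alpha <- NULL
  if (config$use_adjudicator) {
    fit <- fit_adjudicator(config, bench)
    model <- fit$model
    history <- fit$history
  }
  # operating point on validation only
  if (config$use_adjudicator && config$use_fusion) {
    yh_val <- predict_records(model, va)
    s_val <- vapply(va, function(r) r$s, numeric(1))
    sel <- select_alpha(yh_val, s_val, y_val, config$alpha_grid_step)
    alpha <- sel$alpha
    tau <- sel$tau
  } else {
    val_scores <- decision_scores(va, model)
    sel <- select_threshold(val_scores, y_val)
    tau <- sel$tau
  }

  test_scores <- decision_scores(te, model, alpha)
  cm <- classification_metrics(counts_at_threshold(test_scores, y_test, tau))
  calib <- calibration_report(test_scores, y_test)
  calib_detector <- calibration_report(s_test, y_test)
  f1_ci <- bootstrap_ci(function(sc, lb) f1_at_threshold(sc, lb, tau),
                        test_scores, y_test, n_boot = config$n_boot,
                        seed = bench$seeds$boot)
  sal <- if (config$use_adjudicator) saliency_eval(model, te) else NULL

  report <- structure(list(
    config = config,
    alpha = alpha, tau = tau,
    n_records = c(train = length(tr), val = length(va), test = length(te)),
    metrics = c(cm, list(
      roc_auc = roc_auc(test_scores, y_test),
      average_precision = average_precision(test_scores, y_test),
      map50 = rescored_map(te, test_scores, bench$scenes),
      ece = calib$ece, brier = calib$brier,
      ece_detector = calib_detector$ece,
      brier_detector = calib_detector$brier)),
    f1_ci = f1_ci[c("lower", "upper", "estimate", "level")],
    confounder_fps = count_confounder_fps(test_scores, y_test, on_conf,
                                          config$target_recall),
    saliency = sal,
    history = history,
    calibration = calib,
    test_scores = test_scores, test_labels = y_test,
    test_s = s_test, test_on_confounder = on_conf),
    class = "eval_report")

  if (!is.null(config$out_dir)) persist_report(report, bench, config$out_dir)
  report
}

persist_report <- function(report, bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_roi_manifest(bench$records, file.path(out_dir, "roi_manifest.csv"))
  if (!is.null(report$history)) {
    utils::write.csv(report$history, file.path(out_dir, "train_history.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$calibration$bins,
                   file.path(out_dir, "reliability_bins.csv"),
                   row.names = FALSE)
  scores_df <- data.frame(S = report$test_scores, y = report$test_labels,
                          s = report$test_s,
                          on_confounder = report$test_on_confounder)
  utils::write.csv(scores_df, file.path(out_dir, "test_scores.csv"),
                   row.names = FALSE)
  slim <- report[c("alpha", "tau", "n_records", "metrics", "f1_ci",
                   "confounder_fps", "saliency")]
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Run the ablation ladder
#'
#' Four cumulative configurations on one shared synthetic cohort and split:
#' \describe{
#'   \item{detector}{raw detector confidences, threshold selected on
#'     validation — the detector-only baseline.}
#'   \item{+hnm}{a patch classifier of the same capacity but without
#'     confidence conditioning, trained with hard-negative mining;
#'     decisions from its probability.}
#'   \item{+adjudicator}{the full confidence-conditioned adjudicator,
#'     trained with mining; decisions from \code{y_hat}.}
#'   \item{+fusion}{the same adjudicator with convex score fusion and
#'     validation-selected \code{alpha}, \code{tau}.}
#' }
#'
#' @param config An \code{\link{experiment_config}}.
#' @return Data frame with one row per configuration: \code{configuration},
#'   \code{map50}, \code{f1}, \code{ece}.
#' @export
run_ablation <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  bench <- prepare_benchmark(config)
  va <- bench$splits$val; te <- bench$splits$test
  y_val <- vapply(va, function(r) r$y, numeric(1))
  y_test <- vapply(te, function(r) r$y, numeric(1))

  eval_row <- function(name, test_scores, tau) {
    data.frame(
      configuration = name,
      map50 = rescored_map(te, test_scores, bench$scenes),
      f1 = f1_at_threshold(test_scores, y_test, tau),
      ece = ece(test_scores, y_test))
  }

  # detector-only baseline
  s_val <- vapply(va, function(r) r$s, numeric(1))
  s_test <- vapply(te, function(r) r$s, numeric(1))
  rows <- eval_row("detector", s_test, select_threshold(s_val, y_val)$tau)

  # + hard-negative mining (confidence-blind classifier)
  fit_b <- fit_adjudicator(config, bench, use_confidence = FALSE,
                           use_mining = TRUE)
  vb <- predict_records(fit_b$model, va)
  tb <- predict_records(fit_b$model, te)
  rows <- rbind(rows, eval_row("+hnm", tb, select_threshold(vb, y_val)$tau))

  # + confidence-conditioned adjudicator
  fit_c <- fit_adjudicator(config, bench, use_confidence = TRUE,
                           use_mining = TRUE)
  vc <- predict_records(fit_c$model, va)
  tc <- predict_records(fit_c$model, te)
  rows <- rbind(rows, eval_row("+adjudicator", tc,
                               select_threshold(vc, y_val)$tau))

  # + score fusion
  sel <- select_alpha(vc, s_val, y_val, config$alpha_grid_step)
  fused_test <- fuse_scores(tc, s_test, sel$alpha)
  rows <- rbind(rows, eval_row("+fusion", fused_test, sel$tau))

  rownames(rows) <- NULL
  rows
}
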