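#' Configuration for synthetic radiograph scenes
#'
#' The generator emulates the ROI-level structure of pediatric wrist
#' radiographs at desk scale: bright elongated "bone" bands on a noisy
#' background, thin dark fracture-like discontinuities crossing a band
#' (positives), smooth transverse lucent growth-plate-like bands and
#' overlapping-edge crossings (hard negatives), and plain background
#' regions (easy negatives). It makes no claim of photorealism; its purpose
#' is to give every downstream stage annotated ground truth.
#'
#' @param image_height,image_width Scene size in pixels (at least 64).
#'   Default 256, chosen so a full benchmark run stays desk-scale.
#' @param n_bones Number of bone bands per scene.
#' @param fracture_rate Probability that a bone carries a fracture.
#' @param confounder_rates Named numeric vector with elements
#'   \code{growth_plate} and \code{overlap}: per-bone probabilities of each
#'   confounder type. An optional \code{implant} element adds small
#'   saturated blobs (off by default).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; (config, seed) fully determines a scene.
#' @return A \code{scene_config} list.
#' @export
scene_config <- function(image_height = 256L, image_width = 256L,
                         n_bones = 2L, fracture_rate = 0.8,
                         confounder_rates = c(growth_plate = 0.7,
                                              overlap = 0.5, implant = 0),
                         noise_sd = 0.02, seed = 1L) {
  if (image_height < 64 || image_width < 64) {
    abort_input("scene dimensions must be at least 64 pixels")
  }
  if (is.null(names(confounder_rates))) {
    names(confounder_rates) <- c("growth_plate", "overlap", "implant")[
      seq_along(confounder_rates)]
  }
  cr <- c(growth_plate = 0, overlap = 0, implant = 0)
  cr[names(confounder_rates)] <- confounder_rates
  rates <- c(fracture_rate, cr)
  if (!is_prob(rates)) abort_input("all rates must lie in [0, 1]")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_bones = as.integer(n_bones),
                 fracture_rate = fracture_rate,
                 confounder_rates = cr,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate one synthetic radiograph scene
#'
#' @param config A \code{\link{scene_config}}.
#' @param patient_id Character patient identifier attached to the scene
#'   (used downstream for patient-disjoint splitting).
#' @return A \code{synthetic_scene}: list with \code{image} (H x W matrix,
#'   intensities in \code{[0, 1]}), \code{fracture_boxes},
#'   \code{confounder_boxes} (each box carries a \code{kind} attribute:
#'   \code{"growth_plate"}, \code{"overlap"} or \code{"implant"}) and
#'   \code{patient_id}.
#' @export
generate_scene <- function(config, patient_id = "P001") {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config, patient_id))
}

# Clip a candidate box to image bounds, preserving a minimal 4 px extent
# for features whose center lands near or beyond the border.
bounded_box <- function(x0, y0, x1, y1, H, W) {
  x0 <- clamp(x0, 0, W - 4); y0 <- clamp(y0, 0, H - 4)
  x1 <- clamp(x1, x0 + 4, W); y1 <- clamp(y1, y0 + 4, H)
  box(x0, y0, x1, y1)
}

generate_scene_impl <- function(config, patient_id) {
  H <- config$image_height; W <- config$image_width
  # coordinate grids at pixel centers, 0-based half-open convention
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  img <- matrix(0.12, H, W)
  # slow illumination gradient
  img <- img + 0.04 * (xs / W) + 0.03 * (ys / H)

  fracture_boxes <- list()
  confounder_boxes <- list()

  for (bone in seq_len(max(config$n_bones, 0L))) {
    # bone band: center point, orientation mostly along the long image axis
    cx <- runif(1, 0.25 * W, 0.75 * W)
    cy <- runif(1, 0.25 * H, 0.75 * H)
    theta <- runif(1, -pi / 5, pi / 5) + pi / 2  # near-vertical
    ux <- cos(theta); uy <- sin(theta)           # along-bone unit vector
    nx <- -uy; ny <- ux                          # across-bone unit vector
    halfw <- runif(1, 9, 13)
    # signed distances
    d_perp <- (xs - cx) * nx + (ys - cy) * ny
    d_along <- (xs - cx) * ux + (ys - cy) * uy
    shaft <- exp(-(d_perp / halfw)^4)
    img <- img + 0.42 * shaft
    # cortical rims: brighter edges of the band
    img <- img + 0.16 * exp(-((abs(d_perp) - halfw) / 1.8)^2) * shaft^(1 / 8)

    add_transverse <- function(t_along, tilt, thickness, depth, len_scale) {
      # a lucent (dark) band crossing the bone at arc-length position t_along
      px <- cx + t_along * ux; py <- cy + t_along * uy
      phi <- atan2(ny, nx) + tilt
      fx <- cos(phi); fy <- sin(phi)   # along-feature direction
      gfx <- -fy; gfy <- fx            # across-feature direction
      df <- (xs - px) * gfx + (ys - py) * gfy
      dl <- (xs - px) * fx + (ys - py) * fy
      half_len <- len_scale * halfw
      extent <- exp(-(dl / half_len)^6) * exp(-(d_perp / (1.1 * halfw))^6)
      img <<- img - depth * exp(-(df / thickness)^2) * extent
      # analytic box around the feature; a minimum half-extent keeps boxes
      # at annotation-realistic sizes even for hairline features
      ex <- max(abs(fx) * half_len + abs(gfx) * (2 * thickness), 6)
      ey <- max(abs(fy) * half_len + abs(gfy) * (2 * thickness), 6)
      bounded_box(px - ex, py - ey, px + ex, py + ey, H, W)
    }

    span <- 0.3 * min(H, W)
    if (runif(1) < config$fracture_rate) {
      # thin, tilted, irregular dark discontinuity
      t_fr <- runif(1, -span, span)
      b <- add_transverse(t_fr, runif(1, -pi / 6, pi / 6),
                          thickness = runif(1, 1.0, 1.6),
                          depth = runif(1, 0.30, 0.42), len_scale = 1.25)
      fracture_boxes <- c(fracture_boxes, list(b))
    }
    if (runif(1) < config$confounder_rates[["growth_plate"]]) {
      # wider, smoother, exactly transverse lucent band
      t_gp <- runif(1, -span, span)
      b <- add_transverse(t_gp, 0,
                          thickness = runif(1, 3.5, 5.5),
                          depth = runif(1, 0.12, 0.18), len_scale = 1.15)
      attr(b, "kind") <- "growth_plate"
      confounder_boxes <- c(confounder_boxes, list(b))
    }
    if (runif(1) < config$confounder_rates[["overlap"]]) {
      # a second bright edge crossing the bone: overlapping cortical edges
      t_ov <- runif(1, -span, span)
      px <- cx + t_ov * ux; py <- cy + t_ov * uy
      phi <- theta + runif(1, pi / 5, pi / 3) * sample(c(-1, 1), 1)
      ex_ <- cos(phi); ey_ <- sin(phi)
      gx <- -ey_; gy <- ex_
      dg <- (xs - px) * gx + (ys - py) * gy
      dl <- (xs - px) * ex_ + (ys - py) * ey_
      img <- img + 0.22 * exp(-(dg / 1.6)^2) * exp(-(dl / (2.2 * halfw))^4)
      r <- 1.3 * halfw
      b <- bounded_box(px - r, py - r, px + r, py + r, H, W)
      attr(b, "kind") <- "overlap"
      confounder_boxes <- c(confounder_boxes, list(b))
    }
    if (runif(1) < config$confounder_rates[["implant"]]) {
      px <- cx + runif(1, -span, span) * ux
      py <- cy + runif(1, -span, span) * uy
      rr <- runif(1, 4, 7)
      dd <- sqrt((xs - px)^2 + (ys - py)^2)
      img <- img + 0.9 * exp(-(dd / rr)^4)
      b <- bounded_box(px - 1.6 * rr, py - 1.6 * rr,
                       px + 1.6 * rr, py + 1.6 * rr, H, W)
      attr(b, "kind") <- "implant"
      confounder_boxes <- c(confounder_boxes, list(b))
    }
  }

  img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
  img <- clamp(img, 0, 1)
  structure(list(image = img,
                 fracture_boxes = fracture_boxes,
                 confounder_boxes = confounder_boxes,
                 patient_id = patient_id),
            class = "synthetic_scene")
}

#' Generate a multi-patient cohort of scenes
#'
#' Patient identifiers are unique per patient; each scene gets a distinct
#' derived seed so scenes differ while the whole cohort is reproducible from
#' \code{config$seed}.
#'
#' @param config A \code{\link{scene_config}} (its \code{seed} seeds the
#'   whole cohort).
#' @param n_patients Number of patients (at least 1).
#' @param scenes_per_patient Scenes generated per patient.
#' @return List of \code{synthetic_scene} objects of length
#'   \code{n_patients * scenes_per_patient}.
#' @export
generate_cohort <- function(config, n_patients, scenes_per_patient = 1L) {
  stopifnot(inherits(config, "scene_config"))
  if (n_patients < 1) abort_input("n_patients must be at least 1")
  scenes <- vector("list", n_patients * scenes_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    for (s in seq_len(scenes_per_patient)) {
      k <- k + 1L
      cfg_k <- config
      cfg_k$seed <- derive_seed(config$seed, k)
      scenes[[k]] <- generate_scene(cfg_k, patient_id = pid)
    }
  }
  scenes
}

#' Mock high-recall detector configuration
#'
#' A parametric proposal generator standing in for a trained single-stage
#' detector. It emits one jittered proposal per true fracture with
#' high-range confidence, false-positive proposals on confounder structures
#' with intermediate confidence, and random-location false positives with
#' low confidence; proposals below \code{conf_threshold} are dropped and
#' greedy NMS at \code{nms_iou} removes redundancy. Confidences are drawn
#' from type-specific Beta distributions so that the detector confidence is
#' informative but imperfect. Any detector honouring the same proposal
#' contract (box + confidence) can be plugged in instead.
#'
#' @param conf_threshold Minimum retained confidence (default 0.25,
#'   recall-oriented).
#' @param nms_iou NMS IoU threshold (default 0.5).
#' @param jitter_sd Coordinate noise (pixels) applied to true-fracture
#'   proposals.
#' @param fp_rate_confounder Probability that a given confounder box emits a
#'   false-positive proposal.
#' @param fp_rate_random Expected number (Poisson mean) of random-location
#'   false positives per scene.
#' @param conf_distributions Named list of Beta parameters \code{c(a, b)}
#'   for proposal types \code{tp}, \code{confounder}, \code{random}. The
#'   default makes true positives skew high, confounder false positives
#'   intermediate and random false positives low.
#' @param seed Integer seed for the detector's randomness.
#' @return A \code{detector_config} list.
#' @export
detector_config <- function(conf_threshold = 0.25, nms_iou = 0.5,
                            jitter_sd = 1.0, fp_rate_confounder = 0.75,
                            fp_rate_random = 0.6,
                            conf_distributions = list(tp = c(9, 1.5),
                                                      confounder = c(6, 2.5),
                                                      random = c(2, 6)),
                            seed = 1L) {
  if (conf_threshold <= 0 || conf_threshold >= 1 ||
      nms_iou <= 0 || nms_iou >= 1) {
    abort_input("conf_threshold and nms_iou must be in (0, 1)")
  }
  structure(list(conf_threshold = conf_threshold, nms_iou = nms_iou,
                 jitter_sd = jitter_sd,
                 fp_rate_confounder = fp_rate_confounder,
                 fp_rate_random = fp_rate_random,
                 conf_distributions = conf_distributions,
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Overconfident variant of the mock detector
#'
#' Same proposal geometry as \code{\link{detector_config}} but with
#' confidence distributions shifted high for false positives, emulating a
#' detector whose raw scores are badly calibrated. Used to study whether
#' score fusion regularizes overconfident detector outputs.
#'
#' @param ... Passed to \code{\link{detector_config}}.
#' @export
overconfident_detector_config <- function(...) {
  detector_config(conf_distributions = list(tp = c(12, 1.5),
                                            confounder = c(8, 2),
                                            random = c(4, 3)),
                  ...)
}

#' Run the mock detector on a scene
#'
#' @param scene A \code{synthetic_scene}.
#' @param config A \code{\link{detector_config}}.
#' @return List of detections, each a list with \code{box} and \code{conf};
#'   all retained confidences lie in \code{[conf_threshold, 1]}.
#' @export
mock_detect <- function(scene, config) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(config, "detector_config"))
  # per-scene stream derived from image content so detections vary across a
  # cohort while staying bit-reproducible for a given (scene, config)
  stream <- round(sum(scene$image[1:16, 1:16]) * 1e6) %% 1e6
  with_seed(derive_seed(config$seed, stream), mock_detect_impl(scene, config))
}

mock_detect_impl <- function(scene, config) {
  H <- nrow(scene$image); W <- ncol(scene$image)
  props <- list()
  rbeta2 <- function(p) stats::rbeta(1, p[1], p[2])
  jitter_box <- function(b, sd) {
    if (sd <= 0) return(b)
    v <- unclass(b) + stats::rnorm(4, 0, sd)
    # keep validity and bounds
    x0 <- clamp(min(v[1], v[3] - 1), 0, W - 1)
    x1 <- clamp(max(v[3], x0 + 1), x0 + 1, W)
    y0 <- clamp(min(v[2], v[4] - 1), 0, H - 1)
    y1 <- clamp(max(v[4], y0 + 1), y0 + 1, H)
    box(x0, y0, x1, y1)
  }
  for (fb in scene$fracture_boxes) {
    props <- c(props, list(list(box = jitter_box(fb, config$jitter_sd),
                                conf = rbeta2(config$conf_distributions$tp))))
  }
  for (cb in scene$confounder_boxes) {
    if (stats::runif(1) < config$fp_rate_confounder) {
      props <- c(props, list(list(
        box = jitter_box(cb, config$jitter_sd),
        conf = rbeta2(config$conf_distributions$confounder))))
    }
  }
  n_rand <- stats::rpois(1, config$fp_rate_random)
  for (i in seq_len(n_rand)) {
    w <- stats::runif(1, 18, 42); h <- stats::runif(1, 18, 42)
    x0 <- stats::runif(1, 0, W - w); y0 <- stats::runif(1, 0, H - h)
    props <- c(props, list(list(
      box = box(x0, y0, x0 + w, y0 + h),
      conf = rbeta2(config$conf_distributions$random))))
  }
  props <- Filter(function(p) p$conf >= config$conf_threshold, props)
  nms(props, config$nms_iou)
}
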