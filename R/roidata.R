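# Labeled ROI records: label assignment by overlap, cropping / resizing /
# normalization, augmentation, and patient-disjoint splitting.

#' Assign a binary label to a detection
#'
#' A detection is positive iff its maximum IoU against any ground-truth
#' fracture box reaches \code{iou_threshold}. The default 0.5 matches the
#' IoU used for NMS and detection evaluation.
#'
#' @param detection A detection (list with \code{box}).
#' @param fracture_boxes List of ground-truth \code{box}es (may be empty,
#'   in which case the label is 0).
#' @param iou_threshold Matching threshold in \code{(0, 1]}.
#' @return Integer label, 0 or 1.
#' @export
assign_label <- function(detection, fracture_boxes, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1) {
    abort_input("iou_threshold must be in (0, 1]")
  }
  if (length(fracture_boxes) == 0L) return(0L)
  as.integer(max(iou_many(detection$box, fracture_boxes)) >= iou_threshold)
}

#' Crop, resize and normalize an ROI patch
#'
#' The box is clamped to the image, the crop is bilinearly resized to
#' \code{patch_size x patch_size}, and intensities are normalized as
#' \code{(x - mean) / sd}. An optional fractional context margin enlarges
#' the box on every side before cropping (0.5 doubles each side length),
#' which keeps the expert box a strict sub-region of the patch — needed for
#' meaningful saliency localization scores.
#'
#' @param image H x W intensity matrix.
#' @param b A \code{box} that intersects the image.
#' @param patch_size Output side length in pixels.
#' @param mean,sd Normalization constants (defaults leave intensities
#'   unchanged). For a three-channel ImageNet-pretrained backbone the usual
#'   per-channel statistics would be applied after channel replication.
#' @param context_pad Fractional margin added on each side (0 = tight box).
#' @return \code{patch_size x patch_size} numeric matrix.
#' @export
crop_roi <- function(image, b, patch_size, mean = 0, sd = 1,
                     context_pad = 0) {
  H <- nrow(image); W <- ncol(image)
  if (context_pad > 0) {
    bw <- b[["x_max"]] - b[["x_min"]]; bh <- b[["y_max"]] - b[["y_min"]]
    b <- box(b[["x_min"]] - context_pad * bw, b[["y_min"]] - context_pad * bh,
             b[["x_max"]] + context_pad * bw, b[["y_max"]] + context_pad * bh)
  }
  b <- clip_box(b, H, W)
  # pixel index ranges covered by the half-open box
  rows <- (floor(b[["y_min"]]) + 1):ceiling(b[["y_max"]])
  cols <- (floor(b[["x_min"]]) + 1):ceiling(b[["x_max"]])
  crop <- image[rows, cols, drop = FALSE]
  if (nrow(crop) != patch_size || ncol(crop) != patch_size) {
    crop <- EBImage::resize(EBImage::Image(crop), w = patch_size,
                            h = patch_size, filter = "bilinear")
    crop <- matrix(EBImage::imageData(crop), patch_size, patch_size)
  }
  (crop - mean) / sd
}

# Map a box given in image coordinates into the pixel coordinates of the
# patch produced by crop_roi(image, crop_box, patch_size, context_pad).
# Returns NULL when the intersection with the crop window is empty.
map_box_to_patch <- function(crop_b, b, patch_size, image_height,
                             image_width, context_pad = 0) {
  if (context_pad > 0) {
    bw <- crop_b[["x_max"]] - crop_b[["x_min"]]
    bh <- crop_b[["y_max"]] - crop_b[["y_min"]]
    crop_b <- box(crop_b[["x_min"]] - context_pad * bw,
                  crop_b[["y_min"]] - context_pad * bh,
                  crop_b[["x_max"]] + context_pad * bw,
                  crop_b[["y_max"]] + context_pad * bh)
  }
  crop_b <- clip_box(crop_b, image_height, image_width)
  # the crop actually spans whole pixels, mirroring crop_roi
  x0 <- floor(crop_b[["x_min"]]); x1 <- ceiling(crop_b[["x_max"]])
  y0 <- floor(crop_b[["y_min"]]); y1 <- ceiling(crop_b[["y_max"]])
  sx <- patch_size / (x1 - x0); sy <- patch_size / (y1 - y0)
  px0 <- (max(b[["x_min"]], x0) - x0) * sx
  px1 <- (min(b[["x_max"]], x1) - x0) * sx
  py0 <- (max(b[["y_min"]], y0) - y0) * sy
  py1 <- (min(b[["y_max"]], y1) - y0) * sy
  if (px0 >= px1 || py0 >= py1) return(NULL)
  box(px0, py0, px1, py1)
}

#' Augmentation configuration
#'
#' Moderate geometric and photometric jitter used during training only:
#' random rotation, brightness shift, and a small affine perturbation
#' (isotropic scale and shear). All ranges are half-widths of symmetric
#' uniform distributions; zero ranges give the identity transform.
#'
#' @param rotate_deg Max absolute rotation (degrees).
#' @param brightness Max absolute additive intensity shift.
#' @param scale Max absolute log-scale deviation (0.1 = roughly +/-10 pct).
#' @param shear Max absolute shear coefficient.
#' @param translate_px Max absolute translation (pixels).
#' @return An \code{aug_config} list.
#' @export
aug_config <- function(rotate_deg = 10, brightness = 0.1, scale = 0.08,
                       shear = 0.06, translate_px = 2) {
  structure(list(rotate_deg = rotate_deg, brightness = brightness,
                 scale = scale, shear = shear, translate_px = translate_px),
            class = "aug_config")
}

#' Apply a seeded random augmentation to a patch
#'
#' Output shape equals input shape; transform parameters are drawn
#' deterministically from \code{seed}. Geometric warps use inverse mapping
#' with bilinear interpolation and clamp-to-edge boundary handling;
#' intensities are clipped to \code{[0, 1]} after the brightness shift.
#'
#' @param patch Square numeric matrix.
#' @param config An \code{\link{aug_config}}.
#' @param seed Integer seed.
#' @return Augmented patch, same dimensions.
#' @export
augment <- function(patch, config = aug_config(), seed = 1L) {
  stopifnot(inherits(config, "aug_config"))
  with_seed(seed, {
    ang <- stats::runif(1, -config$rotate_deg, config$rotate_deg) * pi / 180
    dbr <- stats::runif(1, -config$brightness, config$brightness)
    sc <- exp(stats::runif(1, -config$scale, config$scale))
    sh <- stats::runif(1, -config$shear, config$shear)
    tx <- stats::runif(1, -config$translate_px, config$translate_px)
    ty <- stats::runif(1, -config$translate_px, config$translate_px)
    out <- patch
    if (ang != 0 || sc != 1 || sh != 0 || tx != 0 || ty != 0) {
      # forward map: rotate * scale * shear around center, then translate
      m <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2) %*%
        matrix(c(sc, 0, 0, sc), 2, 2) %*%
        matrix(c(1, sh, 0, 1), 2, 2)
      out <- warp_affine(patch, m, c(tx, ty))
    }
    if (dbr != 0) out <- clamp(out + dbr, 0, 1)
    out
  })
}

# Inverse-mapped affine warp about the patch center, bilinear sampling with
# clamp-to-edge. `m` is the 2x2 forward matrix, `tr` the translation.
warp_affine <- function(patch, m, tr = c(0, 0)) {
  n <- nrow(patch); stopifnot(ncol(patch) == n)
  c0 <- (n + 1) / 2
  minv <- solve(m)
  xs <- rep(seq_len(n), each = n) - c0   # column coordinate per output pixel
  ys <- rep(seq_len(n), times = n) - c0  # row coordinate
  sx <- minv[1, 1] * (xs - tr[1]) + minv[1, 2] * (ys - tr[2]) + c0
  sy <- minv[2, 1] * (xs - tr[1]) + minv[2, 2] * (ys - tr[2]) + c0
  sx <- clamp(sx, 1, n); sy <- clamp(sy, 1, n)
  x0 <- pmin(floor(sx), n - 1); y0 <- pmin(floor(sy), n - 1)
  fx <- sx - x0; fy <- sy - y0
  idx <- function(r, c) patch[cbind(r, c)]
  v <- (1 - fx) * (1 - fy) * idx(y0, x0) +
    fx * (1 - fy) * idx(y0, x0 + 1) +
    (1 - fx) * fy * idx(y0 + 1, x0) +
    fx * fy * idx(y0 + 1, x0 + 1)
  matrix(v, n, n)
}

#' Split specification
#'
#' @param ratios Three fractions in \code{(0, 1)} summing to 1 (train /
#'   validation / test). Default 0.8 / 0.1 / 0.1.
#' @param seed Integer seed for the patient shuffle.
#' @return A \code{split_spec} list.
#' @export
split_spec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0) || any(ratios >= 1)) {
    abort_input("each split fraction must lie in (0, 1)")
  }
  if (abs(sum(ratios) - 1) > 1e-9) abort_input("split fractions must sum to 1")
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

#' Patient-disjoint train/validation/test split
#'
#' Patients are shuffled with the spec's seed, then assigned greedily: each
#' patient goes to the split with the largest remaining deficit against its
#' target ROI count (ties toward the earlier split). The three outputs
#' partition the input and no patient appears in more than one split.
#'
#' @param records List of ROI records, each with a \code{patient_id}.
#' @param spec A \code{\link{split_spec}}.
#' @return List with elements \code{train}, \code{val}, \code{test}.
#' @export
split_by_patient <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  pids <- vapply(records, function(r) r$patient_id, character(1))
  patients <- unique(pids)
  if (length(patients) < 3L) {
    abort_input("patient-disjoint splitting needs at least 3 patients")
  }
  counts <- table(pids)[patients]
  ord <- with_seed(spec$seed, sample(seq_along(patients)))
  targets <- spec$ratios * length(records)
  assigned <- numeric(3)
  split_of <- integer(length(patients))
  for (i in ord) {
    deficit <- targets - assigned
    j <- which.max(deficit)  # ties -> earliest split
    split_of[i] <- j
    assigned[j] <- assigned[j] + counts[[i]]
  }
  pick <- function(j) records[pids %in% patients[split_of == j]]
  out <- list(train = pick(1), val = pick(2), test = pick(3))
  assert_patient_disjoint(out)
  out
}

# Leakage guard: asserted after every split and before training.
assert_patient_disjoint <- function(splits) {
  sets <- lapply(splits, function(recs) {
    unique(vapply(recs, function(r) r$patient_id, character(1)))
  })
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0L) {
        stop("patient overlap between splits: leakage", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Build labeled ROI records from scenes and detections
#'
#' Runs label assignment and patch extraction for every detection of every
#' scene. Each record carries the patch, box, detector confidence, label,
#' patient id, provenance (\code{orig_pos} / \code{orig_neg}) and a flag
#' marking whether the detection sits on a confounder structure (its center
#' inside a confounder box) — used later to analyse which false positives
#' mining removes.
#'
#' @param scenes List of \code{synthetic_scene}s.
#' @param detections_per_scene List of detection lists, parallel to
#'   \code{scenes}.
#' @param patch_size Patch side length.
#' @param iou_threshold Label-assignment IoU threshold.
#' @param context_pad Fractional crop margin (see \code{\link{crop_roi}}).
#' @param mean,sd Patch normalization constants.
#' @return List of ROI records.
#' @export
build_roi_records <- function(scenes, detections_per_scene, patch_size = 64L,
                              iou_threshold = 0.5, context_pad = 0.5,
                              mean = 0, sd = 1) {
  stopifnot(length(scenes) == length(detections_per_scene))
  records <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    H <- nrow(sc$image); W <- ncol(sc$image)
    for (d in detections_per_scene[[i]]) {
      y <- assign_label(d, sc$fracture_boxes, iou_threshold)
      cx <- (d$box[["x_min"]] + d$box[["x_max"]]) / 2
      cy <- (d$box[["y_min"]] + d$box[["y_max"]]) / 2
      on_conf <- any(vapply(sc$confounder_boxes, function(cb) {
        cx >= cb[["x_min"]] && cx < cb[["x_max"]] &&
          cy >= cb[["y_min"]] && cy < cb[["y_max"]]
      }, logical(1)))
      patch <- crop_roi(sc$image, d$box, patch_size, mean = mean, sd = sd,
                        context_pad = context_pad)
      gt_patch_box <- NULL
      if (y == 1L && length(sc$fracture_boxes) > 0L) {
        gt <- sc$fracture_boxes[[which.max(iou_many(d$box, sc$fracture_boxes))]]
        gt_patch_box <- map_box_to_patch(d$box, gt, patch_size, H, W,
                                         context_pad = context_pad)
      }
      records <- c(records, list(list(
        patch = patch, box = d$box, s = d$conf, y = y,
        patient_id = sc$patient_id,
        provenance = if (y == 1L) "orig_pos" else "orig_neg",
        scene_index = i, on_confounder = isTRUE(on_conf),
        gt_patch_box = gt_patch_box)))
    }
  }
  records
}
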