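# Grad-CAM saliency for the adjudicator and quantitative ROI-level
# localization scoring against expert boxes.

#' Grad-CAM saliency map for one ROI
#'
#' Channel importances are spatial means of the gradient of the adjudicator
#' probability with respect to the target convolutional stage's activation
#' maps; the map is the ReLU of the importance-weighted sum of those maps,
#' bilinearly upsampled to patch size and divided by its maximum when
#' positive.
#'
#' @param model An \code{adjudicator_model}.
#' @param patch Square numeric matrix of side \code{model$patch_size}.
#' @param s Detector confidence in \code{[0, 1]}.
#' @param target_layer Index of the convolutional stage whose activations
#'   are explained; defaults to the last stage.
#' @return A \code{saliency_result}: list with \code{heatmap} (patch-sized,
#'   non-negative, max 1 unless identically zero), \code{channel_weights},
#'   \code{target_layer} and \code{yhat}.
#' @export
gradcam <- function(model, patch, s, target_layer = NULL) {
  stopifnot(inherits(model, "adjudicator_model"))
  nl <- length(model$channels)
  target_layer <- target_layer %||% nl
  if (!target_layer %in% seq_len(nl)) {
    abort_input("target_layer must index a convolutional stage of the model")
  }
  fw <- model_forward(model, patch, s, cache = TRUE)
  # d yhat / d logit, then propagate to the target activations
  dlogit <- fw$yhat * (1 - fw$yhat)
  dA <- model_backward(model, fw, dlogit, wrt_activation = target_layer)$dA
  A <- if (target_layer == nl) fw$A else relu(fw$pre[[target_layer]])
  A <- array(A, dim(A)[1:3])
  omega <- apply(dA, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(omega)) cam <- cam + omega[k] * A[, , k]
  cam <- pmax(cam, 0)
  if (any(dim(cam) != model$patch_size)) {
    cam <- EBImage::resize(EBImage::Image(cam), w = model$patch_size,
                           h = model$patch_size, filter = "bilinear")
    cam <- matrix(EBImage::imageData(cam), model$patch_size,
                  model$patch_size)
    cam <- pmax(cam, 0)
  }
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(heatmap = cam, channel_weights = omega,
                 target_layer = target_layer, yhat = fw$yhat),
            class = "saliency_result")
}

#' Threshold a heatmap into a binary mask
#'
#' @param heatmap Non-negative matrix.
#' @param rel_threshold Relative threshold in \code{(0, 1)}: mask pixels
#'   where \code{heatmap >= rel_threshold * max(heatmap)}. An identically
#'   zero heatmap yields an all-zero mask.
#' @return Logical matrix of the same dimensions.
#' @export
heatmap_to_mask <- function(heatmap, rel_threshold = 0.5) {
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    abort_input("rel_threshold must be in (0, 1)")
  }
  mx <- max(heatmap)
  if (mx <= 0) return(matrix(FALSE, nrow(heatmap), ncol(heatmap)))
  heatmap >= rel_threshold * mx
}

# Rasterize a half-open box into a logical pixel mask of given size.
box_to_mask <- function(b, nrow, ncol) {
  m <- matrix(FALSE, nrow, ncol)
  rows <- max(floor(b[["y_min"]]) + 1, 1):min(ceiling(b[["y_max"]]), nrow)
  cols <- max(floor(b[["x_min"]]) + 1, 1):min(ceiling(b[["x_max"]]), ncol)
  m[rows, cols] <- TRUE
  m
}

#' Localization scores of a saliency map against an expert box
#'
#' The binary mask is compared with the filled rectangle of the expert box
#' (mask IoU and Dice); the pointing-game criterion scores a hit iff the
#' heatmap's maximum-activation pixel lies inside the box. Argmax ties are
#' broken by first occurrence in row-major order (top row first, then
#' left-most column), so pointing results are deterministic.
#'
#' @param heatmap Patch-sized saliency map.
#' @param mask Logical matrix (e.g. from \code{\link{heatmap_to_mask}}).
#' @param expert_box A \code{box} in patch coordinates.
#' @return List with \code{mask_iou}, \code{dice}, \code{pointing_hit}.
#' @export
localization_scores <- function(heatmap, mask, expert_box) {
  if (!is_box(expert_box)) abort_input("expert_box must be a box")
  if (expert_box[["x_min"]] < 0 || expert_box[["y_min"]] < 0 ||
      expert_box[["x_max"]] > ncol(heatmap) ||
      expert_box[["y_max"]] > nrow(heatmap)) {
    abort_input("expert_box must lie within patch coordinates")
  }
  ref <- box_to_mask(expert_box, nrow(heatmap), ncol(heatmap))
  inter <- sum(mask & ref)
  uni <- sum(mask | ref)
  mask_iou <- if (uni > 0) inter / uni else 0
  dice <- if (sum(mask) + sum(ref) > 0) 2 * inter / (sum(mask) + sum(ref)) else 0
  # row-major argmax: scan rows top to bottom, left to right within a row
  mx <- max(heatmap)
  hits <- which(heatmap == mx, arr.ind = TRUE)
  first <- hits[order(hits[, "row"], hits[, "col"])[1], ]
  px <- first[["col"]] - 0.5
  py <- first[["row"]] - 0.5
  pointing_hit <- as.integer(
    px >= expert_box[["x_min"]] && px < expert_box[["x_max"]] &&
      py >= expert_box[["y_min"]] && py < expert_box[["y_max"]])
  list(mask_iou = mask_iou, dice = dice, pointing_hit = pointing_hit)
}

#' Export a heatmap overlay as PNG
#'
#' Writes the patch in gray with the saliency map alpha-blended in red.
#'
#' @param patch Intensity matrix in \code{[0, 1]}.
#' @param heatmap Saliency map in \code{[0, 1]}, same size.
#' @param path Output PNG path.
#' @param alpha Maximum blend weight of the heatmap.
#' @export
write_heatmap_overlay <- function(patch, heatmap, path, alpha = 0.5) {
  g <- clamp(patch, 0, 1)
  a <- alpha * clamp(heatmap, 0, 1)
  rgb <- array(0, c(nrow(g), ncol(g), 3))
  rgb[, , 1] <- g * (1 - a) + a
  rgb[, , 2] <- g * (1 - a)
  rgb[, , 3] <- g * (1 - a)
  png::writePNG(rgb, target = path)
  invisible(path)
}
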