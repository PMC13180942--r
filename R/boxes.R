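#' Axis-aligned bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates: a box covers the pixel
#' region \code{[x_min, x_max) x [y_min, y_max)}, so its width is
#' \code{x_max - x_min} and a 1-pixel box at the image origin is
#' \code{box(0, 0, 1, 1)}. All internal coordinates follow this convention;
#' YOLO-txt (center-normalized) and COCO-style (x, y, w, h) forms are
#' converted only at the I/O boundary.
#'
#' @param x_min,y_min,x_max,y_max Numeric pixel coordinates with
#'   \code{x_min < x_max} and \code{y_min < y_max}.
#' @return An object of class \code{"box"}: a named numeric vector with
#'   elements \code{x_min}, \code{y_min}, \code{x_max}, \code{y_max}.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) abort_input("box coordinates must be finite")
  if (b[["x_min"]] >= b[["x_max"]] || b[["y_min"]] >= b[["y_max"]]) {
    abort_input("degenerate box: need x_min < x_max and y_min < y_max")
  }
  class(b) <- "box"
  b
}

is_box <- function(x) inherits(x, "box")

#' @rdname box
#' @param b A \code{box}.
#' @export
box_area <- function(b) {
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' Clip a box to image bounds
#'
#' @param b A \code{box}.
#' @param height,width Image dimensions in pixels.
#' @return The clipped \code{box}, or an error if the intersection with the
#'   image is empty.
#' @export
clip_box <- function(b, height, width) {
  x0 <- max(b[["x_min"]], 0); y0 <- max(b[["y_min"]], 0)
  x1 <- min(b[["x_max"]], width); y1 <- min(b[["y_max"]], height)
  if (x0 >= x1 || y0 >= y1) abort_input("box has zero-area intersection with image")
  box(x0, y0, x1, y1)
}

box_in_bounds <- function(b, height, width) {
  b[["x_min"]] >= 0 && b[["y_min"]] >= 0 &&
    b[["x_max"]] <= width && b[["y_max"]] <= height
}

# Boxes as a 4-column matrix (one row per box) for vectorized work.
boxes_to_matrix <- function(boxes) {
  if (length(boxes) == 0L) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max"))))
  }
  do.call(rbind, lapply(boxes, function(b) unclass(b)))
}
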