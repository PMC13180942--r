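# Scene and annotation I/O: PNG images, YOLO-txt and COCO-style JSON
# annotations, and CSV manifests of ROI records. Internal coordinates are
# 0-based half-open pixel boxes; conversions happen only here.

#' Write / read a scene image as PNG
#'
#' @param scene A \code{synthetic_scene}.
#' @param path Output PNG path.
#' @return \code{write_scene_png} returns \code{path} invisibly;
#'   \code{read_scene_png} returns an H x W intensity matrix in
#'   \code{[0, 1]}.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image, target = path)
  invisible(path)
}

#' @rdname write_scene_png
#' @export
read_scene_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' YOLO-txt annotations
#'
#' One line per box: \code{class cx cy w h} with center coordinates and
#' sizes normalized by image width/height. Class 0 is fracture; confounder
#' kinds map to classes 1 (growth_plate), 2 (overlap), 3 (implant).
#'
#' @param scene A \code{synthetic_scene}.
#' @param path Output text path.
#' @export
write_yolo <- function(scene, path) {
  H <- nrow(scene$image); W <- ncol(scene$image)
  kinds <- c(growth_plate = 1L, overlap = 2L, implant = 3L)
  lines <- character(0)
  emit <- function(b, cls) {
    cx <- (b[["x_min"]] + b[["x_max"]]) / 2 / W
    cy <- (b[["y_min"]] + b[["y_max"]]) / 2 / H
    w <- (b[["x_max"]] - b[["x_min"]]) / W
    h <- (b[["y_max"]] - b[["y_min"]]) / H
    sprintf("%d %.17g %.17g %.17g %.17g", cls, cx, cy, w, h)
  }
  for (b in scene$fracture_boxes) lines <- c(lines, emit(b, 0L))
  for (b in scene$confounder_boxes) {
    lines <- c(lines, emit(b, kinds[[attr(b, "kind") %||% "growth_plate"]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo
#' @param image_height,image_width Image size used to de-normalize.
#' @return \code{read_yolo} returns a list with \code{fracture_boxes} and
#'   \code{confounder_boxes} (kind attributes restored). Round-trips with
#'   \code{write_yolo} bit-exactly.
#' @export
read_yolo <- function(path, image_height, image_width) {
  lines <- readLines(path)
  kinds <- c("fracture", "growth_plate", "overlap", "implant")
  fb <- list(); cb <- list()
  for (ln in lines) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    cx <- v[2] * image_width; cy <- v[3] * image_height
    w <- v[4] * image_width; h <- v[5] * image_height
    b <- box(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    if (v[1] == 0) {
      fb <- c(fb, list(b))
    } else {
      attr(b, "kind") <- kinds[v[1] + 1]
      cb <- c(cb, list(b))
    }
  }
  list(fracture_boxes = fb, confounder_boxes = cb)
}

#' COCO-style JSON annotations
#'
#' Dialect: \code{{"images": [{"id", "file", "patient_id", "height",
#' "width"}], "annotations": [{"image_id", "bbox": [x_min, y_min, width,
#' height], "category"}]}} with categories \code{fracture},
#' \code{growth_plate}, \code{overlap}, \code{implant}.
#'
#' @param scenes List of \code{synthetic_scene}s.
#' @param path Output JSON path.
#' @param files Optional character vector of image file names (defaults to
#'   \code{scene_<i>.png}).
#' @export
write_coco <- function(scenes, path, files = NULL) {
  files <- files %||% sprintf("scene_%04d.png", seq_along(scenes))
  images <- lapply(seq_along(scenes), function(i) {
    list(id = i, file = files[i], patient_id = scenes[[i]]$patient_id,
         height = nrow(scenes[[i]]$image), width = ncol(scenes[[i]]$image))
  })
  anns <- list()
  for (i in seq_along(scenes)) {
    for (b in scenes[[i]]$fracture_boxes) {
      anns <- c(anns, list(list(image_id = i,
                                bbox = c(b[["x_min"]], b[["y_min"]],
                                         b[["x_max"]] - b[["x_min"]],
                                         b[["y_max"]] - b[["y_min"]]),
                                category = "fracture")))
    }
    for (b in scenes[[i]]$confounder_boxes) {
      anns <- c(anns, list(list(image_id = i,
                                bbox = c(b[["x_min"]], b[["y_min"]],
                                         b[["x_max"]] - b[["x_min"]],
                                         b[["y_max"]] - b[["y_min"]]),
                                category = attr(b, "kind") %||% "growth_plate")))
    }
  }
  jsonlite::write_json(list(images = images, annotations = anns), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @return \code{read_coco} returns a list with \code{images} (data frame)
#'   and per-image box lists under \code{fracture_boxes} /
#'   \code{confounder_boxes}. Round-trips with \code{write_coco} bit-exactly.
#' @export
read_coco <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- do.call(rbind, lapply(doc$images, function(im) {
    data.frame(id = im$id, file = im$file, patient_id = im$patient_id,
               height = im$height, width = im$width,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(images)
  fb <- replicate(n, list(), simplify = FALSE)
  cb <- replicate(n, list(), simplify = FALSE)
  for (a in doc$annotations) {
    bb <- as.numeric(unlist(a$bbox))
    b <- box(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
    i <- a$image_id
    if (identical(a$category, "fracture")) {
      fb[[i]] <- c(fb[[i]], list(b))
    } else {
      attr(b, "kind") <- a$category
      cb[[i]] <- c(cb[[i]], list(b))
    }
  }
  list(images = images, fracture_boxes = fb, confounder_boxes = cb)
}

#' ROI manifest CSV
#'
#' Persists the tabular part of ROI records (patches are recreated from the
#' source images): columns \code{image_file, x_min, y_min, x_max, y_max, s,
#' y, patient_id, provenance} plus \code{epoch_mined} for mined negatives.
#'
#' @param records List of ROI records (see \code{\link{build_roi_records}}).
#' @param path Output CSV path.
#' @param image_files Character vector mapping each record's scene index to
#'   a file name; defaults to \code{scene_<index>.png}.
#' @export
write_roi_manifest <- function(records, path, image_files = NULL) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      image_file = if (!is.null(image_files)) {
        image_files[r$scene_index]
      } else {
        sprintf("scene_%04d.png", r$scene_index %||% NA_integer_)
      },
      x_min = r$box[["x_min"]], y_min = r$box[["y_min"]],
      x_max = r$box[["x_max"]], y_max = r$box[["y_max"]],
      s = r$s, y = r$y, patient_id = r$patient_id,
      provenance = r$provenance,
      epoch_mined = r$epoch_mined %||% NA_integer_,
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_manifest
#' @return \code{read_roi_manifest} returns the manifest data frame.
#' @export
read_roi_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
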