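test_that("scene generation honours requested structure counts", {
  cfg0 <- scene_config(fracture_rate = 0, confounder_rates = c(0, 0, 0),
                       seed = 3)
  sc0 <- generate_scene(cfg0, "P001")
  expect_length(sc0$fracture_boxes, 0)
  expect_length(sc0$confounder_boxes, 0)

  cfg3 <- scene_config(n_bones = 3, fracture_rate = 1,
                       confounder_rates = c(0, 0, 0), seed = 4)
  sc3 <- generate_scene(cfg3, "P001")
  expect_length(sc3$fracture_boxes, 3)

  expect_error(scene_config(image_height = 32), "at least 64")
  expect_error(scene_config(fracture_rate = 1.2), "rates")
})

test_that("scene generation is bit-deterministic and produces valid boxes", {
  cfg <- scene_config(seed = 11)
  a <- generate_scene(cfg, "P007")
  b <- generate_scene(cfg, "P007")
  expect_identical(a, b)
  expect_true(all(a$image >= 0 & a$image <= 1))
  for (bx in c(a$fracture_boxes, a$confounder_boxes)) {
    expect_true(bx[["x_min"]] < bx[["x_max"]])
    expect_true(bx[["y_min"]] < bx[["y_max"]])
    expect_true(bx[["x_min"]] >= 0 && bx[["x_max"]] <= 256)
    expect_true(bx[["y_min"]] >= 0 && bx[["y_max"]] <= 256)
  }
})

test_that("cohorts have unique patient ids and are seed-sensitive", {
  cfg <- scene_config(seed = 2)
  coh <- generate_cohort(cfg, n_patients = 5, scenes_per_patient = 2)
  expect_length(coh, 10)
  pids <- vapply(coh, function(s) s$patient_id, character(1))
  expect_length(unique(pids), 5)
  expect_true(all(table(pids) == 2))

  cfg2 <- scene_config(seed = 3)
  coh2 <- generate_cohort(cfg2, 5, 2)
  expect_false(identical(coh[[1]]$image, coh2[[1]]$image))

  one <- generate_cohort(cfg, 1, 3)
  expect_length(unique(vapply(one, function(s) s$patient_id, character(1))), 1)
})

test_that("noiseless mock detector reproduces fracture boxes exactly", {
  cfg <- scene_config(n_bones = 2, fracture_rate = 1,
                      confounder_rates = c(0, 0, 0), seed = 21)
  sc <- generate_scene(cfg, "P001")
  det <- detector_config(jitter_sd = 0, fp_rate_confounder = 0,
                         fp_rate_random = 0, seed = 5)
  props <- mock_detect(sc, det)
  expect_length(props, length(sc$fracture_boxes))
  got <- boxes_to_matrix(lapply(props, function(p) p$box))
  want <- boxes_to_matrix(sc$fracture_boxes)
  # NMS orders proposals by confidence; compare as sets of rows
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ],
               tolerance = 1e-12)
})

test_that("retained confidences respect the threshold and NMS removes dups", {
  cfg <- scene_config(seed = 31)
  det <- detector_config(seed = 13)
  coh <- generate_cohort(cfg, 15)
  for (sc in coh) {
    props <- mock_detect(sc, det)
    confs <- vapply(props, function(p) p$conf, numeric(1))
    expect_true(all(confs >= det$conf_threshold & confs <= 1))
    if (length(props) > 1) {
      for (i in seq_along(props)) {
        for (j in seq_len(i - 1)) {
          expect_lte(iou(props[[i]]$box, props[[j]]$box), det$nms_iou)
        }
      }
    }
  }
})

test_that("detector recall at IoU 0.5 is high under default jitter", {
  cfg <- scene_config(seed = 5)
  det <- detector_config(seed = 9)
  matched <- 0L; total <- 0L
  for (sc in generate_cohort(cfg, 100)) {
    props <- mock_detect(sc, det)
    for (fb in sc$fracture_boxes) {
      total <- total + 1L
      if (length(props) > 0 &&
          max(vapply(props, function(p) iou(p$box, fb), numeric(1))) >= 0.5) {
        matched <- matched + 1L
      }
    }
  }
  expect_gte(matched / total, 0.95)
})

test_that("annotation writers round-trip bit-exactly", {
  cfg <- scene_config(seed = 41, fracture_rate = 1)
  sc <- generate_scene(cfg, "P003")
  tmp <- withr::local_tempdir()

  yolo <- file.path(tmp, "scene.txt")
  write_yolo(sc, yolo)
  back <- read_yolo(yolo, nrow(sc$image), ncol(sc$image))
  expect_equal(boxes_to_matrix(back$fracture_boxes),
               boxes_to_matrix(sc$fracture_boxes))
  expect_equal(vapply(back$confounder_boxes, attr, character(1), "kind"),
               vapply(sc$confounder_boxes, attr, character(1), "kind"))

  coco <- file.path(tmp, "ann.json")
  write_coco(list(sc), coco)
  cb <- read_coco(coco)
  expect_identical(cb$images$patient_id, "P003")
  expect_equal(boxes_to_matrix(cb$fracture_boxes[[1]]),
               boxes_to_matrix(sc$fracture_boxes))
  expect_equal(boxes_to_matrix(cb$confounder_boxes[[1]]),
               boxes_to_matrix(sc$confounder_boxes))

  pngf <- file.path(tmp, "scene.png")
  write_scene_png(sc, pngf)
  img <- read_scene_png(pngf)
  expect_equal(dim(img), dim(sc$image))
  expect_lt(max(abs(img - sc$image)), 1 / 255)
})
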