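test_that("degenerate scene specs produce exact output", {
  mh <- microhabitat("only", c(50, 5, 10), c(0, 0, 0), 1)
  sc <- generate_scene(scene_spec(32, 48, 0.8, list(mh), seed = 1))
  expect_true(all(sc$labels == 1L))
  expect_equal(dim(sc$lab), c(48, 32, 3))  # height x width x 3
  # sd 0: every pixel is exactly the mean
  expect_true(all(sc$lab[, , 1] == 50))
  expect_true(all(sc$lab[, , 2] == 5))
  expect_true(all(sc$lab[, , 3] == 10))
})

test_that("scene weights are respected and scenes are reproducible", {
  for (seed in 1:5) {
    sp <- separated_spec(256, seed = seed)
    sc <- generate_scene(sp)
    frac <- tabulate(sc$labels, 4) / length(sc$labels)
    expect_true(all(abs(frac - 0.25) < 0.05))
  }
  sp <- separated_spec(128, seed = 3)
  expect_identical(generate_scene(sp)$labels, generate_scene(sp)$labels)
  sp2 <- separated_spec(128, seed = 4)
  expect_false(identical(generate_scene(sp)$labels, generate_scene(sp2)$labels))
})

test_that("invalid scene specs are rejected", {
  mh <- list(microhabitat("a", c(50, 0, 0), weight = 0.6),
             microhabitat("b", c(60, 0, 0), weight = 0.6))
  expect_error(scene_spec(64, 64, 0.8, mh), "sum to 1")
  expect_error(microhabitat("a", c(50, 0, 0), sd_lab = c(-1, 0, 0)),
               "non-negative")
  expect_error(scene_spec(0, 64, 0.8, list(microhabitat("a", c(50, 0, 0)))),
               "> 0")
})

test_that("per-label colour means converge to the generating means", {
  sp <- separated_spec(256, seed = 2, sd = 3)
  sc <- generate_scene(sp)
  for (k in 1:4) {
    n_k <- sum(sc$labels == k)
    for (ch in 1:3) {
      emp <- mean(sc$lab[, , ch][sc$labels == k])
      tru <- sp$microhabitats[[k]]$mean_lab[ch]
      expect_lt(abs(emp - tru), 3 * 3 / sqrt(n_k))
    }
  }
})

test_that("target placement scales the silhouette by the scene resolution", {
  mh <- microhabitat("only", c(50, 0, 0), weight = 1)
  sc8 <- generate_scene(scene_spec(400, 400, 0.8, list(mh), seed = 1))
  sc8 <- place_target(sc8, height_mm = 400)
  rows <- which(rowSums(sc8$target_mask) > 0)
  expect_equal(diff(range(rows)) + 1L, 320L)  # 400 mm at 0.8 px/mm
  expect_true(all(is.na(sc8$labels[sc8$target_mask])))
  expect_true(all(!is.na(sc8$labels[!sc8$target_mask])))

  sc3 <- generate_scene(scene_spec(200, 200, 0.3, list(mh), seed = 1))
  sc3 <- place_target(sc3, height_mm = 400)
  rows <- which(rowSums(sc3$target_mask) > 0)
  expect_equal(diff(range(rows)) + 1L, 120L)  # 400 mm at 0.3 px/mm

  # empty silhouette leaves the scene unchanged
  sc0 <- generate_scene(scene_spec(64, 64, 0.3, list(mh), seed = 1))
  sc0b <- place_target(sc0, silhouette = matrix(FALSE, 10, 10))
  expect_identical(sc0b, sc0)
  # oversized target is refused
  expect_error(place_target(sc0, height_mm = 5000), "fit")
})

test_that("hare silhouette has the right frame and orientation behaviour", {
  m <- hare_silhouette(320)
  expect_equal(dim(m), c(320, 208))
  expect_true(any(m[1, ]) && any(m[320, ]))  # spans full height
  expect_identical(hare_silhouette(64, flip = TRUE)[, 42:1],
                   hare_silhouette(64))
})

test_that("detection trials follow the transformed-scale hazard law", {
  # huge baseline hazard: everything detected essentially at d_max
  d_hi <- trial_design(n_subjects = 5, baseline_hazard = 1e7,
                       subject_sd = 0, position_sd = 0, seed = 2)
  tr <- generate_detection_trials(d_hi)
  expect_true(all(tr$detected))
  expect_true(all(abs(tr$d_detect - tr$d_max) / tr$d_max < 0.01))
  # zero baseline hazard: everything censored
  d_lo <- trial_design(n_subjects = 5, baseline_hazard = 0, seed = 2)
  expect_true(all(!generate_detection_trials(d_lo)$detected))
  # detected distances always lie in [d_min, d_max]
  d_mid <- trial_design(seed = 5)
  tr <- generate_detection_trials(d_mid)
  det <- tr[tr$detected, ]
  expect_true(all(det$d_detect >= det$d_min & det$d_detect <= det$d_max))
})

test_that("censoring fraction decreases in the baseline hazard and seeds reproduce", {
  miss <- vapply(c(0.5, 2.5, 10), function(h) {
    d <- trial_design(baseline_hazard = h, seed = 9)
    mean(!generate_detection_trials(d)$detected)
  }, 0.0)
  expect_true(all(diff(miss) < 0))
  d <- trial_design(seed = 13)
  expect_identical(generate_detection_trials(d), generate_detection_trials(d))
})

test_that("trial designs are validated", {
  expect_error(trial_design(subject_sd = -1), ">= 0")
  expect_error(trial_design(d_min_range = c(1, 40)), "below")
})

test_that("scene specs round-trip through YAML and scenes write to PNG", {
  tmp <- withr::local_tempdir()
  spec_file <- file.path(tmp, "spec.yaml")
  yaml::write_yaml(list(
    width_px = 48, height_px = 32, px_per_mm = 0.8, seed = 7,
    microhabitats = list(
      list(name = "grass", mean_lab = c(52, -16, 30), sd_lab = c(2, 2, 2),
           weight = 0.5, patch_scale_px = 4),
      list(name = "litter", mean_lab = c(44, 8, 24), sd_lab = c(2, 2, 2),
           weight = 0.5, patch_scale_px = 4))), spec_file)
  sp <- read_scene_spec(spec_file)
  expect_s3_class(sp, "scene_spec")
  expect_equal(habitat_names(sp), c("grass", "litter"))
  expect_equal(sp$width_px, 48L)
  sc <- place_target(generate_scene(sp), height_mm = 20)
  paths <- write_scene(sc, tmp, "demo")
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_equal(dim(img), c(32, 48, 3))
  mask <- png::readPNG(paths[3])
  expect_equal(mask == 1, unname(sc$target_mask))
})
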