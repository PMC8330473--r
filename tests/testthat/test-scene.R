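make_lab <- function(L, a = 0, b = 0, h = 32, w = 32) {
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- L; arr[, , 2] <- a; arr[, , 3] <- b
  arr
}

test_that("ranked smoothing has a uniform fixed point and preserves edges", {
  img <- make_lab(50, 5, -5)
  expect_equal(ranked_smooth(img), img)
  # two homogeneous half-planes far above the gates stay put
  half <- make_lab(30, 0, 0, 40, 40)
  half[, 21:40, 1] <- 70   # delta L 40 across the boundary
  sm <- ranked_smooth(half)
  expect_lt(delta_e_ciede2000(
    region_mean_lab(sm, cbind(matrix(TRUE, 40, 20), matrix(FALSE, 40, 20))),
    c(30, 0, 0)), 0.5)
  expect_lt(delta_e_ciede2000(
    region_mean_lab(sm, cbind(matrix(FALSE, 40, 20), matrix(TRUE, 40, 20))),
    c(70, 0, 0)), 0.5)
})

test_that("ranked smoothing removes sub-threshold outlier pixels", {
  set.seed(21)
  img <- make_lab(50, 0, 0, 64, 64)
  out_idx <- sample(64 * 64, 41)  # 1% isolated outliers
  plane <- img[, , 1]
  plane[out_idx] <- 55            # 5 L units: inside the luminance gate
  img[, , 1] <- plane
  sm <- ranked_smooth(img)
  before <- sum(abs(img[, , 1] - 50) > 2)
  after <- sum(abs(sm[, , 1] - 50) > 2)
  expect_gte(before, 41)
  expect_lte(after, 0.1 * before)
})

test_that("the naive Bayes classifier follows its probability contract", {
  gA <- microhabitat("A", c(40, 0, 0), c(2, 2, 2), 0.5)
  gB <- microhabitat("B", c(60, 0, 0), c(2, 2, 2), 0.5)
  clf <- fit_classifier(list(gA, gB))
  # pixel at a class mean goes to that class
  img <- make_lab(40, 0, 0, 2, 2)
  expect_true(all(classify_pixels(clf, img) == 1L))
  img[, , 1] <- 60
  expect_true(all(classify_pixels(clf, img) == 2L))
  # posteriors normalise
  set.seed(5)
  p <- posterior_probs(clf, cbind(runif(20, 30, 70), rnorm(20), rnorm(20)))
  expect_equal(rowSums(p), rep(1, 20))
  # degenerate prior forces a single class
  clf10 <- fit_classifier(list(gA, gB), priors = c(1, 0))
  expect_true(all(classify_pixels(clf10, img) == 1L))
  # exact ties break to the lowest index
  clf_tie <- fit_classifier(list(microhabitat("A", c(50, 0, 0), c(2, 2, 2)),
                                 microhabitat("B", c(50, 0, 0), c(2, 2, 2))),
                            priors = c(0.5, 0.5))
  expect_true(all(classify_pixels(clf_tie, img) == 1L))
  # exclusion masks become NA labels
  lab <- classify_pixels(clf, img, exclude = matrix(TRUE, 2, 2))
  expect_true(all(is.na(lab)))
  expect_error(fit_classifier(list(gA)), "two groups")
  expect_error(fit_classifier(list(gA, gB), priors = c(0.4, 0.4)), "sum to 1")
})

test_that("segmentation recovers well-separated synthetic ground truth", {
  sp <- separated_spec(128, seed = 4)
  sc <- generate_scene(sp)
  clf <- fit_classifier(sp$microhabitats)
  got <- classify_pixels(clf, sc$lab)
  expect_gte(mean(got == sc$labels), 0.99)
  # accuracy degrades monotonically as separation shrinks
  acc <- vapply(c(2, 5, 10), function(s) {
    spx <- separated_spec(96, seed = 4, sd = s)
    scx <- generate_scene(spx)
    mean(classify_pixels(fit_classifier(spx$microhabitats), scx$lab) ==
           scx$labels)
  }, 0.0)
  expect_true(all(diff(acc) < 0))
})

test_that("particle analysis counts connected patches correctly", {
  uni <- matrix(1L, 100, 100)
  pt <- particle_analysis(uni)
  expect_equal(nrow(pt), 1L)
  expect_equal(pt$area_px, 10000L)
  # checkerboard under 4-connectivity: every cell is its own patch
  chk <- matrix(0L, 8, 8)
  chk <- ((row(chk) + col(chk)) %% 2L) + 1L
  pt4 <- particle_analysis(chk, connectivity = 4)
  expect_equal(nrow(pt4), 64L)
  expect_true(all(pt4$area_px == 1L))
  # under 8-connectivity the two colours form two diagonal patches
  pt8 <- particle_analysis(chk, connectivity = 8)
  expect_equal(nrow(pt8), 2L)
  expect_true(all(pt8$area_px == 32L))
  # NA pixels belong to no patch
  chk[1, 1] <- NA
  ptNA <- particle_analysis(chk, connectivity = 4)
  expect_equal(sum(ptNA$area_px), 63L)
})

test_that("median patch area grows with the generator's patch scale", {
  med <- function(scale, seed) {
    sp <- separated_spec(192, seed = seed, patch_scale = scale)
    sc <- generate_scene(sp)
    lab <- sc$labels
    attr(lab, "habitats") <- habitat_names(sp)
    median(particle_analysis(lab)$area_px)
  }
  for (seed in 1:5) expect_lt(med(8, seed), med(32, seed))
})

test_that("near zone matches closed-form dilation arithmetic", {
  target <- matrix(FALSE, 60, 60)
  target[26:35, 26:35] <- TRUE  # 10 x 10 square
  nz <- near_zone_mask(target, band_width_px = 3, exclusion_px = 1)
  expect_equal(sum(nz), 18^2 - 12^2)  # 180 px
  expect_true(!any(nz & target))
  # matches the brute-force Chebyshev-distance oracle
  expect_identical(nz, oracle_near_zone(target, 3, 1))
  # irregular target against the oracle too
  target[20:22, 40:55] <- TRUE
  expect_identical(near_zone_mask(target, 4, 2), oracle_near_zone(target, 4, 2))
  # zero-width band gives an empty mask
  expect_false(any(near_zone_mask(target, 0, 1)))
  expect_error(near_zone_mask(target, -1), ">= 0")
})

test_that("contrast predictors resolve near and whole backgrounds", {
  img <- make_lab(50, 0, 0, 80, 80)
  target <- matrix(FALSE, 80, 80)
  target[36:45, 36:45] <- TRUE
  # uniform background equal to the target: both contrasts zero
  cp <- contrast_predictors(c(50, 0, 0), img, target, 10, 1)
  expect_equal(cp$delta_e_near, 0)
  expect_equal(cp$delta_e_whole, 0)
  # uniform background, any colour: near and whole coincide
  cp2 <- contrast_predictors(c(60, 10, 0), img, target, 10, 1)
  expect_equal(cp2$delta_e_near, cp2$delta_e_whole)
  expect_gt(cp2$delta_e_near, 0)
  # habitat A ringing the target, habitat B beyond: near tracks A,
  # whole lies between the contrast to A and to B
  ring <- make_lab(70, 0, 0, 80, 80)   # B far field everywhere
  nz <- near_zone_mask(target, 12, 1)
  plane <- ring[, , 1]
  plane[nz] <- 40                      # A in the near zone
  ring[, , 1] <- plane
  cp3 <- contrast_predictors(c(45, 0, 0), ring, target, 12, 1)
  deA <- delta_e_ciede2000(c(45, 0, 0), c(40, 0, 0))
  deB <- delta_e_ciede2000(c(45, 0, 0), c(70, 0, 0))
  expect_equal(cp3$delta_e_near, deA, tolerance = 1e-6)
  expect_gt(cp3$delta_e_whole, cp3$delta_e_near)
  expect_lt(cp3$delta_e_whole, deB)
  expect_error(contrast_predictors(c(50, 0, 0), img, matrix(TRUE, 80, 80), 5, 0),
               "empty")
})

test_that("contrast predictors are invariant to image translation", {
  set.seed(9)
  img <- array(rnorm(40 * 40 * 3, 50, 5), dim = c(40, 40, 3))
  target <- matrix(FALSE, 40, 40)
  target[18:22, 18:22] <- TRUE
  cp <- contrast_predictors(c(55, 2, 2), img, target, 5, 1)
  sh <- function(m, d) rbind(m[(nrow(m) - d + 1):nrow(m), ], m[1:(nrow(m) - d), ])
  img2 <- array(0, dim = dim(img))
  for (ch in 1:3) img2[, , ch] <- sh(img[, , ch], 7)
  cp2 <- contrast_predictors(c(55, 2, 2), img2, sh(target, 7), 5, 1)
  expect_equal(cp$delta_e_near, cp2$delta_e_near, tolerance = 1e-12)
  expect_equal(cp$delta_e_whole, cp2$delta_e_whole, tolerance = 1e-12)
})

test_that("habitat proportions sum to one and respect regions", {
  lab <- matrix(1L, 10, 10)
  lab[, 6:10] <- 2L
  attr(lab, "habitats") <- c("A", "B")
  p <- habitat_proportions(lab)
  expect_equal(unname(p), c(0.5, 0.5))
  expect_equal(sum(p), 1)
  region <- matrix(FALSE, 10, 10); region[, 1:5] <- TRUE
  expect_equal(unname(habitat_proportions(lab, region)), c(1, 0))
  # near-zone proportion of the ringing habitat exceeds the whole-image one
  lab2 <- matrix(2L, 40, 40)
  target <- matrix(FALSE, 40, 40); target[18:22, 18:22] <- TRUE
  ring <- near_zone_mask(target, 4, 0)
  lab2[ring] <- 1L
  lab2[target] <- NA_integer_
  attr(lab2, "habitats") <- c("A", "B")
  p_near <- habitat_proportions(lab2, near_zone_mask(target, 4, 0))
  p_whole <- habitat_proportions(lab2)
  expect_gt(p_near[["A"]], p_whole[["A"]])
  lab2[] <- NA_integer_
  expect_error(habitat_proportions(lab2), "no labelled")
})
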