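# Volumetric preprocessing: flip, smooth, normalize, extract — each checked
# against constructions with exactly known answers.

make_lr_table <- function() {
  # two left/right region pairs plus a midline reference
  tab <- data.frame(
    region_id = 1:5,
    name = c("A_L", "B_L", "A_R", "B_R", "Ref"),
    hemisphere = c("left", "left", "right", "right", "midline"),
    category = c("neocortical", "neocortical", "neocortical", "neocortical",
                 "reference"),
    is_seed = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    is_reference = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  mcnet:::validate_region_table(tab)
  tab
}

test_that("flip is an involution applied only to right-focus images", {
  vol <- array(stats::rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  right <- subject_image(vol, "s1", focus_side = "right")
  once <- flip_lr(right)
  expect_false(identical(once$volume, vol))
  expect_identical(flip_lr(once)$volume, vol)
  left <- subject_image(vol, "s2", focus_side = "left")
  expect_identical(flip_lr(left)$volume, vol)
  unknown <- subject_image(vol, "s3", focus_side = "right",
                           lr_first_axis = NA)
  expect_error(flip_lr(unknown), class = "mcnet_orientation_error")
})

test_that("flipping a lateralized phantom moves right-side uptake to the left", {
  tab <- make_lr_table()
  u <- c(A_L = 1, B_L = 1, A_R = 2, B_R = 2)
  ph <- simulate_phantom(tab, u, phantom_spec(grid = c(8, 9, 9)))
  img <- subject_image(ph$image, "s1", focus_side = "right")
  flipped <- flip_lr(img)
  # after flipping, the left-labelled blocks hold the right-side value 2.0
  expect_equal(mean(flipped$volume[ph$labels == 1]), 2)
  expect_equal(mean(flipped$volume[ph$labels == 3]), 1)
})

test_that("smoothing leaves constants unchanged and conserves interior mass", {
  vol <- array(3.7, dim = c(12, 12, 12))
  img <- subject_image(vol, "s1")
  sm <- smooth_gaussian(img, fwhm_mm = 5)
  expect_equal(sm$volume, vol, tolerance = 1e-10)
  # an interior blob, far from boundaries, keeps its total mass
  blob <- array(0, dim = c(31, 31, 31))
  blob[14:18, 14:18, 14:18] <- 2
  smb <- smooth_gaussian(subject_image(blob, "s2"), fwhm_mm = 3)
  expect_equal(sum(smb$volume), sum(blob), tolerance = sum(blob) * 1e-3)
})

test_that("smoothing a unit impulse matches brute-force 3-D convolution", {
  n <- 21
  vol <- array(0, dim = c(n, n, n))
  vol[11, 11, 11] <- 1
  fwhm <- 2 # voxels (voxel size 1 mm)
  sm <- smooth_gaussian(subject_image(vol, "s1"), fwhm_mm = fwhm)
  # oracle: direct dense convolution with the same truncated kernel
  s <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * s))
  w1 <- stats::dnorm(-r:r, sd = s)
  w1 <- w1 / sum(w1)
  k3 <- outer(outer(w1, w1), w1)
  dim(k3) <- c(length(w1), length(w1), length(w1))
  oracle <- array(0, dim = dim(vol))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    oracle[11 + dx, 11 + dy, 11 + dz] <-
      k3[dx + r + 1, dy + r + 1, dz + r + 1]
  }
  expect_equal(sm$volume, oracle, tolerance = 1e-12)
  expect_error(smooth_gaussian(subject_image(vol, "s1"), fwhm_mm = 0),
               class = "mcnet_validation_error")
})

test_that("reference normalization rescales to unit reference mean", {
  tab <- tiny_table()
  u <- c(2, 1.5, 0.5, 1.2, 0.8)
  ph <- simulate_phantom(tab, u, phantom_spec(grid = c(10, 12, 12),
                                              reference_uptake = 2.5))
  img <- subject_image(ph$image, "s1")
  ref_id <- tab$region_id[tab$is_reference]
  norm1 <- normalize_to_reference(img, ph$labels, ref_id)
  expect_equal(mean(norm1$volume[ph$labels == ref_id]), 1, tolerance = 1e-12)
  # global rescaling of the input changes nothing after normalization
  scaled <- img
  scaled$volume <- scaled$volume * 3.7
  norm2 <- normalize_to_reference(scaled, ph$labels, ref_id)
  expect_equal(norm2$volume, norm1$volume, tolerance = 1e-12)
  # degenerate reference
  zero <- img
  zero$volume[ph$labels == ref_id] <- 0
  expect_error(normalize_to_reference(zero, ph$labels, ref_id),
               class = "mcnet_normalization_error")
})

test_that("extraction recovers a noiseless phantom row exactly", {
  tab <- tiny_table()
  u <- c(Insula = 2, Neocortical_02 = 1.5, Neocortical_03 = 0.5,
         Subcortical_01 = 1.2, Brainstem_01 = 0.8)
  ph <- simulate_phantom(tab, u, phantom_spec(grid = c(10, 12, 12)))
  m <- extract_uptake(list(subject_image(ph$image, "s1")), ph$labels, tab)
  expect_equal(m["s1", ], u)
  expect_equal(colnames(m), mcnet:::region_nodes(tab)$name)
  # missing region in the label volume is an informative error
  lab2 <- ph$labels
  lab2[lab2 == 2L] <- 0L
  err <- expect_error(
    extract_uptake(list(subject_image(ph$image, "s1")), lab2, tab),
    class = "mcnet_extraction_error")
  expect_match(conditionMessage(err), "Neocortical_02")
})

test_that("noisy extraction is accurate to the standard error of the mean", {
  tab <- make_region_table(1, 1, 1, include_reference = FALSE)
  truth <- c(1, 2, 3)
  ph <- simulate_phantom(tab, truth,
                         phantom_spec(grid = c(20, 20, 20), noise_sd = 0.1,
                                      block = c(10, 10), seed = 8))
  m <- extract_uptake(list(subject_image(ph$image, "s1")), ph$labels, tab)
  expect_true(all(abs(m["s1", ] - truth) < 0.02))
})

test_that("extraction after flipping equals extraction with L/R columns swapped", {
  tab <- make_lr_table()
  u <- c(A_L = 1.1, B_L = 0.9, A_R = 1.8, B_R = 1.4)
  ph <- simulate_phantom(tab, u, phantom_spec(grid = c(8, 9, 9)))
  plain <- extract_uptake(list(subject_image(ph$image, "s1")), ph$labels, tab)
  flip <- flip_lr(subject_image(ph$image, "s1", focus_side = "right"))
  flipped <- extract_uptake(list(flip), ph$labels, tab)
  expect_equal(unname(flipped[1, c("A_L", "B_L", "A_R", "B_R")]),
               unname(plain[1, c("A_R", "B_R", "A_L", "B_L")]))
})

test_that("the preprocessing chain composes: flip, smooth, normalize, extract", {
  tab <- tiny_table()
  u <- c(Insula = 2, Neocortical_02 = 1.5, Neocortical_03 = 0.5,
         Subcortical_01 = 1.2, Brainstem_01 = 0.8)
  ph <- simulate_phantom(tab, u, phantom_spec(grid = c(16, 24, 24),
                                              reference_uptake = 2))
  img <- subject_image(ph$image, "s1", focus_side = "none")
  ref_id <- tab$region_id[tab$is_reference]
  pre <- preprocess_subject(img, ph$labels, ref_id, fwhm_mm = NULL)
  m <- extract_uptake(list(pre), ph$labels, tab)
  expect_equal(m["s1", ], u / 2, tolerance = 1e-12)
})
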