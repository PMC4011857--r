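# single bright sheet in a uniform parenchyma block (the minimal detection
# scenario: +150 HU contrast, mildly tilted so all rasterisation effects
# are exercised)
slab_fixture <- function(noise_sd = 0, seed = 1) {
  d <- c(48, 48, 48)
  sp <- c(0.7, 0.7, 0.625)
  arr <- array(-850, d)
  g <- expand.grid(i = 5:44, j = 5:44)
  k <- round(24 + (g$j - 24) * 0.3 * sp[2] / sp[3])
  vox <- cbind(g$i, g$j, k)
  arr[(vox[, 3] - 1) * d[1] * d[2] + (vox[, 2] - 1) * d[1] + vox[, 1]] <- -700
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(prod(d), sd = noise_sd), d)
  }
  list(volume = image_volume(arr, sp), sheet = vox,
       mask = array(TRUE, d), d = d, sp = sp)
}

test_that("uniform volumes yield zero plateness", {
  v <- image_volume(array(5, c(24, 24, 24)), c(1, 1, 1))
  pm <- compute_plateness(v, scales = 1, lung_mask = array(TRUE, c(24, 24, 24)))
  expect_equal(max(pm$response), 0)
})

test_that("a bright sheet scores high on-sheet and low off-sheet", {
  fx <- slab_fixture()
  pm <- compute_plateness(fx$volume, lung_mask = fx$mask)
  lin <- (fx$sheet[, 3] - 1) * fx$d[1] * fx$d[2] +
    (fx$sheet[, 2] - 1) * fx$d[1] + fx$sheet[, 1]
  expect_gte(mean(pm$response[lin] > 0.5), 0.95)
  # voxels at least 3 mm from the sheet (same columns, offset in z)
  far <- cbind(fx$sheet[, 1], fx$sheet[, 2], fx$sheet[, 3] + 8)
  far <- far[far[, 3] <= fx$d[3], , drop = FALSE]
  lfar <- (far[, 3] - 1) * fx$d[1] * fx$d[2] + (far[, 2] - 1) * fx$d[1] +
    far[, 1]
  expect_true(all(pm$response[lfar] < 0.1))
})

test_that("a bright ball is suppressed relative to a sheet", {
  d <- c(48, 48, 48)
  sp <- c(0.7, 0.7, 0.625)
  arr <- array(-850, d)
  ctr <- c(24, 24, 24) * sp
  g <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  rr <- sqrt(colSums((t(g - 1) * sp - ctr)^2))
  arr[rr <= 5] <- -700
  pm_ball <- compute_plateness(image_volume(arr, sp),
                               lung_mask = array(TRUE, d))
  ball_mean <- mean(pm_ball$response[rr <= 5])
  fx <- slab_fixture()
  pm_sheet <- compute_plateness(fx$volume, lung_mask = fx$mask)
  lin <- (fx$sheet[, 3] - 1) * fx$d[1] * fx$d[2] +
    (fx$sheet[, 2] - 1) * fx$d[1] + fx$sheet[, 1]
  expect_lt(ball_mean, mean(pm_sheet$response[lin]))
})

test_that("plateness input contracts are enforced", {
  v <- image_volume(array(0, c(16, 16, 16)), c(0.7, 0.7, 0.625))
  m <- array(TRUE, c(16, 16, 16))
  expect_error(compute_plateness(v, scales = 0.2, lung_mask = m),
               "half the smallest")
  expect_error(compute_plateness(v, scales = numeric(0), lung_mask = m),
               "at least one scale")
  expect_error(compute_plateness(v, scales = 1, lung_mask = m & FALSE),
               "empty")
})

test_that("extraction recovers the sheet and obeys its contracts", {
  fx <- slab_fixture()
  pm <- compute_plateness(fx$volume, lung_mask = fx$mask)
  det <- extract_fissure_voxels(pm)
  expect_gte(dice_overlap(det, fx$sheet, fx$d), 0.9)

  # monotone in threshold: raising it never adds voxels
  lin <- function(v) (v[, 3] - 1) * fx$d[1] * fx$d[2] +
    (v[, 2] - 1) * fx$d[1] + v[, 1]
  det_hi <- extract_fissure_voxels(pm, threshold = 0.7)
  expect_true(all(lin(det_hi) %in% lin(det)))

  # all-zero plateness gives a legal empty result
  v0 <- image_volume(array(0, c(16, 16, 16)), fx$sp)
  pm0 <- compute_plateness(v0, scales = 1,
                           lung_mask = array(TRUE, c(16, 16, 16)))
  expect_identical(nrow(extract_fissure_voxels(pm0)), 0L)
})

test_that("small components fall to the minimum-area filter", {
  # hand-built map: one supra-threshold voxel in an otherwise silent field
  d <- c(24, 24, 24)
  resp <- array(0, d)
  resp[12, 12, 12] <- 0.9
  pm <- structure(list(response = resp, scale_used = array(1, d),
                       spacing = c(0.7, 0.7, 0.625),
                       mask_index = which(resp >= 0),
                       normals = matrix(rep(c(0, 0, 1),
                                            each = prod(d)), ncol = 3)),
                  class = "plateness_map")
  expect_identical(nrow(extract_fissure_voxels(pm, min_component_mm2 = 20)), 0L)
  expect_identical(nrow(extract_fissure_voxels(pm, min_component_mm2 = 0.1)), 1L)
})

test_that("detection approaches the truth as noise vanishes", {
  spec0 <- coarse_spec(target_integrity = c(80, 70, 90), seed = 21)
  ph <- generate_phantom(spec0)
  pm <- compute_plateness(ph$volume, lung_mask = ph$truth$lung_mask)
  det <- extract_fissure_voxels(pm)
  truth <- do.call(rbind, ph$truth$fissure_truth)
  d0 <- dice_overlap(det, truth, spec0$grid_shape)
  expect_gte(d0, 0.85)

  spec_n <- coarse_spec(target_integrity = c(80, 70, 90), seed = 21,
                        noise_sd = 50)
  phn <- generate_phantom(spec_n)
  pmn <- compute_plateness(phn$volume, lung_mask = phn$truth$lung_mask)
  detn <- extract_fissure_voxels(pmn)
  expect_gte(d0, dice_overlap(detn, truth, spec_n$grid_shape) - 0.02)
})
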