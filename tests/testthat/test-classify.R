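test_that("split_lungs uses side labels when present and geometry otherwise", {
  ph <- generate_phantom(coarse_spec())
  lungs <- split_lungs(ph$truth$lung_mask)
  expect_identical(nrow(lungs$right), sum(ph$truth$lung_mask == 1L))
  expect_identical(nrow(lungs$left), sum(ph$truth$lung_mask == 2L))

  # binary mask: split by the two largest components ordered left-right
  bin <- (ph$truth$lung_mask > 0) * 1L
  lungs2 <- split_lungs(bin)
  expect_equal(sort(fissint:::voxel_linear(lungs2$right, dim(bin))),
               sort(fissint:::voxel_linear(lungs$right, dim(bin))))

  # mirroring the volume along the left-right axis swaps the sides
  mir <- bin[dim(bin)[1]:1, , ]
  lungs3 <- split_lungs(mir)
  expect_equal(nrow(lungs3$right), nrow(lungs2$left))
  expect_gt(mean(lungs3$left[, 1]), mean(lungs3$right[, 1]))
})

test_that("a single merged component without labels is an error", {
  m <- array(0L, c(16, 16, 16))
  m[4:12, 4:12, 4:12] <- 1L
  expect_error(split_lungs(m), "fewer than 2")
})

test_that("phantom sheets receive their anatomical labels", {
  spec <- coarse_spec(target_integrity = c(85, 85, 85), seed = 2)
  ph <- generate_phantom(spec)
  sp <- spec$spacing
  lungs <- split_lungs(ph$truth$lung_mask)

  right <- classify_patches(list(ph$truth$fissure_truth$RHF,
                                 ph$truth$fissure_truth$ROF),
                            side = "right", lung_voxels = lungs$right,
                            spacing = sp)
  expect_setequal(names(right), c("RHF", "ROF"))
  expect_identical(right$RHF$label, "RHF")
  expect_equal(nrow(right$RHF$voxels), nrow(ph$truth$fissure_truth$RHF))
  expect_equal(nrow(right$ROF$voxels), nrow(ph$truth$fissure_truth$ROF))

  left <- classify_patches(list(ph$truth$fissure_truth$LOF), side = "left")
  expect_identical(names(left), "LOF")
})

test_that("labels are invariant under rigid translation", {
  spec <- coarse_spec(target_integrity = c(85, 85, 85), seed = 2)
  ph <- generate_phantom(spec)
  lungs <- split_lungs(ph$truth$lung_mask)
  shift <- function(v) sweep(v, 2, c(3, 2, 1), "+")
  a <- classify_patches(list(ph$truth$fissure_truth$RHF,
                             ph$truth$fissure_truth$ROF),
                        side = "right", lung_voxels = lungs$right,
                        spacing = spec$spacing)
  b <- classify_patches(lapply(list(ph$truth$fissure_truth$RHF,
                                    ph$truth$fissure_truth$ROF), shift),
                        side = "right", lung_voxels = shift(lungs$right),
                        spacing = spec$spacing)
  expect_setequal(names(a), names(b))
  expect_equal(nrow(a$RHF$voxels), nrow(b$RHF$voxels))
})

test_that("every component gets exactly one label", {
  spec <- coarse_spec(target_integrity = c(50, 50, 50), seed = 13)
  ph <- generate_phantom(spec)
  lungs <- split_lungs(ph$truth$lung_mask)
  comps <- list(ph$truth$fissure_truth$ROF[1:50, ],
                ph$truth$fissure_truth$ROF[51:120, ],
                ph$truth$fissure_truth$RHF)
  out <- classify_patches(comps, side = "right", lung_voxels = lungs$right,
                          spacing = spec$spacing)
  total <- sum(vapply(out, function(p) nrow(p$voxels), 1L))
  expect_identical(total, sum(vapply(comps, nrow, 1L)))
})
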