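test_that("undefected phantom has fully complete fissures", {
  ph <- generate_phantom(coarse_spec(target_integrity = c(100, 100, 100)))
  expect_equal(unname(ph$truth$true_integrity), c(100, 100, 100))
  expect_equal(ph$truth$true_elf, 100)
  for (lb in c("ROF", "RHF", "LOF"))
    expect_identical(ph$truth$fissure_truth[[lb]],
                     ph$truth$boundary_truth[[lb]])
})

test_that("carved integrity hits its target and respects the subset law", {
  spec <- phantom_spec(target_integrity = c(70, 50, 80), seed = 1)
  ph <- generate_phantom(spec)
  expect_true(all(abs(ph$truth$true_integrity - c(70, 50, 80)) <= 2))
  d <- spec$grid_shape
  for (lb in c("ROF", "RHF", "LOF")) {
    fis <- ph$truth$fissure_truth[[lb]]
    bnd <- ph$truth$boundary_truth[[lb]]
    lf <- (fis[, 3] - 1) * d[1] * d[2] + (fis[, 2] - 1) * d[1] + fis[, 1]
    lb_ <- (bnd[, 3] - 1) * d[1] * d[2] + (bnd[, 2] - 1) * d[1] + bnd[, 1]
    expect_true(all(lf %in% lb_))
    # stored truth matches recomputation from the masks
    rec <- 100 * surface_area(fis, spec$spacing) /
      surface_area(bnd, spec$spacing)
    expect_equal(unname(ph$truth$true_integrity[[lb]]), min(rec, 100),
                 tolerance = 1e-10)
  }
})

test_that("marginal defects are supported and still hit their target", {
  ph <- generate_phantom(coarse_spec(target_integrity = c(60, 60, 60),
                                     allow_marginal = TRUE, seed = 4))
  expect_true(all(abs(ph$truth$true_integrity - 60) <= 2))
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- coarse_spec(target_integrity = c(70, 50, 80), noise_sd = 30,
                      seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$fissure_truth, b$truth$fissure_truth)
  expect_identical(a$truth$lobe_mask, b$truth$lobe_mask)
})

test_that("lobe mask partitions the lungs into five lobes", {
  ph <- generate_phantom(coarse_spec(target_integrity = c(70, 50, 80)))
  inside <- ph$truth$lung_mask > 0
  expect_identical(sort(unique(as.integer(ph$truth$lobe_mask[inside]))), 1:5)
  expect_true(all(ph$truth$lobe_mask[!inside] == 0L))
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(target_integrity = c(110, 50, 50)), "0, 100")
  expect_error(phantom_spec(spacing = c(0.7, -1, 0.625)), "positive")
  expect_error(generate_phantom(phantom_spec(grid_shape = c(8, 8, 8))),
               "too small")
})

test_that("carve_defects honors the trivial targets and hits 60%", {
  sheet <- plane_sheet(100, 50)
  sp <- c(0.7, 0.7, 0.625)
  expect_identical(carve_defects(sheet, 100, 3, seed = 1, spacing = sp),
                   fissint:::as_voxel_matrix(sheet))
  expect_equal(nrow(carve_defects(sheet, 0, 3, seed = 1, spacing = sp)), 0)
  kept <- carve_defects(sheet, 60, 4, seed = 2, spacing = sp)
  frac <- nrow(kept) * 0.49 / (nrow(sheet) * 0.49)
  expect_gte(frac, 0.58)
  expect_lte(frac, 0.62)
})

test_that("cohort simulator lands subjects in their intended GOLD bands", {
  subj <- simulate_cohort(10, gold_mix = c(1, 0, 0, 0, 0), seed = 3)
  spiro <- do.call(rbind, lapply(subj, `[[`, "spirometry"))
  expect_true(all(classify_gold(spiro$fev1_fvc_pct,
                                spiro$fev1_pct_pred) == "non-COPD"))

  subj <- simulate_cohort(200, seed = 5)
  spiro <- do.call(rbind, lapply(subj, `[[`, "spirometry"))
  got <- classify_gold(spiro$fev1_fvc_pct, spiro$fev1_pct_pred)
  expect_identical(as.character(got), as.character(spiro$intended_gold))
  # intended counts within multinomial sampling error of the default mix
  p <- c(0.387, 0.145, 0.246, 0.110, 0.112)
  cnt <- as.integer(table(got))
  expect_true(all(abs(cnt - 200 * p) <= 4 * sqrt(200 * p * (1 - p))))
})

test_that("cohort integrity targets follow the requested distribution", {
  subj <- simulate_cohort(5, integrity_dist = list(ROF = c(80, 0),
                                                   RHF = c(62, 22),
                                                   LOF = c(82, 12)),
                          seed = 6)
  rof <- vapply(subj, function(s) s$spec$target_integrity[["ROF"]], 1)
  expect_true(all(rof == 80))
  expect_identical(simulate_cohort(4, seed = 9), simulate_cohort(4, seed = 9))
  expect_error(simulate_cohort(10, gold_mix = c(0.5, 0.5, 0.5, 0, 0)),
               "summing to 1")
  # spirometry invariants
  spiro <- simulate_spirometry(rep(c("non-COPD", "GOLD-IV"), 20), seed = 2)
  expect_true(all(spiro$fev1_l <= spiro$fvc_l))
  expect_true(all(spiro$fev1_l > 0))
})
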