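# shared fixtures: all synthetic, generated at test time

# coarse phantom for fast unit tests (same anatomy, 2x voxel size)
coarse_spec <- function(...) {
  phantom_spec(grid_shape = c(64, 64, 64), spacing = c(1.4, 1.4, 1.25), ...)
}

dice_overlap <- function(a, b, d) {
  la <- (a[, 3] - 1) * d[1] * d[2] + (a[, 2] - 1) * d[1] + a[, 1]
  lb <- (b[, 3] - 1) * d[1] * d[2] + (b[, 2] - 1) * d[1] + b[, 1]
  2 * length(intersect(la, lb)) / (length(la) + length(lb))
}

# one-voxel-thick spherical shell: nearest voxel along the locally dominant
# axis of the radial normal (one voxel per column in each cap)
sphere_sheet <- function(r, s) {
  nr <- ceiling(r / s) + 3
  out <- NULL
  for (ax in 1:3) {
    g <- as.matrix(expand.grid(-nr:nr, -nr:nr))
    pp <- g * s
    rr2 <- r^2 - rowSums(pp^2)
    ok <- rr2 > 0
    h <- sqrt(rr2[ok])
    dom <- h >= pmax(abs(pp[ok, 1]), abs(pp[ok, 2]))
    k <- round(h[dom] / s)
    gi <- g[ok, , drop = FALSE][dom, , drop = FALSE]
    both <- rbind(cbind(gi, k), cbind(gi, -k))
    idx <- switch(ax,
                  cbind(both[, 3], both[, 1], both[, 2]),
                  cbind(both[, 1], both[, 3], both[, 2]),
                  both)
    out <- rbind(out, idx)
  }
  unique(out) + nr + 1
}

# flat/tilted plane sheets on the CT-like grid
plane_sheet <- function(n = 100, z = 50) as.matrix(expand.grid(1:n, 1:n, z))

tilted_sheet <- function(n = 100, slope_vox = 1, z0 = 10) {
  g <- expand.grid(i = 1:n, j = 1:n)
  cbind(g$i, g$j, round(z0 + (g$i - 1) * slope_vox))
}

# independent brute-force correlation oracles (direct formulas, no stats::cor)
pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# mid-ranks by exhaustive counting, then the Pearson oracle on them
midrank_bf <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}
spearman_bf <- function(x, y) {
  res <- pearson_bf(midrank_bf(x), midrank_bf(y))
  list(rho = res$r, p = res$p)
}

# cohort records straight from the generator's ground truth (no imaging):
# spirometry plus per-subject integrity targets drawn independently of GOLD
truth_records <- function(n, seed = 1, ...) {
  subj <- simulate_cohort(n, seed = seed, ...)
  spiro <- do.call(rbind, lapply(subj, `[[`, "spirometry"))
  ti <- t(vapply(subj, function(s) s$spec$target_integrity, numeric(3)))
  data.frame(id = seq_len(n), spiro,
             gold = classify_gold(spiro$fev1_fvc_pct, spiro$fev1_pct_pred),
             rof = ti[, 1], rhf = ti[, 2], lof = ti[, 3],
             elf = (ti[, 1] + 0.5 * ti[, 2] + ti[, 3]) / 2.5)
}
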