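#' Specification of a synthetic thoracic phantom
#'
#' Describes a CT-like volume holding two ellipsoidal lungs, five lobes and
#' three inter-lobar fissure sheets (right oblique ROF, right horizontal
#' RHF, left oblique LOF) with controllable per-fissure completeness. The
#' default geometry emulates thin-section inspiratory CT: 0.7 mm in-plane
#' pixels, 0.625 mm slice spacing, parenchyma around -850 HU and fissures
#' slightly denser at -700 HU.
#'
#' @param grid_shape voxels per axis (x: right-to-left, y:
#'   anterior-to-posterior, z: caudo-cranial).
#' @param spacing mm per voxel per axis, strictly positive.
#' @param target_integrity named or positional length-3 vector, percent of
#'   each complete boundary (ROF, RHF, LOF) retained as visible fissure;
#'   values in [0, 100].
#' @param defect_count number of holes carved per fissure.
#' @param noise_sd additive Gaussian noise, HU.
#' @param intensity_parenchyma,intensity_fissure,intensity_background HU.
#' @param allow_marginal if \code{TRUE}, defects may be seeded at the sheet
#'   margin (the clinically typical pattern of peripheral incompleteness);
#'   by default defects are carved interior to the sheet.
#' @param seed integer seed controlling defect placement and noise.
#' @return An object of class \code{phantom_spec}.
#' @seealso \code{\link{generate_phantom}}
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128),
                         spacing = c(0.7, 0.7, 0.625),
                         target_integrity = c(ROF = 100, RHF = 100, LOF = 100),
                         defect_count = 3,
                         noise_sd = 0,
                         intensity_parenchyma = -850,
                         intensity_fissure = -700,
                         intensity_background = 0,
                         allow_marginal = FALSE,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be strictly positive on all axes")
  ti <- as.numeric(target_integrity)
  if (length(ti) != 3L || any(ti < 0) || any(ti > 100))
    stop("`target_integrity` must be 3 values in [0, 100]")
  names(ti) <- c("ROF", "RHF", "LOF")
  if (defect_count < 1) stop("`defect_count` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 target_integrity = ti, defect_count = as.integer(defect_count),
                 noise_sd = noise_sd,
                 intensity_parenchyma = intensity_parenchyma,
                 intensity_fissure = intensity_fissure,
                 intensity_background = intensity_background,
                 allow_marginal = isTRUE(allow_marginal),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %s mm, target integrity ROF/RHF/LOF = %s%%\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              paste(round(x$target_integrity, 1), collapse = "/")))
  cat(sprintf("  defects: %d per fissure (%s), noise sd %g HU, seed %d\n",
              x$defect_count,
              if (x$allow_marginal) "marginal allowed" else "interior only",
              x$noise_sd, x$seed))
  invisible(x)
}

# analytic phantom geometry shared by rasterisation and truth bookkeeping
phantom_geometry <- function(spec) {
  ext <- spec$grid_shape * spec$spacing
  list(
    right = list(centre = c(0.26, 0.50, 0.50) * ext,
                 semi = c(0.165, 0.30, 0.38) * ext),
    left = list(centre = c(0.74, 0.50, 0.50) * ext,
                semi = c(0.165, 0.30, 0.38) * ext),
    # fissure sheets as height fields z = f(x, y); slopes kept below 0.9 so
    # one voxel per axial column stays 26-connected after rasterisation
    oblique_slope = 0.8,
    oblique_bow = 0.004,
    horizontal_offset_frac = 0.25,   # of the z semi-axis, above centre
    horizontal_slope = 0.1
  )
}

fissure_height_fun <- function(spec, label) {
  geo <- phantom_geometry(spec)
  lung <- if (label == "LOF") geo$left else geo$right
  cx <- lung$centre[1]; cy <- lung$centre[2]; cz <- lung$centre[3]
  if (label == "RHF") {
    zh <- cz + geo$horizontal_offset_frac * lung$semi[3]
    function(x, y) zh + geo$horizontal_slope * (y - cy)
  } else {
    function(x, y) cz + geo$oblique_slope * (y - cy) + geo$oblique_bow * (x - cx)^2
  }
}

# rasterise a height field to one voxel per (x, y) column inside the lung
rasterise_sheet <- function(spec, label) {
  geo <- phantom_geometry(spec)
  lung <- if (label == "LOF") geo$left else geo$right
  f <- fissure_height_fun(spec, label)
  d <- spec$grid_shape; sp <- spec$spacing
  xv <- (seq_len(d[1]) - 1) * sp[1]
  yv <- (seq_len(d[2]) - 1) * sp[2]
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  x <- xv[g$i]; y <- yv[g$j]
  z <- f(x, y)
  e <- ((x - lung$centre[1]) / lung$semi[1])^2 +
    ((y - lung$centre[2]) / lung$semi[2])^2 +
    ((z - lung$centre[3]) / lung$semi[3])^2
  inside <- e <= 0.99
  if (label == "RHF") {
    # the horizontal sheet exists only above the oblique sheet (the wedge
    # roof of the middle lobe)
    frof <- fissure_height_fun(spec, "ROF")
    inside <- inside & (z > frof(x, y) + 2 * sp[3])
  }
  k <- round(z / sp[3]) + 1L
  inside <- inside & k >= 1L & k <= d[3]
  cbind(g$i[inside], g$j[inside], k[inside])
}

#' Carve defects into a fissure sheet
#'
#' Removes roughly circular patches from a one-voxel-thick voxel sheet until
#' the retained area fraction matches \code{target_integrity}. Defect
#' centres are sampled away from the sheet margin unless
#' \code{allow_marginal}; the removed region is the union of balls around
#' the centres, grown (shared radius) until the removed area reaches the
#' deficit, so a small \code{defect_count} simply yields wider holes.
#'
#' @param surface_voxels n x 3 voxel index matrix (one-voxel-thick sheet).
#' @param target_integrity percent of the sheet area to retain, in [0, 100].
#' @param defect_count number of defect centres.
#' @param seed integer seed.
#' @param spacing mm per axis (area bookkeeping).
#' @param allow_marginal allow defect centres at the sheet margin.
#' @param edge_margin_mm minimal distance of interior defect centres from
#'   the sheet margin.
#' @return The retained subset of \code{surface_voxels}.
#' @export
carve_defects <- function(surface_voxels, target_integrity, defect_count,
                          seed, spacing = c(1, 1, 1), allow_marginal = FALSE,
                          edge_margin_mm = 3) {
  if (target_integrity < 0 || target_integrity > 100)
    stop("`target_integrity` must lie in [0, 100]")
  surface_voxels <- as_voxel_matrix(surface_voxels)
  if (target_integrity >= 100 || nrow(surface_voxels) == 0L)
    return(surface_voxels)
  if (target_integrity <= 0)
    return(surface_voxels[integer(0), , drop = FALSE])
  defect_count <- max(1L, as.integer(defect_count))

  normals <- sheet_normals(surface_voxels, spacing)
  areas <- voxel_sheet_areas(surface_voxels, spacing, normals)
  total <- sum(areas)
  deficit <- (1 - target_integrity / 100) * total

  eligible <- seq_len(nrow(surface_voxels))
  if (!allow_marginal) {
    dist_edge <- sheet_edge_distance(surface_voxels, spacing)
    interior <- which(dist_edge > edge_margin_mm)
    if (length(interior) >= defect_count) eligible <- interior
    else message("carve_defects: sheet too small for interior-only defects; ",
                 "allowing marginal centres")
  }
  with_seed(seed, {
    ctr_rows <- sample(eligible, min(defect_count, length(eligible)))
  })
  pos <- voxel_to_mm(surface_voxels, spacing)
  ctr <- pos[ctr_rows, , drop = FALSE]
  dmin <- rep(Inf, nrow(pos))
  for (k in seq_len(nrow(ctr)))
    dmin <- pmin(dmin, sqrt((pos[, 1] - ctr[k, 1])^2 +
                            (pos[, 2] - ctr[k, 2])^2 +
                            (pos[, 3] - ctr[k, 3])^2))
  # remove voxels in order of distance to the nearest centre until the
  # removed area reaches the deficit: the removal set is a union of balls
  ord <- order(dmin)
  cum <- cumsum(areas[ord])
  ncut <- findInterval(deficit, cum) + 1L
  ncut <- min(ncut, nrow(surface_voxels))
  removed <- ord[seq_len(ncut)]
  surface_voxels[-removed, , drop = FALSE]
}

# physical distance of each sheet voxel to the sheet margin, measured in the
# footprint plane perpendicular to the sheet's average normal
sheet_edge_distance <- function(voxels, spacing) {
  pos <- voxel_to_mm(voxels, spacing)
  ctr <- colMeans(pos)
  cc <- crossprod(sweep(pos, 2, ctr)) / nrow(pos)
  ax <- which.max(abs(eigen(cc, symmetric = TRUE)$vectors[, 3]))
  uv_axes <- setdiff(1:3, ax)
  u <- voxels[, uv_axes[1]]; v <- voxels[, uv_axes[2]]
  lo_u <- min(u) - 1L; lo_v <- min(v) - 1L
  du <- max(u) - lo_u + 2L; dv <- max(v) - lo_v + 2L
  occ <- matrix(FALSE, du, dv)
  occ[cbind(u - lo_u + 1L, v - lo_v + 1L)] <- TRUE
  # margin cells: occupied but not 8-surrounded
  nb <- matrix(0L, du, dv)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- pmin(pmax(seq_len(du) + di, 1L), du)
    jj <- pmin(pmax(seq_len(dv) + dj, 1L), dv)
    nb <- nb + occ[ii, jj]
  }
  edge <- occ & nb < 8L
  eu <- row(edge)[edge]; ev <- col(edge)[edge]
  if (length(eu) == 0L) return(rep(Inf, nrow(voxels)))
  su <- spacing[uv_axes[1]]; sv <- spacing[uv_axes[2]]
  qu <- (u - lo_u + 1L) * su; qv <- (v - lo_v + 1L) * sv
  dmin <- rep(Inf, nrow(voxels))
  for (chunk in split(seq_along(eu), ceiling(seq_along(eu) / 200))) {
    dd <- outer(qu, eu[chunk] * su, "-")^2 + outer(qv, ev[chunk] * sv, "-")^2
    dmin <- pmin(dmin, sqrt(do.call(pmin, as.data.frame(dd))))
  }
  dmin
}

#' Generate a synthetic thoracic phantom with ground truth
#'
#' Builds a CT-like volume containing two ellipsoidal lungs; the right lung
#' is cut by an oblique and a near-axial (horizontal) fissure sheet, the
#' left lung by one oblique sheet. Each sheet is carved down to its target
#' integrity and rasterised one voxel thick at the fissure intensity, then
#' Gaussian noise is added. The returned truth holds lung and lobe label
#' masks, the defected (\code{fissure_truth}) and complete
#' (\code{boundary_truth}) sheet voxels per fissure, and per-fissure /
#' entire-lung integrities measured on those masks with
#' \code{\link{surface_area}}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{phantom}: list with \code{volume}
#'   (an \code{\link{image_volume}}), \code{truth} and \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
#'                                     spacing = c(1.4, 1.4, 1.25)))
#' ph$truth$true_integrity
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  d <- spec$grid_shape; sp <- spec$spacing
  if (any(geo$right$semi < 4 * sp))
    stop("grid too small to contain both lungs")

  xv <- (seq_len(d[1]) - 1) * sp[1]
  yv <- (seq_len(d[2]) - 1) * sp[2]
  zv <- (seq_len(d[3]) - 1) * sp[3]
  ell <- function(lung) {
    ex <- ((xv - lung$centre[1]) / lung$semi[1])^2
    ey <- ((yv - lung$centre[2]) / lung$semi[2])^2
    ez <- ((zv - lung$centre[3]) / lung$semi[3])^2
    outer(outer(ex, ey, "+"), ez, "+") <= 1
  }
  right <- ell(geo$right)
  left <- ell(geo$left)
  lung_mask <- array(0L, d)
  lung_mask[right] <- 1L
  lung_mask[left] <- 2L

  labels <- c("ROF", "RHF", "LOF")
  boundary <- lapply(labels, function(lb) rasterise_sheet(spec, lb))
  names(boundary) <- labels
  fissure <- lapply(labels, function(lb) {
    carve_defects(boundary[[lb]], spec$target_integrity[[lb]],
                  spec$defect_count,
                  seed = spec$seed + match(lb, labels),
                  spacing = sp, allow_marginal = spec$allow_marginal)
  })
  names(fissure) <- labels

  # lobe labels: 1 RUL, 2 RML, 3 RLL, 4 LUL, 5 LLL
  lobe_mask <- array(0L, d)
  xg <- array(rep(xv, times = d[2] * d[3]), d)
  yg <- array(rep(rep(yv, each = d[1]), times = d[3]), d)
  zg <- array(rep(zv, each = d[1] * d[2]), d)
  frof <- fissure_height_fun(spec, "ROF")
  frhf <- fissure_height_fun(spec, "RHF")
  flof <- fissure_height_fun(spec, "LOF")
  ridx <- which(right)
  below_rof <- zg[ridx] < frof(xg[ridx], yg[ridx])
  below_rhf <- zg[ridx] < frhf(xg[ridx], yg[ridx])
  lobe_mask[ridx[below_rof]] <- 3L
  lobe_mask[ridx[!below_rof & below_rhf]] <- 2L
  lobe_mask[ridx[!below_rof & !below_rhf]] <- 1L
  lidx <- which(left)
  below_lof <- zg[lidx] < flof(xg[lidx], yg[lidx])
  lobe_mask[lidx[below_lof]] <- 5L
  lobe_mask[lidx[!below_lof]] <- 4L

  vol <- array(spec$intensity_background, d)
  vol[lung_mask > 0L] <- spec$intensity_parenchyma
  for (lb in labels) {
    vx <- fissure[[lb]]
    if (nrow(vx)) vol[voxel_linear(vx, d)] <- spec$intensity_fissure
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    })
  }

  area_b <- vapply(boundary, function(v) surface_area(v, sp), numeric(1))
  area_f <- vapply(labels, function(lb) {
    v <- fissure[[lb]]
    if (nrow(v) == 0L) 0 else surface_area(v, sp)
  }, numeric(1))
  true_int <- pmin(100 * area_f / area_b, 100)
  true_elf <- 100 * sum(area_f) / sum(area_b)

  structure(list(
    volume = image_volume(vol, spacing = sp),
    truth = list(lung_mask = lung_mask, lobe_mask = lobe_mask,
                 fissure_truth = fissure, boundary_truth = boundary,
                 boundary_area_mm2 = area_b, fissure_area_mm2 = area_f,
                 true_integrity = true_int, true_elf = true_elf),
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  print(x$volume)
  cat(sprintf("  true integrity ROF/RHF/LOF = %s%%, entire lung %.1f%%\n",
              paste(round(x$truth$true_integrity, 1), collapse = "/"),
              x$truth$true_elf))
  invisible(x)
}
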