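#' Extrapolate a fissure patch to the complete inter-lobar boundary
#'
#' Fits a smooth height-field surface through the detected fissure voxels
#' and extends it across the full lateral extent of the lung, realizing the
#' notion that the complete boundary "cuts through" the lung. The patch
#' voxels are expressed in their principal-axis frame (the minor axis is
#' the sheet normal); the normal offset is modeled as a thin-plate
#' regression spline over the in-plane coordinates (\code{mgcv::gam}, basis
#' \code{"tp"}), evaluated on a regular in-plane grid covering the lung's
#' projection, clipped to the lung mask at the voxel level, and
#' triangulated.
#'
#' @param patch a \code{\link{fissure_patch}} or an n x 3 voxel index
#'   matrix.
#' @param lung voxel set (n x 3) of the containing lung.
#' @param spacing mm per axis.
#' @param smoothing fixed smoothing parameter passed to \code{mgcv::gam}
#'   (\code{sp}). The default of 100 keeps the extrapolated boundary stiff,
#'   which stabilises the area of the completed surface when the patch is
#'   sparse or fragmented; \code{NULL} lets REML choose (softer, follows
#'   genuine curvature more closely, but chases rasterisation artefacts on
#'   heavily defected patches).
#' @param k basis dimension of the spline; reduced automatically for small
#'   patches.
#' @param max_fit_points patch voxels are thinned deterministically to at
#'   most this many before fitting.
#' @param grid_mm in-plane grid step of the completed surface; defaults to
#'   the smallest voxel spacing.
#' @return A \code{complete_boundary}: list with \code{label},
#'   \code{vertices} (mm), \code{faces}, \code{area_mm2} and the fitting
#'   frame.
#' @export
fit_complete_surface <- function(patch, lung, spacing = NULL,
                                 smoothing = 100, k = 50,
                                 max_fit_points = 2000, grid_mm = NULL) {
  if (inherits(patch, "fissure_patch")) {
    label <- patch$label
    spacing <- spacing %||% patch$spacing
    vox <- patch$voxels
  } else {
    label <- "unlabeled"
    vox <- as_voxel_matrix(patch)
  }
  if (is.null(spacing)) stop("`spacing` required")
  if (is.null(grid_mm)) grid_mm <- min(spacing)
  pos <- voxel_to_mm(vox, spacing)
  if (nrow(pos) < 3L) stop("patch too small to define a plane (<3 points)")
  ctr <- colMeans(pos)
  cpos <- sweep(pos, 2, ctr)
  ee <- eigen(crossprod(cpos) / nrow(cpos), symmetric = TRUE)
  if (ee$values[2] < 1e-9)
    stop("patch too small to define a plane (<3 non-collinear points)")
  axes <- ee$vectors                  # columns: major, mid, normal
  if (axes[3, 3] < 0) axes[, 3] <- -axes[, 3]   # normal points towards +z
  uvw <- cpos %*% axes

  fit_idx <- seq_len(nrow(uvw))
  if (length(fit_idx) > max_fit_points)
    fit_idx <- fit_idx[seq(1L, length(fit_idx), length.out = max_fit_points)]
  df <- data.frame(u = uvw[fit_idx, 1], v = uvw[fit_idx, 2],
                   w = uvw[fit_idx, 3])
  kk <- min(k, nrow(df) - 2L)
  if (kk >= 10L) {
    fit <- mgcv::gam(w ~ s(u, v, bs = "tp", k = kk), data = df,
                     method = "REML", sp = smoothing)
  } else {
    fit <- stats::lm(w ~ u + v, data = df)
  }

  lung <- as_voxel_matrix(lung)
  lpos <- sweep(voxel_to_mm(lung, spacing), 2, ctr)
  luv <- lpos %*% axes[, 1:2]
  ur <- range(luv[, 1]); vr <- range(luv[, 2])
  ug <- seq(ur[1], ur[2], by = grid_mm)
  vg <- seq(vr[1], vr[2], by = grid_mm)
  nodes <- expand.grid(u = ug, v = vg)
  wp <- as.numeric(stats::predict(fit, newdata = nodes))
  pts <- sweep(cbind(nodes$u, nodes$v, wp) %*% t(axes), 2, ctr, "+")

  # voxel-level clip to the lung
  d <- apply(lung, 2, max) + 1L
  occ <- array(FALSE, d)
  occ[voxel_linear(lung, d)] <- TRUE
  vi <- round(sweep(pts, 2, spacing, "/")) + 1
  inside <- vi[, 1] >= 1 & vi[, 1] <= d[1] & vi[, 2] >= 1 & vi[, 2] <= d[2] &
    vi[, 3] >= 1 & vi[, 3] <= d[3]
  inside[inside] <- occ[voxel_linear(vi[inside, , drop = FALSE], d)]

  nu <- length(ug); nv <- length(vg)
  node_id <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  q00 <- node_id(i, j); q10 <- node_id(i + 1L, j)
  q01 <- node_id(i, j + 1L); q11 <- node_id(i + 1L, j + 1L)
  tri <- rbind(cbind(q00, q10, q11), cbind(q00, q11, q01))
  # majority rule at the rim: dropping triangles with any outside vertex
  # shrinks the surface by ~half a grid cell all around, requiring all-out
  # inflates it; two-of-three is area-neutral on average
  tri_ok <- (inside[tri[, 1]] + inside[tri[, 2]] + inside[tri[, 3]]) >= 2
  tri <- tri[tri_ok, , drop = FALSE]

  used <- sort(unique(as.integer(tri)))
  remap <- integer(nu * nv)
  remap[used] <- seq_along(used)
  faces <- matrix(remap[tri], ncol = 3)
  vertices <- pts[used, , drop = FALSE]
  area <- if (nrow(faces)) mesh_area(vertices, faces) else 0

  structure(list(label = label, vertices = vertices, faces = faces,
                 area_mm2 = area, centre = ctr, axes = axes, fit = fit,
                 height_grid = list(u = ug, v = vg,
                                    w = matrix(wp, nu, nv)),
                 spacing = spacing, grid_mm = grid_mm),
            class = "complete_boundary")
}

#' Signed offset of points from a completed boundary surface
#'
#' Positive values lie on the side of the surface normal (oriented towards
#' +z, the cranial direction).
#'
#' @param boundary a \code{\link{fit_complete_surface}} result.
#' @param points_mm n x 3 matrix of physical coordinates.
#' @return Numeric vector of signed normal offsets in mm.
#' @export
surface_side <- function(boundary, points_mm) {
  uvw <- sweep(points_mm, 2, boundary$centre) %*% boundary$axes
  hg <- boundary$height_grid
  # bilinear interpolation on the precomputed height-field grid (clamped at
  # the borders; the grid spans the lung's full in-plane projection)
  fi <- (uvw[, 1] - hg$u[1]) / (hg$u[2] - hg$u[1])
  fj <- (uvw[, 2] - hg$v[1]) / (hg$v[2] - hg$v[1])
  fi <- pmin(pmax(fi, 0), length(hg$u) - 1 - 1e-9)
  fj <- pmin(pmax(fj, 0), length(hg$v) - 1 - 1e-9)
  i0 <- floor(fi); j0 <- floor(fj)
  ti <- fi - i0; tj <- fj - j0
  w <- hg$w
  idx <- cbind(i0 + 1, j0 + 1)
  what <- w[idx] * (1 - ti) * (1 - tj) +
    w[cbind(i0 + 2, j0 + 1)] * ti * (1 - tj) +
    w[cbind(i0 + 1, j0 + 2)] * (1 - ti) * tj +
    w[cbind(i0 + 2, j0 + 2)] * ti * tj
  uvw[, 3] - what
}

#' @export
print.complete_boundary <- function(x, ...) {
  cat(sprintf("<complete_boundary> %s: %d vertices, %d faces, %.1f mm^2\n",
              x$label, nrow(x$vertices), nrow(x$faces), x$area_mm2))
  invisible(x)
}

#' Rasterize a completed boundary surface back to voxels
#'
#' @param boundary a \code{\link{fit_complete_surface}} result.
#' @return n x 3 integer matrix of voxel indices covered by the mesh
#'   vertices (unique).
#' @export
boundary_to_voxels <- function(boundary) {
  vi <- round(sweep(boundary$vertices, 2, boundary$spacing, "/")) + 1
  unique(vi)
}

#' Write a completed boundary mesh as ASCII PLY
#'
#' @param boundary a \code{complete_boundary}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_boundary_ply <- function(boundary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(boundary$vertices); nf <- nrow(boundary$faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.4f %.4f %.4f", boundary$vertices[, 1],
                     boundary$vertices[, 2], boundary$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", boundary$faces[, 1] - 1L,
                     boundary$faces[, 2] - 1L, boundary$faces[, 3] - 1L), con)
  invisible(path)
}
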