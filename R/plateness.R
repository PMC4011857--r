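#' Multi-scale Hessian plate-likeness (sheetness) filter
#'
#' Enhances bright sheet-like structures such as pulmonary fissures. At each
#' Gaussian scale the image Hessian is computed with physical-unit
#' derivative-of-Gaussian kernels (so anisotropic voxel spacing is handled
#' natively), its eigenvalues are sorted by magnitude
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|}, and a Frangi-style
#' sheet measure is evaluated that is high where \eqn{|\lambda_3| \gg
#' |\lambda_2| \approx |\lambda_1|} with \eqn{\lambda_3 < 0} (bright sheet
#' on dark background):
#' \deqn{P = \exp(-R_{sheet}^2/2\alpha^2)\,(1 - \exp(-R_{blob}^2/2\beta^2))
#'   \,(1 - \exp(-S^2/2c^2))}
#' with \eqn{R_{sheet} = |\lambda_2|/|\lambda_3|}, \eqn{R_{blob} =
#' |2|\lambda_3| - |\lambda_2| - |\lambda_1||/|\lambda_3|}, \eqn{S} the
#' Frobenius norm of the Hessian and \eqn{c} set adaptively to
#' \code{c_frac} times the in-mask 99th percentile of \eqn{S}. The response is
#' the maximum over scales, in [0, 1], and zero outside the lung mask.
#' Intensities outside the mask are replaced by the in-mask median before
#' filtering so the lung wall does not shed spurious sheet responses into
#' the field.
#'
#' @param volume an \code{\link{image_volume}}.
#' @param scales Gaussian scales in mm; each must be at least half the
#'   smallest voxel spacing.
#' @param lung_mask logical or integer array matching the volume grid;
#'   non-zero marks lung.
#' @param alpha,beta sheet/blob discrimination parameters.
#' @param c_frac fraction of the in-mask 99th-percentile Frobenius norm
#'   used as the structure cut-off \eqn{c}.
#' @return An object of class \code{plateness_map}: list with
#'   \code{response} (3D array in [0, 1]), \code{scale_used} (mm, argmax
#'   scale per voxel), \code{spacing}, and the per-voxel sheet normals at
#'   the winning scale (used for non-maximum suppression downstream).
#' @export
compute_plateness <- function(volume, scales = c(0.7, 1.0, 1.4), lung_mask,
                              alpha = 0.5, beta = 0.5, c_frac = 0.5) {
  stopifnot(inherits(volume, "image_volume"))
  sp <- volume$spacing
  if (length(scales) < 1L) stop("at least one scale required")
  if (any(scales < min(sp) / 2))
    stop("scale smaller than half the smallest voxel spacing")
  mask <- lung_mask != 0
  if (!any(mask)) stop("lung mask is empty")
  if (!all(dim(mask) == dim(volume$data)))
    stop("mask grid does not match volume grid")

  arr <- volume$data
  med <- stats::median(arr[mask])
  arr[!mask] <- med
  arr <- arr - med
  full_dim <- dim(arr)
  midx_full <- which(mask)

  # crop to the mask bounding box (plus filter support) — the convolutions
  # dominate the cost and the thorax rarely fills the grid
  pad <- ceiling(4 * max(scales) / min(sp)) + 1L
  bb <- linear_voxel(midx_full, full_dim)
  lo <- pmax(apply(bb, 2, min) - pad, 1L)
  hi <- pmin(apply(bb, 2, max) + pad, full_dim)
  arr <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  midx <- which(mask)

  best <- rep(0, length(midx))
  best_scale <- rep(NA_real_, length(midx))
  best_nrm <- matrix(rep(c(0, 0, 1), each = length(midx)), ncol = 3)

  for (sg in scales) {
    H <- hessian_at_scale(arr, sp, sg)
    l <- eig3_sym(H$xx[midx], H$yy[midx], H$zz[midx],
                  H$xy[midx], H$xz[midx], H$yz[midx])
    # magnitude sort: l1 <= l2 <= l3 by value, the extreme of larger
    # magnitude is lambda3
    la <- abs(l$l1); lc <- abs(l$l3)
    big <- ifelse(la >= lc, l$l1, l$l3)
    oth <- ifelse(la >= lc, l$l3, l$l1)
    use2 <- abs(l$l2) >= abs(oth)
    mid <- ifelse(use2, l$l2, oth)
    sml <- ifelse(use2, oth, l$l2)

    ab <- abs(big)
    S <- sqrt(l$l1^2 + l$l2^2 + l$l3^2)
    # robust structure scale: the 99th percentile is insensitive to the few
    # extreme noise responses that inflate the plain maximum
    cpar <- c_frac * stats::quantile(S, 0.99, names = FALSE)
    resp <- rep(0, length(midx))
    ok <- big < 0 & ab > 0
    if (cpar > 0 && any(ok)) {
      rsheet <- abs(mid[ok]) / ab[ok]
      rblob <- abs(2 * ab[ok] - abs(mid[ok]) - abs(sml[ok])) / ab[ok]
      resp[ok] <- exp(-rsheet^2 / (2 * alpha^2)) *
        (1 - exp(-rblob^2 / (2 * beta^2))) *
        (1 - exp(-S[ok]^2 / (2 * cpar^2)))
    }
    upd <- resp > best
    if (any(upd)) {
      nrm <- eigvec3_sym(H$xx[midx[upd]], H$yy[midx[upd]], H$zz[midx[upd]],
                         H$xy[midx[upd]], H$xz[midx[upd]], H$yz[midx[upd]],
                         mu1 = mid[upd], mu2 = sml[upd])
      best[upd] <- resp[upd]
      best_scale[upd] <- sg
      best_nrm[upd, ] <- nrm
    }
  }

  response <- array(0, full_dim)
  response[midx_full] <- pmin(pmax(best, 0), 1)
  scale_used <- array(NA_real_, full_dim)
  scale_used[midx_full] <- best_scale
  structure(list(response = response, scale_used = scale_used,
                 spacing = sp, mask_index = midx_full, normals = best_nrm),
            class = "plateness_map")
}

#' @export
print.plateness_map <- function(x, ...) {
  cat(sprintf("<plateness_map> %s voxels, %d in mask, response range [%.3f, %.3f]\n",
              paste(dim(x$response), collapse = "x"), length(x$mask_index),
              min(x$response), max(x$response)))
  invisible(x)
}

# Hessian of a 3D array at Gaussian scale `sigma` (mm), physical units;
# returns the six unique component arrays, scale-normalised by sigma^2
hessian_at_scale <- function(arr, spacing, sigma) {
  kern <- lapply(1:3, function(ax) {
    s <- spacing[ax]
    m <- max(3L, ceiling(4 * sigma / s))
    m <- min(m, dim(arr)[ax] - 1L)
    t <- (-m:m) * s
    g <- exp(-t^2 / (2 * sigma^2))
    g0 <- g / sum(g)
    g1 <- (t / sigma^2) * g * s          # correlation kernel of d/dx
    g1 <- g1 - mean(g1)
    g2 <- ((t^2 - sigma^2) / sigma^4) * g * s
    g2 <- g2 - mean(g2)
    list(g0 = g0, g1 = g1, g2 = g2)
  })
  cv <- function(o1, o2, o3)
    conv_separable(arr, list(kern[[1]][[o1]], kern[[2]][[o2]], kern[[3]][[o3]]))
  s2 <- sigma^2
  list(xx = s2 * cv("g2", "g0", "g0"),
       yy = s2 * cv("g0", "g2", "g0"),
       zz = s2 * cv("g0", "g0", "g2"),
       xy = s2 * cv("g1", "g1", "g0"),
       xz = s2 * cv("g1", "g0", "g1"),
       yz = s2 * cv("g0", "g1", "g1"))
}

#' Extract fissure voxels from a plateness map
#'
#' Thresholds the sheetness response, thins the supra-threshold set to one
#' voxel thickness by non-maximum suppression along the grid axis best
#' aligned with the local sheet normal (in voxel units, so anisotropic
#' spacing is respected), and removes connected components whose estimated
#' area falls below \code{min_component_mm2}. Optional hysteresis
#' (\code{hysteresis_low < threshold}) keeps weak voxels whose connected
#' component contains at least one strong voxel — useful when the sheet
#' margin tapers below the main threshold — and is off by default.
#'
#' @param plateness a \code{\link{compute_plateness}} result.
#' @param threshold strong response threshold in (0, 1).
#' @param min_component_mm2 minimal component area retained.
#' @param hysteresis_low weak threshold; set equal to \code{threshold} to
#'   disable hysteresis.
#' @return n x 3 integer matrix of fissure voxel indices (possibly empty).
#' @export
extract_fissure_voxels <- function(plateness, threshold = 0.5,
                                   min_component_mm2 = 20,
                                   hysteresis_low = 0.5) {
  stopifnot(inherits(plateness, "plateness_map"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  low <- min(hysteresis_low, threshold)
  resp <- plateness$response
  d <- dim(resp)
  sp <- plateness$spacing
  sel <- plateness$response[plateness$mask_index] >= low
  if (!any(sel)) return(matrix(integer(0), 0, 3))
  lin <- plateness$mask_index[sel]
  nrm <- plateness$normals[sel, , drop = FALSE]
  vox <- linear_voxel(lin, d)

  # non-maximum suppression along the traversal axis (argmax |n_k|/s_k)
  ax <- max.col(sweep(abs(nrm), 2, sp, "/"), ties.method = "first")
  step <- c(1, d[1], d[1] * d[2])[ax]
  at_lo <- vox[cbind(seq_along(ax), ax)] <= 1L
  at_hi <- vox[cbind(seq_along(ax), ax)] >= d[ax]
  r0 <- resp[lin]
  rm1 <- ifelse(at_lo, -Inf, resp[pmax(lin - step, 1)])
  rp1 <- ifelse(at_hi, -Inf, resp[pmin(lin + step, length(resp))])
  keep <- r0 > rm1 & r0 >= rp1
  vox <- vox[keep, , drop = FALSE]
  if (nrow(vox) == 0L) return(vox)
  strong <- resp[voxel_linear(vox, d)] >= threshold

  labs <- label_components(vox)
  areas <- voxel_sheet_areas(vox, sp)
  comp_area <- tapply(areas, labs, sum)
  comp_strong <- tapply(strong, labs, any)
  ok_lab <- as.integer(names(comp_area))[comp_area >= min_component_mm2 &
                                           comp_strong]
  vox[labs %in% ok_lab, , drop = FALSE]
}
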