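#' Split a lung mask into left and right lung voxel sets
#'
#' When the mask carries side labels (1 = right, 2 = left) these are used
#' directly. An unlabeled (binary) mask is split into its two largest
#' connected components, ordered along the first grid axis: the component
#' with the smaller mean index lies on the patient's right (axis 1
#' increases towards the patient's left).
#'
#' @param lung_mask integer or logical 3D array.
#' @return List with \code{right} and \code{left}: n x 3 voxel index
#'   matrices.
#' @export
split_lungs <- function(lung_mask) {
  d <- dim(lung_mask)
  vals <- sort(unique(as.integer(lung_mask[lung_mask != 0])))
  if (identical(vals, c(1L, 2L))) {
    return(list(right = linear_voxel(which(lung_mask == 1L), d),
                left = linear_voxel(which(lung_mask == 2L), d)))
  }
  vox <- linear_voxel(which(lung_mask != 0), d)
  labs <- label_components(vox, connectivity = 6)
  if (max(labs) < 2L)
    stop("lung mask has fewer than 2 connected components and no side labels")
  a <- vox[labs == 1L, , drop = FALSE]
  b <- vox[labs == 2L, , drop = FALSE]
  if (mean(a[, 1]) <= mean(b[, 1])) list(right = a, left = b)
  else list(right = b, left = a)
}

#' Assign anatomical fissure labels to detected sheet components
#'
#' Components in the left lung are all labeled LOF (the left lung has a
#' single, oblique fissure). In the right lung a component is labeled RHF
#' (horizontal/minor fissure) when its mean surface normal lies within
#' \code{cone_deg} of the cranio-caudal axis \emph{and} its centroid falls
#' in the anterior-superior half of the lung; otherwise it is ROF.
#' Components are merged per label.
#'
#' @param components list of n x 3 voxel index matrices (detected sheet
#'   components).
#' @param side \code{"left"} or \code{"right"}.
#' @param lung_voxels voxel set of the containing lung (used for the
#'   anterior-superior gate); required for the right side.
#' @param spacing mm per axis.
#' @param cone_deg half-angle of the cranio-caudal normal cone for RHF.
#' @return List of \code{fissure_patch} objects (fields \code{label},
#'   \code{voxels}, \code{area_mm2}, \code{mean_normal}), at most one per
#'   label.
#' @export
classify_patches <- function(components, side = c("right", "left"),
                             lung_voxels = NULL, spacing = c(1, 1, 1),
                             cone_deg = 35) {
  side <- match.arg(side)
  components <- components[vapply(components, nrow, 1L) > 0]
  if (length(components) == 0L) return(list())
  labels <- character(length(components))
  if (side == "left") {
    labels[] <- "LOF"
  } else {
    if (is.null(lung_voxels))
      stop("`lung_voxels` required to classify right-lung components")
    lpos <- voxel_to_mm(lung_voxels, spacing)
    lc <- colMeans(lpos)
    lsd <- apply(lpos, 2, stats::sd)
    for (i in seq_along(components)) {
      vx <- components[[i]]
      nrm <- patch_mean_normal(vx, spacing)
      ang <- acos(pmin(abs(nrm[3]), 1)) * 180 / pi
      ctr <- colMeans(voxel_to_mm(vx, spacing))
      # anterior-superior half-space along the anterosuperior diagonal,
      # scaled by the lung's extent per axis (y grows posteriorly)
      ant_sup <- (ctr[3] - lc[3]) / lsd[3] > (ctr[2] - lc[2]) / lsd[2]
      labels[i] <- if (ang <= cone_deg && ant_sup) "RHF" else "ROF"
    }
  }
  out <- lapply(unique(labels), function(lb) {
    vx <- do.call(rbind, components[labels == lb])
    fissure_patch(lb, vx, spacing)
  })
  names(out) <- vapply(out, function(p) p$label, "")
  out
}

#' Construct a fissure patch
#'
#' @param label one of \code{"ROF"}, \code{"RHF"}, \code{"LOF"}.
#' @param voxels n x 3 voxel index matrix.
#' @param spacing mm per axis.
#' @return A \code{fissure_patch}: list with the label, voxel set, area in
#'   mm^2 and mean unit normal.
#' @export
fissure_patch <- function(label, voxels, spacing) {
  label <- match.arg(label, c("ROF", "RHF", "LOF"))
  voxels <- as_voxel_matrix(voxels)
  area <- if (nrow(voxels)) surface_area(voxels, spacing) else 0
  structure(list(label = label, voxels = voxels, area_mm2 = area,
                 mean_normal = patch_mean_normal(voxels, spacing),
                 spacing = spacing),
            class = "fissure_patch")
}

#' @export
print.fissure_patch <- function(x, ...) {
  cat(sprintf("<fissure_patch> %s: %d voxels, %.1f mm^2, normal (%.2f, %.2f, %.2f)\n",
              x$label, nrow(x$voxels), x$area_mm2,
              x$mean_normal[1], x$mean_normal[2], x$mean_normal[3]))
  invisible(x)
}

# mean surface normal of a voxel patch: minor principal axis of the voxel
# coordinates in mm (sign chosen with positive z component)
patch_mean_normal <- function(voxels, spacing) {
  voxels <- as_voxel_matrix(voxels)
  if (nrow(voxels) < 3L) return(c(0, 0, 1))
  pos <- voxel_to_mm(voxels, spacing)
  cc <- stats::cov(pos)
  v <- eigen(cc, symmetric = TRUE)$vectors[, 3]
  if (v[3] < 0) v <- -v
  v
}
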