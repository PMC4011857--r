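#' 3D image volume with physical voxel spacing
#'
#' Lightweight container for a scalar 3D grid with per-axis voxel spacing in
#' millimetres and a physical origin. Intensities are Hounsfield-unit-like.
#' Axis convention: axis 1 runs right-to-left (increasing index towards the
#' patient's left), axis 2 posterior-to-anterior reversed (increasing index
#' towards the posterior), axis 3 caudo-cranial (increasing index towards the
#' head). Orientation is assumed consistent with this convention; no
#' orientation inference is performed.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, physical offset in mm of voxel (1,1,1).
#' @return An object of class \code{image_volume}: a list with elements
#'   \code{data}, \code{spacing} and \code{origin}.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), spacing = c(0.7, 0.7, 0.625))
#' dim(v)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("grid must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a volume from a NIfTI file
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- as.numeric(sp)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' Write a volume to a NIfTI file
#'
#' @param volume an \code{\link{image_volume}} or a 3D array.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @param spacing voxel spacing, used when \code{volume} is a bare array.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (inherits(volume, "image_volume")) {
    arr <- volume$data
    spacing <- volume$spacing
  } else arr <- volume
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# physical coordinates (mm) of voxel indices (n x 3 integer matrix)
voxel_to_mm <- function(idx, spacing, origin = c(0, 0, 0)) {
  idx <- as_voxel_matrix(idx)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

as_voxel_matrix <- function(idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  storage.mode(idx) <- "double"
  idx
}

# linear indices of an n x 3 voxel index matrix within a grid of dims `d`
voxel_linear <- function(idx, d) {
  (idx[, 3] - 1) * (d[1] * d[2]) + (idx[, 2] - 1) * d[1] + idx[, 1]
}

# inverse of voxel_linear
linear_voxel <- function(lin, d) {
  lin0 <- lin - 1
  k <- lin0 %/% (d[1] * d[2])
  r <- lin0 %% (d[1] * d[2])
  cbind(r %% d[1] + 1, r %/% d[1] + 1, k + 1)
}
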