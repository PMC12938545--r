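#' 3-D scalar or label volume with physical geometry
#'
#' A `volume_grid` is the common substrate for CT images, binary masks,
#' instance-label volumes and distance fields: a 3-D array plus per-axis
#' voxel spacing and origin, both in millimetres. Axis order is the native
#' R/NIfTI (x, y, z) order with the first index fastest; all geometry is
#' computed in world millimetres. World coordinate of voxel (i, j, k)
#' (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3-D numeric, integer or logical array.
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world position of the first voxel centre.
#' @return An object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v)
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume_grid: 'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume_grid: 'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("volume_grid: 'origin' must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
as.array.volume_grid <- function(x, ...) x$data

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x "),
              storage.mode(x$data)))
  rng <- suppressWarnings(range(x$data, finite = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' @rdname volume_grid
#' @param x Object to coerce (array, or a `volume_grid` returned unchanged).
#' @export
as_volume_grid <- function(x, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is_volume_grid(x)) return(x)
  volume_grid(x, spacing, origin)
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes differ in shape: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("volumes differ in spacing")
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' @param vol A [volume_grid].
#' @param idx Integer matrix (n x 3) of 1-based voxel indices, or a vector of
#'   linear indices.
#' @return `voxel_to_world()`: n x 3 matrix of world mm coordinates of voxel
#'   centres. `world_to_voxel()`: n x 3 matrix of continuous 1-based voxel
#'   indices.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- linear_to_ijk(vol, idx)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname voxel_to_world
#' @param world Numeric matrix (n x 3) of world mm coordinates.
#' @export
world_to_voxel <- function(vol, world) {
  if (is.null(dim(world))) world <- matrix(world, ncol = 3)
  sweep(sweep(world, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

linear_to_ijk <- function(vol, lin) {
  d <- dim(vol$data)
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(i, j, k) + 1L
}

ijk_to_linear <- function(vol, ijk) {
  d <- dim(vol$data)
  as.integer((ijk[, 1] - 1L) + d[1] * ((ijk[, 2] - 1L) + d[2] * (ijk[, 3] - 1L)) + 1L)
}

voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the `volume_grid` spacing in
#' the NIfTI pixdim. Origin is stored in the sform translation.
#'
#' @param vol A [volume_grid].
#' @param path Output (or input) file path, conventionally `.nii` or `.nii.gz`.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a [volume_grid].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(is_volume_grid(vol))
  arr <- vol$data
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  hdr <- RNifti::niftiHeader(img)
  hdr$srow_x <- c(vol$spacing[1], 0, 0, vol$origin[1])
  hdr$srow_y <- c(0, vol$spacing[2], 0, vol$origin[2])
  hdr$srow_z <- c(0, 0, vol$spacing[3], vol$origin[3])
  hdr$sform_code <- 2L
  img <- RNifti::asNifti(img, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  if (!all(is.finite(org))) org <- c(0, 0, 0)
  arr <- array(as.vector(img), dim = dim(img)[1:3])
  volume_grid(arr, spacing = sp, origin = org)
}
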