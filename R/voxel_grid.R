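#' Create a voxel grid
#'
#' A voxel grid is a 3-D scalar field (HU, relative electron density, or Gy)
#' with voxel spacing in mm and a world-coordinate origin.  Voxel centre
#' `(i, j, k)` (0-based) sits at `origin + c(i, j, k) * spacing`; masks are
#' half-open voxel sets.
#'
#' @param data numeric 3-D array (or a scalar, recycled over `dim`).
#' @param spacing numeric length-3, mm per axis.
#' @param origin numeric length-3, world mm of voxel (0, 0, 0). Default 0.
#' @param dim integer length-3, required when `data` is a scalar.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0), dim = NULL) {
  if (length(data) == 1L && !is.null(dim)) {
    data <- array(as.numeric(data), dim = dim)
  }
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Voxel volume in cc
#' @param grid a `voxel_grid` (or anything with a `spacing` field).
#' @return scalar, cm^3 per voxel.
#' @export
voxel_cc <- function(grid) prod(grid$spacing) / 1000

#' Do two grids share geometry?
#' @param a,b `voxel_grid` objects.
#' @param tol numeric tolerance in mm.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_geometry_mismatch <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop(what, " do not share grid geometry (dim/spacing/origin)", call. = FALSE)
  }
  invisible(TRUE)
}

#' World coordinates of every voxel centre
#'
#' @param grid a `voxel_grid`.
#' @return n-voxel x 3 matrix of world mm, in array (column-major) order.
#' @export
world_coords <- function(grid) {
  d <- dim(grid$data)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Volume of a logical mask in cc
#' @param mask logical array.
#' @param grid `voxel_grid` supplying the geometry.
#' @return scalar cc.
#' @export
mask_volume_cc <- function(mask, grid) sum(mask) * voxel_cc(grid)

#' Read/write voxel grids as NIfTI
#'
#' Scalar grids are stored as 3-D NIfTI volumes; displacement fields as 4-D
#' volumes with three displacement components (mm) in the fourth dimension.
#'
#' @param grid a `voxel_grid`, or for `write_dvf_nifti` a 4-D array
#'   `dim x 3` of displacements plus the geometry of a reference grid.
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_nifti_grid` returns a `voxel_grid`;
#'   `read_dvf_nifti` a list with `dvf` (4-D array) and `grid` geometry.
#' @export
write_nifti_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_grid(array(as.numeric(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname write_nifti_grid
#' @param dvf 4-D array (nx, ny, nz, 3) of displacements in mm.
#' @param ref `voxel_grid` giving geometry for the DVF.
#' @export
write_dvf_nifti <- function(dvf, ref, path) {
  stopifnot(length(dim(dvf)) == 4L, dim(dvf)[4] == 3L)
  img <- RNifti::asNifti(dvf)
  RNifti::pixdim(img) <- c(ref$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_dvf_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4L, d[4] == 3L)
  list(dvf = array(as.numeric(img), dim = d),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Trilinear interpolation of a grid at world points
#'
#' Samples outside the voxel-centre lattice return `fill` and are counted.
#'
#' @param grid a `voxel_grid`.
#' @param pts n x 3 matrix of world mm.
#' @param fill value for out-of-grid samples (default 0).
#' @return list with `values` (length n) and `n_outside`.
#' @export
interp_trilinear <- function(grid, pts, fill = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_trilinear(grid$data, dim(grid$data), grid$spacing, grid$origin, pts, fill)
}
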