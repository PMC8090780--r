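#' Voxel-space geometry for masked volumetric data
#'
#' A `voxel_space` ties a 3D grid to a binary brain mask and fixes the
#' bijection between in-mask voxels and columns of a subjects-by-voxels
#' data matrix. Columns are ordered by the 0-based row-major (C-order,
#' last axis fastest) flat index of the voxel, so tables of voxel
#' coordinates written by the pipeline are unambiguous regardless of the
#' host language's native array order.
#'
#' @param mask logical 3D array; `TRUE` marks in-mask voxels.
#' @param voxel_size numeric length-3, voxel edge length in mm per axis.
#'
#' @return An object of class `voxel_space` with elements `dims`,
#'   `voxel_size`, `mask`, `coords` (V x 3 integer matrix of 0-based grid
#'   coordinates, one row per matrix column) and `flat_index` (0-based
#'   C-order index per column).
#' @export
voxel_space <- function(mask, voxel_size = c(4, 4, 4)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must not contain NA")
  nvox <- sum(mask)
  if (nvox == 0L) stop("mask contains zero voxels")
  dims <- dim(mask)
  idx <- which(mask)                       # column-major linear indices
  ijk <- arrayInd(idx, dims) - 1L          # 0-based grid coordinates
  flat <- ijk[, 1L] * dims[2L] * dims[3L] + ijk[, 2L] * dims[3L] + ijk[, 3L]
  ord <- order(flat)
  structure(
    list(dims = dims,
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         mask = mask,
         coords = ijk[ord, , drop = FALSE],
         flat_index = flat[ord],
         lin_index = idx[ord]),            # column-major index into arrays
    class = "voxel_space")
}

#' Number of in-mask voxels
#' @param vs a [voxel_space()].
#' @return Integer voxel count.
#' @export
n_voxels <- function(vs) {
  stopifnot(inherits(vs, "voxel_space"))
  length(vs$flat_index)
}

#' @export
print.voxel_space <- function(x, ...) {
  cat(sprintf("voxel_space: %d x %d x %d grid, %d in-mask voxels (%.0f%%)\n",
              x$dims[1], x$dims[2], x$dims[3], n_voxels(x),
              100 * n_voxels(x) / prod(x$dims)))
  invisible(x)
}

#' Embed an in-mask vector into the full 3D grid
#'
#' @param vs a [voxel_space()].
#' @param values numeric vector, one value per in-mask voxel (matrix-column
#'   order).
#' @param fill value used outside the mask.
#' @return 3D numeric array with the grid dimensions of `vs`.
#' @export
unmask <- function(vs, values, fill = 0) {
  stopifnot(inherits(vs, "voxel_space"), length(values) == n_voxels(vs))
  out <- array(fill, dim = vs$dims)
  out[vs$lin_index] <- values
  out
}

#' Extract in-mask values from a 3D array
#'
#' Inverse of [unmask()]: returns values in the column order of the
#' subjects-by-voxels matrix.
#' @param vs a [voxel_space()].
#' @param arr 3D array matching the grid dimensions of `vs`.
#' @return Numeric vector of length `n_voxels(vs)`.
#' @export
mask_values <- function(vs, arr) {
  stopifnot(inherits(vs, "voxel_space"))
  if (!identical(dim(arr), vs$dims)) stop("array dimensions do not match voxel space")
  arr[vs$lin_index]
}

#' Ellipsoidal brain-like mask
#'
#' Builds a centred ellipsoid inscribed in the grid, the stand-in brain
#' mask used by the synthetic cohort generator.
#'
#' @param dims integer length-3 grid dimensions.
#' @param shrink fraction of the half-extent used as semi-axis (default
#'   0.92, leaving a rim of background voxels).
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(dims, shrink = 0.92) {
  dims <- as.integer(dims)
  centre <- (dims - 1) / 2
  semi <- pmax((dims - 1) / 2 * shrink, 0.5)
  i <- (seq_len(dims[1]) - 1 - centre[1]) / semi[1]
  j <- (seq_len(dims[2]) - 1 - centre[2]) / semi[2]
  k <- (seq_len(dims[3]) - 1 - centre[3]) / semi[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  array(r2 <= 1, dim = dims)
}
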