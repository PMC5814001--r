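#' Voxelized linear attenuation map
#'
#' Container for a voxel grid of linear attenuation coefficients mu (1/cm)
#' with physical voxel spacing and world origin. World coordinates refer to
#' voxel centers: the voxel at index (1,1,1) is centered at `origin`, and the
#' grid occupies the half-open box `[origin - spacing/2, origin +
#' (n - 1/2) * spacing)` per axis. A single-slice (nz = 1) map is the
#' degenerate 2D case used by the single-slice planner and fan-beam studies.
#'
#' @param values numeric matrix (2D) or 3D array of mu values in 1/cm; all
#'   finite and non-negative.
#' @param spacing voxel size per axis in cm; a scalar is recycled, a length-2
#'   vector gets a slice thickness equal to the in-plane spacing.
#' @param origin world coordinate (cm) of the center of voxel (1,1,1); default
#'   centers the grid on the isocenter.
#' @return An object of class `attenuation_map` with fields `values` (3D
#'   array), `spacing` and `origin` (length-3 numerics).
#' @examples
#' m <- attenuation_map(matrix(0.206, 8, 8), spacing = 0.25)
#' dim(m$values)
#' @export
attenuation_map <- function(values, spacing, origin = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    .stop_validation("values must be a matrix or 3D array")
  if (any(dim(values) < 1L)) .stop_validation("grid needs >= 1 voxel per axis")
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    .stop_validation("attenuation values must be finite and >= 0")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) == 2L) spacing <- c(spacing, spacing[[1L]])
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .stop_validation("spacing must be strictly positive on every axis")
  n <- dim(values)
  if (is.null(origin)) origin <- -(n - 1) / 2 * spacing
  if (length(origin) != 3L || any(!is.finite(origin)))
    .stop_validation("origin must be a finite length-3 numeric")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "attenuation_map")
}

#' @export
print.attenuation_map <- function(x, ...) {
  n <- dim(x$values)
  cat(sprintf("attenuation_map: %d x %d x %d voxels, spacing (%g, %g, %g) cm\n",
              n[1], n[2], n[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  mu range [%.4g, %.4g] 1/cm, origin (%g, %g, %g) cm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Extract one axial slice as a 2D degenerate map
#'
#' The planner operates on a single chosen slice of the prior CT; this pulls
#' slice `slice_index` (1-based, along the third axis) preserving in-plane
#' spacing and the slice's world position.
#'
#' @param map an [attenuation_map()].
#' @param slice_index 1-based slice index along the z axis.
#' @return A single-slice `attenuation_map`.
#' @export
select_slice <- function(map, slice_index) {
  stopifnot(inherits(map, "attenuation_map"))
  nz <- dim(map$values)[3L]
  if (length(slice_index) != 1L || !is.finite(slice_index) ||
      slice_index != round(slice_index) || slice_index < 1 || slice_index > nz)
    .stop_validation("slice_index must be an integer in [1, ", nz, "]")
  k <- as.integer(slice_index)
  vals <- map$values[, , k, drop = FALSE]
  origin <- map$origin
  origin[3] <- map$origin[3] + (k - 1) * map$spacing[3]
  attenuation_map(vals, map$spacing, origin)
}

# voxel-center world coordinates along one axis
.axis_coords <- function(map, axis) {
  n <- dim(map$values)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$spacing[axis]
}
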