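#' Regularly gridded 3D scalar field
#'
#' Container for a scalar function sampled on a regular 3D grid. Values are
#' stored in a 3D array with the x index varying fastest (R's native array
#' order); 2D data is represented with a trailing singleton dimension.
#'
#' @param values numeric vector or array of scalar values; all finite.
#' @param dims integer vector of length 3 (grid size per axis). May be omitted
#'   when `values` is already a 3D array.
#' @param spacing positive numeric vector of length 3, physical voxel spacing.
#' @return An object of class `scalar_field` with elements `values` (3D array),
#'   `dims`, `spacing` and `value_range`.
#' @examples
#' f <- scalar_field(0:3, dims = c(4, 1, 1))
#' f$value_range
#' @export
scalar_field <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dims)) {
    if (is.array(values) && length(dim(values)) == 3L) {
      dims <- dim(values)
    } else {
      stop("`dims` must be given unless `values` is a 3D array")
    }
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be 3 positive integers")
  }
  values <- as.numeric(values)
  if (length(values) != prod(dims)) {
    stop(sprintf("length(values) = %d does not match prod(dims) = %d",
                 length(values), prod(dims)))
  }
  if (!all(is.finite(values))) stop("all scalar values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive reals")
  }
  structure(
    list(values = array(values, dim = dims),
         dims = dims,
         spacing = spacing,
         value_range = range(values)),
    class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field: %d x %d x %d (%d voxels)\n",
              x$dims[1], x$dims[2], x$dims[3], prod(x$dims)))
  cat(sprintf("  spacing: %g x %g x %g\n", x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range: [%g, %g]\n", x$value_range[1], x$value_range[2]))
  invisible(x)
}

is_scalar_field <- function(x) inherits(x, "scalar_field")

stopifnot_field <- function(field) {
  if (!is_scalar_field(field)) stop("expected a `scalar_field` object")
}

#' Voxel physical volume of a field's grid cell
#' @param field a `scalar_field`.
#' @return product of the grid spacings.
#' @keywords internal
voxel_volume <- function(field) prod(field$spacing)
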