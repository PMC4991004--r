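#' Synthetic volumes with known topology
#'
#' Fixture generators producing scalar fields whose contour trees are known
#' analytically, so every stage of the pipeline can be tested without external
#' data: a monotone ramp (single arc), sums of well-separated Gaussian blobs
#' (one maximum leaf per blob), and a nested peak hierarchy (a branch chain of
#' prescribed depth emulating inclusion relations between structures).
#'
#' @name synthetic_volumes
NULL

#' Monotone ramp volume
#'
#' `f(x, y, z) = x` (0-based voxel index along x). The contour tree is a
#' single arc from the minimum slab (x = 0) to the maximum slab.
#'
#' @param dims grid dimensions (3 positive integers).
#' @param spacing voxel spacing.
#' @return a [scalar_field].
#' @examples
#' ramp_volume(c(4, 1, 1))$values
#' @export
ramp_volume <- function(dims, spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  vals <- rep(seq_len(dims[1]) - 1, times = prod(dims[2:3]))
  scalar_field(vals, dims, spacing)
}

#' Multi-blob volume
#'
#' Sum of isotropic Gaussian bumps, `f(x) = sum_j h_j exp(-||x - c_j||^2 /
#' (2 w_j^2))` over 0-based voxel coordinates. For well-separated blobs the
#' contour tree has one maximum leaf per blob; saddle values are approximately
#' the field value at the ridge point between blob pairs.
#'
#' @param dims grid dimensions.
#' @param centers numeric matrix (one row per blob) of 0-based voxel
#'   coordinates.
#' @param heights distinct positive peak heights, one per blob.
#' @param widths Gaussian standard deviations (voxels), one per blob
#'   (recycled).
#' @param spacing voxel spacing.
#' @return a [scalar_field].
#' @examples
#' f <- multi_blob_volume(c(16, 8, 8),
#'                        centers = rbind(c(4, 4, 4), c(11, 4, 4)),
#'                        heights = c(9, 8), widths = 1.6)
#' @export
multi_blob_volume <- function(dims, centers, heights, widths,
                              spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  centers <- rbind(centers)
  k <- nrow(centers)
  if (k < 1L) stop("need at least one blob")
  if (length(heights) != k) stop("one height per blob required")
  if (anyDuplicated(heights)) stop("blob heights must be distinct")
  if (anyDuplicated(centers)) stop("blob centers must be distinct")
  widths <- rep_len(widths, k)
  gx <- seq_len(dims[1]) - 1
  gy <- seq_len(dims[2]) - 1
  gz <- seq_len(dims[3]) - 1
  co <- expand.grid(x = gx, y = gy, z = gz)
  fval <- function(x, y, z) {
    out <- 0
    for (j in seq_len(k)) {
      d2 <- (x - centers[j, 1])^2 + (y - centers[j, 2])^2 + (z - centers[j, 3])^2
      out <- out + heights[j] * exp(-d2 / (2 * widths[j]^2))
    }
    out
  }
  vals <- fval(co$x, co$y, co$z)
  f <- scalar_field(vals, dims, spacing)
  # analytic ground truth: one maximum leaf per blob; inter-blob saddles are
  # approximately the field value at the midpoint between center pairs. The
  # far Gaussian tails add only branches of near-zero persistence, separated
  # from the real structure by `simplify_threshold`.
  mids <- if (k > 1) {
    apply(utils::combn(k, 2), 2, function(pp) {
      m <- (centers[pp[1], ] + centers[pp[2], ]) / 2
      fval(m[1], m[2], m[3])
    })
  } else numeric(0)
  attr(f, "tree_summary") <- list(
    n_max_leaves = k, peak_heights = sort(heights, decreasing = TRUE),
    approx_saddles = mids,
    simplify_threshold = if (k > 1) min(heights) / 4 else min(heights) / 4)
  f
}

#' Nested peak hierarchy volume
#'
#' Produces a field whose branch decomposition is a chain of `levels`
#' branches at topological depths `0 .. levels - 1`, emulating inclusion
#' relations between structures. Peaks of strictly decreasing height are
#' placed along the x axis with strictly decreasing gaps, so each peak's
#' superlevel component merges into the previous peak's component at a
#' successively higher saddle: peak k joins peak k-1 before the pair joins
#' peak k-2, attaching branch k under branch k-1.
#'
#' @param dims grid dimensions; x extent must accommodate the chain
#'   (roughly `6 + 5 * levels` voxels for the defaults).
#' @param levels number of branches in the chain (>= 1).
#' @param spacing voxel spacing.
#' @return a [scalar_field].
#' @examples
#' f <- nested_shell_volume(c(26, 9, 9), levels = 3)
#' @export
nested_shell_volume <- function(dims, levels, spacing = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (levels < 1L) stop("levels must be >= 1")
  # peak x positions: decreasing gaps (8, 7, 6, ...) so deeper saddles are higher
  gaps <- pmax(8 - seq_len(max(levels - 1L, 0L)) + 1, 3)
  xs <- cumsum(c(4, gaps))[seq_len(levels)]
  if (max(xs) + 4 > dims[1]) {
    stop(sprintf("levels = %d needs x extent >= %d (got %d)",
                 levels, max(xs) + 4, dims[1]))
  }
  yc <- (dims[2] - 1) / 2
  zc <- (dims[3] - 1) / 2
  heights <- 10 * 0.85^(seq_len(levels) - 1)
  f <- multi_blob_volume(dims,
                         centers = cbind(xs, yc, zc),
                         heights = heights,
                         widths = 1.8,
                         spacing = spacing)
  # consecutive-peak saddles only; deeper saddles are higher, so the branch
  # decomposition (after pruning tail noise below simplify_threshold) is a
  # chain with depths 0 .. levels - 1
  cons <- if (levels > 1) {
    vapply(seq_len(levels - 1), function(j) {
      m <- (xs[j] + xs[j + 1]) / 2
      vtx <- round(m) + 1
      f$values[vtx, round(yc) + 1, round(zc) + 1]
    }, numeric(1))
  } else numeric(0)
  attr(f, "tree_summary") <- list(
    n_max_leaves = levels, peak_heights = heights,
    approx_saddles = cons, depths = seq_len(levels) - 1L,
    simplify_threshold = 1)
  f
}

#' Add seeded Gaussian noise to a field
#'
#' @param field a [scalar_field].
#' @param sigma noise standard deviation (>= 0); 0 returns the field
#'   unchanged.
#' @param seed integer RNG seed; the caller's RNG state is preserved.
#' @return a [scalar_field].
#' @export
add_noise <- function(field, sigma, seed = 1L) {
  stopifnot_field(field)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(field)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  vals <- as.vector(field$values) + stats::rnorm(prod(field$dims), 0, sigma)
  scalar_field(vals, field$dims, field$spacing)
}

#' Quantize a field to uint8 range
#'
#' Linearly rescales values to integers in `[0, 255]`, mimicking typical
#' 8-bit volume data.
#' @param field a [scalar_field].
#' @return a [scalar_field] with integer values in `[0, 255]`.
#' @export
quantize_uint8 <- function(field) {
  stopifnot_field(field)
  r <- field$value_range
  v <- if (diff(r) == 0) rep(0, prod(field$dims)) else
    round(255 * (as.vector(field$values) - r[1]) / diff(r))
  scalar_field(v, field$dims, field$spacing)
}
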