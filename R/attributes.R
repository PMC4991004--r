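#' Area of the importance triangle
#'
#' Concrete realization of the three-measure importance triangle: the three
#' normalized measures are laid out as distances along three coplanar axes
#' 120 degrees apart and the triangle through the three points is measured.
#' That area is `(sqrt(3)/4) * (p*v + v*hv + hv*p)`; it is symmetric in its
#' arguments, zero iff at least two of the three are zero, and monotone
#' non-decreasing in each.
#'
#' @param p,v,hv normalized persistence, volume and hypervolume in `[0, 1]`
#'   (vectors recycled to common length).
#' @return the triangle area (max `3*sqrt(3)/4` at `(1, 1, 1)`).
#' @examples
#' importance_triangle_area(1, 1, 1)  # ~1.299
#' @export
importance_triangle_area <- function(p, v, hv) {
  k <- max(length(p), length(v), length(hv))
  p <- rep_len(p, k); v <- rep_len(v, k); hv <- rep_len(hv, k)
  if (any(p < 0 | p > 1 | v < 0 | v > 1 | hv < 0 | hv > 1)) {
    stop("inputs to importance_triangle_area must be normalized to [0, 1]")
  }
  (sqrt(3) / 4) * (p * v + v * hv + hv * p)
}

#' Topological saliency of branches
#'
#' Relative local importance of each branch: `S_i = t_i / sum_j w_ij t_j`
#' with Gaussian depth weights `w_ij = exp(-d(i,j)^2 / r^2)`, where `d(i,j)`
#' is the topological depth difference between branches and `r` the
#' neighborhood radius (by default the maximum topological depth of the
#' tree; for a flat tree `r = 1`, making all weights 1 so saliency reduces
#' to `t_i / sum t_j`). The sum runs over all branches, `w_ii = 1`, and
#' `S_i` lies in `(0, 1]`. Scaling all `t` by a constant leaves `S`
#' unchanged.
#'
#' @param attrs branch attribute table from [annotate_structure()] (needs
#'   columns `depth` and the measure column).
#' @param t which measure feeds the saliency: `"persistence"` or `"volume"`.
#' @param r neighborhood radius; default `max(depth)`, floored at 1.
#' @return numeric vector of saliencies, one per row of `attrs`.
#' @export
topological_saliency <- function(attrs, t = c("persistence", "volume"), r = NULL) {
  t <- match.arg(t)
  ti <- switch(t, persistence = attrs$persistence, volume = attrs$volume)
  if (all(ti == 0)) stop("all branch measures are zero; saliency undefined")
  depth <- attrs$depth
  if (is.null(r)) r <- max(max(depth), 1L)
  if (r <= 0) stop("r must be > 0")
  d <- abs(outer(depth, depth, "-"))
  w <- exp(-d^2 / r^2)
  as.vector(ti / (w %*% ti))
}

#' Annotate branches with topological attributes
#'
#' Fills, for every branch of the decomposition: persistence (absolute
#' scalar difference between the branch's endpoint critical nodes), volume
#' (voxel count of its segmented region), hypervolume (Riemann sum of the
#' field over that region times the voxel volume), topological depth (root =
#' 0), sibling and child counts, attachment saddle value, topological
#' saliency, and the importance-triangle area with persistence / volume /
#' hypervolume each normalized to `[0, 1]` within the branch's sibling group.
#'
#' @param bd a `branch_decomposition`.
#' @param field the originating [scalar_field].
#' @param seg optional `segmentation_map`; recomputed from `bd` when absent.
#' @param saliency_measure measure feeding [topological_saliency()].
#' @return data.frame of class `branch_attributes`, one row per branch:
#'   `branch_id`, `persistence`, `volume`, `hypervolume`, `depth`,
#'   `n_siblings`, `n_children`, `saddle_value`, `saliency`, `triangle_area`.
#' @export
annotate_structure <- function(bd, field, seg = NULL,
                               saliency_measure = "persistence") {
  if (!inherits(bd, "branch_decomposition")) stop("expected a `branch_decomposition`")
  stopifnot_field(field)
  if (is.null(seg)) seg <- segment_field(field, bd)
  if (!identical(as.integer(seg$dims), as.integer(field$dims))) {
    stop("segmentation does not match the field")
  }
  br <- bd$branches
  labs <- as.vector(seg$labels)
  vv <- voxel_volume(field)
  counts <- vapply(br$id, function(b) sum(labs == b), numeric(1))
  vsums <- vapply(br$id, function(b) sum(field$values[labs == b]), numeric(1))

  n_children <- vapply(br$id, function(b)
    sum(!is.na(br$parent) & br$parent == b), integer(1))
  n_siblings <- vapply(seq_len(nrow(br)), function(i) {
    p <- br$parent[i]
    if (is.na(p)) 0L else sum(!is.na(br$parent) & br$parent == p) - 1L
  }, integer(1))
  saddle_value <- ifelse(is.na(br$saddle_node), NA_real_,
                         bd$nodes$value[match(br$saddle_node, bd$nodes$id)])

  attrs <- data.frame(
    branch_id = br$id,
    persistence = br$persistence,
    volume = counts,
    hypervolume = vsums * vv,
    depth = br$depth,
    n_siblings = n_siblings,
    n_children = n_children,
    saddle_value = saddle_value)
  # a fully degenerate tree (all persistences zero, e.g. a constant field)
  # falls back to volume, which is positive for any non-empty branch
  if (saliency_measure == "persistence" && all(attrs$persistence == 0)) {
    saliency_measure <- "volume"
  }
  attrs$saliency <- topological_saliency(attrs, saliency_measure)

  # importance triangle normalized within each sibling group (root = own group)
  grp <- ifelse(is.na(br$parent), 0L, br$parent)
  tri <- numeric(nrow(attrs))
  for (g in unique(grp)) {
    i <- which(grp == g)
    tri[i] <- importance_triangle_area(
      .norm_by_max(attrs$persistence[i]),
      .norm_by_max(attrs$volume[i]),
      .norm_by_max(abs(attrs$hypervolume[i])))
  }
  attrs$triangle_area <- tri
  class(attrs) <- c("branch_attributes", "data.frame")
  attrs
}

# normalize by the group maximum; all-zero groups stay zero
.norm_by_max <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x * 0
}

#' Write a branch attribute table to CSV
#' @param attrs a `branch_attributes` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_attributes_csv <- function(attrs, path) {
  utils::write.csv(as.data.frame(attrs), path, row.names = FALSE)
  invisible(path)
}
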