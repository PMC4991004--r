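#' Branch decomposition of a contour tree
#'
#' Decomposes the contour tree into monotone paths (branches): the root
#' branch connects the globally most important extremum pair and every other
#' branch runs from a leaf extremum to the saddle where it attaches to its
#' parent. The decomposition is built by greedy leaf pruning: at each step
#' the leaf arc with the smallest importance measure is peeled off and
#' becomes a branch, and saddles left with one arc above and one below are
#' smoothed into a single arc, so the surviving paths always carry the
#' highest-measure monotone routes.
#'
#' @param ct a `contour_tree` (see [contour_tree()]).
#' @param measure importance measure driving the greedy pairing:
#'   `"persistence"` (absolute scalar difference between the branch's
#'   endpoints), `"volume"` (voxel count of the region the branch indexes),
#'   `"hypervolume"` (integral of the field over that region), or
#'   `"triangle_area"` (area of the importance triangle spanned by the three,
#'   each normalized across the current leaf candidates).
#' @return an object of class `branch_decomposition` with a `branches`
#'   data.frame (id, top/bottom/extremum/saddle node ids, parent, depth,
#'   n_voxels, value_sum), `node_paths` (ordered node ids per branch),
#'   `vertex_branch` (per-voxel branch id) and the contour-tree node table.
#' @examples
#' bd <- decompose_branches(contour_tree(ramp_volume(c(4, 1, 1))))
#' bd$branches
#' @export
decompose_branches <- function(ct, measure = c("persistence", "volume",
                                               "hypervolume", "triangle_area")) {
  if (!inherits(ct, "contour_tree")) stop("expected a `contour_tree`")
  measure <- match.arg(measure)
  nodes <- ct$nodes
  vol <- prod(ct$spacing)

  if (nrow(ct$arcs) == 0L) {  # degenerate single-node tree
    branches <- data.frame(
      id = 1L, top_node = 1L, bottom_node = 1L, extremum_node = 1L,
      saddle_node = NA_integer_, parent = NA_integer_, depth = 0L,
      n_voxels = length(ct$values), value_sum = sum(ct$values),
      persistence = 0)
    return(structure(list(branches = branches, node_paths = list(`1` = 1L),
                          vertex_branch = rep(1L, length(ct$values)),
                          nodes = nodes, values = ct$values, dims = ct$dims,
                          spacing = ct$spacing, measure = measure,
                          root = 1L),
                     class = "branch_decomposition"))
  }

  # per reduced arc: voxel count and field sum (for volume / hypervolume)
  n_arc0 <- nrow(ct$arcs)
  a_nvox <- tabulate(ct$vertex_arc, nbins = n_arc0)
  a_vsum <- as.vector(rowsum(ct$values, group = factor(ct$vertex_arc,
                                                       levels = seq_len(n_arc0))))
  # mutable arc state; merged arcs get fresh slots appended
  a_upper <- ct$arcs$upper
  a_lower <- ct$arcs$lower
  a_path <- mapply(function(u, l) c(u, l), a_upper, a_lower, SIMPLIFY = FALSE)
  a_members <- as.list(seq_len(n_arc0))   # original arc ids merged in
  a_alive <- rep(TRUE, n_arc0)
  val <- nodes$value
  m <- nrow(nodes)
  inc <- lapply(seq_len(m), function(v) integer(0))
  for (a in seq_len(n_arc0)) {
    inc[[a_upper[a]]] <- c(inc[[a_upper[a]]], a)
    inc[[a_lower[a]]] <- c(inc[[a_lower[a]]], a)
  }
  deg <- lengths(inc)

  # the root branch must connect the global extremum pair, so arcs whose
  # leaf endpoint is the global maximum or minimum are never pruned
  # (ties broken by vertex index, as in the sweep)
  gmax <- which.max(val + 1e-12 * nodes$vertex_index / max(nodes$vertex_index))
  gmin <- which.min(val - 1e-12 * nodes$vertex_index / max(nodes$vertex_index))

  br_extremum <- integer(0); br_saddle <- integer(0)
  br_nvox <- numeric(0); br_vsum <- numeric(0)
  br_paths <- list()
  branch_of_orig_arc <- integer(n_arc0)
  nb <- 0L

  arc_measure <- function(cand, leaf_end) {
    p <- abs(val[leaf_end] - ifelse(a_upper[cand] == leaf_end,
                                    val[a_lower[cand]], val[a_upper[cand]]))
    v <- a_nvox[cand]
    hv <- a_vsum[cand] * vol
    switch(measure,
      persistence = p,
      volume = v,
      hypervolume = hv,
      triangle_area = {
        pn <- if (max(p) > 0) p / max(p) else p * 0
        vn <- if (max(v) > 0) v / max(v) else v * 0
        hn <- if (max(abs(hv)) > 0) abs(hv) / max(abs(hv)) else hv * 0
        importance_triangle_area(pn, vn, hn)
      })
  }

  new_branch <- function(arc, leaf_node, saddle_node) {
    nb <<- nb + 1L
    br_extremum[nb] <<- leaf_node
    br_saddle[nb] <<- saddle_node
    br_nvox[nb] <<- a_nvox[arc]
    br_vsum[nb] <<- a_vsum[arc]
    br_paths[[nb]] <<- a_path[[arc]]
    branch_of_orig_arc[a_members[[arc]]] <<- nb
  }

  while (sum(a_alive) > 1L) {
    live <- which(a_alive)
    leaf_end <- integer(length(live)); is_leaf <- logical(length(live))
    for (i in seq_along(live)) {
      a <- live[i]
      if (deg[a_upper[a]] == 1L) { is_leaf[i] <- TRUE; leaf_end[i] <- a_upper[a] }
      else if (deg[a_lower[a]] == 1L) { is_leaf[i] <- TRUE; leaf_end[i] <- a_lower[a] }
    }
    keep <- is_leaf & !(leaf_end %in% c(gmax, gmin))
    cand <- live[keep]; cend <- leaf_end[keep]
    if (!length(cand)) break
    mv <- arc_measure(cand, cend)
    pick <- which.min(mv)
    a <- cand[pick]; leaf <- cend[pick]
    s <- if (a_upper[a] == leaf) a_lower[a] else a_upper[a]
    new_branch(a, leaf, s)
    a_alive[a] <- FALSE
    inc[[leaf]] <- setdiff(inc[[leaf]], a)
    inc[[s]] <- setdiff(inc[[s]], a)
    deg[leaf] <- deg[leaf] - 1L
    deg[s] <- deg[s] - 1L
    # smooth the saddle if it became regular (one arc above, one below)
    if (deg[s] == 2L) {
      rest <- inc[[s]]
      aup <- rest[a_lower[rest] == s]
      adn <- rest[a_upper[rest] == s]
      if (length(aup) == 1L && length(adn) == 1L) {
        k <- length(a_alive) + 1L
        a_upper[k] <- a_upper[aup]; a_lower[k] <- a_lower[adn]
        a_nvox[k] <- a_nvox[aup] + a_nvox[adn]
        a_vsum[k] <- a_vsum[aup] + a_vsum[adn]
        a_path[[k]] <- c(a_path[[aup]], a_path[[adn]][-1L])
        a_members[[k]] <- c(a_members[[aup]], a_members[[adn]])
        a_alive[k] <- TRUE
        a_alive[aup] <- FALSE; a_alive[adn] <- FALSE
        inc[[a_upper[k]]] <- c(setdiff(inc[[a_upper[k]]], aup), k)
        inc[[a_lower[k]]] <- c(setdiff(inc[[a_lower[k]]], adn), k)
        inc[[s]] <- integer(0)
        deg[s] <- 0L
      }
    }
  }
  # the remaining arcs form the root branch: the monotone path between the
  # global extrema (a single arc, except when the path runs through
  # degenerate saddles that resist smoothing)
  rest <- which(a_alive)
  nb <- nb + 1L
  root_nodes <- unique(unlist(a_path[rest]))
  root_nodes <- root_nodes[order(val[root_nodes], nodes$vertex_index[root_nodes],
                                 decreasing = TRUE)]
  br_extremum[nb] <- root_nodes[1L]
  br_saddle[nb] <- NA_integer_
  br_nvox[nb] <- sum(a_nvox[rest])
  br_vsum[nb] <- sum(a_vsum[rest])
  br_paths[[nb]] <- root_nodes
  branch_of_orig_arc[unlist(a_members[rest])] <- nb
  root <- nb

  # parent = the branch whose path runs through the attachment saddle
  owner <- integer(m)
  for (b in seq_len(nb)) {
    pth <- br_paths[[b]]
    own <- if (is.na(br_saddle[b])) pth else setdiff(pth, br_saddle[b])
    owner[own] <- b
  }
  parent <- rep(NA_integer_, nb)
  for (b in seq_len(nb)) {
    if (!is.na(br_saddle[b])) parent[b] <- owner[br_saddle[b]]
  }
  depth <- rep(NA_integer_, nb)
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    p0 <- queue[1]; queue <- queue[-1]
    kids <- which(!is.na(parent) & parent == p0)
    depth[kids] <- depth[p0] + 1L
    queue <- c(queue, kids)
  }

  top_bot <- t(vapply(seq_len(nb), function(b) {
    pth <- br_paths[[b]]
    ends <- c(pth[1L], pth[length(pth)])
    if (val[ends[1]] >= val[ends[2]]) ends else rev(ends)
  }, integer(2)))

  branches <- data.frame(
    id = seq_len(nb),
    top_node = top_bot[, 1], bottom_node = top_bot[, 2],
    extremum_node = br_extremum, saddle_node = br_saddle,
    parent = parent, depth = depth,
    n_voxels = br_nvox, value_sum = br_vsum,
    persistence = abs(val[top_bot[, 1]] - val[top_bot[, 2]]))

  structure(list(branches = branches,
                 node_paths = stats::setNames(br_paths, seq_len(nb)),
                 vertex_branch = branch_of_orig_arc[ct$vertex_arc],
                 nodes = nodes, values = ct$values, dims = ct$dims,
                 spacing = ct$spacing, measure = measure, root = root),
            class = "branch_decomposition")
}

#' @export
print.branch_decomposition <- function(x, ...) {
  cat(sprintf("branch_decomposition: %d branches (max depth %d), measure = %s\n",
              nrow(x$branches), max(x$branches$depth), x$measure))
  invisible(x)
}

branch_children <- function(bd) {
  br <- bd$branches
  lapply(stats::setNames(br$id, br$id),
         function(b) br$id[!is.na(br$parent) & br$parent == b])
}

.branch_measure <- function(bd, measure, ids = bd$branches$id) {
  br <- bd$branches[match(ids, bd$branches$id), , drop = FALSE]
  vol <- prod(bd$spacing)
  switch(measure,
    persistence = br$persistence,
    volume = br$n_voxels,
    hypervolume = br$value_sum * vol,
    triangle_area = {
      p <- br$persistence; v <- br$n_voxels; hv <- abs(br$value_sum * vol)
      pn <- if (max(p) > 0) p / max(p) else p * 0
      vn <- if (max(v) > 0) v / max(v) else v * 0
      hn <- if (max(hv) > 0) hv / max(hv) else hv * 0
      importance_triangle_area(pn, vn, hn)
    },
    stop(sprintf("unknown measure '%s'", measure)))
}

#' Simplify a branch decomposition
#'
#' Iteratively prunes leaf branches (branches without children) whose
#' importance measure falls below `threshold`, smallest first, never removing
#' the root; parent eligibility is recomputed after each removal. Voxels of a
#' pruned branch are reassigned to its parent, so the segmentation remains a
#' partition. Alternatively prunes down to `target_branch_count` branches.
#'
#' @param bd a `branch_decomposition`.
#' @param measure importance measure; defaults to the one used to build `bd`.
#' @param threshold prune leaf branches with measure strictly below this.
#' @param target_branch_count prune smallest-measure leaf branches until this
#'   many remain. If larger than the current count, the input is returned
#'   unchanged with a warning.
#' @return a simplified `branch_decomposition` (original branch ids kept).
#' @export
simplify_tree <- function(bd, measure = bd$measure, threshold = NULL,
                          target_branch_count = NULL) {
  if (!inherits(bd, "branch_decomposition")) stop("expected a `branch_decomposition`")
  if (is.null(threshold) == is.null(target_branch_count)) {
    stop("give exactly one of `threshold` or `target_branch_count`")
  }
  if (!is.null(threshold) && threshold < 0) stop("threshold must be >= 0")
  if (!is.null(target_branch_count)) {
    if (target_branch_count < 1) stop("target_branch_count must be >= 1")
    if (target_branch_count > nrow(bd$branches)) {
      warning("target_branch_count exceeds current branch count; returning input unchanged")
      return(bd)
    }
  }
  br <- bd$branches
  vb <- bd$vertex_branch
  paths <- bd$node_paths
  repeat {
    if (!is.null(target_branch_count) && nrow(br) <= target_branch_count) break
    has_child <- br$id %in% br$parent[!is.na(br$parent)]
    cand <- which(!has_child & br$id != bd$root)
    if (!length(cand)) break
    sub <- bd
    sub$branches <- br
    mv <- .branch_measure(sub, measure, br$id[cand])
    pick <- cand[which.min(mv)]
    if (!is.null(threshold) && min(mv) >= threshold) break
    rid <- br$id[pick]
    pid <- br$parent[pick]
    pidx <- match(pid, br$id)
    br$n_voxels[pidx] <- br$n_voxels[pidx] + br$n_voxels[pick]
    br$value_sum[pidx] <- br$value_sum[pidx] + br$value_sum[pick]
    vb[vb == rid] <- pid
    paths[[as.character(rid)]] <- NULL
    br <- br[-pick, , drop = FALSE]
  }
  out <- bd
  out$branches <- br
  out$vertex_branch <- vb
  out$node_paths <- paths
  out
}

#' Segment a field by its branch decomposition
#'
#' Labels every voxel with the branch it belongs to: the voxel's superlevel /
#' sublevel sweep component assigns it to an arc of the augmented contour
#' tree, and the arc to the most specific branch containing it. The labels
#' partition the volume.
#'
#' @param field the [scalar_field] the decomposition was built from.
#' @param bd a `branch_decomposition`.
#' @return an object of class `segmentation_map` with `labels` (3D array of
#'   branch ids), `dims`, `spacing`.
#' @export
segment_field <- function(field, bd) {
  stopifnot_field(field)
  if (!inherits(bd, "branch_decomposition")) stop("expected a `branch_decomposition`")
  if (!identical(as.integer(field$dims), as.integer(bd$dims)) ||
      length(bd$vertex_branch) != prod(field$dims)) {
    stop("field and branch decomposition do not match")
  }
  structure(list(labels = array(bd$vertex_branch, dim = field$dims),
                 dims = field$dims, spacing = field$spacing,
                 branch_ids = sort(unique(bd$vertex_branch))),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("segmentation_map: %d x %d x %d, %d branch labels\n",
              x$dims[1], x$dims[2], x$dims[3], length(x$branch_ids)))
  invisible(x)
}
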