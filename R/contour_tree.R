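# Neighborhood offsets for 6- or 26-connectivity on a regular grid.
.neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else if (connectivity == 26) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
  } else stop("connectivity must be 6 or 26")
}

# n x K neighbor linear-index matrix, NA outside the grid. x varies fastest.
.neighbor_matrix <- function(dims, connectivity) {
  off <- .neighbor_offsets(connectivity)
  n <- prod(dims)
  ix <- seq_len(n) - 1L
  x <- ix %% dims[1]
  y <- (ix %/% dims[1]) %% dims[2]
  z <- ix %/% (dims[1] * dims[2])
  nb <- matrix(NA_integer_, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    nx <- x + off[k, 1]; ny <- y + off[k, 2]; nz <- z + off[k, 3]
    ok <- nx >= 0 & nx < dims[1] & ny >= 0 & ny < dims[2] & nz >= 0 & nz < dims[3]
    nb[ok, k] <- 1L + nx[ok] + dims[1] * (ny[ok] + dims[2] * nz[ok])
  }
  nb
}

# Total order implementing simulation of simplicity: vertices compared by
# (value, linear index), so every event in the sweep is distinct.
.sos_rank <- function(values) {
  n <- length(values)
  perm <- order(values, seq_len(n))
  rk <- integer(n)
  rk[perm] <- seq_len(n)
  list(rank = rk, perm = perm)
}

#' Build a merge tree (join or split tree) of a scalar field
#'
#' Sweeps the vertices in sorted order with a union-find, tracking connected
#' components of superlevel sets (`direction = "ascending"`, the join tree:
#' components appear at maxima and merge at join saddles) or sublevel sets
#' (`direction = "descending"`, the split tree). Ties between equal scalar
#' values are broken by linear vertex index (simulation of simplicity), so
#' all critical events are distinct.
#'
#' The returned tree is augmented: every grid vertex is a tree vertex, with a
#' parent pointer toward the sweep's later (lower for join, higher for split)
#' values. [merge_tree_nodes()] extracts the critical nodes.
#'
#' @param field a [scalar_field].
#' @param direction `"ascending"` (join tree) or `"descending"` (split tree).
#' @param connectivity 6 or 26.
#' @return an object of class `merge_tree`.
#' @export
build_merge_tree <- function(field, direction = c("ascending", "descending"),
                             connectivity = 6) {
  stopifnot_field(field)
  direction <- match.arg(direction)
  if (max(field$dims) < 2L) stop("field must extend over at least 2 voxels in some axis")
  values <- as.vector(field$values)
  n <- length(values)
  if (diff(field$value_range) == 0) {
    return(structure(list(parent = integer(n), constant = TRUE, n = n,
                          values = values, direction = direction,
                          connectivity = connectivity, dims = field$dims),
                     class = "merge_tree"))
  }
  so <- .sos_rank(values)
  proc <- if (direction == "ascending") rev(so$perm) else so$perm
  nb <- .neighbor_matrix(field$dims, connectivity)
  uf <- integer(n)          # 0 = unprocessed; else union-find parent
  lowest <- integer(n)      # per-root: most recently absorbed vertex
  parent <- integer(n)      # merge-tree parent pointer (0 = tree root)
  for (v in proc) {
    uf[v] <- v
    lowest[v] <- v
    rv <- v
    for (u in nb[v, ]) {
      if (is.na(u) || uf[u] == 0L) next
      ru <- u
      while (uf[ru] != ru) { uf[ru] <- uf[uf[ru]]; ru <- uf[ru] }
      while (uf[rv] != rv) { uf[rv] <- uf[uf[rv]]; rv <- uf[rv] }
      if (ru != rv) {
        parent[lowest[ru]] <- v
        uf[ru] <- rv
        lowest[rv] <- v
      }
    }
  }
  structure(list(parent = parent, constant = FALSE, n = n, values = values,
                 rank = so$rank, direction = direction,
                 connectivity = connectivity, dims = field$dims),
            class = "merge_tree")
}

#' Critical nodes of a merge tree
#'
#' @param mt a `merge_tree`.
#' @return a data.frame with `vertex_index` (1-based linear index), `value`,
#'   and `kind` (`leaf` for extrema where components appear, `saddle` for
#'   merge events, `root` for the sweep's final vertex).
#' @export
merge_tree_nodes <- function(mt) {
  if (!inherits(mt, "merge_tree")) stop("expected a `merge_tree`")
  if (mt$constant) {
    return(data.frame(vertex_index = 1L, value = mt$values[1], kind = "root"))
  }
  nchild <- tabulate(mt$parent[mt$parent > 0L], nbins = mt$n)
  kind <- rep(NA_character_, mt$n)
  kind[nchild == 0L] <- "leaf"
  kind[nchild >= 2L] <- "saddle"
  kind[mt$parent == 0L] <- "root"
  keep <- !is.na(kind)
  out <- data.frame(vertex_index = which(keep), value = mt$values[keep],
                    kind = kind[keep])
  out[order(-out$value), , drop = FALSE]
}

#' @export
print.merge_tree <- function(x, ...) {
  kind <- if (x$direction == "ascending") "join" else "split"
  if (x$constant) {
    cat(sprintf("merge_tree (%s): degenerate constant field, 1 node\n", kind))
  } else {
    nd <- merge_tree_nodes(x)
    cat(sprintf("merge_tree (%s): %d vertices, %d leaves, %d interior saddles\n",
                kind, x$n, sum(nd$kind == "leaf"), sum(nd$kind == "saddle")))
  }
  invisible(x)
}

#' Combine join and split trees into a contour tree
#'
#' Standard leaf-pruning merge: vertices that are leaves in one augmented
#' merge tree and regular in the other are peeled off one at a time; each
#' peel contributes one contour-tree arc. The augmented contour tree is then
#' reduced to its critical nodes, keeping a map from every grid vertex to the
#' reduced arc it lies on (the basis of the contour-tree segmentation).
#'
#' @param join join tree from `build_merge_tree(field, "ascending", ...)`.
#' @param split split tree over the same vertex set.
#' @param field the originating [scalar_field] (used for the voxel-to-arc
#'   bookkeeping and value spans).
#' @return an object of class `contour_tree`; see [contour_tree()].
#' @export
combine_trees <- function(join, split, field) {
  if (!inherits(join, "merge_tree") || !inherits(split, "merge_tree"))
    stop("expected two `merge_tree` objects")
  if (join$n != split$n || !identical(join$dims, split$dims))
    stop("join and split trees must be built over the same vertex set")
  if (join$direction != "ascending" || split$direction != "descending")
    stop("`join` must be ascending and `split` descending")
  stopifnot_field(field)
  if (prod(field$dims) != join$n) stop("field does not match the trees")
  values <- as.vector(field$values)
  n <- join$n

  if (join$constant || split$constant) {
    return(.degenerate_contour_tree(field))
  }

  jp <- join$parent
  sp <- split$parent
  up_deg <- tabulate(jp[jp > 0L], nbins = n)     # join children
  down_deg <- tabulate(sp[sp > 0L], nbins = n)   # split children
  # child adjacency for vertex deletion (degrees stay small)
  jt_children <- split(which(jp > 0L), factor(jp[jp > 0L], levels = seq_len(n)))
  st_children <- split(which(sp > 0L), factor(sp[sp > 0L], levels = seq_len(n)))

  alive <- rep(TRUE, n)
  arc_hi <- integer(n - 1L)
  arc_lo <- integer(n - 1L)
  prune_arc <- integer(n)
  stack <- which(up_deg + down_deg == 1L)
  top <- length(stack)
  n_arc <- 0L
  remaining <- n
  while (remaining > 1L) {
    if (top == 0L) stop("internal error: merge queue exhausted")
    v <- stack[top]; top <- top - 1L
    if (!alive[v] || up_deg[v] + down_deg[v] != 1L) next
    n_arc <- n_arc + 1L
    if (up_deg[v] == 0L) {           # upper leaf: arc descends to join parent
      j <- jp[v]
      arc_hi[n_arc] <- v; arc_lo[n_arc] <- j
      jt_children[[j]] <- setdiff(jt_children[[j]], v)
      up_deg[j] <- up_deg[j] - 1L
      # splice v out of the split tree (v has exactly one split child)
      c1 <- st_children[[v]][1L]
      sp[c1] <- sp[v]
      if (sp[v] > 0L) {
        st_children[[sp[v]]] <- c(setdiff(st_children[[sp[v]]], v), c1)
      }
    } else {                         # lower leaf: arc ascends to split parent
      j <- sp[v]
      arc_hi[n_arc] <- j; arc_lo[n_arc] <- v
      st_children[[j]] <- setdiff(st_children[[j]], v)
      down_deg[j] <- down_deg[j] - 1L
      c1 <- jt_children[[v]][1L]
      jp[c1] <- jp[v]
      if (jp[v] > 0L) {
        jt_children[[jp[v]]] <- c(setdiff(jt_children[[jp[v]]], v), c1)
      }
    }
    prune_arc[v] <- n_arc
    alive[v] <- FALSE
    remaining <- remaining - 1L
    if (alive[j] && up_deg[j] + down_deg[j] == 1L) {
      top <- top + 1L
      if (top > length(stack)) stack <- c(stack, integer(n))
      stack[top] <- j
    }
  }
  last <- which(alive)

  .reduce_contour_tree(arc_hi, arc_lo, prune_arc, last, values, field)
}

# Reduce the augmented contour tree (arcs between grid vertices) to the tree
# on critical nodes, recording for every grid vertex the reduced arc it
# belongs to.
.reduce_contour_tree <- function(arc_hi, arc_lo, prune_arc, last, values, field) {
  n <- length(values)
  n_arc <- length(arc_hi)
  up_arcs <- split(seq_len(n_arc), factor(arc_lo, levels = seq_len(n)))
  down_arcs <- split(seq_len(n_arc), factor(arc_hi, levels = seq_len(n)))
  up_ct <- lengths(up_arcs)
  down_ct <- lengths(down_arcs)
  critical <- up_ct != 1L | down_ct != 1L

  crit_v <- which(critical)
  node_of <- integer(n)
  node_of[crit_v] <- seq_along(crit_v)
  # leaves are degree-1 nodes; degenerate extrema that simultaneously merge
  # components (e.g. a local minimum joining two superlevel components) have
  # degree >= 2 and are interior saddles
  kind <- ifelse(up_ct[crit_v] == 0L & down_ct[crit_v] == 1L, "maximum",
                 ifelse(down_ct[crit_v] == 0L & up_ct[crit_v] == 1L,
                        "minimum", "saddle"))
  nodes <- data.frame(id = seq_along(crit_v), vertex_index = crit_v,
                      value = values[crit_v], kind = kind)

  arc2red <- integer(n_arc)
  red_upper <- integer(0); red_lower <- integer(0)
  r <- 0L
  for (c0 in crit_v) {
    for (a in up_arcs[[c0]]) {
      r <- r + 1L
      cur_a <- a
      cur_v <- arc_hi[cur_a]
      arc2red[cur_a] <- r
      while (!critical[cur_v]) {
        cur_a <- up_arcs[[cur_v]][1L]
        arc2red[cur_a] <- r
        cur_v <- arc_hi[cur_a]
      }
      red_upper[r] <- node_of[cur_v]
      red_lower[r] <- node_of[c0]
    }
  }
  arcs <- data.frame(id = seq_len(r), upper = red_upper, lower = red_lower)

  vertex_arc <- integer(n)
  pruned <- prune_arc > 0L
  vertex_arc[pruned] <- arc2red[prune_arc[pruned]]
  # the final unpruned vertex joins any incident reduced arc
  inc <- c(which(arc_hi == last), which(arc_lo == last))[1L]
  vertex_arc[last] <- arc2red[inc]

  structure(list(nodes = nodes, arcs = arcs, vertex_arc = vertex_arc,
                 values = values, dims = field$dims, spacing = field$spacing,
                 constant = FALSE),
            class = "contour_tree")
}

.degenerate_contour_tree <- function(field) {
  values <- as.vector(field$values)
  structure(list(
    nodes = data.frame(id = 1L, vertex_index = 1L, value = values[1],
                       kind = "maximum"),
    arcs = data.frame(id = integer(0), upper = integer(0), lower = integer(0)),
    vertex_arc = rep(1L, length(values)),
    values = values, dims = field$dims, spacing = field$spacing,
    constant = TRUE), class = "contour_tree")
}

#' Contour tree of a scalar field
#'
#' Convenience wrapper building the join and split trees and combining them.
#' The contour tree tracks how connected components of level sets appear,
#' merge, split and vanish as the isovalue sweeps the data range; its leaves
#' are the field's extrema and its interior nodes its saddles.
#'
#' A constant field yields a degenerate single-node tree that all downstream
#' operations treat as one root branch.
#'
#' @param field a [scalar_field].
#' @param connectivity 6 (default) or 26. 6-connectivity is used symmetrically
#'   for both sweep directions; the Morse-consistent mixed 6/26 variant is not
#'   implemented.
#' @return an object of class `contour_tree` with elements `nodes` (critical
#'   nodes: id, vertex_index, value, kind), `arcs` (node-id pairs, upper/lower)
#'   and `vertex_arc` (per-voxel arc membership).
#' @examples
#' ct <- contour_tree(ramp_volume(c(4, 1, 1)))
#' ct$nodes
#' @export
contour_tree <- function(field, connectivity = 6) {
  stopifnot_field(field)
  if (diff(field$value_range) == 0) return(.degenerate_contour_tree(field))
  join <- build_merge_tree(field, "ascending", connectivity)
  split <- build_merge_tree(field, "descending", connectivity)
  combine_trees(join, split, field)
}

#' @export
print.contour_tree <- function(x, ...) {
  cat(sprintf("contour_tree: %d nodes (%d maxima, %d minima, %d saddles), %d arcs\n",
              nrow(x$nodes), sum(x$nodes$kind == "maximum"),
              sum(x$nodes$kind == "minimum"), sum(x$nodes$kind == "saddle"),
              nrow(x$arcs)))
  invisible(x)
}
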