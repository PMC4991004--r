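# Brute-force contour-tree oracle for fields with distinct values.
#
# For every distinct scalar value h (descending), the connected components of
# the superlevel set {f >= h} are recomputed from scratch by flood fill; a
# vertex is a maximum if its addition increases the component count, a join
# saddle if it decreases it. The sublevel sweep gives minima and split
# saddles. Entirely independent of the union-find sweep implementation.

oracle_components <- function(members, nb) {
  # members: logical vector over vertices; nb: neighbor matrix
  n_comp <- 0L
  seen <- !members
  for (s in which(members)) {
    if (seen[s]) next
    n_comp <- n_comp + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (u in nb[v, ]) {
        if (!is.na(u) && !seen[u]) {
          seen[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
  }
  n_comp
}

oracle_critical_points <- function(field, connectivity = 6) {
  values <- as.vector(field$values)
  stopifnot(!anyDuplicated(values))
  nb <- topolight:::.neighbor_matrix(field$dims, connectivity)
  ord_desc <- order(values, decreasing = TRUE)
  ord_asc <- rev(ord_desc)
  n <- length(values)

  sweep_kinds <- function(ord, grow_kind, merge_kind) {
    members <- rep(FALSE, n)
    kinds <- character(0); vals <- numeric(0); verts <- integer(0)
    prev <- 0L
    for (v in ord) {
      members[v] <- TRUE
      cur <- oracle_components(members, nb)
      if (cur == prev + 1L) {
        kinds <- c(kinds, grow_kind); vals <- c(vals, values[v])
        verts <- c(verts, v)
      } else if (cur < prev) {
        kinds <- c(kinds, merge_kind); vals <- c(vals, values[v])
        verts <- c(verts, v)
      }
      prev <- cur
    }
    data.frame(vertex = verts, value = vals, kind = kinds)
  }
  sup <- sweep_kinds(ord_desc, "maximum", "join_saddle")
  sub <- sweep_kinds(ord_asc, "minimum", "split_saddle")
  rbind(sup, sub)
}

# leaves (extrema) and the set of saddle values, as the oracle sees them.
# A vertex can play a dual role (e.g. a local minimum whose addition also
# merges two superlevel components); such vertices are interior contour-tree
# nodes, not leaves, and are counted among the saddles.
oracle_summary <- function(field, connectivity = 6) {
  cp <- oracle_critical_points(field, connectivity)
  is_max <- cp$vertex[cp$kind == "maximum"]
  is_min <- cp$vertex[cp$kind == "minimum"]
  is_join <- cp$vertex[cp$kind == "join_saddle"]
  is_split <- cp$vertex[cp$kind == "split_saddle"]
  vals <- as.vector(field$values)
  list(
    max_values = sort(vals[setdiff(is_max, is_split)]),
    min_values = sort(vals[setdiff(is_min, is_join)]),
    saddle_values = sort(unique(vals[union(is_join, is_split)])))
}

# the same summary from the package's contour tree
ct_summary <- function(ct) {
  nd <- ct$nodes
  list(
    max_values = sort(nd$value[nd$kind == "maximum"]),
    min_values = sort(nd$value[nd$kind == "minimum"]),
    saddle_values = sort(unique(nd$value[nd$kind == "saddle"])))
}
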