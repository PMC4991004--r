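# Hand-designed 5x5x1 field with two local maxima (9, 8) joined through a
# saddle at 5 and a single minimum at 0.1. The background cells form one
# monotone snake path (0.1 .. 2.2) ending next to the taller bump, so the
# only critical points are the two maxima, the join saddle, and the global
# minimum. Verified independently by the level-set oracle below.
two_blob_5x5 <- function() {
  v <- matrix(NA_real_, 5, 5)  # v[x, y]
  snake <- list(
    c(1, 1), c(2, 1), c(3, 1), c(4, 1), c(5, 1),
    c(5, 2), c(5, 3), c(5, 4), c(5, 5), c(4, 5), c(3, 5), c(2, 5), c(1, 5),
    c(1, 4), c(2, 4), c(3, 4), c(4, 4), c(4, 3), c(3, 3), c(2, 3), c(1, 3),
    c(1, 2))
  for (i in seq_along(snake)) v[snake[[i]][1], snake[[i]][2]] <- 0.1 * i
  v[2, 2] <- 9; v[3, 2] <- 5; v[4, 2] <- 8
  scalar_field(as.vector(v), dims = c(5, 5, 1))
}

# well-separated two-blob 3D volume (heights 9 and 8); centers and their
# midpoint lie on grid vertices, so the inter-blob saddle is predictable
two_blob_3d <- function(dims = c(21, 9, 9)) {
  multi_blob_volume(dims,
                    centers = rbind(c(5, 4, 4), c(15, 4, 4)),
                    heights = c(9, 8), widths = 1.8)
}

# tallest blob in the middle, two flanking blobs: both flanks attach to the
# root branch, giving two sibling children with different persistences
three_blob_siblings <- function(dims = c(26, 10, 10)) {
  multi_blob_volume(dims,
                    centers = rbind(c(13, 4.5, 4.5), c(4, 4.5, 4.5),
                                    c(21, 4.5, 4.5)),
                    heights = c(9, 8, 6.5), widths = 1.8)
}

# small random field with all-distinct values
random_distinct_field <- function(dims, seed) {
  set.seed(seed)
  n <- prod(dims)
  scalar_field(sample(seq_len(n)) + stats::runif(n, -0.2, 0.2), dims)
}
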