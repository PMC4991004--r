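test_that("ramp volume is the canonical single-arc field", {
  f <- ramp_volume(c(4, 1, 1))
  expect_equal(as.vector(f$values), c(0, 1, 2, 3))
  ct <- contour_tree(f)
  expect_equal(sum(ct$nodes$kind %in% c("maximum", "minimum")), 2L)
  bd <- decompose_branches(ct)
  expect_equal(nrow(bd$branches), 1L)
  expect_equal(bd$branches$persistence, 3)  # dims_x - 1
})

test_that("multi-blob fields have one maximum leaf per blob", {
  one <- multi_blob_volume(c(12, 8, 8), rbind(c(5.5, 3.5, 3.5)), 5, 1.6)
  ct1 <- contour_tree(one)
  expect_equal(sum(ct1$nodes$kind == "maximum"), 1L)

  f <- two_blob_3d()
  truth <- attr(f, "tree_summary")
  bd <- simplify_tree(decompose_branches(contour_tree(f)),
                      threshold = truth$simplify_threshold)
  expect_equal(nrow(bd$branches), 2L)
  # child branch persistence = lower peak height - inter-blob saddle
  child <- bd$branches[!is.na(bd$branches$parent), ]
  expect_equal(child$persistence, 8 - truth$approx_saddles, tolerance = 0.05)

  four <- multi_blob_volume(c(24, 24, 6),
                            centers = rbind(c(5, 5, 2.5), c(18, 5, 2.5),
                                            c(5, 18, 2.5), c(18, 18, 2.5)),
                            heights = c(9, 8, 7, 6), widths = 1.7)
  bd4 <- simplify_tree(decompose_branches(contour_tree(four)),
                       threshold = attr(four, "tree_summary")$simplify_threshold)
  n_max <- sum(bd4$nodes$kind[match(bd4$branches$extremum_node,
                                    bd4$nodes$id)] == "maximum")
  expect_equal(n_max, 4L)
  expect_error(multi_blob_volume(c(8, 8, 8), rbind(c(2, 2, 2), c(2, 2, 2)),
                                 c(3, 4), 1), "distinct")
})

test_that("nested peak hierarchy yields a depth chain with nested regions", {
  f <- nested_shell_volume(c(26, 9, 9), levels = 3)
  truth <- attr(f, "tree_summary")
  bd <- simplify_tree(decompose_branches(contour_tree(f)),
                      threshold = truth$simplify_threshold)
  expect_equal(sort(bd$branches$depth), 0:2)
  # chain: each non-root branch's parent is the branch one level up
  for (d in 1:2) {
    b <- bd$branches[bd$branches$depth == d, ]
    expect_equal(bd$branches$depth[match(b$parent, bd$branches$id)], d - 1L)
  }
  # saddles between consecutive peaks increase with depth
  expect_true(all(diff(truth$approx_saddles) > 0))

  # child region lies inside the parent's superlevel component: every voxel
  # of the child branch exceeds the child's attachment saddle value
  seg <- segment_field(f, bd)
  attrs <- annotate_structure(bd, f, seg)
  kid <- attrs[attrs$depth == 2, ]
  expect_true(all(f$values[seg$labels == kid$branch_id] >= kid$saddle_value))

  expect_equal(nrow(simplify_tree(decompose_branches(contour_tree(
    nested_shell_volume(c(16, 9, 9), levels = 1))), threshold = 1)$branches), 1L)
  expect_error(nested_shell_volume(c(10, 9, 9), levels = 4), "extent")
})

test_that("add_noise is seeded, reproducible, and identity at sigma 0", {
  f <- two_blob_3d(c(10, 8, 8))
  expect_identical(add_noise(f, 0), f)
  n1 <- add_noise(f, 0.1, seed = 7)
  n2 <- add_noise(f, 0.1, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(f, 0.1, seed = 8)$values, n1$values))
  # caller RNG state is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_noise(f, 0.1, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise adds small-scale branches that simplification removes", {
  f <- two_blob_3d(c(14, 8, 8))
  clean <- decompose_branches(contour_tree(f))
  n_clean_leaves <- 3L  # 2 maxima + 1 minimum after pruning tail noise
  sigma <- 0.05
  recovered <- 0L
  for (s in 1:20) {
    noisy <- add_noise(f, sigma, seed = s)
    bd <- decompose_branches(contour_tree(noisy))
    expect_gte(nrow(bd$branches), nrow(clean$branches))
    simp <- simplify_tree(bd, threshold = 3 * sigma)
    simp <- simplify_tree(simp, target_branch_count = 2)
    n_max <- sum(simp$nodes$kind[match(simp$branches$extremum_node,
                                       simp$nodes$id)] == "maximum")
    if (n_max == 2L) recovered <- recovered + 1L
  }
  expect_gte(recovered, 19L)  # allow <= 5% failures
})

test_that("uint8 quantization spans the 8-bit range", {
  f <- quantize_uint8(two_blob_3d(c(10, 8, 8)))
  expect_equal(range(f$values), c(0, 255))
  expect_true(all(f$values == round(f$values)))
})
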