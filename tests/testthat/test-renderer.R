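test_that("gradient normals recover analytic gradients", {
  ramp <- ramp_volume(c(8, 4, 4))
  n <- gradient_normals(ramp)
  # interior normals point along +x
  expect_true(all(abs(n$nx[2:7, , ] - 1) < 1e-12))
  expect_true(all(abs(n$ny[2:7, , ]) < 1e-12))

  const <- scalar_field(rep(2, 64), c(4, 4, 4))
  nc <- gradient_normals(const)
  expect_true(all(nc$nx == 0 & nc$ny == 0 & nc$nz == 0))

  # spherical blob: normals point radially outward of the gradient,
  # i.e. toward the center for a decreasing Gaussian
  blob <- multi_blob_volume(c(13, 13, 13), rbind(c(6, 6, 6)), 5, 2.5)
  nb <- gradient_normals(blob)
  co <- expand.grid(x = 0:12, y = 0:12, z = 0:12)
  toward <- cbind(6 - co$x, 6 - co$y, 6 - co$z)
  r <- sqrt(rowSums(toward^2))
  sel <- r > 2 & r < 5    # away from center (zero gradient) and boundary
  dots <- (as.vector(nb$nx) * toward[, 1] + as.vector(nb$ny) * toward[, 2] +
             as.vector(nb$nz) * toward[, 3]) / r
  expect_true(all(dots[sel] > 0.99))
})

test_that("compositing reproduces analytic single-sample cases", {
  # fully transparent volume: background everywhere
  f <- scalar_field(rep(1, 6 * 6 * 4), c(6, 6, 4))
  bd <- decompose_branches(contour_tree(f))
  seg <- segment_field(f, bd)
  tab <- build_lighting_table(annotate_structure(bd, f), "constant",
                              w = 0, ka = 0.3, ks = 0)
  tf0 <- transfer_function(bd$root, matrix(c(1, 0, 0), 1), opacity = 0)
  cfg <- render_config(width = 12, height = 12,
                       position = c(2.5, 2.5, -10), look_at = c(2.5, 2.5, 1.5),
                       background = c(0, 0, 0.5))
  img0 <- raycast_image(f, seg, tab, tf0, cfg)
  expect_true(all(img0$rgb[, , 1] == 0))
  expect_true(all(img0$rgb[, , 3] == 0.5))

  # opaque constant red slab with ambient-only lighting: covered pixels 0.3
  tf1 <- transfer_function(bd$root, matrix(c(1, 0, 0), 1), opacity = 1)
  img1 <- raycast_image(f, seg, tab, tf1, cfg)
  center <- img1$rgb[6, 6, ]
  expect_equal(as.vector(center), c(0.3, 0, 0), tolerance = 1e-10)
  # corner rays miss the slab
  expect_equal(as.vector(img1$rgb[1, 1, ]), c(0, 0, 0.5))
})

test_that("output is bounded, deterministic, and monotone in kd", {
  f <- two_blob_3d(c(14, 10, 10))
  bd <- simplify_tree(decompose_branches(contour_tree(f)),
                      threshold = attr(f, "tree_summary")$simplify_threshold)
  seg <- segment_field(f, bd)
  attrs <- annotate_structure(bd, f, seg)
  tabA <- build_lighting_table(attrs, "constant", w = 0.3)
  tf <- transfer_function(bd$branches$id, opacity = 0.4)
  ext <- (f$dims - 1) * f$spacing
  cfg <- render_config(width = 28, height = 20,
                       position = c(ext[1] / 2, ext[2] / 2, -30),
                       look_at = ext / 2)
  imgA <- raycast_image(f, seg, tabA, tf, cfg)
  expect_true(all(imgA$rgb >= 0 & imgA$rgb <= 1))
  imgA2 <- raycast_image(f, seg, tabA, tf, cfg)
  expect_identical(imgA$rgb, imgA2$rgb)

  # raising kd for one branch brightens its projection, nothing dims
  child <- bd$branches$id[!is.na(bd$branches$parent)][1]
  tabB <- tabA
  tabB$kd[tabB$branch_id == child] <- 0.9
  imgB <- raycast_image(f, seg, tabB, tf, cfg)
  expect_true(all(imgB$rgb >= imgA$rgb - 1e-12))
  expect_gt(mean(image_luminance(imgB)), mean(image_luminance(imgA)))
})

test_that("PPM images round-trip losslessly at 8 bits", {
  f <- two_blob_3d(c(10, 8, 8))
  bd <- decompose_branches(contour_tree(f))
  seg <- segment_field(f, bd)
  tab <- build_lighting_table(annotate_structure(bd, f), "distance")
  img <- raycast_image(f, seg, tab, transfer_function(bd$branches$id),
                       render_config(width = 16, height = 12,
                                     position = c(4.5, 3.5, -20),
                                     look_at = c(4.5, 3.5, 3.5)))
  p1 <- tempfile(fileext = ".ppm")
  write_image(img, p1)
  back <- read_ppm(p1)
  expect_lt(max(abs(back$rgb - img$rgb)), 1 / 255)  # 8-bit quantization bound
  p2 <- tempfile(fileext = ".png")
  write_image(img, p2)
  expect_true(file.size(p2) > 0)
  expect_error(write_image(img, tempfile(fileext = ".bmp")), "extension")
})

test_that("attenuation sweep dims low-persistence structures preferentially", {
  f <- three_blob_siblings()
  bd <- simplify_tree(decompose_branches(contour_tree(f)),
                      threshold = attr(f, "tree_summary")$simplify_threshold)
  seg <- segment_field(f, bd)
  attrs <- annotate_structure(bd, f, seg)
  kids <- attrs$branch_id[attrs$depth == 1]
  lo <- kids[which.min(attrs$persistence[attrs$depth == 1])]
  hi <- kids[which.max(attrs$persistence[attrs$depth == 1])]
  ext <- (f$dims - 1) * f$spacing
  cfg <- render_config(width = 52, height = 20,
                       position = c(ext[1] / 2, ext[2] / 2, -40),
                       look_at = ext / 2)
  tf <- transfer_function(bd$branches$id, opacity = 0.5)

  render_at <- function(V) {
    tab <- build_lighting_table(attrs, "attenuation", V = V, w = 0.71)
    raycast_image(f, seg, tab, tf, cfg)
  }
  # projected region of a branch: pixels its solo render covers
  mask_of <- function(b) {
    tfm <- tf
    tfm$opacity <- ifelse(tfm$branch_id == b, 0.5, 0)
    tabm <- build_lighting_table(attrs, "constant", w = 0.5)
    image_luminance(raycast_image(f, seg, tabm, tfm, cfg)) > 1e-6
  }
  m_lo <- mask_of(lo); m_hi <- mask_of(hi)
  bright <- render_at(229)
  dim <- render_at(42)
  mean_drop <- function(m) {
    mean(image_luminance(bright)[m]) - mean(image_luminance(dim)[m])
  }
  # lowering V dims the low-persistence blob's region more
  expect_gt(mean_drop(m_lo), mean_drop(m_hi))
  expect_gt(mean_drop(m_lo), 0)
})
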