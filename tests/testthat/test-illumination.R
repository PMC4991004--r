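test_that("Blinn-Phong shading evaluates the lighting equation", {
  red <- c(1, 0, 0)
  n <- c(0, 0, 1)
  # ambient-only identity
  expect_equal(as.vector(shade_blinn_phong(red, n, n, n, ka = 0.3, kd = 0,
                                           ks = 0, shininess = 8)),
               c(0.3, 0, 0))
  # full diffuse alignment: (ka + kd * 1) * C
  expect_equal(as.vector(shade_blinn_phong(red, n, n, n, ka = 0.1, kd = 0.6,
                                           ks = 0, shininess = 8)),
               c(0.7, 0, 0))
  # attenuation halves diffuse and specular but not ambient
  full <- shade_blinn_phong(red, n, n, n, 0.1, 0.4, 0.2, 8, f_att = 1)
  half <- shade_blinn_phong(red, n, n, n, 0.1, 0.4, 0.2, 8, f_att = 0.5)
  expect_equal(half[1], 0.1 + (full[1] - 0.1) / 2)
  # white specular adds to all channels
  spec <- shade_blinn_phong(c(0, 0, 1), n, n, n, 0, 0, 0.4, 8)
  expect_equal(as.vector(spec), c(0.4, 0.4, 0.4 + 0))
  # back-facing normals clamp to ambient
  away <- shade_blinn_phong(red, c(0, 0, -1), n, n, 0.2, 0.9, 0.9, 8)
  expect_equal(as.vector(away), c(0.2, 0, 0))
  # zero normal: ambient only
  expect_equal(as.vector(shade_blinn_phong(red, c(0, 0, 0), n, n,
                                           0.2, 0.9, 0.9, 8)), c(0.2, 0, 0))
})

test_that("attenuation coefficient implements the Stokes law", {
  expect_equal(attenuation_coefficient(0, V = 1, scale = 1), 0)
  expect_equal(attenuation_coefficient(2, V = 1, scale = 1),
               2 * 0.001002 * 4 / (3 * 998.2071), tolerance = 1e-12)
  # defaults carry the documented water constants
  expect_equal(eval(formals(attenuation_coefficient)$eta), 0.001002)
  expect_equal(eval(formals(attenuation_coefficient)$rho), 998.2071)
  # strictly decreasing in V, strictly increasing in xi
  a <- attenuation_coefficient(2, V = c(40, 50, 60))
  expect_true(all(diff(a) < 0))
  b <- attenuation_coefficient(c(1, 2, 3), V = 50)
  expect_true(all(diff(b) > 0))
  expect_error(attenuation_coefficient(1, V = 0), "V must be")
})

test_that("attenuation factor is the Beer-Lambert falloff", {
  expect_equal(attenuation_factor(0, 5), 1)
  expect_equal(attenuation_factor(3, 0), 1)
  expect_equal(attenuation_factor(log(2), 1), 0.5)
  z <- seq(0, 4, by = 0.5)
  expect_true(all(diff(attenuation_factor(0.7, z)) < 0))
  expect_true(all(attenuation_factor(2, z) > 0 & attenuation_factor(2, z) <= 1))
  # default scale calibration: V = 50, one sibling, unit distance -> 1/2
  expect_equal(attenuation_factor(attenuation_coefficient(1, V = 50), 1), 0.5)
})

test_that("saliency and distance diffuse coefficients follow their maps", {
  expect_equal(saliency_diffuse(0.4, 0), 0)
  expect_equal(saliency_diffuse(1, 0.71), 0.71)
  s <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(saliency_diffuse(s, 0.6)) > 0))

  expect_equal(distance_diffuse(0, 1), 0.5)
  expect_equal(distance_diffuse(3, 0.71), 0.71 / (1 + exp(-3)))
  expect_equal(distance_diffuse(3, 0.71), 0.6763, tolerance = 1e-4)
  expect_lt(distance_diffuse(30, 0.71), 0.71)
  expect_equal(distance_diffuse(30, 0.71), 0.71, tolerance = 1e-6)
  expect_true(all(diff(distance_diffuse(0:5, 0.9)) > 0))
  expect_error(distance_diffuse(1, 1.4), "w must be")
})

test_that("lighting tables wire the mode-specific coefficient", {
  f <- nested_shell_volume(c(26, 9, 9), levels = 3)
  bd <- simplify_tree(decompose_branches(contour_tree(f)), threshold = 1)
  attrs <- annotate_structure(bd, f)

  # saliency mode: ranking by kd equals ranking by saliency
  tab_s <- build_lighting_table(attrs, "saliency", w = 0.71)
  expect_equal(order(tab_s$kd), order(attrs$saliency))
  expect_equal(tab_s$kd, 0.71 * attrs$saliency)

  # distance mode: kd strictly increasing with depth on the chain
  tab_d <- build_lighting_table(attrs, "distance", w = 0.71)
  o <- order(attrs$depth)
  expect_true(all(diff(tab_d$kd[o]) > 0))

  # attenuation mode: table equals the composed pure operations
  tab_a <- build_lighting_table(attrs, "attenuation", V = 42)
  phat <- attrs$persistence / max(attrs$persistence)
  expect_equal(tab_a$f_att,
               attenuation_factor(attenuation_coefficient(attrs$n_siblings, 42),
                                  1 - phat))
  # all coefficients within range
  for (tab in list(tab_s, tab_d, tab_a)) {
    expect_true(all(tab$kd >= 0 & tab$kd <= 1))
    expect_true(all(tab$f_att > 0 & tab$f_att <= 1))
  }
  # single-branch saliency table: kd = w
  one <- annotate_structure(decompose_branches(contour_tree(
    ramp_volume(c(6, 2, 2)))), ramp_volume(c(6, 2, 2)))
  expect_equal(build_lighting_table(one, "saliency", w = 0.5)$kd, 0.5)
  expect_error(build_lighting_table(attrs, "psychedelic"))
})

test_that("decreasing V never increases any branch's attenuation factor", {
  f <- three_blob_siblings()
  bd <- simplify_tree(decompose_branches(contour_tree(f)),
                      threshold = attr(f, "tree_summary")$simplify_threshold)
  attrs <- annotate_structure(bd, f)
  Vs <- c(229, 154, 42)
  fmat <- sapply(Vs, function(V)
    build_lighting_table(attrs, "attenuation", V = V)$f_att)
  expect_true(all(fmat[, 2] <= fmat[, 1] + 1e-15))
  expect_true(all(fmat[, 3] <= fmat[, 2] + 1e-15))
  # siblings with lower persistence are dimmed harder at any fixed V
  kids <- which(attrs$depth == 1)
  lo <- kids[which.min(attrs$persistence[kids])]
  hi <- kids[which.max(attrs$persistence[kids])]
  expect_lt(fmat[lo, 3], fmat[hi, 3])
})

test_that("lighting JSON round-trips", {
  f <- two_blob_3d(c(12, 8, 8))
  bd <- decompose_branches(contour_tree(f))
  tab <- build_lighting_table(annotate_structure(bd, f), "distance")
  path <- tempfile(fileext = ".json")
  write_lighting_json(tab, path)
  back <- read_lighting_json(path)
  expect_equal(back$branch_id, tab$branch_id)
  expect_equal(back$kd, tab$kd, tolerance = 1e-12)
  expect_equal(back$f_att, tab$f_att, tolerance = 1e-12)
})
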