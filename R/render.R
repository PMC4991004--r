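#' Central-difference gradient normals of a field
#'
#' Normalized gradient per voxel (central differences in the interior,
#' one-sided at the boundary, scaled by the grid spacing). Voxels whose
#' gradient magnitude falls below `eps` get a zero normal; the shader then
#' applies the ambient term only there.
#'
#' @param field a [scalar_field].
#' @param eps gradient-magnitude threshold for a degenerate normal.
#' @return list of three arrays (`nx`, `ny`, `nz`) matching the field dims.
#' @export
gradient_normals <- function(field, eps = 1e-12) {
  stopifnot_field(field)
  v <- field$values
  d <- field$dims
  sp <- field$spacing
  ix <- function(k, n) pmin(pmax(k, 1L), n)
  gx <- (v[ix(2:(d[1] + 1), d[1]), , , drop = FALSE] -
           v[ix(0:(d[1] - 1), d[1]), , , drop = FALSE]) / (2 * sp[1])
  gy <- (v[, ix(2:(d[2] + 1), d[2]), , drop = FALSE] -
           v[, ix(0:(d[2] - 1), d[2]), , drop = FALSE]) / (2 * sp[2])
  gz <- (v[, , ix(2:(d[3] + 1), d[3]), drop = FALSE] -
           v[, , ix(0:(d[3] - 1), d[3]), drop = FALSE]) / (2 * sp[3])
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  zero <- mag < eps
  mag[zero] <- 1
  gx <- gx / mag; gy <- gy / mag; gz <- gz / mag
  gx[zero] <- 0; gy[zero] <- 0; gz[zero] <- 0
  list(nx = gx, ny = gy, nz = gz)
}

#' Per-branch transfer function
#'
#' Simple per-branch constant color and opacity, used as plumbing so that
#' the lighting tables can be demonstrated on the contour-tree
#' segmentation.
#'
#' @param branch_ids integer branch ids to cover.
#' @param colors `n x 3` RGB matrix in `[0, 1]`; defaults to a qualitative
#'   palette.
#' @param opacity per-branch opacity in `[0, 1]` (recycled).
#' @return data.frame of class `transfer_function`.
#' @export
transfer_function <- function(branch_ids, colors = NULL, opacity = 0.15) {
  nb <- length(branch_ids)
  if (is.null(colors)) {
    cols <- grDevices::hcl.colors(max(nb, 2L), "Dark 3")[seq_len(nb)]
    colors <- t(grDevices::col2rgb(cols)) / 255
  }
  colors <- rbind(colors)
  opacity <- rep_len(opacity, nb)
  if (any(opacity < 0 | opacity > 1)) stop("opacity must be in [0, 1]")
  structure(data.frame(branch_id = branch_ids, r = colors[, 1],
                       g = colors[, 2], b = colors[, 3], opacity = opacity),
            class = c("transfer_function", "data.frame"))
}

#' @rdname transfer_function
#' @param path JSON path; entries `{"<branch_id>": {"rgb": [r,g,b],
#'   "opacity": a}}`.
#' @param tf a `transfer_function` (for writing).
#' @export
write_transfer_json <- function(tf, path) {
  entries <- lapply(seq_len(nrow(tf)), function(i) {
    list(rgb = c(tf$r[i], tf$g[i], tf$b[i]), opacity = tf$opacity[i])
  })
  names(entries) <- as.character(tf$branch_id)
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transfer_function
#' @export
read_transfer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(names(x))
  cols <- t(vapply(x, function(e) as.numeric(e$rgb), numeric(3)))
  transfer_function(ids, cols, vapply(x, function(e) e$opacity, numeric(1)))
}

#' Render configuration
#'
#' Orthographic camera by default: rays run parallel to `view_dir` (the
#' normalized direction from `position` to `look_at`), the image plane is
#' spanned to cover the volume bounds. `step` is the ray sampling interval
#' as a fraction of the smallest voxel spacing; opacity is corrected for the
#' step size as `1 - (1 - a)^(step / reference)` with a one-voxel reference.
#'
#' @param width,height image dimensions in pixels.
#' @param position,look_at,up camera specification (world coordinates; the
#'   volume occupies `[0, (dims - 1) * spacing]`).
#' @param light_dir light direction (pointing toward the light), normalized
#'   internally.
#' @param step ray step as a fraction of the smallest spacing.
#' @param background background RGB.
#' @return list of class `render_config`.
#' @export
render_config <- function(width = 160, height = 160,
                          position = c(0.5, 0.5, -3), look_at = c(0.5, 0.5, 0.5),
                          up = c(0, 1, 0), light_dir = c(0.3, 0.5, -1),
                          step = 0.5, background = c(0, 0, 0)) {
  if (width < 1 || height < 1) stop("image dims must be positive")
  if (step <= 0) stop("step must be > 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 position = as.numeric(position), look_at = as.numeric(look_at),
                 up = as.numeric(up), light_dir = as.numeric(light_dir),
                 step = step, background = as.numeric(background)),
            class = "render_config")
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction")
  v / n
}

# trilinear interpolation of array `a` at fractional voxel coords (0-based),
# vectorized over points; coords clamped to the grid
.trilerp <- function(a, d, px, py, pz) {
  px <- pmin(pmax(px, 0), d[1] - 1)
  py <- pmin(pmax(py, 0), d[2] - 1)
  pz <- pmin(pmax(pz, 0), d[3] - 1)
  x0 <- pmin(floor(px), d[1] - 2); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(py), d[2] - 2); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(pz), d[3] - 2); z0 <- pmax(z0, 0)
  if (d[1] == 1) x0 <- rep(0, length(px))
  if (d[2] == 1) y0 <- rep(0, length(py))
  if (d[3] == 1) z0 <- rep(0, length(pz))
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  lin <- function(i, j, k) a[1L + i + d[1] * (j + d[2] * k)]
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  c000 <- lin(x0, y0, z0); c100 <- lin(x1, y0, z0)
  c010 <- lin(x0, y1, z0); c110 <- lin(x1, y1, z0)
  c001 <- lin(x0, y0, z1); c101 <- lin(x1, y0, z1)
  c011 <- lin(x0, y1, z1); c111 <- lin(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

# nearest-neighbor lookup (categorical labels)
.nearest <- function(a, d, px, py, pz) {
  xi <- pmin(pmax(round(px), 0), d[1] - 1)
  yi <- pmin(pmax(round(py), 0), d[2] - 1)
  zi <- pmin(pmax(round(pz), 0), d[3] - 1)
  a[1L + xi + d[1] * (yi + d[2] * zi)]
}

#' Ray-cast a segmented, per-branch-lit volume
#'
#' Orthographic front-to-back alpha compositing: at every sample along a
#' ray, the scalar value is interpolated trilinearly, the branch label is
#' looked up nearest-neighbor, and the sample is shaded with that branch's
#' Blinn-Phong coefficients and colored/weighted by the branch's transfer
#' function entry. Rays terminate early once accumulated opacity reaches
#' 0.99. The output is deterministic: identical inputs give an identical
#' image.
#'
#' @param field a [scalar_field].
#' @param seg matching `segmentation_map`.
#' @param table a `lighting_table` covering all labels.
#' @param tf a `transfer_function` covering all labels.
#' @param cfg a [render_config()]; camera coordinates are in voxel units
#'   scaled by the spacing.
#' @return object of class `volume_image`: `rgb` array `height x width x 3`
#'   in `[0, 1]`.
#' @export
raycast_image <- function(field, seg, table, tf, cfg = render_config()) {
  stopifnot_field(field)
  if (!inherits(seg, "segmentation_map")) stop("expected a `segmentation_map`")
  if (!identical(as.integer(seg$dims), as.integer(field$dims))) {
    stop("segmentation dims do not match the field")
  }
  labs_all <- unique(as.vector(seg$labels))
  if (!all(labs_all %in% table$branch_id)) stop("lighting table misses branch labels")
  if (!all(labs_all %in% tf$branch_id)) stop("transfer function misses branch labels")

  d <- field$dims
  sp <- field$spacing
  ext <- (d - 1) * sp                       # physical extent
  vdir <- .unit(cfg$look_at - cfg$position)
  right <- .unit(.cross3(vdir, .unit(cfg$up)))
  upv <- .cross3(right, vdir)
  ldir <- .unit(cfg$light_dir)
  half <- .unit(ldir - vdir)                # view dir = -ray dir toward eye

  # orthographic image plane spanning the volume's bounding sphere
  ctr <- ext / 2
  rad <- sqrt(sum((ext / 2)^2)) + max(sp)
  px <- (seq_len(cfg$width) - 0.5) / cfg$width * 2 - 1    # [-1, 1]
  py <- (seq_len(cfg$height) - 0.5) / cfg$height * 2 - 1
  grid <- expand.grid(u = px, v = py)
  n_ray <- nrow(grid)
  orig <- cbind(ctr[1] + grid$u * rad * right[1] + grid$v * rad * upv[1] - vdir[1] * 2 * rad,
                ctr[2] + grid$u * rad * right[2] + grid$v * rad * upv[2] - vdir[2] * 2 * rad,
                ctr[3] + grid$u * rad * right[3] + grid$v * rad * upv[3] - vdir[3] * 2 * rad)

  # ray-box intersection with [0, ext]
  tmin <- rep(0, n_ray); tmax <- rep(4 * rad, n_ray)
  for (ax in 1:3) {
    if (abs(vdir[ax]) < 1e-12) {
      out <- orig[, ax] < 0 | orig[, ax] > ext[ax]
      tmax[out] <- -1
    } else {
      t1 <- (0 - orig[, ax]) / vdir[ax]
      t2 <- (ext[ax] - orig[, ax]) / vdir[ax]
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
  }
  step_len <- cfg$step * min(sp)
  ref_len <- min(sp)                        # opacity reference: one voxel
  normals <- gradient_normals(field)
  lab_vec <- as.vector(seg$labels)

  # per-branch shading lookups as dense vectors indexed by label id
  maxid <- max(table$branch_id)
  ka_l <- kd_l <- ks_l <- nsh_l <- fat_l <- rep(NA_real_, maxid)
  ka_l[table$branch_id] <- table$ka; kd_l[table$branch_id] <- table$kd
  ks_l[table$branch_id] <- table$ks; nsh_l[table$branch_id] <- table$shininess
  fat_l[table$branch_id] <- table$f_att
  tr_l <- tg_l <- tb_l <- ta_l <- rep(NA_real_, max(tf$branch_id, maxid))
  tr_l[tf$branch_id] <- tf$r; tg_l[tf$branch_id] <- tf$g
  tb_l[tf$branch_id] <- tf$b; ta_l[tf$branch_id] <- tf$opacity

  accR <- accG <- accB <- rep(0, n_ray)
  accA <- rep(0, n_ray)
  t_cur <- tmin
  active <- tmax > tmin
  while (any(active)) {
    ai <- which(active)
    pos <- orig[ai, , drop = FALSE] + t_cur[ai] * matrix(vdir, length(ai), 3, byrow = TRUE)
    vx <- pos[, 1] / sp[1]; vy <- pos[, 2] / sp[2]; vz <- pos[, 3] / sp[3]
    lab <- .nearest(lab_vec, d, vx, vy, vz)
    a_s <- ta_l[lab]
    take <- a_s > 0
    if (any(take)) {
      ti <- ai[take]
      vxt <- vx[take]; vyt <- vy[take]; vzt <- vz[take]
      labt <- lab[take]
      nx <- .trilerp(normals$nx, d, vxt, vyt, vzt)
      ny <- .trilerp(normals$ny, d, vxt, vyt, vzt)
      nz <- .trilerp(normals$nz, d, vxt, vyt, vzt)
      nmag <- sqrt(nx^2 + ny^2 + nz^2)
      nz0 <- nmag < 1e-9
      nmag[nz0] <- 1
      nx <- nx / nmag; ny <- ny / nmag; nz <- nz / nmag
      ndl <- pmax(nx * ldir[1] + ny * ldir[2] + nz * ldir[3], 0)
      ndh <- pmax(nx * half[1] + ny * half[2] + nz * half[3], 0)
      ndl[nz0] <- 0; ndh[nz0] <- 0
      fatt <- fat_l[labt]
      diff_f <- ka_l[labt] + kd_l[labt] * fatt * ndl
      spec <- ks_l[labt] * fatt * ndh^nsh_l[labt]
      csr <- pmin(pmax(tr_l[labt] * diff_f + spec, 0), 1)
      csg <- pmin(pmax(tg_l[labt] * diff_f + spec, 0), 1)
      csb <- pmin(pmax(tb_l[labt] * diff_f + spec, 0), 1)
      a_corr <- 1 - (1 - a_s[take])^(step_len / ref_len)
      wgt <- (1 - accA[ti]) * a_corr
      accR[ti] <- accR[ti] + wgt * csr
      accG[ti] <- accG[ti] + wgt * csg
      accB[ti] <- accB[ti] + wgt * csb
      accA[ti] <- accA[ti] + wgt
    }
    t_cur[ai] <- t_cur[ai] + step_len
    active[ai] <- t_cur[ai] <= tmax[ai] & accA[ai] < 0.99
  }
  accR <- accR + (1 - accA) * cfg$background[1]
  accG <- accG + (1 - accA) * cfg$background[2]
  accB <- accB + (1 - accA) * cfg$background[3]

  img <- array(0, dim = c(cfg$height, cfg$width, 3))
  # grid rows iterate u (x) fastest; image row 1 = top (v = +1)
  img[, , 1] <- matrix(accR, cfg$height, cfg$width, byrow = TRUE)[cfg$height:1, ]
  img[, , 2] <- matrix(accG, cfg$height, cfg$width, byrow = TRUE)[cfg$height:1, ]
  img[, , 3] <- matrix(accB, cfg$height, cfg$width, byrow = TRUE)[cfg$height:1, ]
  structure(list(rgb = pmin(pmax(img, 0), 1), width = cfg$width,
                 height = cfg$height), class = "volume_image")
}

# cross product (kept internal; avoids a dependency for one line)
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %d x %d, mean luminance %.4f\n",
              x$width, x$height, mean(image_luminance(x))))
  invisible(x)
}

#' @export
plot.volume_image <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = x$height / x$width)
  graphics::rasterImage(grDevices::as.raster(x$rgb), 0, 0, 1, 1, interpolate = FALSE)
  invisible(x)
}

#' Relative luminance of an image
#'
#' Rec. 709 weights: `0.2126 R + 0.7152 G + 0.0722 B`.
#' @param img a `volume_image`.
#' @return matrix of per-pixel luminance.
#' @export
image_luminance <- function(img) {
  0.2126 * img$rgb[, , 1] + 0.7152 * img$rgb[, , 2] + 0.0722 * img$rgb[, , 3]
}

#' Write an image as PPM (plain text) or PNG
#'
#' @param img a `volume_image`.
#' @param path output path; `.ppm` writes plain-text P3, `.png` an 8-bit PNG.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.ppm$", path, ignore.case = TRUE)) {
    m <- round(img$rgb * 255)
    lines <- character(img$height)
    for (r in seq_len(img$height)) {
      row <- as.vector(rbind(m[r, , 1], m[r, , 2], m[r, , 3]))
      lines[r] <- paste(row, collapse = " ")
    }
    writeLines(c("P3", sprintf("%d %d", img$width, img$height), "255", lines),
               path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img$rgb, path)
  } else stop("unsupported image extension (use .ppm or .png)")
  invisible(path)
}

#' Read a plain-text PPM image
#' @param path a P3 PPM file.
#' @return a `volume_image`.
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop("only plain P3 PPM supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); mx <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)]) / mx
  rgbm <- matrix(vals, ncol = 3, byrow = TRUE)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgbm[, ch], h, w, byrow = TRUE)
  structure(list(rgb = img, width = w, height = h), class = "volume_image")
}
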