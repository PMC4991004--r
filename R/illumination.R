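#' Blinn-Phong shading with lighting attenuation
#'
#' Evaluates `C = (k_a + k_d * f_att * (N.L)) * C_tf + k_s * f_att * (N.H)^n`
#' with white specular color; the classic model is the `f_att = 1` special
#' case. Dot products are clamped at 0 (no negative light) and the result is
#' clamped to `[0, 1]` per channel. A zero normal (zero-gradient voxel)
#' yields the ambient term only.
#'
#' @param base_color RGB triple in `[0, 1]` (the transfer-function color), or
#'   an `n x 3` matrix of colors.
#' @param normal unit normal (normalized gradient), or `n x 3` matrix.
#' @param light_dir unit light direction.
#' @param halfway unit halfway vector between light and view directions.
#' @param ka,kd,ks ambient / diffuse / specular coefficients in `[0, 1]`.
#' @param shininess specular exponent `n > 0`.
#' @param f_att attenuation factor in `(0, 1]`, applied to the diffuse and
#'   specular terms but not the ambient term.
#' @return RGB matrix (`n x 3`) of shaded colors in `[0, 1]`.
#' @examples
#' shade_blinn_phong(c(1, 0, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, 1),
#'                   ka = 0.1, kd = 0.6, ks = 0, shininess = 32)
#' @export
shade_blinn_phong <- function(base_color, normal, light_dir, halfway,
                              ka, kd, ks, shininess, f_att = 1) {
  base_color <- rbind(base_color)
  normal <- rbind(normal)
  n <- max(nrow(base_color), nrow(normal))
  if (nrow(base_color) == 1L) base_color <- base_color[rep(1, n), , drop = FALSE]
  if (nrow(normal) == 1L) normal <- normal[rep(1, n), , drop = FALSE]
  light_dir <- as.numeric(light_dir)
  halfway <- as.numeric(halfway)
  ndl <- pmax(normal %*% light_dir, 0)
  ndh <- pmax(normal %*% halfway, 0)
  diffuse <- as.vector(ka + kd * f_att * ndl)
  spec <- as.vector(ks * f_att * ndh^shininess)
  out <- base_color * diffuse + spec  # white specular
  pmin(pmax(out, 0), 1)
}

#' Stokes-law attenuation coefficient
#'
#' `alpha = 2 * eta * xi^2 / (3 * rho * V^3)`, the attenuation rate of a
#' plane wave in a viscous Newtonian fluid, adapted to lighting: the medium
#' is water at 20 C (`eta = 0.001002` Pa.s, `rho = 998.2071` kg/m^3), the
#' frequency `xi` is the branch's sibling count, and the speed `V` is a
#' user-controlled dial. With SI constants and `V` of order 10-100 the raw
#' coefficient is numerically negligible over unit distances, so a
#' documented `scale` factor reconciles units; the default is chosen so that
#' `V = 50`, `xi = 1` over a unit distance give an attenuation factor of
#' 0.5. Monotonicities of the raw law (increasing in `xi`, decreasing in
#' `V`) are preserved exactly.
#'
#' @param xi frequency term: number of sibling branches (>= 0).
#' @param V positive wave speed (user dial).
#' @param eta dynamic viscosity (Pa.s).
#' @param rho fluid density (kg/m^3).
#' @param scale unit-reconciliation factor; `scale = 1` gives the raw SI
#'   coefficient.
#' @return attenuation coefficient `alpha >= 0` (vectorized over `xi`, `V`).
#' @seealso [attenuation_factor()]
#' @export
attenuation_coefficient <- function(xi, V, eta = 0.001002, rho = 998.2071,
                                    scale = attenuation_scale()) {
  if (any(V <= 0)) stop("V must be > 0")
  if (any(xi < 0)) stop("xi must be >= 0")
  scale * 2 * eta * xi^2 / (3 * rho * V^3)
}

#' @rdname attenuation_coefficient
#' @export
attenuation_scale <- function(eta = 0.001002, rho = 998.2071) {
  log(2) * 3 * rho * 50^3 / (2 * eta)
}

#' Beer-Lambert attenuation factor
#'
#' `f_att = exp(-alpha * z)`, the fraction of intensity surviving distance
#' `z` at attenuation rate `alpha` (`I_z = I_0 * exp(-alpha * z)`). Always in
#' `(0, 1]`; 1 when either argument is 0.
#'
#' @param alpha attenuation coefficient (>= 0).
#' @param z traveled distance (>= 0); in the topology-aware model this is a
#'   function of branch persistence.
#' @return attenuation factor in `(0, 1]`.
#' @export
attenuation_factor <- function(alpha, z) {
  if (any(alpha < 0) || any(z < 0)) stop("alpha and z must be >= 0")
  exp(-alpha * z)
}

#' Saliency-driven diffuse coefficient
#'
#' `k_d = w * S`, clamped to `[0, 1]`: branches ranked higher by topological
#' saliency receive proportionally more diffuse light.
#'
#' @param S topological saliency in `(0, 1]`.
#' @param w user weight in `[0, 1]`.
#' @return diffuse coefficient in `[0, 1]`.
#' @export
saliency_diffuse <- function(S, w) {
  if (any(w < 0 | w > 1)) stop("w must be in [0, 1]")
  pmin(pmax(w * S, 0), 1)
}

#' Distance-driven diffuse coefficient
#'
#' `k_d = w / (1 + exp(-z))` with `z` the topological depth: a sigmoid that
#' strictly increases with depth, so inner structures are lit more strongly.
#' Ranges over `[w/2, w)` for `z >= 0`.
#'
#' @param z topological depth (>= 0).
#' @param w user weight in `[0, 1]`.
#' @return diffuse coefficient.
#' @export
distance_diffuse <- function(z, w) {
  if (any(w < 0 | w > 1)) stop("w must be in [0, 1]")
  if (any(z < 0)) stop("z must be >= 0")
  w / (1 + exp(-z))
}

#' Per-branch lighting transfer function
#'
#' Assembles a lighting table (one row of Blinn-Phong coefficients per
#' branch) from branch attributes under one of the topology-aware
#' mechanisms:
#' \describe{
#'   \item{saliency}{`k_d = w * S_i` ([saliency_diffuse()]).}
#'   \item{distance}{`k_d = w * sigmoid(depth)` ([distance_diffuse()]).}
#'   \item{attenuation}{shared `k_d = w`; per-branch
#'     `f_att = exp(-alpha_i * z_i)` with `alpha_i` from the branch's sibling
#'     count and the user speed `V`, and `z_i = 1 - p_hat_i` (normalized
#'     persistence, inverted) so that low-persistence structures are dimmed
#'     out while high-persistence structures are protected.}
#'   \item{importance}{comparison mode: `k_a = w * m_hat_i` for a normalized
#'     importance measure (persistence), `k_d = w`.}
#'   \item{constant}{`k_d = w` everywhere (conventional Blinn-Phong).}
#' }
#' `k_a`, `k_s` and the shininess are shared across branches. The perceptual
#' mechanism builds its table through [optimize_luminance()] and
#' [luminance_to_coefficients()] instead.
#'
#' @param attrs a `branch_attributes` table ([annotate_structure()]).
#' @param mode one of `"saliency"`, `"distance"`, `"attenuation"`,
#'   `"importance"`, `"constant"`.
#' @param w user weight in `[0, 1]`.
#' @param V attenuation-mode speed dial (> 0).
#' @param ka,ks,shininess shared coefficients.
#' @param eta,rho,scale attenuation constants, see
#'   [attenuation_coefficient()].
#' @return data.frame of class `lighting_table`: `branch_id`, `ka`, `kd`,
#'   `ks`, `shininess`, `f_att`.
#' @export
build_lighting_table <- function(attrs, mode = c("saliency", "distance",
                                                 "attenuation", "importance",
                                                 "constant"),
                                 w = 0.71, V = 50, ka = 0.1, ks = 0.2,
                                 shininess = 32, eta = 0.001002,
                                 rho = 998.2071, scale = attenuation_scale()) {
  mode <- match.arg(mode)
  nb <- nrow(attrs)
  kd <- rep(w, nb)
  kav <- rep(ka, nb)
  f_att <- rep(1, nb)
  if (mode == "saliency") {
    kd <- saliency_diffuse(attrs$saliency, w)
  } else if (mode == "distance") {
    kd <- distance_diffuse(attrs$depth, w)
  } else if (mode == "attenuation") {
    phat <- .norm_by_max(attrs$persistence)
    alpha <- attenuation_coefficient(attrs$n_siblings, V, eta, rho, scale)
    f_att <- attenuation_factor(alpha, 1 - phat)
  } else if (mode == "importance") {
    kav <- pmin(pmax(w * .norm_by_max(attrs$persistence), 0), 1)
  }
  structure(data.frame(branch_id = attrs$branch_id, ka = kav,
                       kd = pmin(pmax(kd, 0), 1), ks = ks,
                       shininess = shininess, f_att = f_att),
            class = c("lighting_table", "data.frame"))
}

#' Serialize a lighting table to JSON
#'
#' Written as `{"<branch_id>": {"ka":., "kd":., "ks":., "n":., "f_att":.}}`,
#' importable by the renderer and by external tools.
#' @param table a `lighting_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lighting_json <- function(table, path) {
  entries <- lapply(seq_len(nrow(table)), function(i) {
    list(ka = table$ka[i], kd = table$kd[i], ks = table$ks[i],
         n = table$shininess[i], f_att = table$f_att[i])
  })
  names(entries) <- as.character(table$branch_id)
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lighting table from JSON
#' @param path JSON path written by [write_lighting_json()].
#' @return a `lighting_table`.
#' @export
read_lighting_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(names(x))
  structure(data.frame(
    branch_id = ids,
    ka = vapply(x, function(e) e$ka, numeric(1)),
    kd = vapply(x, function(e) e$kd, numeric(1)),
    ks = vapply(x, function(e) e$ks, numeric(1)),
    shininess = vapply(x, function(e) e$n, numeric(1)),
    f_att = vapply(x, function(e) e$f_att, numeric(1)),
    row.names = NULL), class = c("lighting_table", "data.frame"))
}
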