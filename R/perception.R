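#' Just-Noticeable-Difference luminance curve
#'
#' Piecewise threshold-versus-intensity function spanning the whole human
#' vision range (scotopic rod response through photopic Weber behaviour),
#' giving the log10 of the minimal perceivable luminance increment
#' `delta L` as a function of background luminance `L` (cd/m^2, log base
#' 10):
#' \preformatted{
#' log dL = -2.86                                   if log L < -3.94
#'          (0.405 log L + 1.6)^2.18 - 2.86         if -3.94 <= log L < -1.44
#'          log L - 0.395                           if -1.44 <= log L < -0.0184
#'          (0.294 log L + 0.65)^2.7 - 0.72         if -0.0184 <= log L < 1.9
#'          log L - 1.255                           if log L >= 1.9
#' }
#'
#' @param L luminance in cd/m^2 (> 0), vectorized.
#' @return `log10(delta L)`; the JND itself is `10^` the returned value
#'   ([jnd_delta()]).
#' @examples
#' jnd_log_delta(1e-5)  # -2.86 (absolute rod threshold floor)
#' jnd_log_delta(100)   # 2 - 1.255
#' @export
jnd_log_delta <- function(L) {
  if (any(L <= 0)) stop("luminance must be > 0")
  lg <- log10(L)
  out <- numeric(length(lg))
  r1 <- lg < -3.94
  r2 <- lg >= -3.94 & lg < -1.44
  r3 <- lg >= -1.44 & lg < -0.0184
  r4 <- lg >= -0.0184 & lg < 1.9
  r5 <- lg >= 1.9
  out[r1] <- -2.86
  out[r2] <- (0.405 * lg[r2] + 1.6)^2.18 - 2.86
  out[r3] <- lg[r3] - 0.395
  out[r4] <- (0.294 * lg[r4] + 0.65)^2.7 - 0.72
  out[r5] <- lg[r5] - 1.255
  out
}

#' @rdname jnd_log_delta
#' @export
jnd_delta <- function(L) 10^jnd_log_delta(L)

#' Initialization phase: JND-spaced luminance down the tree
#'
#' Assigns the user luminance `L_0` to the root branch; every child receives
#' its parent's luminance plus the JND at the parent's luminance, recursively
#' from root to leaves. The result is the minimal assignment in which every
#' parent-child pair is just distinguishable.
#'
#' @param bd a `branch_decomposition`.
#' @param L0 root luminance in cd/m^2 (> 0).
#' @return data.frame `branch_id`, `luminance`.
#' @export
initialize_luminance <- function(bd, L0) {
  if (!inherits(bd, "branch_decomposition")) stop("expected a `branch_decomposition`")
  if (L0 <= 0) stop("L0 must be > 0")
  br <- bd$branches
  lum <- stats::setNames(rep(NA_real_, nrow(br)), br$id)
  lum[as.character(bd$root)] <- L0
  queue <- bd$root
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    kids <- br$id[!is.na(br$parent) & br$parent == p]
    if (length(kids)) {
      lum[as.character(kids)] <- lum[as.character(p)] +
        jnd_delta(lum[as.character(p)])
      queue <- c(queue, kids)
    }
  }
  data.frame(branch_id = br$id, luminance = as.numeric(lum[as.character(br$id)]))
}

#' Head loss of the contrast-ratio residue flow
#'
#' `dh = (1/K) * Q * p / n_c`, clamped to `[0, 1]`: the share of the
#' contrast-ratio "head" a branch absorbs before passing the residue to its
#' children, in analogy to water flowing through a porous medium (`K = 300`,
#' the hydraulic conductivity of sand).
#'
#' @param p branch persistence, normalized to `[0, 1]` over the tree.
#' @param n_c number of children (>= 1; leaves carry no flow).
#' @param Q fluid flow speed (> 0).
#' @param K hydraulic conductivity (> 0).
#' @return head loss in `[0, 1]`.
#' @export
head_loss <- function(p, n_c, Q = 1, K = 300) {
  if (any(n_c < 1)) stop("head loss applies to branches with children (n_c >= 1)")
  if (Q <= 0 || K <= 0) stop("Q and K must be > 0")
  pmin(pmax((Q * p / n_c) / K, 0), 1)
}

#' Contrast-ratio residue
#'
#' `gamma_i = (1 - dh) * gamma_prev`, floored at `gamma_min`: the contrast
#' ratio shrinks monotonically with depth, so deeper (inner) structures get
#' relatively higher luminance than their parents.
#'
#' @param gamma_prev previous level's contrast ratio in `(0, 1]`.
#' @param dh head loss in `[0, 1]`.
#' @param gamma_min floor keeping downstream divisions finite.
#' @return the residue contrast ratio.
#' @export
gamma_residue <- function(gamma_prev, dh, gamma_min = 1e-3) {
  if (any(gamma_prev <= 0 | gamma_prev > 1)) stop("gamma_prev must be in (0, 1]")
  if (any(dh < 0 | dh > 1)) stop("dh must be in [0, 1]")
  pmax((1 - dh) * gamma_prev, gamma_min)
}

#' Base luminance of the next depth level
#'
#' `L' = L_prev / gamma_prev`; since `gamma` is in `(0, 1]` the base
#' luminance never decreases, and smaller contrast ratios amplify it.
#'
#' @param L_prev parent-level luminance.
#' @param gamma_prev contrast ratio (> 0).
#' @return base luminance for the children's level.
#' @export
parent_child_base <- function(L_prev, gamma_prev) {
  if (any(gamma_prev <= 0)) stop("gamma_prev must be > 0")
  L_prev / gamma_prev
}

#' Distribute a level's base luminance among siblings
#'
#' Each sibling receives `L' * f_b * f_d`, where `f_b` is the normalized
#' importance-triangle area of the sibling's (persistence, volume,
#' hypervolume) triple, each measure normalized within the sibling group
#' (an all-zero measure contributes 0), `f_b` itself normalized by the
#' triangle's maximal area so `f_b` is in `[0, 1]` with a singleton group at
#' 1; and `f_d = (s - s_min) / (s_max - s_min)` ranks siblings by their
#' attachment saddle value (degenerate groups with `s_max = s_min`,
#' including singletons, get `f_d = 1`).
#'
#' @param L_base the level's base luminance ([parent_child_base()]).
#' @param siblings rows of a `branch_attributes` table forming one sibling
#'   group (columns `persistence`, `volume`, `hypervolume`, `saddle_value`).
#' @return numeric vector of candidate luminances, one per sibling.
#' @export
sibling_luminance <- function(L_base, siblings) {
  if (nrow(siblings) < 1L) stop("sibling group must be non-empty")
  f_b <- importance_triangle_area(
    .norm_by_max(siblings$persistence),
    .norm_by_max(siblings$volume),
    .norm_by_max(abs(siblings$hypervolume))) / importance_triangle_area(1, 1, 1)
  s <- siblings$saddle_value
  ds <- max(s) - min(s)
  f_d <- if (nrow(siblings) == 1L || ds == 0) rep(1, nrow(siblings)) else
    (s - min(s)) / ds
  L_base * f_b * f_d
}

#' Enforce the JND condition on a candidate luminance
#'
#' If the candidate's increment over the parent luminance already reaches
#' the JND at the parent's luminance, it is kept. Otherwise the branch falls
#' back to its initialization-phase luminance plus the shortfall
#' `|dL - dL_JND|`; a final correction (applied at most once) lifts the
#' result to `L_parent + JND(L_parent)` if the fallback still falls short,
#' so the output always satisfies the JND bound and never drops below the
#' initialization luminance.
#'
#' @param L_candidate candidate luminance from the sibling distribution.
#' @param L_parent the parent branch's (final) luminance.
#' @param L_init this branch's initialization-phase luminance.
#' @return final luminance (vectorized over candidates).
#' @export
enforce_jnd <- function(L_candidate, L_parent, L_init) {
  dl_jnd <- jnd_delta(L_parent)
  dl <- L_candidate - L_parent
  short <- dl < dl_jnd
  out <- L_candidate
  out[short] <- L_init[short] + abs(dl[short] - dl_jnd)
  out <- pmax(out, L_parent + dl_jnd)  # post-hoc correction, at most once
  pmax(out, L_init)
}

#' Optimization phase: contrast-ratio flow with JND enforcement
#'
#' Starting from the root (`L_0`, contrast ratio `gamma_0`), processes the
#' tree breadth-first: each parent's children receive the base luminance
#' `L_parent / gamma_parent`, split among siblings by importance and saddle
#' value ([sibling_luminance()]), then lifted where needed to respect the
#' JND bound against the parent ([enforce_jnd()]). Each branch's contrast
#' ratio is the residue of its parent's after the head loss of the flow
#' model ([head_loss()], [gamma_residue()]), with persistence normalized to
#' `[0, 1]` over the tree. The model is fully deterministic.
#'
#' @param bd a `branch_decomposition`.
#' @param attrs matching `branch_attributes`.
#' @param L0 root luminance (> 0).
#' @param gamma0 root contrast ratio in `(0, 1)`.
#' @param Q flow speed (> 0).
#' @param K hydraulic conductivity.
#' @param gamma_min floor for the contrast ratio.
#' @return object of class `luminance_assignment`: data.frame `branch_id`,
#'   `luminance`, `init_luminance`, `gamma`, `head_loss`, `depth`, plus
#'   attributes `L0`, `gamma0`.
#' @export
optimize_luminance <- function(bd, attrs, L0 = 10, gamma0 = 0.8, Q = 1,
                               K = 300, gamma_min = 1e-3) {
  if (!inherits(bd, "branch_decomposition")) stop("expected a `branch_decomposition`")
  if (gamma0 <= 0 || gamma0 > 1) stop("gamma0 must be in (0, 1]")
  br <- bd$branches
  init <- initialize_luminance(bd, L0)
  id2row <- match(br$id, attrs$branch_id)
  pnorm <- .norm_by_max(attrs$persistence[id2row])

  lum <- stats::setNames(rep(NA_real_, nrow(br)), br$id)
  gam <- stats::setNames(rep(NA_real_, nrow(br)), br$id)
  dhv <- stats::setNames(rep(NA_real_, nrow(br)), br$id)
  lum[as.character(bd$root)] <- L0
  gam[as.character(bd$root)] <- gamma0
  init_l <- stats::setNames(init$luminance, init$branch_id)

  queue <- bd$root
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    kids <- br$id[!is.na(br$parent) & br$parent == p]
    if (!length(kids)) next
    pc <- as.character(p)
    L_base <- parent_child_base(lum[pc], gam[pc])
    sib <- attrs[match(kids, attrs$branch_id), , drop = FALSE]
    cand <- sibling_luminance(L_base, sib)
    fin <- enforce_jnd(cand, lum[pc], init_l[as.character(kids)])
    lum[as.character(kids)] <- fin
    for (k in kids) {
      nck <- max(sum(!is.na(br$parent) & br$parent == k), 1L)
      dh <- head_loss(pnorm[match(k, br$id)], nck, Q, K)
      dhv[as.character(k)] <- dh
      gam[as.character(k)] <- gamma_residue(gam[pc], dh, gamma_min)
    }
    queue <- c(queue, kids)
  }
  out <- data.frame(branch_id = br$id,
                    luminance = as.numeric(lum[as.character(br$id)]),
                    init_luminance = as.numeric(init_l[as.character(br$id)]),
                    gamma = as.numeric(gam[as.character(br$id)]),
                    head_loss = as.numeric(dhv[as.character(br$id)]),
                    depth = br$depth)
  attr(out, "L0") <- L0
  attr(out, "gamma0") <- gamma0
  class(out) <- c("luminance_assignment", "data.frame")
  out
}

#' Map a luminance assignment to lighting coefficients
#'
#' Luminance drives the diffuse coefficient (the most instinctive reflection
#' of an object's illumination): `k_d = w * L / max(L)`, clamped to
#' `[0, 1]`, so branch ranking by `k_d` equals ranking by luminance and the
#' brightest branch receives `k_d = w`. `k_a`, `k_s`, shininess are shared.
#'
#' @param la a `luminance_assignment`.
#' @param w user weight in `[0, 1]`.
#' @param ka,ks,shininess shared coefficients.
#' @return a `lighting_table`.
#' @export
luminance_to_coefficients <- function(la, w = 0.71, ka = 0.1, ks = 0.2,
                                      shininess = 32) {
  if (any(la$luminance <= 0)) stop("luminances must be > 0")
  kd <- pmin(pmax(w * la$luminance / max(la$luminance), 0), 1)
  structure(data.frame(branch_id = la$branch_id, ka = ka, kd = kd, ks = ks,
                       shininess = shininess, f_att = 1),
            class = c("lighting_table", "data.frame"))
}

#' Export per-level perceptual diagnostics as CSV
#' @param la a `luminance_assignment`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_luminance_csv <- function(la, path) {
  utils::write.csv(as.data.frame(la), path, row.names = FALSE)
  invisible(path)
}
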