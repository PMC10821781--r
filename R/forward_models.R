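# Analytical field-autocorrelation solvers.
#
# Internal unit system: mm and seconds. The wavelength is converted nm->mm in
# acquisition(); lag times are seconds internally and microseconds at I/O.

#' Semi-infinite homogeneous field autocorrelation g1
#'
#' Correlation-diffusion solution for a homogeneous half-space with the
#' extrapolated boundary condition,
#' G1 = (3 musp / 4 pi) (exp(-K r1)/r1 - exp(-K r2)/r2) with
#' K^2 = 3 mua musp + alpha musp^2 k0^2 <dr^2(tau)>, <dr^2(tau)> = 6 Db tau,
#' source depth z0 = 1/(mua + musp) and extrapolation length zb = 5/(3 musp).
#' The returned curve is normalized, g1 = G1(tau)/G1(0).
#'
#' @param layer a [tissue_layer()] describing the medium
#' @param acq a [acquisition()]
#' @param grid a [make_tau_grid()]
#' @return a field-type [correlation_curve()]
#' @export
semi_infinite_g1 <- function(layer, acq, grid) {
  stopifnot(inherits(layer, "tissue_layer"), inherits(acq, "dcs_acquisition"),
            inherits(grid, "tau_grid"))
  if (layer$musp <= 0) stop("musp must be positive (z0, zb undefined)")
  g1 <- semi_infinite_g1_num(as.numeric(grid), layer$mua, layer$musp,
                             layer$alpha * layer$Db, acq$rho, acq$k0)
  correlation_curve(grid, g1, "field",
                    provenance = list(generator = "semi_infinite",
                                      mua = layer$mua, musp = layer$musp,
                                      BFi = layer$alpha * layer$Db,
                                      rho = acq$rho, noise = "noiseless"))
}

# vectorized core: g1(tau) for the homogeneous half-space
semi_infinite_g1_num <- function(tau, mua, musp, bfi, rho, k0) {
  K <- sqrt(3 * mua * musp + musp^2 * k0^2 * 6 * bfi * tau)
  K0 <- sqrt(3 * mua * musp)
  z0 <- 1 / (mua + musp)
  zb <- 5 / (3 * musp)
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  G <- exp(-K * r1) / r1 - exp(-K * r2) / r2
  G0 <- exp(-K0 * r1) / r1 - exp(-K0 * r2) / r2
  G / G0
}

#' Intensity autocorrelation from a field curve (Siegert relation)
#'
#' g2(tau) = 1 + beta g1(tau)^2. Grid and provenance are preserved; the
#' coherence factor is recorded in the provenance.
#'
#' @param curve a field-type [correlation_curve()]
#' @param beta coherence factor in (0, 1]
#' @return an intensity-type [correlation_curve()]
#' @export
siegert_g2 <- function(curve, beta) {
  stopifnot(inherits(curve, "dcs_curve"))
  if (curve$kind != "field") stop("siegert_g2() expects a field curve")
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  prov <- curve$provenance
  prov$beta <- beta
  correlation_curve(curve$grid, 1 + beta * curve$values^2, "intensity", prov)
}

# per-layer Theta^2(q, tau) = 3 mua musp + 6 k0^2 musp^2 Db tau + q^2
.theta <- function(layer, k0, q, tau) {
  sqrt(3 * layer$mua * layer$musp +
         6 * k0^2 * layer$musp^2 * (layer$alpha * layer$Db) * tau + q^2)
}

#' Fourier-domain three-layer solution at the surface
#'
#' Evaluates the transverse-Fourier-transformed correlation-diffusion
#' solution G^(q, z = 0, tau) for a three-layer slab with the deepest layer
#' semi-infinite. The per-layer interior coefficients are eliminated
#' analytically; hyperbolic terms are evaluated as exponentials of
#' non-positive arguments so that the expression stays finite for large q
#' and thick layers. The isotropic source sits at z' = 1/musp1; the top
#' boundary is the extrapolated boundary G = 0 at z = -zb, zb = 5/(3 musp1),
#' which reduces exactly to the semi-infinite image solution when the three
#' layers are identical.
#'
#' @param q spatial frequency, mm^-1 (vectorized)
#' @param tau lag time, s (scalar)
#' @param head a [head_model()]
#' @param acq an [acquisition()]
#' @return G^(q, 0, tau), same length as `q`
#' @export
three_layer_ghat <- function(q, tau, head, acq) {
  stopifnot(inherits(head, "head_model"), inherits(acq, "dcs_acquisition"))
  if (length(head$layers) != 3L) stop("head must have exactly 3 layers")
  stopifnot(all(q >= 0), length(tau) == 1L, tau >= 0)
  l1 <- head$layers[[1]]; l2 <- head$layers[[2]]; l3 <- head$layers[[3]]
  d1 <- l1$thickness; d2 <- l2$thickness
  k0 <- acq$k0
  c_t <- .C_MM_S / l1$n_ref           # in-tissue speed of light
  T1 <- .theta(l1, k0, q, tau)
  T2 <- .theta(l2, k0, q, tau)
  T3 <- .theta(l3, k0, q, tau)
  D1 <- c_t / (3 * l1$musp); D2 <- c_t / (3 * l2$musp); D3 <- c_t / (3 * l3$musp)
  # isotropic source depth: one transport mean free path, 1/(mua + musp),
  # matching the semi-infinite image construction so the homogeneous limit
  # of the layered solution is exact
  zp <- 1 / (l1$mua + l1$musp)
  zb <- 5 / (3 * l1$musp)
  # scaled hyperbolics: chm(x) = cosh(x) e^-x, shm(x) = sinh(x) e^-x
  chm <- function(x) (1 + exp(-2 * x)) / 2
  shm <- function(x) (1 - exp(-2 * x)) / 2
  # layer-2/3 stack, scaled by e^{-T2 d2}:
  #   P = T2 D2 cosh(T2 d2) + T3 D3 sinh(T2 d2)
  #   Q = T2 D2 (T3 D3 cosh(T2 d2) + T2 D2 sinh(T2 d2))
  Pt <- T2 * D2 * chm(T2 * d2) + T3 * D3 * shm(T2 * d2)
  Qt <- T2 * D2 * (T3 * D3 * chm(T2 * d2) + T2 * D2 * shm(T2 * d2))
  # numerator core, scaled by e^{-T1 (d1 - z')}
  num <- T1 * D1 * Pt * chm(T1 * (d1 - zp)) + Qt * shm(T1 * (d1 - zp))
  # denominator, scaled by e^{-T1 (d1 + zb)}
  den <- T1 * (T1 * D1 * Pt * chm(T1 * (d1 + zb)) + Qt * shm(T1 * (d1 + zb)))
  g <- 3 * l1$musp * shm(T1 * zb) * num * exp(-T1 * zp) / den
  if (any(!is.finite(g)))
    stop("three_layer_ghat: non-finite value; check layer parameters")
  g
}

# Gauss-Legendre nodes/weights with J0(q rho) prefactor on [0, qmax]
.quad_rule <- function(n_nodes, rho, qmax = 30) {
  gl <- pracma::gaussLegendre(n_nodes, 0, qmax)
  list(q = gl$x, wj = gl$w * gl$x * besselJ(gl$x * rho, 0), n = n_nodes)
}

# integrate ghat over the rule for each tau (rows: tau)
.hankel_g <- function(taus, head, acq, rule) {
  vapply(taus, function(tt)
    sum(three_layer_ghat(rule$q, tt, head, acq) * rule$wj), numeric(1))
}

#' Three-layer field autocorrelation g1 by inverse Hankel transform
#'
#' g1(tau) = G(rho, 0, tau) / G(rho, 0, 0) with
#' G = (1/2pi) Int_0^30 G^(q, 0, tau) q J0(q rho) dq. The 1/2pi prefactor
#' cancels in the normalization. Quadrature is fixed-order Gauss-Legendre on
#' [0, 30] mm^-1, starting at `n_nodes` nodes and doubled until successive
#' curve estimates agree to `rel_tol` in the maximum relative sense (at most
#' `max_doublings` doublings).
#'
#' @param head a [head_model()]
#' @param acq an [acquisition()]
#' @param grid a [make_tau_grid()]
#' @param n_nodes starting Gauss-Legendre order
#' @param rel_tol relative convergence tolerance of the doubling rule
#' @param max_doublings refinement cap
#' @param quad optional frozen quadrature rule (as returned in the curve's
#'   provenance by a previous call) to skip the doubling loop; used by the
#'   fitters to avoid re-converging the rule at every objective evaluation
#' @return a field-type [correlation_curve()]; the converged rule size is in
#'   `provenance$quad_nodes`
#' @export
three_layer_g1 <- function(head, acq, grid, n_nodes = 300, rel_tol = 1e-8,
                           max_doublings = 4, quad = NULL) {
  stopifnot(inherits(grid, "tau_grid"))
  taus <- c(0, as.numeric(grid))
  if (is.null(quad)) {
    rule <- .quad_rule(n_nodes, acq$rho)
    G <- .hankel_g(taus, head, acq, rule)
    converged <- FALSE
    for (i in seq_len(max_doublings)) {
      rule2 <- .quad_rule(2L * rule$n, acq$rho)
      G2 <- .hankel_g(taus, head, acq, rule2)
      # measured against the tau = 0 value: what matters is the accuracy of
      # the normalized g1, and the raw G underflows at late lags
      dev <- max(abs(G2 - G)) / abs(G2[1])
      rule <- rule2; G <- G2
      if (dev < rel_tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf(paste0("three_layer_g1: quadrature not converged after %d ",
                          "doublings (last relative change %.3g)"),
                   max_doublings, dev))
  } else {
    rule <- quad
    G <- .hankel_g(taus, head, acq, rule)
  }
  g1 <- G[-1] / G[1]
  correlation_curve(grid, g1, "field",
                    provenance = list(generator = "three_layer",
                                      rho = acq$rho, noise = "noiseless",
                                      quad_nodes = rule$n))
}

#' Frozen quadrature rule for repeated three-layer evaluations
#'
#' Runs the doubling rule once for a representative head and returns the
#' converged Gauss-Legendre rule, which [three_layer_g1()] and the
#' three-layer fitter can then reuse.
#'
#' @inheritParams three_layer_g1
#' @return an opaque rule object
#' @export
three_layer_quadrature <- function(head, acq, grid, n_nodes = 300,
                                   rel_tol = 1e-8, max_doublings = 4) {
  curve <- three_layer_g1(head, acq, grid, n_nodes, rel_tol, max_doublings)
  .quad_rule(curve$provenance$quad_nodes, acq$rho)
}
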