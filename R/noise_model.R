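# Correlator noise: magnitude model and seeded Gaussian injection.

#' Noise specification of a correlator measurement
#'
#' @param Tint integration time, s
#' @param Tb correlator bin width, s (default 1 us, the smallest lag)
#' @param count_rate detected photon rate, counts/s
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(Tint, Tb = 1e-6, count_rate = 8050) {
  stopifnot(Tint > 0, Tb > 0, count_rate > 0, count_rate * Tb > 0)
  structure(list(Tint = Tint, Tb = Tb, count_rate = count_rate),
            class = "noise_spec")
}

#' Named noise presets
#'
#' Presets "Tint1", "Tint10", "Tint30" correspond to integration times of
#' 1, 10 and 30 s at 8.05 kcps; "noiseless" returns `NULL`.
#'
#' @param name preset name
#' @return a [noise_spec()] or `NULL`
#' @export
noise_preset <- function(name = c("Tint1", "Tint10", "Tint30", "noiseless")) {
  name <- match.arg(name)
  switch(name,
         Tint1 = noise_spec(1),
         Tint10 = noise_spec(10),
         Tint30 = noise_spec(30),
         noiseless = NULL)
}

#' Single-exponential decay-rate estimate of an intensity curve
#'
#' Least-squares fit of g2(tau) ~ 1 + beta exp(-Gamma tau), used to supply
#' the decay rate entering the noise-magnitude model. The fit is initialized
#' from the intercept and the 1/e crossing and refined by damped
#' Gauss-Newton iterations on (beta, log Gamma).
#'
#' @param curve an intensity-type [correlation_curve()] (or a bare numeric
#'   vector paired with `tau`)
#' @param beta_guess starting coherence factor; default taken from the
#'   curve's intercept
#' @param tau lag times, only when `curve` is a bare vector
#' @return list with elements `beta`, `gamma` (s^-1) and `converged`;
#'   a non-decaying curve yields `converged = FALSE` and `gamma = 0`
#' @export
estimate_decay_rate <- function(curve, beta_guess = NULL, tau = NULL) {
  if (inherits(curve, "dcs_curve")) {
    if (curve$kind != "intensity")
      stop("estimate_decay_rate() expects an intensity curve")
    y <- curve$values
    tau <- as.numeric(curve$grid)
  } else {
    y <- as.numeric(curve)
    if (is.null(tau)) stop("tau required for a bare vector")
  }
  d <- y - 1
  b0 <- beta_guess %||% max(d)
  n <- length(d)
  # non-decaying input: no amplitude, or no drop between early and late lags
  if (!(b0 > 1e-12) ||
      mean(d[seq_len(max(n %/% 8, 1))]) - mean(d[(n - n %/% 8):n]) <
        1e-9 * max(abs(d)))
    return(list(beta = max(b0, 0), gamma = 0, converged = FALSE))
  # 1/e crossing of (g2-1)/b0 for the initial decay rate
  yn <- d / b0
  idx <- which(yn <= exp(-1))
  g0 <- if (length(idx)) 1 / tau[idx[1]] else 0.1 / tau[length(tau)]
  p <- c(b0, log(g0))
  conv <- FALSE
  for (it in 1:50) {
    e <- exp(-exp(p[2]) * tau)
    r <- p[1] * e - d
    J <- cbind(e, -p[1] * exp(p[2]) * tau * e)
    step <- tryCatch(solve(crossprod(J) + diag(1e-12, 2), crossprod(J, -r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    p <- p + as.numeric(step)
    if (max(abs(step)) < 1e-12) { conv <- TRUE; break }
  }
  gamma <- exp(p[2])
  if (!is.finite(gamma) || gamma <= 0)
    return(list(beta = b0, gamma = 0, converged = FALSE))
  list(beta = p[1], gamma = gamma, converged = conv)
}

#' Standard deviation of correlator noise per lag
#'
#' Shot-noise-limited correlator noise magnitude
#' sigma(tau) = sqrt(Tb/Tint) [ beta^2 ((1+e^{-2 G Tb})(1+e^{-2 G tau}) +
#' 2 m (1-e^{-2 G Tb}) e^{-2 G tau}) / (1-e^{-2 G Tb}) +
#' 2 <n>^-1 beta (1+e^{-2 G tau}) + <n>^-2 (1+e^{-G tau}) ]^{1/2},
#' with <n> = I Tb the mean counts per bin and m = round(tau/Tb) the bin
#' index. sigma scales exactly as Tint^(-1/2).
#'
#' @param spec a [noise_spec()]
#' @param beta coherence factor
#' @param gamma decay rate, s^-1 (>= 0)
#' @param grid a [make_tau_grid()] (or numeric lag vector, s)
#' @return numeric vector sigma(tau), same length as the grid
#' @export
noise_sigma <- function(spec, beta, gamma, grid) {
  stopifnot(inherits(spec, "noise_spec"), gamma >= 0, beta > 0)
  tau <- as.numeric(grid)
  Tb <- spec$Tb
  n_mean <- spec$count_rate * Tb
  m <- round(tau / Tb)
  e2b <- exp(-2 * gamma * Tb)
  e2t <- exp(-2 * gamma * tau)
  e1t <- exp(-gamma * tau)
  bracket <- beta^2 * ((1 + e2b) * (1 + e2t) + 2 * m * (1 - e2b) * e2t) /
    (1 - e2b) +
    2 / n_mean * beta * (1 + e2t) +
    1 / n_mean^2 * (1 + e1t)
  sqrt(Tb / spec$Tint * bracket)
}

#' Add seeded correlator noise to an intensity curve
#'
#' Draws independent zero-mean Gaussian deviates with per-lag standard
#' deviation from [noise_sigma()]; the decay rate is refit from the input
#' curve. Values are not clipped: noisy g2 may fall below 1 or exceed
#' 1 + beta. Deterministic given `seed`.
#'
#' @param curve a noiseless intensity-type [correlation_curve()]
#' @param spec a [noise_spec()]
#' @param seed integer seed
#' @return an intensity-type [correlation_curve()] with noise provenance
#' @export
add_noise <- function(curve, spec, seed) {
  stopifnot(inherits(curve, "dcs_curve"), curve$kind == "intensity",
            inherits(spec, "noise_spec"))
  est <- estimate_decay_rate(curve)
  if (!est$converged || est$gamma <= 0)
    stop("add_noise: could not estimate a positive decay rate")
  sig <- noise_sigma(spec, est$beta, est$gamma, curve$grid)
  eps <- withr_seed(seed, rnorm(length(sig), sd = sig))
  prov <- curve$provenance
  prov$noise <- sprintf("Tint%g", spec$Tint)
  prov$noise_seed <- seed
  correlation_curve(curve$grid, curve$values + eps, "intensity", prov)
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
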