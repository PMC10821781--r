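#' @useDynLib dcsflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif approx coef median sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# speed of light in vacuum, mm/s
.C_MM_S <- 2.99792458e11

#' Optical and dynamic description of one tissue slab
#'
#' A tissue layer is described by its absorption coefficient, reduced
#' scattering coefficient, scattering anisotropy, refractive index,
#' thickness, and the effective Brownian diffusion coefficient of its moving
#' scatterers. The blood flow index of the layer is `alpha * Db`.
#'
#' @param mua absorption coefficient, mm^-1 (> 0)
#' @param musp reduced scattering coefficient, mm^-1 (> 0)
#' @param Db effective Brownian diffusion coefficient, mm^2/s (>= 0)
#' @param thickness slab thickness, mm; `Inf` allowed for the deepest layer
#' @param alpha fraction of dynamic scattering events, in [0, 1]
#' @param g_anis scattering anisotropy (used only by the Monte Carlo)
#' @param n_ref refractive index
#' @return an object of class `tissue_layer`
#' @export
tissue_layer <- function(mua, musp, Db, thickness = Inf, alpha = 1,
                         g_anis = 0.89, n_ref = 1.37) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua), mua > 0)
  stopifnot(is.numeric(musp), length(musp) == 1L, is.finite(musp), musp > 0)
  stopifnot(is.numeric(Db), length(Db) == 1L, is.finite(Db), Db >= 0)
  stopifnot(is.numeric(thickness), length(thickness) == 1L, thickness > 0)
  stopifnot(alpha >= 0, alpha <= 1)
  stopifnot(g_anis > -1, g_anis < 1, n_ref > 0)
  structure(list(mua = mua, musp = musp, Db = Db, thickness = thickness,
                 alpha = alpha, g_anis = g_anis, n_ref = n_ref),
            class = "tissue_layer")
}

#' @export
print.tissue_layer <- function(x, ...) {
  cat(sprintf(
    "<tissue_layer> mua=%.4g mm^-1, musp=%.4g mm^-1, Db=%.3g mm^2/s, d=%s mm\n",
    x$mua, x$musp, x$Db,
    if (is.finite(x$thickness)) format(x$thickness) else "Inf"))
  invisible(x)
}

#' Three-layer head model
#'
#' Orders three [tissue_layer()] objects top-down (scalp, skull, brain) and
#' derives the interface coordinates as cumulative thicknesses. The deepest
#' layer is treated as semi-infinite by the analytical solver regardless of
#' its nominal thickness; the Monte Carlo uses the stated thickness.
#'
#' @param scalp,skull,brain the three layers, top first
#' @return an object of class `head_model`
#' @export
head_model <- function(scalp, skull, brain) {
  layers <- list(scalp, skull, brain)
  ok <- vapply(layers, inherits, logical(1), "tissue_layer")
  if (!all(ok)) stop("head_model() expects three tissue_layer objects")
  if (!is.finite(scalp$thickness) || !is.finite(skull$thickness))
    stop("scalp and skull thicknesses must be finite")
  bt <- if (is.finite(brain$thickness)) brain$thickness else 50
  structure(list(layers = layers,
                 boundaries = cumsum(c(scalp$thickness, skull$thickness, bt))),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> 3 layers, interfaces at z =",
      paste(format(x$boundaries), collapse = ", "), "mm\n")
  for (l in x$layers) print(l)
  invisible(x)
}

#' Baseline human-head model at 785 nm
#'
#' Scalp (5 mm), skull (7 mm) and brain (50 mm) layers with literature
#' optical properties at 785 nm and baseline flow indices of 1e-6, 0 and
#' 6e-6 mm^2/s. Any field can be overridden.
#'
#' @param Db_scalp,Db_skull,Db_brain layer flow indices, mm^2/s
#' @param delta1,delta2 scalp and skull thicknesses, mm
#' @param mua,musp length-3 vectors of optical properties (scalp, skull, brain)
#' @return a [head_model()]
#' @export
baseline_head <- function(Db_scalp = 1e-6, Db_skull = 0, Db_brain = 6e-6,
                          delta1 = 5, delta2 = 7,
                          mua = c(0.019, 0.014, 0.019),
                          musp = c(0.660, 0.860, 1.110)) {
  head_model(
    tissue_layer(mua[1], musp[1], Db_scalp, delta1),
    tissue_layer(mua[2], musp[2], Db_skull, delta2),
    tissue_layer(mua[3], musp[3], Db_brain, 50))
}

#' Measurement context of a DCS acquisition
#'
#' @param rho source-detector distance, mm
#' @param wavelength laser wavelength, nm
#' @param beta coherence factor in (0, 1]
#' @param n_medium tissue refractive index entering the wavenumber
#' @param Tb correlator bin width, s
#' @param Tint integration time, s
#' @param count_rate detected photon rate, counts/s
#' @return an object of class `dcs_acquisition` with the wavenumber `k0`
#'   (mm^-1) precomputed
#' @export
acquisition <- function(rho, wavelength = 785, beta = 0.5, n_medium = 1.37,
                        Tb = 1e-6, Tint = 1, count_rate = 8050) {
  stopifnot(rho > 0, wavelength > 0, beta > 0, beta <= 1, n_medium > 0,
            Tb > 0, Tint > 0, count_rate > 0)
  lambda_mm <- wavelength * 1e-6
  structure(list(rho = rho, wavelength = wavelength, beta = beta,
                 n_medium = n_medium, k0 = 2 * pi * n_medium / lambda_mm,
                 Tb = Tb, Tint = Tint, count_rate = count_rate),
            class = "dcs_acquisition")
}

#' @export
print.dcs_acquisition <- function(x, ...) {
  cat(sprintf("<dcs_acquisition> rho=%g mm, lambda=%g nm, beta=%g, k0=%.1f mm^-1\n",
              x$rho, x$wavelength, x$beta, x$k0))
  invisible(x)
}

#' Lag-time grid of a correlator
#'
#' Builds a strictly increasing grid of lag times. The default reproduces
#' the 127-point grid spanning 1 us to (not including) 10,000 us with
#' logarithmic spacing; linear spacing is available via `spacing`.
#'
#' @param n_points number of lags (>= 2)
#' @param tau_min first lag, s
#' @param tau_max open upper bound, s; the last lag is strictly below it
#' @param spacing "log" (constant adjacent-lag ratio) or "linear"
#' @return an object of class `tau_grid`: numeric lag vector (s) with the
#'   construction recorded in attributes
#' @export
make_tau_grid <- function(n_points = 127, tau_min = 1e-6, tau_max = 1e-2,
                          spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2)
    stop("n_points must be an integer >= 2")
  if (!(tau_min > 0) || !(tau_max > tau_min))
    stop("need 0 < tau_min < tau_max")
  n_points <- as.integer(n_points)
  # half-open [tau_min, tau_max): place n_points lags as if n_points+... the
  # (n_points+1)-th lag would land exactly on tau_max
  tau <- if (spacing == "log") {
    exp(seq(log(tau_min), log(tau_max), length.out = n_points + 1L))[seq_len(n_points)]
  } else {
    seq(tau_min, tau_max, length.out = n_points + 1L)[seq_len(n_points)]
  }
  structure(tau, class = "tau_grid", spacing = spacing,
            tau_min = tau_min, tau_max = tau_max)
}

#' @export
print.tau_grid <- function(x, ...) {
  cat(sprintf("<tau_grid> %d lags, %.3g us .. %.4g us (%s spacing)\n",
              length(x), x[1] * 1e6, x[length(x)] * 1e6, attr(x, "spacing")))
  invisible(x)
}

#' Correlation curve container
#'
#' Holds a field (g1) or intensity (g2) autocorrelation curve on a lag grid
#' together with provenance metadata (generator, parameters, seed, noise
#' condition).
#'
#' @param grid a [make_tau_grid()] grid
#' @param values curve values, same length as `grid`
#' @param kind "field" (g1) or "intensity" (g2)
#' @param provenance named list of metadata
#' @return an object of class `dcs_curve`
#' @export
correlation_curve <- function(grid, values, kind = c("field", "intensity"),
                              provenance = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "tau_grid"), length(values) == length(grid),
            all(is.finite(values)))
  structure(list(grid = grid, values = as.numeric(values), kind = kind,
                 provenance = provenance),
            class = "dcs_curve")
}

#' @export
print.dcs_curve <- function(x, ...) {
  gen <- x$provenance$generator %||% "?"
  cat(sprintf("<dcs_curve:%s> %d lags, value[1]=%.6f, generator=%s\n",
              x$kind, length(x$values), x$values[1], gen))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read correlation curves as columnar text
#'
#' Curves are written as CSV (`tau_us,value` header, lags reported in
#' microseconds) with a JSON sidecar (`<path>.json`) carrying kind and
#' provenance.
#'
#' @param curve a [correlation_curve()]
#' @param path CSV path
#' @return `read_curve` returns the reconstructed curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dcs_curve"))
  df <- data.frame(tau_us = as.numeric(curve$grid) * 1e6, value = curve$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(kind = curve$kind, provenance = curve$provenance,
               spacing = attr(curve$grid, "spacing"),
               tau_max_us = attr(curve$grid, "tau_max") * 1e6)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tau <- df$tau_us * 1e-6
  grid <- structure(tau, class = "tau_grid",
                    spacing = meta$spacing %||% "log",
                    tau_min = tau[1],
                    tau_max = (meta$tau_max_us %||% (tau[length(tau)] * 1e6)) * 1e-6)
  correlation_curve(grid, df$value, kind = meta$kind,
                    provenance = as.list(meta$provenance))
}
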