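# Layered-slab photon Monte Carlo: geometry, simulation, Eq.-15-style
# re-weighting, and history persistence.

#' Slab geometry for the photon Monte Carlo
#'
#' Three-layer slab with a flat-beam source at the origin (normal incidence)
#' and annular ring detectors on the top surface. Rings centred at the
#' source-detector distance collect all azimuths, which raises detection
#' efficiency at reduced photon budgets relative to discrete detectors at a
#' single azimuth; the collected physics (path-length and momentum-transfer
#' distributions at radius rho) is identical.
#'
#' @param head a [head_model()]; layer thicknesses must be finite for the
#'   Monte Carlo (the default brain layer is 50 mm)
#' @param detectors data.frame with columns `rho` (ring centre, mm) and
#'   `radius` (ring half-width, mm)
#' @param source_diameter flat beam diameter, mm
#' @param n_external refractive index outside the slab
#' @param r_kill absorbing side boundary radius, mm
#' @param max_path total path-length cap per photon, mm; defaults to 10x the
#'   slab depth
#' @return an object of class `slab_geometry`
#' @export
slab_geometry <- function(head,
                          detectors = data.frame(rho = c(5, 10, 15, 20, 25, 30),
                                                 radius = c(0.13, 0.28, 0.45,
                                                            0.7, 1, 1.5)),
                          source_diameter = 1, n_external = 1,
                          r_kill = 100, max_path = NULL) {
  stopifnot(inherits(head, "head_model"),
            all(c("rho", "radius") %in% names(detectors)),
            all(detectors$rho - detectors$radius > source_diameter / 2))
  depth <- head$boundaries[3]
  if (is.null(max_path)) max_path <- 10 * depth
  structure(list(head = head, detectors = detectors,
                 source_radius = source_diameter / 2,
                 n_external = n_external, r_kill = r_kill,
                 max_path = max_path),
            class = "slab_geometry")
}

# stable short hash of the geometry for history-file compatibility checks
.geometry_hash <- function(geom) {
  h <- geom$head
  key <- paste(
    paste(vapply(h$layers, function(l)
      sprintf("%.6g/%.6g/%.6g/%.6g", l$musp, l$g_anis, l$n_ref, l$thickness),
      character(1)), collapse = ";"),
    paste(sprintf("%.6g:%.6g", geom$detectors$rho, geom$detectors$radius),
          collapse = ","),
    sprintf("%.6g|%.6g|%.6g|%.6g", geom$source_radius, geom$n_external,
            geom$r_kill, geom$max_path))
  # tiny FNV-style rolling hash; stability matters, not cryptography
  acc <- 0
  for (b in utf8ToInt(key)) acc <- (acc * 131 + b) %% 2147483647
  sprintf("g%010d", acc)
}

#' Simulate photon histories through the layered slab
#'
#' Scattering-only transport (absorption is applied analytically when
#' curves are reconstructed) with Henyey-Greenstein phase function,
#' per-layer scattering coefficient mus = musp/(1 - g), Fresnel reflection
#' at the refractive-index-mismatched top surface, and absorbing bottom and
#' side boundaries. Records, for each photon exiting through a detector
#' ring, the per-layer total path length L_i (mm) and accumulated momentum
#' transfer Y_i = sum(1 - cos theta) over scattering events in layer i.
#'
#' @param geom a [slab_geometry()]
#' @param n_photons number of launched photons
#' @param seed integer seed (runs are deterministic given the seed)
#' @return a `photon_histories` data.frame with columns `detector`,
#'   `L1..L3`, `Y1..Y3`; the geometry hash, seed and photon budget are
#'   attached as attributes
#' @export
simulate_photons <- function(geom, n_photons, seed) {
  stopifnot(inherits(geom, "slab_geometry"), n_photons >= 1)
  layers <- geom$head$layers
  mus <- vapply(layers, function(l) l$musp / (1 - l$g_anis), numeric(1))
  res <- .mc_simulate(
    as.integer(n_photons), geom$head$boundaries, mus,
    layers[[1]]$g_anis, layers[[1]]$n_ref, geom$n_external,
    geom$source_radius, geom$detectors$rho, geom$detectors$radius,
    geom$r_kill, geom$max_path, as.integer(seed))
  if (length(res$detector) == 0L)
    warning("simulate_photons: no photons detected")
  df <- data.frame(detector = res$detector,
                   L1 = res$L[, 1], L2 = res$L[, 2], L3 = res$L[, 3],
                   Y1 = res$Y[, 1], Y2 = res$Y[, 2], Y3 = res$Y[, 3])
  structure(df, class = c("photon_histories", "data.frame"),
            geometry_hash = .geometry_hash(geom), seed = seed,
            n_photons = n_photons)
}

#' Field autocorrelation from photon histories
#'
#' Reconstructs G1(tau) = (1/Np) sum_s exp(-(k0^2/3) sum_i Y_si 6 Db_i tau)
#' exp(-sum_i mua_i L_si) and returns the normalized g1 = G1/G1(0).
#' Arbitrary layer dynamics and absorption can be applied to a fixed photon
#' set without re-simulation.
#'
#' @param histories a `photon_histories` object from [simulate_photons()]
#' @param Db_per_layer length-3 vector of layer flow indices, mm^2/s
#' @param mua_per_layer length-3 vector of absorption coefficients, mm^-1
#' @param acq an [acquisition()] (supplies the wavenumber)
#' @param grid a [make_tau_grid()]
#' @param detector which detector ring to use (index into the geometry's
#'   detector table)
#' @return a field-type [correlation_curve()]
#' @export
g1_from_histories <- function(histories, Db_per_layer, mua_per_layer,
                              acq, grid, detector = 1L) {
  stopifnot(inherits(histories, "photon_histories"),
            length(Db_per_layer) == 3L, length(mua_per_layer) == 3L)
  sel <- histories$detector == detector
  if (!any(sel)) stop("g1_from_histories: no histories for this detector")
  L <- as.matrix(histories[sel, c("L1", "L2", "L3")])
  Y <- as.matrix(histories[sel, c("Y1", "Y2", "Y3")])
  G <- .mc_g1_weights(L, Y, mua_per_layer, Db_per_layer,
                      c(0, as.numeric(grid)), acq$k0)
  correlation_curve(grid, G[-1] / G[1], "field",
                    provenance = list(generator = "monte_carlo",
                                      detector = detector,
                                      n_detected = sum(sel),
                                      seed = attr(histories, "seed"),
                                      noise = "noiseless"))
}

#' Persist photon histories as columnar text
#'
#' Histories round-trip losslessly through a CSV table whose header comment
#' lines carry the geometry hash, seed and photon budget. Reading into an
#' incompatible analysis is guarded by the geometry hash.
#'
#' @param histories a `photon_histories` object
#' @param path file path
#' @param expected_hash optional geometry hash to enforce on read (pass
#'   `.geometry_hash`-compatible value via [slab_geometry()])
#' @return `read_histories` returns the reconstructed object
#' @export
write_histories <- function(histories, path) {
  stopifnot(inherits(histories, "photon_histories"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# geometry_hash=%s", attr(histories, "geometry_hash")),
    sprintf("# seed=%d", attr(histories, "seed")),
    sprintf("# n_photons=%.0f", attr(histories, "n_photons"))), con)
  # full 17-significant-digit text so re-weighting after a round-trip is
  # bit-for-bit identical
  df <- as.data.frame(histories)
  for (nm in c("L1", "L2", "L3", "Y1", "Y2", "Y3"))
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @param geom optional [slab_geometry()]; when given, the stored geometry
#'   hash must match or reading fails
#' @export
read_histories <- function(path, geom = NULL) {
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# [a-z_]+=", "", hdr)
  df <- read.csv(path, comment.char = "#")
  out <- structure(df, class = c("photon_histories", "data.frame"),
                   geometry_hash = meta[1], seed = as.integer(meta[2]),
                   n_photons = as.numeric(meta[3]))
  if (!is.null(geom) && .geometry_hash(geom) != meta[1])
    stop("read_histories: geometry hash mismatch (",
         meta[1], " vs ", .geometry_hash(geom), ")")
  out
}
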