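# Layered-slab Monte Carlo: transport contracts, the momentum-transfer
# estimator, and history persistence. Heavier statistical comparisons with
# diffusion theory run in the acceptance suite.

mc_geom <- function(...) slab_geometry(baseline_head(), ...)

test_that("simulation is deterministic and histories are well-formed", {
  geom <- mc_geom(max_path = 100)
  h1 <- simulate_photons(geom, 2e4, seed = 3)
  h2 <- simulate_photons(geom, 2e4, seed = 3)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_gt(nrow(h1), 0)
  expect_true(all(as.matrix(h1[, 2:7]) >= 0))
  expect_true(all(rowSums(h1[, c("L1", "L2", "L3")]) > 0))
  expect_false(identical(as.data.frame(h1),
                         as.data.frame(simulate_photons(geom, 2e4, seed = 4))))
})

test_that("detected paths are at least as long as the source-ring chord", {
  geom <- mc_geom(max_path = 100)
  h <- simulate_photons(geom, 2e4, seed = 9)
  # straight-line lower bound: ring inner radius minus the source radius
  lower <- geom$detectors$rho[h$detector] -
    geom$detectors$radius[h$detector] - geom$source_radius
  expect_true(all(rowSums(h[, c("L1", "L2", "L3")]) >= lower))
})

test_that("static dynamics and zero lag leave g1 at exactly 1", {
  geom <- mc_geom(max_path = 100)
  h <- simulate_photons(geom, 5e4, seed = 2)
  acq <- acquisition(rho = 10)
  g_static <- g1_from_histories(h, c(0, 0, 0), c(0.019, 0.014, 0.019),
                                acq, std_grid, detector = 2L)
  expect_equal(g_static$values, rep(1, 127))
  g <- g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.019, 0.014, 0.019),
                         acq, std_grid, detector = 2L)
  # tau -> 0 normalization regardless of dynamics
  tiny <- make_tau_grid(2, 1e-12, 1e-11)
  gt <- g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.019, 0.014, 0.019),
                          acq, tiny, detector = 2L)
  expect_equal(gt$values[1], 1, tolerance = 1e-6)
  expect_true(all(g$values <= 1 & g$values > 0))
})

test_that("a single synthetic history reproduces the closed-form weight", {
  # one photon with Y = 1, L = 10 mm in a single effective layer:
  # g1(tau) = exp(-(k0^2/3) * 6 Db tau); frozen against a 40-digit
  # evaluation at tau = 100 us, Db = 6e-6, 785 nm, n = 1.37
  h <- structure(data.frame(detector = 1L, L1 = 10, L2 = 0, L3 = 0,
                            Y1 = 1, Y2 = 0, Y3 = 0),
                 class = c("photon_histories", "data.frame"),
                 geometry_hash = "ghand", seed = 0L, n_photons = 1)
  acq <- acquisition(rho = 30)
  tau100 <- make_tau_grid(2, 100e-6, 200e-6)
  g <- g1_from_histories(h, c(6e-6, 0, 0), c(0.019, 0, 0), acq, tau100)
  expect_equal(g$values[1], exp(-acq$k0^2 / 3 * 6 * 6e-6 * 100e-6),
               tolerance = 1e-12)
  expect_equal(g$values[1], 0.86563478743096941, tolerance = 1e-10)
})

test_that("raising layer flow or absorption acts as expected on the estimator", {
  geom <- mc_geom(max_path = 100)
  h <- simulate_photons(geom, 5e4, seed = 21)
  acq <- acquisition(rho = 10)
  base <- g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.019, 0.014, 0.019),
                            acq, std_grid, detector = 2L)
  up <- g1_from_histories(h, c(1e-6, 0, 9e-6), c(0.019, 0.014, 0.019),
                          acq, std_grid, detector = 2L)
  expect_true(all(up$values <= base$values + 1e-12))
  # higher absorption reduces the total weight but not the normalization
  hi_mua <- g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.05, 0.05, 0.05),
                              acq, std_grid, detector = 2L)
  tiny <- make_tau_grid(2, 1e-12, 1e-11)
  expect_equal(g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.05, 0.05, 0.05),
                                 acq, tiny, detector = 2L)$values[1], 1,
               tolerance = 1e-6)
  expect_false(identical(hi_mua$values, base$values))
})

test_that("the estimator is linear over photon subsets", {
  geom <- mc_geom(max_path = 100)
  h <- simulate_photons(geom, 4e4, seed = 5)
  sel <- which(h$detector == 2L)
  acq <- acquisition(rho = 10)
  Db <- c(1e-6, 0, 6e-6); mua <- c(0.019, 0.014, 0.019)
  L <- as.matrix(h[sel, c("L1", "L2", "L3")])
  Y <- as.matrix(h[sel, c("Y1", "Y2", "Y3")])
  taus <- as.numeric(std_grid)
  half <- seq_len(length(sel) %/% 2)
  G_a <- dcsflow:::.mc_g1_weights(L[half, ], Y[half, ], mua, Db, taus, acq30$k0)
  G_b <- dcsflow:::.mc_g1_weights(L[-half, ], Y[-half, ], mua, Db, taus, acq30$k0)
  G_all <- dcsflow:::.mc_g1_weights(L, Y, mua, Db, taus, acq30$k0)
  w <- length(half) / length(sel)
  expect_equal(w * G_a + (1 - w) * G_b, G_all, tolerance = 1e-12)
})

test_that("histories round-trip with geometry guard", {
  geom <- mc_geom(max_path = 100)
  h <- simulate_photons(geom, 1e4, seed = 12)
  path <- file.path(tempdir(), "hist.csv")
  write_histories(h, path)
  back <- read_histories(path, geom = geom)
  expect_equal(as.data.frame(back), as.data.frame(h), tolerance = 1e-12)
  expect_identical(attr(back, "seed"), 12L)
  # re-weighting read histories reproduces the pre-write curve bit-for-bit
  acq <- acquisition(rho = 10)
  g_pre <- g1_from_histories(h, c(1e-6, 0, 6e-6), c(0.019, 0.014, 0.019),
                             acq, std_grid, detector = 2L)
  g_post <- g1_from_histories(back, c(1e-6, 0, 6e-6), c(0.019, 0.014, 0.019),
                              acq, std_grid, detector = 2L)
  expect_identical(g_pre$values, g_post$values)
  other <- slab_geometry(baseline_head(), max_path = 99)
  expect_error(read_histories(path, geom = other), "hash mismatch")
})
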