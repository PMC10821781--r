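# Analytical solvers: lag grid, semi-infinite and three-layer field curves.

test_that("lag grid spans the half-open interval with constant log ratio", {
  g <- make_tau_grid(127, 1e-6, 1e-2)
  expect_length(g, 127)
  expect_equal(g[1], 1e-6)
  expect_lt(g[127], 1e-2)
  expect_true(all(diff(g) > 0))
  ratios <- exp(diff(log(as.numeric(g))))
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-12)

  g2 <- make_tau_grid(2, 1e-6, 1e-5)
  expect_length(g2, 2)
  expect_equal(g2[1], 1e-6)

  lin <- make_tau_grid(10, 1e-6, 1e-5, spacing = "linear")
  expect_equal(max(abs(diff(diff(as.numeric(lin))))), 0, tolerance = 1e-18)

  expect_error(make_tau_grid(1), "n_points")
  expect_error(make_tau_grid(10, 0, 1e-2), "tau_min")
  expect_error(make_tau_grid(10, 1e-2, 1e-3), "tau_min")
})

test_that("semi-infinite g1 matches the arbitrary-precision point value", {
  # frozen from a 40-digit evaluation of the closed form (scalar K, image
  # sources) at Table-1 brain parameters, rho = 30 mm, tau = 10 us
  g <- semi_infinite_g1(brain_layer, acq30, std_grid)
  i10 <- which.min(abs(as.numeric(std_grid) - 10e-6))
  v <- semi_infinite_g1_num(10e-6, 0.019, 1.110, 6e-6, 30, acq30$k0)
  expect_equal(v, 0.087562855183733682, tolerance = 1e-10)
  # and the packaged curve agrees with the raw evaluation on its own grid
  expect_equal(g$values[i10],
               semi_infinite_g1_num(as.numeric(std_grid)[i10], 0.019, 1.110,
                                    6e-6, 30, acq30$k0), tolerance = 1e-14)
})

test_that("semi-infinite g1 is normalized, bounded and monotone", {
  draws <- draw_layers(8, seed = 11)
  for (i in seq_len(nrow(draws))) {
    l <- tissue_layer(draws$mua[i], draws$musp[i], draws$Db[i])
    acq <- acquisition(rho = draws$rho[i])
    g <- semi_infinite_g1(l, acq, std_grid)
    expect_true(all(g$values > 0 & g$values <= 1))
    expect_true(all(diff(g$values) <= 0))
    # tau -> 0 limit
    tiny <- make_tau_grid(4, 1e-15, 1e-13)
    expect_equal(semi_infinite_g1(l, acq, tiny)$values[1], 1,
                 tolerance = 1e-9)
  }
  # static medium: flat curve at exactly 1
  static <- tissue_layer(0.019, 1.110, 0)
  expect_equal(semi_infinite_g1(static, acq30, std_grid)$values,
               rep(1, 127), tolerance = 1e-12)
  expect_error(semi_infinite_g1(tissue_layer(0.019, 1e-9, 1e-6), acq30,
                                std_grid), NA)
})

test_that("Siegert relation maps field to intensity curves", {
  g1 <- semi_infinite_g1(brain_layer, acq30, std_grid)
  g2 <- siegert_g2(g1, 0.5)
  expect_equal(g2$values, 1 + 0.5 * g1$values^2, tolerance = 1e-15)
  expect_identical(g2$kind, "intensity")
  # intercept: at a vanishing lag g2 -> 1 + beta
  tiny <- make_tau_grid(2, 1e-15, 1e-13)
  g2t <- siegert_g2(semi_infinite_g1(brain_layer, acq30, tiny), 0.5)
  expect_equal(g2t$values[1], 1.5, tolerance = 1e-9)
  flat <- correlation_curve(std_grid, rep(1, 127), "field")
  expect_equal(siegert_g2(flat, 0.5)$values, rep(1.5, 127))
  expect_error(siegert_g2(g2, 0.5), "field")
  expect_error(siegert_g2(g1, 1.5), "beta")
})

test_that("Fourier-domain three-layer solution matches the frozen oracle", {
  # 40-digit mpmath solve of the 7x7 boundary-condition system
  # (baseline head, 785 nm, n = 1.37) agrees with the closed form; values
  # frozen here at three (q, tau) points
  head <- baseline_head()
  expect_equal(three_layer_ghat(1, 100e-6, head, acq30),
               0.2077331886815462475, tolerance = 1e-10)
  expect_equal(three_layer_ghat(10, 1e-3, head, acq30),
               3.8684695549815158545e-8, tolerance = 1e-10)
  expect_equal(three_layer_ghat(0.1, 0, head, acq30),
               2.2511915222930591694, tolerance = 1e-10)
})

test_that("static limit of the layered kernel drops only the flow terms", {
  head <- baseline_head()
  static <- baseline_head(Db_scalp = 0, Db_skull = 0, Db_brain = 0)
  expect_equal(three_layer_ghat(0.7, 0, head, acq30),
               three_layer_ghat(0.7, 123e-6, static, acq30),
               tolerance = 1e-13)
  expect_error(three_layer_ghat(1, 1e-4,
                                structure(list(layers = list(brain_layer)),
                                          class = "head_model"), acq30),
               "3 layers")
})

test_that("layered solver reduces to the semi-infinite model for identical layers", {
  draws <- draw_layers(20, seed = 5)
  worst <- 0
  for (i in seq_len(nrow(draws))) {
    l <- tissue_layer(draws$mua[i], draws$musp[i], draws$Db[i])
    acq <- acquisition(rho = draws$rho[i])
    g3 <- three_layer_g1(homogeneous_head(l), acq, std_grid)
    gs <- semi_infinite_g1(l, acq, std_grid)
    worst <- max(worst, max(abs(g3$values - gs$values)))
  }
  expect_lt(worst, 1e-3)
})

test_that("larger separations decay faster in the layered model", {
  head <- baseline_head()
  g30 <- three_layer_g1(head, acquisition(rho = 30), std_grid)
  g5 <- three_layer_g1(head, acquisition(rho = 5), std_grid)
  mid <- 30:90
  expect_true(all(g30$values[mid] < g5$values[mid]))
})

test_that("quadrature doubling changes the converged curve below 1e-6", {
  head <- baseline_head()
  g <- three_layer_g1(head, acq30, std_grid)
  rule2 <- dcsflow:::.quad_rule(2L * g$provenance$quad_nodes, acq30$rho)
  g2 <- three_layer_g1(head, acq30, std_grid, quad = rule2)
  expect_lt(max(abs(g$values - g2$values)), 1e-6)
})

test_that("the speed-of-light convention cancels out of g1", {
  # Dp = c/(3 musp') rescales numerator and denominator jointly; changing
  # the layer refractive index (which only enters through c in the layered
  # kernel) must leave the normalized curve unchanged
  h1 <- baseline_head()
  h2 <- baseline_head()
  for (i in 1:3) h2$layers[[i]]$n_ref <- 1.0
  g1 <- three_layer_g1(h1, acq30, std_grid)
  g2 <- three_layer_g1(h2, acq30, std_grid)
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
})

test_that("flow monotonicity: raising any layer's Db never raises g1", {
  base <- baseline_head()
  g0 <- three_layer_g1(base, acq30, std_grid)$values
  for (up in list(baseline_head(Db_scalp = 3e-6),
                  baseline_head(Db_skull = 1e-6),
                  baseline_head(Db_brain = 9e-6))) {
    g1v <- three_layer_g1(up, acq30, std_grid)$values
    expect_true(all(g1v <= g0 + 1e-12))
  }
})

test_that("curves round-trip through the columnar text format", {
  g2 <- siegert_g2(semi_infinite_g1(brain_layer, acq30, std_grid), 0.5)
  path <- file.path(tempdir(), "curve.csv")
  write_curve(g2, path)
  back <- read_curve(path)
  expect_equal(back$values, g2$values, tolerance = 1e-12)
  expect_equal(as.numeric(back$grid), as.numeric(g2$grid), tolerance = 1e-12)
  expect_identical(back$kind, "intensity")
  expect_equal(back$provenance$beta, 0.5)
})
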