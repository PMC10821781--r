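# Training-corpus generation: sampling, normalization, encoding, storage.

test_that("parameter draws respect bounds and are uniform", {
  p <- sample_params(1e5, seed = 42)
  expect_true(all(p$mua > 0.01 & p$mua <= 1))
  expect_true(all(p$musp > 0.5 & p$musp <= 1.6))
  expect_true(all(p$beta > 0 & p$beta <= 1))
  expect_true(all(p$bfi >= 1e-8 & p$bfi <= 1e-5))
  expect_true(all(p$rho >= 5 & p$rho <= 30))
  # Kolmogorov-Smirnov against the stated uniforms, alpha = 0.01
  # (suppressWarnings: the 32-bit RNG resolution produces ~1 tie per 1e5
  # draws, which ks.test flags but which does not affect the decision)
  ks <- function(x, lo, hi)
    suppressWarnings(ks.test(x, "punif", lo, hi)$p.value)
  expect_gt(ks(p$mua, 0.01, 1), 0.01)
  expect_gt(ks(p$musp, 0.5, 1.6), 0.01)
  expect_gt(ks(p$beta, 0, 1), 0.01)
  expect_gt(ks(p$bfi, 1e-8, 1e-5), 0.01)
  expect_gt(ks(p$rho, 5, 30), 0.01)
  expect_identical(p, sample_params(1e5, seed = 42))
  plog <- sample_params(1e4, seed = 1, log_bfi = TRUE)
  expect_gt(ks(log10(plog$bfi), -8, -5), 0.01)
})

test_that("label encoding is exactly invertible over the whole range", {
  expect_equal(encode_labels(0.5, 1e-8)[1, "u_bfi"], 0, ignore_attr = TRUE)
  expect_equal(encode_labels(0.5, 1e-5)[1, "u_bfi"], 1, ignore_attr = TRUE)
  expect_equal(encode_labels(0.5, 1e-6)[1, "u_beta"], 0.5,
               ignore_attr = TRUE)
  p <- sample_params(1000, seed = 3)
  u <- encode_labels(p$beta, p$bfi)
  d <- decode_labels(u[, 1], u[, 2])
  expect_equal(d$beta, p$beta, tolerance = 1e-12)
  expect_equal(d$bfi, p$bfi, tolerance = 1e-12)
  expect_error(encode_labels(0.5, 2e-5), "BFi")
  expect_error(encode_labels(1.2, 1e-6), "beta")
})

test_that("input normalization maps onto (0, 1] with max exactly 1", {
  x <- matrix(runif(50 * 127, 0.5, 2), 50)
  nx <- normalize_input(x)
  expect_equal(apply(nx, 1, max), rep(1, 50))
  expect_true(all(nx > 0 & nx <= 1))
})

test_that("a noiseless synthesized sample is the normalized forward curve", {
  p <- sample_params(1, seed = 8)
  s <- synthesize_sample(p, "noiseless")
  acq <- acquisition(rho = p$rho, beta = p$beta)
  g2 <- siegert_g2(semi_infinite_g1(tissue_layer(p$mua, p$musp, p$bfi),
                                    acq, std_grid), p$beta)
  expect_equal(s$input, g2$values / max(g2$values), tolerance = 1e-12)
  expect_equal(which.max(s$input), 1L)  # monotone decay: max at first lag
  d <- decode_labels(s$labels[1], s$labels[2])
  expect_equal(d$beta, p$beta, tolerance = 1e-12)
  expect_equal(d$bfi, p$bfi, tolerance = 1e-12)
})

test_that("noisy samples deviate consistently with the sigma model", {
  p <- sample_params(1, seed = 15)
  acq <- acquisition(rho = p$rho, beta = p$beta)
  g2 <- siegert_g2(semi_infinite_g1(tissue_layer(p$mua, p$musp, p$bfi),
                                    acq, std_grid), p$beta)
  est <- estimate_decay_rate(g2)
  sig <- noise_sigma(noise_spec(30), est$beta, est$gamma, std_grid)
  pred_rms <- sqrt(mean(sig^2))
  devs <- vapply(1:50, function(s) {
    noisy <- add_noise(g2, noise_spec(30), seed = s)
    sqrt(mean((noisy$values - g2$values)^2))
  }, numeric(1))
  expect_equal(mean(devs), pred_rms, tolerance = 0.15)
})

test_that("corpus splits are disjoint, sized and reproducible", {
  ds <- build_dataset(10, split_fraction = 0.8, seed = 5)
  expect_equal(nrow(ds$train$x), 8)
  expect_equal(nrow(ds$val$x), 2)
  ds2 <- build_dataset(200, seed = 6)
  expect_equal(nrow(ds2$train$x), 160)
  expect_equal(nrow(ds2$val$x), 40)
  expect_equal(apply(rbind(ds2$train$x, ds2$val$x), 1, max), rep(1, 200))
  # disjointness via provenance rows
  key <- function(p) paste(p$mua, p$musp, p$bfi)
  expect_length(intersect(key(ds2$train$prov), key(ds2$val$prov)), 0)
  # byte-identical rebuild
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  build_dataset(60, seed = 9, dir = d1)
  build_dataset(60, seed = 9, dir = d2)
  for (f in c("train_inputs.csv", "train_labels.csv", "val_inputs.csv",
              "val_labels.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the four noise conditions all appear in the default mixture
  expect_setequal(unique(c(ds2$train$prov$noise, ds2$val$prov$noise)),
                  c("noiseless", "Tint1", "Tint10", "Tint30"))
})
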