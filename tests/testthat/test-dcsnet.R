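# The curve regressor: architecture anchors, gradients, training loop
# mechanics, inference contracts. Accuracy at scale is covered by the
# acceptance suite.

test_that("the reference configuration hits both architecture anchors", {
  spec <- dcsnet_spec()
  m <- build_model(spec, seed = 1)
  expect_equal(m$n_params, 25506)
  expect_equal(count_layers(spec), 18)
})

test_that("parameter counts follow the layer arithmetic for any widths", {
  # independent hand count: k Cin Cout + Cout per conv, 2C per BN
  hand_count <- function(k, f1, f2, h1, h2) {
    conv <- function(cin, cout, kk = k) kk * cin * cout + cout
    shared <- conv(1, f1) + 2 * f1 + conv(f1, f2) + 2 * f2
    head <- conv(f2, h1) + 2 * h1 + conv(h1, h2) + 2 * h2 + conv(h2, 1, 1)
    shared + 2 * head
  }
  expect_equal(hand_count(13, 16, 32, 16, 12), 25506)
  doubled <- dcsnet_spec(shared_filters = c(32, 64),
                         head_filters = c(32, 24))
  expect_equal(build_model(doubled, seed = 1)$n_params,
               hand_count(13, 32, 64, 32, 24))
})

test_that("forward pass maps a batch to bounded scalar pairs", {
  m <- build_model(seed = 2)
  X <- matrix(runif(128 * 127, 0.1, 1), 128)
  out <- dcsflow:::.net_forward(m, X, train = FALSE)
  expect_equal(dim(out), c(128L, 2L))
  expect_true(all(out > 0 & out < 1))
  # duplicate curves give identical predictions
  p <- predict_flow(m, rbind(X[1, ], X[1, ]))
  expect_identical(p[1, ], p[2, ], ignore_attr = TRUE)
  expect_error(predict_flow(m, X[, 1:100]), "lags")
})

test_that("analytic gradients agree with numerical differentiation", {
  m <- build_model(dcsnet_spec(shared_filters = c(4, 6),
                               head_filters = c(4, 3)), seed = 3)
  set.seed(4)
  X <- matrix(runif(6 * 127, 0.2, 1), 6)
  Y <- cbind(runif(6), runif(6))
  fw <- dcsflow:::.net_forward(m, X, train = TRUE, keep_cache = TRUE)
  dout <- 2 * (fw$out - Y) / 6
  gb <- dcsflow:::.block_bw(m$layers$head_beta, fw$hb$cache,
                            array(dout[, 1], c(6, 1, 1)))
  gf <- dcsflow:::.block_bw(m$layers$head_bfi, fw$hf$cache,
                            array(dout[, 2], c(6, 1, 1)))
  gs <- dcsflow:::.block_bw(m$layers$shared, fw$sh$cache, gb$dX + gf$dX)
  pmap <- dcsflow:::.build_pmap(m$layers)
  gvec <- dcsflow:::.flatten(m$layers, list(shared = gs$grads,
                                            head_beta = gb$grads,
                                            head_bfi = gf$grads), pmap)
  theta <- dcsflow:::.flatten(m$layers, pmap = pmap)
  lossf <- function(th) {
    m2 <- m
    m2$layers <- dcsflow:::.unflatten(m$layers, th, pmap)
    out <- dcsflow:::.net_forward(m2, X, train = TRUE)
    mean(rowSums((out - Y)^2))
  }
  idx <- sort(sample(length(theta), 40))
  num <- vapply(idx, function(i) {
    e <- 1e-6
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    (lossf(tp) - lossf(tm)) / (2 * e)
  }, numeric(1))
  expect_equal(num, gvec[idx], tolerance = 1e-5)
})

test_that("the fused training step matches the layer-by-layer path", {
  m <- build_model(seed = 5)
  set.seed(6)
  X <- matrix(runif(32 * 127, 0.2, 1), 32)
  Y <- cbind(runif(32), runif(32))
  pmap <- dcsflow:::.build_pmap(m$layers)
  theta <- dcsflow:::.flatten(m$layers, pmap = pmap)
  run <- dcsflow:::.gather_running(m$layers)
  fw <- dcsflow:::.net_forward(m, X, train = TRUE, keep_cache = TRUE)
  loss_ref <- mean(rowSums((fw$out - Y)^2))
  loss_fused <- dcsflow:::.nn_train_batch(X, Y, theta,
                                          numeric(length(theta)),
                                          numeric(length(theta)), run,
                                          dcsflow:::.ispec(m$spec),
                                          1e-5, 0.1, 1L)
  expect_equal(loss_fused, loss_ref, tolerance = 1e-12)
  theta2 <- dcsflow:::.flatten(m$layers, pmap = pmap)
  o1 <- dcsflow:::.net_forward(m, X, train = FALSE)
  o2 <- dcsflow:::.nn_forward_fused(X, theta2,
                                    dcsflow:::.gather_running(m$layers),
                                    dcsflow:::.ispec(m$spec))
  expect_equal(o1, o2, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("training descends, stops on patience, and is reproducible", {
  ds <- tiny_corpus(640, seed = 31)
  cfg <- train_config(lr = 1e-3, epochs = 8, patience = 7, seed = 1)
  m1 <- train_model(build_model(seed = 7), ds$train, ds$val, cfg)
  expect_lt(m1$history$train_loss[5], m1$history$train_loss[1])
  m2 <- train_model(build_model(seed = 7), ds$train, ds$val, cfg)
  expect_identical(m1$history, m2$history)
  # an effectively frozen optimizer plateaus and stops after the patience
  cfg0 <- train_config(lr = 1e-30, epochs = 50, patience = 3, seed = 1)
  m0 <- train_model(build_model(seed = 7), ds$train, ds$val, cfg0)
  expect_lte(nrow(m0$history), 1 + 3)
})

test_that("a small identifiable noiseless corpus trains to low validation error", {
  # wiring-correctness oracle. With the optics and separation fixed, the
  # normalized curve -> (beta, BFi) map is invertible, so the only floor is
  # optimization: an aggressive learning rate must drive a 1,000-sample
  # noiseless corpus below 1e-3 validation MSE. (Over the full parameter
  # ranges the inverse problem is aliased -- several (mua, musp, rho, BFi)
  # combinations share one normalized curve -- and no regressor can beat
  # that posterior width, so the full-range corpus is not used here.)
  n <- 1000
  p <- withr_seed(32, data.frame(beta = runif(n, 0.2, 1),
                                 bfi = 10^runif(n, -8, -5)))
  g2 <- t(vapply(seq_len(n), function(i) {
    acq <- acquisition(rho = 20, beta = p$beta[i])
    siegert_g2(semi_infinite_g1(tissue_layer(0.019, 1.1, p$bfi[i]),
                                acq, std_grid), p$beta[i])$values
  }, numeric(127)))
  x <- normalize_input(g2)
  y <- encode_labels(p$beta, p$bfi)
  tr <- list(x = x[1:800, ], y = y[1:800, ])
  va <- list(x = x[801:1000, ], y = y[801:1000, ])
  cfg <- train_config(lr = 3e-3, epochs = 400, patience = 100, seed = 2)
  m <- train_model(build_model(seed = 8), tr, va, cfg)
  expect_lt(min(m$history$val_loss), 1e-3)
})

test_that("checkpoints round-trip through the JSON format", {
  ds <- tiny_corpus(256, seed = 33)
  m <- train_model(build_model(seed = 9), ds$train, ds$val,
                   train_config(lr = 1e-3, epochs = 2, patience = 1, seed = 3))
  path <- file.path(tempdir(), "model.json")
  save_dcsnet(m, path)
  m2 <- load_dcsnet(path)
  X <- ds$val$x
  expect_equal(predict_flow(m, X), predict_flow(m2, X), tolerance = 1e-12)
  expect_equal(m2$n_params, 25506)
})

test_that("decoded predictions stay inside the physical label ranges", {
  m <- build_model(seed = 10)
  X <- matrix(runif(64 * 127, 0.05, 1), 64)
  p <- predict_flow(m, X)
  expect_true(all(p$beta > 0 & p$beta < 1))
  expect_true(all(p$bfi >= 1e-8 & p$bfi <= 1e-5))
})
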