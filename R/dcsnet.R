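# Compact 1D-CNN regressor mapping a normalized g2 curve to the coherence
# factor and blood flow index.
#
# The network has a shared convolutional trunk (2 conv layers, kernel 13,
# stride 5, "same" padding, each followed by batch normalization with a
# fused ReLU) and two independent heads of the same structure, each closed
# by a pointwise (kernel-1) convolution with a sigmoid that emits one scalar
# in (0, 1). Layer counting convention: framework modules = 1 input +
# (conv + BN) x 2 shared + [(conv + BN) x 2 + pointwise conv + sigmoid
# activation] x 2 heads + 1 output concatenation = 18 for the reference
# configuration; ReLUs are fused into the BN modules and not counted
# separately, the closing sigmoid is its own activation module.

#' Architecture specification of the curve regressor
#'
#' The reference configuration (16/32 shared filters, 16/12 head filters)
#' has 18 layers under the convention documented in the package and exactly
#' 25,506 trainable parameters.
#'
#' @param shared_filters filter counts of the two shared conv layers
#' @param head_filters filter counts of the two conv layers in each head
#' @param kernel convolution kernel size
#' @param stride convolution stride
#' @param n_input input curve length
#' @return an object of class `dcsnet_spec`
#' @export
dcsnet_spec <- function(shared_filters = c(16, 32), head_filters = c(16, 12),
                        kernel = 13, stride = 5, n_input = 127) {
  stopifnot(length(shared_filters) == 2, length(head_filters) == 2,
            all(c(shared_filters, head_filters) >= 1), kernel >= 1,
            stride >= 1, n_input >= kernel)
  structure(list(shared_filters = as.integer(shared_filters),
                 head_filters = as.integer(head_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 n_input = as.integer(n_input)),
            class = "dcsnet_spec")
}

# conv parameter count: k*Cin*Cout + Cout; BN: 2*C
.count_params_spec <- function(spec) {
  k <- spec$kernel
  f1 <- spec$shared_filters[1]; f2 <- spec$shared_filters[2]
  h1 <- spec$head_filters[1]; h2 <- spec$head_filters[2]
  shared <- (k * 1 * f1 + f1) + 2 * f1 + (k * f1 * f2 + f2) + 2 * f2
  head <- (k * f2 * h1 + h1) + 2 * h1 + (k * h1 * h2 + h2) + 2 * h2 +
    (1 * h2 * 1 + 1)
  shared + 2 * head
}

#' Number of framework layers of a specification
#'
#' Counts input, convolution, batch-normalization, sigmoid-activation and
#' output-concatenation modules (ReLUs fused into BN); the reference
#' configuration counts 18.
#'
#' @param spec a [dcsnet_spec()]
#' @return integer layer count
#' @export
count_layers <- function(spec) {
  stopifnot(inherits(spec, "dcsnet_spec"))
  1L + 4L + 2L * 6L + 1L
}

.he_init <- function(k, cin, cout) {
  matrix(rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))), k * cin, cout)
}

.new_conv <- function(k, cin, cout, stride, act) {
  list(type = "conv", W = .he_init(k, cin, cout), b = numeric(cout),
       k = k, cin = cin, cout = cout, stride = stride, act = act)
}

.new_bn <- function(C, act) {
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       rmean = numeric(C), rvar = rep(1, C), C = C, act = act,
       eps = 1e-5, momentum = 0.1)
}

#' Build the curve-regression network
#'
#' Constructs the network and reports its trainable parameter count; the
#' reference configuration must count 25,506. Weight initialization is
#' He-normal, seeded.
#'
#' @param spec a [dcsnet_spec()]
#' @param seed integer seed for weight initialization
#' @return an object of class `dcsnet` with elements `spec`, `layers`
#'   (named list), `n_params`
#' @export
build_model <- function(spec = dcsnet_spec(), seed = 1) {
  stopifnot(inherits(spec, "dcsnet_spec"))
  k <- spec$kernel; s <- spec$stride
  f <- spec$shared_filters; h <- spec$head_filters
  layers <- withr_seed(seed, {
    mk_head <- function() list(
      conv1 = .new_conv(k, f[2], h[1], s, act = 0L),
      bn1 = .new_bn(h[1], act = 1L),
      conv2 = .new_conv(k, h[1], h[2], s, act = 0L),
      bn2 = .new_bn(h[2], act = 1L),
      point = .new_conv(1L, h[2], 1L, 1L, act = 2L))
    list(shared = list(conv1 = .new_conv(k, 1L, f[1], s, act = 0L),
                       bn1 = .new_bn(f[1], act = 1L),
                       conv2 = .new_conv(k, f[1], f[2], s, act = 0L),
                       bn2 = .new_bn(f[2], act = 1L)),
         head_beta = mk_head(),
         head_bfi = mk_head())
  })
  model <- structure(list(spec = spec, layers = layers,
                          n_params = .count_params_spec(spec)),
                     class = "dcsnet")
  # the head's two strided convolutions must reduce the trunk output to one
  # position so the pointwise layer emits a 1x1 scalar
  L <- spec$n_input
  for (i in 1:4) L <- ceiling(L / s)
  if (L != 1L)
    stop(sprintf(paste0("build_model: input length %d does not reduce to a ",
                        "1x1 output (got %d positions after layer 'head conv2'); ",
                        "adjust kernel/stride/n_input"), spec$n_input, L))
  model
}

#' @export
print.dcsnet <- function(x, ...) {
  cat(sprintf("<dcsnet> %d layers, %d trainable parameters (input 1x%d)\n",
              count_layers(x$spec), x$n_params, x$spec$n_input))
  invisible(x)
}

# forward through one named block; returns list(Y, cache)
.block_fw <- function(block, X, train) {
  cache <- vector("list", length(block))
  names(cache) <- names(block)
  for (nm in names(block)) {
    l <- block[[nm]]
    d <- dim(X)
    if (l$type == "conv") {
      r <- .nn_conv_fw(X, d[1], d[2], d[3], l$W, l$b, l$k, l$stride, l$act)
      cache[[nm]] <- list(X_dim = d, cols = r$cols, Y = r$Y, Lo = r$Lo,
                          pl = r$pl)
      X <- r$Y
    } else {
      r <- .nn_bn_fw(X, d[1], d[2], d[3], l$gamma, l$beta,
                     l$rmean, l$rvar, l$eps, train, l$act)
      cache[[nm]] <- list(X_dim = d, Y = r$Y, xhat = r$xhat, istd = r$istd,
                          mu = r$mu, var = r$var)
      X <- r$Y
    }
  }
  list(Y = X, cache = cache)
}

# backward through one named block; returns list(dX, grads)
.block_bw <- function(block, cache, dY) {
  grads <- list()
  for (nm in rev(names(block))) {
    l <- block[[nm]]
    cc <- cache[[nm]]
    d <- cc$X_dim
    if (l$type == "conv") {
      r <- .nn_conv_bw(dY, cc$Y, cc$cols, d[1], d[2], d[3], l$W, l$k,
                       l$stride, l$act, cc$Lo, cc$pl)
      grads[[nm]] <- list(W = r$dW, b = r$db)
      dY <- r$dX
    } else {
      r <- .nn_bn_bw(dY, cc$Y, cc$xhat, cc$istd, l$gamma, d[1], d[2], d[3],
                     l$act)
      grads[[nm]] <- list(gamma = r$dg, beta = r$dbe)
      dY <- r$dX
    }
  }
  list(dX = dY, grads = grads)
}

# full forward; X is an n x n_input matrix; returns n x 2 (u_beta, u_bfi)
.net_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  sh <- .block_fw(model$layers$shared, A, train)
  hb <- .block_fw(model$layers$head_beta, sh$Y, train)
  hf <- .block_fw(model$layers$head_bfi, sh$Y, train)
  out <- cbind(as.numeric(hb$Y), as.numeric(hf$Y))
  if (keep_cache) list(out = out, sh = sh, hb = hb, hf = hf) else out
}

# update running BN statistics from a training-mode cache
.update_running <- function(model, caches) {
  for (bk in c("shared", "head_beta", "head_bfi")) {
    key <- c(shared = "sh", head_beta = "hb", head_bfi = "hf")[[bk]]
    for (nm in names(model$layers[[bk]])) {
      l <- model$layers[[bk]][[nm]]
      if (l$type != "bn") next
      cc <- caches[[key]]$cache[[nm]]
      mom <- l$momentum
      model$layers[[bk]][[nm]]$rmean <- (1 - mom) * l$rmean + mom * cc$mu
      model$layers[[bk]][[nm]]$rvar <- (1 - mom) * l$rvar + mom * cc$var
    }
  }
  model
}

# flatten/unflatten trainable parameters for the Adam update; a fixed
# traversal map avoids repeated concatenation in the training loop
.param_names <- function(l) if (l$type == "conv") c("W", "b") else c("gamma", "beta")
.build_pmap <- function(layers) {
  map <- list(); i <- 0L
  for (bk in names(layers)) for (nm in names(layers[[bk]])) {
    l <- layers[[bk]][[nm]]
    for (p in .param_names(l)) {
      n <- length(l[[p]])
      map[[length(map) + 1L]] <- list(bk = bk, nm = nm, p = p,
                                      idx = (i + 1L):(i + n),
                                      dim = dim(l[[p]]))
      i <- i + n
    }
  }
  attr(map, "n_total") <- i
  map
}
.flatten <- function(layers, grads = NULL, pmap = .build_pmap(layers)) {
  out <- numeric(attr(pmap, "n_total"))
  for (e in pmap) {
    src <- if (is.null(grads)) layers[[e$bk]][[e$nm]] else grads[[e$bk]][[e$nm]]
    out[e$idx] <- as.numeric(src[[e$p]])
  }
  out
}
.unflatten <- function(layers, vec, pmap = .build_pmap(layers)) {
  for (e in pmap) {
    val <- vec[e$idx]
    if (!is.null(e$dim)) dim(val) <- e$dim
    layers[[e$bk]][[e$nm]][[e$p]] <- val
  }
  layers
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 1e-5,
#' batch size 128, at most 800 epochs, early stopping after 20 epochs
#' without validation improvement, mean-squared-error loss on the encoded
#' label pair.
#'
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param epochs maximum epochs
#' @param patience early-stopping patience, epochs
#' @param seed integer seed for shuffling
#' @return an object of class `train_config`
#' @export
train_config <- function(lr = 1e-5, batch_size = 128, epochs = 800,
                         patience = 20, seed = 1) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, patience >= 1,
            patience < epochs)
  structure(list(lr = lr, batch_size = batch_size, epochs = epochs,
                 patience = patience, seed = seed), class = "train_config")
}

# mean over samples of the squared 2-norm of the output error
.mse_loss <- function(out, y) mean(rowSums((out - y)^2))

# architecture integers handed to the fused C++ step
.ispec <- function(spec) as.integer(c(spec$kernel, spec$stride,
                                      spec$shared_filters, spec$head_filters,
                                      spec$n_input))

# BN running statistics as one flat vector, in the fused kernel's order
.bn_order <- list(c("shared", "bn1"), c("shared", "bn2"),
                  c("head_beta", "bn1"), c("head_beta", "bn2"),
                  c("head_bfi", "bn1"), c("head_bfi", "bn2"))
.gather_running <- function(layers) {
  unlist(lapply(.bn_order, function(e) {
    l <- layers[[e[1]]][[e[2]]]
    c(l$rmean, l$rvar)
  }), use.names = FALSE)
}
.scatter_running <- function(layers, running) {
  i <- 0L
  for (e in .bn_order) {
    l <- layers[[e[1]]][[e[2]]]
    C <- l$C
    layers[[e[1]]][[e[2]]]$rmean <- running[(i + 1L):(i + C)]
    layers[[e[1]]][[e[2]]]$rvar <- running[(i + C + 1L):(i + 2L * C)]
    i <- i + 2L * C
  }
  layers
}

# validation loss in inference mode, batched (fused forward)
.val_loss <- function(theta, running, ispec, val, chunk = 4096L) {
  n <- nrow(val$x)
  tot <- 0
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out <- .nn_forward_fused(val$x[i0:i1, , drop = FALSE], theta, running,
                             ispec)
    tot <- tot + sum(rowSums((out - val$y[i0:i1, , drop = FALSE])^2))
  }
  tot / n
}

#' Train the curve regressor
#'
#' Minibatch Adam on the mean-squared error of the encoded (beta, BFi)
#' labels, with per-epoch validation loss, early stopping, and retention of
#' the best-validation weights. Training is deterministic given the seeds
#' (all computation is single-threaded R/C).
#'
#' @param model a [build_model()] network
#' @param train,val lists with `x` (n x 127) and `y` (n x 2), e.g. from
#'   [build_dataset()]
#' @param config a [train_config()]
#' @param verbose print per-epoch losses
#' @return the trained model, with `history` (data.frame of epoch losses),
#'   `best_epoch`, and `config` attached
#' @export
train_model <- function(model, train, val, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "dcsnet"), inherits(config, "train_config"))
  n <- nrow(train$x)
  bs <- config$batch_size
  pmap <- .build_pmap(model$layers)
  ispec <- .ispec(model$spec)
  theta <- .flatten(model$layers, pmap = pmap)
  running <- .gather_running(model$layers)
  m_ad <- numeric(length(theta)); v_ad <- numeric(length(theta))
  t_ad <- 0L
  best <- list(loss = Inf, theta = theta + 0, running = running + 0,
               epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  wait <- 0L
  withr_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, n - bs + 1L, by = bs)) {
        idx <- perm[b0:(b0 + bs - 1L)]
        t_ad <- t_ad + 1L
        loss <- .nn_train_batch(train$x[idx, , drop = FALSE],
                                train$y[idx, , drop = FALSE],
                                theta, m_ad, v_ad, running, ispec,
                                config$lr, 0.1, t_ad)
        if (!is.finite(loss))
          stop(sprintf("train_model: non-finite loss at epoch %d", ep))
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      vl <- .val_loss(theta, running, ispec, val)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %d: train %.6f val %.6f", ep, ep_loss / nb, vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, theta = theta + 0, running = running + 0,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$layers <- .scatter_running(.unflatten(model$layers, best$theta, pmap),
                                   best$running)
  model$history <- hist
  model$best_epoch <- best$epoch
  model$config <- config
  model
}

#' Predict coherence factor and blood flow index from g2 curves
#'
#' Applies the input normalization, runs the network in inference mode and
#' decodes the outputs to physical units.
#'
#' @param model a trained [build_model()] network
#' @param curves an intensity-type [correlation_curve()], a list of them,
#'   or a numeric matrix of g2 rows on the standard grid
#' @return data.frame with columns `beta` and `bfi` (mm^2/s), one row per
#'   curve
#' @export
predict_flow <- function(model, curves) {
  stopifnot(inherits(model, "dcsnet"))
  X <- if (is.matrix(curves)) curves
  else if (inherits(curves, "dcs_curve")) matrix(curves$values, 1L)
  else do.call(rbind, lapply(curves, function(cv) {
    stopifnot(inherits(cv, "dcs_curve"))
    cv$values
  }))
  if (ncol(X) != model$spec$n_input)
    stop(sprintf("predict_flow: curves have %d lags, model expects %d",
                 ncol(X), model$spec$n_input))
  out <- .net_forward(model, normalize_input(X), train = FALSE)
  decode_labels(out[, 1], out[, 2])
}

#' Save / load a trained network
#'
#' The checkpoint is a single JSON document holding the architecture
#' specification and all weights and running statistics, so inference does
#' not require the training environment.
#'
#' @param model a `dcsnet`
#' @param path file path (JSON)
#' @return `load_dcsnet` returns the reconstructed model
#' @export
save_dcsnet <- function(model, path) {
  stopifnot(inherits(model, "dcsnet"))
  ser <- list(spec = unclass(model$spec), n_params = model$n_params,
              layers = lapply(model$layers, function(bk)
                lapply(bk, function(l) {
                  l$W_dim <- if (!is.null(l$W)) dim(l$W) else NULL
                  l
                })))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dcsnet
#' @export
load_dcsnet <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(dcsnet_spec, ser$spec[c("shared_filters", "head_filters",
                                          "kernel", "stride", "n_input")])
  layers <- lapply(ser$layers, function(bk)
    lapply(bk, function(l) {
      if (!is.null(l$W_dim)) {
        l$W <- matrix(l$W, l$W_dim[1], l$W_dim[2])
        l$W_dim <- NULL
      }
      l
    }))
  structure(list(spec = spec, layers = layers, n_params = ser$n_params),
            class = "dcsnet")
}
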