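# Training-corpus generation: parameter sampling, curve synthesis,
# normalization, label encoding, and storage.

.BFI_LO <- 1e-8
.BFI_HI <- 1e-5

#' Draw physical parameter samples for the training corpus
#'
#' Independent uniform draws of the semi-infinite model parameters:
#' mua in (0.01, 1] mm^-1, musp in (0.5, 1.6] mm^-1, beta in (0, 1],
#' BFi in [1e-8, 1e-5] mm^2/s (uniform on the linear scale by default,
#' log-uniform via `log_bfi`), rho in [5, 30] mm.
#'
#' @param n number of samples
#' @param seed integer seed
#' @param log_bfi draw BFi log-uniformly instead of linearly
#' @return data.frame with columns mua, musp, beta, bfi, rho
#' @export
sample_params <- function(n, seed, log_bfi = FALSE) {
  withr_seed(seed, {
    data.frame(
      mua = runif(n, 0.01, 1),
      musp = runif(n, 0.5, 1.6),
      beta = runif(n, 0, 1),
      bfi = if (log_bfi) 10^runif(n, log10(.BFI_LO), log10(.BFI_HI))
            else runif(n, .BFI_LO, .BFI_HI),
      rho = runif(n, 5, 30))
  })
}

#' Normalize a g2 curve into (0, 1]
#'
#' Divides the vector (or each row of a matrix) by its maximum. For
#' noiseless curves the maximum sits at the first lag; for noisy curves it
#' may not, and the global maximum is still used.
#'
#' @param g2 numeric vector or matrix (rows = curves)
#' @return same shape, maximum exactly 1
#' @export
normalize_input <- function(g2) {
  if (is.matrix(g2)) {
    mx <- apply(g2, 1L, max)
    if (any(mx <= 0)) stop("normalize_input: curve maximum must be positive")
    g2 / mx
  } else {
    mx <- max(g2)
    if (mx <= 0) stop("normalize_input: curve maximum must be positive")
    g2 / mx
  }
}

#' Encode / decode network labels
#'
#' beta is already in (0, 1] and maps identically; BFi spans three decades
#' and is encoded logarithmically, u = (log10(BFi) + 8) / 3, so that
#' [1e-8, 1e-5] maps onto [0, 1]. `decode_labels` inverts exactly.
#'
#' @param beta coherence factor(s) in (0, 1]
#' @param bfi blood flow index(es) in [1e-8, 1e-5] mm^2/s
#' @return `encode_labels`: matrix with columns `u_beta`, `u_bfi`;
#'   `decode_labels`: data.frame with columns `beta`, `bfi`
#' @export
encode_labels <- function(beta, bfi) {
  if (any(bfi < .BFI_LO | bfi > .BFI_HI))
    stop("encode_labels: BFi outside [1e-8, 1e-5] mm^2/s")
  if (any(beta <= 0 | beta > 1)) stop("encode_labels: beta outside (0, 1]")
  cbind(u_beta = beta, u_bfi = (log10(bfi) + 8) / 3)
}

#' @rdname encode_labels
#' @param u_beta,u_bfi encoded labels in [0, 1]
#' @export
decode_labels <- function(u_beta, u_bfi) {
  data.frame(beta = u_beta, bfi = 10^(3 * u_bfi - 8))
}

# vectorized semi-infinite g2 for a parameter table: n x n_tau matrix
.semi_g2_batch <- function(p, tau, k0) {
  n <- nrow(p)
  K2_0 <- 3 * p$mua * p$musp
  slope <- 6 * p$musp^2 * k0^2 * p$bfi
  z0 <- 1 / (p$mua + p$musp)
  zb <- 5 / (3 * p$musp)
  r1 <- sqrt(p$rho^2 + z0^2)
  r2 <- sqrt(p$rho^2 + (z0 + 2 * zb)^2)
  K <- sqrt(outer(slope, tau) + K2_0)       # n x n_tau
  G <- exp(-K * r1) / r1 - exp(-K * r2) / r2
  K0 <- sqrt(K2_0)
  G0 <- exp(-K0 * r1) / r1 - exp(-K0 * r2) / r2
  g1 <- G / G0
  1 + p$beta * g1^2
}

# vectorized Gauss-Newton fit of d ~ b exp(-gamma tau) across rows
.fit_exp_batch <- function(d, tau, iters = 30) {
  b <- apply(d, 1L, max)
  b[b <= 0] <- 1e-6
  # 1/e crossing for the initial rate
  g <- vapply(seq_len(nrow(d)), function(i) {
    idx <- which(d[i, ] / b[i] <= exp(-1))
    if (length(idx)) 1 / tau[idx[1]] else 0.1 / tau[length(tau)]
  }, numeric(1))
  lg <- log(g)
  for (it in seq_len(iters)) {
    e <- exp(-exp(lg) * tau[col(d)])
    dim(e) <- dim(d)
    r <- b * e - d
    # J columns: e, -b gamma tau e  (w.r.t. b and log gamma)
    j2 <- -b * exp(lg) * e * tau[col(d)]
    a11 <- rowSums(e * e); a12 <- rowSums(e * j2); a22 <- rowSums(j2 * j2)
    g1v <- rowSums(e * r); g2v <- rowSums(j2 * r)
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    db <- (-a22 * g1v + a12 * g2v) / det
    dl <- (a12 * g1v - a11 * g2v) / det
    dl <- pmin(pmax(dl, -2), 2)
    b <- b + db
    lg <- lg + dl
  }
  list(beta = b, gamma = exp(lg))
}

#' Synthesize one training sample
#'
#' Builds the semi-infinite g2 on the 127-lag grid for one parameter draw,
#' adds correlator noise if requested, normalizes the input and encodes the
#' labels.
#'
#' @param p one-row data.frame from [sample_params()]
#' @param noise_condition one of "noiseless", "Tint1", "Tint10", "Tint30"
#' @param seed integer seed for the noise draw
#' @param grid lag grid (default the 127-point standard grid)
#' @return list with `input` (length-127, max 1), `labels` (u_beta, u_bfi),
#'   and `provenance`
#' @export
synthesize_sample <- function(p, noise_condition = "noiseless", seed = 1,
                              grid = make_tau_grid()) {
  stopifnot(nrow(p) == 1L)
  acq <- acquisition(rho = p$rho, beta = p$beta)
  layer <- tissue_layer(p$mua, p$musp, p$bfi)
  g2 <- siegert_g2(semi_infinite_g1(layer, acq, grid), p$beta)
  spec <- noise_preset(noise_condition)
  if (!is.null(spec)) g2 <- add_noise(g2, spec, seed)
  list(input = as.numeric(normalize_input(g2$values)),
       labels = encode_labels(p$beta, p$bfi)[1, ],
       provenance = c(as.list(p), list(noise = noise_condition, seed = seed)))
}

#' Build a training/validation corpus of normalized g2 curves
#'
#' Draws `n_total` parameter samples, synthesizes semi-infinite g2 curves
#' on the 127-lag grid, applies the noise mixture (equal quarters
#' noiseless / Tint = 1, 10, 30 s by default), normalizes inputs, encodes
#' labels and splits into disjoint train/validation sets.
#'
#' @param n_total corpus size (>= 10)
#' @param split_fraction training fraction (default 0.8)
#' @param seed integer seed driving sampling, noise and the split
#' @param noise_mix character vector recycled over samples giving each
#'   sample's noise condition
#' @param log_bfi passed to [sample_params()]
#' @param dir optional directory; when given, writes `train_inputs.csv`,
#'   `train_labels.csv`, `val_inputs.csv`, `val_labels.csv`, provenance
#'   tables and a `meta.json` sidecar
#' @return list with elements `train` and `val`, each a list of `x`
#'   (n x 127 input matrix), `y` (n x 2 encoded labels), `prov`
#'   (provenance data.frame); and `meta`
#' @export
build_dataset <- function(n_total, split_fraction = 0.8, seed = 1,
                          noise_mix = c("noiseless", "Tint1", "Tint10", "Tint30"),
                          log_bfi = FALSE, dir = NULL) {
  stopifnot(n_total >= 10)
  grid <- make_tau_grid()
  tau <- as.numeric(grid)
  p <- sample_params(n_total, seed, log_bfi)
  acq0 <- acquisition(rho = 10)  # only k0 is used below
  g2 <- .semi_g2_batch(p, tau, acq0$k0)
  cond <- rep_len(noise_mix, n_total)
  noisy <- cond != "noiseless"
  if (any(noisy)) {
    fit <- .fit_exp_batch(g2[noisy, , drop = FALSE] - 1, tau)
    tints <- as.numeric(sub("Tint", "", cond[noisy]))
    eps <- withr_seed(seed + 1L, {
      sig <- vapply(seq_along(tints), function(i)
        noise_sigma(noise_spec(tints[i]), fit$beta[i], fit$gamma[i], grid),
        numeric(length(tau)))
      matrix(rnorm(length(sig)), nrow = length(tau)) * sig
    })
    g2[noisy, ] <- g2[noisy, , drop = FALSE] + t(eps)
  }
  x <- normalize_input(g2)
  y <- encode_labels(p$beta, p$bfi)
  prov <- cbind(p, noise = cond, stringsAsFactors = FALSE)
  n_train <- floor(split_fraction * n_total)
  idx <- withr_seed(seed + 2L, sample.int(n_total))
  tr <- idx[seq_len(n_train)]
  va <- idx[-seq_len(n_train)]
  meta <- list(n_total = n_total, split_fraction = split_fraction,
               seed = seed, noise_mix = noise_mix, log_bfi = log_bfi,
               ranges = list(mua = c(0.01, 1), musp = c(0.5, 1.6),
                             beta = c(0, 1), bfi = c(.BFI_LO, .BFI_HI),
                             rho = c(5, 30)))
  out <- list(train = list(x = x[tr, , drop = FALSE], y = y[tr, , drop = FALSE],
                           prov = prov[tr, , drop = FALSE]),
              val = list(x = x[va, , drop = FALSE], y = y[va, , drop = FALSE],
                         prov = prov[va, , drop = FALSE]),
              meta = meta)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in c("train", "val")) {
      write.csv(out[[s]]$x, file.path(dir, paste0(s, "_inputs.csv")),
                row.names = FALSE)
      write.csv(out[[s]]$y, file.path(dir, paste0(s, "_labels.csv")),
                row.names = FALSE)
      write.csv(out[[s]]$prov, file.path(dir, paste0(s, "_provenance.csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
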