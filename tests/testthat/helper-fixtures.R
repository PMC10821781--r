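# shared fixtures, built in code at test time

std_grid <- make_tau_grid()
acq30 <- acquisition(rho = 30)
brain_layer <- tissue_layer(0.019, 1.110, 6e-6)

# three identical layers (homogeneous limit of the layered solver)
homogeneous_head <- function(layer = brain_layer) {
  head_model(
    tissue_layer(layer$mua, layer$musp, layer$Db, 5),
    tissue_layer(layer$mua, layer$musp, layer$Db, 7),
    tissue_layer(layer$mua, layer$musp, layer$Db, 50))
}

# random physiological single-layer draws used by homogeneity/recovery tests
draw_layers <- function(n, seed) {
  withr_seed(seed, data.frame(
    mua = runif(n, 0.01, 0.03),
    musp = runif(n, 0.5, 1.6),
    Db = runif(n, 1e-7, 1e-5),
    rho = runif(n, 5, 30)))
}

# a tiny noiseless training corpus for network wiring tests
tiny_corpus <- function(n, seed, noise_mix = "noiseless") {
  build_dataset(n, seed = seed, noise_mix = noise_mix)
}
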