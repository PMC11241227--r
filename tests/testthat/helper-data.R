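# Small fixtures built in code.

tiny_spectra <- function(n = 5, p = 40, seed = 1, lo = 900, hi = 5000) {
  set.seed(seed)
  wn <- seq(lo, hi, length.out = p)
  milk_spectra(matrix(rnorm(n * p), n, p), wn)
}

# reduced-size generator config so pipeline-level tests stay fast
small_config <- function(n_samples = 250, n_points = 300, ...) {
  synthetic_config(n_samples = n_samples, n_points = n_points, ...)
}

# config with every noise source switched off (exact latent structure)
noiseless_config <- function(n_samples = 300, n_points = 1060) {
  cfg <- synthetic_config(n_samples = n_samples, n_points = n_points,
                          mult_sd = 0, noise_sd = 0, water_noise_sd = 0,
                          baseline_offset_sd = 0, baseline_slope_sd = 0,
                          baseline_curvature_sd = 0, censor_rate = 0)
  cfg$trait_model <- lapply(cfg$trait_model, function(tm) {
    tm$noise_sd <- 0
    tm
  })
  cfg$water_bands$jitter_sd <- 0
  cfg
}

# low-rank regression problem with known latent dimension r
latent_rank_problem <- function(n = 80, p = 60, r = 4, noise = 0.05,
                                seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * r), n, r)
  loadings <- matrix(rnorm(r * p), r, p)
  X <- scores %*% loadings + matrix(rnorm(n * p, 0, noise), n, p)
  beta <- rnorm(r)
  y <- drop(scores %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, r = r)
}
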