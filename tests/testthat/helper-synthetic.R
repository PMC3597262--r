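## shared single-response generators for threshold-detection tests

## strong regime switching: level shift plus sign-flipped slope on z,
## threshold at 0 on x
gen_strong_threshold <- function(n, seed, noise_sd = 0.4) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- ifelse(d$x <= 0, -0.3 - 0.7 * d$z, 0.3 + 0.7 * d$z) +
    rnorm(n, sd = noise_sd)
  d
}

## additive truth on the same covariates (no threshold)
gen_additive_truth <- function(n, seed, noise_sd = 0.4) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.7 * d$z + rnorm(n, sd = noise_sd)
  d
}

st_threshold <- function() {
  model_structure("y", threshold_spec("x"), low = "z", high = "z")
}

st_additive <- function() {
  model_structure("y", whole = "z")
}

## default-truth food-web dataset of n years
gen_default_foodweb <- function(n_years, seed) {
  drv <- gen_drivers(driver_params(n_years = n_years), seed = seed)
  gen_foodweb(true_params_default(), drv, seed = seed)
}
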