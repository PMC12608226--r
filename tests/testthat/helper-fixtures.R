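# Shared fixtures: all synthetic, built in code at test time.

# deterministic spectrum model (no noise of any kind)
noiseless_model <- function(...) {
  leaf_spectrum_model(mult_noise_sd = 0, add_noise_sd = 0,
                      plateau_sd = 0, gain_sd = 0, offset_sd = 0, ...)
}

# small sample set for optimizer tests: spectra on the full 1 nm grid
# (so every channel has support); search grids are coarsened separately
toy_sample_set <- function(n = 10, seed = 42, noise = "low",
                           preset = "cucumber-like") {
  simulate_samples(n, preset, noise = noise, seed = seed)
}

# independent dense-sum band reflectance oracle (no truncation window)
oracle_band <- function(wl, refl, center, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  w <- exp(-(wl - center)^2 / (2 * sig^2))
  w[abs(wl - center) > 4 * sig] <- 0
  sum(w * refl) / sum(w)
}

# independently coded one-line VI oracles (criterion: formula identities)
oracle_vi <- list(
  SR   = function(r1, r2, ra) r1 / r2,
  DI   = function(r1, r2, ra) r1 - r2,
  NDVI = function(r1, r2, ra) (r1 - r2) / (r1 + r2),
  mSR  = function(r1, r2, ra) (r1 - ra) / (r2 - ra),
  mNDI = function(r1, r2, ra) (r1 - r2) / (r1 + r2 - 2 * ra),
  TVI  = function(r1, r2, ra) 0.5 * (120 * (r2 - ra) - 200 * (r1 - ra)),
  SAVI = function(r1, r2, ra) 1.5 * (r1 - r2) / (r1 + r2 + 0.5)
)

# independent log-scale fit + metrics oracle via lm()
oracle_fit_metrics <- function(x, y) {
  fit <- lm(log(y) ~ x)
  a <- exp(unname(coef(fit)[1]))
  b <- unname(coef(fit)[2])
  yhat <- a * exp(b * x)
  list(a = a, b = b,
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean((yhat - y)^2)),
       re = mean(abs(yhat - y)) * 100 / mean(y))
}
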