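#' Crop pigment presets
#'
#' Statistical presets for the bivariate distribution of total chlorophyll
#' and carotenoid concentrations of a leaf population. Two presets ship by
#' default, reproducing the published reference moments of a juvenile
#' cucumber group (Chl 7.88 ± 2.77, Car 1.86 ± 0.31 mg/L) and a low-pigment
#' lettuce cultivar (Chl 3.94 ± 0.83, Car 1.13 ± 0.17 mg/L). The two pigments
#' are strongly correlated in leaves; the default correlation is 0.8.
#'
#' @param name Preset label.
#' @param chl_mean,chl_sd Chlorophyll mean and SD, mg/L.
#' @param car_mean,car_sd Carotenoid mean and SD, mg/L.
#' @param pigment_correlation Pearson correlation between the pigments, in
#'   \[0, 1\].
#' @return An object of class `crop_preset`.
#' @examples
#' crop_presets()$`cucumber-like`
#' @export
crop_preset <- function(name, chl_mean, chl_sd, car_mean, car_sd,
                        pigment_correlation = 0.8) {
  if (chl_mean <= 0 || car_mean <= 0) stop("pigment means must be > 0")
  if (chl_sd < 0 || car_sd < 0) stop("pigment SDs must be >= 0")
  if (pigment_correlation < 0 || pigment_correlation > 1) {
    stop("`pigment_correlation` must lie in [0, 1]")
  }
  structure(list(name = name, chl_mean = chl_mean, chl_sd = chl_sd,
                 car_mean = car_mean, car_sd = car_sd,
                 pigment_correlation = pigment_correlation),
            class = "crop_preset")
}

#' @rdname crop_preset
#' @export
crop_presets <- function() {
  list(
    "cucumber-like" = crop_preset("cucumber-like", 7.88, 2.77, 1.86, 0.31),
    "lettuce-like"  = crop_preset("lettuce-like", 3.94, 0.83, 1.13, 0.17)
  )
}

#' @export
print.crop_preset <- function(x, ...) {
  cat(sprintf("<crop_preset> %s: Chl %g±%g, Car %g±%g mg/L (r = %g)\n",
              x$name, x$chl_mean, x$chl_sd, x$car_mean, x$car_sd,
              x$pigment_correlation))
  invisible(x)
}

# internal: resolve a preset by name or pass one through
resolve_preset <- function(preset) {
  if (inherits(preset, "crop_preset")) return(preset)
  ps <- crop_presets()
  if (is.character(preset) && preset %in% names(ps)) return(ps[[preset]])
  stop("unknown preset; use one of ",
       paste(names(ps), collapse = ", "), " or a crop_preset object")
}

#' Draw pigment profiles from a crop preset
#'
#' Samples (Chl, Car) pairs from a bivariate normal with the preset's means,
#' SDs and correlation, truncated at zero by resampling (negative draws are
#' redrawn, so sample moments are only approximate for presets close to
#' zero). With `sd = 0` the distribution is degenerate at the means.
#'
#' @param n Number of profiles, >= 1.
#' @param preset A [crop_preset()] or the name of a shipped preset.
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Data frame with columns `sample_id`, `chl`, `car` (mg/L).
#' @examples
#' head(sample_pigments(5, "cucumber-like", seed = 1))
#' @export
sample_pigments <- function(n, preset = "cucumber-like", seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive count")
  n <- as.integer(n)
  preset <- resolve_preset(preset)
  if (!is.null(seed)) withr::local_seed(seed)
  sigma <- matrix(c(
    preset$chl_sd^2,
    preset$pigment_correlation * preset$chl_sd * preset$car_sd,
    preset$pigment_correlation * preset$chl_sd * preset$car_sd,
    preset$car_sd^2), 2, 2)
  mu <- c(preset$chl_mean, preset$car_mean)
  draws <- matrix(NA_real_, n, 2)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    m <- sum(todo)
    d <- MASS::mvrnorm(m, mu = mu, Sigma = sigma)
    if (m == 1L) d <- matrix(d, 1, 2)
    draws[todo, ] <- d
    todo <- draws[, 1] < 0 | draws[, 2] < 0
  }
  data.frame(sample_id = paste0("S", seq_len(n)),
             chl = draws[, 1], car = draws[, 2],
             stringsAsFactors = FALSE)
}

#' Synthetic leaf-spectrum model
#'
#' Parametric stand-in for measured leaf reflectance: a smooth baseline (flat
#' near-infrared plateau plus a green-peak bump at 550 nm) attenuated
#' Beer–Lambert style by pigment-dependent Gaussian absorption components,
#' \deqn{R(\lambda) = clamp(B(\lambda) e^{-[Chl \cdot A_{chl}(\lambda) +
#'   Car \cdot A_{car}(\lambda)]} (1 + \epsilon_m) + \epsilon_a,\ 0,\ 1).}
#' Default absorption components place chlorophyll features in the blue
#' (430 nm) and red (649/662 nm) plus a red-edge shoulder near 700 nm, and
#' carotenoid features at 450/478 nm, so the generated spectra show the
#' qualitative structure real leaves do: a 550 nm reflectance peak, deep red
#' absorption, a red edge that shifts to longer wavelengths with increasing
#' chlorophyll, and a pigment-insensitive NIR plateau.
#'
#' Beyond wavelength-wise measurement noise, real leaf populations vary in
#' ways uncorrelated with pigment content: internal leaf structure shifts the
#' NIR plateau from leaf to leaf, measurement geometry scales the whole
#' spectrum, and stray light adds a small offset. These per-sample draws
#' (`plateau_sd`, `gain_sd`, `offset_sd`) are what limits calibration
#' quality and what makes ratio-type and difference-type indices perform
#' differently; with all noise parameters zero the model is fully
#' deterministic.
#'
#' @param nir_plateau Baseline plateau reflectance, in (0, 1).
#' @param green_bump Additive amplitude of the 550 nm baseline bump.
#' @param absorption Data frame with columns `pigment` (`"chl"`/`"car"`),
#'   `center` (nm), `width` (Gaussian SD, nm), `strength` (per mg/L).
#' @param mult_noise_sd SD of wavelength-wise multiplicative Gaussian noise
#'   (dimensionless).
#' @param add_noise_sd SD of wavelength-wise additive Gaussian noise
#'   (reflectance units).
#' @param plateau_sd Per-sample SD of the NIR plateau level (leaf structural
#'   variability).
#' @param gain_sd Per-sample SD of a multiplicative gain (illumination /
#'   geometry variability).
#' @param offset_sd Per-sample SD of an additive offset (stray light).
#' @return An object of class `leaf_spectrum_model`.
#' @export
leaf_spectrum_model <- function(nir_plateau = 0.55, green_bump = 0.06,
                                absorption = default_absorption(),
                                mult_noise_sd = 0.01, add_noise_sd = 0.002,
                                plateau_sd = 0.04, gain_sd = 0.03,
                                offset_sd = 0.004) {
  if (nir_plateau <= 0 || nir_plateau + max(green_bump, 0) >= 1) {
    stop("baseline must stay within (0, 1)")
  }
  need <- c("pigment", "center", "width", "strength")
  if (!all(need %in% names(absorption))) {
    stop("`absorption` needs columns: ", paste(need, collapse = ", "))
  }
  if (any(absorption$width <= 0)) stop("absorption widths must be > 0")
  if (any(absorption$strength < 0)) stop("absorption strengths must be >= 0")
  if (mult_noise_sd < 0 || add_noise_sd < 0 || plateau_sd < 0 ||
      gain_sd < 0 || offset_sd < 0) {
    stop("noise SDs must be >= 0")
  }
  structure(list(nir_plateau = nir_plateau, green_bump = green_bump,
                 absorption = absorption, mult_noise_sd = mult_noise_sd,
                 add_noise_sd = add_noise_sd, plateau_sd = plateau_sd,
                 gain_sd = gain_sd, offset_sd = offset_sd),
            class = "leaf_spectrum_model")
}

#' @rdname leaf_spectrum_model
#' @export
default_absorption <- function() {
  data.frame(
    pigment  = c("chl", "chl", "chl", "chl", "car", "car"),
    center   = c(430, 662, 649, 700, 450, 478),
    width    = c(28, 22, 20, 16, 20, 18),
    strength = c(0.30, 0.22, 0.12, 0.05, 0.30, 0.22),
    stringsAsFactors = FALSE
  )
}

# internal: specific absorption curves A_chl, A_car on a grid (per mg/L)
absorption_curves <- function(model, grid) {
  ab <- model$absorption
  acc <- list(chl = numeric(length(grid)), car = numeric(length(grid)))
  for (i in seq_len(nrow(ab))) {
    g <- ab$strength[i] * exp(-(grid - ab$center[i])^2 / (2 * ab$width[i]^2))
    acc[[ab$pigment[i]]] <- acc[[ab$pigment[i]]] + g
  }
  acc
}

# internal: pigment-free baseline B(lambda)
baseline_curve <- function(model, grid) {
  model$nir_plateau +
    model$green_bump * exp(-(grid - 550)^2 / (2 * 45^2))
}

#' Generate synthetic leaf reflectance spectra
#'
#' Applies the [leaf_spectrum_model()] forward model to one or more pigment
#' profiles. With zero noise SDs generation is deterministic; with a fixed
#' seed it is bitwise repeatable. Reflectance is clamped to \[0, 1\].
#'
#' @param pigments Data frame with columns `chl`, `car` (mg/L; optional
#'   `sample_id`), e.g. from [sample_pigments()].
#' @param model A [leaf_spectrum_model()].
#' @param grid Wavelength grid in nm within \[450, 950\]; default 1 nm steps.
#' @param seed Optional integer seed for the noise draws.
#' @return A `spectra` object, one column per profile.
#' @examples
#' pg <- data.frame(chl = c(5, 10), car = c(1.2, 2))
#' generate_reflectance(pg, leaf_spectrum_model(mult_noise_sd = 0,
#'                                              add_noise_sd = 0))
#' @export
generate_reflectance <- function(pigments, model = leaf_spectrum_model(),
                                 grid = seq(450, 950, by = 1), seed = NULL) {
  stopifnot(inherits(model, "leaf_spectrum_model"),
            all(c("chl", "car") %in% names(pigments)))
  if (min(grid) < 450 || max(grid) > 950) {
    stop("wavelength grid must lie within [450, 950] nm")
  }
  if (any(pigments$chl < 0) || any(pigments$car < 0)) {
    stop("pigment concentrations must be >= 0")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  a <- absorption_curves(model, grid)
  n <- nrow(pigments)
  vals <- matrix(NA_real_, length(grid), n)
  for (j in seq_len(n)) {
    m_j <- model
    if (model$plateau_sd > 0) {
      m_j$nir_plateau <- min(max(rnorm(1, model$nir_plateau,
                                       model$plateau_sd), 0.1),
                             1 - model$green_bump - 0.05)
    }
    gain <- if (model$gain_sd > 0) rnorm(1, 1, model$gain_sd) else 1
    offset <- if (model$offset_sd > 0) rnorm(1, 0, model$offset_sd) else 0
    base <- baseline_curve(m_j, grid)
    r <- base * exp(-(pigments$chl[j] * a$chl + pigments$car[j] * a$car))
    if (model$mult_noise_sd > 0) {
      r <- r * (1 + rnorm(length(grid), 0, model$mult_noise_sd))
    }
    r <- gain * r + offset
    if (model$add_noise_sd > 0) {
      r <- r + rnorm(length(grid), 0, model$add_noise_sd)
    }
    vals[, j] <- pmin(pmax(r, 0), 1)
  }
  ids <- pigments$sample_id %||% paste0("S", seq_len(n))
  spectra(grid, vals, sample_id = as.character(ids))
}

#' Red-edge position of a spectrum
#'
#' The wavelength at which reflectance first crosses the midpoint between
#' its red absorption minimum (660–690 nm) and the NIR plateau (mean over
#' 780–900 nm), located by linear interpolation on the 690–780 nm flank.
#' The position moves to longer wavelengths as chlorophyll increases.
#'
#' @param x A `spectra` object covering 660–900 nm.
#' @return Named numeric vector of red-edge positions (nm), one per sample.
#' @export
red_edge_position <- function(x) {
  stopifnot(inherits(x, "spectra"))
  wl <- x$wavelength
  vapply(seq_len(n_samples(x)), function(j) {
    v <- x$values[, j]
    rmin <- min(v[wl >= 660 & wl <= 690])
    plateau <- mean(v[wl >= 780 & wl <= 900])
    mid <- (rmin + plateau) / 2
    flank <- which(wl >= 690 & wl <= 780)
    above <- which(v[flank] >= mid)
    if (!length(above)) return(NA_real_)
    i2 <- flank[above[1]]
    if (above[1] == 1L) return(wl[i2])
    i1 <- i2 - 1L
    wl[i1] + (mid - v[i1]) * (wl[i2] - wl[i1]) / (v[i2] - v[i1])
  }, numeric(1)) |> setNames(x$sample_id)
}

#' Extract optical densities consistent with a pigment profile
#'
#' Inverts the spectrophotometric reference equations: given (Chl, Car) and a
#' chlorophyll a:b partition fraction `a_b_split` (the share of the summed
#' D665/D649 signal assigned to D665), returns optical densities whose
#' forward pass through [chl_from_od()] and [car_from_od()] reproduces the
#' profile exactly. The partition only splits the chlorophyll signal between
#' the two red bands and does not affect the round trip.
#'
#' @param pigments Data frame with columns `chl`, `car` (optional
#'   `sample_id`).
#' @param a_b_split Fraction in (0, 1), default 0.7.
#' @param coef Coefficient set from [reference_coefficients()].
#' @return Data frame with columns `sample_id`, `d440_5`, `d649`, `d665`.
#' @examples
#' ods_from_pigments(data.frame(chl = 8.06, car = 1.8))
#' @export
ods_from_pigments <- function(pigments, a_b_split = 0.7,
                              coef = reference_coefficients()) {
  stopifnot(all(c("chl", "car") %in% names(pigments)))
  if (a_b_split <= 0 || a_b_split >= 1) {
    stop("`a_b_split` must lie strictly within (0, 1)")
  }
  phi <- a_b_split
  s <- pigments$chl / (coef$chl_d665 * phi + coef$chl_d649 * (1 - phi))
  data.frame(
    sample_id = pigments$sample_id %||% paste0("S", seq_len(nrow(pigments))),
    d440_5 = (pigments$car + coef$car_chl * pigments$chl) / coef$car_d440,
    d649 = (1 - phi) * s,
    d665 = phi * s,
    stringsAsFactors = FALSE
  )
}

#' Noise level presets for the generator
#'
#' Maps a label to all five noise SDs of [leaf_spectrum_model()] — the
#' wavelength-wise measurement noise and the per-sample structural
#' variability. `"none"` zeroes everything (deterministic generation),
#' `"low"` is the model default, `"high"` doubles the structural SDs and
#' quadruples the measurement noise.
#'
#' @param level One of `"none"`, `"low"`, `"high"`.
#' @return Named list of noise SDs.
#' @export
noise_level <- function(level = c("low", "none", "high")) {
  level <- match.arg(level)
  switch(level,
    none = list(mult_noise_sd = 0, add_noise_sd = 0,
                plateau_sd = 0, gain_sd = 0, offset_sd = 0),
    low  = list(mult_noise_sd = 0.01, add_noise_sd = 0.002,
                plateau_sd = 0.04, gain_sd = 0.03, offset_sd = 0.004),
    high = list(mult_noise_sd = 0.04, add_noise_sd = 0.008,
                plateau_sd = 0.08, gain_sd = 0.06, offset_sd = 0.008))
}

#' Simulate a complete sample set
#'
#' One call producing everything the downstream analysis needs: pigment
#' profiles drawn from a crop preset, reflectance spectra from the forward
#' model, and extract optical densities consistent with the reference
#' equations. A single seed controls all randomness.
#'
#' @param n Number of leaf samples.
#' @param preset A [crop_preset()] or shipped preset name.
#' @param model A [leaf_spectrum_model()]; its noise SDs are overridden when
#'   `noise` is given.
#' @param noise Optional noise level label, see [noise_level()].
#' @param grid Wavelength grid in nm.
#' @param a_b_split Chlorophyll a:b partition for the optical densities.
#' @param seed Optional integer seed.
#' @return An object of class `sample_set`: list with `spectra` (a
#'   `spectra` object), `pigments` and `ods` data frames, and the `preset`.
#' @examples
#' ss <- simulate_samples(10, "cucumber-like", seed = 1)
#' ss$pigments[1:3, ]
#' @export
simulate_samples <- function(n, preset = "cucumber-like",
                             model = leaf_spectrum_model(), noise = NULL,
                             grid = seq(450, 950, by = 1), a_b_split = 0.7,
                             seed = NULL) {
  preset <- resolve_preset(preset)
  if (!is.null(noise)) {
    model[names(noise_level(noise))] <- noise_level(noise)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  pigments <- sample_pigments(n, preset)
  sp <- generate_reflectance(pigments, model, grid)
  ods <- ods_from_pigments(pigments, a_b_split)
  structure(list(spectra = sp, pigments = pigments, ods = ods,
                 preset = preset),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, preset '%s'\n",
              nrow(x$pigments), x$preset$name))
  print(x$spectra)
  invisible(x)
}

#' Write a sample set to a directory
#'
#' Writes `spectra.csv` (wide), `pigments.csv` and `ods.csv`, round-trippable
#' by [read_sample_set()].
#'
#' @param x A `sample_set`.
#' @param dir Output directory (created if missing).
#' @export
write_sample_set <- function(x, dir) {
  stopifnot(inherits(x, "sample_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra_wide(x$spectra, file.path(dir, "spectra.csv"))
  write_pigments(x$pigments, file.path(dir, "pigments.csv"))
  write_ods(x$ods, file.path(dir, "ods.csv"))
  invisible(dir)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(dir) {
  structure(list(
    spectra = read_spectra_wide(file.path(dir, "spectra.csv")),
    pigments = read_pigments(file.path(dir, "pigments.csv")),
    ods = read_ods(file.path(dir, "ods.csv")),
    preset = NULL
  ), class = "sample_set")
}
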