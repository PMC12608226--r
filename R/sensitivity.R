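# internal: re-fit one configuration (formula + two channels) on a sample
# set and return a flat metrics row; the same path the optimizer's scalar
# engine takes, shared by all sensitivity profiles.
refit_config <- function(samples, pigment, formula, lambda1, dl1,
                         lambda2, dl2, aux_fwhm = NULL, aux_centers = NULL,
                         model = NULL) {
  sp <- samples$spectra
  y_all <- samples$pigments[[pigment]]
  ok <- is.finite(y_all) & y_all > 0
  sp_ok <- spectra(sp$wavelength, sp$values[, ok, drop = FALSE],
                   sample_id = sp$sample_id[ok])
  y <- y_all[ok]
  r1 <- band_reflectance(sp_ok, channel_spec(lambda1, dl1))
  r2 <- band_reflectance(sp_ok, channel_spec(lambda2, dl2))
  rho_aux <- aux_reflectance(sp_ok, formula, aux_fwhm %||% dl1, aux_centers)
  x <- compute_vi(formula, r1, r2, rho_aux = rho_aux)
  fit <- if (is.null(model)) fit_exponential(x, y) else model
  met <- evaluate_metrics(fit, x, y)
  yhat <- predict(fit, x)
  dev <- abs(yhat - y) * 100 / mean(y)
  list(a = fit$a, b = fit$b, r2 = met$r2, rmse = met$rmse,
       re_percent = met$re_percent, n = met$n,
       max_dev_percent = max(dev, na.rm = TRUE),
       mean_dev_percent = mean(dev, na.rm = TRUE),
       per_sample_dev = dev, vi = x, y = y)
}

# internal: coerce a calibration row (data.frame row or list) to a list
reference_fields <- function(reference) {
  need <- c("formula", "pigment", "lambda1", "dl1", "lambda2", "dl2")
  ref <- as.list(reference)
  if (!all(need %in% names(ref))) {
    stop("reference must carry fields: ", paste(need, collapse = ", "))
  }
  ref
}

#' Wavelength-shift sensitivity profile
#'
#' Quantifies how calibration quality degrades when the channel centers are
#' displaced from a reference configuration. For each offset the calibration
#' is re-fitted at the shifted centers (same FWHM) — the comparison is
#' between calibrated models, not a frozen model applied to shifted bands —
#' and R2, RMSE, RE plus the maximum and mean per-sample prediction
#' deviation (percent of the mean measured concentration) are reported.
#' `mode = "joint"` shifts both channels together over a 1-D offset range;
#' `mode = "per_channel"` explores the full 2-D offset grid. Offsets that
#' would push a center outside \[450, 950\] nm are dropped (count recorded in
#' `attr(, "n_dropped")`). With `frozen = TRUE` the reference model's (a, b)
#' are kept and only the band positions move, emulating uncorrected device
#' drift.
#'
#' @param samples A `sample_set`.
#' @param reference A calibration row from [select_optimal()] /
#'   [optimize_bands()] (needs `formula`, `pigment`, `lambda1`, `dl1`,
#'   `lambda2`, `dl2`).
#' @param max_shift Maximum |offset| in nm (default 20).
#' @param step Offset step in nm (default 1).
#' @param mode `"joint"` (default) or `"per_channel"`.
#' @param frozen Keep the reference model instead of re-fitting (default
#'   `FALSE`).
#' @param aux_fwhm,aux_centers Auxiliary-band settings, see
#'   [evaluate_map()].
#' @return Object of class `shift_profile`: data frame with `offset1`,
#'   `offset2`, `r2`, `rmse`, `re_percent`, `max_dev_percent`,
#'   `mean_dev_percent`; the reference row is the zero-offset entry.
#' @export
shift_profile <- function(samples, reference, max_shift = 20, step = 1,
                          mode = c("joint", "per_channel"), frozen = FALSE,
                          aux_fwhm = NULL, aux_centers = NULL) {
  mode <- match.arg(mode)
  ref <- reference_fields(reference)
  offsets <- seq(-max_shift, max_shift, by = step)
  grid <- if (mode == "joint") {
    data.frame(offset1 = offsets, offset2 = offsets)
  } else {
    expand.grid(offset1 = offsets, offset2 = offsets,
                KEEP.OUT.ATTRS = FALSE)
  }
  inside <- ref$lambda1 + grid$offset1 >= 450 &
    ref$lambda1 + grid$offset1 <= 950 &
    ref$lambda2 + grid$offset2 >= 450 &
    ref$lambda2 + grid$offset2 <= 950
  n_dropped <- sum(!inside)
  grid <- grid[inside, , drop = FALSE]
  model <- if (frozen) {
    structure(list(a = ref$a, b = ref$b, n_valid = NA_integer_,
                   n_dropped = 0L, refined = FALSE), class = "exp_model")
  } else NULL
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    r <- tryCatch(
      refit_config(samples, ref$pigment, ref$formula,
                   ref$lambda1 + grid$offset1[k], ref$dl1,
                   ref$lambda2 + grid$offset2[k], ref$dl2,
                   aux_fwhm = aux_fwhm, aux_centers = aux_centers,
                   model = model),
      error = function(e) NULL)
    if (is.null(r)) {
      r <- list(r2 = NA_real_, rmse = NA_real_, re_percent = NA_real_,
                max_dev_percent = NA_real_, mean_dev_percent = NA_real_)
    }
    data.frame(offset1 = grid$offset1[k], offset2 = grid$offset2[k],
               r2 = r$r2, rmse = r$rmse, re_percent = r$re_percent,
               max_dev_percent = r$max_dev_percent,
               mean_dev_percent = r$mean_dev_percent)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "mode") <- mode
  attr(out, "frozen") <- frozen
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("shift_profile", "data.frame")
  out
}

#' Bandwidth sensitivity profile
#'
#' Re-fits the reference configuration at each candidate bandwidth (applied
#' to both channels jointly by default, or to one channel at a time) with
#' centers fixed, and computes a stability score per bandwidth: the maximum
#' |R2(center ± 5 nm) − R2(center)| under a joint 5 nm displacement. Wider
#' channels average over more of the spectrum, so the score quantifies the
#' sensitivity-versus-stability trade-off of broadening the bands.
#'
#' @param samples A `sample_set`.
#' @param reference A calibration row (see [shift_profile()]).
#' @param bandwidths FWHM values to probe, nm; default `c(1, 5, 10, 30,
#'   50)`. The reference bandwidths are probed as given.
#' @param mode `"joint"` (both channels get the probed FWHM) or
#'   `"channel1"`/`"channel2"` (vary one, hold the other at its reference).
#' @param stability_shift Displacement (nm) used for the stability score
#'   (default 5).
#' @param aux_fwhm,aux_centers Auxiliary-band settings.
#' @return Object of class `bandwidth_profile`: data frame with `dl1`,
#'   `dl2`, `r2`, `rmse`, `re_percent`, `stability`.
#' @export
bandwidth_profile <- function(samples, reference,
                              bandwidths = c(1, 5, 10, 30, 50),
                              mode = c("joint", "channel1", "channel2"),
                              stability_shift = 5,
                              aux_fwhm = NULL, aux_centers = NULL) {
  mode <- match.arg(mode)
  ref <- reference_fields(reference)
  rows <- lapply(bandwidths, function(bw) {
    d1 <- switch(mode, joint = bw, channel1 = bw, channel2 = ref$dl1)
    d2 <- switch(mode, joint = bw, channel1 = ref$dl2, channel2 = bw)
    base <- tryCatch(
      refit_config(samples, ref$pigment, ref$formula,
                   ref$lambda1, d1, ref$lambda2, d2,
                   aux_fwhm = aux_fwhm, aux_centers = aux_centers),
      error = function(e) NULL)
    if (is.null(base)) {
      return(data.frame(dl1 = d1, dl2 = d2, r2 = NA_real_,
                        rmse = NA_real_, re_percent = NA_real_,
                        stability = NA_real_))
    }
    shifts <- c(-stability_shift, stability_shift)
    r2_shift <- vapply(shifts, function(dlt) {
      l1 <- ref$lambda1 + dlt
      l2 <- ref$lambda2 + dlt
      if (l1 < 450 || l1 > 950 || l2 < 450 || l2 > 950) return(NA_real_)
      tryCatch(
        refit_config(samples, ref$pigment, ref$formula, l1, d1, l2, d2,
                     aux_fwhm = aux_fwhm, aux_centers = aux_centers)$r2,
        error = function(e) NA_real_)
    }, numeric(1))
    data.frame(dl1 = d1, dl2 = d2, r2 = base$r2, rmse = base$rmse,
               re_percent = base$re_percent,
               stability = max(abs(r2_shift - base$r2), na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "mode") <- mode
  class(out) <- c("bandwidth_profile", "data.frame")
  out
}

#' Index-formula substitution comparison
#'
#' Evaluates all seven index formulas at one fixed channel pair — identical
#' band reflectances, each formula with its own exponential calibration —
#' and reports the metric spread plus per-sample relative prediction errors.
#' This isolates the contribution of the formula (and its regression) to
#' estimation error from that of the channel placement.
#'
#' @param samples A `sample_set`.
#' @param lambda1,dl1,lambda2,dl2 The fixed channel pair (centers and FWHM,
#'   nm), typically an optimum from [optimize_bands()].
#' @param pigment `"chl"` or `"car"`.
#' @param formulas Formula names to compare (default all seven).
#' @param aux_fwhm,aux_centers Auxiliary-band settings.
#' @return Object of class `formula_comparison`: list with `metrics` (one
#'   row per formula, ranked by R2) and `per_sample` (per-sample relative
#'   errors in percent, samples x formulas).
#' @export
formula_comparison <- function(samples, lambda1, dl1, lambda2, dl2,
                               pigment = c("chl", "car"),
                               formulas = vi_formulas()$name,
                               aux_fwhm = NULL, aux_centers = NULL) {
  pigment <- match.arg(pigment)
  res <- lapply(formulas, function(f) {
    refit_config(samples, pigment, f, lambda1, dl1, lambda2, dl2,
                 aux_fwhm = aux_fwhm, aux_centers = aux_centers)
  })
  metrics <- do.call(rbind, lapply(seq_along(formulas), function(k) {
    r <- res[[k]]
    data.frame(formula = formulas[k], lambda1 = lambda1, dl1 = dl1,
               lambda2 = lambda2, dl2 = dl2, a = r$a, b = r$b, r2 = r$r2,
               rmse = r$rmse, re_percent = r$re_percent,
               stringsAsFactors = FALSE)
  }))
  metrics$rank <- rank(-metrics$r2, ties.method = "min")
  metrics <- metrics[order(metrics$rank), ]
  rownames(metrics) <- NULL
  per_sample <- do.call(cbind, lapply(res, function(r) r$per_sample_dev))
  colnames(per_sample) <- formulas
  structure(list(metrics = metrics, per_sample = per_sample,
                 pigment = pigment),
            class = "formula_comparison")
}

#' @export
print.formula_comparison <- function(x, ...) {
  cat(sprintf("<formula_comparison> %s at fixed channels\n", x$pigment))
  print(x$metrics[, c("formula", "r2", "rmse", "re_percent", "rank")],
        digits = 4)
  invisible(x)
}
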