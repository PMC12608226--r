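#' Search-grid configuration
#'
#' Defines the exhaustive search space of the band optimizer: the wavelength
#' grid for both channel centers, the candidate bandwidths (FWHM) and the
#' index formulas to evaluate. By default bandwidths are paired as the full
#' Cartesian product (channel 1 and channel 2 may have different FWHM, as
#' optimal configurations with unequal widths are commonly reported);
#' `pairing = "equal"` restricts to equal pairs.
#'
#' @param start,stop,step Wavelength grid in nm; defaults 450–950 at 1 nm
#'   (501 centers).
#' @param bandwidths Candidate FWHM values in nm, default `c(1, 5, 10, 30,
#'   50)`.
#' @param formulas Character vector of formula names, default all seven.
#' @param pairing `"product"` (default) or `"equal"` bandwidth pairing.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(start = 450, stop = 950, step = 1,
                        bandwidths = c(1, 5, 10, 30, 50),
                        formulas = vi_formulas()$name,
                        pairing = c("product", "equal")) {
  if (start >= stop) stop("`start` must be < `stop`")
  if (step <= 0) stop("`step` must be > 0")
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  bad <- setdiff(formulas, vi_formulas()$name)
  if (length(bad)) stop("unknown formulas: ", paste(bad, collapse = ", "))
  structure(list(start = start, stop = stop, step = step,
                 bandwidths = bandwidths, formulas = formulas,
                 pairing = match.arg(pairing)),
            class = "grid_config")
}

# internal: wavelength centers of a grid_config
grid_centers <- function(grid) seq(grid$start, grid$stop, by = grid$step)

# internal: bandwidth pairs as a two-column matrix
bandwidth_pairs <- function(grid) {
  if (grid$pairing == "equal") {
    cbind(dl1 = grid$bandwidths, dl2 = grid$bandwidths)
  } else {
    as.matrix(expand.grid(dl1 = grid$bandwidths, dl2 = grid$bandwidths,
                          KEEP.OUT.ATTRS = FALSE))
  }
}

#' Enumerate channel-center configurations
#'
#' All ordered pairs (lambda1, lambda2) with lambda1 != lambda2 over the
#' configured wavelength grid, in deterministic row-major order (lambda1
#' outer, lambda2 inner). The diagonal is excluded because every ratio or
#' difference form degenerates there. For the default 450–950 nm grid at
#' 1 nm this yields 501 * 500 = 250,500 configurations per bandwidth pair.
#'
#' @param grid A [grid_config()].
#' @param dl1,dl2 Bandwidths (FWHM, nm) attached to the two channel slots.
#' @return Data frame with columns `lambda1`, `lambda2`, `dl1`, `dl2`; the
#'   total count is `nrow()`.
#' @examples
#' nrow(enumerate_configs(grid_config(step = 5), 10, 10))  # 101 * 100
#' @export
enumerate_configs <- function(grid, dl1 = 1, dl2 = 1) {
  stopifnot(inherits(grid, "grid_config"))
  centers <- grid_centers(grid)
  if (length(centers) < 2L) stop("wavelength grid has fewer than 2 centers")
  # row-major: lambda1 varies slowest
  l1 <- rep(centers, each = length(centers))
  l2 <- rep(centers, times = length(centers))
  keep <- l1 != l2
  data.frame(lambda1 = l1[keep], lambda2 = l2[keep],
             dl1 = dl1, dl2 = dl2)
}

# internal: auxiliary band reflectance per sample for one formula, or NULL.
# Aux centers outside the spectral grid (the default 445 nm band on a
# 450 nm-start grid) are clamped to the grid range before integration.
aux_reflectance <- function(samples_spectra, formula, fwhm,
                            aux_centers = NULL) {
  ctr <- vi_aux_center(formula, aux_centers)
  if (is.na(ctr)) return(NULL)
  wl <- samples_spectra$wavelength
  ctr <- min(max(ctr, min(wl)), max(wl))
  band_reflectance(samples_spectra, channel_spec(ctr, fwhm))
}

#' Metric map over all wavelength pairs
#'
#' The workhorse of the exhaustive search: for every ordered pair of channel
#' centers it band-integrates the spectra, computes the index, fits the
#' exponential calibration on the log scale and evaluates R2, RMSE and RE in
#' the original concentration space. Cells with fewer than 3 valid samples,
#' zero index variance or zero pigment variance are masked. The default
#' vectorized engine accumulates the closed-form regression sums across
#' samples with matrix operations; `engine = "scalar"` runs an explicit
#' per-cell loop through [fit_exponential()] and [evaluate_metrics()] and is
#' kept as a cross-check (both paths agree to floating-point accuracy).
#'
#' @param samples A `sample_set` (or a list with elements `spectra` and
#'   `pigments`).
#' @param pigment `"chl"` or `"car"`.
#' @param formula Index formula name.
#' @param dl1,dl2 Channel bandwidths (FWHM, nm).
#' @param grid A [grid_config()]; only its wavelength axis is used here.
#' @param engine `"vectorized"` (default) or `"scalar"`.
#' @param aux_fwhm FWHM of the fixed auxiliary band (mSR/mNDI/TVI); defaults
#'   to `dl1`.
#' @param aux_centers Optional named list overriding auxiliary band centers.
#' @return An object of class `metric_map`: axes `lambda1`, `lambda2` and
#'   matrices `r2`, `rmse`, `re`, `a`, `b`, `n_valid`, `valid` (rows =
#'   lambda1, columns = lambda2).
#' @export
evaluate_map <- function(samples, pigment = c("chl", "car"), formula,
                         dl1, dl2, grid = grid_config(),
                         engine = c("vectorized", "scalar"),
                         aux_fwhm = NULL, aux_centers = NULL) {
  pigment <- match.arg(pigment)
  engine <- match.arg(engine)
  stopifnot(inherits(grid, "grid_config"))
  sp <- samples$spectra
  y_all <- samples$pigments[[pigment]]
  ok <- is.finite(y_all) & y_all > 0
  if (sum(ok) < 3L) stop("need at least 3 samples with positive pigment")
  sp_ok <- spectra(sp$wavelength, sp$values[, ok, drop = FALSE],
                   sample_id = sp$sample_id[ok])
  y <- y_all[ok]
  centers <- grid_centers(grid)
  nc <- length(centers)

  b1 <- band_matrix(sp_ok, centers, dl1)   # [centers x samples]
  b2 <- band_matrix(sp_ok, centers, dl2)
  rho_aux <- aux_reflectance(sp_ok, formula, aux_fwhm %||% dl1, aux_centers)

  if (engine == "scalar") {
    out <- map_engine_scalar(b1, b2, rho_aux, y, formula, nc)
  } else {
    out <- map_engine_vectorized(b1, b2, rho_aux, y, formula, nc)
  }
  structure(c(list(lambda1 = centers, lambda2 = centers,
                   formula = formula, dl1 = dl1, dl2 = dl2,
                   pigment = pigment, n_samples = length(y)),
              out),
            class = "metric_map")
}

# internal: vectorized map engine. Three passes over samples accumulating
# centered regression sums so results match the per-cell scalar path.
map_engine_vectorized <- function(b1, b2, rho_aux, y, formula, nc) {
  ns <- length(y)
  z <- log(y)
  vi_s <- function(s) {
    m1 <- matrix(b1[, s], nc, nc)                # rho1 varies with rows
    m2 <- matrix(b2[, s], nc, nc, byrow = TRUE)  # rho2 varies with columns
    x <- compute_vi(formula, m1, m2,
                    rho_aux = if (is.null(rho_aux)) NULL else rho_aux[s])
    diag(x) <- NA_real_
    x
  }
  zero <- matrix(0, nc, nc)
  n_v <- zero; sx <- zero; sz <- zero; sy <- zero
  for (s in seq_len(ns)) {
    x <- vi_s(s)
    m <- is.finite(x)
    x[!m] <- 0
    n_v <- n_v + m
    sx <- sx + x
    sz <- sz + z[s] * m
    sy <- sy + y[s] * m
  }
  enough <- n_v >= 3
  n_safe <- ifelse(enough, n_v, NA_real_)
  xbar <- sx / n_safe
  zbar <- sz / n_safe
  ybar <- sy / n_safe
  sxx <- zero; sxz <- zero
  for (s in seq_len(ns)) {
    x <- vi_s(s)
    m <- is.finite(x)
    xc <- ifelse(m, x - xbar, 0)
    sxx <- sxx + xc^2
    sxz <- sxz + xc * (z[s] - zbar)
  }
  has_var <- enough & sxx > 0
  b <- ifelse(has_var, sxz / sxx, NA_real_)
  a <- exp(zbar - b * xbar)
  ssres <- zero; sae <- zero; sstot <- zero
  for (s in seq_len(ns)) {
    x <- vi_s(s)
    m <- is.finite(x)
    # centered prediction exp(zbar + b (x - xbar)): stable where exp(log a)
    # would overflow at near-degenerate cells
    yhat <- exp(zbar + b * (x - xbar))
    e <- ifelse(m, y[s] - yhat, 0)
    ssres <- ssres + e^2
    sae <- sae + abs(e)
    sstot <- sstot + ifelse(m, (y[s] - ybar)^2, 0)
  }
  valid <- has_var & is.finite(sstot) & sstot > 0 &
    is.finite(a) & is.finite(b)
  r2 <- ifelse(valid, 1 - ssres / sstot, NA_real_)
  rmse <- ifelse(valid, sqrt(ssres / n_v), NA_real_)
  re <- ifelse(valid, (sae / n_v) * 100 / ybar, NA_real_)
  a[!valid] <- NA_real_
  b[!valid] <- NA_real_
  list(r2 = r2, rmse = rmse, re = re, a = a, b = b,
       n_valid = n_v, valid = valid)
}

# internal: explicit per-cell loop through the scalar fit/metric functions
map_engine_scalar <- function(b1, b2, rho_aux, y, formula, nc) {
  na <- matrix(NA_real_, nc, nc)
  out <- list(r2 = na, rmse = na, re = na, a = na, b = na,
              n_valid = matrix(0, nc, nc),
              valid = matrix(FALSE, nc, nc))
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i == j) next
      x <- compute_vi(formula, b1[i, ], b2[j, ], rho_aux = rho_aux)
      m <- is.finite(x)
      out$n_valid[i, j] <- sum(m)
      if (sum(m) < 3L) next
      if (max(x[m]) - min(x[m]) == 0) next
      if (max(y[m]) - min(y[m]) == 0) next
      fit <- fit_exponential(x, y)
      if (!is.finite(fit$a) || !is.finite(fit$b)) next
      met <- evaluate_metrics(fit, x, y)
      out$r2[i, j] <- met$r2
      out$rmse[i, j] <- met$rmse
      out$re[i, j] <- met$re_percent
      out$a[i, j] <- fit$a
      out$b[i, j] <- fit$b
      out$valid[i, j] <- TRUE
    }
  }
  out
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf(
    "<metric_map> %s / %s, FWHM (%g, %g) nm, %d x %d cells (%d valid)\n",
    x$formula, x$pigment, x$dl1, x$dl2, length(x$lambda1),
    length(x$lambda2), sum(x$valid)))
  if (any(x$valid)) {
    cat(sprintf("  best R2 = %.4f\n", max(x$r2[x$valid])))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_map <- function(x, ...) {
  nc <- length(x$lambda1)
  data.frame(
    lambda1_nm = rep(x$lambda1, times = nc),
    lambda2_nm = rep(x$lambda2, each = nc),
    r2 = as.vector(x$r2), rmse = as.vector(x$rmse),
    re_percent = as.vector(x$re),
    n_valid = as.vector(x$n_valid), valid = as.vector(x$valid)
  )
}

#' Plot a metric map
#'
#' Heat-map of one metric over the (lambda1, lambda2) plane.
#'
#' @param x A `metric_map`.
#' @param metric `"r2"`, `"rmse"` or `"re"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.metric_map <- function(x, metric = c("r2", "rmse", "re"), ...) {
  metric <- match.arg(metric)
  graphics::image(x$lambda1, x$lambda2, x[[metric]],
                  xlab = expression(lambda[1] ~ "(nm)"),
                  ylab = expression(lambda[2] ~ "(nm)"),
                  main = sprintf("%s %s (%s)", x$formula, toupper(metric),
                                 x$pigment), ...)
  invisible(x)
}

# internal: best cell of one map under a criterion, with deterministic
# tie-breaks: max R2 (or min RMSE), then min RMSE (max R2), then smallest
# (lambda1, lambda2).
best_cell <- function(map, criterion = c("r2", "rmse")) {
  criterion <- match.arg(criterion)
  if (!any(map$valid)) stop("all map cells are masked; nothing to select")
  idx <- which(map$valid, arr.ind = TRUE)
  score1 <- if (criterion == "r2") -map$r2[map$valid] else map$rmse[map$valid]
  score2 <- if (criterion == "r2") map$rmse[map$valid] else -map$r2[map$valid]
  ord <- order(score1, score2, map$lambda1[idx[, 1]], map$lambda2[idx[, 2]])
  i <- idx[ord[1], 1]
  j <- idx[ord[1], 2]
  data.frame(
    formula = map$formula, pigment = map$pigment,
    lambda1 = map$lambda1[i], dl1 = map$dl1,
    lambda2 = map$lambda2[j], dl2 = map$dl2,
    a = map$a[i, j], b = map$b[i, j],
    r2 = map$r2[i, j], rmse = map$rmse[i, j], re_percent = map$re[i, j],
    n_valid = map$n_valid[i, j],
    stringsAsFactors = FALSE
  )
}

#' Select optimal configurations from metric maps
#'
#' Applies the selection rule to one or more metric maps: maximize R2
#' (ties broken by minimum RMSE, then by the lexicographically smallest
#' wavelength pair), or minimize RMSE with `criterion = "rmse"`. Returns one
#' calibration row per map plus the overall best across maps.
#'
#' @param maps A `metric_map` or list of them.
#' @param criterion `"r2"` (default) or `"rmse"`.
#' @return Object of class `calibration_results`: data frame with one row
#'   per map (columns `formula`, `lambda1`, `dl1`, `lambda2`, `dl2`, `a`,
#'   `b`, `r2`, `rmse`, `re_percent`, `n_valid`) sorted by the criterion;
#'   the overall optimum is the first row, also in `attr(, "overall")`.
#' @export
select_optimal <- function(maps, criterion = c("r2", "rmse")) {
  criterion <- match.arg(criterion)
  if (inherits(maps, "metric_map")) maps <- list(maps)
  rows <- do.call(rbind, lapply(maps, best_cell, criterion = criterion))
  ord <- if (criterion == "r2") {
    order(-rows$r2, rows$rmse, rows$lambda1, rows$lambda2)
  } else {
    order(rows$rmse, -rows$r2, rows$lambda1, rows$lambda2)
  }
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "overall") <- rows[1, , drop = FALSE]
  attr(rows, "criterion") <- criterion
  class(rows) <- c("calibration_results", "data.frame")
  rows
}

#' Compare R2-maximizing and RMSE-minimizing selection
#'
#' Selects the optimum of each map under both criteria and reports the
#' wavelength displacement between them, the robustness check that the two
#' rules usually agree to within a nanometer.
#'
#' @param maps A `metric_map` or list of them.
#' @return Data frame with, per map, the optima under both criteria and
#'   `shift1_nm`/`shift2_nm` displacements.
#' @export
compare_criteria <- function(maps) {
  if (inherits(maps, "metric_map")) maps <- list(maps)
  do.call(rbind, lapply(maps, function(m) {
    by_r2 <- best_cell(m, "r2")
    by_rmse <- best_cell(m, "rmse")
    data.frame(
      formula = m$formula, pigment = m$pigment,
      dl1 = m$dl1, dl2 = m$dl2,
      lambda1_r2 = by_r2$lambda1, lambda2_r2 = by_r2$lambda2,
      lambda1_rmse = by_rmse$lambda1, lambda2_rmse = by_rmse$lambda2,
      shift1_nm = abs(by_r2$lambda1 - by_rmse$lambda1),
      shift2_nm = abs(by_r2$lambda2 - by_rmse$lambda2),
      dr2 = abs(by_r2$r2 - by_rmse$r2),
      drmse = abs(by_r2$rmse - by_rmse$rmse),
      stringsAsFactors = FALSE
    )
  }))
}

#' Exhaustive band optimization
#'
#' Runs the full search: every formula in the configuration, every bandwidth
#' pair, every ordered wavelength pair; then selects optima. This is the
#' complete calibration-design engine; with the default 1 nm grid it
#' evaluates 250,500 wavelength pairs per (formula, bandwidth-pair)
#' combination.
#'
#' @param samples A `sample_set`.
#' @param pigment `"chl"` or `"car"`.
#' @param grid A [grid_config()].
#' @param criterion Selection criterion, see [select_optimal()].
#' @param keep_maps Keep all metric maps in the result (memory-hungry at
#'   full grid scale; default `FALSE`).
#' @param aux_fwhm,aux_centers Auxiliary-band settings, see
#'   [evaluate_map()].
#' @return A list with `results` (a `calibration_results` data frame over
#'   all formula/bandwidth combinations), `overall` (its best row),
#'   `n_configs` (total configurations evaluated) and optionally `maps`.
#' @examples
#' ss <- simulate_samples(12, seed = 1, noise = "none",
#'                        grid = seq(450, 950, 10))
#' opt <- optimize_bands(ss, "chl",
#'                       grid_config(step = 10, bandwidths = 10,
#'                                   formulas = "NDVI"))
#' opt$overall
#' @export
optimize_bands <- function(samples, pigment = c("chl", "car"),
                           grid = grid_config(),
                           criterion = c("r2", "rmse"),
                           keep_maps = FALSE,
                           aux_fwhm = NULL, aux_centers = NULL) {
  pigment <- match.arg(pigment)
  criterion <- match.arg(criterion)
  pairs <- bandwidth_pairs(grid)
  rows <- list()
  maps <- if (keep_maps) list() else NULL
  n_configs <- 0L
  for (f in grid$formulas) {
    for (p in seq_len(nrow(pairs))) {
      map <- evaluate_map(samples, pigment, f,
                          dl1 = pairs[p, 1], dl2 = pairs[p, 2],
                          grid = grid, aux_fwhm = aux_fwhm,
                          aux_centers = aux_centers)
      n_configs <- n_configs + sum(lower.tri(map$r2) | upper.tri(map$r2))
      key <- sprintf("%s_%g_%g", f, pairs[p, 1], pairs[p, 2])
      rows[[key]] <- best_cell(map, criterion)
      if (keep_maps) maps[[key]] <- map
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  ord <- if (criterion == "r2") {
    order(-res$r2, res$rmse, res$lambda1, res$lambda2)
  } else {
    order(res$rmse, -res$r2, res$lambda1, res$lambda2)
  }
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("calibration_results", "data.frame")
  out <- list(results = res, overall = res[1, , drop = FALSE],
              n_configs = n_configs, criterion = criterion, grid = grid)
  if (keep_maps) out$maps <- maps
  out
}

#' Serialize calibration results to JSON
#'
#' @param results A `calibration_results` data frame (or any data frame with
#'   the standard columns).
#' @param path Output path.
#' @export
write_calibration_json <- function(results, path) {
  jsonlite::write_json(as.data.frame(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
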