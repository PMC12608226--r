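#' Fit the exponential pigment~index calibration
#'
#' Fits the two-parameter saturating calibration y = a * exp(b * x), where y
#' is the pigment concentration (mg/L) and x a vegetation index value. The
#' primary fit is closed-form least squares of ln(y) on x (exact on
#' noiseless exponential data and fast enough for full metric maps); an
#' optional refinement re-fits a and b by nonlinear least squares in the
#' original concentration space starting from the log-linear solution.
#' Pairs with non-finite index values or non-positive concentrations are
#' excluded and counted.
#'
#' @param vi Numeric vector of index values.
#' @param pigment Numeric vector of concentrations (mg/L), same length.
#' @param refine Logical; refine in original space with
#'   [minpack.lm::nlsLM()] (default `FALSE`).
#' @return An object of class `exp_model`: list with `a`, `b`, `n_valid`,
#'   `n_dropped`, `refined`.
#' @examples
#' x <- seq(0, 1, 0.1)
#' fit_exponential(x, 2 * exp(3 * x))
#' @export
fit_exponential <- function(vi, pigment, refine = FALSE) {
  stopifnot(length(vi) == length(pigment))
  ok <- is.finite(vi) & is.finite(pigment) & pigment > 0
  x <- vi[ok]
  y <- pigment[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 valid (vi, pigment) pairs, got ", n)
  if (max(x) - min(x) == 0) stop("zero variance in vi: cannot calibrate")
  z <- log(y)
  xc <- x - mean(x)
  b <- sum(xc * (z - mean(z))) / sum(xc^2)
  log_a <- mean(z) - b * mean(x)
  a <- exp(log_a)
  refined <- FALSE
  if (refine && is.finite(a) && a > 0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x),
                        start = list(a = a, b = b),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      a <- unname(cf["a"])
      b <- unname(cf["b"])
      log_a <- log(a)
      refined <- TRUE
    }
  }
  structure(list(a = a, b = b, log_a = log_a, n_valid = n,
                 n_dropped = sum(!ok), refined = refined),
            class = "exp_model")
}

#' @export
print.exp_model <- function(x, ...) {
  cat(sprintf("<exp_model> y = %.6g * exp(%.6g * x)  (n = %d%s)\n",
              x$a, x$b, x$n_valid, if (x$refined) ", refined" else ""))
  invisible(x)
}

#' @export
predict.exp_model <- function(object, newdata, ...) {
  # exp(log a + b x) rather than a * exp(b x): immune to overflow of a
  # when b is large and the data are far from the origin
  log_a <- object$log_a %||% log(object$a)
  exp(log_a + object$b * newdata)
}

#' Calibration performance metrics
#'
#' Evaluates a fitted exponential calibration in the original concentration
#' space: coefficient of determination
#' R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2), root-mean-square error
#' RMSE = sqrt(mean((yhat - y)^2)) in mg/L, and the mean relative error
#' RE = mean(|yhat - y|) * 100 / ybar in percent (one aggregate percentage
#' per model, normalized by the mean measured concentration). With
#' `literal = TRUE` two historically used variants are returned instead:
#' an uncentered first-order R2 ratio sum(yhat - ybar)/sum(y - ybar) and an
#' RMSE computed about ybar; these are for auditing alternative definitions
#' only.
#'
#' @param model An `exp_model` from [fit_exponential()].
#' @param vi,pigment The data to evaluate on (same validity rules as the
#'   fit).
#' @param literal Use the non-standard literal metric variants (default
#'   `FALSE`).
#' @return List with `r2`, `rmse`, `re_percent`, `n`. If the measured
#'   concentrations have zero variance, `r2` is `NA` and a warning is
#'   raised.
#' @examples
#' x <- seq(0, 1, 0.1); y <- 2 * exp(3 * x)
#' m <- fit_exponential(x, y)
#' evaluate_metrics(m, x, y)
#' @export
evaluate_metrics <- function(model, vi, pigment, literal = FALSE) {
  stopifnot(inherits(model, "exp_model"), length(vi) == length(pigment))
  ok <- is.finite(vi) & is.finite(pigment) & pigment > 0
  x <- vi[ok]
  y <- pigment[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 valid pairs to evaluate, got ", n)
  yhat <- predict(model, x)
  ybar <- mean(y)
  sstot <- sum((y - ybar)^2)
  if (literal) {
    r2 <- if (sum(y - ybar) == 0) NA_real_ else
      sum(yhat - ybar) / sum(y - ybar)
    rmse <- sqrt(sum((yhat - ybar)^2) / n)
  } else {
    if (sstot == 0) {
      warning("zero variance in measured pigment: R2 undefined")
      r2 <- NA_real_
    } else {
      r2 <- 1 - sum((y - yhat)^2) / sstot
    }
    rmse <- sqrt(sum((yhat - y)^2) / n)
  }
  re <- mean(abs(yhat - y)) * 100 / ybar
  list(r2 = r2, rmse = rmse, re_percent = re, n = n)
}

# internal: fit + evaluate in one step, returning a flat row
fit_and_evaluate <- function(vi, pigment, refine = FALSE) {
  m <- fit_exponential(vi, pigment, refine = refine)
  met <- evaluate_metrics(m, vi, pigment)
  c(list(a = m$a, b = m$b), met)
}
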