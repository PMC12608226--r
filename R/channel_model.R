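#' Spectral channel specification
#'
#' A sensor channel is modeled as a Gaussian transmission function with a
#' central wavelength (nm) and a bandwidth given as full width at half
#' maximum (FWHM, nm).
#'
#' @param center Central wavelength in nm, within \[450, 950\].
#' @param fwhm Bandwidth (FWHM) in nm, > 0.
#' @return An object of class `channel_spec`.
#' @examples
#' channel_spec(670, 10)
#' @export
channel_spec <- function(center, fwhm) {
  if (!is.finite(center) || center < 450 || center > 950) {
    stop("`center` must be within [450, 950] nm")
  }
  if (!is.finite(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  structure(list(center = center, fwhm = fwhm), class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel> center %g nm, FWHM %g nm\n", x$center, x$fwhm))
  invisible(x)
}

#' Convert FWHM to Gaussian standard deviation
#'
#' Uses the exact relation sigma = FWHM / (2 sqrt(2 ln 2)).
#'
#' @param fwhm Full width at half maximum, nm.
#' @return Standard deviation in nm.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian channel weights on a wavelength grid
#'
#' Evaluates the channel's Gaussian transmission on a uniform grid, truncated
#' at ±4 sigma (clipped to the grid bounds) and normalized to sum to one.
#' Channels whose truncation window is partially clipped by the grid boundary
#' are renormalized over the visible part rather than excluded, so channels
#' sitting on the 450/950 nm edges remain usable.
#'
#' @param channel A [channel_spec()].
#' @param grid Uniform numeric wavelength grid in nm.
#' @return Numeric weight vector aligned with `grid` (zero outside the
#'   truncation window) summing to one.
#' @export
gaussian_weights <- function(channel, grid) {
  stopifnot(inherits(channel, "channel_spec"))
  grid_step(grid)  # uniformity check
  sig <- fwhm_to_sigma(channel$fwhm)
  inside <- abs(grid - channel$center) <= 4 * sig
  if (!any(inside)) {
    stop("channel support (center ", channel$center, " nm, FWHM ",
         channel$fwhm, " nm) lies entirely outside the wavelength grid")
  }
  w <- numeric(length(grid))
  w[inside] <- exp(-(grid[inside] - channel$center)^2 / (2 * sig^2))
  w / sum(w)
}

#' Band-integrated reflectance
#'
#' The reflectance a sensor channel would record: the spectrum weighted by
#' the channel's normalized Gaussian transmission and summed over the grid
#' (a convex combination of the reflectances within the channel support).
#'
#' @param spectrum A `spectra` object on a uniform grid covering the
#'   channel's truncated support.
#' @param channel A [channel_spec()].
#' @return Named numeric vector, one band reflectance per sample.
#' @examples
#' sp <- spectra(450:950, matrix(runif(501), ncol = 1))
#' band_reflectance(sp, channel_spec(680, 30))
#' @export
band_reflectance <- function(spectrum, channel) {
  stopifnot(inherits(spectrum, "spectra"))
  w <- gaussian_weights(channel, spectrum$wavelength)
  drop(crossprod(spectrum$values, w))
}

# internal: band reflectance for many centers at one FWHM.
# Returns matrix [centers x samples]; rows are normalized weight vectors.
band_matrix <- function(spectrum, centers, fwhm) {
  grid <- spectrum$wavelength
  grid_step(grid)
  sig <- fwhm_to_sigma(fwhm)
  d <- outer(centers, grid, "-")
  w <- exp(-d^2 / (2 * sig^2))
  w[abs(d) > 4 * sig] <- 0
  rs <- rowSums(w)
  if (any(rs == 0)) {
    stop("some channel centers have no support on the wavelength grid")
  }
  (w / rs) %*% spectrum$values
}

#' Instrument channel presets
#'
#' Named channel configurations of published VI-based instruments (handheld
#' leaf-clip sensors through hyperspectral imagers), for comparing the
#' package's optimized channels with deployed hardware. Shipped as a JSON
#' file under `inst/extdata`.
#'
#' @param path Optional path to an alternative preset JSON file.
#' @return Data frame with columns `instrument`, `model`, `vi`,
#'   `center1_nm`, `fwhm1_nm`, `center2_nm`, `fwhm2_nm`.
#' @export
instrument_presets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "instruments.json",
                                package = "viband", mustWork = TRUE)
  df <- jsonlite::fromJSON(path)
  as.data.frame(df, stringsAsFactors = FALSE)
}
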