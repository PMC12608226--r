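#' Reflectance from raw radiance
#'
#' Divides the spectral radiance measured on the leaf by that of the
#' uniformly reflecting reference panel, sample by sample. Both inputs must
#' be on the identical wavelength grid. If the reference has a single sample
#' column it is recycled across all object samples.
#'
#' @param i_obj `spectra` of leaf radiance counts.
#' @param i_ref `spectra` of reference-panel radiance counts; all values must
#'   be strictly positive.
#' @return A `spectra` object of reflectance values.
#' @export
compute_reflectance <- function(i_obj, i_ref) {
  stopifnot(inherits(i_obj, "spectra"), inherits(i_ref, "spectra"))
  if (!isTRUE(all.equal(i_obj$wavelength, i_ref$wavelength))) {
    stop("object and reference spectra are on different wavelength grids")
  }
  if (any(i_ref$values <= 0)) {
    stop("reference radiance must be strictly positive everywhere")
  }
  ref <- i_ref$values
  if (ncol(ref) == 1L && n_samples(i_obj) > 1L) {
    ref <- ref[, rep(1L, n_samples(i_obj)), drop = FALSE]
  }
  if (ncol(ref) != n_samples(i_obj)) {
    stop("reference must have 1 sample or as many as the object spectra")
  }
  spectra(i_obj$wavelength, i_obj$values / ref, sample_id = i_obj$sample_id)
}

#' Gaussian smoothing of spectra
#'
#' Convolves each spectrum with a normalized Gaussian kernel of standard
#' deviation `sigma` (in nm, converted to grid samples), the standard
#' high-frequency denoising step before index computation. The kernel is
#' truncated at ±4 sigma and renormalized; boundaries are handled by
#' reflection so the 450/950 nm ends are not attenuated. `sigma = 0` is the
#' identity.
#'
#' @param x A `spectra` object on a uniform grid.
#' @param sigma Kernel standard deviation in nm (default 20).
#' @return A smoothed `spectra` object on the same grid.
#' @export
gaussian_smooth <- function(x, sigma = 20) {
  stopifnot(inherits(x, "spectra"))
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(x)
  step <- grid_step(x$wavelength)
  sigma_pts <- sigma / step
  half <- ceiling(4 * sigma_pts)
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_pts^2))
  k <- k / sum(k)
  n <- length(x$wavelength)
  if (half >= n) {
    stop("kernel half-width (", half, " samples) exceeds spectrum length")
  }
  # reflect-pad: mirror without repeating the edge sample
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  sm <- apply(x$values, 2L, function(v) {
    padded <- v[idx]
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1L):(half + n)]
  })
  spectra(x$wavelength, sm, sample_id = x$sample_id)
}

#' Resample spectra onto a uniform wavelength grid
#'
#' Linear interpolation of each sample onto `seq(start, stop, by = step)`.
#' The input grid must span the requested range. Already-conforming input is
#' returned unchanged up to floating point, making the operation idempotent.
#'
#' @param x A `spectra` object.
#' @param start,stop,step Target grid in nm; defaults give the 501-point
#'   450–950 nm grid used throughout the package.
#' @return A `spectra` object on the target grid.
#' @export
resample_to_grid <- function(x, start = 450, stop = 950, step = 1) {
  stopifnot(inherits(x, "spectra"), start < stop, step > 0)
  grid <- seq(start, stop, by = step)
  if (min(x$wavelength) > start || max(x$wavelength) < stop) {
    stop("input grid [", min(x$wavelength), ", ", max(x$wavelength),
         "] does not span the requested range [", start, ", ", stop, "]")
  }
  vals <- apply(x$values, 2L, function(v) {
    approx(x$wavelength, v, xout = grid, method = "linear")$y
  })
  spectra(grid, vals, sample_id = x$sample_id)
}
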