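#' Spectra container
#'
#' A `spectra` object stores one or more spectra sampled on a common,
#' strictly increasing wavelength grid: reflectance (dimensionless) or raw
#' radiance counts, one column per sample.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Numeric matrix (rows = wavelengths, columns = samples) or a
#'   vector for a single sample. All values must be finite.
#' @param sample_id Character vector of sample labels (defaults to
#'   `"S1"`, `"S2"`, ...).
#'
#' @return An object of class `spectra`: a list with elements `wavelength`,
#'   `values` (matrix) and `sample_id`.
#' @examples
#' sp <- spectra(450:950, matrix(runif(501 * 2), 501, 2))
#' n_samples(sp)
#' @export
spectra <- function(wavelength, values, sample_id = NULL) {
  wavelength <- as.numeric(wavelength)
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(wavelength) != nrow(values)) {
    stop("`wavelength` length (", length(wavelength),
         ") does not match rows of `values` (", nrow(values), ")")
  }
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing with at least 2 points")
  }
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(ncol(values)))
  if (length(sample_id) != ncol(values)) {
    stop("`sample_id` length does not match number of sample columns")
  }
  colnames(values) <- sample_id
  structure(list(wavelength = wavelength, values = values,
                 sample_id = as.character(sample_id)),
            class = "spectra")
}

#' @rdname spectra
#' @param x A `spectra` object.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spectra"))
  ncol(x$values)
}

#' @export
print.spectra <- function(x, ...) {
  rng <- range(x$wavelength)
  cat(sprintf("<spectra> %d samples, %d wavelengths (%g-%g nm)\n",
              n_samples(x), length(x$wavelength), rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.spectra <- function(x, ...) {
  data.frame(
    sample_id = rep(x$sample_id, each = length(x$wavelength)),
    wavelength_nm = rep(x$wavelength, times = n_samples(x)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

# internal: grid step with uniformity check
grid_step <- function(wavelength, tol = 1e-8) {
  d <- diff(wavelength)
  if (diff(range(d)) > tol * max(d)) stop("wavelength grid is not uniform")
  d[1]
}

#' Read and write spectra as CSV
#'
#' Wide format: first column `wavelength_nm`, one column per sample. Long
#' format: columns `sample_id`, `wavelength_nm`, `value`.
#'
#' @param x A `spectra` object.
#' @param path Path to a CSV file.
#' @return `read_*` return a `spectra` object; `write_*` return `path`
#'   invisibly.
#' @export
write_spectra_wide <- function(x, path) {
  stopifnot(inherits(x, "spectra"))
  df <- data.frame(wavelength_nm = x$wavelength, x$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_wide
#' @export
read_spectra_wide <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("wide spectra CSV must start with a `wavelength_nm` column")
  }
  spectra(df[[1]], as.matrix(df[-1]), sample_id = names(df)[-1])
}

#' @rdname write_spectra_wide
#' @export
write_spectra_long <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_wide
#' @export
read_spectra_long <- function(path) {
  df <- read.csv(path)
  need <- c("sample_id", "wavelength_nm", "value")
  if (!all(need %in% names(df))) {
    stop("long spectra CSV needs columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(df$sample_id)
  wl <- sort(unique(df$wavelength_nm))
  m <- matrix(NA_real_, length(wl), length(ids),
              dimnames = list(NULL, ids))
  for (id in ids) {
    sub <- df[df$sample_id == id, ]
    sub <- sub[order(sub$wavelength_nm), ]
    if (!isTRUE(all.equal(sub$wavelength_nm, wl))) {
      stop("sample ", id, " is not on the common wavelength grid")
    }
    m[, id] <- sub$value
  }
  spectra(wl, m, sample_id = as.character(ids))
}

#' Read a raw radiance pair (object and reference panel)
#'
#' Convenience reader for two wide CSV files of radiance counts measured for
#' the leaf (`obj_path`) and the uniformly reflecting reference panel
#' (`ref_path`), as used by [compute_reflectance()].
#'
#' @param obj_path,ref_path Paths to wide-format radiance CSVs.
#' @return A list with `spectra` elements `i_obj` and `i_ref`.
#' @export
read_radiance_pair <- function(obj_path, ref_path) {
  list(i_obj = read_spectra_wide(obj_path),
       i_ref = read_spectra_wide(ref_path))
}

#' Read and write per-sample pigment tables
#'
#' CSV columns: `sample_id`, `chl_mg_per_l`, `car_mg_per_l`.
#'
#' @param pigments Data frame with columns `sample_id`, `chl`, `car`
#'   (mg/L).
#' @param path Path to a CSV file.
#' @export
write_pigments <- function(pigments, path) {
  stopifnot(all(c("sample_id", "chl", "car") %in% names(pigments)))
  out <- data.frame(sample_id = pigments$sample_id,
                    chl_mg_per_l = pigments$chl,
                    car_mg_per_l = pigments$car)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pigments
#' @export
read_pigments <- function(path) {
  df <- read.csv(path)
  need <- c("sample_id", "chl_mg_per_l", "car_mg_per_l")
  if (!all(need %in% names(df))) {
    stop("pigment CSV needs columns: ", paste(need, collapse = ", "))
  }
  data.frame(sample_id = as.character(df$sample_id),
             chl = df$chl_mg_per_l, car = df$car_mg_per_l,
             stringsAsFactors = FALSE)
}
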