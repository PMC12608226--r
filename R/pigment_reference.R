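#' Spectrophotometric reference coefficients
#'
#' Coefficients of the empirical equations converting ethanol-extract optical
#' densities to total chlorophyll and carotenoid concentrations (mg/L):
#' \deqn{Chl = 6.1 \cdot D_{665} + 20.04 \cdot D_{649}}
#' \deqn{Car = 4.695 \cdot D_{440.5} - 0.268 \cdot Chl}
#' These are fixed constants of the reference method; override only to model
#' a different extraction protocol.
#'
#' @param chl_d665,chl_d649 Multipliers of D665 and D649 in the chlorophyll
#'   equation.
#' @param car_d440,car_chl Multiplier of D440.5 and the chlorophyll
#'   correction term in the carotenoid equation.
#' @return A named list of the four coefficients.
#' @export
reference_coefficients <- function(chl_d665 = 6.1, chl_d649 = 20.04,
                                   car_d440 = 4.695, car_chl = 0.268) {
  list(chl_d665 = chl_d665, chl_d649 = chl_d649,
       car_d440 = car_d440, car_chl = car_chl)
}

#' Pigment concentrations from extract optical densities
#'
#' `chl_from_od()` applies the total-chlorophyll equation; `car_from_od()`
#' applies the carotenoid equation, which subtracts a chlorophyll term and can
#' therefore return negative values for inconsistent inputs. Negative results
#' are returned as-is with a warning so that calibration code sees the raw
#' behaviour of the formula (silent clipping would bias round-trip checks).
#'
#' @param d665,d649,d440_5 Optical densities (dimensionless, >= 0) of the
#'   extract at 665, 649 and 440.5 nm. Vectorized.
#' @param chl Total chlorophyll concentration in mg/L (>= 0), typically from
#'   `chl_from_od()`.
#' @param coef Coefficient set from [reference_coefficients()].
#' @return Concentration(s) in mg/L.
#' @examples
#' chl <- chl_from_od(0.5, 0.25)   # 8.06 mg/L
#' car_from_od(2, chl)
#' @export
chl_from_od <- function(d665, d649, coef = reference_coefficients()) {
  if (any(!is.finite(d665)) || any(!is.finite(d649)) ||
      any(d665 < 0) || any(d649 < 0)) {
    stop("optical densities must be finite and non-negative")
  }
  coef$chl_d665 * d665 + coef$chl_d649 * d649
}

#' @rdname chl_from_od
#' @export
car_from_od <- function(d440_5, chl, coef = reference_coefficients()) {
  if (any(!is.finite(d440_5)) || any(!is.finite(chl)) ||
      any(d440_5 < 0) || any(chl < 0)) {
    stop("optical density and chlorophyll must be finite and non-negative")
  }
  car <- coef$car_d440 * d440_5 - coef$car_chl * chl
  if (any(car < 0)) {
    warning("carotenoid formula returned negative value(s); ",
            "inputs are inconsistent with the reference method")
  }
  car
}

#' Apply the reference equations to a table of optical densities
#'
#' Takes a data frame with columns `sample_id`, `d440_5`, `d649`, `d665`
#' (e.g. from [read_ods()]) and returns the pigment table in the package's
#' standard layout.
#'
#' @param ods Data frame of optical densities.
#' @param coef Coefficient set from [reference_coefficients()].
#' @return Data frame with columns `sample_id`, `chl`, `car` (mg/L).
#' @export
pigments_from_ods <- function(ods, coef = reference_coefficients()) {
  stopifnot(all(c("d440_5", "d649", "d665") %in% names(ods)))
  chl <- chl_from_od(ods$d665, ods$d649, coef)
  car <- car_from_od(ods$d440_5, chl, coef)
  data.frame(sample_id = ods$sample_id %||% paste0("S", seq_along(chl)),
             chl = chl, car = car, stringsAsFactors = FALSE)
}

#' Read and write extract optical-density tables
#'
#' CSV columns: `sample_id`, `d440_5`, `d649`, `d665`.
#'
#' @param ods Data frame of optical densities.
#' @param path Path to a CSV file.
#' @export
write_ods <- function(ods, path) {
  stopifnot(all(c("sample_id", "d440_5", "d649", "d665") %in% names(ods)))
  write.csv(ods[, c("sample_id", "d440_5", "d649", "d665")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_ods
#' @export
read_ods <- function(path) {
  df <- read.csv(path)
  need <- c("sample_id", "d440_5", "d649", "d665")
  if (!all(need %in% names(df))) {
    stop("OD CSV needs columns: ", paste(need, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df
}
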