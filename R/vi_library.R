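#' Vegetation index formula registry
#'
#' The seven two-band vegetation index forms the package searches over:
#' Simple Ratio (SR), Difference Index (DI), Modified Simple Ratio (mSR),
#' Modified Normalized Difference Index (mNDI), Triangular Vegetation Index
#' (TVI), Soil-Adjusted Vegetation Index (SAVI) and the Normalized Difference
#' Vegetation Index (NDVI). All are functions of two searched band
#' reflectances rho1, rho2; mSR and mNDI additionally use a fixed auxiliary
#' band (default 445 nm), TVI a fixed green band (default 550 nm). The
#' auxiliary centers are configurable; the optimizer searches only the two
#' (lambda1, lambda2) slots, matching the two-column schema in which optimal
#' configurations are conventionally reported.
#'
#' @return Data frame with columns `name`, `expression`, `aux_center_nm`
#'   (NA where no auxiliary band is used) and `constants`.
#' @examples
#' vi_formulas()
#' @export
vi_formulas <- function() {
  data.frame(
    name = c("SR", "DI", "mSR", "mNDI", "TVI", "SAVI", "NDVI"),
    expression = c(
      "rho1 / rho2",
      "rho1 - rho2",
      "(rho1 - rhoA) / (rho2 - rhoA)",
      "(rho1 - rho2) / (rho1 + rho2 - 2*rhoA)",
      "0.5 * (120*(rho2 - rhoG) - 200*(rho1 - rhoG))",
      "(1 + L) * (rho1 - rho2) / (rho1 + rho2 + L)",
      "(rho1 - rho2) / (rho1 + rho2)"
    ),
    aux_center_nm = c(NA, NA, 445, 445, 550, NA, NA),
    constants = c("", "", "", "", "coef 120, 200, 0.5", "L = 0.5", ""),
    stringsAsFactors = FALSE
  )
}

# internal: auxiliary band center for a formula (NA if none)
vi_aux_center <- function(name, aux_centers = NULL) {
  reg <- vi_formulas()
  default <- reg$aux_center_nm[match(name, reg$name)]
  if (!is.null(aux_centers) && name %in% names(aux_centers)) {
    return(aux_centers[[name]])
  }
  default
}

#' Compute a two-band vegetation index
#'
#' Evaluates one of the seven registered index formulas from band
#' reflectances. Inputs are vectorized (vectors or matrices of identical
#' shape); `rho_aux` may be a scalar. Any denominator with magnitude below
#' `guard` yields `NA` (an invalid-cell marker the optimizer can mask) rather
#' than an infinite value.
#'
#' @param name Formula name, one of `vi_formulas()$name`.
#' @param rho1,rho2 Band reflectances of the two searched channels, in
#'   \[0, 1\].
#' @param rho_aux Auxiliary band reflectance, required for mSR, mNDI (445 nm
#'   band) and TVI (550 nm green band).
#' @param savi_l Soil adjustment factor L of SAVI (default 0.5).
#' @param guard Denominator magnitude below which the result is `NA`
#'   (default 1e-9).
#' @return Index value(s), same shape as `rho1`.
#' @examples
#' compute_vi("NDVI", 0.5, 0.25)
#' compute_vi("SAVI", 0.5, 0.25)          # 0.3
#' compute_vi("mNDI", 0.5, 0.25, rho_aux = 0.05)
#' @export
compute_vi <- function(name, rho1, rho2, rho_aux = NULL,
                       savi_l = 0.5, guard = 1e-9) {
  if (!name %in% vi_formulas()$name) {
    stop("unknown vegetation index formula: ", name)
  }
  if (name %in% c("mSR", "mNDI", "TVI") && is.null(rho_aux)) {
    stop(name, " requires an auxiliary band reflectance `rho_aux`")
  }
  div <- function(num, den) {
    out <- num / den
    out[abs(den) < guard] <- NA_real_
    out
  }
  switch(name,
    SR   = div(rho1, rho2),
    DI   = rho1 - rho2,
    NDVI = div(rho1 - rho2, rho1 + rho2),
    mSR  = div(rho1 - rho_aux, rho2 - rho_aux),
    mNDI = div(rho1 - rho2, rho1 + rho2 - 2 * rho_aux),
    TVI  = 0.5 * (120 * (rho2 - rho_aux) - 200 * (rho1 - rho_aux)),
    SAVI = div((1 + savi_l) * (rho1 - rho2), rho1 + rho2 + savi_l)
  )
}
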