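#' Maximum quantum yield of PSII from dark-adapted fluorescence
#'
#' `phi_max = (FM - FO) / FM`, with `FM` the maximal fluorescence during a
#' saturating pulse on dark-acclimated plants and `FO` the dark
#' fluorescence. Scale-invariant: multiplying both inputs by a constant
#' leaves the result unchanged.
#'
#' @param FM,FO fluorescence values (vectors recycle).
#' @return Numeric, in `[0, 1]` when `0 <= FO <= FM`.
#' @export
phi_max <- function(FM, FO) {
  if (any(FM <= 0)) stop("FM must be > 0")
  (FM - FO) / FM
}

#' Operating quantum yield of PSII at a light step
#'
#' `phi_psii = (FM' - FS) / FM'`, with `FM'` the maximal fluorescence at the
#' end of a light step and `FS` the steady-state fluorescence. `FS > FM'`
#' yields a negative value, physically a measurement anomaly; it is returned
#' with a warning rather than suppressed.
#'
#' @param FM_prime,FS fluorescence values (vectors recycle).
#' @return Numeric yield; negative entries flagged by a warning.
#' @export
phi_psii <- function(FM_prime, FS) {
  if (any(FM_prime <= 0)) stop("FM_prime must be > 0")
  out <- (FM_prime - FS) / FM_prime
  if (any(out < 0)) {
    warning(sum(out < 0), " value(s) with FS > FM': negative yield, ",
            "likely a measurement anomaly")
  }
  out
}

#' Two-wavelength chlorophyll coefficients
#'
#' Linear-form coefficients for total chlorophyll from absorbances at 664
#' and 647 nm: `chl_a = a664 * A664 - a647 * A647` and
#' `chl_b = b647 * A647 - b664 * A664` (ug/ml per absorbance unit). The
#' shipped defaults are the standard values for
#' N,N-dimethylformamide extracts; they are configuration, to be replaced
#' for other solvents.
#'
#' @param a664,a647,b647,b664 positive coefficients.
#' @return Named list of class `chl_coefficients`.
#' @export
chl_coefficients <- function(a664 = 12.00, a647 = 3.11,
                             b647 = 20.78, b664 = 4.88) {
  vals <- c(a664 = a664, a647 = a647, b647 = b647, b664 = b664)
  if (any(vals <= 0)) stop("all chlorophyll coefficients must be > 0")
  structure(as.list(vals), class = "chl_coefficients")
}

#' Total chlorophyll per unit fresh weight
#'
#' Chlorophyll a + b from the two-wavelength linear forms, scaled by the
#' extraction volume per mg fresh weight. With coefficients in ug/ml per
#' absorbance unit and `volume_per_mg` in ul/mg, the result is in ng per mg
#' fresh weight.
#'
#' @param A664,A647 absorbances (>= 0, vectors recycle).
#' @param coeffs [chl_coefficients()].
#' @param volume_per_mg extraction volume in ul per mg fresh weight.
#' @return Total chlorophyll concentration (ng/mg fresh weight).
#' @export
chlorophyll_total <- function(A664, A647, coeffs = chl_coefficients(),
                              volume_per_mg = 10) {
  if (!inherits(coeffs, "chl_coefficients")) {
    stop("coeffs must come from chl_coefficients(); ",
         "supply solvent-appropriate values there")
  }
  if (any(A664 < 0) || any(A647 < 0)) stop("absorbances must be >= 0")
  chl_a <- coeffs$a664 * A664 - coeffs$a647 * A647
  chl_b <- coeffs$b647 * A647 - coeffs$b664 * A664
  (chl_a + chl_b) * volume_per_mg
}
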