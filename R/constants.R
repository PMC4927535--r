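#' Physical constants of the activity-coefficient and temperature model
#'
#' Bundles the fixed coefficients of the extended Debye-Hueckel / SIT
#' ionic-strength model and of the Clarke-Glew temperature expansion.
#' All downstream evaluations take a `model_constants` object so that the
#' conventional values can be overridden in one place.
#'
#' @param A_debye Debye-Hueckel slope multiplying `sqrt(I)` (dimensionless,
#'   default 0.51, treated as temperature independent).
#' @param B_factor coefficient of `sqrt(I)` in the Debye-Hueckel denominator
#'   (default 1.5).
#' @param CG_factor Clarke-Glew multiplier converting the enthalpic term to
#'   log10 units, in K mol kJ^-1 (default 52.23).
#' @param theta reference temperature in K (default 298.15).
#' @param dh_enthalpy_coeff Debye-Hueckel limiting coefficient of the
#'   protonation-enthalpy ionic-strength correction, in kJ mol^-1 per unit
#'   `z*` (default 1.5).
#'
#' @return An object of class `model_constants`.
#' @examples
#' cst <- model_constants()
#' cst$A_debye
#' @export
model_constants <- function(A_debye = 0.51, B_factor = 1.5, CG_factor = 52.23,
                            theta = 298.15, dh_enthalpy_coeff = 1.5) {
  vals <- c(A_debye = A_debye, B_factor = B_factor, CG_factor = CG_factor,
            theta = theta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("A_debye, B_factor, CG_factor and theta must be finite and positive")
  if (!is.finite(dh_enthalpy_coeff))
    stop("dh_enthalpy_coeff must be finite")
  structure(list(A_debye = A_debye, B_factor = B_factor,
                 CG_factor = CG_factor, theta = theta,
                 dh_enthalpy_coeff = dh_enthalpy_coeff),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Model constants:\n")
  cat(sprintf("  A (DH slope)          %.4g\n", x$A_debye))
  cat(sprintf("  B (DH denominator)    %.4g\n", x$B_factor))
  cat(sprintf("  Clarke-Glew factor    %.4g K mol/kJ\n", x$CG_factor))
  cat(sprintf("  theta (reference T)   %.2f K\n", x$theta))
  cat(sprintf("  DH enthalpy coeff.    %.4g kJ/mol per z*\n",
              x$dh_enthalpy_coeff))
  invisible(x)
}

.check_I <- function(I) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("ionic strength I must be finite and >= 0")
  invisible(I)
}
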