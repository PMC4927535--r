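#' Density model of an electrolyte solution
#'
#' Polynomial solution density `rho(c) = b0 + b1 c + b2 c^2` (kg dm^-3) as
#' a function of salt molarity at 298.15 K, together with the molar mass of
#' the salt. Used to convert between the molar (mol dm^-3) and molal
#' (mol kg^-1) concentration scales.
#'
#' @param medium medium identifier, e.g. `"nacl"`.
#' @param coef numeric vector of polynomial coefficients `(b0, b1, b2, ...)`
#'   in increasing powers of molarity.
#' @param molar_mass molar mass of the salt in g mol^-1.
#' @param c_max upper validity bound of the polynomial (mol dm^-3).
#' @param T temperature the coefficients refer to, K. Conversions at other
#'   temperatures emit a warning.
#' @return Object of class `density_model`.
#' @examples
#' dm <- density_model("nacl", c(0.99705, 0.04060, -0.00062), 58.443, 5.5)
#' molar_to_molal(1, dm)
#' @export
density_model <- function(medium, coef, molar_mass, c_max, T = 298.15) {
  rho0 <- coef[1]
  if (rho0 < 0.95 || rho0 > 1.05)
    stop("rho(0) = ", rho0, " is not a plausible water density (kg/dm^3)")
  cs <- seq(0, c_max, length.out = 64L)
  rho <- .poly_eval(coef, cs)
  if (any(diff(rho) < 0))
    stop("density must be monotone non-decreasing over [0, c_max]")
  structure(list(medium = medium, coef = coef, molar_mass = molar_mass,
                 c_max = c_max, T = T),
            class = "density_model")
}

.poly_eval <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("Density model for %s at %.2f K: rho(c) = %s (valid c <= %.2f)\n",
              x$medium, x$T,
              paste(signif(x$coef, 5), collapse = " + c*"), x$c_max))
  invisible(x)
}

.density_at <- function(density, c, T = 298.15) {
  if (any(c < 0)) stop("molarity must be >= 0")
  if (any(c > density$c_max))
    stop("molarity ", max(c), " outside validity range of the density model",
         " (c_max = ", density$c_max, ")")
  if (any(T != density$T))
    warning("density model is parameterised at ", density$T,
            " K; conversion at T = ", T, " K uses those coefficients")
  .poly_eval(density$coef, c)
}

#' Convert salt molarity to molality
#'
#' `m = c / (rho(c) - c M / 1000)` where the denominator is the mass of
#' water per litre of solution (kg dm^-3).
#'
#' @param c molarity, mol dm^-3 (vectorised).
#' @param density a [density_model()].
#' @param T temperature in K (checked against the density model).
#' @return Molality in mol kg^-1.
#' @export
molar_to_molal <- function(c, density, T = 298.15) {
  rho <- .density_at(density, c, T)
  denom <- rho - c * density$molar_mass / 1000
  if (any(denom <= 0))
    stop("non-physical conversion: solution density minus salt mass <= 0")
  c / denom
}

#' Convert salt molality to molarity
#'
#' Numerical inverse of [molar_to_molal()] by root finding over the
#' validity range of the density model.
#'
#' @param m molality, mol kg^-1 (vectorised).
#' @inheritParams molar_to_molal
#' @return Molarity in mol dm^-3.
#' @export
molal_to_molar <- function(m, density, T = 298.15) {
  if (any(m < 0)) stop("molality must be >= 0")
  m_max <- molar_to_molal(density$c_max, density, T)
  vapply(m, function(mi) {
    if (mi == 0) return(0)
    if (mi > m_max)
      stop("molality ", mi, " has no molar equivalent inside the validity ",
           "range (max ", signif(m_max, 6), " mol/kg)")
    stats::uniroot(function(cc) molar_to_molal(cc, density, T) - mi,
                   lower = 0, upper = density$c_max, tol = 1e-13)$root
  }, numeric(1))
}

#' Convert an equilibrium constant between concentration scales
#'
#' An equilibrium constant defined on species concentrations changes by the
#' factor `(m/c)^dn` when every concentration is re-expressed on the molal
#' scale, where `dn` is moles of product species minus moles of reactant
#' species and `m/c` is the scale ratio fixed by the supporting-electrolyte
#' density. Reactions with `dn = 0` are scale invariant.
#'
#' @param logK equilibrium constant in log10 units.
#' @param delta_n moles of products minus moles of reactants (solutes only).
#' @param c supporting-electrolyte molarity, mol dm^-3.
#' @param density a [density_model()].
#' @param direction `"molar_to_molal"` (default) or `"molal_to_molar"`.
#' @param T temperature in K.
#' @return Converted log10 constant.
#' @export
convert_logk_scale <- function(logK, delta_n, c, density,
                               direction = c("molar_to_molal",
                                             "molal_to_molar"),
                               T = 298.15) {
  direction <- match.arg(direction)
  if (delta_n == 0 || all(c == 0)) return(logK)
  m <- molar_to_molal(c, density, T)
  shift <- delta_n * log10(ifelse(c > 0, m / c, 1))
  if (direction == "molar_to_molal") logK + shift else logK - shift
}

#' Packaged density models
#'
#' Returns the density model shipped for a supported medium. The
#' coefficients are smooth approximations of solution densities at
#' 298.15 K, packaged so that scale conversions are reproducible and
#' editable; they are package-supplied values, not measured data.
#'
#' @param medium `"nacl"` or `"tmacl"`.
#' @return A [density_model()].
#' @export
aat_density <- function(medium = c("nacl", "tmacl")) {
  medium <- match.arg(tolower(medium), c("nacl", "tmacl"))
  d <- utils::read.csv(system.file("extdata", "densities.csv",
                                   package = "aathermo"),
                       stringsAsFactors = FALSE)
  row <- d[d$medium == medium, ]
  density_model(medium, c(row$b0, row$b1, row$b2), row$molar_mass, row$c_max)
}
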