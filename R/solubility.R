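#' Solubility model of an amino acid in a salt medium
#'
#' Stores the solubility of the neutral zwitterion in pure water and the
#' salting parameters governing its change with supporting-electrolyte
#' concentration. Two forms are supported: the constant-Setschenow law
#' `log S(m) = log S0 - k_m m` and the two-parameter hyperbolic law
#' `log S(m) = log S0 + (a_inf + (a0 - a_inf)/(1 + m)) m`, which reduces to
#' the former when `a0 = a_inf = -k_m`. Positive `k_m` means salting-out.
#'
#' @param ligand,medium identifiers.
#' @param logS0_total log10 total solubility in pure water (mol kg^-1 on
#'   the molal scale).
#' @param logS0_specific log10 solubility of the neutral species in pure
#'   water; defaults to `logS0_total` (for the ligands packaged here the
#'   two are indistinguishable).
#' @param k_m Setschenow coefficient, kg mol^-1. If supplied, `a_zero` and
#'   `a_inf` default to `-k_m`.
#' @param a_zero,a_inf salting parameters of the hyperbolic form,
#'   kg mol^-1.
#' @param scale `"molal"` (default) or `"molar"`.
#' @param ci optional named list of 95 % half-widths.
#' @return Object of class `solubility_model`.
#' @examples
#' leu <- solubility_model("leu", "nacl", logS0_total = -0.772, k_m = 0.088)
#' specific_solubility_at_salt(leu, 1)
#' @export
solubility_model <- function(ligand, medium, logS0_total,
                             logS0_specific = logS0_total,
                             k_m = NULL, a_zero = NULL, a_inf = NULL,
                             scale = c("molal", "molar"), ci = NULL) {
  scale <- match.arg(scale)
  if (is.null(k_m) && (is.null(a_zero) || is.null(a_inf)))
    stop("supply either k_m or both a_zero and a_inf")
  if (is.null(a_zero)) a_zero <- -k_m
  if (is.null(a_inf)) a_inf <- -k_m
  if (is.null(k_m)) k_m <- -a_inf
  stopifnot(is.finite(logS0_total), is.finite(logS0_specific),
            is.finite(k_m), is.finite(a_zero), is.finite(a_inf))
  structure(list(ligand = ligand, medium = medium, scale = scale,
                 logS0_total = logS0_total,
                 logS0_specific = logS0_specific,
                 k_m = k_m, a_zero = a_zero, a_inf = a_inf, ci = ci),
            class = "solubility_model")
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("Solubility model: %s in %s (%s scale)\n", x$ligand, x$medium,
              x$scale))
  cat(sprintf("  log S0 (total)    %7.3f\n", x$logS0_total))
  cat(sprintf("  log S0 (neutral)  %7.3f\n", x$logS0_specific))
  cat(sprintf("  k_m               %7.3f kg/mol", x$k_m))
  if (abs(x$a_zero - x$a_inf) > 1e-12)
    cat(sprintf("  (a0 %.3f, a_inf %.3f)", x$a_zero, x$a_inf))
  cat("\n")
  invisible(x)
}

#' Total solubility from the neutral-species solubility and pH
#'
#' `S_T = S0 (1 + 1/(K1 [H]) + K2 [H])`: the saturated solution contains,
#' besides the neutral zwitterion at its fixed activity, the aminoate anion
#' (dominant at high pH) and the protonated cation (dominant at low pH).
#' `S_T >= S0` for every pH, with the minimum near the isoelectric region.
#'
#' @param S0 solubility of the neutral species, mol kg^-1 (> 0).
#' @param logK1,logK2 stepwise protonation constants (log10) at the same
#'   conditions as `S0`.
#' @param pH numeric vector.
#' @return Total solubility, mol kg^-1.
#' @export
total_solubility <- function(S0, logK1, logK2, pH) {
  if (any(S0 <= 0)) stop("S0 must be positive")
  lH <- -pH
  S0 * (1 + 10^(-logK1 - lH) + 10^(logK2 + lH))
}

#' Neutral-species solubility at a salt concentration
#'
#' Setschenow law `log S0(m) = log S00 - k_m m_MX`: for positive `k_m` the
#' neutral species is salted out linearly in salt molality.
#'
#' @param model a [solubility_model()].
#' @param m_MX supporting-electrolyte molality, mol kg^-1 (vectorised).
#' @return log10 solubility of the neutral species, mol kg^-1.
#' @export
specific_solubility_at_salt <- function(model, m_MX) {
  if (any(m_MX < 0)) stop("m_MX must be >= 0")
  model$logS0_specific - model$k_m * m_MX
}

#' Total solubility at a salt concentration
#'
#' Hyperbolic salting law
#' `log S_T(m) = log S0_T + (a_inf + (a0 - a_inf)/(1 + m)) m`, reducing to
#' a linear law when `a0 = a_inf`.
#'
#' @inheritParams specific_solubility_at_salt
#' @return log10 total solubility, mol kg^-1.
#' @export
total_solubility_at_salt <- function(model, m_MX) {
  if (any(m_MX < 0)) stop("m_MX must be >= 0")
  model$logS0_total +
    (model$a_inf + (model$a_zero - model$a_inf) / (1 + m_MX)) * m_MX
}

#' Activity coefficient of the neutral species
#'
#' `log gamma = k_m m_MX` from the Setschenow analysis; zero in pure water.
#'
#' @inheritParams specific_solubility_at_salt
#' @return log10 activity coefficient of the neutral species.
#' @export
setschenow_gamma <- function(model, m_MX) {
  if (any(m_MX < 0)) stop("m_MX must be >= 0")
  model$k_m * m_MX
}

#' Solubility product from neutral-species solubility and logK1
#'
#' `log K_S0 = log S0 - log K1`, the equilibrium constant of the
#' dissolution of the solid into the aminoate anion and a proton. Both
#' inputs must refer to the same ionic strength, temperature and
#' concentration scale; a declared scale mismatch is an error.
#'
#' @param logS0_specific log10 neutral-species solubility.
#' @param logK1 log10 amino-group protonation constant at matching
#'   conditions.
#' @param scale_S,scale_K declared concentration scales of the two inputs.
#' @return log10 solubility product.
#' @examples
#' solubility_product(-0.772, 9.777)  # leucine in pure water
#' @export
solubility_product <- function(logS0_specific, logK1,
                               scale_S = "molal", scale_K = "molal") {
  if (!identical(scale_S, scale_K))
    stop("scale mismatch: log S0 on the ", scale_S, " scale but logK1 on ",
         "the ", scale_K, " scale; convert one side first")
  stopifnot(is.finite(logS0_specific), is.finite(logK1))
  logS0_specific - logK1
}

#' Fit a salting law to solubility observations
#'
#' Least-squares fit of either the constant-Setschenow law (2 parameters:
#' `logS0`, `k`) or the hyperbolic two-parameter law (3 parameters:
#' `logS0`, `a0`, `a_inf`) to `log S` versus salt molality. Both forms are
#' linear in their parameters after reparameterisation, so the fit is exact
#' ordinary least squares with t-based 95 % confidence intervals.
#'
#' @param observations data frame with columns `m_MX` and `logS` (and
#'   optionally `sigma` for weights `1/sigma^2`).
#' @param form `"constant"` (Setschenow) or `"hyperbolic"`.
#' @param ligand,medium,scale passed through to the returned model.
#' @return A [solubility_model()] with a `fit` attribute holding the `lm`
#'   summary: coefficients, 95 % CIs and residuals.
#' @export
fit_solubility <- function(observations, form = c("constant", "hyperbolic"),
                           ligand = "user", medium = "user",
                           scale = "molal") {
  form <- match.arg(form)
  stopifnot(is.data.frame(observations),
            all(c("m_MX", "logS") %in% names(observations)))
  n <- nrow(observations)
  npar <- if (form == "constant") 2L else 3L
  if (n < npar + 1L)
    stop("under-determined fit: ", n, " observation(s) for ", npar,
         " parameters (need at least ", npar + 1L, ")")
  if (length(unique(observations$m_MX)) < npar)
    stop("design is degenerate: fewer distinct salt concentrations than ",
         "parameters")
  w <- if ("sigma" %in% names(observations) &&
           all(observations$sigma > 0)) 1 / observations$sigma^2
       else rep(1, n)
  m <- observations$m_MX
  if (form == "constant") {
    fit <- stats::lm(logS ~ m, data = data.frame(logS = observations$logS,
                                                 m = m), weights = w)
    cf <- stats::coef(fit)
    est <- list(logS0 = unname(cf[1]), k_m = -unname(cf[2]))
    model <- solubility_model(ligand, medium, logS0_total = est$logS0,
                              k_m = est$k_m, scale = scale)
  } else {
    # log S = logS0 + a_inf*(m - m/(1+m)) + a0*(m/(1+m)): linear regressors
    x_inf <- m - m / (1 + m)
    x0 <- m / (1 + m)
    fit <- stats::lm(logS ~ x_inf + x0,
                     data = data.frame(logS = observations$logS,
                                       x_inf = x_inf, x0 = x0), weights = w)
    cf <- stats::coef(fit)
    if (any(is.na(cf))) stop("design is degenerate for the hyperbolic form")
    model <- solubility_model(ligand, medium, logS0_total = unname(cf[1]),
                              a_inf = unname(cf[2]), a_zero = unname(cf[3]),
                              scale = scale)
  }
  # confint warns on exact (zero-residual) fits; that case is legitimate
  ci <- tryCatch(suppressWarnings(stats::confint(fit, level = 0.95)),
                 error = function(e) NULL)
  attr(model, "fit") <- list(lm = fit, ci95 = ci,
                             residuals = stats::residuals(fit))
  model
}

#' Packaged solubility models
#'
#' Salting parameters of the packaged store (leucine and phenylalanine,
#' NaCl and tetramethylammonium chloride where measured), as
#' [solubility_model()] objects.
#'
#' @param ligand `"leu"` or `"phe"`.
#' @param medium `"nacl"` or `"tmacl"`.
#' @param scale `"molal"` or `"molar"`.
#' @return A [solubility_model()].
#' @export
aat_solubility <- function(ligand, medium = "nacl",
                           scale = c("molal", "molar")) {
  scale <- match.arg(scale)
  tab <- utils::read.csv(system.file("extdata", "solubility_parameters.csv",
                                     package = "aathermo"),
                         stringsAsFactors = FALSE)
  row <- tab[tab$ligand == tolower(ligand) & tab$medium == tolower(medium) &
             tab$scale == scale, ]
  if (nrow(row) != 1L)
    stop("no packaged solubility parameters for ", ligand, " in ", medium,
         " on the ", scale, " scale")
  solubility_model(row$ligand, row$medium, logS0_total = row$logS0,
                   k_m = row$k, scale = scale,
                   ci = list(logS0 = row$logS0_ci, k_m = row$k_ci))
}
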