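#' Reaction charge parameter z*
#'
#' `z* = sum(charges reactants^2) - sum(charges products^2)` scales the
#' Debye-Hueckel term of a reaction. For the stepwise protonation of a
#' neutral zwitterionic amino acid, the amino-group step
#' (H+ + L- = HL0) has `z* = 2` and the carboxylate step
#' (H+ + HL0 = H2L+) has `z* = 0`.
#'
#' @param reactant_charges integer charges of the reactant species.
#' @param product_charges integer charges of the product species.
#' @return Integer z*.
#' @examples
#' z_star(c(1, -1), 0)   # 2
#' z_star(c(1, 0), 1)    # 0
#' @export
z_star <- function(reactant_charges, product_charges) {
  if (length(reactant_charges) == 0L || length(product_charges) == 0L)
    stop("charge lists must be non-empty")
  as.integer(sum(reactant_charges^2) - sum(product_charges^2))
}

#' Define a protonation step
#'
#' @param index step index: 1 for the amino group, 2 for the carboxylate.
#' @param reactant_charges,product_charges species charges; defaults are the
#'   conventional ones for a diprotic amino acid with neutral zwitterion.
#' @return An object of class `protonation_step` with fields `index`,
#'   `reactant_charges`, `product_charges` and `z_star`.
#' @export
protonation_step <- function(index,
                             reactant_charges = NULL,
                             product_charges = NULL) {
  index <- as.integer(index)
  if (!index %in% c(1L, 2L) && (is.null(reactant_charges) ||
                                is.null(product_charges)))
    stop("charges must be given explicitly for step indices other than 1, 2")
  if (is.null(reactant_charges))
    reactant_charges <- if (index == 1L) c(1L, -1L) else c(1L, 0L)
  if (is.null(product_charges))
    product_charges <- if (index == 1L) 0L else 1L
  structure(list(index = index,
                 reactant_charges = reactant_charges,
                 product_charges = product_charges,
                 z_star = z_star(reactant_charges, product_charges)),
            class = "protonation_step")
}

#' Debye-Hueckel term of a reaction
#'
#' `z* A sqrt(I) / (1 + B sqrt(I))`: the electrostatic part of the
#' ionic-strength dependence of an equilibrium constant. Zero at `I = 0`
#' and strictly increasing in `I` for positive `z*`.
#'
#' @param z_star reaction charge parameter (see [z_star()]).
#' @param I ionic strength, mol kg^-1 (vectorised).
#' @param constants a [model_constants()] object.
#' @return Dimensionless term in log10 units.
#' @export
dh_term <- function(z_star, I, constants = model_constants()) {
  .check_I(I)
  s <- sqrt(I)
  z_star * constants$A_debye * s / (1 + constants$B_factor * s)
}

#' Ionic-strength interpolation of a SIT reaction coefficient
#'
#' The reaction-level SIT coefficient is allowed to relax between its
#' infinite-dilution value `eps_zero` and its high-salinity limit `eps_inf`
#' with the hyperbolic form
#' `delta_eps(I) = eps_inf + (eps_zero - eps_inf) / (I + 1)`.
#'
#' @param de list or object with fields `eps_inf` and `eps_zero`
#'   (kg mol^-1), e.g. from [delta_epsilon()].
#' @param I ionic strength, mol kg^-1 (vectorised).
#' @return Coefficient in kg mol^-1.
#' @export
delta_eps_at <- function(de, I) {
  .check_I(I)
  de$eps_inf + (de$eps_zero - de$eps_inf) / (I + 1)
}

#' @rdname delta_eps_at
#' @param eps_inf,eps_zero limiting values of the coefficient (kg mol^-1).
#' @export
delta_epsilon <- function(eps_inf, eps_zero) {
  if (!is.finite(eps_inf) || !is.finite(eps_zero))
    stop("eps_inf and eps_zero must be finite")
  structure(list(eps_inf = eps_inf, eps_zero = eps_zero),
            class = "delta_epsilon")
}

#' Specific interaction coefficient of an ion pair
#'
#' Stores the SIT coefficient of a single (cation, anion) pair with the same
#' hyperbolic ionic-strength relaxation used for reaction coefficients.
#'
#' @param pair character label, e.g. `"Na+,Leu-"`.
#' @param eps_inf,eps_zero limiting values (kg mol^-1).
#' @return Object of class `ion_epsilon`; evaluate with [delta_eps_at()].
#' @export
ion_epsilon <- function(pair, eps_inf, eps_zero) {
  out <- delta_epsilon(eps_inf, eps_zero)
  out$pair <- pair
  class(out) <- c("ion_epsilon", class(out))
  out
}

#' Per-ligand protonation model
#'
#' A parameter bundle describing one ligand in one ionic medium: for each
#' protonation step the infinite-dilution constant at the reference
#' temperature, the SIT ionic-strength parameters, and the thermal
#' parameters of the Clarke-Glew expansion.
#'
#' @param ligand,medium identifiers (lower-case by convention,
#'   e.g. `"gly"`, `"nacl"`).
#' @param steps a list with one entry per protonation step; each entry is a
#'   list with fields `logK0`, `de` (a [delta_epsilon()]), `dH0` (kJ mol^-1),
#'   `dCp` (J K^-1 mol^-1), `de_prime` (kJ mol^-1 per mol kg^-1) and
#'   optionally `ci` (a named list of 95 % half-widths). Thermal fields may
#'   be `NA` when only the reference temperature is of interest.
#' @return Object of class `protonation_model`.
#' @examples
#' m <- protonation_model("gly", "nacl", list(
#'   list(logK0 = 9.777, de = delta_epsilon(0.190, 0.311),
#'        dH0 = -44.33, dCp = 41, de_prime = -0.96),
#'   list(logK0 = 2.329, de = delta_epsilon(0.098, 0.093),
#'        dH0 = -3.99, dCp = 136, de_prime = -0.85)))
#' logk_at(m, step = 1, I = 0.1)
#' @export
protonation_model <- function(ligand, medium, steps) {
  if (length(steps) >= 2L) {
    k1 <- steps[[1]]$logK0; k2 <- steps[[2]]$logK0
    if (is.finite(k1) && is.finite(k2) && k1 <= k2)
      stop("logK0 of step 1 must exceed logK0 of step 2 (amino group is ",
           "more basic than the carboxylate)")
  }
  for (s in steps) {
    if (!is.finite(s$logK0)) stop("logK0 must be finite")
    if (!inherits(s$de, "delta_epsilon"))
      stop("each step needs a delta_epsilon() ionic-strength parameter")
  }
  structure(list(ligand = ligand, medium = medium, steps = steps),
            class = "protonation_model")
}

#' @export
print.protonation_model <- function(x, ...) {
  cat(sprintf("Protonation model: %s in %s (%d step%s)\n", x$ligand,
              x$medium, length(x$steps),
              if (length(x$steps) > 1) "s" else ""))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf(
      "  step %d: logK0 %7.3f  de_inf %6.3f  de0 %6.3f  dH0 %7.2f  dCp %5.0f  de' %6.2f\n",
      i, s$logK0, s$de$eps_inf, s$de$eps_zero,
      if (is.null(s$dH0)) NA else s$dH0,
      if (is.null(s$dCp)) NA else s$dCp,
      if (is.null(s$de_prime)) NA else s$de_prime))
  }
  invisible(x)
}

.get_step <- function(model, step) {
  if (inherits(step, "protonation_step")) {
    idx <- step$index
    zs <- step$z_star
  } else {
    idx <- as.integer(step)
    zs <- protonation_step(idx)$z_star
  }
  if (idx < 1L || idx > length(model$steps))
    stop("model has no parameters for step ", idx)
  list(idx = idx, zs = zs, par = model$steps[[idx]])
}

.thermal_factor <- function(par, I, T, constants) {
  # Clarke-Glew enthalpic bracket, kJ/mol; dCp enters in J and is scaled
  if (all(T == constants$theta)) return(rep(0, max(length(I), length(T))))
  if (is.null(par$dH0) || any(!is.finite(par$dH0)))
    stop("thermal parameters (dH0, dCp) are required when T != theta; ",
         "none are available for this step")
  dCp <- if (is.null(par$dCp) || !is.finite(par$dCp)) 0 else par$dCp
  dep <- if (is.null(par$de_prime) || !is.finite(par$de_prime)) 0 else par$de_prime
  (par$dH0 + dCp * (T - constants$theta) / 1000 + dep * I) *
    constants$CG_factor * (1 / constants$theta - 1 / T)
}

#' Protonation constant at given ionic strength and temperature
#'
#' Evaluates
#' `log K = logK0 - z* A sqrt(I)/(1 + B sqrt(I)) + delta_eps(I) I +
#'  (dH0 + dCp (T - theta)/1000 + de' I) * 52.23 * (1/theta - 1/T)`,
#' i.e. the SIT ionic-strength law combined with the Clarke-Glew
#' temperature expansion. At `T = theta` the temperature term vanishes and
#' the expression reduces to the pure ionic-strength law.
#'
#' @param model a [protonation_model()].
#' @param step step index (1 or 2) or a [protonation_step()].
#' @param I ionic strength, mol kg^-1 (vectorised).
#' @param T temperature, K (vectorised with `I`).
#' @param constants a [model_constants()] object.
#' @return log10 of the stepwise protonation constant (molal scale).
#' @export
logk_at <- function(model, step = 1, I, T = 298.15,
                    constants = model_constants()) {
  .check_I(I)
  if (any(T <= 0)) stop("T must be positive (kelvin)")
  st <- .get_step(model, step)
  par <- st$par
  out <- par$logK0 - dh_term(st$zs, I, constants) +
    delta_eps_at(par$de, I) * I
  if (any(T != constants$theta))
    out <- out + .thermal_factor(par, I, T, constants)
  out
}

#' Protonation enthalpy at given ionic strength and temperature
#'
#' The ionic-strength dependence of the stepwise protonation enthalpy is
#' modelled with a Debye-Hueckel-shaped limiting term plus a linear term:
#' `dH(I, T) = dH0 - z* k_DH sqrt(I)/(1 + 1.5 sqrt(I)) + dCp (T - theta)/1000
#'  + de' I` in kJ mol^-1, with `k_DH` the `dh_enthalpy_coeff` of
#' [model_constants()] (1.5 kJ mol^-1 by default). Equals `dH0` at
#' `I = 0`, `T = theta`.
#'
#' @inheritParams logk_at
#' @return Enthalpy change in kJ mol^-1.
#' @export
enthalpy_at <- function(model, step = 1, I, T = 298.15,
                        constants = model_constants()) {
  .check_I(I)
  st <- .get_step(model, step)
  par <- st$par
  if (is.null(par$dH0) || any(!is.finite(par$dH0)))
    stop("no enthalpy parameters for ", model$ligand, " step ", st$idx)
  dCp <- if (is.null(par$dCp) || !is.finite(par$dCp)) 0 else par$dCp
  dep <- if (is.null(par$de_prime) || !is.finite(par$de_prime)) 0 else par$de_prime
  s <- sqrt(I)
  par$dH0 - st$zs * constants$dh_enthalpy_coeff * s /
    (1 + constants$B_factor * s) +
    dCp * (T - constants$theta) / 1000 + dep * I
}

#' Single-ion (or neutral-species) activity coefficient
#'
#' Extended Debye-Hueckel form
#' `log gamma = -z^2 A sqrt(I)/(1 + B sqrt(I)) + linear_term * I`.
#' For a neutral species (`charge = 0`) only the linear term survives and
#' `linear_term` plays the role of the Setschenow coefficient.
#'
#' @param charge integer ionic charge.
#' @param I ionic strength, mol kg^-1 (vectorised).
#' @param linear_term specific-interaction (or Setschenow) coefficient,
#'   kg mol^-1.
#' @param constants a [model_constants()] object.
#' @return log10 activity coefficient.
#' @export
log_gamma_ion <- function(charge, I, linear_term = 0,
                          constants = model_constants()) {
  .check_I(I)
  s <- sqrt(I)
  -charge^2 * constants$A_debye * s / (1 + constants$B_factor * s) +
    linear_term * I
}

#' Decompose a reaction SIT coefficient into single-pair coefficients
#'
#' For the amino-group step in a chloride medium MCl,
#' `delta_eps_1 = eps(H+,Cl-) + eps(M+,L-) - k_m(MCl)`, so the ligand-pair
#' coefficient is `eps(M+,L-) = delta_eps_1 - eps(H+,Cl-) + k_m`. For the
#' carboxylate step, `delta_eps_2 = eps(H+,Cl-) + k_m - eps(H2L+,Cl-)`,
#' so `eps(H2L+,Cl-) = eps(H+,Cl-) + k_m - delta_eps_2`. `eps(H+,Cl-)` is a
#' required input: no conventional value is assumed.
#'
#' @param delta_eps_value reaction coefficient at the ionic strength of
#'   interest, kg mol^-1.
#' @param step 1 (amino group) or 2 (carboxylate), or a
#'   [protonation_step()].
#' @param eps_H_Cl specific interaction coefficient of (H+, Cl-), kg mol^-1.
#' @param k_m Setschenow coefficient of the neutral species in the medium,
#'   kg mol^-1.
#' @return The single-pair coefficient, kg mol^-1.
#' @export
decompose_delta_eps <- function(delta_eps_value, step, eps_H_Cl, k_m) {
  if (any(!is.finite(c(delta_eps_value, eps_H_Cl, k_m))))
    stop("all inputs must be finite")
  idx <- if (inherits(step, "protonation_step")) step$index else as.integer(step)
  if (idx == 1L) delta_eps_value - eps_H_Cl + k_m
  else if (idx == 2L) eps_H_Cl + k_m - delta_eps_value
  else stop("unknown step index ", idx)
}
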