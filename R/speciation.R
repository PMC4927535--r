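#' Protonation-state distribution of a diprotic amino acid
#'
#' Mole fractions of the aminoate anion L-, the neutral zwitterion HL0 and
#' the cation H2L+ at given pH, from the stepwise constants. Fractions are
#' proportional to `1, beta1 [H], beta2 [H]^2` with `beta1 = K1` and
#' `beta2 = K1 K2`. pH is `-log10[H+]` on the concentration scale, matching
#' the scale of the constants; no activity correction is applied here.
#'
#' @param logK1,logK2 stepwise protonation constants (log10). `logK1` refers
#'   to the amino group and should exceed `logK2` (a warning is issued
#'   otherwise and the computation proceeds).
#' @param pH numeric vector.
#' @return A data frame of class `speciation_result` with columns `pH`,
#'   `L`, `HL`, `H2L` and `p_bar` (mean protons bound per ligand).
#' @examples
#' sp <- species_fractions(9.777, 2.329, pH = seq(2, 12, 0.5))
#' head(sp)
#' @export
species_fractions <- function(logK1, logK2, pH) {
  if (logK1 <= logK2)
    warning("logK1 <= logK2: unusual ordering for an amino acid")
  lH <- -pH
  # work in log space to avoid overflow at extreme pH
  l0 <- rep(0, length(pH))
  l1 <- logK1 + lH
  l2 <- logK1 + logK2 + 2 * lH
  mx <- pmax(l0, l1, l2)
  w0 <- 10^(l0 - mx); w1 <- 10^(l1 - mx); w2 <- 10^(l2 - mx)
  tot <- w0 + w1 + w2
  out <- data.frame(pH = pH, L = w0 / tot, HL = w1 / tot, H2L = w2 / tot)
  out$p_bar <- out$HL + 2 * out$H2L
  class(out) <- c("speciation_result", class(out))
  out
}

#' Mean protons bound from apparent overall constants
#'
#' `p_bar* = sum(i beta_i* [H]^i) / (1 + sum(beta_i* [H]^i))`, the binding
#' polynomial ratio computed from apparent (conditional) overall
#' protonation constants. Bounded by the number of steps.
#'
#' @param overall_logbetas vector of apparent overall constants
#'   `log10 beta_i*`, one per protonation step (length 1 or 2 for the
#'   ligands considered here; `NA` entries are dropped).
#' @param pH numeric vector.
#' @return Mean number of bound protons at each pH.
#' @export
nbar_apparent <- function(overall_logbetas, pH) {
  lb <- overall_logbetas[is.finite(overall_logbetas)]
  if (length(lb) == 0L) return(rep(0, length(pH)))
  i <- seq_along(lb)
  lH <- -pH
  num <- den <- rep(0, length(pH))
  terms <- outer(lH, i) + matrix(lb, nrow = length(pH), ncol = length(lb),
                                 byrow = TRUE)
  mx <- pmax(0, apply(terms, 1, max))
  den <- 10^(0 - mx)
  for (k in i) {
    t <- 10^(terms[, k] - mx)
    den <- den + t
    num <- num + k * t
  }
  num / den
}

#' Weak-complex model of a medium cation
#'
#' Association constants `beta_ji^M` for species `M_j H_i L` formed between
#' the medium cation M and the ligand protonation states, on the molar
#' concentration scale. By default only the ML ion pair (j = 1, i = 0) is
#' considered, matching the single tetramethylammonium-aminoate species
#' that the delta-pK analysis quantifies.
#'
#' @param cation cation identifier, e.g. `"tma"` or `"na"`.
#' @param species data frame with integer columns `j >= 1`, `i >= 0` and a
#'   numeric column `logbeta` (log10, molar scale); optional column `ci`.
#' @param reference free-text reference state, e.g.
#'   `"infinite dilution, 298.15 K"`.
#' @return Object of class `weak_complex_model`.
#' @examples
#' wc <- weak_complex_model("tma", data.frame(j = 1, i = 0, logbeta = -0.38))
#' @export
weak_complex_model <- function(cation, species,
                               reference = "infinite dilution") {
  stopifnot(is.data.frame(species),
            all(c("j", "i", "logbeta") %in% names(species)))
  if (any(species$j < 1)) stop("complex species require j >= 1")
  structure(list(cation = cation, species = species, reference = reference,
                 scale = "molar"),
            class = "weak_complex_model")
}

#' Mean protons bound including medium-cation weak complexes
#'
#' Evaluates the binding polynomial over the full species set
#' `{H_i L} union {M_j H_i L}`: the numerator weights each species by its
#' proton count i, the denominator is the usual partition sum. With
#' `cM = 0` (or no complex model) this reduces to [nbar_apparent()] on the
#' effective constants. Molar scale throughout.
#'
#' @param effective_logbetas effective (baseline) overall protonation
#'   constants `log10 beta_i`, molar scale.
#' @param complex_model a [weak_complex_model()] or `NULL`.
#' @param cM free medium-cation concentration, mol dm^-3.
#' @param pH numeric vector.
#' @return Mean number of bound protons at each pH.
#' @export
nbar_effective <- function(effective_logbetas, complex_model = NULL,
                           cM = 0, pH) {
  if (cM < 0) stop("cM must be >= 0")
  lb <- effective_logbetas[is.finite(effective_logbetas)]
  iH <- seq_along(lb)
  if (!is.null(complex_model) && cM > 0) {
    sp <- complex_model$species
    cx_i <- sp$i
    cx_log <- sp$logbeta + sp$j * log10(cM)
  } else {
    cx_i <- integer(0)
    cx_log <- numeric(0)
  }
  vapply(pH, function(p) {
    lH <- -p
    logs <- c(0, lb + iH * lH, cx_log + cx_i * lH)
    prot <- c(0, iH, cx_i)
    mx <- max(logs)
    w <- 10^(logs - mx)
    sum(prot * w) / sum(w)
  }, numeric(1))
}

#' Speciation over a pH grid, from packaged or fitted constants
#'
#' Convenience wrapper producing distribution-diagram data for a ligand in
#' a medium at given ionic strength and temperature.
#'
#' @param model a [protonation_model()].
#' @param I ionic strength, mol kg^-1.
#' @param T temperature, K.
#' @param pH numeric grid (default 2 to 12 by 0.1).
#' @param constants a [model_constants()] object.
#' @return A `speciation_result` data frame (see [species_fractions()]).
#' @export
speciation_grid <- function(model, I = 0, T = 298.15,
                            pH = seq(2, 12, by = 0.1),
                            constants = model_constants()) {
  k1 <- logk_at(model, 1, I, T, constants)
  k2 <- logk_at(model, 2, I, T, constants)
  species_fractions(k1, k2, pH)
}
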