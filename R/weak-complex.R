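#' Apparent protonation constant in an interacting medium
#'
#' A weak ion pair between the deprotonated ligand and the medium cation
#' depresses the apparent protonation constant:
#' `log K* = log K - log10(1 + 10^logK_M cM)`. Equality with the effective
#' constant holds only at `cM = 0` or vanishing association.
#'
#' @param logK_effective effective (baseline) log10 protonation constant.
#' @param logK_M log10 association constant of the cation-ligand pair,
#'   molar scale.
#' @param cM free medium-cation concentration, mol dm^-3 (vectorised).
#' @return Apparent log10 protonation constant.
#' @examples
#' apparent_logk(9.777, -0.38, 1.0)
#' @export
apparent_logk <- function(logK_effective, logK_M, cM) {
  if (any(cM < 0)) stop("cM must be >= 0")
  logK_effective - log10(1 + 10^logK_M * cM)
}

#' Invert the apparent-constant relation for the association constant
#'
#' Closed-form inverse of [apparent_logk()]:
#' `logK_M = log10((10^(logK - logK*) - 1) / cM)`. Requires an actual
#' depression (`logK* < logK`) at positive cation concentration.
#'
#' @param logK_effective effective (baseline) log10 protonation constant.
#' @param logK_apparent apparent log10 constant in the interacting medium.
#' @param cM free medium-cation concentration, mol dm^-3 (> 0).
#' @return log10 association constant (molar scale).
#' @export
invert_apparent_logk <- function(logK_effective, logK_apparent, cM) {
  if (any(cM <= 0)) stop("cM must be > 0 to infer an association constant")
  dlogK <- logK_effective - logK_apparent
  if (any(dlogK <= 0))
    stop("no detectable complex: apparent constant is not depressed ",
         "relative to the baseline")
  log10((10^dlogK - 1) / cM)
}

#' Objective of the delta-pK fit
#'
#' Sum over all observation conditions and a pH grid of the squared gap
#' between the mean proton number computed from the apparent constants and
#' the one computed from the effective constants plus candidate complexes.
#' Zero exactly at the generating parameters for noise-free data.
#'
#' @param logbeta_M candidate complex constants (log10, molar scale), in
#'   the order of `species` rows.
#' @param data observation table (see [fit_weak_complexes()]).
#' @param species data frame with columns `j`, `i` defining the complex
#'   stoichiometries.
#' @param ph_grid pH evaluation grid.
#' @return The scalar sum of squares U.
#' @export
dpk_objective <- function(logbeta_M, data, species,
                          ph_grid = seq(2, 11.5, by = 0.1)) {
  U <- 0
  for (r in seq_len(nrow(data))) {
    eff <- c(data$logb1_eff[r], data$logb2_eff[r])
    app <- c(data$logb1_app[r], data$logb2_app[r])
    cm <- weak_complex_model("candidate",
                             data.frame(j = species$j, i = species$i,
                                        logbeta = logbeta_M))
    pbar <- nbar_effective(eff, cm, data$cM[r], ph_grid)
    pbar_star <- nbar_apparent(app, ph_grid)
    U <- U + sum((pbar - pbar_star)^2)
  }
  U
}

#' Fit weak cation-ligand association constants (delta-pK method)
#'
#' Estimates the association constant(s) of weak medium-cation complexes
#' from paired observations of overall protonation constants: effective
#' constants from a weakly interacting baseline medium and apparent
#' constants from the interacting medium at known cation concentrations.
#' The fit minimises `U = sum (p_bar - p_bar*)^2` over a pH grid, where
#' `p_bar` uses the effective constants plus candidate complexes and
#' `p_bar*` uses the apparent constants alone. Several observation rows
#' (multiple cation levels, multiple ligands) share the complex constants,
#' so a joint multi-ligand fit is simply a stacked observation table.
#'
#' All constants must be on the molar concentration scale.
#'
#' @param data data frame with one row per (ligand, cM) condition and
#'   columns `cM` (mol dm^-3), `logb1_eff`, `logb2_eff` (effective overall
#'   constants; `logb2_*` may be `NA` for monoprotic systems), `logb1_app`,
#'   `logb2_app` (apparent overall constants).
#' @param species complex stoichiometries as a data frame with columns `j`
#'   and `i`; the default single row `j = 1, i = 0` is the ML ion pair.
#' @param ph_grid pH evaluation grid (default 2 to 11.5 by 0.1, equal
#'   weights).
#' @param n_starts number of Nelder-Mead starts for multi-species fits.
#' @param seed RNG seed for the multi-start dispersion.
#' @param cation label stored in the returned model.
#' @return A [weak_complex_model()] with attributes `U` (minimised sum of
#'   squares), `ci95` (approximate intervals from the curvature of U) and
#'   `n_conditions`.
#' @examples
#' eff <- 9.777
#' cm <- c(0.25, 0.5, 1, 2)
#' obs <- data.frame(cM = cm, logb1_eff = eff, logb2_eff = NA,
#'                   logb1_app = apparent_logk(eff, -0.38, cm),
#'                   logb2_app = NA)
#' fit <- fit_weak_complexes(obs)
#' fit$species$logbeta  # ~ -0.38
#' @export
fit_weak_complexes <- function(data, species = data.frame(j = 1, i = 0),
                               ph_grid = seq(2, 11.5, by = 0.1),
                               n_starts = 5, seed = 1, cation = "M") {
  stopifnot(is.data.frame(data),
            all(c("cM", "logb1_eff", "logb1_app") %in% names(data)))
  if (!"logb2_eff" %in% names(data)) data$logb2_eff <- NA_real_
  if (!"logb2_app" %in% names(data)) data$logb2_app <- NA_real_
  if (length(unique(data$cM[data$cM > 0])) < 2L)
    stop("need observations at >= 2 distinct positive cation ",
         "concentrations")
  npar <- nrow(species)
  obj <- function(th) dpk_objective(th, data, species, ph_grid)
  if (npar == 1L) {
    opt <- stats::optimize(obj, interval = c(-6, 3), tol = 1e-10)
    # polish: optimize() can stop short of full precision on flat valleys
    opt2 <- stats::optimize(obj, interval = opt$minimum + c(-0.05, 0.05),
                            tol = .Machine$double.eps^0.5)
    est <- opt2$minimum
    Umin <- opt2$objective
  } else {
    set.seed(seed)
    starts <- matrix(stats::runif(n_starts * npar, -3, 1),
                     nrow = n_starts)
    best <- NULL
    for (k in seq_len(n_starts)) {
      o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    est <- best$par
    Umin <- best$value
  }
  # curvature-based uncertainty: Var(theta) ~ 2 sigma^2 H^-1 with
  # sigma^2 = U/(N - p); flat curvature flags non-identifiability
  N <- nrow(data) * length(ph_grid)
  h <- 1e-4
  ci95 <- rep(NA_real_, npar)
  hess_ok <- TRUE
  for (k in seq_len(npar)) {
    e <- rep(0, npar); e[k] <- h
    d2 <- (obj(est + e) - 2 * Umin + obj(est - e)) / h^2
    if (!is.finite(d2) || d2 <= 1e-8) { hess_ok <- FALSE; next }
    sigma2 <- max(Umin, 1e-20) / max(N - npar, 1)
    ci95[k] <- 1.96 * sqrt(2 * sigma2 / d2)
  }
  if (!hess_ok)
    stop("objective surface is flat in at least one parameter: the ",
         "requested species set is not identifiable from these data")
  out <- weak_complex_model(cation,
                            data.frame(j = species$j, i = species$i,
                                       logbeta = est, ci = ci95))
  attr(out, "U") <- Umin
  attr(out, "ci95") <- ci95
  attr(out, "n_conditions") <- nrow(data)
  out
}
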