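#' Validate a table of protonation-constant measurements
#'
#' A measurement record is one observed stepwise protonation constant (or
#' enthalpy) with its medium, concentration scale, ionic strength,
#' temperature, uncertainty, source and IUPAC-style quality flag
#' (`recommended`, `tentative`, `doubtful`, `rejected`). Only the first two
#' flag classes are used in fits.
#'
#' @param records data frame with columns `ligand`, `medium`, `scale`
#'   (`"molal"`/`"molar"`), `I`, `T`, `step`, `value`, `sigma`, `source`
#'   (`"experimental"`/`"literature"`), `flag`, and optionally `quantity`
#'   (`"logK"`, the default, or `"dH"` for calorimetric-style enthalpy
#'   values in kJ mol^-1).
#' @return The validated data frame (invisibly unchanged).
#' @export
measurement_records <- function(records) {
  need <- c("ligand", "medium", "scale", "I", "T", "step", "value",
            "sigma", "source", "flag")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"quantity" %in% names(records)) records$quantity <- "logK"
  if (!all(records$quantity %in% c("logK", "dH")))
    stop("quantity must be 'logK' or 'dH'")
  if (any(records$I < 0)) stop("ionic strength must be >= 0")
  if (any(records$T <= 0)) stop("temperature must be positive")
  bad <- !records$flag %in% c("recommended", "tentative", "doubtful",
                              "rejected")
  if (any(bad))
    stop("unknown quality flag(s): ",
         paste(unique(records$flag[bad]), collapse = ", "))
  if (any(!is.na(records$sigma) & records$sigma < 0))
    stop("sigma must be positive (or NA to use the source floor)")
  records
}

.default_fit_config <- function() {
  list(sigma_floors = c(experimental = 0.01,
                        literature_recommended = 0.02,
                        literature_tentative = 0.05),
       sigma_floor_dH = 0.1,
       constants = model_constants(),
       densities = NULL)
}

.effective_sigma <- function(records, floors, floor_dH = 0.1) {
  key <- ifelse(records$source == "experimental", "experimental",
                paste0("literature_", records$flag))
  key[!key %in% names(floors)] <- "literature_tentative"
  floor <- unname(floors[key])
  floor[records$quantity == "dH"] <- floor_dH
  pmax(ifelse(is.na(records$sigma), 0, records$sigma), floor)
}

# Design matrix of the combined ionic-strength/temperature law for one step.
# The law is linear in every fitted parameter. log K rows:
#   logK = logK0 + de_inf*(I - I/(I+1)) + de_zero*(I/(I+1))
#          + dH0*tau + dCp*tau*(T-theta)/1000 + de_prime*tau*I + offset
# with tau = CG*(1/theta - 1/T) and offset the (negated) Debye-Hueckel
# term. Enthalpy rows use the enthalpy law, which is linear in dH0, dCp
# and de_prime with its own Debye-Hueckel-shaped offset. logK0, dH0 and
# dCp are shared across media; the SIT columns are per-medium.
.build_design <- function(records, step, constants) {
  zs <- protonation_step(step)$z_star
  I <- records$I; T <- records$T
  isK <- records$quantity == "logK"
  tau <- constants$CG_factor * (1 / constants$theta - 1 / T)
  media <- sort(unique(records$medium))
  X <- cbind(logK0 = as.numeric(isK),
             dH0 = ifelse(isK, tau, 1),
             dCp = ifelse(isK, tau, 1) * (T - constants$theta) / 1000)
  for (md in media) {
    on <- as.numeric(records$medium == md)
    X <- cbind(X, on * isK * (I - I / (I + 1)), on * isK * (I / (I + 1)),
               on * ifelse(isK, tau, 1) * I)
    colnames(X)[(ncol(X) - 2):ncol(X)] <-
      paste(c("de_inf", "de_zero", "de_prime"), md, sep = ".")
  }
  s <- sqrt(I)
  offset <- ifelse(isK, -dh_term(zs, I, constants),
                   -zs * constants$dh_enthalpy_coeff * s /
                     (1 + constants$B_factor * s))
  list(X = X, offset = offset, media = media)
}

#' Fit the ionic-strength/temperature law to measurement data
#'
#' Weighted linear least squares (weights `1/sigma^2`) of the combined
#' SIT + Clarke-Glew law to stepwise protonation constants measured across
#' ionic strengths, temperatures and media. The law is linear in all
#' fitted parameters (`logK0`, `de_inf`, `de_zero`, `dH0`, `dCp`,
#' `de_prime`), so the solution is exact and needs no starting values.
#' `logK0`, `dH0` and `dCp` are thermodynamic infinite-dilution quantities
#' shared across media; the SIT parameters are per-medium. Parameters whose
#' design column is empty (e.g. the thermal block when all data are at the
#' reference temperature) are reported as not estimable rather than
#' guessed. Records flagged `doubtful` or `rejected` are excluded with a
#' message; molar-scale records are converted to molal first.
#'
#' @param records a [measurement_records()] table for one ligand.
#' @param config optional list overriding `sigma_floors` (named floors for
#'   `experimental`, `literature_recommended`, `literature_tentative`
#'   records), `constants` (a [model_constants()]) and `densities` (named
#'   list of [density_model()] per medium for molar records; packaged
#'   models are used for `nacl`/`tmacl` when omitted).
#' @return Object of class `protonation_fit`: per-step coefficient tables
#'   with 95 % CIs, covariance matrices, residuals, weighted RMS, the
#'   per-medium [protonation_model()] objects, and an exclusion ledger
#'   (`n_input = n_used + n_excluded`).
#' @examples
#' truth <- aat_model("gly", "nacl")
#' des <- design_spec(sigma = 0, seed = 7)
#' rec <- generate_protonation_dataset(truth, des)
#' fit <- fit_protonation_model(rec)
#' fit$steps[["1"]]$coef
#' @export
fit_protonation_model <- function(records, config = list()) {
  cfg <- utils::modifyList(.default_fit_config(), config)
  records <- measurement_records(records)
  if (length(unique(records$ligand)) > 1L)
    stop("records span several ligands; fit one ligand at a time")
  n_input <- nrow(records)
  keep <- records$flag %in% c("recommended", "tentative")
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(n_excl, " record(s) flagged doubtful/rejected excluded (",
            sum(keep), " of ", n_input, " used)")
  records <- records[keep, , drop = FALSE]
  # molar-scale records are converted to the molal scale (SIT convention)
  is_molar <- records$scale == "molar"
  if (any(is_molar)) {
    for (md in unique(records$medium[is_molar])) {
      dm <- if (!is.null(cfg$densities[[md]])) cfg$densities[[md]]
            else aat_density(md)
      sel <- is_molar & records$medium == md
      m <- molar_to_molal(records$I[sel], dm)
      adj <- sel & records$quantity == "logK"   # dH values are scale free
      madj <- molar_to_molal(records$I[adj], dm)
      records$value[adj] <- records$value[adj] -
        log10(ifelse(records$I[adj] > 0, madj / records$I[adj], 1))
      records$I[sel] <- m
      records$scale[sel] <- "molal"
    }
  }
  sig <- .effective_sigma(records, cfg$sigma_floors, cfg$sigma_floor_dH)
  out <- list(steps = list(), constants = cfg$constants,
              n_input = n_input, n_excluded = n_excl, n_used = nrow(records),
              ligand = records$ligand[1])
  for (s in sort(unique(records$step))) {
    sel <- records$step == s
    rs <- records[sel, , drop = FALSE]
    des <- .build_design(rs, s, cfg$constants)
    live <- apply(abs(des$X), 2, max) > 1e-10
    dropped <- colnames(des$X)[!live]
    X <- des$X[, live, drop = FALSE]
    if (nrow(X) < ncol(X))
      stop("step ", s, ": ", nrow(X), " usable records cannot identify ",
           ncol(X), " parameters")
    w <- 1 / sig[sel]^2
    df <- data.frame(y = rs$value - des$offset, X, check.names = FALSE)
    fml <- stats::as.formula(paste(
      "y ~ 0 +", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
    fit <- stats::lm(fml, data = df, weights = w)
    cf <- stats::coef(fit)
    if (any(is.na(cf))) {
      dropped <- c(dropped, names(cf)[is.na(cf)])
      stop("step ", s, ": design is rank deficient; unidentifiable ",
           "parameter(s): ", paste(names(cf)[is.na(cf)], collapse = ", "))
    }
    ci <- stats::confint(fit, level = 0.95)
    coef_tab <- data.frame(parameter = names(cf), estimate = unname(cf),
                           ci95 = unname((ci[, 2] - ci[, 1]) / 2),
                           row.names = NULL)
    if (length(dropped))
      coef_tab <- rbind(coef_tab,
                        data.frame(parameter = dropped, estimate = NA_real_,
                                   ci95 = NA_real_))
    res <- stats::residuals(fit)
    p <- length(cf)
    out$steps[[as.character(s)]] <- list(
      coef = coef_tab, cov = stats::vcov(fit),
      residuals = res, sigma_used = sig[sel],
      wrms = sqrt(sum(w * res^2) / max(nrow(X) - p, 1)),
      not_estimable = dropped, media = des$media,
      records = rs)
  }
  class(out) <- "protonation_fit"
  out
}

#' @export
print.protonation_fit <- function(x, ...) {
  cat(sprintf("Protonation fit for %s: %d used / %d excluded of %d records\n",
              x$ligand, x$n_used, x$n_excluded, x$n_input))
  for (s in names(x$steps)) {
    st <- x$steps[[s]]
    cat(sprintf(" step %s (weighted RMS %.3g):\n", s, st$wrms))
    print(st$coef, digits = 4)
    if (length(st$not_estimable))
      cat("  not estimable:", paste(st$not_estimable, collapse = ", "), "\n")
  }
  invisible(x)
}

.fit_param <- function(st, name) {
  i <- match(name, st$coef$parameter)
  if (is.na(i)) NA_real_ else st$coef$estimate[i]
}

#' Extract per-medium protonation models from a fit
#'
#' @param fit a `protonation_fit` object.
#' @param medium medium identifier present in the fitted data.
#' @return A [protonation_model()] carrying the fitted parameters (and
#'   their 95 % CIs in each step's `ci` field).
#' @export
fitted_model <- function(fit, medium) {
  steps <- lapply(fit$steps, function(st) {
    if (!medium %in% st$media)
      stop("medium ", medium, " not present in the fitted data")
    g <- function(nm) .fit_param(st, nm)
    ci <- stats::setNames(st$coef$ci95, st$coef$parameter)
    list(logK0 = g("logK0"),
         de = delta_epsilon(g(paste0("de_inf.", medium)),
                            g(paste0("de_zero.", medium))),
         dH0 = g("dH0"), dCp = g("dCp"),
         de_prime = g(paste0("de_prime.", medium)),
         ci = as.list(ci))
  })
  names(steps) <- NULL
  protonation_model(fit$ligand, medium, steps)
}

#' Tabulate calculated values with propagated CIs and quality flags
#'
#' Evaluates the fitted law on a grid of (I, T) and propagates the
#' parameter covariance through the (linear) model, so the reported 95 %
#' confidence intervals are exact for the fitted law. Each value receives
#' a quality flag: `R` (recommended) when the propagated CI is below
#' `R_ci` and at least `n_min` fitted records lie within `window` of that
#' ionic strength, `T` (tentative) when the CI is below `T_ci`, else `P`
#' (provisional). Grid points outside the data support are flagged `P`
#' rather than silently extrapolated.
#'
#' @param fit a `protonation_fit`.
#' @param I,T numeric vectors (recycled to a common grid of rows).
#' @param medium medium to tabulate.
#' @param thresholds list with elements `R_ci` (default 0.015), `T_ci`
#'   (0.035), `n_min` (3), `window` (0.5 mol kg^-1).
#' @return Data frame with columns `I`, `T`, `step`, `logK`, `logK_ci`,
#'   `flag`, and when thermal parameters are estimable `dH`, `dH_ci`.
#' @export
recommend_table <- function(fit, I, T = 298.15, medium = NULL,
                            thresholds = list()) {
  th <- utils::modifyList(list(R_ci = 0.015, T_ci = 0.035, n_min = 3,
                               window = 0.5), thresholds)
  cst <- fit$constants
  if (is.null(medium)) medium <- fit$steps[[1]]$media[1]
  grid <- data.frame(I = I, T = T)
  out <- NULL
  for (s in names(fit$steps)) {
    st <- fit$steps[[s]]
    model <- fitted_model(fit, medium)
    pseudo <- data.frame(I = grid$I, T = grid$T, medium = medium,
                         quantity = "logK")
    des <- .build_design(pseudo, as.integer(s), cst)
    live <- colnames(st$cov)
    Xl <- des$X[, live, drop = FALSE]
    var_k <- rowSums((Xl %*% st$cov) * Xl)
    n_obs <- nrow(st$records)
    p <- length(live)
    tq <- stats::qt(0.975, max(n_obs - p, 1))
    logK <- logk_at(model, as.integer(s), grid$I, grid$T, cst)
    kci <- tq * sqrt(var_k)
    support <- vapply(grid$I, function(ii)
      sum(abs(st$records$I - ii) <= th$window), numeric(1))
    flag <- ifelse(kci <= th$R_ci & support >= th$n_min, "R",
                   ifelse(kci <= th$T_ci, "T", "P"))
    flag[support == 0] <- "P"
    row <- data.frame(I = grid$I, T = grid$T, step = as.integer(s),
                      logK = logK, logK_ci = kci, flag = flag)
    if (!any(c("dH0", "dCp") %in% st$not_estimable)) {
      gH <- cbind(dH0 = 1, dCp = (grid$T - cst$theta) / 1000,
                  de_prime = grid$I)
      colnames(gH)[3] <- paste0("de_prime.", medium)
      keepH <- intersect(colnames(gH), live)
      var_h <- rowSums((gH[, keepH, drop = FALSE] %*%
                          st$cov[keepH, keepH]) * gH[, keepH, drop = FALSE])
      row$dH <- enthalpy_at(model, as.integer(s), grid$I, grid$T, cst)
      row$dH_ci <- tq * sqrt(var_h)
    }
    out <- rbind(out, row)
  }
  out[order(out$step, out$I, out$T), , drop = FALSE]
}

#' Average parameter values across ligands
#'
#' Arithmetic mean and sample standard deviation of each model parameter
#' over a set of ligands, as used to summarise how uniform the
#' thermodynamic behaviour of the amino-acid family is. All rows must
#' refer to one medium (mixing media without grouping is an error).
#'
#' @param params parameter table in the layout of [aat_parameters()]
#'   (columns `ligand`, `medium`, `step` and numeric parameter columns).
#' @param ligands optional subset of ligands to average over.
#' @param medium medium to select (required when `params` spans several).
#' @return Data frame with one row per (step, parameter): `mean`, `spread`
#'   (sample SD across ligands) and `n`.
#' @examples
#' av <- parameter_averages(aat_parameters(), medium = "nacl")
#' subset(av, parameter == "logK0" & step == 1)$mean  # 9.618
#' @export
parameter_averages <- function(params, ligands = NULL, medium = NULL) {
  if (!is.null(medium)) params <- params[params$medium == medium, ]
  if (length(unique(params$medium)) > 1L)
    stop("parameter table spans several media: pass `medium` explicitly")
  if (!is.null(ligands)) params <- params[params$ligand %in% ligands, ]
  if (length(unique(params$ligand)) < 2L)
    stop("need at least two ligands to average")
  cols <- intersect(c("logK0", "de_inf", "de_zero", "dH0", "dCp",
                      "de_prime"), names(params))
  out <- NULL
  for (s in sort(unique(params$step))) {
    sub <- params[params$step == s, ]
    for (cl in cols) {
      v <- sub[[cl]]
      v <- v[is.finite(v)]
      out <- rbind(out, data.frame(step = s, parameter = cl,
                                   mean = mean(v), spread = stats::sd(v),
                                   n = length(v)))
    }
  }
  out
}
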