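#' Design of a synthetic measurement campaign
#'
#' Describes the grid on which synthetic observations are generated. The
#' default ionic-strength grid is denser below 1.5 mol kg^-1, mimicking
#' the typical literature situation of abundant scattered data at low
#' ionic strength and few points up to 5 mol kg^-1; the default
#' temperature grid spans 278.15-318.15 K.
#'
#' @param I_grid ionic strengths, mol kg^-1.
#' @param T_grid temperatures, K.
#' @param media character vector of medium ids.
#' @param replicates observations per grid point.
#' @param sigma Gaussian noise SD in log10 units (observations are noised
#'   on the log K scale). `sigma = 0` reproduces the model exactly.
#' @param sigma_slope optional heteroscedastic component: the SD applied
#'   at ionic strength I is `sigma + sigma_slope * I`, mimicking sparser,
#'   noisier high-salinity literature data.
#' @param seed RNG seed; the same seed yields byte-identical datasets.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(I_grid = c(0.1, 0.25, 0.5, 0.75, 1.0, 1.5, 2.0,
                                   3.0, 4.0, 5.0),
                        T_grid = c(278.15, 288.15, 298.15, 310.15, 318.15),
                        media = "nacl", replicates = 1L, sigma = 0.02,
                        sigma_slope = 0, seed = 1L) {
  if (length(I_grid) == 0L || length(T_grid) == 0L)
    stop("grids must be non-empty")
  if (sigma < 0 || sigma_slope < 0) stop("noise levels must be >= 0")
  structure(list(I_grid = I_grid, T_grid = T_grid, media = media,
                 replicates = as.integer(replicates), sigma = sigma,
                 sigma_slope = sigma_slope, seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate synthetic protonation-constant measurements
#'
#' Forward-evaluates a generating model on the design grid and adds
#' Gaussian noise on the log K scale. Records carry the generating SD in
#' their `sigma` column so refits are correctly weighted.
#'
#' @param truth a [protonation_model()] (single medium) or a named list of
#'   them keyed by medium, covering `design$media`.
#' @param design a [design_spec()].
#' @param steps which protonation steps to observe (default both).
#' @param constants a [model_constants()] object.
#' @return A [measurement_records()] data frame, flagged `recommended`,
#'   source `experimental`, molal scale.
#' @examples
#' rec <- generate_protonation_dataset(aat_model("gly"), design_spec(seed = 3))
#' head(rec)
#' @export
generate_protonation_dataset <- function(truth, design, steps = c(1L, 2L),
                                         constants = model_constants()) {
  if (inherits(truth, "protonation_model"))
    truth <- stats::setNames(list(truth), truth$medium)
  if (!all(design$media %in% names(truth)))
    stop("truth models missing for medium: ",
         paste(setdiff(design$media, names(truth)), collapse = ", "))
  grid <- expand.grid(I = design$I_grid, T = design$T_grid,
                      medium = design$media, step = steps,
                      rep = seq_len(design$replicates),
                      stringsAsFactors = FALSE)
  set.seed(design$seed)
  sd_pt <- design$sigma + design$sigma_slope * grid$I
  vals <- numeric(nrow(grid))
  for (md in design$media) {
    sel <- grid$medium == md
    for (s in steps) {
      ss <- sel & grid$step == s
      vals[ss] <- logk_at(truth[[md]], s, grid$I[ss], grid$T[ss], constants)
    }
  }
  noise <- if (all(sd_pt == 0)) 0 else stats::rnorm(nrow(grid), 0, sd_pt)
  out <- data.frame(ligand = truth[[1]]$ligand, medium = grid$medium,
                    scale = "molal", I = grid$I, T = grid$T,
                    step = grid$step, value = vals + noise,
                    sigma = sd_pt, source = "experimental",
                    flag = "recommended", stringsAsFactors = FALSE)
  attr(out, "seed") <- design$seed
  out
}

#' Generate synthetic solubility observations
#'
#' Total solubility versus salt molality from a generating
#' [solubility_model()], with Gaussian noise in log10 units. By
#' convention the tetramethylammonium medium is sampled only up to
#' 3.5 mol kg^-1 (its practical solubility range); NaCl designs reach
#' 5 mol kg^-1.
#'
#' @param truth a [solubility_model()].
#' @param m_grid salt molalities; defaults depend on the medium.
#' @param sigma Gaussian noise SD (log10 units).
#' @param replicates observations per salt level.
#' @param seed RNG seed.
#' @return Data frame with columns `ligand`, `medium`, `scale`, `m_MX`,
#'   `logS`, `sigma`.
#' @export
generate_solubility_dataset <- function(truth, m_grid = NULL, sigma = 0.005,
                                        replicates = 1L, seed = 1L) {
  if (is.null(m_grid)) {
    m_max <- if (identical(truth$medium, "tmacl")) 3.5 else 5
    m_grid <- c(0, 0.1, 0.25, 0.5, 1, 1.5, 2, 3, if (m_max > 3.5) c(4, 5)
                else m_max)
  }
  grid <- expand.grid(m_MX = m_grid, rep = seq_len(replicates))
  set.seed(seed)
  vals <- total_solubility_at_salt(truth, grid$m_MX)
  noise <- if (sigma == 0) 0 else stats::rnorm(nrow(grid), 0, sigma)
  out <- data.frame(ligand = truth$ligand, medium = truth$medium,
                    scale = truth$scale, m_MX = grid$m_MX,
                    logS = vals + noise, sigma = sigma,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Generate paired baseline/interacting apparent-constant data
#'
#' The canonical input of the delta-pK analysis: effective overall
#' protonation constants in a non-interacting baseline medium, and
#' apparent constants in an interacting medium where every ligand-
#' containing species is depleted by complexation of the free aminoate,
#' `log beta_i* = log beta_i - log10(1 + 10^logK_M cM)`. Gaussian noise is
#' added to both media independently. Molar concentration scale.
#'
#' @param truth_effective a [protonation_model()] providing the effective
#'   constants, a numeric vector of stepwise constants `c(logK1)` or
#'   `c(logK1, logK2)` applied at every cation level, or a data frame with
#'   columns `cM`, `logb1_eff` and optionally `logb2_eff`.
#' @param complex_truth a [weak_complex_model()] with the single ML
#'   species, or a number taken as `logK_M`.
#' @param cM_grid medium-cation concentrations, mol dm^-3.
#' @param I_eval ionic strength at which the effective constants are
#'   evaluated when `truth_effective` is a model (one value per `cM` or a
#'   scalar).
#' @param sigma Gaussian noise SD (log10 units).
#' @param seed RNG seed.
#' @param constants a [model_constants()] object.
#' @return Data frame in the layout required by [fit_weak_complexes()]:
#'   `cM`, `logb1_eff`, `logb2_eff`, `logb1_app`, `logb2_app`.
#' @export
generate_paired_media_dataset <- function(truth_effective, complex_truth,
                                          cM_grid = c(0.25, 0.5, 1, 1.5,
                                                      2, 3),
                                          I_eval = cM_grid, sigma = 0,
                                          seed = 1L,
                                          constants = model_constants()) {
  logK_M <- if (inherits(complex_truth, "weak_complex_model"))
    complex_truth$species$logbeta[1] else as.numeric(complex_truth)
  if (inherits(truth_effective, "protonation_model")) {
    I_eval <- rep(I_eval, length.out = length(cM_grid))
    lk1 <- logk_at(truth_effective, 1, I_eval, constants$theta, constants)
    lk2 <- tryCatch(logk_at(truth_effective, 2, I_eval, constants$theta,
                            constants), error = function(e) NA_real_)
    eff <- data.frame(cM = cM_grid, logb1_eff = lk1,
                      logb2_eff = lk1 + lk2)
  } else if (is.numeric(truth_effective)) {
    # stepwise constants given directly: logK1 (and optionally logK2)
    lb1 <- truth_effective[1]
    lb2 <- if (length(truth_effective) > 1L)
      lb1 + truth_effective[2] else NA_real_
    eff <- data.frame(cM = cM_grid, logb1_eff = lb1, logb2_eff = lb2)
  } else {
    eff <- as.data.frame(truth_effective)
    if (!"logb2_eff" %in% names(eff)) eff$logb2_eff <- NA_real_
  }
  depress <- log10(1 + 10^logK_M * eff$cM)
  set.seed(seed)
  n <- nrow(eff)
  noise <- function() if (sigma == 0) 0 else stats::rnorm(n, 0, sigma)
  out <- data.frame(cM = eff$cM,
                    logb1_eff = eff$logb1_eff + noise(),
                    logb2_eff = eff$logb2_eff + noise(),
                    logb1_app = eff$logb1_eff - depress + noise(),
                    logb2_app = eff$logb2_eff - depress + noise())
  attr(out, "seed") <- seed
  attr(out, "logK_M") <- logK_M
  out
}
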