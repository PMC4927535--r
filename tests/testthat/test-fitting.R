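test_that("measurement records are validated", {
  rec <- make_records(I = c(0.1, 0.5), value = c(9.6, 9.6))
  expect_silent(measurement_records(rec))
  bad <- rec; bad$flag <- "dubious"
  expect_error(measurement_records(bad), "unknown quality flag")
  bad2 <- rec; bad2$I[1] <- -1
  expect_error(measurement_records(bad2), ">= 0")
  expect_error(measurement_records(rec[, -4]), "missing columns")
})

test_that("noise-free synthetic data are recovered to machine precision", {
  for (lig in PACKAGED_LIGANDS) {
    truth <- aat_model(lig, "nacl")
    rec <- generate_protonation_dataset(truth, design_spec(sigma = 0,
                                                           seed = 11))
    fit <- fit_protonation_model(rec)
    for (s in 1:2) {
      cf <- fit$steps[[as.character(s)]]$coef
      est <- stats::setNames(cf$estimate, cf$parameter)
      tp <- truth$steps[[s]]
      want <- c(logK0 = tp$logK0, dH0 = tp$dH0, dCp = tp$dCp,
                de_inf.nacl = tp$de$eps_inf, de_zero.nacl = tp$de$eps_zero,
                de_prime.nacl = tp$de_prime)
      expect_lt(max(abs(est[names(want)] - want)), 1e-6)
    }
  }
})

test_that("shared thermodynamic parameters fit jointly across media", {
  truth <- list(nacl = aat_model("gly", "nacl"),
                tmacl = aat_model("gly", "tmacl"))
  rec <- generate_protonation_dataset(
    truth, design_spec(media = c("nacl", "tmacl"), sigma = 0, seed = 12))
  fit <- fit_protonation_model(rec)
  cf <- fit$steps[["1"]]$coef
  est <- stats::setNames(cf$estimate, cf$parameter)
  expect_equal(unname(est["logK0"]), 9.777, tolerance = 1e-8)
  expect_equal(unname(est["de_inf.nacl"]), 0.190, tolerance = 1e-8)
  expect_equal(unname(est["de_inf.tmacl"]), 0.048, tolerance = 1e-8)
  expect_equal(unname(est["de_prime.tmacl"]), -0.09, tolerance = 1e-8)
  m_nacl <- fitted_model(fit, "nacl")
  expect_equal(logk_at(m_nacl, 1, 0.5), logk_at(truth$nacl, 1, 0.5),
               tolerance = 1e-10)
})

test_that("point estimates are invariant to rescaling all sigmas", {
  truth <- gly_nacl()
  rec <- generate_protonation_dataset(truth, design_spec(sigma = 0.02,
                                                         seed = 13))
  f1 <- fit_protonation_model(rec)
  rec2 <- rec; rec2$sigma <- rec2$sigma * 3
  f2 <- fit_protonation_model(rec2)
  expect_equal(f1$steps[["1"]]$coef$estimate, f2$steps[["1"]]$coef$estimate,
               tolerance = 1e-12)
})

test_that("doubtful and rejected records are excluded and accounted for", {
  truth <- gly_nacl()
  rec <- generate_protonation_dataset(truth, design_spec(sigma = 0,
                                                         seed = 14))
  rec$flag[1:5] <- "doubtful"
  rec$flag[6:8] <- "rejected"
  rec$value[1:8] <- 0   # grossly wrong, must not influence the fit
  expect_message(fit <- fit_protonation_model(rec), "excluded")
  expect_identical(fit$n_excluded, 8L)
  expect_identical(fit$n_used + fit$n_excluded, fit$n_input)
  est <- fit$steps[["1"]]$coef
  expect_equal(est$estimate[est$parameter == "logK0"], 9.777,
               tolerance = 1e-8)
})

test_that("isothermal datasets leave thermal parameters unestimated", {
  truth <- gly_nacl()
  rec <- generate_protonation_dataset(truth,
                                      design_spec(T_grid = 298.15,
                                                  sigma = 0, seed = 15))
  fit <- fit_protonation_model(rec)
  st <- fit$steps[["1"]]
  expect_setequal(st$not_estimable, c("dH0", "dCp", "de_prime.nacl"))
  est <- stats::setNames(st$coef$estimate, st$coef$parameter)
  expect_equal(unname(est["logK0"]), 9.777, tolerance = 1e-8)
  expect_equal(unname(est["de_zero.nacl"]), 0.311, tolerance = 1e-8)
  expect_true(is.na(est["dH0"]))
})

test_that("molar-scale records are converted before fitting", {
  truth <- gly_nacl()
  dm <- aat_density("nacl")
  cs <- c(0.1, 0.25, 0.5, 1, 2, 3, 4)
  ms <- molar_to_molal(cs, dm)
  # observations generated on the molar scale from the molal-scale law
  rec <- make_records(I = cs, value = logk_at(truth, 1, ms) +
                        log10(ms / cs), scale = "molar", sigma = 0.01)
  fit <- fit_protonation_model(rec)
  est <- stats::setNames(fit$steps[["1"]]$coef$estimate,
                         fit$steps[["1"]]$coef$parameter)
  expect_equal(unname(est["logK0"]), 9.777, tolerance = 1e-6)
  expect_equal(unname(est["de_zero.nacl"]), 0.311, tolerance = 1e-6)
})

test_that("joint logK + enthalpy data reproduce the parameter table", {
  # tabulated values at 298.15 K, fed back as pseudo-measurements with
  # their printed uncertainties, must return the generating parameters
  # within twice the printed parameter CIs
  ref <- aat_reference_values()
  ref <- ref[ref$ligand == "gly" & ref$T == 298.15, ]
  mk <- function(step, q) {
    v <- ref[[paste0(if (q == "logK") "logK" else "dH", step)]]
    s <- ref[[paste0(if (q == "logK") "logK" else "dH", step, "_ci")]]
    make_records(I = ref$I, step = step, value = v, sigma = s,
                 source = "literature", quantity = q)
  }
  rec <- rbind(mk(1, "logK"), mk(2, "logK"), mk(1, "dH"), mk(2, "dH"))
  rec <- rec[!is.na(rec$value), ]
  fit <- fit_protonation_model(rec)
  tab <- aat_parameters()
  tab <- tab[tab$ligand == "gly" & tab$medium == "nacl", ]
  for (s in 1:2) {
    cf <- fit$steps[[as.character(s)]]$coef
    est <- stats::setNames(cf$estimate, cf$parameter)
    r <- tab[tab$step == s, ]
    expect_lt(abs(est["logK0"] - r$logK0), 2 * r$logK0_ci)
    expect_lt(abs(est["de_inf.nacl"] - r$de_inf), 2 * r$de_inf_ci)
    expect_lt(abs(est["de_zero.nacl"] - r$de_zero), 2 * r$de_zero_ci)
    expect_lt(abs(est["dH0"] - r$dH0), 2 * r$dH0_ci)
    expect_lt(abs(est["de_prime.nacl"] - r$de_prime), 2 * r$de_prime_ci)
  }
})

test_that("per-parameter CI calibration stays within Monte-Carlo bounds", {
  # t-based CIs on this linear model are exactly calibrated, so each
  # parameter's empirical coverage over 200 replicates is Bin(200, 0.95);
  # the assertion band is +-3 binomial SDs around 0.95
  truth <- gly_nacl()
  true_par <- c(logK0 = 9.777, dH0 = -44.33, dCp = 41, de_inf.nacl = 0.190,
                de_zero.nacl = 0.311, de_prime.nacl = -0.96)
  nrep <- 200L
  cover <- matrix(0, nrep, 6, dimnames = list(NULL, names(true_par)))
  for (r in seq_len(nrep)) {
    rec <- generate_protonation_dataset(
      truth, design_spec(sigma = 0.02, seed = 1000L + r), steps = 1L)
    cf <- fit_protonation_model(rec)$steps[["1"]]$coef
    i <- match(names(true_par), cf$parameter)
    cover[r, ] <- abs(cf$estimate[i] - true_par) <= cf$ci95[i]
  }
  band <- 3 * sqrt(0.95 * 0.05 / nrep)    # 0.046
  cov_par <- colMeans(cover)
  expect_true(all(abs(cov_par - 0.95) <= band),
              info = paste(sprintf("%s=%.3f", names(cov_par), cov_par),
                           collapse = " "))
})

test_that("tabulation propagates CIs and assigns flags sensibly", {
  truth <- gly_nacl()
  rec <- generate_protonation_dataset(truth, design_spec(sigma = 0.02,
                                                         seed = 16,
                                                         replicates = 3L))
  fit <- fit_protonation_model(rec)
  tab <- recommend_table(fit, I = c(0.1, 1, 5, 20), T = 298.15)
  expect_true(all(tab$logK_ci > 0))
  expect_true(all(tab$flag %in% c("R", "T", "P")))
  # far outside the data support: provisional, never silent extrapolation
  expect_true(all(tab$flag[tab$I == 20] == "P"))
  # values match the closed-form law for the fitted model
  m <- fitted_model(fit, "nacl")
  expect_equal(tab$logK[tab$step == 1],
               logk_at(m, 1, c(0.1, 1, 5, 20)), tolerance = 1e-12)
  expect_true(all(c("dH", "dH_ci") %in% names(tab)))
})

test_that("parameter averages reproduce the cross-ligand summaries", {
  av <- parameter_averages(aat_parameters(), medium = "nacl")
  g <- function(s, p) av[av$step == s & av$parameter == p, ]
  expect_lt(abs(g(1, "logK0")$mean - 9.618), 1e-3)
  expect_lt(abs(g(1, "logK0")$spread - 0.287), 1e-3)
  expect_lt(abs(g(1, "de_inf")$mean - 0.197), 1e-3)
  sub <- parameter_averages(aat_parameters(),
                            ligands = c("gly", "ala", "val", "leu"),
                            medium = "nacl")
  expect_lt(abs(sub[sub$step == 1 & sub$parameter == "logK0", ]$mean -
                  9.80), 5e-3)
  expect_error(parameter_averages(aat_parameters()), "several media")
  expect_error(parameter_averages(aat_parameters(), ligands = "gly",
                                  medium = "nacl"), "at least two")
})
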