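test_that("z_star is the difference of summed squared charges", {
  cases <- list(list(r = c(1, -1), p = 0, want = 2L),
                list(r = c(1, 0), p = 1, want = 0L),
                list(r = c(2, -1), p = 1, want = 4L))
  for (cs in cases) expect_identical(z_star(cs$r, cs$p), cs$want)
  expect_error(z_star(integer(0), 1), "non-empty")
  expect_identical(protonation_step(1)$z_star, 2L)
  expect_identical(protonation_step(2)$z_star, 0L)
})

test_that("Debye-Hueckel term vanishes at I = 0 and grows with I", {
  expect_identical(dh_term(2, 0), 0)
  expect_equal(dh_term(2, 1), 2 * 0.51 / 2.5)           # 0.408
  expect_equal(dh_term(2, 0.1), 1.02 * sqrt(0.1) / (1 + 1.5 * sqrt(0.1)),
               tolerance = 1e-12)
  expect_equal(dh_term(2, 0.1), 0.21878, tolerance = 1e-4)
  grid <- seq(0, 5, by = 0.05)
  expect_true(all(diff(dh_term(2, grid)) > 0))
  expect_error(dh_term(2, -0.1), ">= 0")
})

test_that("SIT coefficient relaxes hyperbolically between its limits", {
  de <- delta_epsilon(0.190, 0.311)
  expect_identical(delta_eps_at(de, 0), 0.311)
  expect_equal(delta_eps_at(de, 1e12), 0.190, tolerance = 1e-10)
  expect_equal(delta_eps_at(de, 1), (0.190 + 0.311) / 2)
  I <- seq(0, 50, by = 0.5)
  v <- delta_eps_at(de, I)
  expect_true(all(v <= 0.311 & v >= 0.190))
  expect_true(all(diff(v) < 0))  # monotone towards the high-I limit
  expect_error(delta_eps_at(de, -1), ">= 0")
  expect_error(delta_epsilon(NA, 0.1), "finite")
})

test_that("logk_at reproduces tabulated constants at 298.15 K", {
  gly <- gly_nacl()
  expect_equal(logk_at(gly, 1, 0), 9.777)
  expect_equal(logk_at(gly, 1, 0.1), 9.588, tolerance = 5e-4)
  expect_equal(logk_at(gly, 2, 5.0), 2.814, tolerance = 1e-3)
  leu <- aat_model("leu", "nacl")
  expect_equal(logk_at(leu, 1, 3.0), 10.137, tolerance = 1e-4)
})

test_that("temperature term vanishes at the reference temperature", {
  cst <- model_constants()
  for (lig in PACKAGED_LIGANDS) {
    m <- aat_model(lig, "nacl")
    I <- c(0, 0.3, 2, 5)
    pure_I <- m$steps[[1]]$logK0 - dh_term(2, I, cst) +
      delta_eps_at(m$steps[[1]]$de, I) * I
    expect_equal(logk_at(m, 1, I, T = cst$theta, cst), pure_I,
                 tolerance = 1e-14)
    # infinite-dilution, reference-T limit is logK0 for every ligand
    expect_equal(logk_at(m, 1, 0, cst$theta), m$steps[[1]]$logK0)
    expect_equal(logk_at(m, 2, 0, cst$theta), m$steps[[2]]$logK0)
  }
})

test_that("missing thermal parameters are an error away from theta", {
  m <- protonation_model("toy", "nacl", list(
    list(logK0 = 9.5, de = delta_epsilon(0.2, 0.3), dH0 = NA_real_,
         dCp = NA_real_, de_prime = NA_real_)))
  expect_equal(logk_at(m, 1, 0.5, T = 298.15), logk_at(m, 1, 0.5))
  expect_error(logk_at(m, 1, 0.5, T = 310.15), "thermal parameters")
})

test_that("enthalpy_at reproduces tabulated enthalpies", {
  gly <- gly_nacl()
  expect_equal(enthalpy_at(gly, 1, 0), -44.33)
  expect_equal(enthalpy_at(gly, 1, 1.0), -46.5, tolerance = 1e-2 / 46.5)
  leu <- aat_model("leu", "nacl")
  expect_equal(enthalpy_at(leu, 1, 3.0), -55.0, tolerance = 0.1 / 55)
  # carboxylate step has no Debye-Hueckel enthalpy term (z* = 0)
  expect_equal(enthalpy_at(gly, 2, 1.0), -3.99 - 0.85)
})

test_that("single-ion activity coefficients follow the extended DH form", {
  expect_equal(log_gamma_ion(0, 2.5, linear_term = 0.088), 0.088 * 2.5)
  expect_identical(log_gamma_ion(1, 0), 0)
  expect_equal(log_gamma_ion(1, 1), -0.51 / 2.5)  # -0.204
  expect_error(log_gamma_ion(1, -2), ">= 0")
})

test_that("reaction coefficients decompose into single-pair coefficients", {
  expect_equal(decompose_delta_eps(0.3, 1, 0, 0), 0.3)
  expect_equal(decompose_delta_eps(0.10, 2, 0.12, 0.07), 0.09)
  expect_equal(decompose_delta_eps(0.2, 1, 0.12, 0.088), 0.168)
  expect_error(decompose_delta_eps(0.2, 3, 0.1, 0.1), "unknown step")
  expect_error(decompose_delta_eps(NA, 1, 0.1, 0.1), "finite")
})

test_that("overall-constant shift is consistent with single-ion gammas", {
  # the SIT linear terms implied by the decomposition must recompose into
  # the same ionic-strength shift of log beta2 = logK1 + logK2
  cst <- model_constants()
  eps_H_Cl <- 0.12
  k_m <- 0.088
  for (lig in c("gly", "leu", "phe")) {
    m <- aat_model(lig, "nacl")
    for (I in c(0.1, 0.7, 2, 5)) {
      de1 <- delta_eps_at(m$steps[[1]]$de, I)
      de2 <- delta_eps_at(m$steps[[2]]$de, I)
      eps_NaL <- decompose_delta_eps(de1, 1, eps_H_Cl, k_m)
      eps_H2LCl <- decompose_delta_eps(de2, 2, eps_H_Cl, k_m)
      lhs <- (logk_at(m, 1, I) + logk_at(m, 2, I)) -
        (logk_at(m, 1, 0) + logk_at(m, 2, 0))
      rhs <- 2 * log_gamma_ion(1, I, eps_H_Cl, cst) +
        log_gamma_ion(-1, I, eps_NaL, cst) -
        log_gamma_ion(1, I, eps_H2LCl, cst)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("packaged single-pair coefficients match the chain from the store", {
  # eps(Na+, Leu-) as shipped versus decomposition of the reaction value
  eps_NaLeu <- ion_epsilon("Na+,Leu-", 0.195, 0.410)
  m <- aat_model("leu", "nacl")
  km <- aat_solubility("leu", "nacl")$k_m
  # the decomposition at the infinite-dilution limit with the implied
  # eps(H+,Cl-): consistency of the shipped numbers with each other
  eps_H_Cl_inf <- m$steps[[1]]$de$eps_inf + km - eps_NaLeu$eps_inf
  expect_equal(decompose_delta_eps(m$steps[[1]]$de$eps_inf, 1,
                                   eps_H_Cl_inf, km),
               eps_NaLeu$eps_inf, tolerance = 1e-12)
})
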