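test_that("the packaged store covers six ligands in two media", {
  tab <- aat_parameters()
  expect_setequal(unique(tab$ligand), PACKAGED_LIGANDS)
  expect_setequal(unique(tab$medium), c("nacl", "tmacl"))
  expect_equal(nrow(tab), 6 * 2 * 2)
  for (lig in PACKAGED_LIGANDS) {
    for (med in c("nacl", "tmacl")) {
      m <- aat_model(lig, med)
      expect_s3_class(m, "protonation_model")
      expect_gt(m$steps[[1]]$logK0, m$steps[[2]]$logK0)
    }
  }
  expect_error(aat_model("xyz", "nacl"), "no packaged parameters")
})

test_that("store save/load round trips byte-identically", {
  st <- default_store()
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_store(st, f1)
  st2 <- load_store(f1)
  save_store(st2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(st2$protonation$logK0, st$protonation$logK0)
})

test_that("YAML stores load like JSON stores", {
  st <- default_store()
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(st), fy)
  sty <- load_store(fy)
  expect_equal(sty$protonation$logK0, st$protonation$logK0)
})

test_that("invalid stores are rejected with field-level messages", {
  fe <- tempfile(fileext = ".json")
  writeLines("{}", fe)
  expect_error(load_store(fe), "protonation")
  st <- default_store()
  bad <- unclass(st)
  i1 <- with(bad$protonation, which(ligand == "gly" & medium == "nacl" &
                                      step == 1))
  i2 <- with(bad$protonation, which(ligand == "gly" & medium == "nacl" &
                                      step == 2))
  bad$protonation$logK0[c(i1, i2)] <- bad$protonation$logK0[c(i2, i1)]
  fb <- tempfile(fileext = ".json")
  save_store(bad, fb)
  expect_error(load_store(fb), "gly nacl")
  expect_error(load_store(tempfile()), "no such file")
})

test_that("reference fixtures are complete", {
  ref <- aat_reference_values()
  expect_equal(nrow(ref), 42L)
  expect_setequal(unique(ref$ligand), PACKAGED_LIGANDS)
  ks <- aat_reference_ks0()
  expect_equal(nrow(ks), 18L)
})

test_that("cli evaluates constants and reports usage errors", {
  out <- capture.output(status <- aat_cli(
    c("logk", "--ligand", "gly", "--medium", "nacl", "--I", "0",
      "--T", "298.15", "--step", "1")))
  expect_identical(status, 0L)
  df <- read.csv(textConnection(out))
  expect_equal(df$value, 9.777)
  expect_identical(suppressMessages(
    aat_cli(c("logk", "--ligand", "xyz", "--I", "0"))), 2L)
  expect_identical(suppressMessages(aat_cli(c("frobnicate"))), 2L)
  usage <- capture.output(status0 <- aat_cli(character(0)))
  expect_identical(status0, 2L)
  expect_match(usage[1], "usage")
})

test_that("cli speciate and tables write well-formed CSV artifacts", {
  f <- tempfile(fileext = ".csv")
  status <- aat_cli(c("speciate", "--ligand", "gly", "--I", "0.5",
                      "--ph-min", "2", "--ph-max", "12",
                      "--ph-step", "0.5", "--out", f))
  expect_identical(status, 0L)
  sp <- read.csv(f)
  expect_equal(nrow(sp), 21L)
  expect_lt(max(abs(sp$L + sp$HL + sp$H2L - 1)), 1e-5)
  f2 <- tempfile(fileext = ".csv")
  status2 <- suppressMessages(aat_cli(c("tables", "--which", "table4",
                                        "--T", "298.15", "--out", f2)))
  expect_identical(status2, 0L)
  tab <- read.csv(f2)
  expect_lt(max(abs(tab$deviation[tab$quantity == "logK"])), 0.005)
  # identical invocations produce identical files
  f3 <- tempfile(fileext = ".csv")
  suppressMessages(aat_cli(c("tables", "--which", "table4",
                             "--T", "298.15", "--out", f3)))
  expect_identical(readLines(f2), readLines(f3))
})

test_that("cli simulate is seed deterministic", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  expect_identical(aat_cli(c("simulate", "--kind", "paired", "--sigma",
                             "0.01", "--seed", "42", "--out", f1)), 0L)
  expect_identical(aat_cli(c("simulate", "--kind", "paired", "--sigma",
                             "0.01", "--seed", "42", "--out", f2)), 0L)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cli solubility reports the full chain", {
  out <- capture.output(status <- aat_cli(
    c("solubility", "--ligand", "leu", "--medium", "nacl", "--m", "3")))
  expect_identical(status, 0L)
  df <- read.csv(textConnection(out))
  expect_equal(df$logS_specific, -1.036, tolerance = 1e-3)
  expect_equal(df$logKs0, -11.17, tolerance = 1e-2)
})
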