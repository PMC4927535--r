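#' Packaged protonation parameter table
#'
#' The evaluated ionic-strength and temperature dependence parameters for
#' the six packaged amino acids (gly, ala, val, leu, ser, phe) in NaCl and
#' tetramethylammonium chloride: `logK0` (infinite dilution, 298.15 K),
#' the SIT limits `de_inf`/`de_zero` (kg mol^-1), `dH0` (kJ mol^-1),
#' `dCp` (J K^-1 mol^-1) and `de_prime` (kJ mol^-1 per mol kg^-1), each
#' with its 95 % half-width. In the tetramethylammonium medium `de_prime`
#' is a global per-step value applied to every ligand, as only global
#' values were evaluated.
#'
#' @return Data frame with one row per (ligand, medium, step).
#' @export
aat_parameters <- function() {
  utils::read.csv(system.file("extdata", "protonation_parameters.csv",
                              package = "aathermo"),
                  stringsAsFactors = FALSE)
}

#' Packaged protonation model for one ligand and medium
#'
#' @param ligand one of `"gly"`, `"ala"`, `"val"`, `"leu"`, `"ser"`,
#'   `"phe"`.
#' @param medium `"nacl"` or `"tmacl"`.
#' @return A [protonation_model()] built from [aat_parameters()].
#' @examples
#' logk_at(aat_model("gly", "nacl"), step = 1, I = 0.1)
#' @export
aat_model <- function(ligand, medium = "nacl") {
  tab <- aat_parameters()
  sub <- tab[tab$ligand == tolower(ligand) & tab$medium == tolower(medium), ]
  if (nrow(sub) == 0L)
    stop("no packaged parameters for ", ligand, " in ", medium)
  sub <- sub[order(sub$step), ]
  steps <- lapply(seq_len(nrow(sub)), function(k) {
    r <- sub[k, ]
    list(logK0 = r$logK0, de = delta_epsilon(r$de_inf, r$de_zero),
         dH0 = r$dH0, dCp = r$dCp, de_prime = r$de_prime,
         ci = list(logK0 = r$logK0_ci, de_inf = r$de_inf_ci,
                   de_zero = r$de_zero_ci, dH0 = r$dH0_ci,
                   dCp = r$dCp_ci, de_prime = r$de_prime_ci))
  })
  protonation_model(sub$ligand[1], sub$medium[1], steps)
}

#' Reference tables packaged for regression checks
#'
#' `aat_reference_values()` returns the tabulated calculated protonation
#' constants and enthalpies (with flags) used as a regression fixture;
#' `aat_reference_ks0()` the tabulated solubility products.
#'
#' @return Data frames.
#' @export
aat_reference_values <- function() {
  utils::read.csv(system.file("extdata", "recommended_values_ref.csv",
                              package = "aathermo"),
                  stringsAsFactors = FALSE)
}

#' @rdname aat_reference_values
#' @export
aat_reference_ks0 <- function() {
  utils::read.csv(system.file("extdata", "solubility_products_ref.csv",
                              package = "aathermo"),
                  stringsAsFactors = FALSE)
}

#' Forward-evaluate the packaged models on the reference grid
#'
#' Recomputes every reference table entry from the packaged parameters
#' and reports computed and tabulated values side by side, the key
#' self-consistency check of the packaged store.
#'
#' @param T_filter optional temperature filter (e.g. 298.15) applied to
#'   the reference rows.
#' @param constants a [model_constants()] object.
#' @return Data frame with columns `ligand`, `I`, `T`, `step`, `quantity`
#'   (`"logK"` or `"dH"`), `computed`, `tabulated`, `deviation`.
#' @export
evaluate_reference_grid <- function(T_filter = NULL,
                                    constants = model_constants()) {
  ref <- aat_reference_values()
  if (!is.null(T_filter)) ref <- ref[ref$T %in% T_filter, ]
  out <- NULL
  for (lig in unique(ref$ligand)) {
    model <- aat_model(lig, "nacl")
    sub <- ref[ref$ligand == lig, ]
    for (s in 1:2) {
      kcol <- paste0("logK", s); hcol <- paste0("dH", s)
      ck <- logk_at(model, s, sub$I, sub$T, constants)
      ch <- enthalpy_at(model, s, sub$I, sub$T, constants)
      out <- rbind(out,
        data.frame(ligand = lig, I = sub$I, T = sub$T, step = s,
                   quantity = "logK", computed = ck,
                   tabulated = sub[[kcol]]),
        data.frame(ligand = lig, I = sub$I, T = sub$T, step = s,
                   quantity = "dH", computed = ch,
                   tabulated = sub[[hcol]]))
    }
  }
  out <- out[!is.na(out$tabulated), ]
  out$deviation <- out$computed - out$tabulated
  rownames(out) <- NULL
  out
}

#' Solubility-product chain from the packaged store
#'
#' Chains the Setschenow law (neutral-species solubility at salt molality
#' I) with the protonation-constant law (`logK1` at the same I) into
#' `log K_S0 = log S0(I) - log K1(I)`, on the molal scale.
#'
#' @param ligand `"leu"` or `"phe"`.
#' @param medium `"nacl"` or `"tmacl"`.
#' @param I salt molality grid, mol kg^-1.
#' @param constants a [model_constants()] object.
#' @return Data frame with columns `I`, `logS0`, `logK1`, `logKs0`.
#' @examples
#' solubility_product_chain("leu", I = c(0, 0.5, 3, 5))
#' @export
solubility_product_chain <- function(ligand, medium = "nacl",
                                     I = c(0, 0.1, 0.5, 1, 3, 5),
                                     constants = model_constants()) {
  sm <- aat_solubility(ligand, medium, scale = "molal")
  pm <- aat_model(ligand, medium)
  logS0 <- specific_solubility_at_salt(sm, I)
  logK1 <- logk_at(pm, 1, I, constants$theta, constants)
  data.frame(I = I, logS0 = logS0, logK1 = logK1,
             logKs0 = solubility_product(logS0, logK1))
}

# ---- user parameter stores (JSON/YAML) -------------------------------------

.validate_store <- function(store) {
  if (is.null(store$protonation))
    stop("store has no `protonation` section")
  pr <- store$protonation
  need <- c("ligand", "medium", "step", "logK0", "de_inf", "de_zero")
  miss <- setdiff(need, names(pr))
  if (length(miss))
    stop("protonation table is missing field(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(pr$logK0)))
    stop("protonation: logK0 must be finite for every entry")
  key <- paste(pr$ligand, pr$medium)
  for (k in unique(key)) {
    sub <- pr[key == k, ]
    if (all(c(1, 2) %in% sub$step)) {
      k1 <- sub$logK0[sub$step == 1]; k2 <- sub$logK0[sub$step == 2]
      if (k1 <= k2)
        stop("invariant violation for ", k, ": logK0 of step 1 (", k1,
             ") must exceed logK0 of step 2 (", k2, ")")
    }
  }
  invisible(store)
}

#' Load a parameter store from JSON or YAML
#'
#' A store file bundles parameter tables under named sections
#' (`protonation`, optionally `solubility`, `densities`, `weak_complex`,
#' `version`, `provenance`). The protonation section is validated on load:
#' required fields must be present and the step-1 constant must exceed the
#' step-2 constant for every (ligand, medium). Violations are rejected
#' with a message naming the entry.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return A validated list of class `parameter_store` whose sections are
#'   data frames.
#' @seealso [save_store()], [default_store()]
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  if (is.null(raw)) stop("empty or invalid store file")
  for (s in intersect(names(raw),
                      c("protonation", "solubility", "densities",
                        "weak_complex")))
    raw[[s]] <- as.data.frame(raw[[s]], stringsAsFactors = FALSE)
  .validate_store(raw)
  structure(raw, class = "parameter_store")
}

#' Save a parameter store to JSON
#'
#' Writes with fixed formatting so that load/save round trips are
#' byte-identical.
#'
#' @param store a `parameter_store` (or compatible list).
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_store <- function(store, path) {
  out <- unclass(store)
  json <- jsonlite::toJSON(out, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, pretty = 2, na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' The packaged default store
#'
#' Assembles the packaged parameter tables into one `parameter_store`
#' object (6 ligands x 2 media protonation entries, the solubility
#' parameters, density models and the evaluated weak-complex constant).
#'
#' @return A `parameter_store`.
#' @export
default_store <- function() {
  st <- list(
    version = "1.0",
    provenance = "packaged evaluated parameters; see package documentation",
    protonation = aat_parameters(),
    solubility = utils::read.csv(
      system.file("extdata", "solubility_parameters.csv",
                  package = "aathermo"), stringsAsFactors = FALSE),
    densities = utils::read.csv(
      system.file("extdata", "densities.csv", package = "aathermo"),
      stringsAsFactors = FALSE),
    weak_complex = data.frame(cation = "tma", j = 1, i = 0,
                              logbeta = -0.38, ci = 0.07,
                              reference = "infinite dilution, 298.15 K",
                              scale = "molar"))
  .validate_store(st)
  structure(st, class = "parameter_store")
}
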