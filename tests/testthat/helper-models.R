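# shared fixtures, built in code

# glycine in NaCl straight from the packaged parameter table
gly_nacl <- function() aat_model("gly", "nacl")

# a toy density model with rho = 1 and massless salt: molar == molal
identity_density <- function() {
  density_model("toy", c(1, 0, 0), molar_mass = 0, c_max = 10)
}

# ligands packaged in the default store
PACKAGED_LIGANDS <- c("gly", "ala", "val", "leu", "ser", "phe")

# measurement-record table from vectors, with sensible defaults
make_records <- function(I, T = 298.15, step = 1L, value, sigma = 0.01,
                         ligand = "gly", medium = "nacl", scale = "molal",
                         source = "experimental", flag = "recommended",
                         quantity = "logK") {
  data.frame(ligand = ligand, medium = medium, scale = scale, I = I, T = T,
             step = step, value = value, sigma = sigma, source = source,
             flag = flag, quantity = quantity, stringsAsFactors = FALSE)
}
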