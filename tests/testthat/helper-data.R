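# Fixture builders shared across test files.

noiseless_config <- function(seed = 1, ...) {
  sim_config(seed = seed, p_misannotation = 0, p_incomplete = 0, ...)
}

# One genome record block (7 evidence rows) with a given number of
# present subunits, all supported by annotation.
genome_block <- function(genome_id, species_id, n_present, n_cds = 10) {
  data.frame(genome_id = genome_id, species_id = species_id, n_cds = n_cds,
             subunit = CI_SUBUNITS,
             annotated = seq_len(7) <= n_present,
             coverage = 0, stringsAsFactors = FALSE)
}

# Tiny states table for a hand-built tree.
states_for <- function(tips, status, genus = NULL, supergroup = NULL) {
  data.frame(species_id = tips, status = status,
             genus = if (is.null(genus)) paste0("g_", tips) else genus,
             supergroup = if (is.null(supergroup)) "fungi" else supergroup,
             stringsAsFactors = FALSE)
}

# Deterministic localization profile with a given compartment vector.
profile_row <- function(protein_id, probs, species_id = "spX",
                        membrane = 0.5) {
  stopifnot(length(probs) == 9)
  out <- data.frame(protein_id = protein_id, species_id = species_id,
                    stringsAsFactors = FALSE)
  out[LOC_COMPARTMENTS] <- as.list(probs)
  out$membrane <- membrane
  out
}

# Profile with the given mitochondrial probability, remainder on cytoplasm.
mito_profile <- function(protein_id, p_mito, species_id = "spX") {
  profile_row(protein_id, c(p_mito, 1 - p_mito, rep(0, 7)),
              species_id = species_id)
}
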