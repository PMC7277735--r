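# The default study genome is expensive enough to build once and share
# across test files (lazily, memoised for the whole test run).
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- suppressMessages(simulate_genome(sim_config(seed = 1)))
  }
  .sim_cache$sim
}

# Tiny genome for cheap structural tests.
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    cfg <- sim_config(
      seed = 11, n_chromosomes = 1, genes_per_chromosome = 90,
      n_tandem_events = 2, n_segmental_events = 0, n_mirna_loci = 2,
      mirna_mutation_counts = c(0L, 3L), mirna_strands = c("+", "-"),
      mirna_inside_coding = FALSE, mirna_hairpin = TRUE,
      n_face_to_face_pairs = 1, face_to_face_gaps = 5000L,
      family_fraction = 0.1
    )
    .sim_cache$small <- suppressMessages(simulate_genome(cfg))
  }
  .sim_cache$small
}
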