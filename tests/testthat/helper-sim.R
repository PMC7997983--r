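# Simulations shared across test files, computed once per test run.

.sim_cache <- new.env(parent = emptyenv())

# A small, fast configuration for unit tests of the generator itself.
small_config <- function(seed = 11, ...) {
  defaults <- list(
    seed = seed,
    n_microbial_species = 12L,
    n_human_proteins = 6L,
    n_trim_like_paralogs = 3L,
    protein_length_range = c(60L, 120L),
    pools = c("case_P20", "control_P20"),
    n_true_epitopes_per_pool = 12L,
    n_shared_epitopes = 4L,
    noise_peptide_count = 150L,
    n_mimicry_pairs = 2L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# The default study conditions, run end to end through read processing and
# the noise floor; reused by several suites.
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    cfg <- sim_config(seed = 101)
    ref <- generate_reference(cfg)
    lib <- generate_library(cfg, ref)
    tables <- lapply(stats::setNames(nm = cfg$pools), function(p) {
      process_pool(lib$pools[[p]], p, cfg$flank5, cfg$flank3)
    })
    floors <- lapply(tables, noise_floor)
    .sim_cache$default <- list(cfg = cfg, ref = ref, lib = lib,
                               tables = tables, floors = floors)
  }
  .sim_cache$default
}

# An epitope table built directly from counts.
counts_table <- function(counts, pool = "pool") {
  as_epitope_table(
    data.frame(peptide = sprintf("PEPSEQ%04dAA", seq_along(counts)),
               count = counts),
    pool = pool)
}

random_aa <- function(n, len = 12) {
  vapply(seq_len(n), function(i) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                 replace = TRUE), collapse = "")
  }, character(1))
}
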