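#' Configuration for the synthetic display-library simulator
#'
#' Bundles every knob of the synthetic reference proteome and display-library
#' read generator. The defaults describe a desk-scale emulation of a
#' competitive-biopanning experiment: two cohorts (case and control) each
#' pooled at two depths (P10 and P20), a 12-residue random-peptide display
#' insert encoded by a 36-bp DNA variance region between the display vector's
#' PCR primer flanks, roughly 13.5% of inserts carrying a premature stop codon,
#' planted immunogenic epitopes with heavy-tailed (log-normal) read counts
#' riding on a floor of low-count (geometric) noise peptides, and a handful of
#' planted human-viral molecular-mimicry 12-mers differing at a single
#' position.
#'
#' @param seed Integer seed; fixes every random choice downstream so that the
#'   same configuration reproduces byte-identical FASTA/FASTQ/TSV output.
#' @param n_microbial_species Number of microbial species in the reference.
#' @param n_proteins_per_species Proteins simulated per microbial species.
#' @param n_human_proteins Number of ordinary human proteins.
#' @param n_trim_like_paralogs Size of the human paralog family (TRIM-like,
#'   pairwise identity >= 60%) added on top of `n_human_proteins`.
#' @param protein_length_range Length range (amino acids) for simulated
#'   proteins, inclusive.
#' @param pools Character vector of pool labels, each `"<cohort>_<depth>"`
#'   with cohort `case`/`control` and depth tag `P10`/`P20`.
#' @param n_true_epitopes_per_pool Planted (truly enriched) epitopes per pool.
#' @param n_shared_epitopes How many planted epitopes are shared between the
#'   case and control pool of the same depth (must not exceed
#'   `n_true_epitopes_per_pool`).
#' @param fold_structure Numeric vector of target fold-changes for the shared
#'   epitopes, recycled; directions alternate between the case and control
#'   pool. Values below the downstream fold threshold (default 5) plant
#'   "unassigned" shared epitopes on purpose.
#' @param viral_count_multiplier Multiplier applied to the intended counts of
#'   epitopes whose source protein is viral, emulating the virus-dominated
#'   read depth seen after competitive panning.
#' @param noise_peptide_count Number of low-count noise peptides per pool.
#' @param stop_codon_rate Fraction of emitted inserts carrying a premature
#'   stop codon.
#' @param flank5,flank3 DNA context flanking the 36-nt insert in each read
#'   (defaults: the display vector's forward primer and the reverse complement
#'   of its reverse primer).
#' @param count_distribution List with `meanlog` and `sdlog` of the log-normal
#'   intended-count distribution for planted epitopes.
#' @param noise_count_mean Mean of the geometric count distribution (support
#'   starting at 1) for noise peptides.
#' @param substitution_error_rate Per-base substitution error rate applied to
#'   emitted reads.
#' @param n_mimicry_pairs Number of planted human-viral mimicry 12-mer pairs.
#' @param mimicry_mismatches Positions at which the two members of a mimicry
#'   pair differ (default 1).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, n_microbial_species = 12, n_human_proteins = 6)
#' cfg$pools
sim_config <- function(seed = 1L,
                       n_microbial_species = 60L,
                       n_proteins_per_species = 2L,
                       n_human_proteins = 40L,
                       n_trim_like_paralogs = 8L,
                       protein_length_range = c(120L, 300L),
                       pools = c("case_P10", "case_P20",
                                 "control_P10", "control_P20"),
                       n_true_epitopes_per_pool = 40L,
                       n_shared_epitopes = 12L,
                       fold_structure = c(10, 8, 6, 2),
                       viral_count_multiplier = 3,
                       noise_peptide_count = 5000L,
                       stop_codon_rate = 0.135,
                       flank5 = "ATTCACCTGACTGACGAC",
                       flank3 = "CGCTGACGAATATCAGGG",
                       count_distribution = list(meanlog = log(500), sdlog = 0.8),
                       noise_count_mean = 1.5,
                       substitution_error_rate = 0,
                       n_mimicry_pairs = 3L,
                       mimicry_mismatches = 1L) {
  assert_count(seed, "seed", min = 0L)
  assert_count(n_microbial_species, "n_microbial_species", min = 1L)
  assert_count(n_proteins_per_species, "n_proteins_per_species", min = 1L)
  assert_count(n_human_proteins, "n_human_proteins", min = 1L)
  assert_count(n_trim_like_paralogs, "n_trim_like_paralogs", min = 0L)
  assert_count(n_true_epitopes_per_pool, "n_true_epitopes_per_pool", min = 1L)
  assert_count(n_shared_epitopes, "n_shared_epitopes", min = 0L)
  assert_count(noise_peptide_count, "noise_peptide_count", min = 0L)
  assert_count(n_mimicry_pairs, "n_mimicry_pairs", min = 0L)
  assert_fraction(stop_codon_rate, "stop_codon_rate")
  assert_fraction(substitution_error_rate, "substitution_error_rate")
  if (n_shared_epitopes > n_true_epitopes_per_pool) {
    abort("`n_shared_epitopes` must not exceed `n_true_epitopes_per_pool`.")
  }
  if (length(protein_length_range) != 2L ||
      protein_length_range[1] < 20L ||
      protein_length_range[2] < protein_length_range[1]) {
    abort("`protein_length_range` must be c(min, max) with min >= 20.")
  }
  if (!all(grepl("^(case|control)_P[0-9]+$", pools))) {
    abort("pool labels must look like 'case_P20' / 'control_P10'.")
  }
  if (anyDuplicated(pools)) abort("pool labels must be distinct.")
  if (nchar(flank5) < 6L || nchar(flank3) < 6L) {
    abort("flanking sequences must be at least 6 nt long.")
  }
  if (!all(strsplit(paste0(flank5, flank3), "")[[1]] %in% c("A", "C", "G", "T"))) {
    abort("flanking sequences must be DNA over {A,C,G,T}.")
  }
  if (2L * n_mimicry_pairs + n_shared_epitopes > n_true_epitopes_per_pool) {
    abort(paste0("n_true_epitopes_per_pool must accommodate the shared ",
                 "epitopes plus two planted peptides per mimicry pair."))
  }
  if (n_mimicry_pairs > 0L && n_trim_like_paralogs < 1L) {
    abort("mimicry planting needs at least one TRIM-like human paralog.")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_microbial_species = as.integer(n_microbial_species),
      n_proteins_per_species = as.integer(n_proteins_per_species),
      n_human_proteins = as.integer(n_human_proteins),
      n_trim_like_paralogs = as.integer(n_trim_like_paralogs),
      protein_length_range = as.integer(protein_length_range),
      pools = pools,
      n_true_epitopes_per_pool = as.integer(n_true_epitopes_per_pool),
      n_shared_epitopes = as.integer(n_shared_epitopes),
      fold_structure = fold_structure,
      viral_count_multiplier = viral_count_multiplier,
      noise_peptide_count = as.integer(noise_peptide_count),
      stop_codon_rate = stop_codon_rate,
      flank5 = flank5,
      flank3 = flank3,
      count_distribution = count_distribution,
      noise_count_mean = noise_count_mean,
      substitution_error_rate = substitution_error_rate,
      n_mimicry_pairs = as.integer(n_mimicry_pairs),
      mimicry_mismatches = as.integer(mimicry_mismatches)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  pools:", paste(x$pools, collapse = ", "), "\n")
  cat(sprintf("  reference: %d microbial species (x%d proteins), %d + %d human\n",
              x$n_microbial_species, x$n_proteins_per_species,
              x$n_human_proteins, x$n_trim_like_paralogs))
  cat(sprintf("  epitopes/pool: %d (%d shared), noise peptides: %d\n",
              x$n_true_epitopes_per_pool, x$n_shared_epitopes,
              x$noise_peptide_count))
  cat(sprintf("  stop-codon rate: %.3f, substitution rate: %g, mimicry pairs: %d\n",
              x$stop_codon_rate, x$substitution_error_rate, x$n_mimicry_pairs))
  invisible(x)
}

pool_cohort <- function(pool) sub("_.*$", "", pool)
pool_depth <- function(pool) sub("^[^_]*_", "", pool)
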