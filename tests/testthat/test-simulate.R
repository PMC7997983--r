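test_that("configuration validation rejects impossible study designs", {
  expect_error(sim_config(n_microbial_species = 0), "n_microbial_species")
  expect_error(sim_config(n_human_proteins = 0), "n_human_proteins")
  expect_error(sim_config(stop_codon_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_true_epitopes_per_pool = 5, n_shared_epitopes = 6),
               "must not exceed")
  expect_error(sim_config(flank5 = "ACGT"), "6 nt")
  expect_error(sim_config(pools = c("case_P10", "case_P10")), "distinct")
})

test_that("the same seed reproduces byte-identical reference and reads", {
  cfg <- small_config(seed = 3)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(ref1, ref2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_reference(ref1, d1); write_reference(ref2, d2)
  for (f in c("reference.fasta", "lineage.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  lib1 <- generate_library(cfg, ref1)
  lib2 <- generate_library(cfg, ref2)
  expect_identical(lib1$pools, lib2$pools)
})

test_that("reference record counts and structure match the configuration", {
  cfg <- small_config(seed = 5)
  ref <- generate_reference(cfg)
  n_expected <- cfg$n_microbial_species * cfg$n_proteins_per_species +
    cfg$n_human_proteins + cfg$n_trim_like_paralogs + 2L  # isoform copies
  expect_equal(nrow(ref$proteins), n_expected)
  expect_setequal(unique(ref$lineage$superkingdom),
                  c("Viruses", "Bacteria", "Eukaryota", "Archaea"))
  # viral rows carry a genome type; cellular rows do not
  vir <- ref$lineage$superkingdom == "Viruses"
  expect_true(all(!is.na(ref$lineage$genome_type[vir])))
  expect_true(all(is.na(ref$lineage$genome_type[!vir])))
  # TRIM-like paralogs share >= 60% identity pairwise
  tl <- ref$proteins$sequence[grepl("^TRIML", ref$proteins$protein_id)]
  for (i in seq_along(tl)) for (j in seq_len(i - 1L)) {
    a <- strsplit(tl[i], "")[[1]]; b <- strsplit(tl[j], "")[[1]]
    expect_gte(mean(a == b), 0.6)
  }
})

test_that("mimicry pairs are planted verbatim in their named proteins", {
  cfg <- small_config(seed = 7, n_mimicry_pairs = 2L)
  ref <- generate_reference(cfg)
  pairs <- ref$truth$mimicry_pairs
  expect_equal(nrow(pairs), 2L)
  seq_of <- function(id) ref$proteins$sequence[ref$proteins$protein_id == id]
  for (i in seq_len(nrow(pairs))) {
    expect_true(grepl(pairs$human_peptide[i], seq_of(pairs$human_protein[i]),
                      fixed = TRUE))
    expect_true(grepl(pairs$microbial_peptide[i],
                      seq_of(pairs$microbial_protein[i]), fixed = TRUE))
    expect_lte(pairs$n_mismatches[i], 2L)
    expect_gte(pairs$n_mismatches[i], 1L)
  }
})

test_that("every planted epitope is a substring of a reference protein", {
  ref <- generate_reference(small_config(seed = 13))
  whole <- paste(ref$proteins$sequence, collapse = "#")
  for (pep in unique(ref$truth$planted$peptide)) {
    expect_true(grepl(pep, whole, fixed = TRUE))
  }
})

test_that("reverse translation round-trips and respects its seed", {
  dna <- reverse_translate(strrep("A", 12), seed = 1)
  expect_equal(nchar(dna), 36L)
  expect_equal(oracle_translate(dna)$peptide, strrep("A", 12))

  pep <- "ACDEFGHIKLMN"
  expect_identical(reverse_translate(pep, seed = 9),
                   reverse_translate(pep, seed = 9))
  for (p in random_aa(25)) {
    expect_equal(oracle_translate(reverse_translate(p))$peptide, p)
  }
  expect_error(reverse_translate("ACDEFGHIKLM"), "12 residues")
  expect_error(reverse_translate("ACDEFGHIKLM*"), "standard amino acids")
  expect_error(reverse_translate("ACDEFGHIKLMX"), "standard amino acids")
})

test_that("per-pool read totals equal the sum of intended counts", {
  cfg <- small_config(seed = 17)
  ref <- generate_reference(cfg)
  lib <- generate_library(cfg, ref)
  for (p in cfg$pools) {
    intended <- sum(lib$truth_counts$intended_count[lib$truth_counts$pool == p])
    expect_equal(nrow(lib$pools[[p]]), intended)
  }
})

test_that("premature-stop fraction matches the configured rate", {
  cfg <- small_config(seed = 19, stop_codon_rate = 0.13,
                      noise_peptide_count = 400L)
  ref <- generate_reference(cfg)
  lib <- generate_library(cfg, ref)
  reads <- lib$pools$case_P20
  tr <- translate_inserts(
    extract_inserts(reads, cfg$flank5, cfg$flank3)$insert)
  n <- sum(!is.na(tr$truncated))
  frac <- mean(tr$truncated, na.rm = TRUE)
  se <- sqrt(0.13 * 0.87 / n)
  expect_lt(abs(frac - 0.13), 3 * se)
})

test_that("with no substitution errors every stop-free insert is a planted or noise peptide", {
  cfg <- small_config(seed = 23, substitution_error_rate = 0)
  ref <- generate_reference(cfg)
  lib <- generate_library(cfg, ref)
  reads <- lib$pools$control_P20
  tr <- translate_inserts(
    extract_inserts(reads, cfg$flank5, cfg$flank3)$insert)
  full <- tr$peptide[!is.na(tr$truncated) & !tr$truncated]
  truth <- lib$truth_counts$peptide[lib$truth_counts$pool == "control_P20"]
  expect_true(all(full %in% truth))
})

test_that("recovered full-length counts follow the binomial stop-thinning oracle", {
  rate <- 0.135
  cfg <- small_config(seed = 29, stop_codon_rate = rate)
  ref <- generate_reference(cfg)
  lib <- generate_library(cfg, ref)
  tr <- translate_inserts(
    extract_inserts(lib$pools$case_P20, cfg$flank5, cfg$flank3)$insert)
  obs <- table(tr$peptide[!is.na(tr$truncated) & !tr$truncated])
  truth <- dplyr::filter(lib$truth_counts, pool == "case_P20",
                         role == "planted")
  for (i in seq_len(nrow(truth))) {
    n <- truth$intended_count[i]
    got <- if (truth$peptide[i] %in% names(obs)) obs[[truth$peptide[i]]] else 0
    # Binomial(n, 1 - rate): allow 4 sd to keep the all-epitope sweep stable
    expect_lt(abs(got - n * (1 - rate)), 4 * sqrt(n * rate * (1 - rate)) + 1)
  }
})

test_that("FASTQ round trip preserves reads and pairs carry the same insert", {
  cfg <- small_config(seed = 31, noise_peptide_count = 30L)
  ref <- generate_reference(cfg)
  lib <- generate_library(cfg, ref)
  dir <- withr::local_tempdir()
  write_library_fastq(lib, dir)
  back <- read_fastq_reads(file.path(dir, "case_P20_R1.fastq"),
                           file.path(dir, "case_P20_R2.fastq"))
  expect_equal(back$r1, lib$pools$case_P20$r1)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(back$r2)))
  expect_equal(rc, back$r1)
})
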