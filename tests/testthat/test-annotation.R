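toy_proteome <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    taxid = c(101L, 102L, 9606L),
    isoform_group = c("P1", "P2", "P3"),
    sequence = c(
      paste0("MKT", "WLDERANGQSVH", "PLY", "AACDEFGHIKLM", "TTR"),
      strrep("ACDEFGHIKLMNPQRSTVWY", 3),
      paste0("MSS", "WLDERANGQSVH", "KKE")
    )
  )
}

test_that("the k-mer index enumerates every window with verifiable positions", {
  one <- tibble::tibble(protein_id = "P", taxid = 1L,
                        sequence = paste(rep("ACDEFGHIKL", 5), collapse = ""))
  idx <- build_peptide_index(one, k = 10)
  expect_equal(idx$total_positions, 50L - 10L + 1L)
  expect_equal(sum(idx$background), 1)

  dup <- dplyr::bind_rows(one, dplyr::mutate(one, protein_id = "Q"))
  idx2 <- build_peptide_index(dup, k = 10)
  expect_equal(length(igome:::index_lookup(idx2, "ACDEFGHIKL")), 2L * 5L)

  expect_error(build_peptide_index(one, k = 5), "at least 6")
  expect_error(build_peptide_index(one[0, ]), "empty")

  set.seed(3)
  prot <- tibble::tibble(protein_id = sprintf("R%d", 1:5), taxid = 1:5,
                         sequence = vapply(1:5, function(i)
                           paste(random_aa(1, 80), collapse = ""),
                           character(1)))
  idx3 <- build_peptide_index(prot, k = 10)
  # spot-check 50 random windows
  for (w in sample(idx3$total_positions, 50)) {
    r <- idx3$windows$prot_row[w]; o <- idx3$windows$offset[w]
    kmer <- substr(prot$sequence[r], o, o + 9L)
    expect_true(w %in% igome:::index_lookup(idx3, kmer))
  }
})

test_that("strict annotation reports exact occurrences with correct spans", {
  idx <- build_peptide_index(toy_proteome(), k = 10)
  got <- annotate_epitopes("WLDERANGQSVH", idx)
  expect_equal(nrow(got), 2L)
  expect_setequal(got$protein_id, c("P1", "P3"))
  expect_true(all(got$identity == 1))
  for (i in seq_len(nrow(got))) {
    seqs <- toy_proteome()$sequence[match(got$protein_id[i],
                                          toy_proteome()$protein_id)]
    expect_equal(substr(seqs, got$span_start[i] + 1L, got$span_end[i]),
                 got$epitope[i])
  }
  # multi-protein ambiguity is penalised through the significance
  expect_equal(got$significance[1],
               significance_score("WLDERANGQSVH", idx, 2))
  solo <- annotate_epitopes("AACDEFGHIKLM", idx)
  expect_equal(solo$protein_id, "P1")
  expect_equal(solo$significance,
               significance_score("AACDEFGHIKLM", idx, 1))
})

test_that("a 12-mer absent in full falls back to its maximal sub-match", {
  idx <- build_peptide_index(toy_proteome(), k = 10)
  # 10-AA prefix present in P1/P3, full 12-mer absent
  pep <- paste0("WLDERANGQS", "WW")
  got <- annotate_epitopes(pep, idx)
  expect_true(all(got$match_len == 10L))
  orc <- oracle_window_scan(pep, toy_proteome(), min_len = 10)
  expect_setequal(paste(got$protein_id, got$span_start),
                  paste(orc$protein_id, orc$start - 1L))
  expect_error(annotate_epitopes("SHORTPEP", idx), "shorter")
})

test_that("strict mode equals a naive substring scan on a random proteome", {
  set.seed(17)
  prot <- tibble::tibble(
    protein_id = sprintf("N%02d", 1:20), taxid = 1:20,
    sequence = vapply(1:20, function(i) paste(random_aa(1, 150), collapse = ""),
                      character(1)))
  idx <- build_peptide_index(prot, k = 10)
  # half planted windows, half random peptides
  planted <- vapply(1:15, function(i) {
    r <- sample(20, 1); s <- sample(139, 1)
    substr(prot$sequence[r], s, s + 11L)
  }, character(1))
  eps <- unique(c(planted, random_aa(15)))
  for (pep in eps) {
    got <- annotate_epitopes(pep, idx, collapse_isoforms = FALSE)
    full <- oracle_substring_scan(pep, prot)
    if (!is.null(full)) {
      expect_setequal(paste(got$protein_id, got$span_start),
                      paste(full$protein_id, full$start - 1L))
      expect_true(all(got$match_len == 12L))
    } else {
      orc <- oracle_window_scan(pep, prot, min_len = 10)
      if (is.null(orc)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_setequal(paste(got$protein_id, got$span_start, got$match_len),
                        paste(orc$protein_id, orc$start - 1L, orc$match_len))
      }
    }
  }
})

test_that("isoform redundancy collapses to one best hit per group", {
  prot <- tibble::tibble(
    protein_id = c("G1-iso1", "G1-iso2", "G1-iso3", "OTHER"),
    taxid = rep(9606L, 4),
    isoform_group = c("G1", "G1", "G1", "OTHER"),
    sequence = c(rep(paste0("MKL", "WLDERANGQSVH", strrep("PA", 20)), 3),
                 strrep("ACDEFGHIKLMNPQRSTVWY", 3)))
  idx <- build_peptide_index(prot, k = 10)
  got <- annotate_epitopes("WLDERANGQSVH", idx)
  expect_equal(nrow(got), 1L)
  expect_equal(got$protein_id, "G1-iso1")  # lexicographic tie-break
  raw <- annotate_epitopes("WLDERANGQSVH", idx, collapse_isoforms = FALSE)
  expect_equal(nrow(raw), 3L)
})

test_that("relaxed identity mode admits near-matches gated by the threshold", {
  idx <- build_peptide_index(toy_proteome(), k = 10)
  mutated <- "WLDERANGQSWW"  # 10/12 identity to the planted window
  expect_equal(nrow(annotate_epitopes(mutated, idx,
                                      relaxed_identity = 0.9)), 0L)
  got <- annotate_epitopes(mutated, idx, relaxed_identity = 0.8)
  expect_setequal(got$protein_id, c("P1", "P3"))
  expect_true(all(abs(got$identity - 10 / 12) < 1e-9))
})

test_that("the significance surrogate obeys its closed form and monotonicity", {
  idx <- list(background = stats::setNames(rep(1 / 20, 20), igome:::AA_STANDARD),
              total_positions = 1e4)
  class(idx) <- "peptide_index"
  # E = 1e4 * 20^-12; sig ~ E for E << 1
  e <- 1e4 * 20^-12
  expect_equal(significance_score(strrep("A", 12), idx, 1), -expm1(-e),
               tolerance = 1e-12)
  expect_lt(abs(significance_score(strrep("A", 12), idx, 1) - 2.4e-12),
            1e-13)

  # saturation: homopolymer against a homopolymer-rich background
  rich <- list(background = stats::setNames(c(0.9, rep(0.1 / 19, 19)),
                                            igome:::AA_STANDARD),
               total_positions = 1e6)
  class(rich) <- "peptide_index"
  expect_gt(significance_score(strrep("A", 6), rich, 5), 0.999)

  # extending a match strictly decreases the score
  s_old <- significance_score(strrep("A", 10), idx, 1)
  s_new <- significance_score(strrep("A", 11), idx, 1)
  expect_lt(s_new, s_old)

  # composition-based: residue order is irrelevant
  expect_equal(significance_score("ACDEFGHIKL", idx, 2),
               significance_score("LKIHGFEDCA", idx, 2))
})

test_that("planted epitopes annotate to their source proteins at zero error rate", {
  sim <- default_sim()
  idx <- build_peptide_index(sim$ref$proteins)
  tr <- dplyr::filter(sim$ref$truth$planted, pool == "case_P20")
  got <- annotate_epitopes(
    tibble::tibble(peptide = tr$peptide, reads = tr$intended_count), idx)
  found <- dplyr::inner_join(tr, got,
                             by = c(peptide = "epitope",
                                    protein_id = "protein_id"))
  expect_equal(nrow(found), nrow(tr))
  expect_true(all(found$identity == 1))
})

test_that("protein summaries compute mean significance and log10 intensity", {
  hits <- tibble::tibble(
    epitope = c("AAAAAAAAAAAA", "CCCCCCCCCCCC"),
    protein_id = "P", taxid = 1L, span_start = 0L, span_end = 12L,
    match_len = 12L, identity = 1, significance = c(0.2, 0.4),
    reads = c(10L, 1000L))
  got <- protein_summary(hits)
  expect_equal(got$mean_log10_intensity, 2)
  expect_equal(got$mean_sig, 0.3)
  one <- protein_summary(hits[1, ] |> dplyr::mutate(reads = 20L))
  expect_equal(one$mean_log10_intensity, log10(20), tolerance = 1e-4)
})
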