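test_that("global alignment matches a brute-force affine-gap dynamic program", {
  ident <- global_align("ACDEFGHIKLMN", "ACDEFGHIKLMN")
  expect_equal(ident$identity, 1)
  expect_false(grepl("-", ident$a_aln))

  near <- global_align("RIPDDVRRRPGC", "RIQDDVRRRPGC")
  expect_false(grepl("-", near$a_aln))
  expect_equal(near$identity, 11 / 12)

  set.seed(21)
  for (i in 1:60) {
    a <- random_aa(1, sample(6:15, 1))
    b <- random_aa(1, sample(6:15, 1))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                 tolerance = 1e-9)
  }
  expect_error(global_align("", "ACD"), "non-empty")
})

test_that("Kimura protein distance follows its closed form", {
  expect_equal(kimura_distance(global_align("AAAAAAAAAAAA", "AAAAAAAAAAAA")),
               0)
  d1 <- kimura_distance(global_align("RIPDDVRRRPGC", "RIQDDVRRRPGC"))
  D <- 1 / 12
  expect_equal(d1, -log(1 - D - 0.2 * D^2), tolerance = 1e-12)
  expect_equal(round(d1, 4), 0.0885)

  # strictly increasing in D on the valid domain
  ds <- vapply(seq(0, 0.8, by = 0.05), function(D) -log(1 - D - 0.2 * D^2),
               numeric(1))
  expect_true(all(diff(ds) > 0))

  expect_error(
    kimura_distance("AAAAAAAAAAAA", "CCCCCCCCCCCC"), "saturates")
  expect_error(kimura_distance("--A", "A--"), "non-gap")
})

test_that("neighbour joining recovers closed-form and additive trees", {
  # three taxa: closed-form pendant branches
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  got <- nj_tree(d3)
  tips <- got$tree$tip.label
  lens <- got$tree$edge.length[match(match(c("A", "B", "C"), tips),
                                     got$tree$edge[, 2])]
  expect_equal(lens, c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2, (4 + 5 - 3) / 2))

  # additive five-taxon distances are reproduced exactly
  tr <- ape::rtree(5, br = function(n) runif(n, 0.1, 1))
  d5 <- ape::cophenetic.phylo(tr)
  fit <- nj_tree(d5)
  path <- ape::cophenetic.phylo(fit$tree)
  expect_equal(path[rownames(d5), colnames(d5)], d5, tolerance = 1e-9)

  # two identical taxa: a zero-length cherry
  d2 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  cherry <- nj_tree(d2)
  expect_equal(sum(cherry$tree$edge.length), 0)
  expect_equal(length(cherry$tree$tip.label), 2L)

  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("neighbour joining agrees with a naive quartic-time reference", {
  set.seed(33)
  for (n in c(4, 6, 9, 12)) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    d <- ape::cophenetic.phylo(tr)
    # mild perturbation keeps the matrix metric-like but non-additive
    noise <- matrix(runif(n * n, -0.01, 0.01), n, n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- d + noise
    fit <- nj_tree(d)
    orc <- oracle_nj_edges(d)
    expect_setequal(
      edges_bipartitions(phylo_to_edges(fit$tree), n),
      edges_bipartitions(orc, n))
    got_path <- ape::cophenetic.phylo(fit$tree)[rownames(d), rownames(d)]
    orc_path <- edges_path_matrix(orc, n)
    dimnames(orc_path) <- dimnames(d)
    expect_equal(got_path, orc_path, tolerance = 1e-8)
  }
})

test_that("negative branch estimates are clamped and counted", {
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 0.1, 1,
                1, 0.1, 0, 0.1,
                1, 1, 0.1, 0), 4, 4)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  fit <- suppressWarnings(nj_tree(d))
  expect_true(all(fit$tree$edge.length >= 0))
  expect_gte(fit$n_clamped, 1L)
})

test_that("Newick output round-trips", {
  tr <- ape::rtree(7)
  path <- withr::local_tempfile(fileext = ".nwk")
  fit <- nj_tree(ape::cophenetic.phylo(tr))
  write_newick(fit, path)
  back <- read_newick(path)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("bootstrap supports are seeded, bounded and saturate on clean data", {
  epi <- tibble::tibble(
    label = c("h1", "h2", "v1", "v2", "o1"),
    sequence = c("AAAAAAAAAAAA", "AAAAAAAAAAAC",
                 "WWWWWWWWWWWW", "WWWWWWWWWWWC",
                 "AAAAAAWWWWWW"))
  bs1 <- suppressWarnings(bootstrap_support(epi, n_replicates = 40, seed = 4))
  bs2 <- suppressWarnings(bootstrap_support(epi, n_replicates = 40, seed = 4))
  expect_identical(bs1$supports, bs2$supports)
  sup <- bs1$supports[!is.na(bs1$supports)]
  expect_true(all(sup >= 0 & sup <= 100))

  # conflict-free, well-separated cherries bootstrap to full support
  clean <- tibble::tibble(
    label = c("a1", "a2", "b1", "b2"),
    sequence = c("AAAAAAAAAAAA", "AAAAAAAAAAAA",
                 "WWWWWWWWWWWW", "WWWWWWWWWWWW"))
  bsc <- suppressWarnings(bootstrap_support(clean, n_replicates = 25,
                                            seed = 2))
  expect_true(all(bsc$supports[!is.na(bsc$supports)] == 100))
})

test_that("tight cross-kingdom cherries are reported as mimicry clades", {
  set.seed(2)
  base <- random_aa(8)
  epi <- tibble::tibble(
    label = c("humA", "virA", paste0("bg", 1:6)),
    sequence = c("RIPDDVRRRPGC", "RIQDDVRRRPGC", base[1:6]),
    kingdom = c("human", "viral", rep("viral", 6)))
  phy <- suppressWarnings(epitope_phylogeny(epi))
  mc <- mimicry_clades(phy, max_leaf_branch = 0.1)
  expect_true(any(mc$pairs$human_label == "humA" &
                  mc$pairs$microbial_label == "virA"))
  pair <- mc$pairs[mc$pairs$human_label == "humA", ][1, ]
  expect_equal(pair$n_mismatches, 1L)
  expect_equal(pair$kimura_distance, 0.0885, tolerance = 1e-3)

  # the same pair with a tight ceiling is no longer reported
  mc2 <- mimicry_clades(phy, max_leaf_branch = 0.01)
  expect_false(any(mc2$pairs$human_label == "humA" &
                   mc2$pairs$microbial_label == "virA"))

  no_kingdom <- phy
  no_kingdom$epitopes$kingdom <- NULL
  expect_error(mimicry_clades(no_kingdom), "kingdom")
})

test_that("planted one-mismatch mimicry pairs are recovered at default settings", {
  sim <- default_sim()
  ref <- sim$ref
  tr <- dplyr::filter(ref$truth$planted, pool == "case_P20")
  epi <- tr |>
    dplyr::mutate(kingdom = ifelse(taxid == 9606L, "human", "viral")) |>
    dplyr::transmute(label = paste0(peptide, "|", protein_id),
                     sequence = peptide, kingdom = kingdom)
  epi <- epi[1:20, ]  # mimicry peptides plus background epitopes
  phy <- suppressWarnings(epitope_phylogeny(epi))
  mc <- mimicry_clades(phy)
  pairs <- ref$truth$mimicry_pairs
  for (i in seq_len(nrow(pairs))) {
    expect_true(any(
      grepl(pairs$human_peptide[i], mc$pairs$human_label, fixed = TRUE) &
      grepl(pairs$microbial_peptide[i], mc$pairs$microbial_label,
            fixed = TRUE)),
      label = sprintf("mimicry pair %d recovered", i))
  }
})
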