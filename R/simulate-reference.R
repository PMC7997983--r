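#' Generate a synthetic reference proteome with taxonomy and planted truth
#'
#' Builds the annotation universe the downstream pipeline runs against: random
#' microbial proteins organised into a pseudo-taxonomy (superkingdom through
#' species, with a genome-type column for viruses), a human protein set
#' containing a TRIM-like paralog family (pairwise identity >= 60%) and a few
#' isoform copies, planted human-viral mimicry 12-mers, and per-pool planted
#' epitopes with intended read counts. Every planted epitope is a verbatim
#' substring of at least one reference protein, so exact-match annotation can
#' recover it at 100% identity.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `igome_reference` with elements
#'   * `proteins`: tibble `protein_id`, `taxid`, `isoform_group`, `sequence`;
#'   * `lineage`: tibble `taxid`, `superkingdom`, `kingdom`, `phylum`,
#'     `class`, `order`, `family`, `genus`, `species`, `genome_type`;
#'   * `truth`: list with `planted` (pool, peptide, source protein, intended
#'     count, sharing/fold structure) and `mimicry_pairs`.
#' @export
#' @examples
#' ref <- generate_reference(sim_config(seed = 7, n_microbial_species = 10,
#'                                      n_human_proteins = 5,
#'                                      noise_peptide_count = 50))
#' ref$proteins
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_local(config$seed, {
    lineage <- simulate_lineage(config)
    proteins <- simulate_proteins(config, lineage)

    mim <- plant_mimicry(config, proteins, lineage)
    proteins <- mim$proteins

    planted <- plant_epitopes(config, proteins, lineage, mim$pairs)

    structure(
      list(
        proteins = proteins,
        lineage = lineage,
        truth = list(planted = planted, mimicry_pairs = mim$pairs)
      ),
      class = "igome_reference"
    )
  })
}

# ---- taxonomy ---------------------------------------------------------------

GENOME_TYPES <- c("dsDNA", "ssDNA", "dsRNA", "ssRNA", "RNA-RT", "DNA-RT")

simulate_lineage <- function(config) {
  n <- config$n_microbial_species
  # Virus-rich split mirroring a display-library exposome screen.
  n_vir <- max(1L, round(0.40 * n))
  n_bac <- max(1L, round(0.45 * n))
  n_euk <- max(0L, round(0.12 * n))
  n_arc <- n - n_vir - n_bac - n_euk
  if (n_arc < 0L) { n_bac <- n_bac + n_arc; n_arc <- 0L }
  sk <- rep(c("Viruses", "Bacteria", "Eukaryota", "Archaea"),
            times = c(n_vir, n_bac, n_euk, n_arc))
  prefix <- c(Viruses = "Vir", Bacteria = "Bac",
              Eukaryota = "Euk", Archaea = "Arc")[sk]

  # ~3 species per family, nested pseudo-ranks above.
  fam_idx <- unlist(lapply(table(sk)[unique(sk)], function(m) {
    rep(seq_len(ceiling(m / 3)), each = 3L)[seq_len(m)]
  }), use.names = FALSE)

  tibble(
    taxid = 100000L + seq_len(n),
    superkingdom = sk,
    kingdom = paste0(prefix, "_kingdom", (fam_idx - 1L) %/% 4L + 1L),
    phylum = paste0(prefix, "_phylum", (fam_idx - 1L) %/% 3L + 1L),
    class = paste0(prefix, "_class", (fam_idx - 1L) %/% 2L + 1L),
    order = paste0(prefix, "_order", fam_idx),
    family = sprintf("%sfam%02d", prefix, fam_idx),
    genus = sprintf("%sgen%03d", prefix, seq_len(n)),
    species = sprintf("%s species %03d", prefix, seq_len(n)),
    genome_type = ifelse(
      sk == "Viruses",
      sample(GENOME_TYPES, n, replace = TRUE,
             prob = c(0.30, 0.12, 0.10, 0.30, 0.10, 0.08)),
      NA_character_
    )
  ) |>
    dplyr::bind_rows(tibble(
      taxid = 9606L, superkingdom = "Eukaryota", kingdom = "Metazoa",
      phylum = "Chordata", class = "Mammalia", order = "Primates",
      family = "Hominidae", genus = "Homo", species = "Homo sapiens",
      genome_type = NA_character_
    ))
}

random_protein <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, frac) {
  chars <- strsplit(seq, "")[[1]]
  k <- max(1L, round(frac * length(chars)))
  pos <- sample(length(chars), k)
  chars[pos] <- vapply(chars[pos], function(a) {
    sample(setdiff(AA_STANDARD, a), 1L)
  }, character(1))
  paste(chars, collapse = "")
}

simulate_proteins <- function(config, lineage) {
  rng <- config$protein_length_range
  micro_tax <- lineage$taxid[lineage$taxid != 9606L]
  micro <- tidyr::expand_grid(taxid = micro_tax,
                              idx = seq_len(config$n_proteins_per_species)) |>
    mutate(
      protein_id = sprintf("MSP%05d_P%d", .data$taxid - 100000L, .data$idx),
      sequence = vapply(seq_len(dplyr::n()), function(i) {
        random_protein(sample(rng[1]:rng[2], 1L))
      }, character(1))
    ) |>
    select("protein_id", "taxid", "sequence")

  human <- tibble(
    protein_id = sprintf("HUM%03d", seq_len(config$n_human_proteins)),
    taxid = 9606L,
    sequence = vapply(seq_len(config$n_human_proteins), function(i) {
      random_protein(sample(rng[1]:rng[2], 1L))
    }, character(1))
  )

  # TRIM-like paralog family: point-mutate 15% of a common scaffold, keeping
  # pairwise identity comfortably above the 60% floor.
  triml <- tibble(protein_id = character(), taxid = integer(),
                  sequence = character())
  if (config$n_trim_like_paralogs > 0L) {
    scaffold <- random_protein(max(rng[1], 200L))
    triml <- tibble(
      protein_id = sprintf("TRIML%02d", seq_len(config$n_trim_like_paralogs)),
      taxid = 9606L,
      sequence = vapply(seq_len(config$n_trim_like_paralogs), function(i) {
        mutate_protein(scaffold, 0.15)
      }, character(1))
    )
  }

  out <- dplyr::bind_rows(micro, human, triml) |>
    mutate(isoform_group = .data$protein_id)

  # A small isoform family of the first human protein (same isoform_group),
  # so isoform collapsing has something to collapse.
  iso_base <- human$protein_id[1]
  iso <- tibble(
    protein_id = paste0(iso_base, "-iso", 2:3),
    taxid = 9606L,
    sequence = vapply(1:2, function(i) {
      s <- human$sequence[1]
      tail_start <- nchar(s) - 29L
      paste0(substr(s, 1L, tail_start - 1L),
             mutate_protein(substr(s, tail_start, nchar(s)), 0.1))
    }, character(1)),
    isoform_group = iso_base
  )
  dplyr::bind_rows(out, iso) |>
    select("protein_id", "taxid", "isoform_group", "sequence")
}

# ---- mimicry ----------------------------------------------------------------

random_peptide <- function(len) paste(sample(AA_STANDARD, len, replace = TRUE),
                                      collapse = "")

embed_peptide <- function(sequence, peptide) {
  L <- nchar(sequence)
  w <- nchar(peptide)
  start <- sample(L - w + 1L, 1L)
  list(
    sequence = paste0(substr(sequence, 1L, start - 1L), peptide,
                      substr(sequence, start + w, L)),
    start = start
  )
}

plant_mimicry <- function(config, proteins, lineage) {
  n <- config$n_mimicry_pairs
  pairs <- tibble(pair_id = integer(), human_protein = character(),
                  microbial_protein = character(), human_peptide = character(),
                  microbial_peptide = character(), n_mismatches = integer())
  if (n == 0L) return(list(proteins = proteins, pairs = pairs))

  viral_tax <- lineage$taxid[lineage$superkingdom == "Viruses"]
  viral_rows <- which(proteins$taxid %in% viral_tax)
  triml_rows <- which(grepl("^TRIML", proteins$protein_id))
  if (length(viral_rows) == 0L) abort("mimicry planting needs viral proteins.")

  host <- triml_rows[(seq_len(n) - 1L) %% length(triml_rows) + 1L]
  vir <- sample(viral_rows, n, replace = length(viral_rows) < n)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    pep_h <- random_peptide(12L)
    pep_v <- mutate_protein(pep_h, config$mimicry_mismatches / 12)
    eh <- embed_peptide(proteins$sequence[host[i]], pep_h)
    ev <- embed_peptide(proteins$sequence[vir[i]], pep_v)
    proteins$sequence[host[i]] <- eh$sequence
    proteins$sequence[vir[i]] <- ev$sequence
    recs[[i]] <- tibble(
      pair_id = i,
      human_protein = proteins$protein_id[host[i]],
      microbial_protein = proteins$protein_id[vir[i]],
      human_peptide = pep_h,
      microbial_peptide = pep_v,
      n_mismatches = sum(strsplit(pep_h, "")[[1]] != strsplit(pep_v, "")[[1]])
    )
  }
  list(proteins = proteins, pairs = dplyr::bind_rows(recs))
}

# ---- planted epitopes -------------------------------------------------------

sample_window <- function(proteins, width = 12L) {
  i <- sample(nrow(proteins), 1L, prob = nchar(proteins$sequence))
  L <- nchar(proteins$sequence[i])
  start <- sample(L - width + 1L, 1L)
  list(peptide = substr(proteins$sequence[i], start, start + width - 1L),
       protein_id = proteins$protein_id[i], taxid = proteins$taxid[i])
}

sample_distinct_windows <- function(proteins, n, exclude = character()) {
  out <- vector("list", n)
  seen <- exclude
  i <- 1L
  guard <- 0L
  while (i <= n) {
    w <- sample_window(proteins)
    guard <- guard + 1L
    if (guard > 50L * n + 100L) abort("could not sample enough distinct windows.")
    if (w$peptide %in% seen) next
    seen <- c(seen, w$peptide)
    out[[i]] <- w
    i <- i + 1L
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble_row))
}

draw_counts <- function(n, config) {
  pmax(2, round(rlnorm(n, meanlog = config$count_distribution$meanlog,
                       sdlog = config$count_distribution$sdlog)))
}

plant_epitopes <- function(config, proteins, lineage, mimicry_pairs) {
  viral_tax <- lineage$taxid[lineage$superkingdom == "Viruses"]
  depths <- unique(pool_depth(config$pools))
  n_mim_pep <- 2L * config$n_mimicry_pairs
  taken <- c(mimicry_pairs$human_peptide, mimicry_pairs$microbial_peptide)

  mim_tbl <- NULL
  if (n_mim_pep > 0L) {
    pid <- c(rbind(mimicry_pairs$human_protein, mimicry_pairs$microbial_protein))
    mim_tbl <- tibble(
      peptide = c(rbind(mimicry_pairs$human_peptide,
                        mimicry_pairs$microbial_peptide)),
      protein_id = pid,
      taxid = proteins$taxid[match(pid, proteins$protein_id)]
    )
  }

  res <- list()
  for (d in depths) {
    pools_d <- config$pools[pool_depth(config$pools) == d]
    case_pool <- pools_d[pool_cohort(pools_d) == "case"]
    ctrl_pool <- pools_d[pool_cohort(pools_d) == "control"]

    shared <- sample_distinct_windows(proteins, config$n_shared_epitopes,
                                      exclude = taken)
    taken <- c(taken, shared$peptide)

    folds <- rep_len(config$fold_structure, config$n_shared_epitopes)
    direction <- rep_len(c("case", "control"), config$n_shared_epitopes)
    base <- draw_counts(config$n_shared_epitopes, config)
    boost <- ifelse(shared$taxid %in% viral_tax,
                    config$viral_count_multiplier, 1)
    low <- pmax(2, round(base * boost))
    high <- pmax(2, round(low * folds))

    for (pool in pools_d) {
      cohort <- pool_cohort(pool)
      if (config$n_shared_epitopes > 0L) {
        cnt <- ifelse(direction == cohort, high, low)
        shared_tbl <- shared |>
          mutate(pool = pool, intended_count = cnt, role = "planted",
                 shared = TRUE, fold_target = folds,
                 fold_direction = direction)
      } else {
        shared_tbl <- NULL
      }

      extra <- if (length(case_pool) && pool == case_pool) mim_tbl else NULL
      n_unique <- config$n_true_epitopes_per_pool -
        config$n_shared_epitopes - (if (is.null(extra)) 0L else nrow(extra))
      uniq <- sample_distinct_windows(proteins, n_unique, exclude = taken)
      taken <- c(taken, uniq$peptide)
      uniq <- dplyr::bind_rows(extra, uniq)
      ucnt <- draw_counts(nrow(uniq), config)
      uboost <- ifelse(uniq$taxid %in% viral_tax,
                       config$viral_count_multiplier, 1)
      uniq_tbl <- uniq |>
        mutate(pool = pool, intended_count = pmax(2, round(ucnt * uboost)),
               role = "planted", shared = FALSE, fold_target = NA_real_,
               fold_direction = NA_character_)

      res[[pool]] <- dplyr::bind_rows(shared_tbl, uniq_tbl)
    }
  }
  dplyr::bind_rows(res) |>
    select("pool", "peptide", "protein_id", "taxid", "role",
           "intended_count", "shared", "fold_target", "fold_direction")
}

#' @export
print.igome_reference <- function(x, ...) {
  cat("<igome_reference>\n")
  cat(sprintf("  %d proteins over %d taxa (%d planted epitope records, %d mimicry pairs)\n",
              nrow(x$proteins), nrow(x$lineage), nrow(x$truth$planted),
              nrow(x$truth$mimicry_pairs)))
  invisible(x)
}
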