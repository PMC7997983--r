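#' Reverse-translate a displayed peptide into a 36-nt variance region
#'
#' Inverse of frame-1 translation: each residue is encoded by a synonymous
#' codon drawn uniformly at random (no codon-usage bias), so translating the
#' result in frame 1 with the standard genetic code returns the input peptide.
#'
#' @param peptide A 12-residue peptide over the 20 standard amino acids
#'   (no stop symbol, no ambiguity codes).
#' @param seed Optional integer seed; the same peptide and seed give the same
#'   DNA, different seeds may differ in synonymous codons.
#' @return A 36-character DNA string.
#' @export
#' @examples
#' dna <- reverse_translate("ACDEFGHIKLMN", seed = 1)
#' nchar(dna)
reverse_translate <- function(peptide, seed = NULL) {
  if (!is.character(peptide) || length(peptide) != 1L) {
    abort("`peptide` must be a single string.")
  }
  aas <- strsplit(peptide, "")[[1]]
  if (length(aas) != 12L) {
    abort(sprintf("`peptide` must be exactly 12 residues (got %d).", length(aas)))
  }
  if (!all(aas %in% AA_STANDARD)) {
    abort("`peptide` may only contain the 20 standard amino acids.")
  }
  pick <- function() {
    vapply(aas, function(a) {
      cods <- REV_CODON[[a]]
      cods[sample.int(length(cods), 1L)]
    }, character(1))
  }
  codons <- if (is.null(seed)) pick() else with_seed_local(seed, pick())
  paste(codons, collapse = "")
}

# Amino acid -> synonymous codons, standard genetic code (stops excluded).
REV_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[AA_STANDARD]
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Emit synthetic display-library reads per pool
#'
#' Turns the reference's planted truth into per-pool paired-end reads: each
#' read is `flank5 + 36-nt insert + flank3`, each planted epitope contributes
#' exactly its intended read count, low-count noise peptides ride underneath
#' at geometric counts, a configured fraction of inserts has one codon
#' replaced by a premature stop, and optional per-base substitution errors are
#' applied to the finished reads. Mates carry the same insert (the second mate
#' is the reverse complement of the first).
#'
#' @param config A [sim_config()] object (the one used for the reference).
#' @param reference An [generate_reference()] result.
#' @return A list of class `igome_library`:
#'   * `pools`: named list of tibbles `read_id`, `r1`, `r2`;
#'   * `truth_counts`: tibble `pool`, `peptide`, `role` (planted/noise),
#'     `intended_count`;
#'   * `qc`: tibble `pool`, `n_reads`, `n_stop_inserts`.
#' @export
generate_library <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "igome_reference"))
  if (nchar(config$flank5) < 6L || nchar(config$flank3) < 6L) {
    abort("flanking sequences must be at least 6 nt long.")
  }
  with_seed_local(config$seed + 7L, {
    pools <- list()
    truth_counts <- list()
    qc <- list()
    for (pool in config$pools) {
      planted <- reference$truth$planted |>
        filter(.data$pool == !!pool) |>
        select("peptide", count = "intended_count") |>
        mutate(role = "planted")

      noise <- tibble(
        peptide = vapply(seq_len(config$noise_peptide_count),
                         function(i) random_peptide(12L), character(1)),
        count = rgeom(config$noise_peptide_count,
                      prob = 1 / (1 + config$noise_count_mean)) + 1L,
        role = "noise"
      ) |>
        filter(!.data$peptide %in% planted$peptide) |>
        distinct(.data$peptide, .keep_all = TRUE)

      pep <- dplyr::bind_rows(planted, noise)
      inserts <- vapply(pep$peptide, reverse_translate, character(1),
                        USE.NAMES = FALSE)

      reads <- rep.int(inserts, pep$count)
      n <- length(reads)

      # Premature stop codons: Bernoulli per read, one random codon replaced.
      is_stop <- runif(n) < config$stop_codon_rate
      idx <- which(is_stop)
      if (length(idx)) {
        cod <- sample.int(12L, length(idx), replace = TRUE)
        stp <- sample(STOP_CODONS, length(idx), replace = TRUE)
        substr(reads[idx], 3L * cod - 2L, 3L * cod) <- stp
      }

      full <- paste0(config$flank5, reads, config$flank3)

      if (config$substitution_error_rate > 0 && n > 0L) {
        full <- apply_substitution_errors(full, config$substitution_error_rate)
      }

      ord <- sample.int(n)
      full <- full[ord]
      r2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(full)))
      pools[[pool]] <- tibble(
        read_id = sprintf("%s_read%07d", pool, seq_len(n)),
        r1 = full, r2 = r2
      )
      truth_counts[[pool]] <- pep |>
        mutate(pool = pool) |>
        select("pool", "peptide", "role", intended_count = "count")
      qc[[pool]] <- tibble(pool = pool, n_reads = n,
                           n_stop_inserts = length(idx))
    }
    structure(
      list(pools = pools,
           truth_counts = dplyr::bind_rows(truth_counts),
           qc = dplyr::bind_rows(qc)),
      class = "igome_library"
    )
  })
}

apply_substitution_errors <- function(reads, rate) {
  len <- nchar(reads[1])
  n_err <- rbinom(1L, length(reads) * len, rate)
  if (n_err == 0L) return(reads)
  at_read <- sample.int(length(reads), n_err, replace = TRUE)
  at_pos <- sample.int(len, n_err, replace = TRUE)
  for (i in seq_len(n_err)) {
    cur <- substr(reads[at_read[i]], at_pos[i], at_pos[i])
    substr(reads[at_read[i]], at_pos[i], at_pos[i]) <-
      sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  reads
}

#' @export
print.igome_library <- function(x, ...) {
  cat("<igome_library>\n")
  print(x$qc)
  invisible(x)
}

# ---- on-disk interchange ----------------------------------------------------

#' Write a synthetic reference to FASTA + lineage TSV
#'
#' FASTA headers are `proteinID|taxid|isoformGroup`; the lineage table is a
#' plain TSV with the taxon ranks and the viral genome-type column.
#'
#' @param reference An `igome_reference`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fasta")
  aa <- Biostrings::AAStringSet(reference$proteins$sequence)
  names(aa) <- with(reference$proteins,
                    paste(protein_id, taxid, isoform_group, sep = "|"))
  Biostrings::writeXStringSet(aa, fa)
  tsv <- file.path(dir, "lineage.tsv")
  write.table(reference$lineage, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, lineage = tsv))
}

#' Read a reference proteome written by [write_reference()]
#'
#' @param fasta Path to the FASTA (headers `proteinID|taxid[|isoformGroup]`).
#' @param lineage_tsv Path to the lineage TSV.
#' @return A list with `proteins` and `lineage` tibbles.
#' @export
read_reference <- function(fasta, lineage_tsv) {
  aa <- Biostrings::readAAStringSet(fasta)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  proteins <- tibble(
    protein_id = vapply(parts, `[`, character(1), 1L),
    taxid = as.integer(vapply(parts, `[`, character(1), 2L)),
    isoform_group = vapply(parts, function(p) {
      if (length(p) >= 3L) p[3] else p[1]
    }, character(1)),
    sequence = as.character(aa)
  )
  lineage <- as_tibble(read.delim(lineage_tsv, sep = "\t",
                                  stringsAsFactors = FALSE))
  list(proteins = proteins, lineage = lineage)
}

#' Write library reads as FASTQ (Phred+33, fixed quality)
#'
#' @param library An `igome_library`.
#' @param dir Output directory.
#' @param quality_char Single quality character applied to every base.
#' @return Invisibly, a tibble of the files written.
#' @export
write_library_fastq <- function(library, dir, quality_char = "I") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (pool in names(library$pools)) {
    reads <- library$pools[[pool]]
    for (mate in c("r1", "r2")) {
      dna <- Biostrings::DNAStringSet(reads[[mate]])
      names(dna) <- reads$read_id
      qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads[[mate]])))
      path <- file.path(dir, sprintf("%s_%s.fastq", pool, toupper(mate)))
      Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
      out[[paste(pool, mate)]] <- tibble(pool = pool, mate = mate, path = path)
    }
  }
  invisible(dplyr::bind_rows(out))
}

#' Read FASTQ reads into a tibble
#'
#' @param r1 Path to the first-mate FASTQ (optionally gzipped).
#' @param r2 Optional path to the second-mate FASTQ.
#' @return A tibble `read_id`, `r1` and, when given, `r2`.
#' @export
read_fastq_reads <- function(r1, r2 = NULL) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  out <- tibble(read_id = sub(" .*$", "", names(s1)),
                r1 = unname(as.character(s1)))
  if (!is.null(r2)) {
    s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
    out$r2 <- unname(as.character(s2))
  }
  out
}
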