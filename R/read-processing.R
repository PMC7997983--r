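#' Extract the 36-nt variance region from display-library reads
#'
#' Locates the first occurrence of the 5' flank and the first occurrence of
#' the 3' flank after it (each allowing up to `max_mismatches` substitutions)
#' and returns the insert between them. A read yields `NA` (and is tallied as
#' unparsed) unless the insert is exactly `insert_width` nt and free of `N`.
#' When a second mate is present, reads whose first mate fails are retried on
#' the reverse complement of the second mate.
#'
#' @param reads A tibble with columns `r1` (and optionally `read_id`, `r2`),
#'   or a character vector of reads.
#' @param flank5,flank3 Flanking DNA (non-empty).
#' @param max_mismatches Substitutions tolerated in each flank match.
#' @param insert_width Required insert length (default 36).
#' @return A tibble `read_id`, `insert` (`NA` when unparseable), `status`
#'   (`parsed` / `unparsed`).
#' @export
extract_inserts <- function(reads, flank5, flank3, max_mismatches = 0L,
                            insert_width = 36L) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%07d", seq_along(reads)), r1 = reads)
  }
  if (!nchar(flank5) || !nchar(flank3)) abort("flanks must be non-empty.")
  if (max_mismatches < 0L) abort("`max_mismatches` must be >= 0.")
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))
  }

  insert <- extract_one_mate(reads$r1, flank5, flank3, max_mismatches,
                             insert_width)
  if ("r2" %in% names(reads)) {
    miss <- which(is.na(insert))
    if (length(miss)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$r2[miss])))
      insert[miss] <- extract_one_mate(rc, flank5, flank3, max_mismatches,
                                       insert_width)
    }
  }
  tibble(
    read_id = reads$read_id,
    insert = insert,
    status = ifelse(is.na(insert), "unparsed", "parsed")
  )
}

extract_one_mate <- function(seqs, flank5, flank3, max_mismatches,
                             insert_width) {
  n <- length(seqs)
  if (n == 0L) return(character(0))
  dna <- Biostrings::DNAStringSet(seqs)
  m5 <- Biostrings::vmatchPattern(flank5, dna, max.mismatch = max_mismatches)
  m3 <- Biostrings::vmatchPattern(flank3, dna, max.mismatch = max_mismatches)
  s5 <- Biostrings::startIndex(m5)
  s3 <- Biostrings::startIndex(m3)
  w5 <- nchar(flank5)

  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a <- s5[[i]]
    if (is.null(a) || !length(a)) next
    from <- a[1] + w5
    b <- s3[[i]]
    b <- b[b >= from]
    if (!length(b)) next
    to <- b[1] - 1L
    if (to - from + 1L != insert_width) next
    ins <- substr(seqs[i], from, to)
    if (grepl("N", ins, fixed = TRUE)) next
    out[i] <- ins
  }
  out
}

#' Translate 36-nt inserts in frame 1
#'
#' Standard-code frame-1 translation of the display construct's fixed reading
#' frame. A premature stop truncates the peptide to the prefix before the
#' stop (`truncated = TRUE`); a stop-free insert yields the full 12-mer.
#'
#' @param inserts Character vector of 36-nt inserts (`NA`s are passed through).
#' @return A tibble `insert`, `peptide`, `truncated`.
#' @export
#' @examples
#' translate_inserts(strrep("GCT", 12))
translate_inserts <- function(inserts) {
  ok <- !is.na(inserts)
  if (any(nchar(inserts[ok]) != 36L)) {
    abort("all inserts must be exactly 36 nt.")
  }
  if (length(inserts) == 0L || !any(ok)) {
    return(tibble(insert = inserts, peptide = NA_character_, truncated = NA))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(inserts[ok]), no.init.codon = TRUE))
  pep <- sub("\\*.*$", "", aa)
  out <- tibble(insert = inserts,
                peptide = NA_character_,
                truncated = NA)
  out$peptide[ok] <- pep
  out$truncated[ok] <- nchar(pep) < 12L
  out
}

#' Aggregate translated peptides into an epitope table
#'
#' Collates identical peptide sequences into distinct epitopes with read
#' counts, discarding (and tallying) peptides shorter than `min_len` residues.
#'
#' @param peptides Character vector of peptides (one element per read), or the
#'   tibble returned by [translate_inserts()].
#' @param pool Pool label, e.g. `"case_P20"`.
#' @param min_len Minimum retained peptide length in residues (default 6).
#' @param n_unparsed Reads that failed insert extraction (carried into QC).
#' @return An `epitope_table`: a tibble `peptide`, `count` (sorted by
#'   decreasing count) with attributes `pool`, `total_reads` (parsed +
#'   unparsed input reads) and `qc` (parsed / unparsed / stop-truncated /
#'   short-discarded tallies).
#' @export
build_epitope_table <- function(peptides, pool = "pool", min_len = 6L,
                                n_unparsed = 0L) {
  truncated <- NULL
  if (is.data.frame(peptides)) {
    truncated <- peptides$truncated
    n_unparsed <- n_unparsed + sum(is.na(peptides$peptide))
    truncated <- truncated[!is.na(peptides$peptide)]
    peptides <- peptides$peptide[!is.na(peptides$peptide)]
  }
  n_in <- length(peptides)
  keep <- nchar(peptides) >= min_len
  n_short <- sum(!keep)
  entries <- tibble(peptide = peptides[keep]) |>
    count(.data$peptide, name = "count") |>
    arrange(desc(.data$count), .data$peptide)
  qc <- list(
    parsed = n_in,
    unparsed = as.integer(n_unparsed),
    stop_truncated = if (is.null(truncated)) NA_integer_
                     else sum(truncated, na.rm = TRUE),
    short_discarded = n_short
  )
  new_epitope_table(entries, pool = pool,
                    total_reads = n_in + as.integer(n_unparsed), qc = qc)
}

new_epitope_table <- function(entries, pool, total_reads, qc = list()) {
  stopifnot(all(c("peptide", "count") %in% names(entries)))
  structure(
    as_tibble(entries[c("peptide", "count")]),
    pool = pool, total_reads = total_reads, qc = qc,
    class = c("epitope_table", class(tibble())))
}

#' Turn a plain peptide-count table into an `epitope_table`
#'
#' @param x A data frame with columns `peptide` and `count`.
#' @param pool Pool label.
#' @param total_reads Total reads behind the table; defaults to `sum(count)`.
#' @return An `epitope_table`.
#' @export
as_epitope_table <- function(x, pool = "pool", total_reads = NULL) {
  if (any(x$count < 1)) abort("all counts must be >= 1.")
  new_epitope_table(as_tibble(x), pool = pool,
                    total_reads = total_reads %||% sum(x$count))
}

#' @export
print.epitope_table <- function(x, ...) {
  cat(sprintf("<epitope_table> pool=%s, %d distinct epitopes, %s total reads\n",
              attr(x, "pool"), nrow(x),
              format(attr(x, "total_reads"), big.mark = ",")))
  NextMethod()
}

#' Pool label / QC accessors for epitope tables
#' @param x An `epitope_table`.
#' @return The pool label, total read count, or QC tally list.
#' @export
pool_label <- function(x) attr(x, "pool")

#' @rdname pool_label
#' @export
total_reads <- function(x) attr(x, "total_reads")

#' @rdname pool_label
#' @export
table_qc <- function(x) attr(x, "qc")

#' Process one pool of reads into a cleaned epitope table
#'
#' Convenience wrapper: [extract_inserts()] then [translate_inserts()] then
#' [build_epitope_table()].
#'
#' @inheritParams extract_inserts
#' @inheritParams build_epitope_table
#' @return An `epitope_table`.
#' @export
process_pool <- function(reads, pool, flank5, flank3, max_mismatches = 0L,
                         min_len = 6L) {
  ext <- extract_inserts(reads, flank5, flank3, max_mismatches)
  tr <- translate_inserts(ext$insert)
  build_epitope_table(tr, pool = pool, min_len = min_len)
}
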