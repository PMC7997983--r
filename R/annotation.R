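#' Build an exact k-mer seed index over a reference proteome
#'
#' Enumerates every length-`k` window of every protein and hashes it to its
#' (protein, offset) positions, together with the background amino-acid
#' frequencies of the reference. Because annotation demands 100% identity over
#' the matched span, k-mer seeding plus maximal extension finds exactly the
#' matches a full substring scan would.
#'
#' @param proteins Tibble with columns `protein_id`, `taxid`, `sequence` and
#'   optionally `isoform_group` (defaults to `protein_id`), e.g.
#'   `generate_reference()$proteins` or [read_reference()]`$proteins`.
#' @param k Seed length in residues (>= 6; default 10, the annotation length
#'   floor).
#' @return A list of class `peptide_index`: `k`, `map` (hashed environment
#'   k-mer -> window ids), `windows` (protein row + offset per window id),
#'   `background` (residue frequencies, summing to 1), `total_positions`
#'   (number of indexed windows) and the `proteins` table.
#' @export
build_peptide_index <- function(proteins, k = 10L) {
  if (nrow(proteins) == 0L) abort("`proteins` is empty.")
  if (k < 6L) abort("`k` must be at least 6.")
  if (!"isoform_group" %in% names(proteins)) {
    proteins$isoform_group <- proteins$protein_id
  }
  lens <- nchar(proteins$sequence)
  if (any(lens < k)) abort("every protein must be at least `k` residues long.")

  n_win <- lens - k + 1L
  prot_row <- rep.int(seq_len(nrow(proteins)), n_win)
  offset <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  kmer <- substring(proteins$sequence[prot_row], offset, offset + k - 1L)

  map <- list2env(split(seq_along(kmer), kmer), hash = TRUE)

  residues <- strsplit(paste(proteins$sequence, collapse = ""), "")[[1]]
  bg_tab <- table(factor(residues, levels = AA_STANDARD))
  background <- as.numeric(bg_tab) / length(residues)
  names(background) <- AA_STANDARD

  structure(
    list(k = as.integer(k), map = map,
         windows = list(prot_row = prot_row, offset = offset),
         background = background,
         total_positions = length(kmer),
         proteins = proteins),
    class = "peptide_index"
  )
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> k=%d, %d windows over %d proteins\n",
              x$k, x$total_positions, nrow(x$proteins)))
  invisible(x)
}

index_lookup <- function(index, kmer) {
  hit <- index$map[[kmer]]
  if (is.null(hit)) integer(0) else hit
}

#' Composition-based chance significance of an exact peptide match
#'
#' Maps the chance expectation of observing the matched residues in the
#' reference onto the unit interval: `E = total_positions * prod(background
#' frequency of each matched residue)` and `sig = 1 - exp(-E *
#' n_proteins_hit)`. Lower is more specific; the score is strictly decreasing
#' in match length for a fixed composition, saturates at 1 for unspecific
#' matches, and is penalised by `n_proteins_hit` when one epitope annotates
#' many proteins. Residue order does not enter (composition-based by design).
#'
#' @param matched The matched residue string.
#' @param index The [build_peptide_index()] the match was found in.
#' @param n_proteins_hit Number of distinct proteins the epitope hits.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' # A 12-mer hit in a reference of 1e4 positions is essentially unambiguous:
#' idx <- list(background = setNames(rep(1/20, 20),
#'             strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
#'             total_positions = 1e4)
#' class(idx) <- "peptide_index"
#' significance_score(strrep("A", 12), idx, 1)
significance_score <- function(matched, index, n_proteins_hit = 1L) {
  res <- strsplit(matched, "")[[1]]
  expectation <- index$total_positions * prod(index$background[res])
  -expm1(-expectation * n_proteins_hit)
}

#' Annotate enriched epitopes against the reference proteome
#'
#' Strict mode (`relaxed_identity = 1`) reports every exact occurrence of the
#' full epitope; when an epitope has no full-length occurrence, maximal exact
#' sub-matches of at least `min_match_len` residues are reported instead
#' (several spans per protein are possible — dis-contiguous matches). Relaxed
#' mode reports the best gapless alignment per protein with identity at or
#' above `relaxed_identity`. Isoform redundancy is collapsed to the best hit
#' per isoform group (lowest significance, then longest match, then
#' lexicographic protein id).
#'
#' @param epitopes Tibble with columns `peptide` and optionally `reads`
#'   (carried through; default 1), or a character vector of peptides.
#' @param index A [build_peptide_index()].
#' @param min_match_len Minimum reported match length (>= the index's `k`).
#' @param relaxed_identity Identity threshold in (0, 1]; 1 = strict exact mode.
#' @param collapse_isoforms Collapse hits within an isoform group (default
#'   TRUE).
#' @return A tibble `epitope`, `protein_id`, `taxid`, `span_start`,
#'   `span_end` (0-based, half-open on the protein), `match_len`, `identity`,
#'   `significance`, `reads`.
#' @export
annotate_epitopes <- function(epitopes, index, min_match_len = 10L,
                              relaxed_identity = 1.0,
                              collapse_isoforms = TRUE) {
  stopifnot(inherits(index, "peptide_index"))
  if (is.character(epitopes)) epitopes <- tibble(peptide = epitopes)
  if (!"reads" %in% names(epitopes)) epitopes$reads <- 1L
  if (relaxed_identity <= 0 || relaxed_identity > 1) {
    abort("`relaxed_identity` must be in (0, 1].")
  }
  if (min_match_len < index$k) {
    abort(sprintf(
      "`min_match_len` (%d) below the index seed length k=%d; rebuild the index with a smaller k.",
      min_match_len, index$k))
  }
  short <- nchar(epitopes$peptide) < min_match_len
  if (any(short)) {
    abort(sprintf("%d epitope(s) shorter than min_match_len=%d.",
                  sum(short), min_match_len))
  }

  hits <- purrr::map2(epitopes$peptide, epitopes$reads, function(pep, rds) {
    h <- if (relaxed_identity >= 1) {
      strict_hits(pep, index, min_match_len)
    } else {
      relaxed_hits(pep, index, relaxed_identity)
    }
    if (is.null(h) || nrow(h) == 0L) return(NULL)
    h$epitope <- pep
    h$reads <- rds
    h
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble(epitope = character(), protein_id = character(),
                  taxid = integer(), span_start = integer(),
                  span_end = integer(), match_len = integer(),
                  identity = double(), significance = double(),
                  reads = integer()))
  }

  prot <- index$proteins[hits$prot_row, ]
  hits <- hits |>
    mutate(protein_id = prot$protein_id, taxid = prot$taxid,
           isoform_group = prot$isoform_group)

  hits <- hits |>
    group_by(.data$epitope) |>
    mutate(n_proteins_hit = dplyr::n_distinct(.data$protein_id)) |>
    ungroup()
  hits$significance <- purrr::map2_dbl(
    hits$matched, hits$n_proteins_hit,
    function(m, np) significance_score(m, index, np))

  if (collapse_isoforms) {
    hits <- hits |>
      group_by(.data$epitope, .data$isoform_group) |>
      arrange(.data$significance, desc(.data$match_len), .data$protein_id,
              .by_group = TRUE) |>
      mutate(best_protein = dplyr::first(.data$protein_id)) |>
      filter(.data$protein_id == .data$best_protein) |>
      ungroup()
  }

  hits |>
    mutate(span_start = .data$prot_start - 1L,
           span_end = .data$prot_start - 1L + .data$match_len) |>
    select("epitope", "protein_id", "taxid", "span_start", "span_end",
           "match_len", "identity", "significance", "reads") |>
    arrange(.data$epitope, .data$protein_id, .data$span_start)
}

# All exact occurrences of the full epitope; else maximal exact sub-matches.
strict_hits <- function(pep, index, min_match_len) {
  L <- nchar(pep)
  k <- index$k
  seqs <- index$proteins$sequence

  # Full-length occurrences, seeded by the epitope's first k-mer.
  win <- index_lookup(index, substr(pep, 1L, k))
  full <- NULL
  if (length(win)) {
    pr <- index$windows$prot_row[win]
    off <- index$windows$offset[win]
    ok <- substring(seqs[pr], off, off + L - 1L) == pep
    if (any(ok)) {
      full <- tibble(prot_row = pr[ok], prot_start = off[ok],
                     match_len = L, matched = pep, identity = 1)
    }
  }
  if (!is.null(full)) return(full)

  # Maximal exact sub-matches of length >= min_match_len via every seed.
  found <- list()
  for (i in seq_len(L - k + 1L)) {
    win <- index_lookup(index, substr(pep, i, i + k - 1L))
    if (!length(win)) next
    pr <- index$windows$prot_row[win]
    off <- index$windows$offset[win]
    for (j in seq_along(win)) {
      ext <- extend_match(pep, i, seqs[pr[j]], off[j], k)
      key <- paste(pr[j], ext$prot_start, ext$len, sep = ":")
      if (is.null(found[[key]]) && ext$len >= min_match_len) {
        found[[key]] <- tibble(
          prot_row = pr[j], prot_start = ext$prot_start,
          match_len = ext$len,
          matched = substr(pep, ext$epi_start, ext$epi_start + ext$len - 1L),
          identity = 1)
      }
    }
  }
  if (length(found)) dplyr::bind_rows(found) else NULL
}

# Extend an exact k-seed maximally in both directions.
extend_match <- function(pep, epi_start, protein, prot_start, k) {
  L <- nchar(pep)
  P <- nchar(protein)
  a <- epi_start; b <- prot_start
  while (a > 1L && b > 1L &&
         substr(pep, a - 1L, a - 1L) == substr(protein, b - 1L, b - 1L)) {
    a <- a - 1L; b <- b - 1L
  }
  ae <- epi_start + k - 1L; be <- prot_start + k - 1L
  while (ae < L && be < P &&
         substr(pep, ae + 1L, ae + 1L) == substr(protein, be + 1L, be + 1L)) {
    ae <- ae + 1L; be <- be + 1L
  }
  list(epi_start = a, prot_start = b, len = ae - a + 1L)
}

# Best gapless alignment of the full epitope per protein, identity-thresholded.
relaxed_hits <- function(pep, index, min_identity) {
  L <- nchar(pep)
  pv <- strsplit(pep, "")[[1]]
  out <- list()
  for (r in seq_len(nrow(index$proteins))) {
    s <- index$proteins$sequence[r]
    P <- nchar(s)
    if (P < L) next
    sv <- strsplit(s, "")[[1]]
    best_id <- -1; best_off <- NA_integer_
    for (off in seq_len(P - L + 1L)) {
      id <- sum(sv[off:(off + L - 1L)] == pv) / L
      if (id > best_id) { best_id <- id; best_off <- off }
    }
    if (best_id >= min_identity) {
      matched <- paste(pv[sv[best_off:(best_off + L - 1L)] == pv],
                       collapse = "")
      out[[length(out) + 1L]] <- tibble(
        prot_row = r, prot_start = best_off, match_len = L,
        matched = matched, identity = best_id)
    }
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}

#' Per-protein summary of annotation hits
#'
#' One record per protein: the number of distinct epitopes hitting it, their
#' total read support, the mean of their significances, and the mean over the
#' protein's epitopes of `log10(read count)` (the "mean log10 intensity").
#' When an epitope hits a protein in several spans, its best (lowest
#' significance, then longest) span represents it.
#'
#' @param hits A tibble from [annotate_epitopes()].
#' @return A tibble `protein_id`, `taxid`, `n_epitopes`, `total_reads`,
#'   `mean_sig`, `mean_log10_intensity`.
#' @export
protein_summary <- function(hits) {
  hits |>
    group_by(.data$protein_id, .data$taxid, .data$epitope) |>
    arrange(.data$significance, desc(.data$match_len), .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    group_by(.data$protein_id, .data$taxid) |>
    summarise(
      n_epitopes = dplyr::n(),
      total_reads = sum(.data$reads),
      mean_sig = mean(.data$significance),
      mean_log10_intensity = mean(log10(.data$reads)),
      .groups = "drop"
    )
}
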