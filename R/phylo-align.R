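#' Optimal global alignment of two peptides
#'
#' Needleman-Wunsch global alignment under affine gap costs (default: open
#' 10.0, extend 1.0, BLOSUM62), the scoring used for cross-kingdom epitope
#' comparison.
#'
#' @param a,b Non-empty peptide strings.
#' @param gap_open,gap_ext Affine gap costs (positive).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @return A list of class `peptide_alignment`: `a_aln`, `b_aln` (gapped
#'   strings of equal length), `score`, `identity` (matching fraction of the
#'   both-non-gap columns).
#' @export
#' @examples
#' al <- global_align("RIPDDVRRRPGC", "RIQDDVRRRPGC")
#' al$identity  # 11/12
global_align <- function(a, b, gap_open = 10, gap_ext = 1,
                         substitution_matrix = "BLOSUM62") {
  if (!nchar(a) || !nchar(b)) abort("both sequences must be non-empty.")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_ext)
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  av <- strsplit(a_aln, "")[[1]]
  bv <- strsplit(b_aln, "")[[1]]
  both <- av != "-" & bv != "-"
  structure(
    list(a_aln = a_aln, b_aln = b_aln,
         score = Biostrings::score(pa),
         identity = if (any(both)) mean(av[both] == bv[both]) else 0),
    class = "peptide_alignment"
  )
}

#' @export
print.peptide_alignment <- function(x, ...) {
  cat(x$a_aln, "\n", x$b_aln, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.3f\n", x$score, x$identity))
  invisible(x)
}

#' Kimura protein distance of an aligned pair
#'
#' With `D` the fraction of differing residues among the both-non-gap columns
#' (pairwise deletion), the Kimura protein distance is
#' `d = -ln(1 - D - 0.2 D^2)`, a rate-corrected approximation to protein
#' divergence. The transform saturates: `D >= ~0.8541` has no finite distance
#' and raises an error.
#'
#' @param alignment A [global_align()] result, or a gapped string (with `b`).
#' @param b Optional second gapped string when `alignment` is a string.
#' @return The distance (0 for identical sequences).
#' @export
#' @examples
#' kimura_distance(global_align("AAAAAAAAAAAA", "AAAAAAAAAAAA"))  # 0
#' # one mismatch over 12 columns: about 0.0885
#' kimura_distance(global_align("RIPDDVRRRPGC", "RIQDDVRRRPGC"))
kimura_distance <- function(alignment, b = NULL) {
  if (inherits(alignment, "peptide_alignment")) {
    av <- strsplit(alignment$a_aln, "")[[1]]
    bv <- strsplit(alignment$b_aln, "")[[1]]
  } else {
    av <- strsplit(alignment, "")[[1]]
    bv <- strsplit(b, "")[[1]]
  }
  if (length(av) != length(bv)) abort("aligned strings differ in length.")
  both <- av != "-" & bv != "-"
  if (!any(both)) abort("no aligned (both non-gap) columns.")
  D <- mean(av[both] != bv[both])
  arg <- 1 - D - 0.2 * D^2
  if (arg <= 0) {
    abort(sprintf(
      "difference fraction D=%.3f saturates the Kimura transform (D >= ~0.8541).",
      D))
  }
  -log(arg)
}

# Capped variant for bootstrap replicates, where resampled columns can
# saturate or leave no overlap; such pairs get a large finite distance.
kimura_distance_capped <- function(av, bv, cap = 2) {
  both <- av != "-" & bv != "-"
  if (!any(both)) return(cap)
  D <- mean(av[both] != bv[both])
  arg <- 1 - D - 0.2 * D^2
  if (arg <= 0) return(cap)
  min(-log(arg), cap)
}

#' Pairwise Kimura distance matrix over labelled epitopes
#'
#' Aligns every pair with [global_align()] and records the Kimura protein
#' distance.
#'
#' @param epitopes Tibble with columns `label`, `sequence` (labels unique,
#'   sequences >= 6 residues), or a named character vector.
#' @param on_saturation `"error"` propagates the Kimura saturation error for
#'   pairs with difference fraction `D >= ~0.8541`; `"cap"` (used by the
#'   phylogeny builder) assigns such unrelated pairs the finite ceiling
#'   `cap`.
#' @param cap Distance ceiling under `on_saturation = "cap"` (default
#'   2: beyond a difference fraction of ~0.75 short peptides are effectively
#'   unrelated, and compressing their distances to a common ceiling keeps
#'   the NJ rate terms from absorbing saturation noise).
#' @param ... Passed to [global_align()].
#' @return A symmetric matrix with zero diagonal, dimnames = labels.
#' @export
epitope_distances <- function(epitopes, on_saturation = c("error", "cap"),
                              cap = 2, ...) {
  on_saturation <- match.arg(on_saturation)
  epitopes <- as_labelled_epitopes(epitopes)
  n <- nrow(epitopes)
  d <- matrix(0, n, n, dimnames = list(epitopes$label, epitopes$label))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(epitopes$sequence[i], epitopes$sequence[j], ...)
      d[i, j] <- d[j, i] <- if (on_saturation == "cap") {
        kimura_distance_capped(strsplit(al$a_aln, "")[[1]],
                               strsplit(al$b_aln, "")[[1]], cap = cap)
      } else {
        kimura_distance(al)
      }
    }
  }
  d
}

as_labelled_epitopes <- function(epitopes) {
  if (is.character(epitopes)) {
    labels <- names(epitopes) %||% paste0("epi", seq_along(epitopes))
    epitopes <- tibble(label = labels, sequence = unname(epitopes))
  }
  if (!all(c("label", "sequence") %in% names(epitopes))) {
    abort("`epitopes` needs `label` and `sequence` columns.")
  }
  if (anyDuplicated(epitopes$label)) abort("epitope labels must be unique.")
  if (any(nchar(epitopes$sequence) < 6L)) {
    abort("epitope sequences must be at least 6 residues.")
  }
  as_tibble(epitopes)
}

#' Star-progressive multiple alignment of short epitopes
#'
#' Aligns every epitope to the centre sequence (the one with the smallest
#' total pairwise Kimura distance) and merges the pairwise alignments by the
#' "once a gap, always a gap" rule. Adequate for the short, similar-length
#' peptides this package deals in; not a general-purpose MSA.
#'
#' @inheritParams epitope_distances
#' @return A character matrix (epitopes x alignment columns) with rownames =
#'   labels.
#' @export
align_epitopes <- function(epitopes, ...) {
  epitopes <- as_labelled_epitopes(epitopes)
  n <- nrow(epitopes)
  if (n == 1L) {
    m <- matrix(strsplit(epitopes$sequence, "")[[1]], nrow = 1)
    rownames(m) <- epitopes$label
    return(m)
  }
  d <- epitope_distances(epitopes, on_saturation = "cap", ...)
  centre <- which.min(rowSums(d))
  L <- nchar(epitopes$sequence[centre])

  others <- setdiff(seq_len(n), centre)
  # seg[[k]][i+1]: residues of sequence k inserted after centre position i.
  parse_one <- function(al) {
    cv <- strsplit(al$a_aln, "")[[1]]
    sv <- strsplit(al$b_aln, "")[[1]]
    seg <- vector("list", L + 1L)
    for (i in seq_len(L + 1L)) seg[[i]] <- character(0)
    aligned <- character(L)
    pos <- 0L
    for (col in seq_along(cv)) {
      if (cv[col] == "-") {
        seg[[pos + 1L]] <- c(seg[[pos + 1L]], sv[col])
      } else {
        pos <- pos + 1L
        aligned[pos] <- sv[col]
      }
    }
    list(seg = seg, aligned = aligned)
  }
  parsed <- lapply(others, function(k) {
    parse_one(global_align(epitopes$sequence[centre], epitopes$sequence[k],
                           ...))
  })
  ins <- vapply(seq_len(L + 1L), function(i) {
    if (!length(parsed)) 0L
    else max(vapply(parsed, function(p) length(p$seg[[i]]), integer(1)))
  }, integer(1))

  build_row <- function(seg, aligned) {
    out <- character(0)
    for (i in 0:L) {
      s <- seg[[i + 1L]]
      out <- c(out, s, rep("-", ins[i + 1L] - length(s)))
      if (i < L) out <- c(out, aligned[i + 1L])
    }
    out
  }
  centre_chars <- strsplit(epitopes$sequence[centre], "")[[1]]
  rows <- vector("list", n)
  rows[[centre]] <- build_row(rep(list(character(0)), L + 1L), centre_chars)
  for (j in seq_along(others)) {
    rows[[others[j]]] <- build_row(parsed[[j]]$seg, parsed[[j]]$aligned)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- epitopes$label
  m
}

#' Per-column conservation of a multiple alignment
#'
#' @param msa A character matrix from [align_epitopes()].
#' @return A tibble `column`, `consensus`, `conservation` (modal non-gap
#'   residue frequency among non-gap rows), `gap_fraction`.
#' @export
alignment_conservation <- function(msa) {
  purrr::map_dfr(seq_len(ncol(msa)), function(j) {
    col <- msa[, j]
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    tibble(
      column = j,
      consensus = if (length(tab)) names(tab)[1] else "-",
      conservation = if (length(tab)) as.numeric(tab[1]) / length(res) else 0,
      gap_fraction = mean(col == "-")
    )
  })
}
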