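#' Reads-per-million normalisation of an epitope table
#'
#' Converts read counts to reads per million over the table's entries, making
#' pools of unequal sequencing depth comparable before fold-change tests.
#'
#' @param table An `epitope_table` (non-empty).
#' @return A tibble `peptide`, `count`, `rpm`; the `rpm` column sums to 1e6.
#' @export
normalize_frequencies <- function(table) {
  if (nrow(table) == 0L) abort("cannot normalise an empty table.")
  total <- sum(table$count)
  tibble(peptide = table$peptide, count = table$count,
         rpm = table$count / total * 1e6)
}

#' Partition distinct epitopes between a case and a control pool
#'
#' Implements the epitope signature set analysis: epitopes seen in exactly one
#' pool form the *unique* sets (the symmetric difference); epitopes seen in
#' both are assigned to the pool whose normalised frequency is at least
#' `fold`-times the other's (*common* sets), or left *unassigned* when neither
#' direction reaches the threshold. There are no pseudocounts: absence from a
#' pool is definitionally "unique", never an infinite fold change.
#'
#' @param case,control `epitope_table`s (typically noise-filtered).
#' @param fold Fold-change threshold (> 1; default 5).
#' @param mode `"rpm"` (fold changes on reads-per-million, default) or
#'   `"raw"` (on raw counts).
#' @param min_len_annotation Minimum epitope length (residues) for the
#'   downstream annotation subsets (default 10).
#' @return A tibble of class `set_partition` with columns `peptide`,
#'   `count_case`, `count_control`, `rpm_case`, `rpm_control`, `fold_change`
#'   (enriched/depleted ratio; `NA` for unique epitopes) and `set` (one of
#'   `unique_case`, `unique_control`, `common_case`, `common_control`,
#'   `unassigned`). The attribute `annotation_sets` holds the >=
#'   `min_len_annotation`-residue subsets of the four enriched sets.
#' @export
partition_epitopes <- function(case, control, fold = 5, mode = c("rpm", "raw"),
                               min_len_annotation = 10L) {
  mode <- match.arg(mode)
  if (fold <= 1) abort("`fold` must be greater than 1.")

  norm <- function(tab) {
    if (nrow(tab) == 0L) {
      return(tibble(peptide = character(), count = integer(), rpm = double()))
    }
    normalize_frequencies(tab)
  }
  a <- rename(norm(case), count_case = "count", rpm_case = "rpm")
  b <- rename(norm(control), count_control = "count", rpm_control = "rpm")

  joined <- dplyr::full_join(a, b, by = "peptide")
  score_case <- if (mode == "rpm") joined$rpm_case else joined$count_case
  score_ctrl <- if (mode == "rpm") joined$rpm_control else joined$count_control

  in_case <- !is.na(joined$count_case)
  in_ctrl <- !is.na(joined$count_control)
  ratio <- ifelse(in_case & in_ctrl, score_case / score_ctrl, NA_real_)

  joined <- joined |>
    mutate(
      fold_change = dplyr::case_when(
        !in_case | !in_ctrl ~ NA_real_,
        ratio >= 1 ~ ratio,
        TRUE ~ 1 / ratio
      ),
      set = dplyr::case_when(
        in_case & !in_ctrl ~ "unique_case",
        !in_case & in_ctrl ~ "unique_control",
        ratio >= fold ~ "common_case",
        1 / ratio >= fold ~ "common_control",
        TRUE ~ "unassigned"
      )
    ) |>
    arrange(.data$set, .data$peptide)

  ann <- joined |>
    filter(.data$set != "unassigned",
           nchar(.data$peptide) >= min_len_annotation)
  structure(joined,
            fold = fold, mode = mode,
            annotation_sets = split(ann$peptide, ann$set),
            class = c("set_partition", class(tibble())))
}

#' Enriched epitope subsets long enough for annotation
#'
#' @param partition A [partition_epitopes()] result.
#' @return Named list of peptide character vectors (one per enriched set).
#' @export
annotation_sets <- function(partition) attr(partition, "annotation_sets")

#' The enriched epitopes of one cohort, with read counts
#'
#' The unique plus fold-enriched common epitopes of a cohort, restricted to
#' the annotation length floor — the input expected by [annotate_epitopes()].
#'
#' @param partition A [partition_epitopes()] result.
#' @param cohort `"case"` or `"control"`.
#' @param min_len Minimum epitope length (default 10).
#' @return A tibble `peptide`, `reads`.
#' @export
enriched_epitopes <- function(partition, cohort = c("case", "control"),
                              min_len = 10L) {
  cohort <- match.arg(cohort)
  cnt <- paste0("count_", cohort)
  partition |>
    filter(.data$set %in% paste0(c("unique_", "common_"), cohort),
           nchar(.data$peptide) >= min_len) |>
    select("peptide", reads = dplyr::all_of(cnt)) |>
    as_tibble()
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf("<set_partition> fold >= %s on %s frequencies\n",
              format(attr(x, "fold")), attr(x, "mode")))
  print(count(as_tibble(x), .data$set))
  invisible(x)
}
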