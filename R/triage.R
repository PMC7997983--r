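#' Human autoantibody target summaries split by annotation specificity
#'
#' Summarises annotation hits against the human partition of the reference
#' into per-protein records and splits them into the full target list and the
#' high-specificity subset (`mean_sig` below the threshold).
#'
#' @param hits A tibble from [annotate_epitopes()], restricted to (or
#'   containing) human proteins.
#' @param mean_sig_threshold Mean-significance cut-off in `[0, 1]`.
#' @param human_taxid Taxid of the human partition (default 9606).
#' @return A list with `total` and `high_specificity` protein-summary tibbles
#'   (see [protein_summary()]), each with a `high_specificity` flag column on
#'   `total`.
#' @export
human_hits <- function(hits, mean_sig_threshold = 0.578,
                       human_taxid = 9606L) {
  if (mean_sig_threshold < 0 || mean_sig_threshold > 1) {
    abort("`mean_sig_threshold` must be in [0, 1].")
  }
  total <- hits |>
    filter(.data$taxid == human_taxid) |>
    protein_summary() |>
    mutate(high_specificity = .data$mean_sig < mean_sig_threshold)
  list(
    total = total,
    high_specificity = filter(total, .data$high_specificity)
  )
}

#' Overlap statistics between two protein (or epitope) sets
#'
#' The percentage of the union shared by both pools:
#' `pct_shared = 100 * shared / (a + b - shared)`. Symmetric in the two
#' pools.
#'
#' @param a,b Set sizes of the two pools.
#' @param shared Size of their intersection (`<= min(a, b)`).
#' @return A one-row tibble `a`, `b`, `shared`, `union`, `pct_shared`,
#'   `ratio_a_over_b`.
#' @export
#' @examples
#' overlap_stats(2885, 1450, 498)$pct_shared  # ~13% of total targets shared
overlap_stats <- function(a, b, shared) {
  assert_count(a, "a"); assert_count(b, "b"); assert_count(shared, "shared")
  if (shared > min(a, b)) abort("`shared` cannot exceed min(a, b).")
  u <- a + b - shared
  if (u == 0) abort("the union is empty; the shared percentage is undefined.")
  tibble(a = a, b = b, shared = shared, union = u,
         pct_shared = 100 * shared / u,
         ratio_a_over_b = ifelse(b > 0, a / b, NA_real_))
}

#' Gene-set coverage and hypergeometric enrichment of a protein query
#'
#' For each gene set: the number of query proteins in the set, the coverage
#' percentage `100 * n_observed / set_size`, a one-sided hypergeometric
#' enrichment p-value against an explicit universe, and
#' Benjamini-Hochberg-adjusted q-values across sets.
#'
#' @param query Character vector of protein ids.
#' @param gene_sets Tibble `set_id`, `protein_id` (long membership map).
#' @param universe Character vector: the universe the enrichment is tested
#'   against. Must contain every set.
#' @return A tibble `set_id`, `set_size`, `n_observed`, `coverage_pct`,
#'   `p_value`, `q_value`.
#' @export
gene_set_coverage <- function(query, gene_sets, universe) {
  if (nrow(gene_sets) == 0L) abort("`gene_sets` is empty.")
  query <- unique(query)
  universe <- unique(universe)
  gs <- distinct(gene_sets, .data$set_id, .data$protein_id)
  sets <- split(gs$protein_id, gs$set_id)
  out <- imap(sets, function(members, set_id) {
    if (!all(members %in% universe)) {
      abort(sprintf("gene set '%s' contains proteins outside the universe.",
                    set_id))
    }
    m <- length(members)
    if (m > length(universe)) {
      abort(sprintf("gene set '%s' is larger than the universe.", set_id))
    }
    q_in <- intersect(query, universe)
    k <- length(intersect(q_in, members))
    p <- phyper(k - 1L, m, length(universe) - m, length(q_in),
                lower.tail = FALSE)
    tibble(set_id = set_id, set_size = m, n_observed = k,
           coverage_pct = 100 * k / m, p_value = p)
  })
  dplyr::bind_rows(out) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$set_id)
}

#' Coverage of a query by the union of a gene-set collection
#'
#' The percentage of the query contained in the membership union of the given
#' sets (`100 * |query ∩ ∪ sets| / |query|`); 0 for an empty query.
#'
#' @inheritParams gene_set_coverage
#' @return A one-row tibble `n_query`, `n_in_union`, `coverage_pct`.
#' @export
union_coverage <- function(query, gene_sets) {
  query <- unique(query)
  if (length(query) == 0L) {
    return(tibble(n_query = 0L, n_in_union = 0L, coverage_pct = 0))
  }
  members <- unique(gene_sets$protein_id)
  k <- length(intersect(query, members))
  tibble(n_query = length(query), n_in_union = k,
         coverage_pct = 100 * k / length(query))
}

#' Shared-target membership matrix across enriched gene sets
#'
#' Binary presence/absence matrix of proteins across gene sets, filtered to
#' proteins belonging to at least `min_membership` sets, optionally annotated
#' with per-protein mean log10 read intensity.
#'
#' @param gene_sets Tibble `set_id`, `protein_id` (the enriched sets).
#' @param min_membership Minimum number of sets a protein must belong to.
#' @param intensities Optional tibble `protein_id`, `mean_log10_intensity`.
#' @return A tibble with one row per retained protein: `protein_id`,
#'   `n_sets`, one 0/1 column per set, and `mean_log10_intensity` when
#'   supplied. Zero rows when `min_membership` exceeds the number of sets.
#' @export
shared_target_matrix <- function(gene_sets, min_membership = 6L,
                                 intensities = NULL) {
  if (nrow(gene_sets) == 0L) abort("`gene_sets` is empty.")
  wide <- gene_sets |>
    distinct(.data$set_id, .data$protein_id) |>
    mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "set_id", values_from = "present",
                       values_fill = 0L)
  set_cols <- setdiff(names(wide), "protein_id")
  wide$n_sets <- rowSums(wide[set_cols])
  out <- wide |>
    filter(.data$n_sets >= min_membership) |>
    select("protein_id", "n_sets", dplyr::all_of(sort(set_cols))) |>
    arrange(desc(.data$n_sets), .data$protein_id)
  if (!is.null(intensities)) {
    out <- left_join(out, intensities, by = "protein_id")
  }
  out
}
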