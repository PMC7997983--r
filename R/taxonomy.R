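#' Per-species IgOme profiles with NGSR e-norm
#'
#' Anchors annotation hits to the lineage table and summarises each species:
#' the number of distinct annotated epitopes, their total read support, and
#' the reads-per-epitope normalised abundance
#' `NGSR e-norm = n_reads / n_epitopes`. An epitope that annotates several
#' species is credited in full to each of them (set semantics;
#' `credit = "fractional"` splits its reads evenly instead); within a species
#' each distinct epitope's reads are counted once regardless of how many of
#' the species' proteins it hits.
#'
#' @param hits A tibble from [annotate_epitopes()].
#' @param lineage Lineage tibble (`taxid`, rank columns, `genome_type`), as
#'   emitted by the simulator or parsed from a taxonomy dump.
#' @param credit `"set"` (default) or `"fractional"` read crediting for
#'   multi-species epitopes.
#' @return A tibble, one row per species: `taxid`, `species`, `family`,
#'   `superkingdom`, `group` (`virus`/`cellular`), `genome_type`,
#'   `n_epitopes`, `n_reads`, `ngsr_e_norm`.
#' @export
species_profiles <- function(hits, lineage, credit = c("set", "fractional")) {
  credit <- match.arg(credit)
  missing_tax <- setdiff(unique(hits$taxid), lineage$taxid)
  if (length(missing_tax)) {
    abort(paste0("taxid(s) not resolvable in the lineage table: ",
                 paste(missing_tax, collapse = ", ")))
  }

  per_sp <- hits |>
    distinct(.data$taxid, .data$epitope, .data$reads)
  if (credit == "fractional") {
    per_sp <- per_sp |>
      group_by(.data$epitope) |>
      mutate(reads = .data$reads / dplyr::n()) |>
      ungroup()
  }
  per_sp |>
    group_by(.data$taxid) |>
    summarise(n_epitopes = dplyr::n_distinct(.data$epitope),
              n_reads = sum(.data$reads), .groups = "drop") |>
    inner_join(
      select(lineage, "taxid", "species", "family", "superkingdom",
             "genome_type"),
      by = "taxid") |>
    mutate(
      group = ifelse(.data$superkingdom == "Viruses", "virus", "cellular"),
      ngsr_e_norm = .data$n_reads / .data$n_epitopes
    ) |>
    select("taxid", "species", "family", "superkingdom", "group",
           "genome_type", "n_epitopes", "n_reads", "ngsr_e_norm") |>
    arrange(desc(.data$ngsr_e_norm), desc(.data$n_reads), .data$species)
}

#' Representation of microbial groups in the top-ranked species
#'
#' Ranks species by decreasing NGSR e-norm (ties by more reads, then species
#' name), takes the top `floor(top_frac * N)` species, and reports for each
#' group the percentage of its members present in that top set.
#'
#' @param profiles A [species_profiles()] tibble (at least 10 species).
#' @param top_frac Fraction of species forming the dominant set (default
#'   0.10).
#' @return A tibble `group`, `n_species`, `n_top`, `representation_pct`
#'   (`NA` for a group with no members).
#' @export
dominance_analysis <- function(profiles, top_frac = 0.10) {
  n <- nrow(profiles)
  if (n < 10L) {
    abort("dominance analysis needs at least 10 ranked species.")
  }
  n_top <- floor(top_frac * n)
  if (n_top < 1L) abort("`top_frac` leaves an empty top set.")
  ranked <- profiles |>
    arrange(desc(.data$ngsr_e_norm), desc(.data$n_reads), .data$species)
  top <- ranked[seq_len(n_top), ]
  all_groups <- c("virus", "cellular")
  tibble(group = all_groups) |>
    left_join(count(ranked, .data$group, name = "n_species"), by = "group") |>
    left_join(count(top, .data$group, name = "n_top"), by = "group") |>
    mutate(
      n_species = tidyr::replace_na(.data$n_species, 0L),
      n_top = tidyr::replace_na(.data$n_top, 0L),
      representation_pct = ifelse(.data$n_species == 0L, NA_real_,
                                  100 * .data$n_top / .data$n_species)
    )
}

#' Viral genome-type composition of the IgOme
#'
#' The contribution of each viral genome-type group to the total NGSR e-norm
#' output, as percentages summing to 100.
#'
#' @param profiles A [species_profiles()] tibble; only rows with
#'   `group == "virus"` are used (at least one required).
#' @return A tibble `genome_type`, `ngsr_sum`, `pct`.
#' @export
genome_type_composition <- function(profiles) {
  viral <- filter(profiles, .data$group == "virus")
  if (nrow(viral) == 0L) abort("no viral species in `profiles`.")
  viral |>
    group_by(.data$genome_type) |>
    summarise(ngsr_sum = sum(.data$ngsr_e_norm), .groups = "drop") |>
    mutate(pct = 100 * .data$ngsr_sum / sum(.data$ngsr_sum)) |>
    arrange(desc(.data$pct))
}

#' Family-level richness and Z-transformed NGSR e-norm
#'
#' Summarises species profiles at the family level: richness (number of
#' species), the mean of the member species' NGSR e-norm, and a Z score of
#' that mean across families (sample standard deviation). Families at least
#' one standard deviation above the grand mean are flagged as outliers.
#'
#' @param profiles A [species_profiles()] tibble covering at least two
#'   families.
#' @param z_outlier Z threshold for the outlier flag (default 1).
#' @return A tibble `family`, `richness`, `mean_ngsr`, `z`, `outlier`.
#' @export
family_profiles <- function(profiles, z_outlier = 1) {
  fam <- profiles |>
    group_by(.data$family) |>
    summarise(richness = dplyr::n(),
              mean_ngsr = mean(.data$ngsr_e_norm), .groups = "drop")
  if (nrow(fam) < 2L) abort("Z scores need at least two families.")
  s <- sd(fam$mean_ngsr)
  if (!is.finite(s) || s == 0) {
    abort("all family means are equal; the Z transform is undefined.")
  }
  fam |>
    mutate(z = (.data$mean_ngsr - mean(.data$mean_ngsr)) / s,
           outlier = .data$z >= z_outlier) |>
    arrange(desc(.data$z))
}
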