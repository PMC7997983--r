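#' Rank-count plot of an epitope table with its noise floor
#'
#' Distinct sequences ranked by ascending read count (log10 y-axis) with the
#' retention threshold drawn as a horizontal line — the standard diagnostic
#' for a heavy right tail over a noise floor.
#'
#' @param table An `epitope_table`.
#' @param result Optional [noise_floor()] result; computed if omitted.
#' @return A ggplot object.
#' @export
plot_noise_floor <- function(table, result = NULL) {
  result <- result %||% noise_floor(table)
  df <- as_tibble(table) |>
    arrange(.data$count, .data$peptide) |>
    mutate(rank = row_number(),
           retained = .data$count > result$threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count,
                                   colour = .data$retained)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = result$threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distinct sequences (ranked by count)",
                  y = "read count",
                  colour = "retained",
                  title = sprintf("Noise floor: threshold %.1f",
                                  result$threshold)) +
    ggplot2::theme_minimal()
}

#' Ranked species abundance, viruses over cellular microbes
#'
#' @param profiles A [species_profiles()] tibble.
#' @return A ggplot object.
#' @export
plot_species_ranking <- function(profiles) {
  df <- profiles |>
    arrange(desc(.data$ngsr_e_norm), desc(.data$n_reads), .data$species) |>
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ngsr_e_norm,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(virus = "darkorange",
                                            cellular = "black")) +
    ggplot2::labs(x = "species rank", y = "NGSR e-norm (reads per epitope)") +
    ggplot2::theme_minimal()
}

#' Viral genome-type composition bar chart
#'
#' @param composition A [genome_type_composition()] tibble.
#' @return A ggplot object.
#' @export
plot_genome_type_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = stats::reorder(.data$genome_type,
                                                  -.data$pct),
                               y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "viral genome type",
                  y = "% of total NGSR e-norm") +
    ggplot2::theme_minimal()
}

#' Family richness against Z-transformed NGSR e-norm
#'
#' @param families A [family_profiles()] tibble.
#' @return A ggplot object.
#' @export
plot_family_z <- function(families) {
  ggplot2::ggplot(families, ggplot2::aes(x = .data$richness, y = .data$z,
                                         colour = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "family richness (species)",
                  y = "Z(mean NGSR e-norm)") +
    ggplot2::theme_minimal()
}

#' Plot an epitope phylogeny (radial layout via ape)
#'
#' @param x An `epitope_phylogeny`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @method plot epitope_phylogeny
#' @export
plot.epitope_phylogeny <- function(x, ...) {
  tree <- x$tree$tree
  if (!is.null(x$supports)) {
    tree$node.label <- ifelse(is.na(x$supports), "",
                              format(round(x$supports), trim = TRUE))
  }
  ape::plot.phylo(tree, type = "unrooted", ...)
  invisible(x)
}
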