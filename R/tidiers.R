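#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname partition_epitopes
#' @param x A `set_partition`.
#' @param ... Unused.
glance.set_partition <- function(x, ...) {
  count(as_tibble(x), .data$set) |>
    tidyr::pivot_wider(names_from = "set", values_from = "n",
                       values_fill = 0L) |>
    mutate(fold = attr(x, "fold"), mode = attr(x, "mode"))
}

#' @export
#' @rdname epitope_phylogeny
#' @param x An `epitope_phylogeny`.
#' @param ... Unused.
tidy.epitope_phylogeny <- function(x, ...) {
  tree <- x$tree$tree
  ntip <- length(tree$tip.label)
  tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = tree$edge.length,
    child_label = ifelse(tree$edge[, 2] <= ntip,
                         tree$tip.label[tree$edge[, 2]], NA_character_)
  )
}
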