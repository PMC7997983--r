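#' The 10-sigma-99 read-count noise floor
#'
#' Removes non-specific sequencing noise from an epitope table. Distinct
#' sequences are ranked by ascending read count (ties broken lexicographically
#' by sequence); the bottom set `B` holds the first `floor(bottom_frac * n)`
#' sequences; the retention threshold is `mean(B) + n_sigma * sd(B)`; only
#' sequences whose count strictly exceeds the threshold are retained. The
#' default location + scale reading (population standard deviation of the
#' bottom-99% counts) treats those counts as the noise mass whose floor the
#' threshold sits 10 standard deviations above; `stat = "quantile"` instead
#' anchors the threshold at the `bottom_frac` count quantile plus
#' `n_sigma * sd(B)`.
#'
#' @param table An `epitope_table` (non-empty; the bottom set must hold at
#'   least 2 sequences).
#' @param n_sigma Number of standard deviations above the noise mass
#'   (default 10).
#' @param bottom_frac Fraction of lowest-count sequences forming the noise
#'   mass (default 0.99).
#' @param stat `"mean_sd"` (default) or `"quantile"` (see above).
#' @return A list of class `noise_floor_result`:
#'   * `threshold`: the read-count threshold;
#'   * `retained`: the filtered `epitope_table` (counts > threshold);
#'   * `removed_count`: sequences removed;
#'   * `bottom_set_size`: `|B|`.
#' @export
#' @examples
#' tab <- as_epitope_table(data.frame(
#'   peptide = c(sprintf("PEPTIDE%02dAA", 1:99), "STRONGBINDER"),
#'   count = c(rep(1, 99), 1000)))
#' noise_floor(tab)$threshold  # 1: only the 1000-count epitope survives
noise_floor <- function(table, n_sigma = 10, bottom_frac = 0.99,
                        stat = c("mean_sd", "quantile")) {
  stat <- match.arg(stat)
  n <- nrow(table)
  if (n == 0L) abort("`table` is empty: the noise floor is undefined.")
  ord <- order(table$count, table$peptide)
  counts <- table$count[ord]
  n_bottom <- floor(bottom_frac * n)
  if (n_bottom < 2L) {
    abort(sprintf(
      "bottom set holds %d sequence(s); need >= 2 to estimate a spread.",
      n_bottom))
  }
  bottom <- counts[seq_len(n_bottom)]
  threshold <- switch(stat,
    mean_sd = mean(bottom) + n_sigma * sd_pop(bottom),
    quantile = bottom[n_bottom] + n_sigma * sd_pop(bottom)
  )
  keep <- table$count > threshold
  retained <- new_epitope_table(
    table[keep, c("peptide", "count")],
    pool = attr(table, "pool"),
    total_reads = attr(table, "total_reads"),
    qc = attr(table, "qc")
  )
  structure(
    list(threshold = threshold,
         retained = retained,
         removed_count = sum(!keep),
         bottom_set_size = n_bottom),
    class = "noise_floor_result"
  )
}

#' @export
print.noise_floor_result <- function(x, ...) {
  cat(sprintf(
    "<noise_floor_result> threshold=%.3f, retained %d, removed %d (|B|=%d)\n",
    x$threshold, nrow(x$retained), x$removed_count, x$bottom_set_size))
  invisible(x)
}

#' @export
#' @rdname noise_floor
#' @param x A `noise_floor_result`.
#' @param ... Unused.
glance.noise_floor_result <- function(x, ...) {
  tibble(threshold = x$threshold, n_retained = nrow(x$retained),
         removed_count = x$removed_count, bottom_set_size = x$bottom_set_size)
}

#' @export
#' @rdname noise_floor
tidy.noise_floor_result <- function(x, ...) {
  mutate(as_tibble(x$retained), threshold = x$threshold)
}
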