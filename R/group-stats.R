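#' Choose between t test and Mann-Whitney by normality gating
#'
#' Shapiro-Wilk on each group at `alpha`; if both look normal, an unpaired
#' t test is used (with an F test deciding equal-variance pooling), otherwise
#' the two-tailed Mann-Whitney rank-sum test.
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @param alpha Normality-test level (default 0.05).
#' @param log10_transform Log10-transform first (refuses non-positive
#'   values).
#' @return A one-row tibble `test` (`"t"` or `"mann_whitney"`), `statistic`,
#'   `p_value`, plus the Shapiro-Wilk p-values and, for the t path, the
#'   F-test p and whether variances were pooled.
#' @export
normality_gate <- function(x, y, alpha = 0.05, log10_transform = FALSE) {
  if (log10_transform) {
    if (any(c(x, y) <= 0)) {
      abort("log10 transform needs strictly positive values.")
    }
    x <- log10(x); y <- log10(y)
  }
  for (v in list(x, y)) {
    if (length(v) < 3L || !all(is.finite(v))) {
      abort("each group needs >= 3 finite values.")
    }
    if (diff(range(v)) == 0) {
      abort("a group is constant; normality is undefined.")
    }
  }
  sw_x <- shapiro.test(x)$p.value
  sw_y <- shapiro.test(y)$p.value
  if (sw_x > alpha && sw_y > alpha) {
    f <- var.test(x, y)
    tt <- t.test(x, y, var.equal = f$p.value > alpha)
    tibble(test = "t", statistic = unname(tt$statistic),
           p_value = tt$p.value, shapiro_p_x = sw_x, shapiro_p_y = sw_y,
           f_test_p = f$p.value, equal_variance = f$p.value > alpha)
  } else {
    mw <- mann_whitney(x, y)
    tibble(test = "mann_whitney", statistic = mw$u, p_value = mw$p_value,
           shapiro_p_x = sw_x, shapiro_p_y = sw_y,
           f_test_p = NA_real_, equal_variance = NA)
  }
}

#' Two-tailed Mann-Whitney rank-sum test
#'
#' Exact by full enumeration of all group labelings when the combined sample
#' size is at most `exact_max` (default 12); otherwise the normal
#' approximation with tie correction. The two-tailed p-value is the
#' probability of a U statistic at least as far from its null mean as the
#' observed one.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Combined-size ceiling for exact enumeration.
#' @return A one-row tibble `u` (U for the first group), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) abort("both groups must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (nx + ny <= exact_max) {
    idx <- combn(nx + ny, nx)
    u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu) / sigma
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble(u = u, p_value = p, method = method)
}

#' Kruskal-Wallis test with Dunn's pairwise multiple comparisons
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) across three
#' or more groups, followed by Dunn's rank-sum z for every pair:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`. Adjustment is
#' Bonferroni-style multiplication by the number of comparisons capped at 1
#' (or Sidak).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 2).
#' @param adjust `"bonferroni"` (default) or `"sidak"`.
#' @return A list of class `kruskal_dunn`: `kw` (one-row tibble `statistic`,
#'   `df`, `p_value`) and `pairs` (tibble `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(groups, adjust = c("bonferroni", "sidak")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 3L) {
    abort("`groups` must be a named list of >= 3 numeric vectors.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(lengths(groups) < 2L)) abort("each group needs n >= 2.")

  kw <- kruskal.test(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))

  combos <- combn(names(groups), 2)
  m <- ncol(combos)
  pairs <- purrr::map_dfr(seq_len(m), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / nn[[i]] + 1 / nn[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = i, group2 = j, z = z, p_value = p)
  })
  pairs$p_adjusted <- switch(adjust,
    bonferroni = pmin(1, pairs$p_value * m),
    sidak = 1 - (1 - pairs$p_value)^m
  )
  structure(
    list(kw = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p_value = kw$p.value),
         pairs = pairs, adjust = adjust),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f (df %d), p = %.4g; Dunn pairs (%s):\n",
              x$kw$statistic, x$kw$df, x$kw$p_value, x$adjust))
  print(x$pairs)
  invisible(x)
}

#' @export
#' @rdname kruskal_dunn
#' @param x A `kruskal_dunn` object.
#' @param ... Unused.
tidy.kruskal_dunn <- function(x, ...) x$pairs

#' @export
#' @rdname kruskal_dunn
glance.kruskal_dunn <- function(x, ...) x$kw

#' Distribution-free confidence interval of the median
#'
#' The narrowest order-statistic interval `(x_(j), x_(n+1-j))` whose binomial
#' coverage `1 - 2 P(Binom(n, 1/2) <= j - 1)` is at least `level`.
#'
#' @param x Numeric vector; `n` must be large enough for the level (n >= 6 at
#'   95%).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble `median`, `ci_lower`, `ci_upper`, `coverage`.
#' @export
#' @examples
#' median_ci(1:100)
median_ci <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 1L) abort("`x` is empty.")
  max_cov <- 1 - 2 * pbinom(0, n, 0.5)
  if (max_cov < level) {
    n_min <- ceiling(log(1 - level) / log(0.5)) + 1
    abort(sprintf(
      "n = %d is too small for a %.0f%% order-statistic CI (need n >= %d).",
      n, 100 * level, n_min))
  }
  s <- sort(x)
  j <- 1L
  while (1 - 2 * pbinom(j, n, 0.5) >= level) j <- j + 1L
  coverage <- 1 - 2 * pbinom(j - 1L, n, 0.5)
  tibble(median = median(x), ci_lower = s[j], ci_upper = s[n + 1L - j],
         coverage = coverage)
}

#' Compare epitope/read distributions between pools
#'
#' The per-figure statistical recipe in one call: log10 transform (counts are
#' >= 1), normality gating for two groups or Kruskal-Wallis + Dunn for three
#' or more, with per-group medians and order-statistic 95% CIs (a mean with
#' t-based CI is reported alongside, since either may be the annotated
#' centre).
#'
#' @param data Tidy data frame with a value and a group column.
#' @param value,group Column names (strings).
#' @param log10_transform Apply log10 first (default TRUE).
#' @param level CI level (default 0.95).
#' @return A list of class `group_comparison`: `summary` (per-group medians,
#'   CIs, means), `test` (the chosen test's tidy output), `pairs` (Dunn
#'   pairs, when applicable).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           log10_transform = TRUE, level = 0.95) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (log10_transform) {
    if (any(v <= 0)) abort("log10 transform needs strictly positive values.")
    v <- log10(v)
  }
  groups <- split(v, g)
  summary <- purrr::imap_dfr(groups, function(vals, name) {
    ci <- median_ci(vals, level = level)
    tt <- t.test(vals, conf.level = level)
    tibble(group = name, n = length(vals), median = ci$median,
           median_ci_lower = ci$ci_lower, median_ci_upper = ci$ci_upper,
           mean = mean(vals), mean_ci_lower = tt$conf.int[1],
           mean_ci_upper = tt$conf.int[2])
  })
  if (length(groups) == 2L) {
    test <- normality_gate(groups[[1]], groups[[2]])
    pairs <- NULL
  } else {
    kd <- kruskal_dunn(groups)
    test <- kd$kw
    pairs <- kd$pairs
  }
  structure(list(summary = summary, test = test, pairs = pairs,
                 log10 = log10_transform),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", if (x$log10) "(log10 scale)" else "", "\n")
  print(x$summary)
  print(x$test)
  if (!is.null(x$pairs)) print(x$pairs)
  invisible(x)
}

#' @export
#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
tidy.group_comparison <- function(x, ...) x$pairs %||% x$test

#' @export
#' @rdname compare_groups
glance.group_comparison <- function(x, ...) x$test
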