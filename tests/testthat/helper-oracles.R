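# Independent oracles: every one is a deliberately naive re-implementation
# kept separate from the package's code paths.

# Frame-1 translation by direct codon-table lookup.
oracle_translate <- function(insert) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(insert, seq(1, nchar(insert) - 2, by = 3),
                      seq(3, nchar(insert), by = 3))
  aa <- unname(gc[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(peptide = paste(aa[seq_len(stop_at[1] - 1L)], collapse = ""),
         truncated = TRUE)
  } else {
    list(peptide = paste(aa, collapse = ""), truncated = FALSE)
  }
}

# Naive 10-sigma-99 filter: sort, slice, filter.
oracle_noise_floor <- function(peptide, count, n_sigma = 10, frac = 0.99) {
  ord <- order(count, peptide)
  peptide <- peptide[ord]; count <- count[ord]
  nb <- floor(frac * length(count))
  b <- count[seq_len(nb)]
  thr <- mean(b) + n_sigma * sqrt(mean((b - mean(b))^2))
  list(threshold = thr, retained = sort(peptide[count > thr]))
}

# Exhaustive substring scan of an epitope over a protein table.
oracle_substring_scan <- function(pep, proteins) {
  hits <- lapply(seq_len(nrow(proteins)), function(i) {
    m <- gregexpr(pep, proteins$sequence[i], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(protein_id = proteins$protein_id[i], start = as.integer(m))
  })
  do.call(rbind, hits)
}

# Best exact window match (any length >= min_len) by scanning all windows.
oracle_window_scan <- function(pep, proteins, min_len) {
  L <- nchar(pep)
  best <- NULL
  for (len in L:min_len) {
    for (s in 1:(L - len + 1L)) {
      sub <- substr(pep, s, s + len - 1L)
      sc <- oracle_substring_scan(sub, proteins)
      if (!is.null(sc)) {
        sc$match_len <- len
        best <- rbind(best, sc)
      }
    }
    if (!is.null(best)) return(best)
  }
  best
}

# Gotoh affine-gap global alignment score (gap of length k costs open + k*ext).
oracle_align_score <- function(a, b, gap_open = 10, gap_ext = 1,
                               submat = NULL) {
  if (is.null(submat)) {
    submat <- as.matrix(getdata_blosum62())
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

getdata_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# ---- naive quartic-time neighbour joining ----------------------------------
# Returns an edge list (node a, node b, length); tips are 1..n, internal
# nodes n+1, n+2, ...
oracle_nj_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3)
  active <- seq_len(n)
  D <- d
  nxt <- n + 1L
  edges <- NULL
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    edges <- rbind(edges, c(active[i], nxt, vi), c(active[j], nxt, vj))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    D <- D2
    active <- c(active[keep], nxt)
    nxt <- nxt + 1L
  }
  # join the last three through a central node
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(a, nxt, va), c(b, nxt, vb), c(c3, nxt, vc))
  edges
}

# Path-length matrix between tips of an edge list.
edges_path_matrix <- function(edges, n_tips) {
  nodes <- max(edges[, 1:2])
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]; w <- edges[k, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  out <- matrix(0, n_tips, n_tips)
  for (s in seq_len(n_tips)) {
    dist <- rep(NA_real_, nodes); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][k, 2]
          queue <- c(queue, u)
        }
      }
    }
    out[s, ] <- dist[seq_len(n_tips)]
  }
  out
}

# Non-trivial bipartitions of the tip set induced by internal edges.
edges_bipartitions <- function(edges, n_tips) {
  parts <- list()
  for (k in seq_len(nrow(edges))) {
    sub <- edges[-k, , drop = FALSE]
    # tips connected to edges[k, 1] without crossing edge k
    seen <- edges[k, 1]
    repeat {
      nb <- unique(c(sub[sub[, 1] %in% seen, 2], sub[sub[, 2] %in% seen, 1]))
      new <- setdiff(nb, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    side <- sort(intersect(seen, seq_len(n_tips)))
    if (length(side) >= 2 && length(side) <= n_tips - 2) {
      canon <- if (1 %in% side) side else sort(setdiff(seq_len(n_tips), side))
      parts[[paste(canon, collapse = ",")]] <- TRUE
    }
  }
  sort(names(parts))
}

phylo_to_edges <- function(tree) {
  cbind(tree$edge, tree$edge.length)
}

# Exact hypergeometric enrichment p by enumeration of all query subsets.
oracle_hyper_p <- function(universe_n, set_n, query_n, overlap) {
  draws <- utils::combn(universe_n, query_n)
  in_set <- seq_len(set_n)  # first set_n elements form the set
  k <- apply(draws, 2, function(col) sum(col %in% in_set))
  mean(k >= overlap)
}
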