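#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration. Negative estimated branch lengths
#' are clamped to zero and tallied. Two taxa give the degenerate single-edge
#' tree (one internal node, each pendant branch `d/2`).
#'
#' @param d Symmetric distance matrix (zero diagonal) or `dist`.
#' @param labels Optional tip labels (default: dimnames of `d`).
#' @return A list of class `epitope_tree`: `tree` (an [ape::nj()] `phylo`),
#'   `n_clamped` (negative branch lengths clamped to 0).
#' @export
nj_tree <- function(d, labels = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n) || n < 2L) abort("neighbour-joining needs at least 2 taxa.")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("`d` must be symmetric.")
  }
  labels <- labels %||% rownames(d) %||% paste0("t", seq_len(n))
  if (n == 2L) {
    tree <- structure(
      list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
           edge.length = rep(d[1, 2] / 2, 2L),
           tip.label = labels, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(structure(list(tree = tree, n_clamped = 0L),
                     class = "epitope_tree"))
  }
  dimnames(d) <- list(labels, labels)
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  if (any(neg)) {
    warn(sprintf("%d negative branch length(s) clamped to 0.", sum(neg)))
  }
  structure(list(tree = tree, n_clamped = sum(neg)), class = "epitope_tree")
}

#' @export
print.epitope_tree <- function(x, ...) {
  print(x$tree)
  if (x$n_clamped) cat(sprintf("(%d branch lengths clamped to 0)\n",
                               x$n_clamped))
  invisible(x)
}

dist_from_msa <- function(msa, capped = FALSE) {
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (capped) {
        kimura_distance_capped(msa[i, ], msa[j, ])
      } else {
        kimura_distance(paste(msa[i, ], collapse = ""),
                        paste(msa[j, ], collapse = ""))
      }
    }
  }
  d
}

#' Bootstrap supports for a neighbour-joining epitope tree
#'
#' Builds the multiple alignment ([align_epitopes()]), the reference NJ tree
#' from its Kimura distances (pairwise deletion), then resamples alignment
#' columns with replacement `n_replicates` times; each internal edge's support
#' is the percentage of replicate NJ trees containing that bipartition.
#'
#' @inheritParams epitope_distances
#' @param n_replicates Bootstrap replicates (default 100).
#' @param seed Integer seed; same seed, same supports.
#' @return A list: `tree` (`epitope_tree`), `supports` (percentage per
#'   internal node, in `[0, 100]`; the root slot is `NA`), `msa`,
#'   `n_replicates`, `seed`.
#' @export
bootstrap_support <- function(epitopes, n_replicates = 100L, seed = 1L, ...) {
  epitopes <- as_labelled_epitopes(epitopes)
  msa <- align_epitopes(epitopes, ...)
  if (ncol(msa) < 2L) abort("alignment has fewer than 2 columns.")
  d0 <- dist_from_msa(msa, capped = TRUE)
  fit <- nj_tree(d0)
  n <- nrow(msa)

  reps <- with_seed_local(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol(msa), replace = TRUE)
      db <- dist_from_msa(msa[, cols, drop = FALSE], capped = TRUE)
      if (n >= 3L) ape::nj(as.dist(db)) else nj_tree(db)$tree
    })
  })
  counts <- ape::prop.clades(fit$tree, reps, rooted = FALSE)
  supports <- 100 * counts / n_replicates
  supports[1] <- NA_real_  # the root "clade" is not an internal bipartition
  list(tree = fit, supports = supports, msa = msa,
       n_replicates = n_replicates, seed = seed)
}

#' Build an epitope phylogeny with distances, NJ tree and optional bootstrap
#'
#' The end-to-end phylogenetics step for mimicry screening: pairwise global
#' alignment, Kimura protein distances, neighbour joining, and (optionally)
#' column-bootstrap supports.
#'
#' @param epitopes Tibble `label`, `sequence` and (for mimicry detection)
#'   `kingdom` (`human` / `viral` / `other`).
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @param ... Passed to [global_align()].
#' @return A list of class `epitope_phylogeny`: `tree` (`epitope_tree`),
#'   `dist`, `epitopes`, `supports` (or `NULL`), `seed`.
#' @export
epitope_phylogeny <- function(epitopes, bootstrap = 0L, seed = 1L, ...) {
  epitopes <- as_labelled_epitopes(epitopes)
  d <- epitope_distances(epitopes, on_saturation = "cap", ...)
  fit <- nj_tree(d)
  supports <- NULL
  if (bootstrap > 0L) {
    bs <- bootstrap_support(epitopes, n_replicates = bootstrap, seed = seed,
                            ...)
    # supports are computed on the bootstrap reference topology; map them via
    # bipartition identity (the trees share labels)
    fit <- bs$tree
    supports <- bs$supports
  }
  structure(
    list(tree = fit, dist = d, epitopes = epitopes, supports = supports,
         seed = seed),
    class = "epitope_phylogeny"
  )
}

#' @export
print.epitope_phylogeny <- function(x, ...) {
  cat(sprintf("<epitope_phylogeny> %d epitopes%s\n", nrow(x$epitopes),
              if (is.null(x$supports)) "" else
                sprintf(", bootstrap supports (seed %d)", x$seed)))
  print(x$tree)
  invisible(x)
}

#' Write / read an epitope tree in Newick format
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param phylogeny An `epitope_phylogeny` or `epitope_tree`.
#' @param path Output file.
#' @return `write_newick` invisibly returns `path`; `read_newick` returns an
#'   [ape::read.tree()] `phylo`.
#' @export
write_newick <- function(phylogeny, path) {
  tree <- if (inherits(phylogeny, "epitope_phylogeny")) phylogeny$tree$tree
          else if (inherits(phylogeny, "epitope_tree")) phylogeny$tree
          else phylogeny
  sup <- if (inherits(phylogeny, "epitope_phylogeny")) phylogeny$supports
  if (!is.null(sup)) {
    tree$node.label <- ifelse(is.na(sup), "", format(sup, trim = TRUE))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Detect candidate molecular-mimicry clades
#'
#' Reports the maximal clades of the epitope tree in which every leaf branch
#' is shorter than `max_leaf_branch` and the leaves span both a human and a
#' microbial kingdom flag — tight mixed clades being the phylogenetic
#' signature of cross-kingdom epitope mimicry. Every human-microbial leaf
#' pair inside a reported clade is emitted with its Kimura distance and the
#' mismatch positions of its pairwise alignment.
#'
#' @param phylogeny An [epitope_phylogeny()] whose `epitopes` carry a
#'   `kingdom` column (`human` vs anything else) for every leaf.
#' @param max_leaf_branch Leaf branch-length ceiling (default 0.1).
#' @return A list of class `mimicry_result`: `clades` (tibble `clade`,
#'   `node`, `n_leaves`, `leaves` list-column) and `pairs` (tibble `clade`,
#'   `human_label`, `microbial_label`, `kimura_distance`, `n_mismatches`,
#'   `mismatch_positions` list-column).
#' @export
mimicry_clades <- function(phylogeny, max_leaf_branch = 0.1) {
  stopifnot(inherits(phylogeny, "epitope_phylogeny"))
  epi <- phylogeny$epitopes
  if (!"kingdom" %in% names(epi) || any(is.na(epi$kingdom))) {
    abort("every leaf needs a non-missing `kingdom` flag.")
  }
  tree <- phylogeny$tree$tree
  ntip <- length(tree$tip.label)
  kingdom <- epi$kingdom[match(tree$tip.label, epi$label)]
  if (any(is.na(kingdom))) abort("tree tips and epitope labels disagree.")

  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  tip_len <- tree$edge.length[tip_edge]

  # tip sets per internal node, children accumulated in postorder
  tips_of <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_of[[i]] <- i
  edg <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edg))) {
    tips_of[[edg[k, 1]]] <- c(tips_of[[edg[k, 1]]], tips_of[[edg[k, 2]]])
  }
  parts <- tips_of[ntip + seq_len(tree$Nnode)]
  nodes <- ntip + seq_along(parts)
  qualifies <- vapply(seq_along(parts), function(i) {
    tips <- parts[[i]]
    kf <- kingdom[tips]
    all(tip_len[tips] < max_leaf_branch) &&
      "human" %in% kf && any(kf != "human")
  }, logical(1))

  parent_of <- function(node) {
    p <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(p)) p else NA_integer_
  }
  maximal <- vapply(seq_along(parts), function(i) {
    if (!qualifies[i]) return(FALSE)
    p <- parent_of(nodes[i])
    while (!is.na(p)) {
      if (qualifies[p - ntip]) return(FALSE)
      p <- parent_of(p)
    }
    TRUE
  }, logical(1))

  keep <- which(maximal)
  clades <- purrr::map_dfr(seq_along(keep), function(ci) {
    tips <- parts[[keep[ci]]]
    tibble(clade = ci, node = nodes[keep[ci]], n_leaves = length(tips),
           leaves = list(tree$tip.label[tips]))
  })
  pairs <- purrr::map_dfr(seq_along(keep), function(ci) {
    tips <- parts[[keep[ci]]]
    hums <- tips[kingdom[tips] == "human"]
    mics <- tips[kingdom[tips] != "human"]
    purrr::map_dfr(hums, function(h) {
      purrr::map_dfr(mics, function(m) {
        lh <- tree$tip.label[h]; lm <- tree$tip.label[m]
        al <- global_align(epi$sequence[match(lh, epi$label)],
                           epi$sequence[match(lm, epi$label)])
        av <- strsplit(al$a_aln, "")[[1]]
        bv <- strsplit(al$b_aln, "")[[1]]
        mm <- which(av != bv)
        tibble(clade = ci, human_label = lh, microbial_label = lm,
               kimura_distance = phylogeny$dist[lh, lm],
               n_mismatches = length(mm), mismatch_positions = list(mm))
      })
    })
  })
  if (nrow(clades) == 0L) {
    clades <- tibble(clade = integer(), node = integer(),
                     n_leaves = integer(), leaves = list())
    pairs <- tibble(clade = integer(), human_label = character(),
                    microbial_label = character(), kimura_distance = double(),
                    n_mismatches = integer(), mismatch_positions = list())
  }
  structure(list(clades = clades, pairs = pairs,
                 max_leaf_branch = max_leaf_branch),
            class = "mimicry_result")
}

#' @export
print.mimicry_result <- function(x, ...) {
  cat(sprintf("<mimicry_result> %d clade(s), %d cross-kingdom pair(s) (leaf branches < %g)\n",
              nrow(x$clades), nrow(x$pairs), x$max_leaf_branch))
  if (nrow(x$pairs)) print(select(x$pairs, -"mismatch_positions"))
  invisible(x)
}
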