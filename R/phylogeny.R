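#' UPGMA tree from a pairwise distance matrix
#'
#' Classic average-linkage (UPGMA) agglomeration of a complete, symmetric,
#' non-negative distance matrix, e.g. a genome-wide F_ST matrix from
#' [genomewide_matrix()]. The result is a rooted ultrametric tree whose
#' cophenetic distances reproduce the merge structure; two leaves joined at
#' distance *d* sit at height *d*/2.
#'
#' @param d A `pairwise_stat` object, a symmetric matrix, or a `dist`.
#' @return An [ape::as.phylo()] tree (class `phylo`).
#' @export
upgma_tree <- function(d) {
  m <- if (inherits(d, "pairwise_stat")) d$values else as.matrix(d)
  if (any(is.na(m))) abort("distance matrix has missing entries")
  if (any(m < 0)) abort("distance matrix has negative entries")
  if (!isSymmetric(unname(m))) abort("distance matrix must be symmetric")
  phangorn::upgma(stats::as.dist(m))
}

#' UPGMA tree with locus-resampling node support
#'
#' Builds the reference UPGMA tree from the genome-wide statistic over all
#' loci, then rebuilds the tree from `n_trees` random subsets of `n_loci`
#' loci each. The support of an internal node is the fraction of replicate
#' trees containing the identical leaf bipartition (the root, a trivial
#' bipartition, has support 1 by construction). Replicate loci are drawn from
#' the loci recorded in every pool, so every replicate matrix is complete.
#'
#' @param freqs A `pool_freqs` table.
#' @param statistic Differentiation statistic, `"fst"` (default) or
#'   `"reynolds"`.
#' @param n_trees Number of resampling replicates (default 100).
#' @param n_loci Loci per replicate (default 100).
#' @param seed Optional integer seed fixing the replicate stream.
#' @param replace Sample loci with replacement? Default `FALSE` (plain
#'   random subsets, not a bootstrap).
#' @return A `support_tree` object: `$tree` (a `phylo` whose node labels are
#'   the supports), `$support` (tibble: node number, clade size, support),
#'   plus the resampling settings. Write with [write_newick()].
#' @export
resample_support <- function(freqs, statistic = c("fst", "reynolds"),
                             n_trees = 100, n_loci = 100, seed = NULL,
                             replace = FALSE) {
  statistic <- match.arg(statistic)
  ref <- upgma_tree(genomewide_matrix(freqs, statistic))
  fm <- freq_matrix(freqs)
  complete <- which(rowSums(is.na(fm)) == 0)
  if (!replace && length(complete) < n_loci) {
    abort(sprintf("only %d fully recorded loci; %d needed per replicate",
                  length(complete), n_loci))
  }
  pi <- pools(freqs)
  if (!is.null(seed)) set.seed(seed)
  rep_keys <- character(0)
  counts <- NULL
  if (n_trees > 0) {
    for (b in seq_len(n_trees)) {
      take <- sample(complete, n_loci, replace = replace)
      gw <- suppressWarnings(
        gw_matrix_from_fm(fm[take, , drop = FALSE], statistic, pi)
      )
      tr <- upgma_tree(gw)
      rep_keys <- c(rep_keys, unique(bipartition_keys(tr)))
    }
    counts <- table(rep_keys)
  }
  ref_keys <- bipartition_keys(ref)
  support <- if (n_trees > 0) {
    as.numeric(counts[ref_keys]) / n_trees
  } else {
    rep(NA_real_, length(ref_keys))
  }
  support[is.na(support) & n_trees > 0] <- 0
  clades <- ape::prop.part(ref)
  ref$node.label <- format_support(support)
  structure(
    list(tree = ref,
         support = tibble(
           node = ape::Ntip(ref) + seq_along(support),
           clade_size = lengths(clades),
           support = support
         ),
         statistic = statistic, n_trees = n_trees, n_loci = n_loci, seed = seed),
    class = "support_tree"
  )
}

format_support <- function(s) {
  ifelse(is.na(s), "", sub("\\.?0+$", "", sprintf("%.2f", s)))
}

# canonical unrooted-style bipartition keys, one per internal node
bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  vapply(parts, function(p) {
    side <- sort(attr(parts, "labels")[p])
    other <- setdiff(tips, side)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    # identify a bipartition with its complement; pick a canonical side
    # (the root's complement is empty, so prefer the non-empty side there)
    if (length(other) == 0 || length(side) < length(other) ||
        (length(side) == length(other) && a < b)) a else b
  }, character(1))
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("# support_tree (%s): %d leaves, %d replicates of %d loci\n",
              x$statistic, ape::Ntip(x$tree), x$n_trees, x$n_loci))
  print(x$tree)
  invisible(x)
}

#' @export
#' @rdname resample_support
#' @param x A `support_tree` object.
#' @param ... Unused.
#' @method tidy support_tree
tidy.support_tree <- function(x, ...) x$support

#' @export
plot.support_tree <- function(x, ...) {
  ape::plot.phylo(x$tree, show.node.label = TRUE, ...)
  invisible(x)
}

#' Write a tree in Newick format
#'
#' Branch lengths carry the ultrametric heights; node labels carry the
#' resampling supports (for a `support_tree`).
#'
#' @param tree A `support_tree` or `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "support_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
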