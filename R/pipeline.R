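#' Run the full stratification pipeline and write a result bundle
#'
#' Orders the analyses end to end: locus filtering, frequency estimation,
#' colony-level virtual pooling, PCA, genome-wide F_ST and Reynolds
#' matrices, the UPGMA tree with resampling support, the F-test scan,
#' heterozygosity / fixed-locus / private-polymorphism summaries and
#' (when class annotations are given) enrichment tables. All outputs are
#' deterministic plain-text TSV (six decimals) or Newick files, so a rerun
#' with the same inputs, configuration and seed is byte-identical.
#'
#' @param counts A [as_pool_counts()] table (pools carrying colony labels).
#' @param out_dir Output directory, created if needed.
#' @param classes Optional locus-class table (`chrom`, `pos`, `class`).
#' @param drop_chroms Chromosomes to exclude (default `"X"`).
#' @param alpha Nominal F-test level (default 0.05, Bonferroni per contrast).
#' @param n_per_pool Animals per pool for the F-test (default 10).
#' @param bin_edges F_ST bin edges for the enrichment profile.
#' @param n_trees,n_loci_per_tree Resampling settings for tree support.
#' @param seed Seed for the resampling stream.
#' @param stages Character vector of stages to run; any of `"pca"`,
#'   `"differentiation"`, `"tree"`, `"ftest"`, `"diversity"`,
#'   `"enrichment"` (default all).
#' @return Invisibly, a named list of the computed result objects; files are
#'   written under `out_dir` and listed in `run_log.txt`.
#' @export
run_pipeline <- function(counts, out_dir, classes = NULL, drop_chroms = "X",
                         alpha = 0.05, n_per_pool = 10,
                         bin_edges = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
                         n_trees = 100, n_loci_per_tree = 100, seed = 1,
                         stages = c("pca", "differentiation", "tree", "ftest",
                                    "diversity", "enrichment")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("poolstrat pipeline, seed %d", seed))
  res <- list()

  filtered <- filter_loci(counts, drop_chroms = drop_chroms, quiet = TRUE)
  ret <- attr(filtered, "retention")
  log_lines <- c(log_lines, sprintf("filter %s: %d -> %d loci", ret$step,
                                    ret$n_before, ret$n_after))
  freqs <- estimate_frequencies(filtered)
  colony_counts <- virtual_pool(filtered)
  colony_freqs <- estimate_frequencies(colony_counts)
  res$freqs <- freqs
  write_num_tsv(as_tibble(freqs), file.path(out_dir, "frequencies.tsv"))

  if ("pca" %in% stages) {
    res$pca <- pool_pca(freqs)
    write_num_tsv(tidy(res$pca), file.path(out_dir, "pca_scores.tsv"))
    log_lines <- c(log_lines, sprintf("pca: PC1 %.1f%%, PC2 %.1f%%",
                                      100 * res$pca$var_explained[1],
                                      100 * res$pca$var_explained[2]))
  }
  if ("differentiation" %in% stages) {
    res$fst <- genomewide_matrix(freqs, "fst")
    res$reynolds <- genomewide_matrix(freqs, "reynolds")
    write_num_tsv(tidy(res$fst), file.path(out_dir, "fst_matrix.tsv"))
    write_num_tsv(tidy(res$reynolds), file.path(out_dir, "reynolds_matrix.tsv"))
    log_lines <- c(log_lines, sprintf("differentiation: mean fst %.4f",
                                      mean(tidy(res$fst)$value, na.rm = TRUE)))
  }
  if ("tree" %in% stages) {
    res$tree <- resample_support(freqs, "fst", n_trees = n_trees,
                                 n_loci = n_loci_per_tree, seed = seed)
    write_newick(res$tree, file.path(out_dir, "tree.nwk"))
    log_lines <- c(log_lines, sprintf("tree: %d replicates of %d loci",
                                      n_trees, n_loci_per_tree))
  }
  if ("ftest" %in% stages) {
    res$ftest <- ftest_scan(freqs, alpha = alpha, n_per_pool = n_per_pool,
                            keep_loci = FALSE)
    write_num_tsv(res$ftest$summary, file.path(out_dir, "ftest_summary.tsv"))
    log_lines <- c(log_lines, sprintf(
      "ftest: mean flagged proportion %.4f",
      mean(res$ftest$summary$prop_significant[res$ftest$summary$n_loci > 0])
    ))
  }
  if ("diversity" %in% stages) {
    res$het_pools <- expected_het(freqs)
    res$het_colonies <- expected_het(colony_freqs)
    write_num_tsv(res$het_pools, file.path(out_dir, "heterozygosity_pools.tsv"))
    write_num_tsv(res$het_colonies, file.path(out_dir, "heterozygosity_colonies.tsv"))
    res$opp_fixed <- oppositely_fixed(colony_freqs)
    write_num_tsv(res$opp_fixed, file.path(out_dir, "oppositely_fixed.tsv"))
    if (nrow(res$opp_fixed) >= 2) {
      res$fixed_cor <- suppressWarnings(fixed_correlation(res$opp_fixed))
      write_num_tsv(tidy(res$fixed_cor), file.path(out_dir, "fixed_correlation.tsv"))
    }
    res$private_strict <- private_polymorphisms(colony_freqs, allow_missing = FALSE)
    res$private_na <- private_polymorphisms(colony_freqs, allow_missing = TRUE)
    write_num_tsv(res$private_strict, file.path(out_dir, "private_strict.tsv"))
    write_num_tsv(res$private_na, file.path(out_dir, "private_allow_missing.tsv"))
    log_lines <- c(log_lines, sprintf(
      "diversity: %d oppositely fixed, %d / %d private (strict / allow-missing)",
      nrow(res$opp_fixed), nrow(res$private_strict), nrow(res$private_na)
    ))
  }
  if ("enrichment" %in% stages && !is.null(classes)) {
    po <- pools(colony_freqs)$pool
    track <- fst_per_locus(colony_freqs, po[1], po[2])
    binned <- bin_by_fst(track, bin_edges)
    res$abundance <- abundance_by_bin(binned, classes)
    write_num_tsv(res$abundance, file.path(out_dir, "abundance_by_bin.tsv"))
    log_lines <- c(log_lines, sprintf("enrichment: %d bins x %d classes",
                                      dplyr::n_distinct(res$abundance$bin),
                                      dplyr::n_distinct(res$abundance$class)))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

# deterministic TSV writer: fixed column order, 6-decimal numerics
write_num_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.6f", x[[j]])
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
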