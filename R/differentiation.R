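#' Per-locus fixation index between two pools
#'
#' For reference-allele frequencies `p1`, `p2` the per-locus fixation index is
#' `F_ST = (H_T - H_S) / H_T` with `H_T = pbar (1 - pbar)`,
#' `pbar = (p1 + p2) / 2`, and `H_S` the mean of the two within-pool
#' heterozygosities `p (1 - p)`. Loci where both pools are fixed for the same
#' allele (`H_T = 0`) are undefined and returned missing, as are loci with a
#' missing frequency in either pool.
#'
#' @param freqs A `pool_freqs` table from [estimate_frequencies()].
#' @param pool_a,pool_b Pool labels present in `freqs`.
#' @return A locus-track tibble: `chrom`, `pos`, `ref`, `alt`, `value`
#'   (the statistic or `NA`), with attributes `statistic` and `pools`.
#' @export
fst_per_locus <- function(freqs, pool_a, pool_b) {
  locus_stat_track(freqs, pool_a, pool_b, fst_values, "fst")
}

#' Per-locus Reynolds genetic distance between two pools
#'
#' `D_R = (1/2) * sum_i (p1i - p2i)^2 / (1 - sum_i p1i p2i)` over the two
#' alleles `i` of a biallelic locus. Undefined (missing) when both pools are
#' fixed for the same allele.
#'
#' @inheritParams fst_per_locus
#' @return A locus-track tibble as in [fst_per_locus()].
#' @export
reynolds_per_locus <- function(freqs, pool_a, pool_b) {
  locus_stat_track(freqs, pool_a, pool_b, reynolds_values, "reynolds")
}

# vectorized statistic kernels --------------------------------------------

fst_values <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- pbar * (1 - pbar)
  hs <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  ifelse(ht == 0, NA_real_, (ht - hs) / ht)
}

reynolds_values <- function(p1, p2) {
  num <- ((p1 - p2)^2 + ((1 - p1) - (1 - p2))^2) / 2
  den <- 1 - p1 * p2 - (1 - p1) * (1 - p2)
  ifelse(den == 0, NA_real_, num / den)
}

locus_stat_track <- function(freqs, pool_a, pool_b, kernel, statistic) {
  fm <- freq_matrix(freqs)
  for (p in c(pool_a, pool_b)) {
    if (!(p %in% colnames(fm))) abort(paste0("unknown pool label: ", p))
  }
  li <- loci(freqs)
  li$value <- unname(kernel(fm[, pool_a], fm[, pool_b]))
  structure(li, class = c("locus_track", class(tibble())),
            statistic = statistic, pools = c(pool_a, pool_b))
}

#' Genome-wide pairwise differentiation matrix
#'
#' Averages the per-locus statistic over all pairwise-complete loci for each
#' pool pair (the mean of per-locus values, not a ratio of sums). Pairs with
#' no usable locus get a missing entry with a warning.
#'
#' @inheritParams fst_per_locus
#' @param statistic `"fst"` or `"reynolds"`.
#' @return A `pairwise_stat` object: symmetric `values` matrix (diagonal 0),
#'   `n_loci` matrix of per-pair locus counts, pool `labels`, and colony
#'   metadata. Use [tidy()] for a long tibble.
#' @export
genomewide_matrix <- function(freqs, statistic = c("fst", "reynolds")) {
  statistic <- match.arg(statistic)
  fm <- freq_matrix(freqs)
  gw_matrix_from_fm(fm, statistic, pools(freqs))
}

gw_matrix_from_fm <- function(fm, statistic, pool_info) {
  kernel <- switch(statistic, fst = fst_values, reynolds = reynolds_values)
  if (ncol(fm) < 2) abort("need at least two pools")
  labs <- colnames(fm)
  n <- length(labs)
  values <- matrix(0, n, n, dimnames = list(labs, labs))
  n_loci <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      v <- kernel(fm[, i], fm[, j])
      use <- !is.na(v)
      n_loci[i, j] <- n_loci[j, i] <- sum(use)
      if (!any(use)) {
        warn(sprintf("no usable loci for pair (%s, %s)", labs[i], labs[j]))
        values[i, j] <- values[j, i] <- NA_real_
      } else {
        values[i, j] <- values[j, i] <- mean(v[use])
      }
    }
  }
  new_pairwise_stat(values, n_loci, statistic, pool_info)
}

new_pairwise_stat <- function(values, n_loci, statistic, pool_info) {
  structure(
    list(labels = colnames(values), values = values, n_loci = n_loci,
         statistic = statistic, pool_info = pool_info),
    class = "pairwise_stat"
  )
}

#' @export
print.pairwise_stat <- function(x, digits = 4, ...) {
  cat(sprintf("# pairwise_stat (%s), %d units\n", x$statistic, length(x$labels)))
  print(round(x$values, digits))
  invisible(x)
}

#' @export
as.matrix.pairwise_stat <- function(x, ...) x$values

#' @export
#' @rdname genomewide_matrix
#' @param x A `pairwise_stat` object.
#' @param ... Unused.
#' @method tidy pairwise_stat
tidy.pairwise_stat <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    unit_a = x$labels[idx[, 1]],
    unit_b = x$labels[idx[, 2]],
    statistic = x$statistic,
    value = x$values[idx],
    n_loci = x$n_loci[idx]
  )
}

#' Heatmap of a pairwise differentiation matrix
#'
#' @param object A `pairwise_stat` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pairwise_stat
autoplot.pairwise_stat <- function(object, ...) {
  d <- tidy(object)
  d2 <- d
  names(d2)[1:2] <- c("unit_b", "unit_a")
  dd <- dplyr::bind_rows(d, d2)
  ggplot2::ggplot(dd, ggplot2::aes(.data$unit_a, .data$unit_b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$value)), size = 3) +
    ggplot2::scale_fill_viridis_c(name = object$statistic) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Assign loci to differentiation bins
#'
#' Bins the per-locus values of a track (typically F_ST) into half-open
#' intervals `[a, b)`, the last interval closed, e.g. a top class of values
#' above 0.9 with edges `c(0, 0.9, 1)`. Missing loci stay unassigned (`NA`).
#'
#' @param track A locus track from [fst_per_locus()].
#' @param edges Ascending numeric bin edges covering `[0, 1]` (first edge 0,
#'   last edge 1).
#' @return The track with an added factor column `bin`.
#' @export
bin_by_fst <- function(track, edges) {
  if (is.unsorted(edges, strictly = TRUE)) abort("bin edges must be strictly increasing")
  if (edges[1] > 0 || edges[length(edges)] < 1) abort("bin edges must cover [0, 1]")
  track$bin <- cut(track$value, breaks = edges, right = FALSE, include.lowest = TRUE)
  track
}
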