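#' Expected heterozygosity per pool or unit
#'
#' Per-locus expected heterozygosity at a biallelic locus is
#' `H_exp = 2 p (1 - p)`. The summary reports, per pool in `freqs`, the mean
#' and standard deviation over non-missing loci (population SD, divisor *n*)
#' and the locus accounting. To summarise a colony's virtual union, pipe the
#' counts through [virtual_pool()] and [estimate_frequencies()] first.
#'
#' @param freqs A `pool_freqs` table.
#' @param per_locus If `TRUE`, return the per-locus values (long tibble with
#'   `chrom`, `pos`, `pool`, `colony`, `het`) instead of the summary.
#' @return A tibble: one row per pool (`pool`, `colony`, `mean_het`,
#'   `sd_het`, `n_loci`, `n_missing`), or the per-locus table.
#' @export
expected_het <- function(freqs, per_locus = FALSE) {
  x <- as_tibble(freqs)
  x$het <- 2 * x$freq * (1 - x$freq)
  if (per_locus) {
    return(dplyr::select(x, "chrom", "pos", "pool", "colony", "het"))
  }
  x |>
    dplyr::group_by(.data$pool, .data$colony) |>
    dplyr::summarise(
      mean_het = mean(.data$het, na.rm = TRUE),
      sd_het = sd_pop(.data$het[!is.na(.data$het)]),
      n_loci = sum(!is.na(.data$het)),
      n_missing = sum(is.na(.data$het)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$pool, unique(x$pool)))
}

sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Oppositely fixed loci across units
#'
#' Finds loci with a complete record in every unit where each unit is fixed
#' (frequency exactly 0 or exactly 1, within `epsilon`) and the units do not
#' all share the same allele.
#'
#' @param freqs A `pool_freqs` table, typically at colony level (after
#'   [virtual_pool()]).
#' @param epsilon Tolerance around 0 and 1 for "fixed" (default 0: read
#'   counts must be unanimous).
#' @return A tibble with `chrom`, `pos` and one indicator column per unit
#'   (1 = fixed for the reference allele, 0 = fixed for the alternative).
#' @export
oppositely_fixed <- function(freqs, epsilon = 0) {
  fm <- freq_matrix(freqs)
  if (ncol(fm) < 2) abort("need at least two units")
  complete <- rowSums(is.na(fm)) == 0
  fixed_ref <- fm >= 1 - epsilon
  fixed_alt <- fm <= epsilon
  all_fixed <- complete & rowSums(fixed_ref | fixed_alt) == ncol(fm)
  not_uniform <- rowSums(fixed_ref) > 0 & rowSums(fixed_alt) > 0
  keep <- which(all_fixed & not_uniform)
  li <- loci(freqs)[keep, c("chrom", "pos")]
  ind <- matrix(as.integer(fixed_ref[keep, , drop = FALSE]),
                nrow = length(keep), ncol = ncol(fm),
                dimnames = list(NULL, colnames(fm)))
  dplyr::bind_cols(li, as_tibble(ind))
}

#' Correlation of fixation states between units
#'
#' Pearson correlation between the per-unit fixed-allele indicator vectors
#' over the oppositely fixed locus set, describing whether units tend to be
#' fixed for the same allele.
#'
#' @param fixed_tbl Output of [oppositely_fixed()].
#' @return A `pairwise_stat` object (statistic `"fixed_correlation"`,
#'   diagonal 1); zero-variance units give missing entries with a warning.
#' @export
fixed_correlation <- function(fixed_tbl) {
  unit_cols <- setdiff(names(fixed_tbl), c("chrom", "pos", "ref", "alt"))
  m <- as.matrix(fixed_tbl[, unit_cols])
  if (nrow(m) < 2) abort("need at least two oppositely fixed loci")
  novar <- apply(m, 2, function(v) stats::var(v) == 0)
  if (any(novar)) {
    warn(paste0("unit(s) with constant fixation state: ",
                paste(unit_cols[novar], collapse = ", ")))
  }
  cc <- suppressWarnings(cor(m))
  diag(cc) <- 1
  n_loci <- matrix(nrow(m), ncol(m), ncol(m), dimnames = dimnames(cc))
  new_pairwise_stat(cc, n_loci, "fixed_correlation",
                    tibble(pool = unit_cols, colony = unit_cols))
}

#' Private polymorphisms per unit
#'
#' A locus is private to a unit when that unit is variable
#' (`0 < p < 1`) while every other unit is fixed. In strict mode
#' (`allow_missing = FALSE`) the locus must be recorded in every unit; with
#' `allow_missing = TRUE` missing units are ignored, requiring at least one
#' recorded other unit, all recorded others fixed.
#'
#' @inheritParams oppositely_fixed
#' @param allow_missing Ignore units with missing records? (default `FALSE`)
#' @return A tibble of private loci: `chrom`, `pos`, `private_to` (unit
#'   label). Summarise counts with `dplyr::count(x, private_to)`.
#' @export
private_polymorphisms <- function(freqs, allow_missing = FALSE, epsilon = 0) {
  fm <- freq_matrix(freqs)
  if (ncol(fm) < 2) abort("need at least two units")
  variable <- !is.na(fm) & fm > epsilon & fm < 1 - epsilon
  fixed <- !is.na(fm) & (fm <= epsilon | fm >= 1 - epsilon)
  n_var <- rowSums(variable)
  n_fixed <- rowSums(fixed)
  n_rec <- rowSums(!is.na(fm))
  if (allow_missing) {
    keep <- n_var == 1 & n_fixed == n_rec - 1 & n_rec >= 2
  } else {
    keep <- n_rec == ncol(fm) & n_var == 1 & n_fixed == ncol(fm) - 1
  }
  idx <- which(keep)
  li <- loci(freqs)[idx, c("chrom", "pos")]
  li$private_to <- colnames(fm)[max.col(variable[idx, , drop = FALSE])]
  li
}
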