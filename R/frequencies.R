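#' Estimate reference-allele frequencies from pooled read counts
#'
#' The frequency at a locus in pool *k* is the read-count ratio
#' `p_k = R_ref / (R_ref + R_alt)`. Missing cells stay missing; cells whose
#' total depth is below `min_depth` are additionally set missing (at depth 1
#' the estimate can only be 0 or 1, which some analyses may prefer to drop).
#'
#' @param counts A [as_pool_counts()] table.
#' @param min_depth Minimum total read depth for a cell to be used
#'   (default 1, i.e. every recorded cell is used).
#' @return A `pool_freqs` tibble: `chrom`, `pos`, `ref`, `alt`, `pool`,
#'   `colony`, `freq` (in `[0, 1]` or `NA`).
#' @export
estimate_frequencies <- function(counts, min_depth = 1) {
  x <- as_tibble(counts)
  depth <- x$ref_reads + x$alt_reads
  freq <- ifelse(!is.na(depth) & depth >= min_depth, x$ref_reads / depth, NA_real_)
  out <- dplyr::select(x, "chrom", "pos", "ref", "alt", "pool", "colony")
  out$freq <- freq
  structure(out, class = c("pool_freqs", class(tibble())))
}

#' @export
print.pool_freqs <- function(x, ...) {
  cat(sprintf(
    "# pool_freqs: %d loci x %d pools (%d colonies)\n",
    nrow(loci(x)), dplyr::n_distinct(x$pool), dplyr::n_distinct(x$colony)
  ))
  NextMethod()
}

#' Virtually pool read counts by summation
#'
#' Mimics a physical DNA pool by summing reference and alternative read
#' counts of member pools per locus. A group cell is missing only when every
#' member cell is missing; otherwise missing members contribute zero reads.
#' The resulting group frequency equals the depth-weighted mean of member
#' frequencies.
#'
#' @param counts A [as_pool_counts()] table.
#' @param grouping Pool-to-group assignment: a named character vector (names
#'   are pool labels) or a data frame with columns `pool` and `group`. The
#'   default groups pools by their `colony`.
#' @return A [as_pool_counts()] table with one "pool" per group (the group
#'   label is used as both pool and colony label).
#' @export
virtual_pool <- function(counts, grouping = NULL) {
  po <- pools(counts)
  if (is.null(grouping)) {
    grouping <- setNames(po$colony, po$pool)
  } else if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping$group), as.character(grouping$pool))
  }
  unassigned <- setdiff(po$pool, names(grouping))
  if (length(unassigned) > 0) {
    abort(paste0("pools without a group: ", paste(unassigned, collapse = ", ")))
  }
  extra <- setdiff(names(grouping), po$pool)
  if (length(extra) > 0) {
    abort(paste0("grouping names absent pools: ", paste(extra, collapse = ", ")))
  }
  x <- as_tibble(counts)
  x$group <- unname(grouping[x$pool])
  out <- x |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$group) |>
    dplyr::summarise(
      all_missing = all(is.na(.data$ref_reads)),
      ref_reads = sum(.data$ref_reads, na.rm = TRUE),
      alt_reads = sum(.data$alt_reads, na.rm = TRUE),
      .groups = "drop"
    )
  out$ref_reads[out$all_missing] <- NA_integer_
  out$alt_reads[out$all_missing] <- NA_integer_
  out$all_missing <- NULL
  out <- dplyr::rename(out, pool = "group")
  out$colony <- out$pool
  # restore input locus order (group_by sorts)
  keys <- locus_key(loci(counts))
  out <- dplyr::arrange(out, match(paste(.data$chrom, .data$pos, sep = ":"), keys),
                        match(.data$pool, unique(unname(grouping))))
  as_pool_counts(out)
}

#' Filter loci before analysis
#'
#' Removes, in order: loci on excluded chromosomes (e.g. the X chromosome),
#' loci missing in every pool, and loci monomorphic across all retained pools
#' (every non-missing frequency exactly 0, or every one exactly 1). The
#' retention accounting is attached as attribute `"retention"` and reported
#' with a message.
#'
#' @param counts A [as_pool_counts()] table.
#' @param drop_monomorphic Drop monomorphic loci? (default `TRUE`)
#' @param drop_chroms Character vector of chromosome labels to drop.
#' @param drop_all_missing Drop loci with no recorded pool? (default `TRUE`)
#' @param quiet Suppress the retention message.
#' @return The filtered `pool_counts` table; `attr(, "retention")` is a
#'   tibble with one row per filtering step.
#' @export
filter_loci <- function(counts, drop_monomorphic = TRUE, drop_chroms = character(),
                        drop_all_missing = TRUE, quiet = FALSE) {
  x <- counts
  log <- list()
  n0 <- nrow(loci(x))
  if (length(drop_chroms) > 0) {
    x <- as_pool_counts(as_tibble(x)[!(x$chrom %in% drop_chroms), ])
    log$chromosome <- c(n0, nrow(loci(x)))
    n0 <- nrow(loci(x))
  }
  if (drop_all_missing) {
    keep <- as_tibble(x) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(keep = any(!is.na(.data$ref_reads)), .groups = "drop")
    x <- drop_by_locus(x, keep)
    log$all_missing <- c(n0, nrow(loci(x)))
    n0 <- nrow(loci(x))
  }
  if (drop_monomorphic) {
    fr <- estimate_frequencies(x)
    keep <- as_tibble(fr) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(
        keep = {
          f <- .data$freq[!is.na(.data$freq)]
          !(length(f) > 0 && (all(f == 0) || all(f == 1)))
        },
        .groups = "drop"
      )
    x <- drop_by_locus(x, keep)
    log$monomorphic <- c(n0, nrow(loci(x)))
  }
  retention <- tibble(
    step = names(log),
    n_before = vapply(log, `[`, numeric(1), 1),
    n_after = vapply(log, `[`, numeric(1), 2)
  )
  if (!quiet && nrow(retention) > 0) {
    inform(paste(sprintf("%s: %d -> %d loci", retention$step,
                         retention$n_before, retention$n_after),
                 collapse = "; "))
  }
  attr(x, "retention") <- retention
  x
}

drop_by_locus <- function(counts, keep_tbl) {
  keep_keys <- paste(keep_tbl$chrom, keep_tbl$pos)[keep_tbl$keep]
  out <- as_tibble(counts)[paste(counts$chrom, counts$pos) %in% keep_keys, ]
  structure(out, class = c("pool_counts", class(tibble())))
}
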