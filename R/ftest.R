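#' Pooled-variance F-test at a single locus
#'
#' Compares the allele-frequency variation between a breeding unit's two
#' pools with the variation between one of those pools and a remote pool.
#' With pool means `m_I = (p_a1 + p_a2)/2` and `m_O = (p_a1 + p_remote)/2`,
#' the binomial-type variances are `V = m (1 - m) * 2 / n` for `n` animals
#' per pool, and the statistic is `F = V_I / V_O`, referred to an F
#' distribution with `(n - 1, n - 1)` degrees of freedom (9, 9 at the default
#' pool size of ten animals). Loci where `V_O = 0` are undefined (missing).
#'
#' @param p_a1,p_a2 Reference-allele frequencies of the unit's two pools
#'   (vectors recycle as usual).
#' @param p_remote Frequency of the remote pool.
#' @param n_per_pool Animals per pool (default 10).
#' @param sided `"two"` (default): `p = 2 min(P(F <= f), P(F >= f))`, capped
#'   at 1; `"lower"`: lower-tail only (`F` small when the remote pool is
#'   differentiated).
#' @return A tibble with columns `v_i`, `v_o`, `f`, `p` (all `NA` for
#'   undefined loci).
#' @export
ftest_locus <- function(p_a1, p_a2, p_remote, n_per_pool = 10,
                        sided = c("two", "lower")) {
  sided <- match.arg(sided)
  for (p in list(p_a1, p_a2, p_remote)) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) abort("frequencies must lie in [0, 1]")
  }
  m_i <- (p_a1 + p_a2) / 2
  m_o <- (p_a1 + p_remote) / 2
  v_i <- m_i * (1 - m_i) * 2 / n_per_pool
  v_o <- m_o * (1 - m_o) * 2 / n_per_pool
  f <- ifelse(v_o == 0, NA_real_, v_i / v_o)
  df <- n_per_pool - 1
  pval <- switch(
    sided,
    two = pmin(1, 2 * pmin(pf(f, df, df), pf(f, df, df, lower.tail = FALSE))),
    lower = pf(f, df, df)
  )
  tibble(v_i = v_i + 0 * f, v_o = v_o + 0 * f, f = f, p = pval)
}

#' Genome scan of the pooled-variance F-test
#'
#' Runs [ftest_locus()] for every basis unit (a colony with exactly two
#' pools) against every remote pool outside that unit, at all loci where the
#' three frequencies are recorded. Significance is Bonferroni-controlled per
#' contrast: threshold `alpha / n` with `n` the loci evaluated in that
#' (basis colony, remote pool) contrast. The summary has the asymmetric
#' colony-by-pool layout: basis colonies in rows, remote pools in columns;
#' same-colony entries are reported as 0.
#'
#' @param freqs A `pool_freqs` table whose colonies each hold exactly two
#'   pools.
#' @param alpha Nominal significance level before correction (default 0.05).
#' @param n_per_pool Animals per pool (default 10).
#' @param basis_pool Which of the unit's two pools anchors the
#'   unit-vs-remote variance: `"first"` (default) or `"second"`, in pool
#'   order of appearance.
#' @param sided Passed to [ftest_locus()].
#' @param keep_loci Keep the per-locus results (can be large)? Default `TRUE`.
#' @return An `ftest_scan` object with `$summary` (one row per contrast:
#'   `basis_colony`, `remote_pool`, `remote_colony`, `n_loci`,
#'   `n_significant`, `prop_significant`, `threshold`) and `$results`
#'   (per-locus tibble, or `NULL`). [tidy()] returns the summary;
#'   [summary_matrix()] the colony-by-pool proportion matrix.
#' @export
ftest_scan <- function(freqs, alpha = 0.05, n_per_pool = 10,
                       basis_pool = c("first", "second"),
                       sided = c("two", "lower"), keep_loci = TRUE) {
  basis_pool <- match.arg(basis_pool)
  sided <- match.arg(sided)
  po <- pools(freqs)
  by_colony <- split(po$pool, po$colony)[unique(po$colony)]
  bad <- names(by_colony)[lengths(by_colony) != 2L]
  if (length(bad) > 0) {
    abort(paste0("each colony needs exactly two pools; offending: ",
                 paste(bad, collapse = ", ")))
  }
  fm <- freq_matrix(freqs)
  li <- loci(freqs)
  res <- list()
  summ <- list()
  for (colony in names(by_colony)) {
    ps <- by_colony[[colony]]
    anchor <- if (basis_pool == "first") ps[1] else ps[2]
    other <- setdiff(ps, anchor)
    for (rp in po$pool) {
      rcol <- po$colony[po$pool == rp]
      if (rcol == colony) {
        summ[[length(summ) + 1]] <- tibble(
          basis_colony = colony, remote_pool = rp, remote_colony = rcol,
          n_loci = 0L, n_significant = 0L, prop_significant = 0,
          threshold = NA_real_
        )
        next
      }
      use <- !is.na(fm[, anchor]) & !is.na(fm[, other]) & !is.na(fm[, rp])
      ft <- ftest_locus(fm[use, anchor], fm[use, other], fm[use, rp],
                        n_per_pool = n_per_pool, sided = sided)
      defined <- !is.na(ft$p)
      n_eval <- sum(defined)
      thr <- if (n_eval > 0) alpha / n_eval else NA_real_
      sig <- defined & !is.na(ft$p) & ft$p <= thr
      summ[[length(summ) + 1]] <- tibble(
        basis_colony = colony, remote_pool = rp, remote_colony = rcol,
        n_loci = n_eval, n_significant = sum(sig),
        prop_significant = if (n_eval > 0) sum(sig) / n_eval else NA_real_,
        threshold = thr
      )
      if (keep_loci) {
        r <- li[use, ]
        r$basis_colony <- colony
        r$remote_pool <- rp
        r <- dplyr::bind_cols(r, ft)
        r$significant <- sig
        res[[length(res) + 1]] <- r
      }
    }
  }
  structure(
    list(
      summary = dplyr::bind_rows(summ),
      results = if (keep_loci) dplyr::bind_rows(res) else NULL,
      alpha = alpha, n_per_pool = n_per_pool,
      basis_pool = basis_pool, sided = sided
    ),
    class = "ftest_scan"
  )
}

#' @export
print.ftest_scan <- function(x, ...) {
  cat(sprintf("# ftest_scan: alpha = %g (Bonferroni per contrast), basis pool = %s\n",
              x$alpha, x$basis_pool))
  print(round(summary_matrix(x), 3))
  invisible(x)
}

#' @export
#' @rdname ftest_scan
#' @param x An `ftest_scan` object.
#' @param ... Unused.
#' @method tidy ftest_scan
tidy.ftest_scan <- function(x, ...) x$summary

#' Contrast summary as a colony-by-pool matrix
#'
#' @param x An `ftest_scan` object.
#' @param what `"prop_significant"` (default), `"n_loci"` or
#'   `"n_significant"`.
#' @return Basis colonies in rows, remote pools in columns.
#' @export
summary_matrix <- function(x, what = "prop_significant") {
  s <- x$summary
  rows <- unique(s$basis_colony)
  cols <- unique(s$remote_pool)
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(s$basis_colony, rows), match(s$remote_pool, cols))] <- s[[what]]
  m
}
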