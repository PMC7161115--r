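#' Prepare a frequency table for PCA
#'
#' Builds the samples-by-loci matrix `X` of centered and scaled
#' reference-allele frequencies and the same-shape missingness indicator `N`
#' (1 = recorded, 0 = missing). Each locus is centered on its mean over
#' recorded samples and divided by its population SD (divisor *n*); missing
#' entries are set to 0 in `X`. Loci with zero SD (constant or observed in a
#' single sample only) are dropped with a message.
#'
#' @param freqs A `pool_freqs` table with at least two pools and two loci.
#' @return A `pca_input` list: `X`, `N`, `n_dropped`, `pool_info`.
#' @export
pca_prepare <- function(freqs) {
  fm <- t(freq_matrix(freqs))  # samples x loci
  if (nrow(fm) < 2 || ncol(fm) < 2) abort("need at least 2 samples and 2 loci")
  n_rec <- colSums(!is.na(fm))
  mu <- colMeans(fm, na.rm = TRUE)
  centered <- sweep(fm, 2, mu)
  sdv <- sqrt(colMeans(centered^2, na.rm = TRUE))
  keep <- !is.na(sdv) & sdv > 0 & n_rec > 0
  if (!any(keep)) abort("all loci have zero variance; nothing to analyse")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) inform(sprintf("dropped %d zero-variance locus/loci", n_dropped))
  x <- sweep(centered[, keep, drop = FALSE], 2, sdv[keep], "/")
  n <- 1 - is.na(x)
  x[is.na(x)] <- 0
  structure(list(X = x, N = n, n_dropped = n_dropped, pool_info = pools(freqs)),
            class = "pca_input")
}

#' Principal component analysis with missing-data-adjusted covariance
#'
#' Models the covariance among samples as `E = XX' / NN'` (elementwise
#' division), i.e. each sample-pair cross-product is averaged over the loci
#' recorded in *both* samples. `E` is decomposed by symmetric
#' eigendecomposition; loadings `L` are the eigenvalues with negative values
#' set to zero (the adjusted `E` need not be positive semi-definite), and
#' component coordinates are `V diag(sqrt(L))`. With complete data the
#' result equals ordinary PCA of the scaled matrix. Component signs are
#' arbitrary, as in any PCA.
#'
#' @param x A `pool_freqs` table or a [pca_prepare()] result.
#' @return A `pool_pca` object: `E`, `values` (eigenvalues), `loadings`
#'   (truncated eigenvalues), `vectors`, `scores` (samples x components),
#'   `var_explained` (fractions of the truncated total), `labels`,
#'   `pool_info`, `n_loci`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
pool_pca <- function(x) {
  if (inherits(x, "pool_freqs")) x <- pca_prepare(x)
  if (!inherits(x, "pca_input")) abort("x must be a pool_freqs table or pca_input")
  xx <- tcrossprod(x$X)
  nn <- tcrossprod(x$N)
  if (any(nn == 0)) {
    idx <- which(nn == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("samples '%s' and '%s' share no recorded locus",
                  rownames(xx)[idx[1]], rownames(xx)[idx[2]]))
  }
  e <- xx / nn
  dec <- eigen(e, symmetric = TRUE)
  l <- pmax(dec$values, 0)
  scores <- dec$vectors %*% diag(sqrt(l), nrow = length(l))
  dimnames(scores) <- list(rownames(x$X), paste0("PC", seq_along(l)))
  structure(
    list(E = e, values = dec$values, loadings = l, vectors = dec$vectors,
         scores = scores, var_explained = if (sum(l) > 0) l / sum(l) else l,
         labels = rownames(x$X), pool_info = x$pool_info, n_loci = ncol(x$X)),
    class = "pool_pca"
  )
}

#' @export
print.pool_pca <- function(x, ...) {
  cat(sprintf("# pool_pca: %d samples, %d loci\n", length(x$labels), x$n_loci))
  cat(sprintf("  variance explained: %s ...\n",
              paste(sprintf("%.1f%%", 100 * head(x$var_explained, 4)), collapse = ", ")))
  invisible(x)
}

#' @export
#' @rdname pool_pca
#' @param ... Unused.
#' @method tidy pool_pca
tidy.pool_pca <- function(x, ...) {
  s <- as_tibble(x$scores)
  s$pool <- x$labels
  s$colony <- x$pool_info$colony[match(x$labels, x$pool_info$pool)]
  tidyr::pivot_longer(s, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @export
#' @rdname pool_pca
#' @method glance pool_pca
glance.pool_pca <- function(x, ...) {
  tibble(
    n_samples = length(x$labels), n_loci = x$n_loci,
    n_negative_eigenvalues = sum(x$values < 0),
    var_explained_pc1 = x$var_explained[1],
    var_explained_pc2 = x$var_explained[2]
  )
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pool_pca` object.
#' @param ... Unused.
#' @return A ggplot object, points labelled by pool and coloured by colony.
#' @export
#' @method autoplot pool_pca
autoplot.pool_pca <- function(object, ...) {
  d <- tibble(
    pool = object$labels,
    colony = object$pool_info$colony[match(object$labels, object$pool_info$pool)],
    pc1 = object$scores[, 1], pc2 = object$scores[, 2]
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$colony)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$pool), vjust = -0.8, size = 3,
                       show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    )
}
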