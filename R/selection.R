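#' Additive relationship matrix from a pedigree
#'
#' Builds the numerator relationship matrix (Wright's additive relationship)
#' by the tabular method on the topologically sorted pedigree:
#' `A[i,i] = 1 + A[sire, dam] / 2` and `A[i,j] = (A[j, sire] + A[j, dam]) / 2`
#' for animals `j` processed before `i`; unknown parents contribute 0.
#'
#' @param ped A data frame with columns `id`, `sire`, `dam`; unknown parents
#'   as `NA` (or `0` / `""`). Parents not listed as individuals are treated
#'   as unknown founders. Cyclic pedigrees raise an error.
#' @param normalize If `TRUE`, return the correlation-normalised coefficients
#'   `A[i,j] / sqrt(A[i,i] A[j,j])` instead of the numerator relationships.
#' @return A symmetric matrix with the individual ids as dimnames.
#' @examples
#' ped <- tibble::tibble(id = c("s", "d", "x", "y"),
#'                       sire = c(NA, NA, "s", "s"),
#'                       dam  = c(NA, NA, "d", "d"))
#' relationship_matrix(ped)["x", "y"]  # full sibs: 0.5
#' @export
relationship_matrix <- function(ped, normalize = FALSE) {
  ped <- as_tibble(ped)
  id <- as.character(ped$id)
  if (anyDuplicated(id) > 0) abort("duplicated individual ids in pedigree")
  clean <- function(v) {
    v <- as.character(v)
    v[v %in% c("", "0", "NA") | is.na(v) | !(v %in% id)] <- NA_character_
    v
  }
  sire <- clean(ped$sire)
  dam <- clean(ped$dam)
  ord <- pedigree_order(id, sire, dam)
  n <- length(id)
  a <- matrix(0, n, n, dimnames = list(id, id))
  pos <- setNames(seq_len(n), id)
  done <- character(0)
  for (i in ord) {
    s <- sire[i]
    d <- dam[i]
    if (length(done) > 0) {
      row <- numeric(length(done))
      if (!is.na(s)) row <- row + a[done, s] / 2
      if (!is.na(d)) row <- row + a[done, d] / 2
      a[done, id[i]] <- row
      a[id[i], done] <- row
    }
    inb <- if (!is.na(s) && !is.na(d)) a[s, d] / 2 else 0
    a[id[i], id[i]] <- 1 + inb
    done <- c(done, id[i])
  }
  if (normalize) {
    dd <- sqrt(diag(a))
    a <- a / outer(dd, dd)
  }
  a
}

# topological order (parents first); errors on cycles
pedigree_order <- function(id, sire, dam) {
  n <- length(id)
  pos <- setNames(seq_len(n), id)
  parents <- cbind(pos[sire], pos[dam])
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  ord <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) abort("pedigree contains a cycle")
  ord
}

#' Relationship index of a candidate subset
#'
#' For a candidate subset of size `k`, `a` is the mean relationship over
#' unordered pairs *within* the subset (diagonal excluded), `b` the mean
#' relationship between subset members and all remaining animals, and the
#' index is `I = wa * a - wb * b`: low within-subset relationship combined
#' with high relationship to the remaining colony makes the subset a good
#' representative sample.
#'
#' @param A A relationship matrix from [relationship_matrix()].
#' @param subset Individual labels (or indices) with `1 < k < n`.
#' @param wa,wb Index weights (defaults 0.8 and 0.2).
#' @return A one-row tibble: `a`, `b`, `index`.
#' @export
index_of <- function(A, subset, wa = 0.8, wb = 0.2) {
  n <- nrow(A)
  if (is.character(subset)) subset <- match(subset, rownames(A))
  if (any(is.na(subset))) abort("subset labels not found in A")
  k <- length(subset)
  if (k <= 1 || k >= n) abort("subset size must satisfy 1 < k < n")
  sub <- A[subset, subset, drop = FALSE]
  a <- (sum(sub) - sum(diag(sub))) / (k * (k - 1))
  b <- mean(A[subset, -subset, drop = FALSE])
  tibble(a = a, b = b, index = wa * a - wb * b)
}

#' Stochastic search for a representative candidate subset
#'
#' Repeatedly draws uniform random subsets of size `k`, keeps the subset
#' with the lowest index `I = wa * a - wb * b` (see [index_of()]), and stops
#' after `max_stall` consecutive draws without improvement.
#'
#' @inheritParams index_of
#' @param k Subset size.
#' @param max_stall Consecutive non-improving draws before stopping
#'   (default 25000).
#' @param seed Optional integer seed; the search is deterministic given a
#'   seed.
#' @param batch_size Draws evaluated per vectorised batch (performance
#'   knob; does not affect the result).
#' @return A `selection_result`: `subset` (sorted labels), `a`, `b`,
#'   `index`, `n_draws`, and `trace` (tibble of improvements: draw, index).
#'   [tidy()] returns the trace; [glance()] a one-row summary.
#' @export
optimize_subset <- function(A, k, wa = 0.8, wb = 0.2, max_stall = 25000,
                            seed = NULL, batch_size = 2000) {
  n <- nrow(A)
  if (k <= 1 || k >= n) abort("subset size must satisfy 1 < k < n")
  if (!is.null(seed)) set.seed(seed)
  labels <- rownames(A) %||% as.character(seq_len(n))
  diag_a <- diag(A)
  best_index <- Inf
  best_subset <- NULL
  total <- 0L        # draws performed so far
  last_imp <- 0L     # global position of the last improvement
  trace_draw <- integer(0)
  trace_index <- numeric(0)
  # the stall counter equals total - last_imp, so the search stops after
  # draw last_imp + max_stall unless an improvement lands at or before it
  repeat {
    m <- batch_size
    draws <- vapply(seq_len(m), function(...) sample.int(n, k), integer(k))
    z <- matrix(0, m, n)
    z[cbind(rep(seq_len(m), each = k), as.vector(draws))] <- 1
    za <- z %*% A
    sum_ss <- rowSums(za * z) - as.vector(z %*% diag_a)
    sum_sc <- rowSums(za * (1 - z))
    idx <- wa * sum_ss / (k * (k - 1)) - wb * sum_sc / (k * (n - k))
    for (j in which(idx < best_index)) {
      if (idx[j] >= best_index) next  # best moved within this batch
      g <- total + j
      if (g > last_imp + max_stall) break  # search stopped before draw g
      best_index <- idx[j]
      best_subset <- draws[, j]
      last_imp <- g
      trace_draw <- c(trace_draw, g)
      trace_index <- c(trace_index, best_index)
    }
    total <- total + m
    if (total >= last_imp + max_stall) break
  }
  n_draws <- last_imp + max_stall
  structure(
    list(subset = sort(labels[best_subset]),
         a = index_of(A, best_subset, wa, wb)$a,
         b = index_of(A, best_subset, wa, wb)$b,
         index = best_index, n_draws = n_draws,
         trace = tibble(draw = trace_draw, index = trace_index),
         k = k, wa = wa, wb = wb, max_stall = max_stall, seed = seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "# selection_result: k = %d, index = %.4f (a = %.4f, b = %.4f) after %d draws\n",
    x$k, x$index, x$a, x$b, x$n_draws
  ))
  cat("  subset:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname optimize_subset
#' @param x A `selection_result` object.
#' @param ... Unused.
#' @method tidy selection_result
tidy.selection_result <- function(x, ...) x$trace

#' @export
#' @rdname optimize_subset
#' @method glance selection_result
glance.selection_result <- function(x, ...) {
  tibble(k = x$k, a = x$a, b = x$b, index = x$index,
         n_draws = x$n_draws, n_improvements = nrow(x$trace))
}
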