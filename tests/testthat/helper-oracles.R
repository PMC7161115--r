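# Independent reference implementations used to cross-check the package.
# These deliberately re-derive each quantity from its definition and share no
# code with the implementation under test.

# direct transcription of the two-pool differentiation formulas
oracle_fst <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- pbar * (1 - pbar)
  if (ht == 0) return(NA_real_)
  hs <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  (ht - hs) / ht
}

oracle_reynolds <- function(p1, p2) {
  q1 <- 1 - p1
  q2 <- 1 - p2
  den <- 1 - (p1 * p2 + q1 * q2)
  if (den == 0) return(NA_real_)
  0.5 * ((p1 - p2)^2 + (q1 - q2)^2) / den
}

# F(d, d) CDF by numerical integration of the density written from the
# definition (independent of stats::pf)
oracle_pf <- function(q, d1, d2) {
  dens <- function(x) {
    exp(
      lgamma((d1 + d2) / 2) - lgamma(d1 / 2) - lgamma(d2 / 2) +
        (d1 / 2) * log(d1 / d2) + (d1 / 2 - 1) * log(x) -
        ((d1 + d2) / 2) * log(1 + d1 * x / d2)
    )
  }
  vapply(q, function(qi) {
    stats::integrate(dens, 0, qi, rel.tol = 1e-13, abs.tol = 1e-13)$value
  }, numeric(1))
}

# textbook UPGMA returning the cophenetic distance matrix (naive O(n^3))
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  dd <- d
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    m <- dd
    diag(m) <- Inf
    ij <- which(m == min(m), arr.ind = TRUE)[1, ]
    i <- min(ij)
    j <- max(ij)
    for (a in clusters[[i]]) {
      for (b in clusters[[j]]) {
        coph[a, b] <- coph[b, a] <- dd[i, j]
      }
    }
    # size-weighted average linkage
    new_row <- (sizes[i] * dd[i, ] + sizes[j] * dd[j, ]) / (sizes[i] + sizes[j])
    dd[i, ] <- dd[, i] <- new_row
    dd[i, i] <- 0
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    dd <- dd[-j, -j, drop = FALSE]
    clusters <- clusters[-j]
    sizes <- sizes[-j]
  }
  coph
}

# recursive kinship (coefficient of coancestry); A = 2 * kinship off the
# diagonal convention, with kin(i, i) = (1 + kin(sire, dam)) / 2
oracle_kinship_matrix <- function(ped) {
  id <- as.character(ped$id)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  names(sire) <- names(dam) <- id
  memo <- new.env()
  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      (1 + kin(sire[[a]], dam[[a]])) / 2
    } else {
      # recurse through the younger individual (appears later in the sorted ped)
      ia <- match(a, id)
      ib <- match(b, id)
      if (ia > ib) {
        (kin(sire[[a]], b) + kin(dam[[a]], b)) / 2
      } else {
        (kin(sire[[b]], a) + kin(dam[[b]], a)) / 2
      }
    }
    memo[[key]] <- val
    val
  }
  n <- length(id)
  k <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      k[i, j] <- k[j, i] <- 2 * kin(id[i], id[j])
    }
  }
  k
}

# random pedigree with parents drawn among earlier individuals (or unknown)
random_pedigree <- function(n = 12, p_known = 0.7) {
  id <- sprintf("I%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    earlier <- id[seq_len(i - 1)]
    if (runif(1) < p_known) sire[i] <- sample(earlier, 1)
    if (runif(1) < p_known) dam[i] <- sample(earlier, 1)
    if (!is.na(sire[i]) && !is.na(dam[i]) && sire[i] == dam[i]) dam[i] <- NA
  }
  tibble::tibble(id = id, sire = sire, dam = dam)
}

# exhaustive minimum of the selection index over all k-subsets
oracle_best_subset <- function(A, k, wa = 0.8, wb = 0.2) {
  n <- nrow(A)
  combs <- utils::combn(n, k)
  idx <- apply(combs, 2, function(s) {
    sub <- A[s, s]
    a <- (sum(sub) - sum(diag(sub))) / (k * (k - 1))
    b <- mean(A[s, -s])
    wa * a - wb * b
  })
  list(index = min(idx), subset = sort(combs[, which.min(idx)]))
}

# small counts table builder: ref/alt matrices are loci x pools
make_counts <- function(ref, alt, pools = paste0("P", seq_len(ncol(ref))),
                        colony = pools, chrom = "1") {
  n <- nrow(ref)
  long <- tidyr::expand_grid(
    tibble::tibble(chrom = chrom, pos = seq_len(n), ref = "A", alt = "G"),
    pool = pools
  )
  long$colony <- rep(colony, times = n)
  long$ref_reads <- as.vector(t(ref))
  long$alt_reads <- as.vector(t(alt))
  as_pool_counts(long)
}

# frequency table straight from a loci x pools frequency matrix, using a
# large even depth so that read ratios reproduce the frequencies exactly
freqs_from_matrix <- function(fm, pools = colnames(fm), colony = pools,
                              depth = 200) {
  ref <- round(fm * depth)
  alt <- depth - ref
  ref[is.na(fm)] <- NA
  alt[is.na(fm)] <- NA
  if (is.null(pools)) pools <- paste0("P", seq_len(ncol(fm)))
  estimate_frequencies(make_counts(ref, alt, pools = pools, colony = colony))
}

expect_tree_matches_oracle <- function(d, tol = 1e-12) {
  tr <- upgma_tree(d)
  coph <- as.matrix(stats::cophenetic(tr))
  oracle <- oracle_upgma_cophenetic(d)
  expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
               tolerance = tol)
}

# three-point ultrametric condition on a cophenetic matrix
expect_ultrametric <- function(coph, tol = 1e-12) {
  labs <- rownames(coph)
  worst <- 0
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      for (k in seq_along(labs)) {
        worst <- max(worst, coph[i, j] - max(coph[i, k], coph[j, k]))
      }
    }
  }
  expect_lte(worst, tol)
}

# wide loci x pools frequency matrix from a long table (test-side helper)
freq_matrix_of <- function(f) {
  w <- tidyr::pivot_wider(tibble::as_tibble(f), id_cols = c("chrom", "pos"),
                          names_from = "pool", values_from = "freq")
  m <- as.matrix(w[, -(1:2)])
  rownames(m) <- paste(w$chrom, w$pos, sep = ":")
  m
}

# wide loci x pools read-depth matrix from a counts table (test-side helper)
freq_depth_matrix <- function(counts) {
  counts <- tibble::as_tibble(counts)
  counts$depth <- counts$ref_reads + counts$alt_reads
  w <- tidyr::pivot_wider(counts, id_cols = c("chrom", "pos"),
                          names_from = "pool", values_from = "depth")
  m <- as.matrix(w[, -(1:2)])
  rownames(m) <- paste(w$chrom, w$pos, sep = ":")
  m
}
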