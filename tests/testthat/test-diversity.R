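test_that("expected heterozygosity follows 2p(1-p) with a population SD", {
  fm <- cbind(P = c(0.5, 0.1, 0, NA))
  f <- freqs_from_matrix(fm)
  h <- expected_het(f, per_locus = TRUE)$het
  expect_equal(h, c(0.5, 0.18, 0, NA), tolerance = 1e-12)
  s <- expected_het(f)
  expect_equal(s$n_loci, 3L)
  expect_equal(s$n_missing, 1L)
  expect_equal(s$mean_het, mean(c(0.5, 0.18, 0)), tolerance = 1e-12)
  v <- c(0.5, 0.18, 0)
  expect_equal(s$sd_het, sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  expect_true(s$mean_het >= 0 && s$mean_het <= 0.5)
})

test_that("union heterozygosity dominates the depth-weighted member mean (concavity)", {
  set.seed(41)
  sim <- simulate_pools(sim_config(n_loci = 500, n_colonies = 2, seed = 41))
  f <- estimate_frequencies(sim$counts)
  uf <- estimate_frequencies(virtual_pool(sim$counts))
  fm <- freq_matrix_of(f)
  um <- freq_matrix_of(uf)
  counts <- tibble::as_tibble(sim$counts)
  depth <- freq_depth_matrix(counts)
  for (col in colnames(um)) {
    members <- grep(paste0("^", col, "_"), colnames(fm), value = TRUE)
    h_mem <- 2 * fm[, members] * (1 - fm[, members])
    w <- depth[, members]
    w[is.na(h_mem)] <- NA
    wmean <- rowSums(h_mem * w, na.rm = TRUE) / rowSums(w, na.rm = TRUE)
    h_union <- 2 * um[, col] * (1 - um[, col])
    ok <- !is.na(h_union) & !is.nan(wmean)
    expect_true(all(h_union[ok] - wmean[ok] >= -1e-12))
  }
  # genome-wide: mean union H at least the mean pool H
  expect_gte(mean(expected_het(uf)$mean_het), mean(expected_het(f)$mean_het))
})

test_that("oppositely fixed loci require unanimity and disagreement", {
  fm <- rbind(
    c(1, 1, 0, 0, 1),     # included
    c(1, 1, 1, 1, 1),     # all share the reference: excluded
    c(1, 0.5, 0, 0, 1),   # a variable colony: excluded
    c(1, NA, 0, 0, 1),    # missing record: excluded
    c(0, 0, 1, 1, 0)      # included
  )
  colnames(fm) <- paste0("C", 1:5)
  f <- freqs_from_matrix(fm)
  off <- oppositely_fixed(f)
  expect_equal(nrow(off), 2L)
  expect_equal(unname(unlist(off[1, paste0("C", 1:5)])), c(1, 1, 0, 0, 1))
  expect_equal(unname(unlist(off[2, paste0("C", 1:5)])), c(0, 0, 1, 1, 0))
})

test_that("fixation-state correlations match hand Pearson values", {
  ind <- tibble::tibble(
    chrom = "1", pos = 1:4,
    A = c(1, 1, 0, 0), B = c(1, 1, 0, 0),
    C = c(0, 0, 1, 1), D = c(1, 0, 1, 0)
  )
  cc <- fixed_correlation(ind)
  expect_equal(cc$values["A", "B"], 1)
  expect_equal(cc$values["A", "C"], -1)
  expect_equal(cc$values["A", "D"], 0)
  expect_equal(diag(cc$values), c(A = 1, B = 1, C = 1, D = 1))
  ind$E <- c(1, 1, 1, 1)
  expect_warning(cc2 <- fixed_correlation(ind), "constant")
  expect_true(is.na(cc2$values["A", "E"]))
})

test_that("private polymorphisms honour the strict and allow-missing contracts", {
  fm <- rbind(
    c(0.3, 0, 0, 1, 1),    # private to C1
    c(0.3, 0.6, 0, 1, 1),  # two variable units: not private
    c(0.3, NA, 0, 1, 1),   # strict: excluded; allow-missing: private to C1
    c(0, 0, 0, 1, 0.7),    # private to C5
    c(NA, NA, NA, NA, 0.5) # no recorded fixed partner
  )
  colnames(fm) <- paste0("C", 1:5)
  f <- freqs_from_matrix(fm)
  strict <- private_polymorphisms(f, allow_missing = FALSE)
  relaxed <- private_polymorphisms(f, allow_missing = TRUE)
  expect_equal(strict$pos, c(1L, 4L))
  expect_equal(strict$private_to, c("C1", "C5"))
  expect_equal(relaxed$pos, c(1L, 3L, 4L))
  expect_gte(nrow(relaxed), nrow(strict))
  # a locus is private to at most one unit
  expect_false(anyDuplicated(strict$pos) > 0)
})

test_that("allow-missing private counts dominate strict counts on simulated drift", {
  sim <- simulate_pools(sim_config(n_loci = 800, generations = 12, n_e = 25,
                                   seed = 99))
  cf <- estimate_frequencies(virtual_pool(sim$counts))
  strict <- dplyr::count(private_polymorphisms(cf, FALSE), private_to)
  relaxed <- dplyr::count(private_polymorphisms(cf, TRUE), private_to)
  merged <- dplyr::left_join(relaxed, strict, by = "private_to",
                             suffix = c("_na", "_strict"))
  merged$n_strict[is.na(merged$n_strict)] <- 0L
  expect_true(all(merged$n_na >= merged$n_strict))
  expect_gt(nrow(strict), 0)
})
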