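test_that("preparation centers and scales per locus with the missing contract", {
  fm <- cbind(P1 = c(0, 0.4, 0.2), P2 = c(1, 0.4, NA), P3 = c(0.5, 0.4, 0.8))
  f <- freqs_from_matrix(fm)
  expect_message(inp <- pca_prepare(f), "dropped 1")
  # locus 2 is constant and dropped; locus 3 uses the two recorded samples
  expect_equal(ncol(inp$X), 2L)
  # locus 1: values (0, 1, 0.5), mean 0.5, population SD sqrt(1/6)
  sd1 <- sqrt(mean((c(0, 1, 0.5) - 0.5)^2))
  expect_equal(unname(inp$X[, 1]), c(-0.5, 0.5, 0) / sd1, tolerance = 1e-12)
  # locus 3 over samples P1, P3: (0.2, 0.8) -> (-1, +1) under population SD 0.3
  expect_equal(unname(inp$X[, 2]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(inp$N[, 2]), c(1, 0, 1))
  # a two-sample locus with values (0, 1) scales to (-1, +1)
  f2 <- freqs_from_matrix(cbind(A = c(0, 0.3), B = c(1, 0.6)))
  expect_equal(unname(pca_prepare(f2)$X[, 1]), c(-1, 1), tolerance = 1e-12)
  # everything constant is a degenerate input
  f3 <- freqs_from_matrix(cbind(A = c(0.5, 0.2), B = c(0.5, 0.2)))
  expect_error(pca_prepare(f3), "zero variance")
})

test_that("with complete data the adjusted PCA equals ordinary covariance PCA", {
  set.seed(77)
  ns <- 20
  nl <- 500
  fm <- matrix(runif(ns * nl, 0.05, 0.95), nl, ns,
               dimnames = list(NULL, sprintf("S%02d", 1:ns)))
  f <- freqs_from_matrix(fm, depth = 1e6)
  res <- pool_pca(f)
  # oracle: scale by hand, E0 = XX'/n, eigendecompose
  x <- t(freq_matrix_of(f))
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")
  e0 <- tcrossprod(x) / ncol(x)
  dec <- eigen(e0, symmetric = TRUE)
  scores0 <- dec$vectors %*% diag(sqrt(pmax(dec$values, 0)))
  for (j in 1:(ns - 1)) {
    agree <- max(abs(res$scores[, j] - scores0[, j]))
    flipped <- max(abs(res$scores[, j] + scores0[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  expect_equal(res$E, e0, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a hand 2x2 case has one positive eigenvalue and a zero second component", {
  f <- freqs_from_matrix(cbind(A = c(0.2, 0.3), B = c(0.8, 0.7)))
  res <- pool_pca(f)
  # X rows are (-1,-1) and (1,1); E = [[1,-1],[-1,1]] with eigenvalues (2, 0);
  # scores are V diag(sqrt(L)), so PC1 lands on +-1 for the two samples
  expect_equal(res$values, c(2, 0), tolerance = 1e-12)
  expect_equal(abs(unname(res$scores[, 1])), c(1, 1), tolerance = 1e-12)
  expect_lt(max(abs(res$scores[, 2])), 1e-7)
  expect_equal(res$var_explained[1], 1)
})

test_that("missingness keeps E exactly symmetric with small eigen-residuals", {
  set.seed(78)
  ns <- 12
  nl <- 300
  fm <- matrix(runif(ns * nl, 0.05, 0.95), nl, ns,
               dimnames = list(NULL, sprintf("S%02d", 1:ns)))
  fm[sample(length(fm), round(0.1 * length(fm)))] <- NA
  f <- freqs_from_matrix(fm, depth = 1e6)
  res <- pool_pca(f)
  expect_identical(res$E, t(res$E))
  v <- res$vectors
  resid <- res$E %*% v - v %*% diag(res$values)
  expect_lt(max(abs(resid)) / max(abs(res$E)), 1e-8)
  expect_true(all(res$loadings >= 0))
  expect_equal(sum(res$var_explained), 1, tolerance = 1e-12)
})

test_that("duplicate samples land on identical coordinates", {
  set.seed(79)
  base <- runif(200, 0.1, 0.9)
  fm <- cbind(A = base, B = base, C = runif(200, 0.1, 0.9),
              D = runif(200, 0.1, 0.9))
  res <- pool_pca(freqs_from_matrix(fm, depth = 1e6))
  # identical up to the numerically null components (sqrt of ~0 eigenvalues)
  expect_lt(max(abs(res$scores["A", ] - res$scores["B", ])), 1e-6)
})

test_that("a sample pair sharing no locus is refused by name", {
  fm <- cbind(A = c(0.2, NA, 0.4), B = c(NA, 0.6, NA), C = c(0.8, 0.3, 0.9))
  f <- freqs_from_matrix(fm)
  expect_error(pool_pca(f), "share no recorded locus")
})

test_that("tidy and glance expose scores and the variance accounting", {
  set.seed(80)
  fm <- matrix(runif(40, 0.1, 0.9), 10, 4,
               dimnames = list(NULL, c("X_1", "X_2", "Y_1", "Y_2")))
  f <- freqs_from_matrix(fm, colony = c("X", "X", "Y", "Y"))
  res <- pool_pca(f)
  td <- tidy(res)
  expect_equal(nrow(td), 4 * 4)
  expect_equal(sort(unique(td$colony)), c("X", "Y"))
  g <- glance(res)
  expect_equal(g$n_samples, 4L)
  expect_s3_class(autoplot(res), "ggplot")
})
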