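test_that("sync parsing maps count pairs and the 0:0 missing convention", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tP1\tP2",
    "1\t100\tA\tG\t10:0\t5:5",
    "1\t200\tC\tT\t0:0\t3:9"
  ), path)
  x <- read_sync(path)
  expect_s3_class(x, "pool_counts")
  r1 <- x[x$pos == 100 & x$pool == "P1", ]
  expect_equal(c(r1$ref_reads, r1$alt_reads), c(10L, 0L))
  r2 <- x[x$pos == 100 & x$pool == "P2", ]
  expect_equal(c(r2$ref_reads, r2$alt_reads), c(5L, 5L))
  miss <- x[x$pos == 200 & x$pool == "P1", ]
  expect_true(is.na(miss$ref_reads) && is.na(miss$alt_reads))
})

test_that("malformed sync lines are rejected with a parse error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tP1", "1\t100\tA\tG\t-3:5"), path)
  expect_error(read_sync(path), "malformed")
  writeLines(c("chrom\tpos\tref\talt\tP1", "1\t100\tA\tG\t35"), path)
  expect_error(read_sync(path), "malformed")
  expect_error(read_sync(file.path(tempdir(), "no-such-file.tsv")), "cannot read")
})

test_that("sync write/read round trip reproduces counts exactly", {
  set.seed(11)
  ref <- matrix(rbinom(60, 40, 0.4), 20, 3)
  alt <- matrix(rbinom(60, 40, 0.6), 20, 3)
  ref[sample(60, 6)] <- NA
  alt[is.na(ref)] <- NA
  x <- make_counts(ref, alt, pools = c("A_1", "A_2", "B_1"),
                   colony = c("A", "A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sync(x, path)
  y <- read_sync(path, pool_map = pools(x))
  expect_equal(as.data.frame(y), as.data.frame(x))
})

test_that("VCF import keeps biallelic SNPs and honours allelic depths", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2",
    "1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:3,7\t0/0:12,0",
    "1\t200\t.\tC\tT,G\t50\tPASS\t.\tGT:AD\t0/1:5,5,0\t0/1:4,4,2",
    "1\t300\t.\tAT\tA\t50\tPASS\t.\tGT:AD\t0/1:6,6\t0/1:6,6",
    "1\t400\t.\tG\tC\t50\tPASS\t.\tGT:AD\t./.\t0/1:8,2"
  ), path)
  expect_message(
    x <- read_pool_vcf(path, pool_map = c(P1 = "East", P2 = "West")),
    "skipped 2"
  )
  expect_equal(nrow(loci(x)), 2L)  # multi-allelic and indel dropped
  r <- x[x$pos == 100 & x$pool == "P1", ]
  expect_equal(c(r$ref_reads, r$alt_reads), c(3L, 7L))
  expect_true(is.na(x$ref_reads[x$pos == 400 & x$pool == "P1"]))
  expect_equal(unique(x$colony[x$pool == "P2"]), "West")
  expect_error(read_pool_vcf(path, pool_map = c(P1 = "East", PX = "West")),
               "absent")
})

test_that("an all-multiallelic VCF yields an empty table with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1",
    "1\t200\t.\tC\tT,G\t50\tPASS\t.\tGT:AD\t0/1:5,5,0"
  ), path)
  expect_warning(x <- read_pool_vcf(path), "empty")
  expect_equal(nrow(x), 0L)
})

test_that("frequency estimation is the read ratio with missing preserved", {
  x <- make_counts(ref = rbind(c(3, 10, NA)), alt = rbind(c(7, 0, NA)))
  f <- estimate_frequencies(x)
  expect_equal(f$freq, c(0.3, 1, NA))
  # a depth floor turns shallow cells missing
  x2 <- make_counts(ref = rbind(c(1, 30)), alt = rbind(c(0, 10)))
  f2 <- estimate_frequencies(x2, min_depth = 5)
  expect_equal(f2$freq, c(NA, 0.75))
})

test_that("virtual pooling sums reads and propagates missing correctly", {
  ref <- rbind(c(3, 5), c(7, NA), c(NA, NA))
  alt <- rbind(c(7, 5), c(3, NA), c(NA, NA))
  x <- make_counts(ref, alt, pools = c("P1", "P2"), colony = c("G", "G"))
  vp <- virtual_pool(x)
  expect_equal(vp$ref_reads, c(8L, 7L, NA))
  expect_equal(vp$alt_reads, c(12L, 3L, NA))
  expect_equal(estimate_frequencies(vp)$freq[1], 0.4)
  # single-member group is the identity
  single <- virtual_pool(x, grouping = c(P1 = "a", P2 = "b"))
  expect_equal(single$ref_reads[single$pool == "a"], ref[, 1])
  expect_error(virtual_pool(x, grouping = c(P1 = "a")), "without a group")
})

test_that("virtual-pool frequency equals depth-weighted mean of member frequencies", {
  set.seed(7)
  ref <- matrix(rbinom(300, 50, 0.3), 100, 3)
  alt <- matrix(rbinom(300, 50, 0.7), 100, 3)
  x <- make_counts(ref, alt, colony = c("G", "G", "G"))
  f_members <- freq_matrix_of(estimate_frequencies(x))
  depth <- ref + alt
  expected <- rowSums(f_members * depth) / rowSums(depth)
  got <- estimate_frequencies(virtual_pool(x))$freq
  expect_equal(got, unname(expected), tolerance = 1e-12)
})

test_that("locus filtering drops chromosomes, empty and monomorphic loci, idempotently", {
  ref <- rbind(c(10, 10), c(0, 0), c(NA, NA), c(5, 10), c(10, 5))
  alt <- rbind(c(0, 0), c(10, 10), c(NA, NA), c(5, 0), c(0, 5))
  x <- make_counts(ref, alt, chrom = c("1", "1", "1", "X", "2"))
  out <- filter_loci(x, drop_chroms = "X", quiet = TRUE)
  # row 1 all-ref monomorphic, row 2 all-alt monomorphic, row 3 empty, row 4 on X
  expect_equal(loci(out)$chrom, "2")
  again <- filter_loci(out, drop_chroms = "X", quiet = TRUE)
  attr(again, "retention") <- attr(out, "retention") <- NULL
  expect_equal(as.data.frame(again), as.data.frame(out))
  # (1.0, 0.5) is polymorphic and must be retained
  keep <- make_counts(rbind(c(10, 5)), rbind(c(0, 5)))
  expect_equal(nrow(loci(filter_loci(keep, quiet = TRUE))), 1L)
})
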