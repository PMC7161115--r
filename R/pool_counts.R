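#' Pooled read-count tables
#'
#' A `pool_counts` table holds per-locus, per-pool reference/alternative read
#' counts from pool sequencing, in long (tidy) form: one row per locus and
#' pool. A cell with zero total depth is *missing* and stored as `NA` counts.
#'
#' Columns: `chrom`, `pos` (1-based), `ref`, `alt` (single-nucleotide
#' alleles), `pool` (pool label), `colony` (breeding-unit of origin),
#' `ref_reads`, `alt_reads` (non-negative integers, both `NA` when missing).
#'
#' @param x A data frame with the columns listed above (`colony` optional; it
#'   defaults to the pool label).
#' @return A `pool_counts` tibble.
#' @examples
#' df <- tidyr::expand_grid(
#'   tibble::tibble(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G"),
#'   pool = c("P1", "P2")
#' )
#' df$ref_reads <- c(3L, 5L, 10L, 0L)
#' df$alt_reads <- c(7L, 5L, 0L, 12L)
#' as_pool_counts(df)
#' @export
as_pool_counts <- function(x) {
  x <- as_tibble(x)
  needed <- c("chrom", "pos", "ref", "alt", "pool", "ref_reads", "alt_reads")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!("colony" %in% names(x))) x$colony <- x$pool
  x <- dplyr::select(
    x, "chrom", "pos", "ref", "alt", "pool", "colony", "ref_reads", "alt_reads"
  )
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$pool <- as.character(x$pool)
  x$colony <- as.character(x$colony)
  x$ref_reads <- as.integer(x$ref_reads)
  x$alt_reads <- as.integer(x$alt_reads)
  validate_pool_counts(x)
  # zero total depth is the missing convention
  zero <- !is.na(x$ref_reads) & !is.na(x$alt_reads) &
    x$ref_reads + x$alt_reads == 0L
  x$ref_reads[zero] <- NA_integer_
  x$alt_reads[zero] <- NA_integer_
  structure(x, class = c("pool_counts", class(tibble())))
}

validate_pool_counts <- function(x) {
  if (any(x$pos < 1L, na.rm = TRUE)) abort("positions must be >= 1")
  if (any(x$ref == x$alt, na.rm = TRUE)) abort("ref and alt allele must differ")
  if (any(x$ref_reads < 0L | x$alt_reads < 0L, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  if (any(is.na(x$ref_reads) != is.na(x$alt_reads))) {
    abort("ref_reads and alt_reads must be missing together")
  }
  key <- paste(x$chrom, x$pos, x$pool)
  if (anyDuplicated(key) > 0) {
    abort("duplicated (locus, pool) rows")
  }
  pool_colony <- unique(x[, c("pool", "colony")])
  if (anyDuplicated(pool_colony$pool) > 0) {
    abort("a pool is assigned to more than one colony")
  }
  invisible(x)
}

#' @export
print.pool_counts <- function(x, ...) {
  li <- loci(x)
  cat(sprintf(
    "# pool_counts: %d loci x %d pools (%d colonies)\n",
    nrow(li), dplyr::n_distinct(x$pool), dplyr::n_distinct(x$colony)
  ))
  NextMethod()
}

#' Loci and pool metadata of a counts or frequency table
#'
#' @param x A `pool_counts` or `pool_freqs` table.
#' @return `loci()`: one row per locus (`chrom`, `pos`, `ref`, `alt`) in input
#'   order; `pools()`: one row per pool (`pool`, `colony`).
#' @export
loci <- function(x) {
  dplyr::distinct(as_tibble(x)[, c("chrom", "pos", "ref", "alt")])
}

#' @rdname loci
#' @export
pools <- function(x) {
  dplyr::distinct(as_tibble(x)[, c("pool", "colony")])
}

locus_key <- function(x) paste(x$chrom, x$pos, sep = ":")

# loci x pools matrix of one value column, preserving input order
value_matrix <- function(x, col) {
  li <- loci(x)
  po <- pools(x)
  keys <- locus_key(li)
  i <- match(paste(x$chrom, x$pos, sep = ":"), keys)
  j <- match(x$pool, po$pool)
  m <- matrix(NA_real_, nrow = nrow(li), ncol = nrow(po),
              dimnames = list(keys, po$pool))
  m[cbind(i, j)] <- as.numeric(x[[col]])
  m
}

freq_matrix <- function(freqs) value_matrix(freqs, "freq")

#' Read pooled counts from a sync-style table
#'
#' The sync-style format is a tab-separated table with header
#' `chrom pos ref alt <pool1> <pool2> ...` and per-pool cells
#' `ref_reads:alt_reads`. A `0:0` cell denotes a missing record.
#'
#' @param path Path to the file.
#' @param pool_map Optional pool-to-colony assignment: a named character
#'   vector (names are pool labels, values colony labels) or a data frame
#'   with columns `pool` and `colony`. Pools absent from the map raise an
#'   error; with `NULL` each pool is its own colony.
#' @return A [as_pool_counts()] table.
#' @export
read_sync <- function(path, pool_map = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 5L || !identical(header[1:4], c("chrom", "pos", "ref", "alt"))) {
    abort("sync header must start with: chrom pos ref alt <pools...>")
  }
  pool_names <- header[-(1:4)]
  raw <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, comment.char = "")
  counts <- lapply(seq_along(pool_names), function(j) {
    cells <- raw[[4L + j]]
    parts <- strsplit(cells, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0) {
      abort(sprintf("malformed count pair on data line %d: '%s'", bad[1], cells[bad[1]]))
    }
    m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
    bad <- which(is.na(m[, 1]) | is.na(m[, 2]) | m[, 1] < 0L | m[, 2] < 0L)
    if (length(bad) > 0) {
      abort(sprintf("malformed count pair on data line %d: '%s'", bad[1], cells[bad[1]]))
    }
    m
  })
  long <- tidyr::expand_grid(
    tibble(chrom = raw$chrom, pos = as.integer(raw$pos), ref = raw$ref, alt = raw$alt),
    pool = pool_names
  )
  # expand_grid is locus-major; t() of the loci x pools matrices matches it
  long$ref_reads <- as.vector(t(vapply(counts, function(m) m[, 1], integer(nrow(raw)))))
  long$alt_reads <- as.vector(t(vapply(counts, function(m) m[, 2], integer(nrow(raw)))))
  long$colony <- resolve_pool_map(pool_names, pool_map)[long$pool]
  as_pool_counts(long)
}

resolve_pool_map <- function(pool_names, pool_map) {
  if (is.null(pool_map)) {
    return(setNames(pool_names, pool_names))
  }
  if (is.data.frame(pool_map)) {
    pool_map <- setNames(as.character(pool_map$colony), as.character(pool_map$pool))
  }
  extra <- setdiff(names(pool_map), pool_names)
  if (length(extra) > 0) {
    abort(paste0("pool_map names pools absent from the input: ",
                 paste(extra, collapse = ", ")))
  }
  unmapped <- setdiff(pool_names, names(pool_map))
  if (length(unmapped) > 0) {
    abort(paste0("pools without a colony assignment: ",
                 paste(unmapped, collapse = ", ")))
  }
  pool_map
}

#' Write pooled counts to a sync-style table
#'
#' Missing cells are written as `0:0`; [read_sync()] restores them as missing,
#' so the round trip is exact.
#'
#' @param counts A `pool_counts` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(counts, path) {
  po <- pools(counts)
  m_ref <- value_matrix(counts, "ref_reads")
  m_alt <- value_matrix(counts, "alt_reads")
  m_ref[is.na(m_ref)] <- 0
  m_alt[is.na(m_alt)] <- 0
  cells <- matrix(paste0(as.integer(m_ref), ":", as.integer(m_alt)),
                  nrow = nrow(m_ref))
  li <- loci(counts)
  out <- cbind(li$chrom, li$pos, li$ref, li$alt, cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chrom", "pos", "ref", "alt", po$pool), collapse = "\t"), con)
  writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read pooled counts from a VCF with allelic depths
#'
#' Reads a VCF 4.x file in which each sample column is a sequenced pool
#' carrying an `AD` (allelic depth) FORMAT field. Only biallelic SNP records
#' are kept; multi-allelic and non-SNP records are skipped with a message.
#' Records with absent or zero-depth `AD` become missing cells.
#'
#' @inheritParams read_sync
#' @param pool_map Pool-to-colony assignment covering every sample column
#'   (see [read_sync()]); required here because VCF sample names carry no
#'   colony information.
#' @return A [as_pool_counts()] table.
#' @export
read_pool_vcf <- function(path, pool_map = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d multi-allelic or non-SNP record(s)", n_skipped))
  }
  samples <- colnames(v@gt)[-1]
  colony_of <- resolve_pool_map(samples, pool_map)
  keep_fix <- fix[is_snp, , drop = FALSE]
  if (nrow(keep_fix) == 0) {
    warn("no biallelic SNP records in file; returning an empty table")
    empty <- tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      pool = character(), colony = character(),
      ref_reads = integer(), alt_reads = integer()
    )
    return(structure(empty, class = c("pool_counts", class(tibble()))))
  }
  ad <- vcfR::extract.gt(v, element = "AD")[is_snp, , drop = FALSE]
  parse_ad <- function(cells) {
    out <- matrix(NA_integer_, nrow = length(cells), ncol = 2)
    ok <- !is.na(cells) & cells != "." & cells != "./."
    parts <- strsplit(cells[ok], ",", fixed = TRUE)
    two <- lengths(parts) >= 2L
    vals <- t(vapply(parts[two], function(p) suppressWarnings(as.integer(p[1:2])),
                     integer(2)))
    out[which(ok)[two], ] <- vals
    out
  }
  long <- tidyr::expand_grid(
    tibble(chrom = keep_fix$CHROM, pos = as.integer(keep_fix$POS),
           ref = keep_fix$REF, alt = keep_fix$ALT),
    pool = samples
  )
  ads <- lapply(samples, function(s) parse_ad(ad[, s]))
  long$ref_reads <- as.vector(t(vapply(ads, function(m) m[, 1], integer(nrow(keep_fix)))))
  long$alt_reads <- as.vector(t(vapply(ads, function(m) m[, 2], integer(nrow(keep_fix)))))
  long$colony <- colony_of[long$pool]
  as_pool_counts(long)
}
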