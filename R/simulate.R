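#' Configuration for the pool-seq drift simulator
#'
#' Describes a pool-sequencing study of isolated breeding colonies that
#' diverged from a common founder gene pool by pure genetic drift. The
#' defaults mirror a five-colony design with two DNA pools of ten diploid
#' animals per colony sequenced to an aimed coverage of 30x, with a sprinkle
#' of missing records.
#'
#' @param n_loci Number of biallelic loci (default 10000).
#' @param n_colonies Number of isolated colonies (default 5).
#' @param n_e Effective population size per colony (default 50).
#' @param generations Generations of Wright-Fisher drift since the founder
#'   split (default 7).
#' @param pools_per_colony Sequenced pools per colony (default 2).
#' @param animals_per_pool Diploid animals per pool (default 10).
#' @param mean_depth Mean Poisson read depth per locus and pool (default 30).
#' @param missing_prob Probability that a (locus, pool) cell is unrecorded
#'   (default 0.1; depth-0 draws are missing as well).
#' @param founder_range Range of the uniform founder reference-allele
#'   frequency spectrum (default `c(0.05, 0.95)`).
#' @param class_probs Named class-label probabilities for the functional
#'   annotation of loci, drawn independently of the frequency history;
#'   `NULL` for a default genome-like mix dominated by intronic and
#'   intergenic classes.
#' @param seed Optional master seed; per-stage streams are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_loci = 10000, n_colonies = 5, n_e = 50, generations = 7,
                       pools_per_colony = 2, animals_per_pool = 10,
                       mean_depth = 30, missing_prob = 0.1,
                       founder_range = c(0.05, 0.95), class_probs = NULL,
                       seed = NULL) {
  if (is.null(class_probs)) class_probs <- default_class_probs()
  cfg <- list(
    n_loci = as.integer(n_loci), n_colonies = as.integer(n_colonies),
    n_e = as.integer(n_e), generations = as.integer(generations),
    pools_per_colony = as.integer(pools_per_colony),
    animals_per_pool = as.integer(animals_per_pool),
    mean_depth = mean_depth, missing_prob = missing_prob,
    founder_range = founder_range,
    class_probs = class_probs / sum(class_probs), seed = seed
  )
  stopifnot(
    cfg$n_loci > 0, cfg$n_colonies > 0, cfg$n_e > 0, cfg$generations >= 0,
    cfg$pools_per_colony > 0, cfg$animals_per_pool > 0, cfg$mean_depth > 0,
    cfg$missing_prob >= 0, cfg$missing_prob <= 1,
    length(cfg$founder_range) == 2,
    cfg$founder_range[1] >= 0, cfg$founder_range[2] <= 1,
    cfg$founder_range[1] <= cfg$founder_range[2]
  )
  structure(cfg, class = "sim_config")
}

# genome-like consequence-class mix (intron/intergenic dominated)
default_class_probs <- function() {
  c(intron_variant = 0.654, intergenic_variant = 0.199,
    downstream_gene_variant = 0.0645, upstream_gene_variant = 0.0602,
    `3_prime_UTR_variant` = 0.0108, `5_prime_UTR_variant` = 0.0027,
    synonymous_variant = 0.0057, missense_variant = 0.0024,
    stop_gained = 0.0001, stop_lost = 0.0001)
}

#' Simulate a pool-sequencing study of drifting colonies
#'
#' Per locus, a founder frequency is drawn from the configured spectrum;
#' each colony then drifts independently for `generations` rounds of
#' Wright-Fisher binomial resampling of `2 n_e` chromosomes. Each pool draws
#' `2 * animals_per_pool` chromosomes binomially from its colony frequency,
#' read depth is Poisson, reference reads are binomial in the pool
#' chromosome frequency, and cells are masked missing with probability
#' `missing_prob`. A colony-structured pedigree (for the candidate
#' optimizer) and random functional-class labels (independent of the
#' frequency history) are generated alongside.
#'
#' @param config A [sim_config()].
#' @return A list of class `pool_sim`:
#'   * `counts`: a [as_pool_counts()] table (pools `C1_P1`, `C1_P2`, ...);
#'   * `truth`: founder frequencies, per-colony and per-pool frequencies,
#'     and the closed-form drift expectation [expected_fst()];
#'   * `pedigree`: tibble `id`, `sire`, `dam`, `colony`;
#'   * `classes`: tibble `chrom`, `pos`, `class`.
#' @export
simulate_pools <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  n <- config$n_loci
  nc <- config$n_colonies
  colonies <- paste0("C", seq_len(nc))

  set.seed(stage_seeds[1])  # founder + drift
  founder <- runif(n, config$founder_range[1], config$founder_range[2])
  colony_freq <- matrix(rep(founder, nc), ncol = nc,
                        dimnames = list(NULL, colonies))
  two_ne <- 2L * config$n_e
  for (g in seq_len(config$generations)) {
    colony_freq[] <- rbinom(n * nc, two_ne, colony_freq) / two_ne
  }

  set.seed(stage_seeds[2])  # pool sampling + sequencing
  np <- config$pools_per_colony
  pool_labels <- as.vector(t(outer(colonies, paste0("P", seq_len(np)), paste, sep = "_")))
  pool_colony <- rep(colonies, each = np)
  chroms_per_pool <- 2L * config$animals_per_pool
  pool_freq <- matrix(NA_real_, n, nc * np, dimnames = list(NULL, pool_labels))
  ref_mat <- matrix(NA_integer_, n, nc * np, dimnames = list(NULL, pool_labels))
  alt_mat <- ref_mat
  for (j in seq_len(nc * np)) {
    pf <- rbinom(n, chroms_per_pool, colony_freq[, pool_colony[j]]) / chroms_per_pool
    pool_freq[, j] <- pf
    depth <- rpois(n, config$mean_depth)
    refs <- rbinom(n, depth, pf)
    miss <- depth == 0L | runif(n) < config$missing_prob
    ref_mat[, j] <- ifelse(miss, NA_integer_, refs)
    alt_mat[, j] <- ifelse(miss, NA_integer_, depth - refs)
  }

  li <- tibble(chrom = "1", pos = seq_len(n), ref = "A", alt = "G")
  long <- tidyr::expand_grid(li, pool = pool_labels)
  long$colony <- rep(pool_colony, times = n)
  long$ref_reads <- as.vector(t(ref_mat))
  long$alt_reads <- as.vector(t(alt_mat))
  counts <- as_pool_counts(long)

  set.seed(stage_seeds[3])  # pedigree
  pedigree <- simulate_pedigree(colonies)

  set.seed(stage_seeds[4])  # annotation, independent of frequencies
  classes <- tibble(
    chrom = li$chrom, pos = li$pos,
    class = sample(names(config$class_probs), n, replace = TRUE,
                   prob = config$class_probs)
  )

  structure(
    list(
      counts = counts,
      truth = list(
        founder = founder, colony_freq = colony_freq, pool_freq = pool_freq,
        expected_fst = expected_fst(config$n_e, config$generations)
      ),
      pedigree = pedigree, classes = classes, config = config
    ),
    class = "pool_sim"
  )
}

# small closed-colony pedigrees: founders plus discrete generations with
# random sire/dam pairs drawn from the previous generation
simulate_pedigree <- function(colonies, n_founders = 16, n_per_gen = 16,
                              n_generations = 3) {
  purrr::map_dfr(colonies, function(col) {
    ids <- sprintf("%s_I%03d", col, seq_len(n_founders + n_generations * n_per_gen))
    sire <- rep(NA_character_, length(ids))
    dam <- rep(NA_character_, length(ids))
    prev <- seq_len(n_founders)
    nxt <- n_founders
    for (g in seq_len(n_generations)) {
      males <- prev[seq_len(floor(length(prev) / 2))]
      females <- setdiff(prev, males)
      cur <- nxt + seq_len(n_per_gen)
      sire[cur] <- ids[sample(males, n_per_gen, replace = TRUE)]
      dam[cur] <- ids[sample(females, n_per_gen, replace = TRUE)]
      prev <- cur
      nxt <- nxt + n_per_gen
    }
    tibble(id = ids, sire = sire, dam = dam, colony = col)
  })
}

#' Expected drift differentiation from the founder population
#'
#' Closed-form expectation `1 - (1 - 1/(2 n_e))^t` of the differentiation a
#' single colony accumulates against its founder gene pool after `t`
#' generations of pure drift at effective size `n_e`. Used as an
#' approximation band for recovering pairwise two-colony F_ST from
#' simulations; the per-locus-ratio pairwise estimator sits below this value
#' for moderate drift while finite pool sizes and read depths push it up.
#'
#' @param n_e Effective population size (>= 1).
#' @param t Generations since the split (>= 0).
#' @return The expected differentiation, in `[0, 1)`.
#' @examples
#' expected_fst(50, 7)  # ~0.0679
#' @export
expected_fst <- function(n_e, t) {
  stopifnot(n_e >= 1, t >= 0)
  1 - (1 - 1 / (2 * n_e))^t
}

#' @export
print.pool_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "# pool_sim: %d loci, %d colonies x %d pools x %d animals, Ne = %d, t = %d\n",
    cfg$n_loci, cfg$n_colonies, cfg$pools_per_colony, cfg$animals_per_pool,
    cfg$n_e, cfg$generations
  ))
  cat(sprintf("  expected drift differentiation vs founder: %.4f\n",
              x$truth$expected_fst))
  invisible(x)
}
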