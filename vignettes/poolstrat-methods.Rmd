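---
title: "Methods: pool-seq stratification statistics in poolstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq stratification statistics in poolstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolstrat)
```

`poolstrat` quantifies genetic stratification among closed subpopulations
("colonies") from pooled whole-genome sequencing. This vignette documents
the statistical model behind each function, the parameters that matter, the
numerical conventions, and what the simulation-based validation does and
does not establish.

## Data model

The substrate is a long table of per-locus, per-pool read counts
(`as_pool_counts()`): biallelic SNPs only, 1-based positions, reference
orientation taken from the input file without re-polarisation. A cell with
zero total depth carries no information about the pool's allele frequency
and is treated as *missing*; both supported input formats (VCF `AD` fields
via `read_pool_vcf()`, `ref:alt` sync-style TSV via `read_sync()`) encode
missing cells that way, so write/read round trips are exact. Multi-allelic
and non-SNP records are skipped rather than split, matching the biallelic
scope of the statistics downstream.

The frequency estimator (`estimate_frequencies()`) is the plug-in read
ratio `p = R_ref/(R_ref + R_alt)`. It ignores that reads are drawn from a
finite pool of chromosomes — the estimator every downstream formula assumes.
A `min_depth` floor (default 1, i.e. inactive) is available because at depth
1 the estimate is necessarily 0 or 1; the default keeps every recorded cell
so that results match the plain read-ratio definition.

`virtual_pool()` mimics a physical DNA pool by summing member read counts
per locus. The group frequency is therefore the depth-weighted mean of
member frequencies (an identity the tests assert). A group cell is missing
only when *all* members are missing: a recorded member contributes
information even when its partner does not.

`filter_loci()` removes, in order, loci on excluded chromosomes (sex
chromosomes are the common case: pool composition confounds X-linked
frequencies), loci recorded in no pool, and loci monomorphic across all
retained pools (all non-missing frequencies exactly 0, or all exactly 1).
The filter is idempotent and logs retention counts.

## Differentiation

Per locus, for two units with frequencies `p1`, `p2`:

* fixation index `F_ST = (H_T − H̄_S)/H_T`, `H_T = p̄(1−p̄)`,
  `p̄ = (p1+p2)/2`, `H̄_S` the mean within-unit heterozygosity. Loci where
  both units are fixed for the same allele have `H_T = 0`; the ratio is
  undefined there and the locus is excluded (it is *not* scored 0 — a
  monomorphic, identical locus carries no differentiation signal).
* Reynolds distance `D_R = ½ Σᵢ (p1ᵢ−p2ᵢ)² / (1 − Σᵢ p1ᵢ p2ᵢ)`, summing
  over the two alleles; undefined under the same co-fixation condition.

Genome-wide values (`genomewide_matrix()`) are unweighted means of the
per-locus values over the loci that are pairwise complete for each pair —
the mean of ratios, not a ratio of sums, and no depth weighting. Per-pair
locus counts are kept alongside the estimates. Colony-level statistics are
computed on the virtual union of the colony's pools; both pool-level and
colony-level groupings remain available because group summaries can
reasonably average either.

Both statistics are validated against independent brute-force
transcriptions of the formulas on 10^4 random frequency pairs at 1e-12, and
their closed-form endpoints (0 at equality, 1 at opposite fixation,
`F_ST(0.8, 0.4) = 1/6`, `D_R(0.8, 0.4) = 0.16/0.56`) are asserted exactly.

## The pooled-variance F-test

For a unit with pools `a1`, `a2` and a remote pool `r`, the statistic is
`F = V_I / V_O` with `V_I = m_I(1−m_I)·2/n` at the within-unit mean
`m_I = (p_a1+p_a2)/2`, and `V_O` the same form at the unit-vs-remote mean
`m_O = (p_a1+p_r)/2`; `n` is the number of animals per pool (default 10).
Both are binomial-type variances evaluated at the pair mean — the statistic
measures whether the *mean* frequencies place the two comparisons in
different variance regimes, and a unit sitting near fixation has a small
`V_I`. Degrees of freedom are fixed at `(n−1, n−1)` — (9, 9) for the
default pool size — regardless of read depth, reflecting that pools of ten
animals carry at most ten independent samples of the colony.

Design choices the formula leaves open:

* **Which basis pool anchors `V_O`.** The defining example uses the unit's
  first pool; `basis_pool = "second"` switches.
* **Sidedness.** Differentiation can inflate either variance (a remote pool
  near 0.5 inflates `V_O`; a near-fixed unit deflates `V_I`), so the default
  p-value is two-sided, `p = 2·min(P(F≤f), P(F≥f))` capped at 1;
  `sided = "lower"` restricts to the lower tail.
* **Multiplicity.** Bonferroni is applied *per contrast* (per basis colony ×
  remote pool), because the natural summary is a per-contrast proportion
  over per-contrast locus counts. Loci where `V_O = 0` are undefined and
  excluded before the correction.

p-values are validated against a numerically integrated F-density at 1e-10.
Because `V_I` depends only on the unit mean, the contrast summary is
asymmetric whenever units have drifted unequally — a strongly drifted unit
(many near-fixed loci, tiny `V_I`) flags moderate remote pools that would
never flag it in return; the tests construct exactly this configuration.

## PCA with missing data

Frequencies are arranged samples × loci, each locus centered on its mean
over recorded samples and scaled by its population SD (divisor *n*; the
choice between population and sample SD is immaterial at genome scale and
population SD keeps the convention consistent with the descriptive
summaries elsewhere in the package). Zero-variance loci — constant, or
recorded in fewer than two samples — cannot be scaled and are dropped with
a message. Missing entries become 0 in `X` and 0 in the indicator `N`.

The adjusted covariance is `E = XX′ / NN′` elementwise: each sample pair is
averaged over exactly the loci both samples recorded. `E` is exactly
symmetric as computed (both cross-products come from `tcrossprod`), but it
need not be positive semi-definite; after the symmetric eigendecomposition,
negative eigenvalues are truncated to zero before taking square roots, and
variance-explained fractions are relative to the truncated total.
Components are `V·diag(√λ⁺)`. Sign per component is arbitrary, as in any
PCA, and equal eigenvalues keep the solver's stable ordering (eigenvector
bases within such an eigenspace are arbitrary). A sample pair sharing no
recorded locus makes `E` undefined; the error names the pair. With complete
data the procedure reduces exactly to ordinary covariance PCA of the scaled
matrix, which the tests verify against an independently coded oracle at
1e-8 on 20 samples × 5 000 loci.

## UPGMA and resampling support

Trees are classic average-linkage (UPGMA) agglomerations of the genome-wide
F_ST matrix, delegated to `phangorn::upgma()`; two units merging at
distance *d* sit at height *d*/2, so cophenetic distances reproduce the
input on ultrametric matrices. Equal off-diagonal distances are resolved by
the clustering backend's merge order; the matrices this package produces
are continuous-valued, so exact ties have measure zero. Output trees are
verified ultrametric (three-point condition at 1e-12) and checked against a
hand-written textbook UPGMA on random 6-leaf matrices.

Node support (`resample_support()`) rebuilds the tree from `n_trees`
(default 100) random subsets of `n_loci` (default 100) loci and reports,
per reference clade, the fraction of replicate trees containing the same
leaf bipartition (compared unrooted-style, clade vs. complement). Sampling
is *without* replacement by default — the procedure is a locus-subsampling
stability check, not a bootstrap — with `replace = TRUE` available.
Replicate loci are drawn from the fully recorded loci so every replicate
matrix is complete; the reference tree itself uses all loci under the
pairwise-complete rule. The root, a trivial bipartition, has support 1 by
construction. Newick output stores supports as internal node labels.

## Diversity summaries

Expected heterozygosity is `2p(1−p)` per locus; unit summaries report the
mean and population SD over non-missing loci plus the locus accounting.
Because `2p(1−p)` is concave, a virtual union's per-locus heterozygosity
always dominates the depth-weighted mean of its members' values — the tests
assert this per locus, and genome-wide union values exceed mean pool values
on simulated data.

"Fixed" means a frequency of exactly 0 or 1 from the read counts — no
tolerance band by default, since read counts are integers and unanimity is
well defined; an `epsilon` parameter exists because deeply sequenced pools
rarely hit exact bounds in other people's pipelines. Oppositely fixed loci
require a complete record across units, unanimous fixation, and
disagreement; the per-unit fixed-allele indicators (1 = reference) feed a
Pearson correlation between units. Private polymorphisms come in a strict
mode (complete records, exactly one unit variable, the rest fixed) and an
allow-missing mode (missing units ignored; at least one recorded fixed
partner required), whose counts dominate the strict counts by construction.

## Functional-class enrichment

Each locus carries one consequence class (the caller resolves severity
upstream; compound labels pass through). Composition is the percentage
breakdown of a locus set; relative abundance divides a subset's composition
by a background's, class by class — a purely descriptive ratio, with no
significance test attached, because a handful of loci in a rare class says
little either way. `abundance_by_bin()` profiles the ratios across F_ST
bins (half-open `[a, b)`, closed top bin) against all binned loci. When
class labels are independent of differentiation the ratios converge to 1;
the tests verify this at 10^5 loci for classes common enough to estimate
(the acceptance summary likewise restricts its neutrality measure to
classes holding at least 1 % of the background, since a class with a few
dozen loci cannot yield a stable ratio at desk-scale locus counts).

## Pedigree-based candidate selection

`relationship_matrix()` builds Wright's numerator relationship matrix by
the tabular method over the topologically sorted pedigree (`A(i,i) = 1 +
A(s,d)/2`, `A(i,j) = (A(j,s)+A(j,d))/2`, unknown parents contributing 0);
cycles are detected and refused, and parents not listed as individuals are
treated as unknown founders. The matrix is cross-checked against an
independent recursive kinship implementation (×2) at 1e-12. The
correlation-normalised coefficient `A(i,j)/√(A(i,i)A(j,j))` is available
behind `normalize = TRUE`; the numerator form is the default because the
selection index was defined on it.

The candidate index for a subset of size `k` is `I = 0.8a − 0.2b`, with `a`
the mean relationship over unordered pairs *within* the subset (diagonal
excluded — an animal's relationship to itself is not within-sample
relationship) and `b` the mean over subset × remainder pairs. Minimising
`I` favours internally diverse subsets that still represent the colony.
`optimize_subset()` is a pure random-restart search, as the index was
originally used: uniform random `k`-subsets, keep the best, stop after
`max_stall` (default 25 000) consecutive draws without improvement. The
keep-best-with-stall-counter reading subsumes the alternative
"restart-on-improvement" reading's stopping behaviour. Draws are evaluated
in vectorised batches; the batch size is a performance knob that provably
does not change the draw sequence or the result. On 12-animal instances
the search recovers the exhaustive optimum over all 792 subsets in ≥ 99 of
100 seeded runs.

## The simulator and what validation shows

`simulate_pools()` emulates the sampling hierarchy of a pooled
re-sequencing study of isolated colonies:

| stage | model | default |
|---|---|---|
| founder frequency | uniform on a range | `[0.05, 0.95]` |
| colony drift | Wright–Fisher binomial, `2N_e` chromosomes, `t` generations | `N_e = 50`, `t = 7` |
| pool composition | binomial draw of `2 × animals` chromosomes per pool | 2 pools × 10 animals per colony |
| sequencing | Poisson depth, binomial reference reads | mean depth 30 |
| missingness | independent cell masking (plus depth-0 cells) | probability 0.1 |
| annotation | class labels independent of frequency history | genome-like mix, intron/intergenic dominated |

The defaults mirror the five-colony, two-pools-of-ten, 30× design the
package targets; the 10 % missingness matches the order of per-pool
unrecorded loci such studies report. A colony-structured pedigree (founders
plus three discrete generations with random parent pairs) is generated for
the selection module. All stages draw from streams derived from one master
seed, so output is bit-reproducible.

The closed form `expected_fst(N_e, t) = 1 − (1 − 1/(2N_e))^t` is the drift
differentiation of a *single* colony against its founder. For a pair of
colonies the per-locus-ratio F_ST estimator recovers roughly half that
value at moderate drift, while two layers of sampling noise — 20
chromosomes per pool and ~30 reads per cell — push the estimate back
upward; the validation therefore checks that the measured mean pairwise
colony F_ST at `N_e = 50`, `t = 7`, 50 000 loci falls within ±30 % of the
closed form, a recovery band rather than an equality. Validation problem
sizes throughout were chosen to make sampling noise small relative to the
asserted effects: 10^4 random pairs for formula equivalence, 20 × 5 000
matrices for PCA, 100 random 6-leaf matrices for UPGMA, 100 seeded runs
for the optimizer, 50 000-locus simulations for drift recovery, 10^5 loci
for enrichment neutrality.

What the simulator does *not* model — and what passing tests therefore do
not establish about real data: linkage and recombination (loci are
independent, so resampling supports on simulated data are optimistic),
selection (pure drift is the null; a per-locus selection hook is a natural
extension point), sequencing error and reference bias (read counts are
clean binomials), ascertainment of the variant set, and overlapping pool
membership (pools are drawn independently). The F-test's null calibration
inherits the statistic's own approximations: with fixed (9, 9) degrees of
freedom the simulated no-drift configuration stays *below* the nominal
Bonferroni level (a conservative bound the tests assert) rather than
attaining it.

## Known limitations

* Biallelic SNPs only; indels and multi-allelic records are skipped.
* The F-test compares means through a binomial variance proxy; it is not a
  read-depth-aware test and inherits the fixed-df approximation.
* Genome-wide averages are unweighted; no sliding windows or
  multi-population F_ST estimators (Weir–Cockerham, Hudson) are provided.
* PCA offers no imputation or projection of new samples; missingness is
  handled in the covariance only.
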