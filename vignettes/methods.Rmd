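---
title: "Methods: paired-cohort microbiome networks, diversity, and abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-cohort microbiome networks, diversity, and abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`micronet`, the assumptions behind them, the tunable parameters and
their defaults, and the numerical and design choices made where more
than one reasonable option existed.

## The analysis problem

The package targets paired two-timepoint cohort designs: each subject
contributes one stool-derived 16S feature table sample at 1 month and
one at 6 months, and subjects are split into a weight-gain and a
weight-loss group. Three families of questions are asked of such data:

1. Does the co-occurrence structure of the community (taxa that rise
   and fall together across subjects) change between timepoints within
   a group?
2. Does within-sample (alpha) or between-sample (beta) diversity
   change between timepoints?
3. Which individual taxa change in relative abundance, after multiple
   testing correction?

## Preprocessing

Counts flow through three distinct branches, and keeping their inputs
separate is deliberate:

- the **abundance/diversity branch** removes taxa with total count
  ≤ 420 and then taxa observed in fewer than
  `ceiling(0.10 × n_samples)` samples (`filter_taxa()`); the diversity
  metrics additionally rarefy to 10,000 reads per sample
  (`rarefy()`); abundance tests use the unrarefied filtered table
  transformed by `log_relative_abundance()`;
- the **network branch** (`filter_for_network()`) keeps absolute
  counts — no rarefaction, no transform — retaining taxa with total
  ≥ 420 and a mean of at least two reads per sample, because SparCC
  consumes raw counts through its own Dirichlet treatment.

Boundary semantics are explicit: the total-count rule removes at
exactly 420 ("less than or equal to"); the prevalence rule retains at
exactly 10% (the minimum sample count uses a ceiling); the total-count
filter runs before the prevalence filter (the two only partially
commute). Rarefaction subsamples reads without replacement — a sample
at exactly the target depth is provably unchanged — and drops samples
below the depth, reporting their ids; downstream paired tests then
restrict to subjects retaining both timepoints.

The log transform is
`log10(count/total × average_sequences_per_sample + 1)`. The scaling
constant defaults to the mean library size of the table being
transformed (after filtering), overridable through
`transform_params()`: with a pseudocount of 1 the transform maps zero
counts to exactly 0 and is strictly monotone in the count at fixed
total.

Taxonomic aggregation (`aggregate_taxa()`) sums counts over the
lineage prefix at the requested rank. Features with an unnamed rank
under a named parent aggregate to a `"Family X - unknown genus"`
group, so unresolved clades remain first-class testable units rather
than being dropped or pooled into one "unclassified" bucket.

## SparCC correlation inference

SparCC assumes log-normal basis abundances observed only through
compositions. The implementation follows the reference algorithm:

1. **Dirichlet resampling** (`draw_fractions()`): each sample's
   fractions are one draw from Dirichlet(counts + 1), which handles
   zeros without an ad-hoc pseudocount and propagates counting
   uncertainty.
2. **Log-ratio variances** (`log_ratio_variances()`):
   t_ij = Var[log(x_i/x_j)], computed from the log-fraction
   covariance matrix.
3. **Basis estimation** (`estimate_basis()`): under sparsity the row
   sums of T are linear in the basis variances ω²; the system is
   solved, variances floored at `variance_floor` (1e-8), and
   correlations r_ij = (ω_i² + ω_j² − t_ij)/(2ω_iω_j) clamped to
   [−1, 1].
4. **Iterative exclusion**: while the largest |r| exceeds
   `exclusion_threshold` (0.1) the single most-correlated pair is
   removed from the system and it is re-solved, up to
   `max_exclusion_rounds` (10) pairs. Removing one pair per round is
   what makes the loop deterministic.
5. **Aggregation**: the estimate is the element-wise *median* over
   `n_estimation_iterations` (20) Dirichlet draws — robust to draw
   outliers, and matching reference behaviour.

Defaults (20 iterations, threshold 0.1, 1000 bootstraps) follow the
algorithm's reference description and are all exposed in
`sparcc_params()`.

Significance (`bootstrap_pvalues()`) permutes every taxon's counts
across samples independently — destroying co-occurrence while
preserving marginal count distributions — re-estimates the matrix, and
reports two-sided p-values with the +1 pseudo-count,
p = (1 + #{|r_boot| ≥ |r_obs|})/(1 + B), so p is never exactly 0.

**Degeneracy is a typed condition, not a crash.** A basis system that
cannot be solved (too many exclusions, or a taxon with no reads in the
sample set) raises `singular_basis_error`, which the subsampling
machinery catches and reacts to. Two remarks a user should know:

- With few taxa (D ≲ 15) the compositional null correlation is around
  −1/(D−1), which already exceeds the default exclusion threshold, so
  aggressive exclusion can make the system singular *by design*. At
  such small D, relax `exclusion_threshold` and/or
  `max_exclusion_rounds`; at the intended scale (≈ 70 taxa) the
  defaults are safe.
- SparCC needs at least 4 taxa and at least 2 samples, enforced as
  preconditions.

## Co-occurrence networks

`build_network()` draws an edge when p < alpha (strict inequality:
p = 0.05 exactly is *not* an edge) and keeps every filtered taxon as a
node whether or not it gains edges. `compute_metrics()` reports edge
count, edge density 2E/(N(N−1)) — the denominator being all unordered
pairs over the full filtered node set — and the average local
clustering coefficient, with nodes of degree < 2 contributing 0 (the
common convention; the triangle counting is delegated to igraph).

**Subsample equalization** (`subsample_networks()`): when groups have
unequal size, the larger group's networks would look denser for purely
statistical reasons. The larger group is therefore subsampled to the
smaller group's size (40-of-65 by default), 250 times, without
replacement within a replicate and independently across replicates;
each replicate runs the full SparCC → network → metrics chain and the
replicate mean is reported. A replicate raising
`singular_basis_error` is discarded and redrawn, with a retry budget
of 10× the replicate count; the retained count always equals the
configured count. By default the per-replicate SparCC seed is drawn
from the master seed sequence, so replicate spread includes estimator
noise — exactly what rerunning a compiled SparCC binary per subsample
would produce; passing a fixed seed in `sparcc_params()` freezes the
estimator instead.

The **representative network** is the replicate minimizing Euclidean
distance over z-scored (edge count, edge density, clustering) from
the replicate means; a metric with zero spread contributes nothing,
and ties break to the lowest replicate index, making selection
deterministic. `compare_timepoints()` reports each metric at both
timepoints and the percent change 100(m₆ − m₁)/m₁ rounded to two
decimals (undefined — `NA` — on a zero baseline, never infinity), and,
when subsampling was used, also the full-sample variant for
comparison.

## Diversity

- **Shannon entropy** defaults to base 2 (bits), the convention of the
  QIIME-lineage tooling; the base is configurable since conventions
  differ.
- **Faith's PD** uses the rooted convention (the minimal subtree
  includes the root), delegated to `picante::pd`; an observed taxon
  missing from the tree is an explicit error naming it, and an empty
  sample scores 0 without consulting the tree.
- **Bray–Curtis** is computed on rarefied relative abundances (the
  input normalization is a package choice; rarefied proportions keep
  depth effects out of the dissimilarity).
- **PERMANOVA** is implemented directly from the distance-based
  sum-of-squares decomposition (SS_total = Σ d²/n within and between
  groups, pseudo-F, permutation p with the +1 correction) rather than
  wrapping an existing implementation, for two reasons: exact control
  of seeding, and a restricted permutation mode (`strata =` subject)
  for paired designs. The free-permutation default matches the
  standard reporting convention for between-timepoint tests; the test
  suite cross-checks R² and pseudo-F against `vegan::adonis2` to ten
  decimal places. The default permutation count is 999.

## Differential abundance

`test_taxa()` runs, per taxon, a two-sided paired t-test on
per-subject differences of the log-transformed relative abundance
(the log scale is where the t-test's assumptions are defensible),
while the *reported* percent change is computed from group-mean raw
relative abundances (ratio-of-means; a mean-of-ratios option exists).
This split — test on the log scale, report on the linear scale — is
the only reading consistent with an integer percent-change reporting
convention alongside a log-scale test.

Benjamini–Hochberg correction is applied within one taxonomic level
within one weight group (pooling levels into a single family would
make the test count hard to interpret; a pooled run is available by
aggregating beforehand). A taxon with zero variance of differences is
reported with `NA` p-values rather than excluded silently. The 5 kg
weight-return stratification uses an inclusive boundary (a difference
of exactly 5.0 kg counts as "within").

Cohort descriptives (`describe_cohort()`) use paired t-tests within
groups across timepoints and *unpaired* t-tests between groups — the
groups contain disjoint subjects, so a paired between-group test is
not defined. Significance letters are assigned greedily in cell order
under the constraint that cells differing at p < 0.05 never share a
letter; variables with no significant comparison get no letters.

## The synthetic study generator

The generator exists because the motivating cohort's sequences are not
public; it emulates the *design*, not the dataset:

- **Basis model**: multivariate log-normal — the generative model
  SparCC itself assumes, which makes parameter-recovery tests
  well-posed. Marginal log-SD defaults to 1; each (group, timepoint)
  cell has its own target correlation matrix (validated for symmetry,
  unit diagonal and positive semi-definiteness; `nearest_psd()`
  repairs hand-written block targets by eigenvalue clipping, with a
  warning).
- **Pairing**: the two timepoints of a subject share a latent subject
  effect carrying 40% of log-abundance variance, so paired tests are
  genuinely more powerful than unpaired ones, as in real cohorts.
- **Rank abundance**: a fixed geometric profile spanning ~6.2 natural
  log units, interleaved across the taxon list by a fixed stride so
  phyla mix; planted-effect taxa are floored at a detectable abundance
  so planted signals are recoverable at realistic depth.
- **Planted effects**: the gain group's 6-month cell applies
  multiplicative fold changes of the reported effect magnitudes
  (e.g. ×1.85, ×0.50) and an *evenness decay* (default 1.35) that
  widens the spread of the unplanted taxa's mean log abundances. The
  decay is mass-preserving over the unplanted taxa, so planted fold
  changes survive closure as matching relative-abundance changes; its
  default was chosen so the mean paired Shannon drop is ≈ 0.35 bits at
  the study's group size, the scale of change the design targets.
  Setting `evenness_decay = 1` and all fold changes to 1 with
  identical correlation targets yields a fully null generator — the
  configuration used by the calibration tests.
- **Sequencing**: multinomial sampling per sample under closure;
  library sizes from a truncated log-normal (meanlog = log 30,785,
  sdlog = 0.65, truncated to [12, 64,069]), chosen to match the
  printed median depth and to drop a handful of samples per cohort at
  the 10,000-read rarefaction depth, as observed.
- **Tree**: random bifurcating topology with exponential branch
  lengths — Faith's PD only requires a valid rooted tree.
- **Zero inflation**: the real table's dropout level is unknown; a
  `dropout` knob (default 0) suppresses random basis entries so
  prevalence filtering under heavy sparsity can be exercised, but no
  published value exists to match.

What the generator does **not** emulate: read-level error, chimeras,
taxonomic misassignment, diet/activity covariates, or the real
cohort's actual correlation structure. Passing tests therefore
demonstrate that the *pipeline* recovers what was planted under its
own generative assumptions — not that the published dataset-dependent
estimates (specific edge densities, specific FDR values) would be
reproduced.

## Determinism and problem sizes

Every stochastic step takes a seed: the pipeline derives stage seeds
from one master seed, and identical seeds give bit-identical results,
including the subsample draws discarded by singular-replicate
redraws. The test suite and the acceptance script run at reduced
sizes chosen as a deliberate accuracy/runtime trade-off: SparCC
recovery and calibration at 70 taxa × 200 samples with 200
bootstraps; subsample determinism at 250 replicates of a 12-taxon
table; the end-to-end planted-effect check at the full 210-sample
design with 15 network replicates and 30 bootstraps; Shannon power
over 20 simulated cohorts. The `pipeline_config()` presets encode the
same idea: `"fast"` (100 bootstraps, 25 replicates) for interactive
work, `"full"` (1000 bootstraps, 250 replicates, 999 permutations)
for study-scale runs.

## Known limitations

- SparCC's estimates attenuate for rare taxa (counting noise dilutes
  log-ratio signal); planted correlations on low-abundance taxa are
  recovered with downward bias. This is a property of the method, not
  of the implementation.
- Bray–Curtis is not a metric (no triangle inequality), which is why
  PERMANOVA is used rather than methods assuming Euclidean geometry.
- The percent change of group means on the linear scale and the paired
  test on the log scale can disagree in borderline cases (a taxon can
  be significant with a small linear percent change, or vice versa);
  both are reported so the tension is visible.
- With very small groups the network branch is fragile by nature:
  few-sample SparCC is noisy and exclusion-driven singularity becomes
  likely, which is why the subsampling machinery treats it as a
  recoverable condition.
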