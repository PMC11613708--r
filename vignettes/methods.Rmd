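---
title: "Scoring cell-to-cell epigenetic heterogeneity with epichaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell-to-cell epigenetic heterogeneity with epichaos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epichaos)
```

## The problem

Single-cell epigenomics assays (scATAC-seq, single-cell DNA methylation,
scChIP-seq) deliver sparse features-by-cells matrices that are routinely
binarized: an entry records whether a peak, tile or bin was detected in a
cell. Clustering answers *which* distinct cell states exist; it does not
answer how *variable* cells are within one state. epichaos assigns each
cluster (or any user-defined cell group) a score of cell-to-cell
epigenetic heterogeneity, so that groups can be ranked — e.g. stem versus
differentiated compartments, or therapy-resistant versus sensitive tumor
cells.

## The score

For two binary cell profiles $x, y$ of length $n$ with $s_1 = |x|$,
$s_2 = |y|$ and intersection $a$, the Jaccard similarity is
$J = a / (s_1 + s_2 - a)$. $J$ is strongly driven by per-cell detection
rates: two dense cells overlap heavily by chance alone. We therefore
center $J$ by its expectation under independence given the marginal
densities $p_i = s_i / n$:

$$E = \frac{p_1 p_2}{p_1 + p_2 - p_1 p_2}, \qquad c(x,y) = J - E.$$

$c$ is zero for chance-level overlap at any density (validated in the
test suite against a 10,000-permutation Monte-Carlo estimate of the
permutation-null mean of $J$; agreement is within 0.01 for $n \ge 100$ —
for very short vectors the permutation null is hypergeometric and the
independence expectation deviates, which is why the oracle is run at
realistic feature counts). When both cells are empty, $J$, $E$ and $c$
are defined as 0 with a warning: an empty cell carries no signal.

Per group, the **raw** score is the mean of $c$ over all unordered cell
pairs, and the **mean count** is the average per-cell number of detected
features. Residual coverage effects (sequencing depth, quiescence,
genome-wide accessibility shifts, false-negative dropout) survive
pair-level centering, so raw scores from *all* observations of a run are
regressed on mean count by OLS; the residuals are the **adjusted**
scores. Finally adjusted scores are min-max scaled to $[0,1]$ and
subtracted from 1, so the most heterogeneous observation of a run scores
1 — a similarity becomes a distance. Final scores are therefore
*relative to the run*; the `raw` and `adjusted` columns are always
emitted for cross-run or invariance analyses where the forced $[0,1]$
range would mislead.

### Degenerate cases and numerical choices

* Fewer than 3 observations, or a constant covariate: OLS would fit
  exactly and return all-zero residuals, erasing the signal. The
  adjustment falls back to mean-centering (`raw - mean(raw)`), recorded
  in the `adjust_method` attribute.
* OLS residuals below $10^{-12} \times \mathrm{range}(raw)$ are snapped
  to 0: duplicated observations and exact fits must tie rather than have
  floating-point dust amplified by the min-max step. Region-set ranks are
  computed on scores rounded to 10 decimals for the same reason.
* All adjusted scores equal: no ordering exists; every final score is
  0.5 with a warning.
* Groups with fewer than 2 cells are skipped with a warning.
* All randomness (subsampling, generators, permutations) flows through a
  single integer seed via `withr::with_seed`, so runs are byte-for-byte
  reproducible and the caller's RNG state is untouched. Pair enumeration
  order is fixed by cell order.

### Subsampling

Group size affects the precision of a mean over $\binom{k}{2}$ pairs, so
by default each group with at least 100 cells is scored on 5 random
subsamples of exactly 100 cells (drawn without replacement within a
replicate, independently across replicates); smaller groups are scored
once on all cells and flagged `all_cells`. The regression is fitted
across all group × replicate observations of the run.

### Per-chromosome (copy-number robust) variant

A whole-chromosome deletion or gain shifts both coverage and apparent
similarity on that chromosome. `per_chromosome_scores()` stratifies by
chromosome (chromosomes with fewer than `min_features = 20` features are
excluded): raw score and chromosome-restricted mean count are computed
per observation and chromosome, the regression is fitted within each
chromosome across observations, and an observation's corrected score is
the mean of its per-chromosome residuals. Min-max inversion is applied
*after* averaging (the alternative — scaling per chromosome before
averaging — would let a single noisy chromosome dominate through its
forced 0/1 endpoints). A single-chromosome matrix reduces exactly to the
global score.

The "uncorrected" comparison arm in the copy-number validation is the
score *without* count regression (`adjust = FALSE`). With only six
groups, a CNA group is a high-leverage point of the global regression and
its residual is shrunk toward zero, so the regression-adjusted global
score is not systematically extreme — the deletion artifact is visible in
the unadjusted score, and that is what the package contrasts with the
per-chromosome correction.

## Region sets and differential heterogeneity

`score_region_sets()` subsets the matrix to the features overlapping
each region set (BED semantics: 0-based half-open, any $\ge 1$ bp
overlap, strand ignored) and scores one cell group across region sets,
with the regression fitted across region sets (covariate: mean per-cell
count within the subset). Region sets with fewer than `min_features = 20`
overlapping features are flagged and excluded from scaling and ranking —
a mean similarity over a handful of features is too unstable to rank.
Ranks are dense (1 = most heterogeneous); rows are ordered by score with
name as the deterministic tiebreak.

`differential_heterogeneity()` tests one region set collection between
two groups: the observed heterogeneity difference is compared with
differences between 1000 random splits of the pooled cells into
pseudo-groups of the original sizes. The statistic is the adjusted but
*unscaled* score difference — min-max over two groups degenerates to
{0, 1}; with two groups the adjustment fallback makes it the raw-score
difference on the heterogeneity scale. P-values use add-one smoothing,
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\}) / (n_{perm} + 1)$,
so $p \ge 1/(n_{perm}+1)$ and a zero observed difference returns exactly
1. The test is two-sided by default (the direction is reported in
`delta`); a one-sided flag exists. One permutation stream is shared
across region sets (paired permutations), anchored to the alphabetical
order of the two labels so that swapping the groups flips `delta` and
leaves `p` unchanged.

## What the synthetic generators emulate

The generators produce the validation world the score is tested in; all
default sizes are package choices recorded in each output's metadata,
picked to resemble a desk-scale scATAC peak matrix.

* **Controlled series** (`gen_controlled_series`): 100 matrices,
  2000 features × 100 cells, density 0.5, constant total count. Matrix
  $i$ homogenizes $10i$ donor rows (emptied) and $10i$ recipient rows
  (saturated with the displaced 1's, spilling into extra rows when donors
  carry more 1's than recipients can absorb), drawn fresh per step.
  Constant rows contribute no cell-to-cell variation, so truth declines
  linearly, $t_i = (100 - i)/100$. The acceptance criterion is
  $|r| \ge 0.99$ between final scores and truth; observed ≈ 0.995.
  Note the raw similarity is mildly convex in the homogenized fraction
  ($\propto (2-h)/(2+h)$), so ≈ 0.995 rather than 1.0 is the expected
  ceiling of a linear correlation against the linear truth.
* **Perturbation series** (`gen_perturbation_series`): from a
  homogeneous base (identical cells), a fraction $f$ of 1's is removed,
  or an equal number of 0's is set — heterogeneity rises with $f$ while
  total count falls or rises. Monotonicity of the final score is
  asserted on a *joint* run of base + add + remove series: within a
  single 5-point one-directional series the raw-vs-count relation is
  convex and its OLS residuals are U-shaped, so no count-adjusted score
  can be monotone there; with both directions present the fitted slope
  is near zero and both branches order correctly.
* **Sparsity series** (`gen_sparsity_series`): 100 pure-noise matrices
  with density rising 0.05 → 0.5. Because the final score is an affine
  function of the regression residuals, its correlation with the total
  1-count is zero by construction — the test asserts $|r| < 0.2$.
* **Mixtures** (`gen_celltype_mixtures`): 5 archetypes with 500-feature
  marker blocks ($p_{on} = 0.6$ on own markers, $p_{off} = 0.05$
  elsewhere); all 31 subsets of 1–5 types are mixed at 100 cells each.
  The median score must rise strictly with the number of mixed types.
* **Depth series** (`gen_depth_series`): exact thinning (sampling reads
  without replacement) of a synthetic counts matrix to totals 50k–100k,
  then binarization; 6 depths × 5 subsample replicates of 100 of 500
  cells. Adjusted scores must be depth-free
  ($|\rho_{Spearman}| < 0.3$). This replaces an external read-level
  simulator and reproduces the depth gradient, not fragment-level
  realism (no fragment sizes, no TSS structure, no doublets).
* **CNA groups** (`gen_cna_groups`): 6 groups from one archetype over 13
  chromosomes × 150 features; the CNA group's target chromosome is
  zeroed (deletion) or doubled-capped (gain). The per-chromosome
  corrected score of the CNA group should sit within 2 SD of the other
  groups. With only 5 reference groups that gate has an inherent ~10%
  false-alarm rate under the null; the acceptance test runs at the
  package default seed.
* **Flip noise** (`gen_flip_noise`): independent symmetric bit flips,
  plumbing for technical-noise experiments. Two passes at rate $r$ are
  not one pass at $2r$ (flips cancel).

What a green suite does **not** establish: the generators contain no
fragment-level structure, no batch effects, no false-negative structure
correlated with biology, and no real peak geometry — conclusions about
real datasets still require the usual QC and the regression diagnostics
(`raw` vs `mean_count`).

## Companion metrics

`transcriptional_noise_cv()` computes per-gene coefficient of variation
($sd/mean$, sample convention, `NA` for zero-mean genes) from a
genes-by-cells matrix. `methylation_region_variability()` computes
per-CpG-site variance across samples (pairwise-available values, sample
convention), after removing sites whose missing fraction exceeds the
0.005 quantile of the per-site missingness distribution, and averages
variances over the sites inside each region set (site position in
half-open interval); optional min-max display scaling. For scoring
methylation-style binary matrices with missing entries,
`compute_epichaos()` exposes two policies: drop features missing in more
than 5% of cells and impute the remainder as 0 (default), or
pairwise-complete scoring with at least 20 co-observed features per pair
— there is no field-standard rule here, so both are explicit options.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `subsample_size` | 100 cells | replicate size; groups below it are scored once, whole |
| `n_subsamples` | 5 | replicates per large group |
| `min_features` | 20 | floor for region sets / chromosomes entering a run |
| `n_perm` | 1000 | permutations of the differential test |
| `na_drop_frac` | 0.05 | missingness threshold of the drop policy |
| `pairwise_min_obs` | 20 | co-observed floor of the pairwise policy |
| `seed` | 1 | the only source of randomness |

## Known limitations

Scores are relative within a run — comparing final scores across runs is
meaningless by design. Binarization discards quantitative accessibility
differences. The independence expectation assumes exchangeable features
within a pair; strong feature-feature dependence (e.g. CNA blocks) is
handled by stratification, not by the pair model. The permutation test
emits raw p-values; multiple-testing correction across region sets is
left to the caller.
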