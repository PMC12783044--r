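---
title: "Control-free scoring of repair-outcome spectra: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-free scoring of repair-outcome spectra: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrascreen)
```

## The problem

CRISPR perturbation screens with mutational-spectra readout knock out (or
silence) one gene per cell population and then sequence a common cut site
after repair. The readout per perturbed gene is a *mutational spectrum*: the
relative frequency of repair outcomes — deletions stratified by flanking
microhomology (0, 1, 2, 3+ bp, the footprint separating blunt end joining
from microhomology-mediated end joining), insertions, combined
deletion-insertions, and donor-templated insertions (homology-directed
repair, HDR). A gene whose loss redistributes these outcomes is a candidate
double-strand-break (DSB) repair factor.

In genome-wide designs there are usually no nontargeting control guides, so
the expected wild-type spectrum is unknown. This package forgoes controls by
treating the task as *outlier detection*: assuming most genes barely affect
repair outcomes, the centre of the distribution of all gene spectra stands in
for the wild type, genes are ranked by their (robust) distance from that
centre, and the most central genes are exported as *pseudo-controls* for
downstream comparative analyses.

## Why compositional analysis and a robust fit

A spectrum is a composition: seven non-negative frequencies summing to one.
Closure induces spurious negative correlation between parts, and Euclidean
operations on the simplex are biased. We therefore work in isometric
log-ratio (ILR) coordinates: `ilr(x) = V clr(x)`, where
`clr(x)_j = ln(x_j / g(x))` and `V` is an orthonormal (D−1)×D contrast
matrix. The package fixes `V` to the Gram–Schmidt sequential-binary-partition
basis, `ilr(x)_i = sqrt(i/(i+1)) ln(g(x_1..x_i)/x_{i+1})`, with the category
order `DEL_MH0, DEL_MH1, DEL_MH2, DEL_MH3P, INS, DELINS, HDR`. The exact
choice is immaterial for the scores — ILR is an isometry, so Mahalanobis
distances are provably basis-invariant (this is asserted in the test suite
to 1e−8) — but pinning one basis makes outputs bit-reproducible across
implementations.

The second bias is the outliers themselves: the genes we want to find inflate
a classical covariance and drag the mean toward themselves. The centre and
scatter in ILR space are therefore fitted with the minimum covariance
determinant (MCD): the h-subset of genes whose covariance has minimal
determinant, h = ⌊(n + p + 1)/2⌋ by default (the highest-breakdown choice;
`support_fraction` exposes it). The implementation is the conventional
FastMCD: 500 random (p+1)-point starts, two concentration steps each, the
ten best candidates iterated to convergence, chi-square consistency
correction of the raw subset covariance
(`median(d²)/qchisq(0.5, p)`), and one reweighting step keeping points with
`d² ≤ qchisq(0.975, p)`, with the trimmed-normal consistency factor so the
scatter is unbiased for Gaussian data. The subset search samples row indices,
so a seed is *mandatory*: identical seeds give identical fits, and permuting
the input rows perturbs distances only within the stochastic accuracy of the
search.

Each gene's score per target site is the robust Mahalanobis distance of its
ILR spectrum to the fitted centre. Distances from different cut sites are not
on a common scale (sequence context and coverage differ), so they are
unified: genes present in *all* targets form a reference set, each target's
distances are z-normalised by the reference mean and standard deviation (n−1
denominator), and the unified score is the mean of available z-scores with
missing targets ignored. Pseudo-controls are the n (default 60) genes with
the lowest unified score — selection uses the full-dimensional distance to
the centre, not proximity in a 2-D projection, which we consider the faithful
reading of "closest to the estimated centre"; a `per_target_common` mode
instead intersects the per-target bottom-n sets and may return fewer than n
genes. Boundary ties are broken by lexicographic gene id so runs are
reproducible.

## Preprocessing model

Filters run in a fixed order, per replicate:

| parameter | default | meaning |
|---|---|---|
| `min_total` | 700 reads | row (sgRNA × replicate) dropped when its 7-category sum is strictly below this |
| `min_guides` | 3 | genes need at least this many distinct surviving sgRNAs per (gene, target, replicate) |
| `min_median_r` | 0.6 | sgRNA dropped when the median pairwise Pearson correlation of its raw count profile, within-gene or cross-replicate, is strictly below this |
| `dl` | 1 read | zero cells imputed from Uniform(0.1·DL, DL) |

Choices that the thresholds alone do not determine:

* Correlations are computed on **raw counts**, not frequencies; both
  criteria are evaluated on the pre-removal table and removals applied
  jointly, so one bad guide cannot save another.
* The guide-count minimum is **re-checked after** the consistency filter:
  consistency removals can leave a gene with one or two guides, whose
  geometric-mean spectrum would be unstable. Both passes are logged
  separately in the filter report (`min_guides`, `min_guides_recheck`). The
  re-check can be disabled (`recheck_min_guides = FALSE`) to reproduce a
  single-pass protocol.
* A median over exactly two correlations is their mean; over one value, that
  value. A zero-variance (constant) profile has undefined correlation and is
  treated as failing the criterion — flagged in the report — rather than
  erroring the run.
* Imputation draws on the half-open interval [0.1·DL, DL) from the standard
  uniform generator; the boundary convention is a measure-zero detail,
  recorded here for reproducibility. Imputation never changes the row-key
  set, and every value is strictly positive afterwards, as the log-ratio
  transforms require.

Gene spectra are then aggregated by closure of each row's counts, a
componentwise geometric mean over the sgRNAs of each (gene, replicate,
target), and a geometric mean over replicates, with closure after every
step. The geometric mean is the natural centre in the Aitchison geometry and
commutes with closure, so raw counts and pre-closed frequencies give the
same spectrum.

## The diagnostic PCA

`pca_diagnostic()` isolates the contribution of the two design elements by
crossing {raw frequencies, ILR coordinates} × {classical, MCD covariance}
and eigendecomposing the fitted scatter (the plug-in notion of robust PCA —
no projection pursuit). Raw closed spectra have a singular covariance (the
unit-sum constraint), so the raw scenarios are fitted in an orthonormal
parametrization of the hyperplane and mapped back; ILR loadings and centre
are mapped to CLR space through the basis so components can be read against
mutation categories.

## The synthetic screen

`simulation_config()` encodes the validation conditions: 525 genes of which
25 are outliers, 5 guides per gene, 2 replicates, 3 target sites. Null genes
share a target-specific base composition (deletion-dominated, with moderate
insertion and HDR fractions that differ between cut sites, as repair spectra
do); each outlier gene is displaced by `effect_size = 1.5` along a uniformly
random direction on the ILR unit sphere — the same direction in every
target, as a genuine gene effect would be, and with directions covering
HDR-loss-like and insertion-gain-like effects without hand-tuning. Each
guide × replicate × target observation draws its spectrum from a Dirichlet
with precision `concentration = 200` around the gene's true composition, its
coverage from a log-normal with median 3000 reads and `sdlog = 1` (a heavy
tail chosen once as realistic for pooled screens: about 7% of rows fall
under the 700-read cutoff, exercising the filters), and its counts from a
multinomial; 1% of cells are zeroed to mimic drop-out.

What the simulator does **not** emulate: sequence-context-specific indel
distributions, guide-specific cutting efficiency, batch effects between
replicates, gene-essentiality drop-out, or correlated off-target effects.
Passing the end-to-end checks therefore shows that the statistical machinery
recovers compositional displacements under realistic noise and coverage; it
does not certify performance on any particular real screen.

Validation uses ten seeds at these conditions (about 4 s per seed on one
CPU): planted-outlier recall among the top 25 ranks and the AUPRC of the
outlier labels, against the prevalence (~0.048) a random ranking attains,
and the Jensen–Shannon distance (JSD) of the pseudo-control geometric mean
to the true base composition versus that of the all-gene geometric mean.

## Downstream statistics

* **JSD** uses base-2 logarithms, making the distance a metric bounded in
  [0, 1]; `base = exp(1)` switches to nats and is recorded by the caller.
* **Average precision** is the step-wise (non-interpolated) sum of
  precision at each gold-standard hit; the baseline is the gold prevalence,
  which a random ranking attains in expectation.
* **Enrichment** is the upper-tail hypergeometric test per term with
  Benjamini–Hochberg correction applied *within* each annotation set;
  terms without background members are skipped.
* **Group regression** fits `frequency ~ membership` per mutation category
  and target site on gene-level spectra (one sample per gene knockout, not
  per replicate); for a binary regressor the coefficient is exactly the
  case-minus-control mean frequency. Combinations with fewer than 3 case
  spectra are excluded; BH correction runs across the reported rows of one
  analysis.
* **Difference heatmaps** subtract the pseudo-control geometric mean per
  target and category; both axes are clustered with Ward linkage
  (`ward.D2`) on the correlation dissimilarity 1 − r, constant profiles
  placed at distance 1, missing blocks imputed as 0 for clustering only,
  and leaf order fixed by seriating each merge deterministically.

## Known limitations

* Distances rank genes; they are not calibrated p-values. Genes whose loss
  affects repair without shifting the seven-category spectrum will rank low.
* With fewer than ~30 genes per target the MCD fit is unstable
  (`fit_center_scatter()` refuses n ≤ 2p), and with heavy contamination
  (>50%) the central-majority assumption itself fails.
* The consistency filter assumes guides of a gene should agree; a gene with
  two genuinely distinct perturbation outcomes (e.g. domain-specific
  effects) can lose guides.
* Scores depend mildly on the MCD seed through the subset search; all
  entry points therefore require explicit seeds and record them.

```{r}
res <- run_pipeline(run_config(
  simulate = list(n_genes = 60, n_outliers = 3, n_targets = 2),
  seed = 7, n_pseudo_controls = 10))
head(res$scores[order(res$scores$rank),
                c("gene", "unified_score", "rank", "is_pseudo_control")])
```
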