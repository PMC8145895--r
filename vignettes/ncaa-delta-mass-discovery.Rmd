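---
title: "Delta-mass clustering and ncAA discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-mass clustering and ncAA discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncaadelta)
```

## The problem

A wildcard (open modification) database search assigns each MS/MS
spectrum a peptide while allowing an arbitrary mass shift on one
residue. The shift — the *delta mass*, observed residue mass minus the
genome-coded residue mass — is a fingerprint of whatever chemistry
altered that residue: a post-translational modification (PTM), an
artifactual adduct, or an amino-acid substitution. Residues carrying a
nonzero delta mass are *non-coded amino acids* (ncAAs). Given a table of
peptide-spectrum matches (PSMs) from such a search over two tissue
conditions (for instance ischemic versus control smooth muscle, three
animals each), the package answers three questions:

1. Which delta masses occur systematically? (clustering)
2. What chemistry could each one be? (annotation)
3. Which modified sites differ between conditions? (differential
   analysis)

## The model

### Filtering and bookkeeping

PSMs are kept when Score ≥ 300, DeltaModsScore ≥ 10, FDR2D ≤ 0.01 and
FDR_uniq2D ≤ 0.01, and a site is considered modified only when
|Δ| > 0.01 Da (strict), so essentially-zero shifts never enter the
analysis. Score bounds are inclusive and the delta bound strict; the
filter is idempotent. Deltas are rounded half-even to four decimals once,
at ingestion; for each rounded delta, `counts` is the total number of
observations and `freq` the number of distinct modified sites
(`protein@positionResidue` keys) carrying it.

### Clustering

Delta masses are partitioned into 1-Da windows
$[n - 0.5, n + 0.5)$, $n = -200, \dots, 1000$. The half-open upper edge
makes the windows a true partition (the choice at the boundary is
otherwise arbitrary, so it is fixed and documented). Within each window
the empirical delta-mass density is modeled as a univariate Gaussian
mixture

$$ f(x) = \sum_{k=1}^{K} \pi_k \,
   \mathcal{N}(x \mid \mu_k, \sigma_k^2), $$

fit by EM for $K = 1, \dots, K_{\max}$ (default 5) with $K$ selected by
BIC in the convention $\mathrm{BIC} = 2 \ln L - k \ln n$, larger values
indicating the stronger model. Observations are assigned to components
by maximum responsibility. Three constraints are then enforced:

* **half-width** — a peak's half width at half maximum,
  $\sigma\sqrt{2\ln 2}$, must exceed 1 ppm of a reference mass. "ppm of
  the delta" is degenerate near zero shift, so the reference defaults to
  a nominal 1000 Da precursor, i.e. a floor of 0.001 Da; both the ppm
  value and the reference are configurable.
* **separation** — adjacent peaks must be more than 2 peak widths
  (FWHM) apart. Components violating this are *merged* (pooled
  moments) rather than one being discarded: peaks this close are not
  distinct clusters, and discarding the smaller of an over-fitted split
  would truncate the survivor and bias its mean — measurably beyond the
  $4\sigma/\sqrt{n}$ recovery bound the package holds itself to.
* **size** — a cluster must contain at least `min_cluster_size`
  observations (default 20; applied as ≥ at both the window and the
  component level so a window of exactly the minimum size can still
  yield its cluster). Published cluster tables report condition-level
  counts as low as 3, so the default is deliberately configurable
  downward when the input is a pre-restricted subset.

Each surviving component is refit by *Gaussian regression*: member
deltas are histogrammed (bin width `max(0.0005, range/25)` Da) and bin
heights fit by Levenberg–Marquardt least squares to
$A\exp(-(x-\mu)^2/2\sigma^2)$, giving the reported peak value
(the clustered delta mass), SD, and $R^2 = 1 - SS_{res}/SS_{tot}$
over bin heights, clamped to $[0, 1]$. Degenerate inputs are flagged
rather than fitted: identical members give $\sigma = 0$ with undefined
$R^2$; fewer than 5 members or fewer than 3 non-empty bins refuse the
fit. A flat (uniform) window fits with $R^2 \approx 0$, which the
significance gate later rejects.

"Multivariate clustering" is implemented as 1-D mixture modeling per
window: the only continuous variable carried by a PSM site is its delta
mass. Residue identity is summarized per cluster post hoc as the residue
composition of its members, which the annotation stage consumes.

### Annotation

The bundled catalog holds twelve curated chemistries (methylation,
formylation, acetylation, dioxidation, carboxylation, carbon and
arginine adducts, aminoethylbenzene-sulfonylation, glutathione
disulfide, deamination/pyroglutamate, didehydrogenation, and H2S loss
converting cysteine to dehydroalanine) plus all 380 ordered amino-acid
substitutions computed from monoisotopic residue masses
(H 1.007825, C 12, N 14.003074, O 15.994915, S 31.972071 Da; constants
carried to ≥ 6 decimals so 4-decimal catalog values are exact). It
stands in for live queries of modification databases (UniMod, RESID,
ExPASy, ABRF); user catalogs in the same TSV dialect merge in.

A cluster matches a record when |peak − record mass| ≤ tolerance. The
default tolerance is 0.0025 Da: wide enough to admit the largest
annotation error observed at instrument-scale dispersion (≈ 0.0021 Da),
narrow enough to exclude next-nearest catalog masses in the bundled
cases. Matched clusters are accepted as true delta masses; unmatched
clusters are kept with confidence only when $R^2 > 0.5$ *or* more than
half their members sit on one residue (the rule's "and/or" is read as
inclusive OR); anything else is retained but marked rejected. Because
several chemistries are mass-identical (e.g. methylation versus any
+CH2 substitution), a *consistency* check asks whether the cluster's
dominant residue is a valid target of the matched record — a −33.9858 Da
cluster on cysteine is consistent with H2S loss but not with an F→L
substitution. For substitutions mass-compatible with a point mutation,
`snp_reachable()` reports whether one codon change suffices under the
standard genetic code, with a witness codon pair (V→I via GTT→ATT).

Display rounding is half-even at 4 decimals; boundary masses
(CH2 = 14.01565 Da) may print as 14.0156 or 14.0157 depending on
constant precision, so every comparison in code uses a ±0.0001 Da
tolerance and never string equality.

### Differential analysis

For each modified site within a cluster, per-sample spectral counts are
compared between conditions. The signed fold change with pseudocount
$c = 0.5$ is

$$ r = \begin{cases} (m_1 + c)/(m_0 + c) & m_1 \ge m_0 \\
   -(m_0 + c)/(m_1 + c) & \text{otherwise,} \end{cases} $$

so $|r| \ge 1$ always and $r < -2$ reads "more than 2-fold down". The
p-value is a two-tailed equal-variance Student t-test on the per-sample
counts (Welch by flag); a site is called when its parent cluster has
$R^2 > 0.5$, $|r| > 2$ and $p < 0.05$. No multiple-testing correction
is applied in the gate — with 3-vs-3 designs and a handful of sites the
published convention is raw p — but a Benjamini–Hochberg column is
emitted for information. Significant sites aggregate to per-direction
protein lists (a protein with both up and down sites appears in both),
exportable for external enrichment services.

Counts are compared raw by default. Library-size normalization
(`"total_psm"`, rescaled to the mean total so values stay on the count
scale, or `"median"`) is available but off: when regulation is
asymmetric, total-count scaling transfers the regulated sites' signal
into every other site's denominator — a composition bias that at desk
scale can push genuinely 4-fold sites below the 2-fold gate and drag
null sites past it. Per-site sample sizes are reported pooled and per
condition, since either convention appears in published site
annotations.

Known small-$n$ caveat: at 3 vs 3 the t-test is anti-conservative
relative to the exact permutation test, whose 20 arrangements bound any
permutation p below by 0.05. The two order sites the same way (rank
correlation near 0.9 in the test suite), but borderline p-values near the
0.05 gate should be read with that granularity in mind.

## The synthetic benchmark

`generate_psm_data()` plants ground truth with the structure the
analysis assumes, so every stage is testable without any data download:

* site deltas ~ Normal(true chemistry mass, `mass_error_sd`), default
  SD 0.002 Da — the dispersion scale at which published cluster-level
  annotation errors of 0.0012–0.0021 Da arise;
* per-sample counts ~ rounded lognormal with CV `count_noise`
  (default 0.2) — lognormal rather than Poisson so the within-group CV,
  which the t-test gate is sensitive to, is directly controllable;
* condition means scaled by the planted signed fold change;
* a `background_rate` fraction (default 5%) of uniform deltas over the
  full window range, stressing the constraint filters;
* a `fail_rate` fraction of rows violating one score filter each.

The default configuration plants the twelve curated chemistries at
3 sites × mean count 3 across 3 + 3 samples (≈ 50–150 observations per
chemistry), with four up (+4), four down (−4) and four unregulated
plantings — sample sizes chosen so the full suite and the recovery
benchmark run in seconds on one CPU while every cluster clears the
size-20 constraint. `score_recovery()` scores cluster recall and
precision at 0.005 Da, peak-mass RMSE, direction sensitivity on
regulated sites and the false-call rate on unregulated ones.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify on real data: correlated site occupancy within
a protein, retention-time or charge-state structure, heavy-tailed mass
errors from co-eluting species, shared peptides mapping one spectrum to
several proteins, and count overdispersion beyond the lognormal. The
benchmark validates the statistical machinery, not instrument realism.

## Numerical and design choices

* Mixture fitting delegates to `mclust` (model-based EM with
  deterministic hierarchical initialization); observations are sorted
  before fitting so results are invariant to input row order, and the
  recorded seed is provenance, not an algorithmic input. `mclust`'s BIC
  sign convention (larger is better) is the one the workflow specifies.
* Gaussian regression uses `minpack.lm` Levenberg–Marquardt with
  moment-based starts; a failed fit flags the cluster `unfit` instead
  of aborting the window.
* Catalog ties at identical mass are ordered PTM < substitution <
  adduct < loss, then by name; errors are rounded to 9 decimals before
  ordering so records identical in exact arithmetic genuinely tie
  instead of being separated by float noise.
* Degenerate t-tests: both groups constant and equal gives p = 1;
  constant and unequal gives p = 0, flagged.
* The windows table covers [−200.5, 1000.5); out-of-range deltas are
  excluded with a message, never silently.
* All output tables are TSV with a provenance footer (config hash,
  seed); re-running an identical configuration reproduces identical
  bytes.

## A worked example

```{r example}
gen <- generate_psm_data(synthetic_config(seed = 1))
obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
cl <- cluster_deltas(obs, seed = 1)
summary(cl)

ann <- annotate_clusters(cl)
head(ann[c("delta_mass", "best_match", "error", "freq", "counts")])

sites <- call_significance(obs, cl)
table(sites$direction)

score_recovery(cl, gen, sites)[c("cluster_recall", "mass_rmse",
                                 "sensitivity", "false_call_rate")]
```

## Limitations

* The pipeline begins at the PSM table: the wildcard search itself,
  raw spectra, and retention-time information are out of scope.
* Enrichment and network analysis of the resulting protein lists is
  delegated to external services; the package only exports the lists.
* One cluster per (site, window): a site genuinely carrying two
  chemistries in the same 1-Da window at overlapping masses will be
  merged by the separation constraint.
* The codon-reachability check is combinatorial only; it does not
  align genomic or cDNA reads to confirm that a mass-compatible
  substitution is in fact genomic.
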