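---
title: "circmeth: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circmeth: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmeth)
```

This vignette documents the statistical models behind each stage of the
pipeline, what the synthetic-data generator does and does not emulate, the
numerical choices that were genuinely open, and the known limitations. It
states no empirical result that the test suite does not itself compute.

## 1. Differential expression of count layers

Counts $y_{ij}$ (feature $i$, sample $j$) are modelled as negative binomial
with mean $\mu_{ij} = s_j \exp(\beta_0 + \beta_1 x_j)$ and variance
$\mu + \alpha\mu^2$, where $x_j$ indicates tumor and $s_j$ is a sample size
factor. The stages are:

* **Size factors** (`size_factors()`): median across all-positive features
  of $y_{ij}/(\prod_j y_{ij})^{1/n}$, rescaled to geometric mean 1. If no
  feature is positive everywhere (common for sparse BSJ matrices) an
  explicit `pseudo_reference = TRUE` fallback uses geometric means over the
  positive entries of features observed in at least half the samples.
* **Dispersion** (`estimate_dispersion()`): per-feature method-of-moments
  $\hat\alpha = \max(0, (v - m)/m^2)$ from the within-group pooled variance,
  shrunk toward a fitted trend $\alpha(\mu) = a_0 + a_1/\mu$ with prior
  weight 8 (chosen once; the weight trades stability for bias and the null
  calibration test would flag a bad choice). Using within-group rather than
  overall variance keeps planted effects from inflating $\hat\alpha$.
* **Wald test** (`nb_wald_test()`): per-feature IRLS for the two-parameter
  GLM, vectorized across features; the closed-form normal equations for a
  binary covariate give $\mathrm{Var}(\hat\beta_1) = 1/\sum_T w +
  1/\sum_N w$ with $w = \mu/(1+\alpha\mu)$. Two-sided normal p-values;
  $\log_2\mathrm{FC} = \hat\beta_1/\ln 2$. Effects are capped at
  $|\hat\beta_1| \le 15$ so one-group-all-zero features converge with
  correspondingly enormous standard errors.
* **Calling**: genes and miRNAs at adjusted $p < 0.05$ and
  $|\log_2 FC| > 1$. circRNAs at adjusted $p < 0.05$ plus junction support.
  The published support rule ("junction read counts >= 2") does not say per
  sample or in total; this package reads it as *BSJ count >= 2 in at least
  2 samples*, consistent with the companion filter "identified in at least
  two samples", and keeps both numbers configurable. No fold-change cutoff
  is applied to circRNAs, following the published cutoffs literally.
* **Multiple testing**: Benjamini–Hochberg (`bh_adjust()`), the convention
  most likely behind an unspecified "adjusted p-value" from count-based DE
  tools.

Deliberately omitted relative to full-featured DE packages: LFC shrinkage,
outlier (Cook's distance) filtering, and independent filtering. These affect
power, not the contracts tested here; the calibration and sensitivity tests
bound the consequences.

The design is treated as unpaired two-group even though samples are paired;
the source analyses do not state that pairing was modelled, and the unpaired
test is the conservative default. A paired analysis can be emulated by
passing per-pair differences to the moderated-t machinery.

## 2. Differential methylation

Beta-values are transformed to M-values, $M = \log_2\!\big(\beta/(1-\beta)\big)$,
after clamping $\beta$ into $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ (the sources are silent on boundary handling; the
clamp only matters for exact 0/1 which the generator never emits).
`moderated_t()` fits the standard empirical-Bayes variance model: per-probe
pooled variances $s^2$ with $d$ degrees of freedom are treated as scaled-F
around a prior $(d_0, s_0^2)$ estimated by moment matching on $\log s^2$
(digamma mean equation, trigamma-inverse variance equation). The posterior
variance $(d_0 s_0^2 + d s^2)/(d_0 + d)$ yields a t-statistic on $d_0 + d$
degrees of freedom. Two edge cases are handled explicitly:

* if the spread of $\log s^2$ is no larger than the $\chi^2_d$ sampling
  spread, the prior degrees of freedom are infinite and $s_0^2$ is the
  geometric mean of the $s^2$ — so equal per-probe variances pass through
  unchanged;
* a non-convergent trigamma solve falls back to $d_0 = \infty$ with a
  warning.

$\Delta M$ is the unpaired difference of group means (the unpaired default
of the reference implementation; a paired estimator was considered and left
out for symmetry with the DE layer). Calls: hyper iff $\Delta M > 0.5$ and
adjusted $p < 0.05$; hypo for the mirrored condition. The test suite checks
agreement of the whole fit (prior, t, p) with the independent reference
implementation on shared data.

## 3. circRNA-relative regions

Each circRNA contributes three disjoint intervals: Interior = its span,
Pre2000 = the 2 kb immediately upstream of the back-splice site, After2000 =
the 2 kb immediately downstream. "Upstream" is read as the strand-aware 5'
flank, so the minus strand mirrors the two flanks; because the published
definition is ambiguous on this point, `convention = "genomic-left"`
reproduces the strand-naive reading. Coordinates are 1-based inclusive
internally (matching "chr:start-end" identifiers); BED I/O converts to
0-based half-open and the conversion is tested in both directions. Flanks
clamp at position 1 and, when chromosome sizes are supplied, at the
chromosome end; whether the original analysis clamped at chromosome or gene
boundaries is unstated, and chromosome bounds were chosen as the only
universally defined option. Probe mapping reports *every* containing
(feature, region) pair — a probe may serve several circRNAs and several
region types — and is checked against a per-base brute-force oracle.

## 4. Integration

The decoupling filter selects exactly the circRNAs with (i) a non-"ns" DE
call, (ii) at least one called DM probe in any of their three regions, and
(iii) a parental gene whose DE call is "ns"; intergenic circRNAs are
excluded for lack of a parental gene. Correlation between methylation and
expression uses tie-aware Spearman rank correlation of the probe M-values
against size-factor-normalized $\log_2(\text{BSJ}+1)$ expression across all
samples jointly (tumor + normal — the span over which the published
correlations were computed); p-values come from the t-approximation for
$n \ge 10$ and full permutation enumeration below that. Raw $p < 0.05$ is
the significance rule, mirroring the published analysis; a BH flag exists
but is off by default. Region summaries are reported both as site counts
(per (circRNA, probe) assignment) and as circRNA counts per region, because
the published tabulation mixes the two conventions; the package resolves
nothing, it reports both.

## 5. ceRNA network

Seed matching follows the canonical site hierarchy (8mer, 7mer-m8, 7mer-A1,
6mer) on Watson–Crick complementarity of miRNA positions 2–7/2–8 with the
t1-A convention. The duplex score is a deliberately simplified miRanda-style
affine-gap alignment (match +5, G:U +2, mismatch −3, gap open −9 / extend
−4, seed positions weighted ×4) and the energy proxy sums
nearest-neighbor-style stack terms (G:C 1.6, A:U 0.9, G:U 0.4 per pair,
+4.1 initiation). The published thresholds — score > 140 and energy < −20 —
are kept meaningful under this scheme: a perfect 22-nt duplex scores 215 and
reaches roughly −50, while a seed-only match cannot exceed 140 or fall below
−20, so the thresholds enforce "seed plus substantial 3' pairing", which is
their role in the original pipelines. Numeric equivalence to miRanda is
explicitly *not* the contract. Whether the original study required both
prediction pipelines to agree or either is unstated; the default is the
intersection (`require = "both"`) with a union flag.

Network assembly keeps only direction-consistent triples — (up circRNA,
down miRNA, up mRNA) and the mirror image — with circRNA–miRNA edges from
predictions and miRNA–mRNA edges from the validated-interaction table,
restricted to miRNAs anchored to at least one circRNA; isolated nodes are
dropped. The tripartite opposite-direction invariant is asserted on fuzzed
inputs.

## 6. Classification harness

The evaluation contract is the protocol, not any particular learner:
stratified k-fold assignment (deterministic per seed, class counts within
±1 per fold), rank-based AUC with half-credit ties, and per-fold scoring by
a pluggable `fit`/`score` object. Two reference classifiers ship with the
package (nearest centroid and k-NN); the six specific algorithms used in the
original study are off-the-shelf and intentionally out of scope. By default
the feature list (which DE circRNAs) is supplied from outside the folds;
this leaks the feature-selection step, exactly as near-1.0 published AUCs
suggest was done, and nested selection is left to the caller.

## 7. What the simulator emulates — and what it does not

`sim_config()` defaults describe the stated world: 20 tumor/normal pairs;
NB counts with dispersion 0.1 and planted $|\log_2 FC| = 2$ in 10% of the
features of each layer; planted $|\Delta M| = 1$ with M-scale SD 0.5;
copula correlation 0.8 for coupled circRNA/probe pairs; origin proportions
0.90/0.04/0.06 (exonic/intronic/intergenic, matching the reported >90%
exonic share of DE circRNAs with 4% intronic and 6% intergenic). Values the
sources do not state were fixed once at what a sequencing study of this
size plausibly looks like, and are free parameters, not estimates:

* baseline means are log-normal with medians ≈ 100 (genes), 15 (BSJ
  counts — low, as junction-spanning coverage is), 200 (miRNAs);
* size factors are log-uniform on [0.5, 2] to exercise normalization;
* null probes draw Beta values around a bimodal baseline with concentration
  30; planted probes are generated on the Gaussian M scale and mapped back
  through the inverse logit, which guarantees $\beta \in (0,1)$;
* among DE circRNAs with a parental gene, classes are assigned
  coupled/decoupled/opposite with proportions 0.4/0.4/0.2 (`class_props`).
  The study gives absolute counts, not rates, for these groups; the split
  was chosen to give each downstream path enough members at 300 circRNAs,
  and a gene parenting several DE circRNAs is constrained once so the
  manifest can never contradict itself (this also makes the decoupled and
  opposite sets disjoint by construction);
* each planted decoupled circRNA is guaranteed one DM probe in its regions
  (region drawn 0.1/0.8/0.1 across Pre2000/Interior/After2000, matching the
  observed predominance of interior sites; hypermethylation probability
  0.8) and is copula-coupled to it, so ground-truth recovery is a fair test
  of the integration stages rather than of probe placement luck;
* DE circRNAs get 1–3 full-complement binding sites for opposite-direction
  DE miRNAs embedded in their synthetic sequences, and the validated target
  table is biased 30% toward DE genes, so the ceRNA stage has admissible
  triples to find.

Randomness is split into one stream per layer, derived deterministically
from the master seed, so changing the probe count never perturbs the count
matrices; identical configurations produce byte-identical bundles on disk.

What the generator does **not** emulate: read-level data (alignment,
BSJ-calling and quantification noise enter only through NB dispersion),
sequence-realistic genomes (circRNA "sequences" are random RNA with planted
sites), batch effects, Infinium probe-type chemistry, SNP/cross-reactive
probe artifacts, and survival outcomes. A green end-to-end test therefore
establishes that the *statistical and integration logic* recovers planted
truth under the stated noise model — not that the upstream read-processing
of a real study is reproduced.

## 8. Numerical choices and degenerate inputs

* $\beta$ clamp $10^{-6}$; IRLS convergence $10^{-10}$ on coefficients,
  linear predictor capped at 30 to keep $\exp$ finite; effect cap
  $|\beta_1| \le 15$ for separated features.
* All-zero count features and zero-variance probes are flagged and excluded
  from testing with $p = 1$ rather than propagating NaN.
* Fisher's exact two-sided p sums hypergeometric probabilities at most
  $(1 + 10^{-7})$ times the observed table's probability — the standard
  tie-tolerant rule.
* Spearman with a constant vector is undefined and returns NA with a
  warning instead of a spurious 0.
* BH adjustment enforces monotonicity by the cumulative-minimum form and
  propagates NA p-values (excluded features) without affecting the rest.
* Empty networks, empty DM sets and empty decoupled sets flow through every
  summary as empty-but-typed objects; the vacuous-threshold pipeline test
  exercises this path end to end.

## 9. Known limitations

* The NB Wald test is anti-conservative in principle when dispersions are
  noisy; the trend shrinkage keeps the null type-I rate inside
  [0.035, 0.065] at the tested design (n = 20/20), but very small designs
  deserve a t-reference or exact test the package does not provide.
* The decoupling filter is a hard threshold chain; features near the
  calling boundaries flip sets under resampling, which is why recovery
  criteria are rates over seeds, not set equality.
* The duplex energy proxy is not a thermodynamic free energy; it ranks
  extended complementarity sensibly but must not be compared with RNA
  folding outputs.
* GO/KEGG term databases, external tissue-expression lookups and survival
  analyses are out of scope; the ORA function takes arbitrary user-supplied
  gene sets.
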