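---
title: "Methods: biclustering-based phenotype discovery for knee osteoarthritis cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biclustering-based phenotype discovery for knee osteoarthritis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeclust)
```

## The problem

Knee osteoarthritis (OA) is a syndrome, not a single disease: similar
symptoms arise from different causes, and pooling all knees in one analysis
masks subgroups that progress differently or would respond differently to
treatment. kneeclust implements an unsupervised phenotype-discovery pipeline
for cohort data in which each knee is the experimental unit: a baseline
matrix of mixed-type clinical features is searched for *biclusters* —
subsets of knees that are coherent across a subset of features — and the
candidate phenotypes are then characterized by their longitudinal outcomes
(radiographic progression, arthroplasty, joint-space-width loss, and pain
trajectories).

Biclustering rather than ordinary clustering is the point: many clinical
variables are informative for one phenotype and noise for another, so
clustering knees on *all* features dilutes every phenotype, while discarding
variables globally throws away exactly the information some other phenotype
needs.

## Baseline matrix preparation

`encode_features()` and `standardize_matrix()` turn a raw table into the
numeric matrix the search consumes:

* unordered categorical features become one 0/1 indicator per level;
* ordered categorical features become integer codes 1, 2, 3, ... ;
* continuous features with |skewness| > 0.5 are passed through a sign-aware
  shifted-log family \(t(x) = s\,\log(s(x-a)+c)\), with \(s \in \{+1,-1\}\)
  and \((a, c)\) chosen from a fixed grid to minimize |sample skewness|
  (identity kept when nothing improves it). Every candidate is monotone, so
  ranks are never changed, and all parameters are logged for exact
  inversion;
* continuous features and ordinal codes are centered and scaled to mean 0,
  sd 1 (sample sd, \(n-1\)); indicator and binary columns stay on their 0/1
  scale. Standardizing ordinal codes is a package decision (they enter the
  same residue computation as continuous features) and can be switched off;
* knees with any missing cell are removed (`drop_incomplete_rows()`) — the
  residue computation needs a complete matrix and no imputation is
  attempted. The removal report names each dropped knee and its offending
  columns.

The transformation objective uses skewness only. Kurtosis and outlier
diagnostics are worth inspecting when preparing real data, but a
single-number objective keeps the automatic step reproducible and easy to
reason about.

## Cheng–Church biclustering

The quality of a bicluster \((I, J)\) is its **mean squared residue**

\[
H(I,J) = \frac{1}{|I||J|}\sum_{i \in I, j \in J}
  (a_{ij} - a_{iJ} - a_{Ij} + a_{IJ})^2 ,
\]

the average squared departure from an additive row + column model; a
perfectly additive block has \(H = 0\). The search is the classical greedy
sequence, applied unmodified:

1. **multiple node deletion** (`alpha = 1.2`, applied only while a dimension
   exceeds 100) removes in one pass every row/column whose mean residue
   score exceeds \(\alpha H\);
2. **single node deletion** removes the single worst row or column until
   \(H \le \delta\) (ties: rows before columns, then lowest index — fixed
   for determinism);
3. **node addition** grows the bicluster back: every column, then row,
   whose score does not exceed the current \(H\) is added, repeating until
   stable. A numerical slack of 1e-12 is used in the comparison so that
   exactly-additive rows are re-admitted at \(H = 0\). Inverse-row addition
   (sign-flipped rows) exists behind a flag but is off: clinical features
   have directional meaning and mirror-image patients are not pooled by
   default.

`find_exclusive_biclusters()` repeats the search, removing each accepted
bicluster's *rows* from the candidate pool (mutually exclusive knees) while
leaving all *columns* available (feature sets may overlap). Extraction stops
at `max_k` (default 6), when fewer than `min_rows` rows remain, or when the
search cannot reach the threshold. The exclusivity device — removing rows
rather than masking cells with random values — is deliberate: masking does
not guarantee disjoint knee sets, and disjointness is the property the
phenotype interpretation needs.

The default threshold is \(\delta = 0.2\), against a ceiling `msr_max` equal
to the whole matrix's residue (the "one big bicluster" value); `delta`
outside \((0, \mathrm{msr\_max})\) is rejected with the ceiling reported.
Each bicluster also reports a two-way-ANOVA \(R^2 = 1 - SSE/SST\) computed
on its own submatrix (\(SSE = |I||J| H\)), the more interpretable fit
measure. Whether that \(R^2\) should instead be computed against the full
matrix is ambiguous in general; the submatrix convention is used and
documented here.

## Statistical validation: SigClust on bicluster pairs

Greedy searches find "biclusters" even in pure noise, so candidate pairs are
tested against a null of *unclustered* data. For a pair of biclusters the
pooled knees (all prepared features, not the biclusters' own feature
subsets) give an observed **cluster index**

\[
CI = \frac{\sum_k \sum_{i \in k} \lVert x_i - \bar x_k \rVert^2}
          {\sum_i \lVert x_i - \bar x \rVert^2},
\]

low for tight, separated groups. The null is a single Gaussian whose
axis-aligned variances are the sample-covariance eigenvalues hard-thresholded
from below at a robust background variance
\((\mathrm{MAD}(\text{centered cells})/0.6745)^2\) (padded at the floor when
features outnumber observations). `simulate_null_ci()` draws datasets from
that Gaussian, splits each by 2-means (10 restarts), and records the CI; the
z-score \((CI_{obs} - \overline{CI}_{null})/sd(CI_{null})\) is reported with
one-sided normal and empirical p-values, and a pair is flagged
"significantly different" when \(z < -2\) (one-sided normal \(p < 0.023\)).

Package decisions, all switchable:

* the observed CI uses the *given* bicluster labels — the hypothesis under
  test is the separation of the biclusters as found, not of a fresh 2-means
  split (`use_given_labels = FALSE` restores the classical formulation);
* the null covariance is estimated from the pooled pair data, not the whole
  cohort;
* hard eigenvalue thresholding follows the original procedure; soft
  variants exist in the literature but are out of scope;
* no multiplicity correction by default, matching exploratory use across
  the \(K(K-1)/2\) pairs (`bonferroni = TRUE` adjusts the flag).

Hard thresholding makes the test **conservative** under the null: inflating
the small eigenvalues makes the simulated null data slightly easier to
split than the observed data, so null z-scores center above 0 and the
\(z < -2\) rate sits below its nominal 2.3%. The calibration test asserts
the rate is *compatible* with 2.3% within Monte-Carlo error; users should
read borderline z-scores near −2 as conservative, not anti-conservative.

`mean_difference_projection()` provides the visualization plane for each
pair: axis 1 is the unit vector between the two cluster means, axis 2 the
first principal component after projecting axis 1 out, so the panel shows
exactly the separation the test scored.

## Pain trajectories: a group-based trajectory model

Change-from-baseline pain scores at months 12–96 (month 0 is identically 0
and excluded from the likelihood) follow a finite mixture of polynomial mean
trajectories:

\[
f(y_i) = \sum_{g=1}^G \pi_g \prod_{t \in obs_i}
   \phi\!\left(\frac{y_{it} - P_g(u_t)}{\sigma}\right)\big/\sigma
   \;\times\; L^{drop}_{ig},
\]

with \(u = \text{month}/96\) (coefficients \(O(1)\) for conditioning; the
per-month scale is reported by `tidy()`), polynomial orders at most 3, and a
shared residual sd \(\sigma\) (per-group \(\sigma\) behind a flag; shared is
the common default in this model family). The **dropout extension**
\(L^{drop}\) is a per-group logistic model for the probability that
observation ends at a visit, with intercept and the previous observed
response as covariates — the simplest informative-attrition form; once a
knee is missing it stays missing (monotone dropout). The response is plain
normal, not censored: change scores are unbounded in this formulation, and
no censoring bounds are assumed (a censored variant is a documented
non-feature rather than a silent default).

Fitting is EM (tolerance 1e-6 on the log-likelihood, at most 500
iterations), best of 10 seeded random starts (short runs, best continued);
the log-likelihood is asserted non-decreasing in debug mode.
`select_model()` fits \(G = 1..G_{max}\) starting from cubic means and
repeatedly removes the highest-order coefficient whose Wald test (from the
weighted-least-squares information at the EM solution) has \(p > 0.05\),
refitting warm-started from the current posterior; the BIC-best model is
returned with the whole path logged. BIC is \(-2\ell + k\log n_{knees}\),
minimized — stated explicitly because some software reports the same
quantity with the opposite sign.

`posterior_assign()` gives each knee its posterior group probabilities,
assigns by the maximum (ties to the lowest group id), and flags assignments
with maximum posterior \(\ge 0.8\) as good fits; only good-fit knees enter
the trajectory-by-bicluster composition plots. `group_proportion_ci()`
reports normal-approximation intervals for the mixing proportions from the
empirical observed information of the multinomial-logit weights, delta-method
mapped back to probabilities and clamped to [0, 1].

## Longitudinal outcomes

`classify_roa_outcome()` assigns the coded radiographic outcome: baseline
KLG 0–1 knees are level 1/2/3 (no follow-up, no incident radiographic OA,
incident OA = any follow-up KLG ≥ 2); baseline KLG ≥ 2 knees are level
4/5/6 (no follow-up, no progression, any increase over baseline); baseline
arthroplasty is 7; absent baseline KLG is 999. A knee with follow-up
readings but no baseline cannot be classified as incident or progressive
and is also coded 999.

`qjsw_percent_loss()` regresses quantitative joint space width (mm) on
month by ordinary least squares and reports
\(100(\hat f(0) - \hat f(96))/\hat f(0)\). Fits losing more than 100% are
truncated to 100; fitted *gains* beyond 40% (medial) / 50% (lateral) are
capped at the threshold. Capping rather than excluding gains is a package
decision (the alternative reading of the rule); `mode = "exclude"` drops
them instead, and truncation counts are reported either way so cohort
bookkeeping can be checked. Knees with an arthroplasty during follow-up
contribute their visits as recorded; no censoring is applied to the
regression. Quartiles in all summaries use linear interpolation (type 7),
stated for exactness.

## The synthetic cohort: what it emulates, and what it does not

`synthetic_spec()` defines the ground-truth cohort every stage is validated
against. Its defaults are the package's benchmark conditions:

* **Baseline matrix** — 300 knees × 40 continuous features. Three
  row-disjoint planted phenotypes of 96 knees each span *all* features;
  12 knees belong to none. Per feature, the three phenotype levels are a
  random permutation of (−0.85, 0, +0.85); phenotype means add a mild
  overall severity shift (0.3, −0.3, 0), within-phenotype row effects have
  sd 0.3, and within-block noise sd is 0.2. Background knees are iid
  standard normal.
* **Pain panel** — a four-group mixture (improvement / stable / worsening /
  up-down, proportions 0.112 / 0.765 / 0.090 / 0.033) of polynomials on
  \(u = \text{month}/96\), residual sd 2 (a realistic score-scale spread),
  monotone dropout with per-visit hazard 0.03 through month 48 and 0.10
  after.
* **Outcomes** — per-visit KLG with non-decreasing progression whose
  per-visit probability depends on phenotype membership, arthroplasty
  probabilities by membership (0.03–0.16), and qJSW series
  baseline + slope·month + noise with membership-dependent slopes.

Two design points deserve explanation. First, planted phenotypes span all
features and are distinguished by their column *profiles* rather than by a
feature island with a large mean shift. This mirrors observed clinical
biclusters — in cohort analyses of this kind each bicluster retains most of
the feature set, feature sets overlap heavily, and groups differ by
characteristic high/low patterns across shared features — and it matters
algorithmically: the residue is invariant to row-wise shifts, so a block
distinguished only by a mean offset looks, to the search, like background,
while a narrow disjoint feature island actively penalizes its own rows on
all other columns during deletion. Exploration of that island design showed
it is essentially unrecoverable by the unmodified greedy search at
\(\delta = 0.2\); the profile design is both more faithful to the data the
method is used on and recoverable. Second, the permutation construction
keeps every feature's variance equal across the cohort, so per-column
standardization preserves within-phenotype additivity exactly — the planted
truth survives preparation, which is what makes row-level recovery
measurable.

What passing the synthetic benchmark does **not** show: robustness to
intermittent (non-monotone) missingness, to instrument-specific marginal
distributions, to phenotypes of very unequal size, or to the mixed
continuous/ordinal/binary composition of a real clinical table (mixed kinds
are generated and tested mechanically, but the recovery benchmark is
all-continuous). Real-data use should treat the benchmark as a correctness
check of the machinery, not as evidence about any particular cohort.

Problem sizes in the validation suite (300×40 matrices, 20-seed recovery
runs, 200 calibration replicates with 200 null simulations each, n = 500
panels) were chosen so the whole suite documents the method at meaningful
power while remaining quick to run routinely.

## Pipeline and reproducibility

`run_pipeline()` executes prepare → bicluster → validate → trajectories →
outcomes from one `pipeline_config()`, writing every intermediate artifact
as CSV/JSON together with a manifest (configuration echo with all defaults
filled, seeds, artifact MD5 hashes, stage timings). All randomness derives
from the single config seed through fixed per-stage offsets, so an
identical configuration reproduces bit-identical artifacts; the test suite
asserts this. `render_reports()` emits the standard figure set — bicluster
heatmap, standardized-feature boxplots, binary-feature barplots, per-pair
mean-difference scatterplots, outcome and arthroplasty bars, qJSW loss
boxplots, trajectory curves and assignment bars — each with a CSV twin
written from the same tibble the figure is drawn from.

## Known limitations

* The greedy search is order-dependent and has no optimality guarantee;
  recovered biclusters can split or absorb a few foreign rows near the
  threshold. The exclusive-extraction stopping rule (`max_k`, `min_rows`)
  is a configuration choice, not an inferred quantity.
* SigClust's hard-thresholded null makes the pair test conservative;
  power at small separations is correspondingly reduced.
* The trajectory model assumes a shared residual sd and polynomial means of
  order ≤ 3; the dropout model conditions only on the previous observed
  response.
* The qJSW regression uses all recorded visits; no within-knee censoring at
  arthroplasty.
* Mixing-proportion intervals use the empirical observed information, which
  can be optimistic for very small groups.
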