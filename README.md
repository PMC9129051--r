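# kneeclust

Phenotype discovery for knee osteoarthritis (OA) cohort data. Knee OA is a
syndrome: knees with similar symptoms progress for different reasons, and
analyses that pool all knees blur the subgroups that matter for prognosis
and trial design. kneeclust finds candidate phenotypes in a baseline
clinical feature matrix by **biclustering** — clustering knees and features
simultaneously, so each phenotype is defined only by the features that are
informative for it — then tests whether the candidates are statistically
distinct, and characterizes them by longitudinal outcomes over 96 months of
follow-up.

The pipeline has five stages, each usable on its own:

1. **Preparation** (`encode_features()`, `standardize_matrix()`,
   `drop_incomplete_rows()`): indicator-encodes nominal features, integer
   codes ordinal features, reduces skewness of continuous features with a
   monotone shifted-log transform `t(x) = s·log(s(x − a) + c)`, standardizes
   to mean 0 / sd 1 (binary features stay 0/1), and removes incomplete
   knees.
2. **Biclustering** (`find_exclusive_biclusters()`): the Cheng–Church
   procedure, unmodified. A bicluster (I, J) is scored by its mean squared
   residue `H(I,J) = mean over (i,j) of (a_ij − a_iJ − a_Ij + a_IJ)²`
   (0 for a perfectly additive block); greedy node deletion shrinks the
   matrix until `H ≤ δ` (default δ = 0.2) and node addition grows it back.
   Accepted biclusters have mutually exclusive knees; feature sets may
   overlap. Each bicluster also reports a two-way-ANOVA R².
3. **Validation** (`pairwise_sigclust()`): SigClust on every bicluster
   pair. The observed cluster index (within-pair over total variation) is
   compared with its distribution under a single-Gaussian null fitted by
   robust eigenvalue thresholding; a pair is significantly different when
   the z-score is below −2 (one-sided normal p < 0.023).
4. **Pain trajectories** (`fit_gbtm()`, `select_model()`,
   `posterior_assign()`): group-based trajectory modeling of
   change-from-baseline pain — an EM-fitted finite mixture of polynomial
   mean trajectories with a logistic dropout extension, group number chosen
   by BIC, trajectory shapes by the significance of polynomial terms, and
   knees assigned by maximum posterior (≥ 0.8 flags a good fit).
5. **Outcomes** (`classify_roa_outcome()`, `qjsw_percent_loss()`,
   `crosstab_bicluster_outcomes()`): coded radiographic progression levels
   (incident vs progressive OA by Kellgren–Lawrence grade), arthroplasty,
   and percentage loss of quantitative joint space width from a per-knee
   linear regression (truncated at 100% loss and at 40%/50% medial/lateral
   gain), summarized per bicluster.

A seeded synthetic-cohort generator (`synthetic_spec()`,
`generate_clinical_matrix()`, `generate_longitudinal_panel()`,
`generate_outcomes()`, `write_fixture_bundle()`) plants ground-truth
phenotypes, a known trajectory mixture and linked progression outcomes, so
every stage is validated against known truth. `run_pipeline()` executes
everything from one config with bit-reproducible artifacts.

## Worked example

Simulate the benchmark cohort (300 knees × 40 features, three planted
phenotypes of 96 knees), prepare it, and extract biclusters:

```r
library(kneeclust)

spec     <- synthetic_spec(seed = 42)
sim      <- generate_clinical_matrix(spec)
prepared <- standardize_matrix(
  encode_features(sim$data, spec_feature_metadata(spec))
)
bset <- find_exclusive_biclusters(prepared$values, delta = 0.2, max_k = 6)
bset
#> <bicluster_set> 6 bicluster(s), 0 unassigned of 300 rows (delta 0.2, msr_max 0.797)
#>   #1: 87 rows x 40 cols, MSR 0.0653, R2 0.928
#>   #2: 84 rows x 40 cols, MSR 0.0645, R2 0.911
#>   #3: 96 rows x 40 cols, MSR 0.0673, R2 0.937
#>   #4: 22 rows x 22 cols, MSR 0.1925, R2 0.587
#>   #5: 7 rows x 9 cols, MSR 0.1734, R2 0.609
#>   #6: 4 rows x 12 cols, MSR 0.1963, R2 0.685
```

The three planted phenotypes surface as the three large biclusters (every
accepted bicluster satisfies MSR ≤ 0.2; R² is the share of submatrix
variance the additive row + column model explains). Pairwise SigClust
separates exactly the planted structure:

```r
sig <- pairwise_sigclust(prepared, bset, n_sim = 200, seed = 42)
dplyr::arrange(sig, z)[1:4, c("bicluster_a", "bicluster_b", "ci", "z", "significant")]
#>   bicluster_a bicluster_b    ci     z significant
#> 1           2           3 0.259 -32.1 TRUE
#> 2           1           3 0.269 -29.5 TRUE
#> 3           1           2 0.270 -27.4 TRUE
#> 4           3           4 0.555 -12.7 TRUE
```

A cluster index near 0.26 with z ≈ −30 means the pair is far tighter than
any 2-means split of comparable single-Gaussian data; pairs involving the
small incidental biclusters are not significant. Trajectories and outcomes:

```r
panel <- generate_longitudinal_panel(spec, sim$truth)
model <- select_model(panel, G_max = 3, seed = 42)
model
#> <gbtm> 2 group(s), degrees (3, 0), n = 291 knees
#>   pi: 0.135, 0.865 | sigma 2.045 | loglik -3746.71 | BIC 7555.83

per_knee <- knee_outcomes(generate_outcomes(spec, sim$truth),
                          posterior_assign(model, panel))
crosstab_bicluster_outcomes(bset, per_knee)$tka
#>   bicluster     n tka_rate
#> 1 1            87   0.115
#> 2 2            84   0.214
#> 3 3            96   0.0521
#> 4 4            22   0.227
#> 5 5             7   0.286
#> 6 6             4   0
#> 7 all         300   0.133
```

At n = 300 the BIC keeps two trajectory groups (a dominant stable group,
87%, and a minority changing group); the small worsening and up-down groups
in the generator are below detectability at this size. The arthroplasty
table shows the planted prognosis gradient: bicluster 2 (the poor-prognosis
phenotype) has four times the arthroplasty rate of bicluster 3.

`autoplot(bset, prepared)` draws the bicluster heatmap, `autoplot(model)`
the estimated trajectories, and `render_reports(run_pipeline(config))`
writes the full figure set with CSV twins.

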