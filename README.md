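# oasustain

Subtype and Stage Inference for knee-osteoarthritis biomarker panels.

Cross-sectional cohorts mix two kinds of heterogeneity: *phenotypic*
(different knees follow different disease courses) and *temporal* (knees are
observed at different points along their course). Clustering alone confuses
the two — it tends to group knees by severity rather than by true subtype —
while single-trajectory staging assumes every knee progresses the same way.
`oasustain` implements the subtypes-progression approach (SuStaIn, a mixture
of linear z-score event-based models) that infers both at once from a single
cross-sectional visit, plus the two baselines it is judged against.

## The model

Each biomarker measurement is expressed as a z-score against a disease-free
control group, sign-flipped where the raw measure decreases with severity
(joint space width, cartilage thickness), so every z-score rises as disease
advances. A *z-score event* is a biomarker crossing a threshold z ∈
{1, 2, 3, 5}; events exceeded by fewer than 10 subjects are dropped. The S
retained events define discrete stages 0..S: at stage k, the first k events
of a subtype's *event sequence* have occurred.

For subtype c with sequence σ_c, biomarker i follows a piecewise-linear
trajectory g_i(k | σ_c) through its event knots, ending at a maximum z
determined by its largest retained event (1→2, 2→3, 3→5, 5→7). With subjects
x_j, mixing fractions f, latent uniform stages, and unit Gaussian noise on
the z-scale:

    P(x_j | σ_c) = 1/(S+1) · Σ_{k=0..S} Π_i N(x_ij ; g_i(k | σ_c), σ_i)
    log L = Σ_j log Σ_c f_c · P(x_j | σ_c)

Fitting alternates greedy coordinate ascent over each sequence with EM
updates of the fractions; the number of subtypes grows hierarchically by
splitting one subtype at a time, and is selected by the cross-validation
information criterion CVIC = −2·log P(X|M) under 10-fold CV. A
Metropolis–Hastings sampler over event orderings quantifies sequence
uncertainty (positional variance matrices). Each subject receives posteriors
over subtypes and stages; a subject is *strongly assigned* when its top
subtype probability is ≥ 1.5× each other subtype's.

Baselines for comparison: a *subtypes-only* model (diagonal-covariance
Gaussian mixture fitted to definite cases, severity grade ≥ 2) and a
*stages-only* model (the same progression model with c = 1). The three are
compared by logistic regression on separating grade 0/1 from grade ≥ 2
knees, with likelihood-ratio statistics.

Because the real cohort data require restricted access, the package ships a
synthetic cohort generator with known ground-truth subtypes, stages, severity
grades and demographics, emulating the statistical structure of such
cohorts; every
pipeline stage is validated against it.

## Worked example

```r
library(oasustain)

# ten single-event biomarkers (z = 3), two subtypes with reversed orderings
defs <- biomarker_defs(paste0("bm", 1:10), 1, rep(list(3), 10))
es   <- event_set_from_defs(defs)
cfg  <- cohort_config(n_subjects = 600, n_controls = 100,
                      defs = defs, eventset = es,
                      subtypes = list(subtype_spec(1:10, 0.5),
                                      subtype_spec(10:1, 0.5)),
                      seed = 1)
cohort <- generate_patient_cohort(cfg)
stats  <- compute_control_stats(generate_control_group(cfg))
Z      <- to_zscores(cohort$raw_values, stats, defs)

fit <- fit_sustain(Z, es, c = 2, n_starts = 25, seed = 1)
fit
#> Subtypes-progression model: 2 subtype(s), 10 events
#>   fractions: 0.535, 0.465
#>   log-likelihood: -9933.141

fit$sequences[[1]]
#>  [1] 10  9  8  7  6  5  4  3  2  1
fit$sequences[[2]]
#>  [1]  1  2  3  4  5  6  7  8  9 10
```

The fitted fractions sit within a few percent of the generating 50/50 split,
and the recovered sequences match the generating orderings exactly (the
first fitted subtype is the reversed ordering; Kendall's τ = 1 after
matching labels). Per-subject assignment then gives subtype and stage
posteriors:

```r
post <- assign_subjects(Z, fit)
strong_assignment_rate_by_group(post, cohort$severity_grade)
#>          0          1          2          3          4
#> 0.08928571 0.98000000 1.00000000 0.99635036 0.96190476
```

Strong assignment is rare at grade 0 and near-universal from grade 1 on —
the earliest knees sit where the two trajectories coincide and are
genuinely hard to subtype, the same qualitative pattern reported for real
cohorts.

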