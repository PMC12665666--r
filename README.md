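# sympdyn — dynamic time warping analysis of longitudinal symptom panels

`sympdyn` is an R package for analysing the *temporal dynamics* of
multi-symptom patient-reported outcomes. It is written for symptom-science
and clinical-epidemiology researchers who follow a cohort with a
multi-item instrument (the packaged catalogue is the 32-item Memorial
Symptom Assessment Scale, scored 0–4 as the mean of frequency, severity
and distress) over a fixed visit grid, and who want to know which
symptoms evolve together, how they group into clusters, and which
symptoms *lead* others — without assuming that every patient's symptoms
move on the same schedule.

## The method

For each patient, every pair of symptom trajectories is aligned by
band-constrained Dynamic Time Warping with the symmetric2 step pattern

D(i, j) = c(i, j)·w + min{ D(i−1, j−1) (w = 2), D(i−1, j) (w = 1), D(i, j−1) (w = 1) },

with local cost c(i, j) = |aᵢ − bⱼ|, a Sakoe–Chiba band of one visit
(trajectories are linearly interpolated, 5 inserted points per gap, and
the band width scales with the interpolation), and distance
D(N, M)/(N + M). This yields one symmetric 32 × 32 distance matrix per
patient, plus a *directed* matrix from a forward-only band in which the
source trajectory may lead but never lag the target.

Group-level structure is extracted with Distatis: per-patient matrices
are double-centered into cross-products, weighted by inter-patient RV
congruence, and summed into a compromise matrix whose eigenvectors place
the 32 symptoms in a factor space (bootstrap envelopes give per-symptom
confidence intervals). Symptoms are clustered there by Ward.D2 with an
elbow (maximal-curvature) criterion; the averaged directed matrices give
a weighted directed symptom network whose in-/out-strength centralities
quantify following/driving tendencies; and repeated random 1:1 cohort
splits with Tucker congruence between the half-cohort networks quantify
stability. A synthetic cohort generator with planted cluster and
lead–lag structure provides ground truth for every stage.

## Worked example

```r
library(sympdyn)

# a 60-patient synthetic cohort with six planted symptom clusters
cfg   <- simulation_config(n_patients = 60, seed = 42,
                           noise_sd = 0.15, shift_sd = 0.3)
gen   <- generate_panel(cfg)
panel <- filter_complete(gen$panel)
panel
#> symptom_panel: 60 patients x 32 symptoms x 6 visits (60 complete)

mats <- cohort_matrices(panel, band_width = 1, k = 5)
cps  <- lapply(mats, function(m) to_crossproduct(m$symmetric))
comp <- distatis_compromise(cps, n_factors = 3)
comp
#> distatis_compromise: 32 symptoms, 60 patients; first 3 factors explain 51.1% / 16.8% / 9.7%

sol <- cluster_symptoms(factor_scores(comp))
sol
#> cluster_solution: 32 symptoms in 6 clusters (sizes 12, 2, 4, 10, 3, 1)

net  <- symptom_network(distance_to_similarity(aggregate_directed(mats)),
                        clusters = sol$labels)
head(strength_centralities(net)[order(strength_centralities(net)$out_rank), ], 3)
#>    symptom out_strength in_strength out_rank in_rank
#> 5      S05     25.79777    25.77161        1       6
#> 16     S16     25.72469    25.95341        2       4
#> 30     S30     25.69019    26.21877        3       1

stability_run(panel, n_splits = 50, seed = 1, matrices = mats)
#> stability_report: 50 splits (30/30); median congruence 0.996 (p25 0.995, p95 0.997)
```

Read this as: the first three compromise factors carry about 77% of the
positive-eigenvalue mass; the elbow criterion selects six clusters whose
sizes match the planted 12/10/4/3/2/1 structure exactly; out-strength
ranks mark the symptoms whose fluctuations tend to precede the others;
and the median Tucker congruence of 0.996 across 50 random half-splits
says the group network is highly replicable in this homogeneous cohort.

The staged command `run_pipeline(run_config(...), outdir)` chains
simulate → dtw → distatis → cluster → network → stability, writes every
stage artifact (CSV/GraphML/Newick/JSON) plus a manifest, and
`rerun_from_manifest()` reproduces a run byte-for-byte.

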