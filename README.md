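# orientclust

Clustering of smartphone accelerometer readings captured during typing,
and prediction of clinically relevant week-to-week changes in depression
severity from the resulting phone-orientation features.

## Who this is for

Digital-phenotyping and mobile-health researchers working with
typing-session accelerometer streams (per-reading `x/y/z` in units of g
at ~10 Hz) and weekly PHQ-8 depression self-reports. The motivating kind
of dataset is private, so the package includes a synthetic cohort
generator with complete ground truth; every method is validated end to
end against it.

## The method

When the user is sedentary the phone measures only gravity, so a reading
normalised to unit length is a point on the unit sphere encoding phone
orientation. Per user-week:

1. **Gravity-band filter** — keep readings with magnitude in
   [0.95, 1.05] g and rescale to unit norm.
2. **Spherical KDE** — estimate the orientation density with a von
   Mises–Fisher kernel, evaluated at N = 1000 near-equidistant grid
   points (Fibonacci lattice):
   f̂(p) = (1/n) Σₖ C₃(κ) exp(κ p·uₖ), with C₃(κ) = κ / (4π sinh κ)
   and κ = 1/h².
3. **Peak detection** — cluster centres are grid points whose density
   strictly exceeds their 8 nearest grid neighbours; peaks below the
   upper edge of bin 2 of a 50-bin histogram of the density are
   discarded as noise.
4. **Graph assignment** — neighbour pairs become edges weighted
   w_ij = exp(−(f̂ᵢ + f̂ⱼ)/2), so high-density regions are "short";
   every grid point joins the peak with the smallest Dijkstra path
   length, readings inherit their nearest grid point's label, and each
   typing session takes the modal reading label.
5. **Weekly features** — cluster counts, session-to-session transitions,
   summed haversine travel between consecutive session centres,
   per-axis medians/motions, and an hourly predominant-cluster series.
6. **Prediction** — weekly features joined with PHQ-8; label = 1 iff
   |PHQ(w+1) − PHQ(w)| ≥ 4; SMOTE balancing inside training folds;
   user-grouped 5-fold cross-validation with random forest or gradient
   boosting; impurity-gain feature ranking; median-split odds ratios
   with Woolf CIs.

## Worked example

```r
library(orientclust)

# synthetic cohort: 6 users x 5 weeks, volatility-change effect injected
sim <- simulate_cohort(inject_effect(cohort_spec(n_users = 6, weeks = 5), 3),
                       seed = 20)
sim
#> cohort_sim: 6 users x 5 weeks | 63692 accel readings, 28 PHQ reports (seed 20)

res <- run_pipeline(sim)          # filter -> weekly vMF KDE -> graph clustering
res
#> pipeline_result: 30 clustered user-week(s), 0 skipped
res$models[[1]]
#> cluster_model: user u001 week 2023-W01 | 4 peak(s), 1256 readings, 36 sessions

head(res$features[, c("user_id", "week_index", "n_clusters",
                      "n_cluster_transitions",
                      "total_distance_between_clusters", "median_Z")])
#>   user_id week_index n_clusters n_cluster_transitions
#> 1    u001       2766          4                    19
#> 2    u001       2767          3                     9
#> 3    u001       2768          3                    12
#> 4    u001       2769          2                     7
#> 5    u001       2770          3                    10
#> 6    u002       2766          2                    10
#>   total_distance_between_clusters median_Z
#> 1                        29.40839    0.373
#> 2                        18.24747    0.373
#> 3                        28.53935   -0.741
#> 4                        11.84576    0.769
#> 5                        21.38369    0.373
#> 6                        12.67557   -0.859
```

`u001` used 4 distinct phone orientations in week `2023-W01` and changed
orientation 19 times between sessions, travelling a summed great-circle
distance of 29.4 rad between consecutive session centres; `median_Z`
near +1 means mostly face-up orientations, negative values screen-down
tilts. At a realistic scale (the generator default of 50 users × 11
weeks) the injected cohort yields a median-split odds ratio for
`n_clusters` of ~7–16 and a grouped-CV AUC of ~0.83–0.89, while null
cohorts (`inject_effect(spec, 1)`) give CIs covering 1.0 and AUC near
0.5 — run `scripts/acceptance.R` below to reproduce those numbers
yourself.

A thin command-line front-end covering simulate / cluster / predict
lives at `inst/scripts/orientclust.R`.

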