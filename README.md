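# microstasis

Longitudinal analysis of host-associated microbiome cohorts that cross an
environmental transition — for example, a small crew sampled before
entering, during, and after leaving a shared closed habitat. The package
is aimed at microbial ecologists and biostatisticians who have an OTU
count table, sample metadata, a rooted phylogeny, and (optionally)
environmental source samples and host immune markers, and who want the
full chain of analyses that this study design calls for:

* **Reference-community normalization** of compositional time series:
  fractions are rescaled toward a reference built from the *other* time
  points, with time-point weights (1 − *j*)² where *j* is the pairwise
  Jensen-Shannon distance (base-2, so *j* ∈ [0, 1]), and per-OTU
  reference values taken as JSD-weighted medians. This damps the ripple a
  single-taxon bloom imposes on every other taxon's fraction.
* **Stationarity and trend**: the sample autocorrelation function with
  ±z₀.₉₇₅/√n bounds, and the Mann-Kendall test
  S = Σᵢ<ⱼ sign(xⱼ − xᵢ) with tie-corrected Var(S) and continuity
  correction.
* **Convergence**: weighted UniFrac distances
  d(P, Q) = Σ_b ℓ_b |P_b − Q_b| (normalized variant divides by
  Σ_b ℓ_b (P_b + Q_b)), pooled between subjects within each experimental
  phase and compared by a Kruskal-Wallis H whose null distribution is
  obtained by permuting phase labels over time points (the pooled pairs
  are pseudo-replicated, so the chi-square reference is invalid here).
* **Individual separation**: PCA on centered fractional abundances, then
  MANOVA (Wilks' lambda) on the first ≤25 PCs, pairwise Hotelling T²,
  and single-linkage clustering of Mahalanobis distances between group
  means.
* **Source tracking**: an expectation-maximization mixture estimator of
  each sink's proportions over named source communities plus an unknown
  pool, with latent source profiles and a uniform Dirichlet prior on the
  unknown that makes the mixture identifiable.
* **Co-occurrence networks**: per-subject Spearman correlations between
  abundant genera (mean relative abundance > 1%) and cytokines, edges at
  |ρ| ≥ 0.5, with raw p and Benjamini-Hochberg q on every edge.

A seeded synthetic-cohort generator reproduces the study design (4
subjects, three phases, shared-environment mixing inside, air sources,
linked cytokines) with known ground truth, so every stage is tested
end-to-end without sequencing data.

## Worked example

```r
library(microstasis)

co <- generate_cohort(cohort_spec(seed = 1))
#> synthetic_cohort: 200 OTUs x 72 samples, 3 air sources, seed 1

ns <- normalize_subject(co$otu_table, "A")
#> normalized_series: 18 time points x 200 OTUs (63 abundant), subject A
#> scale factors:  0.982 1.069 1.096 1.105 1.023 0.959 0.901 0.920 ...
```

The scale factors hover around 1: subject A has no bloom artifacts, so
the reference normalization changes little. Trend and stationarity of a
dominant phylum:

```r
fr <- fractional_normalize(aggregate_to_rank(co$otu_table, co$taxonomy,
                                             "phylum"), "A")
mann_kendall(fr[, "Firmicutes"])
#> Mann-Kendall: S = -13, Var(S) = 697.000, Z = -0.455, p = 0.6494 (none)
```

No significant monotone trend (p = 0.65), consistent with a stable
community. Convergence across phases:

```r
dm <- unifrac_matrix(co$otu_table, co$tree)
ct <- convergence_test(dm, co$otu_table$metadata, seed = 1)
#> H = 173.78, permutation p = 0.006
round(ct$medians, 4)
#>      1      2      3
#> 0.1200 0.0941 0.1163  # inside-phase distances are the smallest
```

Between-subject distances drop from ≈0.12 outside to ≈0.094 inside the
shared habitat (permutation p = 0.006): the crew's communities converge
while they share living space, and diverge again after leaving. The
demo cohort generates this with a shared-environment weight of 0.3.
Individuals nonetheless remain sharply distinct:

```r
scores <- pca_profiles(t(co$otu_table$counts) / colSums(co$otu_table$counts))$scores
group_separation(scores, co$otu_table$metadata$subject)
#> group separation (4 groups, 25 PCs): Wilks = 0.0000, F = 59.030, p = 5.31e-75
```

Source tracking recovers a known two-source mixture at depth 100,000:

```r
g <- generate_air_and_sink(c(0.7, 0.3, 0), unknown_frac = 0,
                           depth = 100000, seed = 1)
em_source_track(g$sink, g$sources)
#> Air1 = 0.702, Air2 = 0.297, Air3 = 0.000, unknown = 0.000 after 304 iterations
```

And the whole chain runs as one pipeline, writing stamped TSVs for every
stage (bitwise reproducible for a given seed and configuration):

```r
run_pipeline(default_pipeline_config(out_dir = "demo_out", seed = 1))
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --out-dir demo_out
--seed 1`.

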