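# nichespace

Quantifying community-scale overlap of fundamental niches from
metagenome-assembled genomes (MAGs), and testing whether high niche overlap
precedes abrupt community collapse.

## The problem

Species with similar resource-use capabilities — encoded in similar gene
repertoires — are candidates for competitive exclusion. In dense microbial
time series, sudden collapses from taxon-rich to oligopolistic states may
therefore be foreshadowed by high community-scale *gene-repertoire overlap*.
`nichespace` turns that idea into a pipeline for ecologists working with
MAG catalogs and abundance time series:

1. **Niche space** — pairwise Jaccard distance `D_ij` between binary gene
   repertoires, ordinated by principal coordinate analysis (PCoA).
2. **Niche-overlap indices** — at each time point, over the detected set
   `T` (MAGs with relative abundance > 0.1%), with `N_T = |T|`:
   - overall mean: `1 − Σ_{i≠j∈T} D_ij / (N_T (N_T − 1))`
   - nearest mean: `1 − Σ_{i∈T} min_{j∈T, j≠i} D_ij / N_T`
   - weighted nearest mean: `1 − Σ_{i∈T} p_i · min_{j∈T, j≠i} D_ij`,
     with abundances `p_i` renormalized over `T`.

   All three live in [0, 1]: 0 = all detected repertoires disjoint,
   1 = all identical. They are `NA` when fewer than two MAGs are detected.
3. **Community dynamics** — Bray–Curtis β-diversity between consecutive
   sampled time points, the 5-day-window *abruptness* index (> 0.5 marks
   turnover of more than half the community), Shannon α-diversity, and 0–1
   rescaling for joint display.
4. **Association** — OLS regression of the β-diversity from time *k* to
   *k+1* on the overlap index at *k* (lagged: does overlap precede change?),
   with slope t-test and 95% confidence band.
5. **Synthetic study system** — a guild-structured genome generator and a
   serial-dilution Lotka–Volterra simulator in which competition strength is
   proportional to gene-repertoire similarity, producing an engineered
   competitive-exclusion collapse so every stage is testable offline.

## Worked example

```r
library(nichespace)

sc <- generate_scenario(seed = 42)        # genomes + 110-day dynamics + 13-point sampling
D  <- pairwise_jaccard(sc$genomes)        # 32 x 32 Jaccard distances
ov <- overlap_series(D, sc$sampled)       # detection + three overlap indices
head(round(ov, 3), 6)
#>   day n_detected overall_mean nearest_mean weighted_nearest_mean
#> 1   1         32        0.272        0.865                 0.864
#> 2  10         20        0.312        0.863                 0.858
#> 3  20          4        0.101        0.101                 0.101
#> 4  24          4        0.101        0.101                 0.101
#> 5  30          4        0.101        0.101                 0.101
#> 6  40          4        0.101        0.101                 0.101
```

On day 1 all 32 MAGs are detected; the nearest-neighbor overlap is high
(0.865) because every MAG has close functional analogs within its guild. By
day 20 competitive exclusion has pruned each guild to one winner: four
dissimilar survivors, overlap 0.101. The collapse is abrupt and the
association between overlap and *subsequent* compositional change is
positive:

```r
sc$collapse_day                       # day of maximum abruptness
#> [1] 8
round(sc$max_abruptness, 3)           # > 0.5: more than half the community turned over
#> [1] 0.576

dyn <- dynamics_series(sc$sampled, rescale = FALSE)
overlap_regression(ov$overall_mean[-13], dyn$beta_next[-13])
#> OLS: slope 2.042, intercept -0.1569, R^2 0.562, p 0.005019 (n = 12)
```

The same computation runs on real data from two TSV files:

```r
run_overlap(gene_matrix = "genes.tsv", abundance_table = "abundance.tsv",
            out_dir = "results/")
```

which writes the distance matrix, PCoA coordinates and eigenvalues, overlap
and dynamics series, paired overlap-vs-change table, regression report, and
a run manifest. A thin shell wrapper with `overlap` and `simulate`
subcommands is installed at `inst/scripts/nichespace.R`.

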