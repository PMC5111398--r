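# mitoskim

Species detection and biomass quantification from bulk-sample mitogenome
skims.

## What it does, and for whom

Bulk invertebrate samples — a pan trap of bees, a Malaise trap of flies —
can be identified *en masse* by shotgun-sequencing the total DNA of the
homogenised sample and mapping the reads against a reference library of
whole mitochondrial genomes, one per candidate species. Almost all reads
are nuclear and fall through; the mitochondrial minority paints each
present species' reference from end to end. mitoskim implements this
pipeline for ecologists running DNA-based biodiversity monitoring, plus
the downstream statistics used to validate it against a morphological
species × sample table, and a seeded simulator so every stage can be
tested end to end with known ground truth.

The stages:

1. **Map** (`build_index()`, `map_reads()`): every read is aligned
   full-length and ungapped at ≥ 99% identity (mismatch budget
   ⌊L × 0.01⌋); only reads unique to a single reference count. Circular
   references are handled natively and an exhaustive-scan oracle
   (`brute_force_map()`) validates the mapper.
2. **Profile** (`profile_table()`): per species × sample — raw uniquely
   mapped reads, coverage fraction (proportion of reference positions hit),
   reads normalised by achieved mitogenome length / 16 kb, and reads
   corrected for the species' mitochondrial-to-nuclear read ratio. A
   species is called **present** when coverage > 10% (strict), a threshold
   that cleanly separates true occupants (typically near-complete
   coverage) from cross-sample contamination (a handful of reads, < 2%
   coverage).
3. **Quantify** (`biomass_read_regression()`, `gls_varexp_fit()`,
   `biomass_to_counts()`): z-transformed corrected-read frequencies
   regressed on biomass frequencies, by OLS and by maximum-likelihood GLS
   with an exponential variance function sd(ε) = σ·exp(δx) to absorb
   heteroscedasticity; read frequencies convert to biomass and count
   estimates given a sample's weighed total biomass.
4. **Community** (`jaccard()`, `nmds()`, `procrustes_protest()`,
   `chao2()`, `welch_from_estimates()`): binary Jaccard and quantitative
   Ružička dissimilarities, NMDS ordination, symmetric Procrustes with
   permutation test, bias-corrected Chao2 richness
   Ŝ = S_obs + ((m−1)/m)·Q₁(Q₁−1)/(2(Q₂+1)) with SE, and Welch t-tests
   between richness estimates.
5. **Evaluate** (`confusion()`, `threshold_sweep()`): detection rate
   TP/(TP+FN) and profiling success (TP+TN)/grid against a morphological
   truth table, over the full reference × sample grid.
6. **Simulate** (`simulate_study()` and friends): reference libraries with
   guaranteed between-species window separability, sample compositions
   (3–11 species, 13–51 individuals per sample by default), shotgun reads
   with a nuclear-background source and iid errors, and contamination
   injection — all deterministic given a seed.

`run_pipeline()` wires the stages together from a YAML config and writes
TSV reports plus an audit manifest; `inst/cli/mitoskim.R` is a thin
command-line wrapper (`simulate`, `map`, `run` subcommands).

## Worked example

```r
library(mitoskim)

st <- simulate_study(seed = 42, n_species = 8, n_samples = 3,
                     total_reads = 10000, species_range = c(3, 5),
                     individuals_range = c(10, 25),
                     length_range = c(4000, 4800),
                     mito_fraction_range = c(0.05, 0.5))
idx <- build_index(st$library)
mappings <- lapply(st$samples, function(s) map_reads(s$reads, idx))
mappings[[1]]
#> mapping_result: 10000 reads ( 1904 unique, 0 multi, 8096 unmapped )
```

8096 unmapped reads are the simulated nuclear background; none of them
(and no read from another species) passes the unique-at-99%-identity
filter. Profiling and evaluating against the simulated truth:

```r
prof <- profile_table(mappings, st$library, st$meta)
head(subset(prof, raw_reads > 0), 3)
#>   species_id sample_id raw_reads coverage_fraction normalized_reads corrected_reads present
#> 1       sp01       S01      1572             1.000             6142           25835    TRUE
#> 3       sp03       S01       151             0.977              601            7937    TRUE
#> 6       sp06       S01       181             0.999              699            4767    TRUE

confusion(presence_matrix(prof), st$truth$counts > 0)
#> confusion: tp=11 tn=13 fp=0 fn=0
#>   detection rate    = 100.0%
#>   profiling success = 100.0%
```

Every species present in the truth reaches near-complete coverage and is
detected; every absent species stays at zero. Corrected-read frequencies
track biomass frequencies:

```r
biomass_read_regression(prof, st$truth$biomass)$gls
#> y ~ 0.0005508 + 1.003 x  (n = 11)
#>   varExp delta = 0.1562, sigma = 0.05125
#>   slope p = 4.26e-12, logLik = 17.07
```

A slope of ~1 between z-scores means read frequency is an unbiased
relative-biomass estimator under the simulation model. Richness
extrapolation and a Welch comparison of two published-scale estimates:

```r
chao2(presence_matrix(prof))
#> Chao2 = 7.0 +/- 1.8 SE (S_obs = 6, Q1 = 3, Q2 = 1, m = 3)

welch_from_estimates(56.3, 15.9, 10, 47.9, 11.8, 10)
#> Welch t(df = 16.6) = 0.42, p = 0.68
```

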