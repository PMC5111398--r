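---
title: "Mitogenome-skim profiling of bulk samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome-skim profiling of bulk samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoskim)
```

## The problem

Monitoring wild pollinator communities requires identifying and counting
hundreds of morphologically difficult species across thousands of bulk
trap samples. mitoskim implements a mitogenomic ("genome skimming")
profiling pipeline for such samples: total DNA from a bulk sample is
shotgun-sequenced, the reads are mapped against a reference library of
whole mitochondrial genomes (one per candidate species), and species
presence and relative biomass are inferred from the mapping profile. The
vast majority of shotgun reads are nuclear and are simply discarded by the
mapping step; the mitochondrial minority carries the taxonomic signal.

This vignette describes the models and numerical choices behind each stage,
what the bundled simulator does and does not emulate, and the known
limitations.

## Read mapping model

A read maps to a reference at a position (on either strand of the circular
molecule) when the **full read** aligns ungapped with at most
$\lfloor L \times (1 - t) \rfloor$ mismatches, where $L$ is the read length
and $t$ the identity threshold (default $t = 0.99$, so one mismatch for a
100-bp read). This formalises the "100% read coverage at 99% identity"
criterion as its strictest reading: indels are excluded (the simulator
emits none) and `N` counts as a mismatch on either side. Ungapped
full-length alignment has the advantage of being exactly checkable by an
exhaustive scan, which is how the mapper is validated: `brute_force_map()`
implements the identical contract in plain R by scanning every position,
strand and reference, and the test suite asserts agreement with the indexed
mapper on more than ten thousand reads, including origin-spanning and
budget-boundary cases.

Reads are assigned at the **reference (species) level**: a read is `unique`
when all of its alignments fall on one reference, even if that reference
holds several placements (repeats); it is `multi_reference` when two or
more references hold alignments, and such reads are discarded — only
uniquely mapped reads contribute to counts and coverage. Best placements
are chosen deterministically (fewest mismatches, then smallest position,
then `+` strand) so depth vectors are bit-reproducible.

The index is an exact-seed table: by the pigeonhole principle, any
alignment with at most $m$ mismatches contains an exact block of length
$\lfloor L / (m+1) \rfloor$, so looking up the $k$-prefix
($k = \min(31, \lfloor L/(m+1) \rfloor)$, 2-bit packed) of each of the
$m+1$ read blocks finds every hit; candidates are verified by direct
comparison. Circularity is handled by logically extending each reference
with $L - 1$ wrap bases; positions are reported modulo the achieved
length. Reads shorter than the seeding guarantee fall back to a full scan.

## From mapping to profiles

For species $s$ in sample $j$, with $R_{sj}$ uniquely mapped reads:

* **coverage fraction** — the proportion of reference positions with depth
  $\ge 1$, computed over the achieved (assembled) length. This is the
  presence statistic: a species is called **present** when coverage is
  *strictly greater than* the detection threshold (default 0.10). The
  strict inequality follows the wording of the detection rule; in practice
  calls are insensitive to the exact cutoff because true detections sit far
  above it and contamination far below (see below).
* **normalised reads** — $R_{sj} / (\ell_s / 16000)$ where $\ell_s$ is the
  achieved mitogenome length; species with incomplete assemblies would
  otherwise be undercounted. The 16 kb canonical length is configurable.
* **corrected reads** — normalised reads divided by the species'
  mitochondrial read fraction $\phi_s$ (the fraction of that species'
  shotgun reads that are mitochondrial, measured once per species from its
  reference sequencing run). $\phi_s$ spans roughly 250-fold across
  species (0.005%–1.319%), so this correction matters for quantification.

Profiles always cover the **full reference library × sample grid**; species
absent from a sample appear as explicit zero rows. This is what makes the
confusion-matrix summaries well defined: true negatives are reference
species correctly absent, and profiling success
$(TP+TN)/(TP+TN+FP+FN)$ is computed over the whole grid.

## Biomass–read regression

Per sample, corrected read counts are converted to frequencies and
compared with biomass frequencies from a morphological truth table. Both
sides are z-transformed (mean 0, sample sd 1). The z-transform is applied
**within sample** by default, across the species cells of that sample
(cells where the species occurs in the truth or is detected in the reads);
this is the scope that corrects for differing sample sizes, and a global
scope is available behind a flag. The regression is fit two ways:

* ordinary least squares, reporting $R^2 = 1 - SSE/SST$ and a t-test on
  the slope;
* generalised least squares with an exponential variance function,
  $y_i = a + b x_i + \varepsilon_i$,
  $\mathrm{sd}(\varepsilon_i) = \sigma e^{\delta x_i}$, fitted by maximum
  likelihood (not REML, so likelihoods are comparable across read-count
  variants). For fixed $\delta$ the weighted least squares solution is
  closed form with weights $e^{-2\delta x_i}$; the one-dimensional profile
  likelihood is maximised over $\delta$ by bounded golden-section search on
  $[-10, 10]$ (tolerance $10^{-8}$). When the profile optimum is no better
  than $\delta = 0$ the fit returns $\delta = 0$ exactly, which makes the
  GLS→OLS reduction exact rather than approximate. The variance covariate
  is the same $x$ that enters the mean model.

The fit is validated three ways in the tests: against a dense grid search
over $\delta$ (step $10^{-4}$), against `nlme::gls(weights = varExp(),
method = "ML")`, and by parameter recovery on simulated heteroscedastic
data. Read frequencies can finally be converted back to count estimates:
multiplying by a sample's total (weighed) biomass gives per-species biomass
estimates, and dividing by species-typical per-individual biomass gives
real-valued counts, with rounding left to the caller.

The regression uses corrected reads by default — the variant with the best
explained variance — and the pipeline reports all three variants
(raw / length-normalised / fully corrected) side by side.

## Community statistics

* **Dissimilarities.** Binary Jaccard over presence sets, and the
  quantitative (Ružička) form $2B/(1+B)$ over the Bray–Curtis ratio
  $B = \sum|x_i-y_i| / \sum(x_i+y_i)$; the two coincide on 0/1 data. Both
  are computed by `vegan::vegdist(method = "jaccard")`.
* **Ordination.** Non-metric multidimensional scaling in $k = 2$
  dimensions (`vegan` engine), minimising Kruskal stress-1 with monotone
  regression, best of 20 restarts by default. A deterministic variant
  (`n_restarts = 0`) descends from the metric (PCoA) start only. The
  deterministic variant exists because of a real numerical hazard: with ten
  samples the stress surface often has near-degenerate optima (stress
  differences below $10^{-3}$), and independent restart schedules applied
  to two nearly identical dissimilarity matrices can land in different
  basins, deflating their Procrustes correlation even when the underlying
  dissimilarities agree to $r > 0.999$. When two ordinations are to be
  compared, the deterministic descent is the appropriate tool; even so the
  comparison retains a heavy lower tail (about one seed in twenty), which
  is a property of NMDS at this sample size, not of the profiling.
* **Procrustes.** Symmetric Procrustes superimposition with a permutation
  test (`vegan::protest(symmetric = TRUE)`): $m^2$ is the symmetric sum of
  squares, $r = \sqrt{1 - m^2}$, and the p-value uses the add-one rule
  $(b+1)/(B+1)$ over $B$ row permutations (default $B = 9999$, so the
  smallest attainable p-value is $10^{-4}$ and p is never zero).
* **Richness.** Bias-corrected Chao2 from the incidence matrix:
  $\hat S = S_{obs} + \frac{m-1}{m}\frac{Q_1(Q_1-1)}{2(Q_2+1)}$ with the
  matching variance, where $Q_1$/$Q_2$ are species occurring in exactly
  one/two samples. The classic estimator
  $S_{obs} + \frac{m-1}{m} Q_1^2/(2Q_2)$ and its variance are available
  behind `bias_corrected = FALSE` (this is also the form most legacy tools
  report when $Q_2 > 0$). Two richness estimates are compared with a Welch
  t-test built from the estimates, their standard errors and the number of
  samples behind each, with Welch–Satterthwaite degrees of freedom using
  $m - 1$ per group.

## The simulator

`simulate_study()` generates a complete study fixture: reference library,
species metadata, ground-truth sample compositions and shotgun reads. Its
defaults are the study design the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 48 | reference mitogenomes |
| `length_range` | 15000–17000 bp | achieved assembly lengths |
| `min_divergence` | 0.05 | per-species per-site substitution rate |
| `n_samples` | 10 | bulk samples |
| `species_range` | 3–11 | species per sample |
| `individuals_range` | 13–51 | individuals per sample |
| `mito_fraction_range` | 5e-5–0.01319 | mitochondrial read fraction, log-uniform |
| `biomass_per_individual` | log-normal, median 50, sdlog 1 | mass units (nominally mg) |
| `total_reads` | 50000 | single-end reads per sample |
| `read_length` | 100 bp | |
| `error_rate` | 0.002 | iid per-base substitutions |

Choices worth explaining:

* **Reference divergence.** Species sequences descend from one random
  ancestor, with substitution sites placed by stratified (systematic)
  sampling — one site per $\lfloor 1/q \rfloor$-bp block — rather than
  iid. Real mitogenomes spread divergence along the molecule; iid placement
  would leave occasional 100-bp windows nearly identical between species,
  which would (correctly but unhelpfully) make cross-species read windows
  ambiguous. Stratified placement guarantees every window carries about
  $2q \times 100$ differences between any two species; the guarantee is
  verified by a pigeonhole shared-50-mer scan and the library is
  regenerated if it fails. A consequence asserted in the tests: no read
  from one species can map to another within the mismatch budget, so false
  positives cannot arise from mapping error — only from contamination.
* **Mitochondrial fraction.** Drawn log-uniformly because the empirical
  range spans ~250-fold; a uniform draw would make small fractions
  vanishingly rare. This is the single most consequential default (see
  *Limitations*).
* **Read model.** Species $i$ contributes mitochondrial reads with
  expectation $N \cdot w_i$, $w_i \propto b_i \phi_i$ normalised over the
  present species plus one nuclear-background pseudo-source of weight
  $\propto \sum_i b_i (1 - \phi_i)$, where $b_i$ is the species' total
  biomass in the sample. Mitochondrial reads are uniform windows of the
  circular reference (they may span the origin) on a uniform strand with
  iid substitution errors; nuclear background is iid uniform random DNA,
  which is unmappable at 99% identity against ≤20 kb references (the
  chance that a random 100-mer aligns within one mismatch anywhere is
  negligible, and the tests confirm zero background mappings). Single-end
  reads only: mate pairs add no information to a full-length ungapped
  mapping contract.
* **Community structure.** By default sample compositions are uniform
  draws from the library with Dirichlet-skewed abundances. With
  `n_groups > 1`, samples belong to landscape groups drawing from
  partially distinct regional species pools (`pool_fraction` of the
  library each), emulating the between-region beta diversity that makes
  real samples cluster in ordinations. Unstructured communities of ten
  samples produce weak, unstable 2-D ordinations; grouped ones behave like
  the real study's.
* **Contamination.** `inject_contamination()` appends error-free windows
  from an absent species. Cross-sample carry-over is whole-tissue DNA, so a
  realistic dose for a fraction $c$ of carried-over material is
  $c N \phi$ *mitochondrial* reads — for $c = 0.5\%$, $N = 5\times10^4$
  and the study's $\phi$ range, between one and a handful of reads. On a
  16 kb reference, coverage exceeds 10% only above
  $n > \ln(0.9^{-1}) \cdot 16000/100 \approx 17$ reads, so realistic
  contamination stays an order of magnitude below the detection threshold.
  This is the separation property that makes the pipeline robust to
  contamination, and the end-to-end tests reproduce it: injected
  contaminants never exceed ~2% coverage.

**What the simulator does not emulate:** indels and quality decay, GC and
library-prep bias, PCR duplicates, numts (nuclear copies of mitochondrial
sequence), within-species polymorphism between the reference individual
and the sampled individuals, and biomass variation among individuals of a
species. Passing tests therefore demonstrate the correctness of the
pipeline's logic and its behaviour under the stated statistical model, not
robustness to every artefact of real libraries.

## Detection power at simulated depth

Detection requires roughly 17 uniquely mapped reads (10% of a 16 kb
reference at 100 bp). A present species' expected read count is
$N \cdot b_i \phi_i / \sum_j b_j$; at the simulated depth of $5\times10^4$
reads per sample, species with small biomass shares and mitochondrial
fractions near the bottom of the empirical range have expected counts well
below one and cannot be detected. This is not a defect of the simulation
scale so much as a faithful miniature of the real method: even at full
sequencing depth (three orders of magnitude more reads), species
combining low biomass with extreme mitonuclear ratios produce false
negatives, which is exactly why the empirical detection rate of this kind
of pipeline is high but not perfect. The end-to-end tests therefore assert
the two properties that are true at any depth — zero false positives
without contamination, and contaminant coverage far below threshold — and
the test suite documents (as an expected failure at this depth) that
perfect recall is not attainable when the mitochondrial fraction spans its
full empirical range. Users quantifying detection power for a planned
depth can do so directly with `expected_coverage()` and the weight formula
above.

## Problem sizes used by the test suite

Oracle-equivalence mapping tests use five references of ~2 kb and >10⁴
reads; the window-separability oracle uses three references of ~1 kb
(exhaustive scans scale quadratically, and the contracts under test are
length-invariant). End-to-end properties run the full default study (48
species × 10 samples × 5×10⁴ reads) over 20 seeds; the GLS recovery study
uses 50 replicates of n = 1000; Procrustes null calibration uses 200 seeds
at 199 permutations. The heteroscedastic-regression property (positive,
significant biomass–read slope) is asserted over the same 20 study seeds.

## Known limitations

* The mapper is exact for its contract but the contract itself is a
  stylised reading of short-read alignment: gapped aligners will rescue
  reads with indels that this mapper discards.
* Coverage fractions are computed over achieved assembly length; for very
  incomplete references this denominator differs from the biological
  molecule's length, and the presence threshold effectively tightens.
* The mitonuclear correction assumes the per-species mitochondrial
  fraction measured from one reference individual transfers to all
  individuals in all samples; in reality it varies with tissue, age and
  condition, which is one reason biomass–read relationships stay noisy.
* Chao2 standard errors assume independent sample incidences;
  comparisons between data sets derived from the *same* samples (as in the
  Welch examples) are conservative descriptions, not independent-sample
  inference.
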