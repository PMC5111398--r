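test_that("library simulation is deterministic and respects length bounds", {
  a <- simulate_reference_library(n_species = 4, length_range = c(2000, 2400),
                                  seed = 11)
  b <- simulate_reference_library(n_species = 4, length_range = c(2000, 2400),
                                  seed = 11)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_reference_library(n_species = 4,
                                  length_range = c(2000, 2400), seed = 12)))
  expect_true(all(a$library$achieved_length >= 2000 &
                    a$library$achieved_length <= 2400))
  expect_equal(a$library$achieved_length, nchar(a$library$sequence))
  expect_true(all(a$meta$mito_fraction > 0 & a$meta$mito_fraction <= 1))
  expect_true(all(a$meta$biomass_per_individual > 0))
})

test_that("study-scale library has 48 species within the canonical range", {
  lm <- simulate_reference_library(seed = 5)
  expect_equal(nrow(lm$library), 48L)
  expect_true(all(lm$library$achieved_length >= 15000 &
                    lm$library$achieved_length <= 17000))
  expect_true(all(lm$meta$mito_fraction >= 5e-5 &
                    lm$meta$mito_fraction <= 0.01319))
})

test_that("no cross-species window lies within the mapping budget", {
  # exhaustive check: every circular window of every species, mapped by the
  # brute-force oracle against the other species only, must be unmapped
  lm <- simulate_reference_library(n_species = 3,
                                   length_range = c(1000, 1100), seed = 21)
  lib <- lm$library
  for (i in seq_len(nrow(lib))) {
    others <- lib[-i, , drop = FALSE]
    wins <- circular_window(lib$sequence[i],
                            seq_len(lib$achieved_length[i]), 100)
    status <- vapply(wins,
                     function(w) brute_force_map(w, others)$status, "")
    expect_true(all(status == "unmapped"),
                label = sprintf("species %d windows vs others", i))
  }
})

test_that("truth compositions respect the sampling design", {
  lm <- small_library
  truth <- simulate_truth(lm, n_samples = 8, species_range = c(2, 4),
                          individuals_range = c(13, 51), seed = 9)
  expect_identical(truth$counts >= 0, truth$counts >= 0)
  sp_per_sample <- colSums(truth$counts > 0)
  expect_true(all(sp_per_sample >= 2 & sp_per_sample <= 4))
  expect_true(all(colSums(truth$counts) >= 13 & colSums(truth$counts) <= 51))
  expect_equal(truth$biomass,
               truth$counts * lm$meta$biomass_per_individual)
})

test_that("bulk-sample reads conserve counts and are seed-deterministic", {
  lm <- small_library
  counts <- c(sp01 = 3L, sp02 = 1L, sp03 = 0L)
  a <- simulate_bulk_sample(lm$library, lm$meta, counts,
                            total_reads = 4000, seed = 31)
  b <- simulate_bulk_sample(lm$library, lm$meta, counts,
                            total_reads = 4000, seed = 31)
  expect_identical(a, b)
  expect_equal(nrow(a$reads), 4000L)
  expect_false("sp03" %in% a$reads$origin)       # count 0 -> 0 reads
  expect_false("sp03" %in% a$expected$species_id)
  expect_equal(sum(a$expected$realized_reads) +
                 sum(a$reads$origin == "nuclear"), 4000L)
})

test_that("a pure single-species sample emits exact reference windows", {
  lib <- tiny_refs[2, , drop = FALSE]
  meta <- data.frame(species_id = "refB", mito_fraction = 1,
                     biomass_per_individual = 10)
  sim <- simulate_bulk_sample(lib, meta, c(refB = 5L), total_reads = 300,
                              error_rate = 0, seed = 13)
  expect_true(all(sim$reads$origin == "refB"))
  all_windows <- c(circular_window(lib$sequence, seq_len(400), 100),
                   circular_window(revcomp_dna(lib$sequence), seq_len(400),
                                   100))
  expect_true(all(sim$reads$sequence %in% all_windows))
})

test_that("mitochondrial read shares follow the biomass-weighting model", {
  # two species, biomass ratio 3:1, equal mito fraction: realized ratio
  # within 3 binomial SDs of 3:1
  lib <- data.frame(species_id = c("a", "b"),
                    sequence = c(with_seed(1, random_dna(2000)),
                                 with_seed(2, random_dna(2000))),
                    achieved_length = 2000L, stringsAsFactors = FALSE)
  meta <- data.frame(species_id = c("a", "b"), mito_fraction = 0.5,
                     biomass_per_individual = c(3, 1))
  sim <- simulate_bulk_sample(lib, meta, c(a = 1L, b = 1L),
                              total_reads = 50000, seed = 17)
  n <- sim$expected$realized_reads
  p <- 0.75
  n_mito <- sum(n)
  sd3 <- 3 * sqrt(n_mito * p * (1 - p))
  expect_lt(abs(n[1] - p * n_mito), sd3)

  # chi-square goodness of fit of per-source counts aggregated over 20 seeds
  obs <- c(0, 0, 0)
  for (s in 1:20) {
    sim_s <- simulate_bulk_sample(lib, meta, c(a = 1L, b = 1L),
                                  total_reads = 2000, seed = 100 + s)
    obs <- obs + c(sim_s$expected$realized_reads,
                   sum(sim_s$reads$origin == "nuclear"))
  }
  w <- c(3 * 0.5, 1 * 0.5, 3 * 0.5 + 1 * 0.5) / 4
  gof <- suppressWarnings(chisq.test(obs, p = w))
  expect_gt(gof$p.value, 0.001)
})

test_that("contamination injection appends exactly the requested reads", {
  lm <- small_library
  counts <- c(sp01 = 5L)
  sim <- simulate_bulk_sample(lm$library, lm$meta, counts,
                              total_reads = 2000, seed = 3)
  expect_identical(inject_contamination(sim$reads, lm$library, "sp02", 0),
                   sim$reads)
  out <- inject_contamination(sim$reads, lm$library, "sp02", 100, seed = 4)
  expect_equal(nrow(out), 2100L)
  expect_equal(sum(out$origin == "contam:sp02"), 100L)
  expect_error(inject_contamination(sim$reads, lm$library, "spXX", 5),
               "not in library")
})

test_that("a realistic contaminant dose stays below the detection threshold", {
  # spec-level arithmetic: coverage ~ 1 - exp(-n L_read / L_ref) < 0.10
  # needs n < 16.9 reads on a 16 kb reference at 100 bp
  expect_lt(expected_coverage(16, 100, 16000), 0.10)
  expect_gt(expected_coverage(17, 100, 16000), 0.10)
  # a 0.5% whole-tissue carry-over at 5e4 reads and the largest mitochondrial
  # fraction in the study range gives at most ~3 mitochondrial reads
  expect_lt(0.005 * 50000 * 0.01319, 16)
})
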