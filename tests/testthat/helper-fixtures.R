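# Shared fixtures, built once per test run. Small reference libraries keep
# the exhaustive-scan oracle affordable; full-size libraries are used only
# where the property under test depends on scale.

small_library <- simulate_reference_library(
  n_species = 5, length_range = c(2000, 2400), seed = 42
)

tiny_refs <- data.frame(
  species_id = c("refA", "refB"),
  sequence = c(
    paste0(strrep("ACGT", 50), strrep("GGCA", 25), strrep("TTAC", 25)),
    with_seed(7, random_dna(400))
  ),
  stringsAsFactors = FALSE
)
tiny_refs$achieved_length <- nchar(tiny_refs$sequence)

# draw n error-free reads from one reference (circular, both strands)
draw_reads <- function(ref_seq, n, read_length = 100, seed = 1) {
  with_seed(seed, {
    starts <- sample.int(nchar(ref_seq), n, replace = TRUE)
    w <- circular_window(ref_seq, starts, read_length)
    minus <- sample(c(FALSE, TRUE), n, replace = TRUE)
    w[minus] <- revcomp_dna(w[minus])
    w
  })
}

# substitute bases of `read` at 1-based positions (cycling A->C->G->T->A)
mutate_read <- function(read, at) {
  v <- utf8ToInt(read)
  codes <- c(65L, 67L, 71L, 84L)
  v[at] <- codes[(match(v[at], codes) %% 4L) + 1L]
  intToUtf8(v)
}

# minimal mapping_result for profile-level tests
fake_mapping <- function(species_ids, raw_reads, depths) {
  n <- sum(raw_reads)
  assignments <- data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    status = rep("unique", n),
    reference_id = rep(species_ids, raw_reads),
    position = rep(0L, n), strand = rep("+", n),
    mismatches = rep(0L, n), stringsAsFactors = FALSE
  )
  structure(list(assignments = assignments, depth = depths),
            class = "mapping_result")
}

# logical truth/detected matrices realising given confusion counts on a
# species x sample grid
confusion_grid <- function(tp, fn, fp, n_species = 48, n_samples = 10) {
  stopifnot(tp + fn + fp <= n_species * n_samples)
  truth <- matrix(FALSE, n_species, n_samples,
                  dimnames = list(sprintf("sp%02d", seq_len(n_species)),
                                  sprintf("S%02d", seq_len(n_samples))))
  detected <- truth
  cells <- arrayInd(seq_len(tp + fn + fp), dim(truth))
  truth[cells[seq_len(tp + fn), , drop = FALSE]] <- TRUE
  detected[cells[seq_len(tp), , drop = FALSE]] <- TRUE
  if (fp > 0)
    detected[cells[tp + fn + seq_len(fp), , drop = FALSE]] <- TRUE
  list(truth = truth, detected = detected)
}
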