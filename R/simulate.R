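#' Simulate a reference mitogenome library with species metadata
#'
#' Generates `n_species` circular mitogenome references descended from one
#' random ancestor, each carrying independent per-species substitutions, plus
#' per-species metadata (mitochondrial read fraction, biomass per
#' individual). Achieved lengths are drawn uniformly from `length_range`,
#' emulating incomplete assemblies truncated against a canonical 16 kb
#' target.
#'
#' Substitution sites are placed by stratified (systematic) sampling: one
#' substituted site per consecutive block of `floor(1/min_divergence)`
#' ancestor positions per species. This spreads divergence evenly along the
#' molecule (as purifying selection does in real mitogenomes) and guarantees
#' that every read-length window between two species carries roughly
#' `2 * min_divergence * read_length` differences, keeping cross-species
#' windows far outside the mapper's mismatch budget. The guarantee is
#' verified by a pigeonhole shared-k-mer scan (any cross-species window pair
#' within a 1-mismatch budget must share an exact
#' `floor(read_length/2)`-mer); if the scan finds a shared k-mer the library
#' is regenerated, up to `max_retries` times.
#'
#' Defaults mirror the study design this simulator emulates: 48 reference
#' species, ~16 kb mitogenomes, mitochondrial read fractions spanning
#' 0.005%-1.319% (drawn log-uniformly, since the range covers ~250-fold),
#' and per-individual biomasses drawn log-normally (median 50 mg, sdlog 1 -
#' a realistic spread from small solitary bees to bumblebees).
#'
#' @param n_species number of species (>= 2); default 48.
#' @param length_range integer range of achieved mitogenome lengths (bp);
#'   default `c(15000, 17000)`.
#' @param min_divergence per-site substitution probability applied to each
#'   species relative to the ancestor (pairwise divergence is about twice
#'   this); default 0.05.
#' @param seed integer seed; identical arguments and seed give byte-identical
#'   output.
#' @param mito_fraction_range range of the per-species mitochondrial read
#'   fraction; default `c(5e-5, 0.01319)`.
#' @param biomass_meanlog,biomass_sdlog log-normal parameters for biomass per
#'   individual (mass units, nominally mg).
#' @param read_length read length the separability guarantee is checked for;
#'   default 100.
#' @param max_retries regeneration attempts before giving up; default 5.
#' @return A list with elements `library` (data frame: `species_id`,
#'   `sequence`, `achieved_length`) and `meta` (data frame: `species_id`,
#'   `mito_fraction`, `biomass_per_individual`).
#' @export
simulate_reference_library <- function(n_species = 48,
                                       length_range = c(15000, 17000),
                                       min_divergence = 0.05,
                                       seed = 1,
                                       mito_fraction_range = c(5e-5, 0.01319),
                                       biomass_meanlog = log(50),
                                       biomass_sdlog = 1,
                                       read_length = 100,
                                       max_retries = 5) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be an increasing pair")
  if (length_range[1] < 10 * read_length)
    stop("length_range[1] must be at least 10 * read_length")
  if (min_divergence <= 0 || min_divergence >= 0.5)
    stop("min_divergence must be in (0, 0.5)")
  with_seed(seed, {
    max_len <- as.integer(length_range[2])
    block <- max(2L, as.integer(floor(1 / min_divergence)))
    for (attempt in seq_len(max_retries)) {
      anc <- utf8ToInt(random_dna(max_len))
      lens <- as.integer(round(runif(n_species, length_range[1],
                                     length_range[2])))
      seqs <- character(n_species)
      for (i in seq_len(n_species)) {
        nb <- ceiling(max_len / block)
        sites <- (seq_len(nb) - 1L) * block +
          sample.int(block, nb, replace = TRUE)
        sites <- sites[sites <= max_len]
        mut <- anc
        # substitute to one of the three other bases
        codes <- c(65L, 67L, 71L, 84L)
        cur <- match(mut[sites], codes)
        shift <- sample.int(3L, length(sites), replace = TRUE)
        mut[sites] <- codes[((cur - 1L + shift) %% 4L) + 1L]
        seqs[i] <- substr(intToUtf8(mut), 1L, lens[i])
      }
      if (!.library_windows_collide(seqs, read_length)) {
        lib <- data.frame(
          species_id = sprintf("sp%02d", seq_len(n_species)),
          sequence = seqs,
          achieved_length = lens,
          stringsAsFactors = FALSE
        )
        lf <- log(mito_fraction_range)
        meta <- data.frame(
          species_id = lib$species_id,
          mito_fraction = exp(runif(n_species, lf[1], lf[2])),
          biomass_per_individual = rlnorm(n_species, biomass_meanlog,
                                          biomass_sdlog),
          stringsAsFactors = FALSE
        )
        return(list(library = lib, meta = meta))
      }
    }
    stop("could not generate a library with separable species after ",
         max_retries, " attempts; increase min_divergence")
  })
}

# Pigeonhole screen with exact verification: a cross-species window pair
# within the mismatch budget floor(read_length * 0.01) must share an exact
# block-aligned floor(read_length/2)-mer (forward strand of one species,
# either strand of the other). Shared k-mers are therefore candidates only;
# the two possible generating windows of each shared occurrence pair are
# checked by direct Hamming distance before declaring a collision.
.library_windows_collide <- function(seqs, read_length) {
  k <- max(12L, read_length %/% 2L)
  budget <- floor(read_length * 0.01 + 1e-9)
  n <- length(seqs)
  oriented <- c(seqs, revcomp_dna(seqs))          # 2n oriented sequences
  osp <- rep(seq_len(n), 2L)                      # species of each
  kmers <- vector("list", 2L * n)
  pos <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    L <- nchar(oriented[i])
    kmers[[i]] <- circular_window(oriented[i], seq_len(L), k)
    pos[[i]] <- seq_len(L)
  }
  oidx <- rep(seq_len(2L * n), lengths(kmers))
  kmers <- unlist(kmers, use.names = FALSE)
  pos <- unlist(pos, use.names = FALSE)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  if (!any(dup)) return(FALSE)
  oidx <- oidx[dup]; pos <- pos[dup]; kmers <- kmers[dup]
  groups <- split(seq_along(kmers), kmers)
  ints <- lapply(seq_len(2L * n),
                 function(i) utf8ToInt(circular_window(oriented[i], 1L,
                                                       2L * nchar(oriented[i]))))
  window_int <- function(o, p) {  # circular read_length window as ints
    L <- nchar(oriented[o])
    p0 <- ((p - 1L) %% L) + 1L
    ints[[o]][p0:(p0 + read_length - 1L)]
  }
  for (g in groups) {
    if (length(unique(osp[oidx[g]])) < 2L) next
    occ <- g[seq_len(min(length(g), 20L))]  # cap pathological repeats
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      ia <- occ[a]; ib <- occ[b]
      if (osp[oidx[ia]] >= osp[oidx[ib]]) next
      for (off in c(0L, k)) {
        wa <- window_int(oidx[ia], pos[ia] - off)
        wb <- window_int(oidx[ib], pos[ib] - off)
        if (sum(wa != wb) <= budget) return(TRUE)
      }
    }
  }
  FALSE
}

#' Simulate ground-truth bulk-sample compositions
#'
#' Draws, for each sample, a species count uniform over `species_range` and a
#' bee count uniform over `individuals_range`, then allocates individuals to
#' the drawn species (each present species gets at least one individual; the
#' remainder is multinomial with Dirichlet-distributed probabilities, giving
#' the skewed dominance structure typical of pan-trap catches).
#'
#' @param library_meta list from [simulate_reference_library()] (or a
#'   `library`/`meta` pair).
#' @param n_samples number of bulk samples; default 10.
#' @param species_range range of species per sample; default `c(3, 11)`.
#' @param individuals_range range of individuals per sample; default
#'   `c(13, 51)`.
#' @param dominance Dirichlet concentration for allocating individuals among
#'   the present species (smaller = more dominance); default 0.8.
#' @param n_groups number of landscape groups; samples are assigned to
#'   groups round-robin and each group draws its species from a partially
#'   distinct regional pool (`pool_fraction` of the library), emulating the
#'   between-landscape beta diversity that makes real samples cluster by
#'   region. Default 1 (no structure).
#' @param pool_fraction fraction of the reference species available to each
#'   group's pool when `n_groups > 1`; default 0.6.
#' @param seed integer seed.
#' @return A list with matrices `counts` (species x samples, integers) and
#'   `biomass` (counts times biomass per individual).
#' @export
simulate_truth <- function(library_meta, n_samples = 10,
                           species_range = c(3, 11),
                           individuals_range = c(13, 51),
                           dominance = 0.8, n_groups = 1,
                           pool_fraction = 0.6, seed = 1) {
  meta <- library_meta$meta
  n_sp <- nrow(meta)
  if (species_range[2] > n_sp)
    stop("species_range exceeds the number of reference species")
  if (n_groups > 1 && species_range[2] > floor(n_sp * pool_fraction))
    stop("species_range exceeds the per-group species pool")
  with_seed(seed, {
    pools <- if (n_groups > 1)
      lapply(seq_len(n_groups),
             function(g) sample.int(n_sp, floor(n_sp * pool_fraction)))
    else list(seq_len(n_sp))
    counts <- matrix(0L, nrow = n_sp, ncol = n_samples,
                     dimnames = list(meta$species_id,
                                     sprintf("S%02d", seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      pool <- pools[[((j - 1L) %% length(pools)) + 1L]]
      k <- sample(seq(species_range[1], species_range[2]), 1L)
      n_ind <- sample(seq(individuals_range[1], individuals_range[2]), 1L)
      who <- pool[sample.int(length(pool), k)]
      # Dirichlet weights via gamma draws
      w <- stats::rgamma(k, shape = dominance)
      w <- w / sum(w)
      extra <- stats::rmultinom(1L, n_ind - k, prob = w)[, 1L]
      counts[who, j] <- 1L + extra
    }
    biomass <- counts * meta$biomass_per_individual
    list(counts = counts, biomass = biomass)
  })
}

#' Simulate shotgun reads for one bulk sample
#'
#' Species `i` (with `count_i > 0`) contributes mitochondrial reads with
#' expectation `total_reads * w_i`, where `w_i` is proportional to
#' `biomass_i * mito_fraction_i`, normalised over the present species plus a
#' nuclear-background pseudo-source of weight proportional to
#' `sum(biomass_i * (1 - mito_fraction_i))`. Mitochondrial reads are
#' `read_length` windows drawn uniformly on the circular reference (they may
#' span the origin) on a uniformly chosen strand, with iid per-base
#' substitution errors; nuclear background reads are iid uniform random DNA
#' (unmappable at 99% identity against <= 20 kb references).
#'
#' @param library reference library data frame (`species_id`, `sequence`,
#'   `achieved_length`).
#' @param meta species metadata data frame (`species_id`, `mito_fraction`,
#'   `biomass_per_individual`).
#' @param truth_counts named integer vector of individuals per species for
#'   this sample (names must exist in `library`).
#' @param total_reads total reads to emit; default 50000.
#' @param read_length read length (bp); default 100.
#' @param error_rate iid per-base substitution probability in `[0, 0.05]`;
#'   default 0.002 (post-quality-filter Illumina scale).
#' @param seed integer seed.
#' @return A list with `reads` (data frame `id`, `sequence`, `quality`,
#'   `origin`; `origin` is the generating species or `"nuclear"`) and
#'   `expected` (data frame per species: weight, expected and realized
#'   mitochondrial read counts).
#' @export
simulate_bulk_sample <- function(library, meta, truth_counts,
                                 total_reads = 50000, read_length = 100,
                                 error_rate = 0.002, seed = 1) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  sp <- names(truth_counts)
  if (is.null(sp) || !all(sp %in% library$species_id))
    stop("every truth species must be present in the library")
  if (read_length > min(library$achieved_length))
    stop("read_length exceeds the shortest reference")
  present <- sp[truth_counts > 0]
  li <- match(present, library$species_id)
  mi <- match(present, meta$species_id)
  b <- truth_counts[present] * meta$biomass_per_individual[mi]
  mf <- meta$mito_fraction[mi]
  w_mito <- b * mf
  w_nuc <- sum(b * (1 - mf))
  p <- c(w_mito, w_nuc) / (sum(w_mito) + w_nuc)
  with_seed(seed, {
    n <- rmultinom(1L, total_reads, prob = p)[, 1L]
    n_sp_reads <- n[seq_along(present)]
    n_nuc <- n[length(n)]
    seqs <- vector("list", length(present) + 1L)
    origin <- vector("list", length(present) + 1L)
    for (i in seq_along(present)) {
      ni <- n_sp_reads[i]
      if (ni == 0L) { seqs[[i]] <- character(); origin[[i]] <- character(); next }
      ref <- library$sequence[li[i]]
      L <- library$achieved_length[li[i]]
      starts <- sample.int(L, ni, replace = TRUE)  # 1-based
      reads <- circular_window(ref, starts, read_length)
      minus <- sample(c(FALSE, TRUE), ni, replace = TRUE)
      if (any(minus)) reads[minus] <- revcomp_dna(reads[minus])
      if (error_rate > 0) {
        k <- rbinom(ni, read_length, error_rate)
        for (r in which(k > 0L)) {
          v <- utf8ToInt(reads[r])
          at <- sample.int(read_length, k[r])
          codes <- c(65L, 67L, 71L, 84L)
          cur <- match(v[at], codes)
          v[at] <- codes[((cur - 1L + sample.int(3L, k[r], replace = TRUE))
                          %% 4L) + 1L]
          reads[r] <- intToUtf8(v)
        }
      }
      seqs[[i]] <- reads
      origin[[i]] <- rep.int(present[i], ni)
    }
    if (n_nuc > 0L) {
      pool <- random_dna(n_nuc * read_length)
      starts <- (seq_len(n_nuc) - 1L) * read_length + 1L
      seqs[[length(seqs)]] <- substring(pool, starts,
                                        starts + read_length - 1L)
      origin[[length(origin)]] <- rep.int("nuclear", n_nuc)
    } else {
      seqs[[length(seqs)]] <- character()
      origin[[length(origin)]] <- character()
    }
    seqs <- unlist(seqs, use.names = FALSE)
    origin <- unlist(origin, use.names = FALSE)
    ord <- sample.int(length(seqs))
    reads <- data.frame(
      id = sprintf("read%06d", seq_along(seqs)),
      sequence = seqs[ord],
      quality = strrep("I", read_length),
      origin = origin[ord],
      stringsAsFactors = FALSE
    )
    expected <- data.frame(
      species_id = present,
      weight = p[seq_along(present)],
      expected_reads = total_reads * p[seq_along(present)],
      realized_reads = n_sp_reads,
      stringsAsFactors = FALSE
    )
    list(reads = reads, expected = expected)
  })
}

#' Inject cross-sample contamination reads
#'
#' Appends `n_reads` error-free read-length windows from a named library
#' species (emulating tissue carry-over between samples) and reshuffles the
#' read order deterministically. Contaminant carry-over is whole-tissue DNA,
#' so a realistic mitochondrial dose for a sample of `N` reads is about
#' `0.005 * N * mito_fraction` reads - a handful, which is what keeps
#' contaminant coverage far below the 10% detection threshold.
#'
#' @param reads read data frame (as from [simulate_bulk_sample()]).
#' @param library reference library data frame.
#' @param species_id contaminating species (must be in the library).
#' @param n_reads number of contaminant reads (>= 0).
#' @param seed integer seed.
#' @param read_length read length; defaults to the width of the first read.
#' @return The augmented read data frame; contaminant rows have
#'   `origin == paste0("contam:", species_id)`.
#' @export
inject_contamination <- function(reads, library, species_id, n_reads,
                                 seed = 1,
                                 read_length = nchar(reads$sequence[1])) {
  if (!species_id %in% library$species_id)
    stop("species not in library: ", species_id)
  if (n_reads == 0) return(reads)
  i <- match(species_id, library$species_id)
  with_seed(seed, {
    starts <- sample.int(library$achieved_length[i], n_reads, replace = TRUE)
    win <- circular_window(library$sequence[i], starts, read_length)
    minus <- sample(c(FALSE, TRUE), n_reads, replace = TRUE)
    if (any(minus)) win[minus] <- revcomp_dna(win[minus])
    extra <- data.frame(
      id = sprintf("contam%04d", seq_len(n_reads)),
      sequence = win,
      quality = strrep("I", read_length),
      origin = rep.int(paste0("contam:", species_id), n_reads),
      stringsAsFactors = FALSE
    )
    out <- rbind(reads, extra)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Simulate a complete study fixture
#'
#' Convenience wrapper: reference library + metadata, ground-truth
#' compositions for `n_samples` bulk samples, and shotgun reads per sample,
#' with optional cross-sample contamination. All randomness flows from
#' `seed` (per-stage seeds are derived from it).
#'
#' @param seed master integer seed.
#' @param n_species,n_samples library and study sizes (defaults 48 and 10).
#' @param total_reads reads per sample; default 50000.
#' @param read_length read length; default 100.
#' @param error_rate per-base substitution error rate; default 0.002.
#' @param contamination logical; if `TRUE` each sample receives a small
#'   error-free read dose (`0.005 * total_reads * mito_fraction`, at least
#'   one read) from one absent species.
#' @param species_range,individuals_range per-sample composition ranges,
#'   passed to [simulate_truth()]; defaults `c(3, 11)` species and
#'   `c(13, 51)` individuals.
#' @param n_groups landscape groups for [simulate_truth()]; default 1.
#' @param ... passed to [simulate_reference_library()].
#' @return A list: `library`, `meta`, `truth` (counts/biomass matrices),
#'   `samples` (per-sample read sets), `contaminants` (named character
#'   vector of injected species per sample, if any).
#' @export
simulate_study <- function(seed = 1, n_species = 48, n_samples = 10,
                           total_reads = 50000, read_length = 100,
                           error_rate = 0.002, contamination = FALSE,
                           species_range = c(3, 11),
                           individuals_range = c(13, 51), n_groups = 1, ...) {
  base <- as.integer(seed) %% 1000000L
  lm <- simulate_reference_library(n_species = n_species, seed = base + 1L,
                                   read_length = read_length, ...)
  truth <- simulate_truth(lm, n_samples = n_samples, seed = base + 2L,
                          species_range = species_range,
                          individuals_range = individuals_range,
                          n_groups = n_groups)
  samples <- vector("list", n_samples)
  names(samples) <- colnames(truth$counts)
  contams <- character(0)
  for (j in seq_len(n_samples)) {
    sim <- simulate_bulk_sample(lm$library, lm$meta, truth$counts[, j],
                                total_reads = total_reads,
                                read_length = read_length,
                                error_rate = error_rate,
                                seed = base + 10L + j)
    if (contamination) {
      absent <- lm$library$species_id[truth$counts[, j] == 0L]
      pick <- with_seed(base + 100L + j, sample(absent, 1L))
      mf <- lm$meta$mito_fraction[match(pick, lm$meta$species_id)]
      dose <- max(1L, as.integer(round(0.005 * total_reads * mf)))
      sim$reads <- inject_contamination(sim$reads, lm$library, pick, dose,
                                        seed = base + 200L + j,
                                        read_length = read_length)
      contams[names(samples)[j]] <- pick
    }
    samples[[j]] <- sim
  }
  list(library = lm$library, meta = lm$meta, truth = truth,
       samples = samples, contaminants = contams)
}

#' Expected coverage fraction from a read count
#'
#' Under uniform random placement of `n` reads of length `read_length` on a
#' circle of length `ref_length`, the expected fraction of covered positions
#' is `1 - exp(-n * read_length / ref_length)` (Poisson approximation).
#'
#' @param n number of reads.
#' @param read_length read length (bp).
#' @param ref_length reference length (bp).
#' @return Expected coverage fraction in `[0, 1)`.
#' @export
expected_coverage <- function(n, read_length, ref_length) {
  1 - exp(-n * read_length / ref_length)
}
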