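#' Detection configuration
#'
#' @param coverage_threshold coverage fraction above which (strictly) a
#'   species is called present; default 0.10. The threshold is strict
#'   because presence is defined as coverage *greater than* the cutoff; a
#'   coverage of exactly 0.10 is called absent. Empirically the calls are
#'   insensitive to moderate threshold increases: true detections sit far
#'   above the cutoff, contaminant coverage far below.
#' @param canonical_length canonical complete mitogenome length used as the
#'   normalisation target; default 16000 bp.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(coverage_threshold = 0.10,
                             canonical_length = 16000) {
  if (coverage_threshold <= 0 || coverage_threshold >= 1)
    stop("coverage_threshold must be in (0, 1)")
  if (canonical_length <= 0) stop("canonical_length must be positive")
  structure(list(coverage_threshold = coverage_threshold,
                 canonical_length = canonical_length),
            class = "detection_config")
}

#' Fraction of reference positions covered by at least one read
#'
#' @param depth integer/numeric depth vector (length >= 1).
#' @return Proportion of positions with depth >= 1, in `[0, 1]`.
#' @export
coverage_fraction <- function(depth) {
  if (length(depth) < 1L) stop("depth vector must have length >= 1")
  mean(depth >= 1)
}

#' Normalise mapped read counts by mitogenome length and mitonuclear ratio
#'
#' Mapped reads per species and sample are divided by
#' `achieved_length / canonical_length` to give a length-normalised read
#' number (species with incomplete reference assemblies would otherwise be
#' undercounted), then divided by the species' mitochondrial read fraction
#' to correct for species-level differences in mitonuclear ratio.
#'
#' @param raw_reads raw uniquely-mapped read count(s), >= 0.
#' @param achieved_length achieved mitogenome length(s), > 0 (bp).
#' @param mito_fraction mitochondrial read fraction(s) in (0, 1].
#' @param canonical_length canonical mitogenome length; default 16000.
#' @return Data frame with columns `normalized` and `corrected`.
#' @export
normalize_reads <- function(raw_reads, achieved_length, mito_fraction,
                            canonical_length = 16000) {
  if (any(achieved_length <= 0)) stop("achieved_length must be positive")
  if (any(mito_fraction <= 0) || any(mito_fraction > 1))
    stop("mito_fraction must be in (0, 1]")
  normalized <- raw_reads / (achieved_length / canonical_length)
  data.frame(normalized = normalized,
             corrected = normalized / mito_fraction)
}

#' Build the species-by-sample profile table
#'
#' Turns per-sample mapping results into the central profile: one row per
#' (species, sample) over the FULL reference library - species never seen in
#' a sample appear as explicit zero rows, which the confusion matrix needs
#' as true negatives. Coverage is computed from uniquely mapped reads only,
#' over the achieved reference length.
#'
#' @param mappings named list of `mapping_result` objects, one per sample
#'   (names are sample ids).
#' @param library reference library data frame (`species_id`,
#'   `achieved_length`).
#' @param meta species metadata data frame (`species_id`, `mito_fraction`).
#' @param config a [detection_config()].
#' @return A data frame of class `profile_table` with columns `species_id`,
#'   `sample_id`, `raw_reads`, `coverage_fraction`, `normalized_reads`,
#'   `corrected_reads`, `present`.
#' @export
profile_table <- function(mappings, library, meta,
                          config = detection_config()) {
  stopifnot(is.list(mappings), !is.null(names(mappings)))
  rows <- lapply(names(mappings), function(sid) {
    mr <- mappings[[sid]]
    stopifnot(inherits(mr, "mapping_result"))
    a <- mr$assignments
    uq <- a[a$status == "unique", , drop = FALSE]
    raw <- vapply(library$species_id,
                  function(s) sum(uq$reference_id == s), 0L)
    cov <- vapply(library$species_id, function(s) {
      d <- mr$depth[[s]]
      if (is.null(d)) stop("mapping result lacks depth for ", s)
      coverage_fraction(d)
    }, 0)
    mf <- meta$mito_fraction[match(library$species_id, meta$species_id)]
    norm <- normalize_reads(raw, library$achieved_length, mf,
                            config$canonical_length)
    data.frame(species_id = library$species_id, sample_id = sid,
               raw_reads = as.integer(raw), coverage_fraction = cov,
               normalized_reads = norm$normalized,
               corrected_reads = norm$corrected,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- call_detections(out, config)
  class(out) <- c("profile_table", "data.frame")
  out
}

#' Call species presence from coverage fractions
#'
#' Presence is strict: `present <=> coverage_fraction > threshold`.
#'
#' @param profile profile data frame with a `coverage_fraction` column.
#' @param config a [detection_config()].
#' @return The profile with a (re)computed logical `present` column.
#' @export
call_detections <- function(profile, config = detection_config()) {
  stopifnot("coverage_fraction" %in% names(profile))
  profile$present <- profile$coverage_fraction > config$coverage_threshold
  profile
}

#' Per-sample read frequencies
#'
#' @param profile a `profile_table`.
#' @param value which read column to normalise; default `"corrected_reads"`.
#' @return A species x samples matrix of frequencies; each column sums to 1.
#'   A sample whose reads are all zero is an error.
#' @export
read_frequencies <- function(profile, value = c("corrected_reads",
                                                "normalized_reads",
                                                "raw_reads")) {
  value <- match.arg(value)
  m <- profile_matrix(profile, value)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero reads: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  sweep(m, 2L, tot, "/")
}

#' Extract a species-by-sample matrix from a profile table
#'
#' @param profile a `profile_table`.
#' @param value column to spread; default `"raw_reads"`.
#' @return A species x samples matrix.
#' @export
profile_matrix <- function(profile, value = "raw_reads") {
  stopifnot(value %in% names(profile))
  sp <- unique(profile$species_id)
  sa <- unique(profile$sample_id)
  m <- matrix(0, nrow = length(sp), ncol = length(sa),
              dimnames = list(sp, sa))
  m[cbind(match(profile$species_id, sp), match(profile$sample_id, sa))] <-
    profile[[value]]
  m
}

#' Presence/absence matrix from a profile table
#'
#' @param profile a `profile_table` with `present` calls.
#' @return A logical species x samples matrix.
#' @export
presence_matrix <- function(profile) {
  profile_matrix(profile, "present") > 0
}
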