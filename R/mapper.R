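#' Build a read-mapping index over a reference library
#'
#' Constructs an exact-seed index over every start position of each
#' circularised reference (logically extended by `read_length - 1` wrap
#' bases). Seed length is chosen by the pigeonhole principle so that any
#' full-length alignment within the mismatch budget
#' `floor(read_length * max_mismatch_rate)` contains at least one exact
#' seed. Minus-strand hits are found by searching the reverse complement of
#' each read, so reported positions are always on the forward strand of the
#' circle.
#'
#' @param library reference library data frame (`species_id`, `sequence`) or
#'   a named character vector of sequences.
#' @param read_length nominal read length the index is tuned for; default
#'   100. Reads of other lengths are still mapped (the budget is recomputed
#'   per read; reads too short for the seeding guarantee fall back to a full
#'   scan).
#' @param max_mismatch_rate maximum mismatch rate; default 0.01, i.e. the
#'   "100% read coverage at 99% identity" mapping criterion.
#' @return An object of class `mito_index`.
#' @export
build_index <- function(library, read_length = 100, max_mismatch_rate = 0.01) {
  if (is.data.frame(library)) {
    seqs <- library$sequence
    ids <- library$species_id %||% library$id
  } else {
    seqs <- unname(library)
    ids <- names(library)
  }
  if (is.null(ids) || anyDuplicated(ids))
    stop("references must have unique ids")
  if (length(seqs) == 0L || any(!nzchar(seqs)))
    stop("references must be non-empty")
  m <- floor(read_length * max_mismatch_rate + 1e-9)
  if (read_length < 2 * (m + 1))
    stop("read_length must be at least 2 * (max_mismatches + 1)")
  ptr <- .mapper_build_index(toupper(seqs), ids, as.integer(read_length),
                             max_mismatch_rate)
  structure(list(ptr = ptr, reference_id = ids,
                 length = nchar(seqs),
                 read_length = as.integer(read_length),
                 max_mismatch_rate = max_mismatch_rate),
            class = "mito_index")
}

#' @export
print.mito_index <- function(x, ...) {
  cat("mito_index:", length(x$reference_id), "references,",
      "read_length", x$read_length,
      sprintf("(budget %d mismatches)\n",
              floor(x$read_length * x$max_mismatch_rate + 1e-9)))
  invisible(x)
}

# diagnostic: number of indexed locations of an exact seed
index_seed_hits <- function(index, seed) {
  stopifnot(inherits(index, "mito_index"))
  .mapper_seed_hits(index$ptr, seed)
}

.assignment_frame <- function(ids, raw, index) {
  status <- c("unique", "multi_reference", "unmapped")[raw$status + 1L]
  data.frame(
    read_id = ids,
    status = status,
    reference_id = ifelse(is.na(raw$ref), NA_character_,
                          index$reference_id[raw$ref]),
    position = raw$position,
    strand = raw$strand,
    mismatches = raw$mismatches,
    stringsAsFactors = FALSE
  )
}

#' Map a single read
#'
#' A hit is a full-length ungapped alignment with at most
#' `floor(read_length * max_mismatch_rate)` mismatches (N counts as a
#' mismatch at every position, in read and reference alike). Status is
#' `unique` when all hits lie on one reference (repeats within a reference
#' still count as unique to that species), `multi_reference` when hits span
#' two or more references, `unmapped` otherwise. The reported hit is the
#' best one: fewest mismatches, then smallest position, then `+` strand.
#'
#' @param read a single read sequence.
#' @param index a `mito_index` from [build_index()].
#' @return One-row assignment data frame (`read_id`, `status`,
#'   `reference_id`, `position` 0-based on the circle, `strand`,
#'   `mismatches`).
#' @export
map_read <- function(read, index) {
  stopifnot(inherits(index, "mito_index"), length(read) == 1L)
  raw <- .mapper_map_reads(index$ptr, toupper(read), FALSE)
  .assignment_frame("read", raw, index)
}

#' Map a read set and accumulate per-base depth
#'
#' Depth is incremented only for uniquely assigned reads, at their best hit,
#' with circular wrap-around; total depth on a reference always equals read
#' length times the number of unique reads assigned to it.
#'
#' @param reads character vector of read sequences, or a data frame with
#'   columns `id` and `sequence` (e.g. from [read_fastq()] or
#'   [simulate_bulk_sample()]).
#' @param index a `mito_index` from [build_index()].
#' @return An object of class `mapping_result`: list with `assignments`
#'   (data frame, input order preserved) and `depth` (named list of integer
#'   vectors, one per reference, length = achieved length).
#' @export
map_reads <- function(reads, index) {
  stopifnot(inherits(index, "mito_index"))
  if (is.data.frame(reads)) {
    ids <- reads$id
    seqs <- reads$sequence
  } else {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    seqs <- unname(reads)
  }
  raw <- .mapper_map_reads(index$ptr, toupper(seqs), TRUE)
  depth <- raw$depth
  names(depth) <- index$reference_id
  structure(list(assignments = .assignment_frame(ids, raw, index),
                 depth = depth),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  tab <- table(factor(x$assignments$status,
                      levels = c("unique", "multi_reference", "unmapped")))
  cat("mapping_result:", nrow(x$assignments), "reads (",
      tab[["unique"]], "unique,", tab[["multi_reference"]], "multi,",
      tab[["unmapped"]], "unmapped )\n")
  invisible(x)
}

#' Exhaustive-scan reference oracle for read mapping
#'
#' Same contract as [map_read()], computed by brute force over every
#' position, strand and reference, in plain R. Intended as an independent
#' oracle on small instances; it shares no code with the indexed mapper.
#'
#' @param read a single read sequence.
#' @param library reference library data frame (`species_id`, `sequence`).
#' @param max_mismatch_rate maximum mismatch rate; default 0.01.
#' @return One-row assignment data frame as in [map_read()].
#' @export
brute_force_map <- function(read, library, max_mismatch_rate = 0.01) {
  read <- toupper(read)
  L <- nchar(read)
  budget <- floor(L * max_mismatch_rate + 1e-9)
  acgt <- c(65L, 67L, 71L, 84L)
  hits <- list()
  for (r in seq_len(nrow(library))) {
    ref <- toupper(library$sequence[r])
    P <- nchar(ref)
    if (L > P) next
    ext <- utf8ToInt(paste0(ref, substr(ref, 1L, L - 1L)))
    for (strand in c("+", "-")) {
      s <- utf8ToInt(if (strand == "+") read else revcomp_dna(read))
      mm <- integer(P)
      for (j in seq_len(L)) {
        slice <- ext[j:(j + P - 1L)]
        mm <- mm + as.integer(slice != s[j] | !(s[j] %in% acgt) |
                                !(slice %in% acgt))
      }
      ok <- which(mm <= budget)
      for (p in ok)
        hits[[length(hits) + 1L]] <-
          list(ref = r, pos = p - 1L, strand = strand, mm = mm[p])
    }
  }
  if (length(hits) == 0L)
    return(data.frame(read_id = "read", status = "unmapped",
                      reference_id = NA_character_, position = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_,
                      stringsAsFactors = FALSE))
  refs <- vapply(hits, `[[`, 0L, "ref")
  if (length(unique(refs)) > 1L)
    return(data.frame(read_id = "read", status = "multi_reference",
                      reference_id = NA_character_, position = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_,
                      stringsAsFactors = FALSE))
  mmv <- vapply(hits, `[[`, 0L, "mm")
  posv <- vapply(hits, `[[`, 0L, "pos")
  strv <- vapply(hits, `[[`, "", "strand")
  ord <- order(mmv, posv, strv)  # "+" < "-" alphabetically
  b <- ord[1]
  data.frame(read_id = "read", status = "unique",
             reference_id = library$species_id[refs[b]],
             position = posv[b], strand = strv[b], mismatches = mmv[b],
             stringsAsFactors = FALSE)
}
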