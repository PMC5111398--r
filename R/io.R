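#' Read a FASTA file
#'
#' Strict reader for the pipeline's reference libraries. Sequences may be
#' wrapped over any number of lines; lower-case bases are upper-cased so the
#' package works with one canonical alphabet. Rejections carry a location:
#' duplicate record ids are reported by id, and characters outside
#' A/C/G/T/N (either case) by line number.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @return A data frame with columns `id` and `sequence` (upper-case,
#'   alphabet A/C/G/T/N), one row per record, in file order. Zero rows for an
#'   empty file.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    if (any(nzchar(trimws(lines))))
      stop("not a FASTA file (no '>' header): ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(nzchar(trimws(lines[seq_len(headers[1] - 1L)]))))
    stop("sequence data before first '>' header in ", path)
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)  # id is the first token of the header
  if (any(!nzchar(ids))) stop("empty FASTA record id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  ends <- c(headers[-1] - 1L, length(lines))
  seqs <- character(length(headers))
  for (i in seq_along(headers)) {
    block <- headers[i] + seq_len(ends[i] - headers[i])
    body <- lines[block]
    bad <- grepl("[^ACGTNacgtn]", body)
    if (any(bad))
      stop("invalid sequence character at line ", block[which(bad)[1]],
           " of ", path)
    seqs[i] <- toupper(paste0(body, collapse = ""))
  }
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = 70L)
    writeLines(substring(s, starts, starts + 69L), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line records (Sanger phred+33 qualities). The quality string of each
#' record must match its sequence length; a truncated final record is an
#' error.
#'
#' @param path path to a FASTQ file (plain text or gzip).
#' @return A data frame with columns `id`, `sequence` (upper-cased) and
#'   `quality`, in file order.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ file (", length(lines),
         " lines is not a multiple of 4): ", path)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  at <- lines[seq(1L, by = 4L, length.out = n)]
  if (any(substr(at, 1L, 1L) != "@"))
    stop("malformed FASTQ header (no '@') at record ",
         which(substr(at, 1L, 1L) != "@")[1], " of ", path)
  ids <- sub("\\s.*$", "", substring(at, 2L))
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(plus, 1L, 1L) != "+"))
    stop("malformed FASTQ separator at record ",
         which(substr(plus, 1L, 1L) != "+")[1], " of ", path)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    stop("invalid sequence character in FASTQ record '", ids[which(bad)[1]],
         "' (line ", (which(bad)[1] - 1L) * 4L + 2L, ") of ", path)
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism))
    stop("sequence/quality length mismatch in FASTQ record '",
         ids[which(mism)[1]], "' of ", path)
  data.frame(id = ids, sequence = toupper(seqs), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data frame with columns `id`, `sequence` and `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "quality") %in% names(records)))
  if (any(nchar(records$sequence) != nchar(records$quality)))
    stop("sequence/quality length mismatch in records to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$sequence, "\n+\n",
                    records$quality), con, sep = "\n")
  invisible(path)
}

#' Read a species-by-sample matrix from TSV
#'
#' Canonical table dialect: tab-delimited, UTF-8, `.` decimal. First row
#' holds sample labels, first column species labels. Every cell must parse
#' as a finite non-negative number; ragged or non-numeric rows are rejected
#' with their row index.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix with species as rownames and samples as
#'   colnames. Zero rows/columns are preserved, never dropped.
#' @seealso [write_matrix_tsv()]
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) == 0L) stop("empty table file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_data <- length(header) - 1L
  if (ncol_data < 1L) stop("no sample columns in ", path)
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample label(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- cells[-1]
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_data)
  species <- character(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_data + 1L)
      stop("ragged row ", i, " in ", path, " (expected ", ncol_data + 1L,
           " fields, got ", length(row), ")")
    species[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v) || any(!is.finite(v)))
      stop("non-numeric or non-finite cell in row ", i, " of ", path)
    if (any(v < 0)) stop("negative value in row ", i, " of ", path)
    vals[i, ] <- v
  }
  if (anyDuplicated(species))
    stop("duplicate species label(s): ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  dimnames(vals) <- list(species, samples)
  vals
}

#' Write a species-by-sample matrix as TSV
#'
#' @param table numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(table, path) {
  stopifnot(is.matrix(table), !is.null(rownames(table)),
            !is.null(colnames(table)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("species", colnames(table)), collapse = "\t"), con)
  for (i in seq_len(nrow(table)))
    writeLines(paste(c(rownames(table)[i],
                       format(table[i, ], trim = TRUE, scientific = FALSE,
                              digits = 15)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write per-reference depth vectors as two-column TSV
#'
#' One file per reference would be wasteful for 48 references; the export is
#' a single long-format table (reference, 0-based position, depth).
#'
#' @param depth named list of integer depth vectors (one per reference).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  df <- data.frame(
    reference_id = rep(names(depth), lengths(depth)),
    position = unlist(lapply(depth, function(d) seq_along(d) - 1L),
                      use.names = FALSE),
    depth = unlist(depth, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-read assignments as a minimal SAM-like TSV
#'
#' Columns: read id, status, reference id, 0-based position, strand,
#' mismatch count.
#'
#' @param assignments assignment data frame from [map_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}
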