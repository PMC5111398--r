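#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` (Mersenne-Twister) and
#' restores the caller's RNG state afterwards, so simulation functions are
#' deterministic without side effects on the session.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
#' @examples
#' with_seed(1, runif(2))
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

.DNA_BASES <- c("A", "C", "G", "T")

#' Generate one uniform random DNA string
#' @param n length in bases.
#' @return A single string over ACGT.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna("ACGTN")
revcomp_dna <- function(x) {
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# circular window extraction: seq extended so windows of `len` exist at any
# 1-based start in [1, nchar(seq)]
circular_window <- function(seq, starts, len) {
  L <- nchar(seq)
  ext <- seq
  while (nchar(ext) < L + len - 1) ext <- paste0(ext, seq)
  substring(ext, starts, starts + len - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
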