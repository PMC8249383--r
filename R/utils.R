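#' @useDynLib slocusmod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
NULL

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

#' Reverse-complement a nucleotide string
#'
#' Operates on the T-normalized alphabet \{A,C,G,T,N\}; the complement of N
#' is N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_chars <- function(ch) unname(COMPLEMENT[ch])

reverse_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Normalize raw residues to the internal DNA alphabet
#'
#' Uppercases, converts U to T, and validates that only \{A,C,G,T,N\} remain.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return normalized character vector.
#' @keywords internal
normalize_residues <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (allowed: A,C,G,T,N,U)",
                 what), call. = FALSE)
  }
  x
}

stopifnot_scalar_seq <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("expected a single non-empty nucleotide string", call. = FALSE)
}

## Deterministic per-operation RNG streams: each generator call seeds a local
## stream from (seed, tag) so adding an operation never perturbs another's
## output. The caller's .Random.seed is restored on exit.
tag_offset <- function(tag) {
  v <- utf8ToInt(tag)
  sum(v * seq_along(v)) %% 100000L
}

with_stream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 1000L + tag_offset(tag))
  force(expr)
}

## empty data.frame with given column names/prototypes
empty_df <- function(proto) proto[0L, , drop = FALSE]
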