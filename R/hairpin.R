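#' Structural filter thresholds for hairpin precursor candidates
#'
#' The retained-precursor rules: terminal loop smaller than 40 nt (strict),
#' more than 20 paired stem columns (strict), at most 4 mismatched columns,
#' and at most 2 asymmetric bulges.
#'
#' @param max_terminal_loop exclusive upper bound on loop length (nt).
#' @param min_paired_stem exclusive lower bound on paired stem columns (bp).
#' @param max_mismatches inclusive bound on mismatched (unpaired, ungapped)
#'   columns.
#' @param max_asym_bulges inclusive bound on bulge count (maximal runs of
#'   gap columns).
#' @return a list of class `hairpin_criteria`.
#' @export
hairpin_criteria <- function(max_terminal_loop = 40L, min_paired_stem = 20L,
                             max_mismatches = 4L, max_asym_bulges = 2L) {
  stopifnot(max_terminal_loop > 0, min_paired_stem > 0,
            max_mismatches >= 0, max_asym_bulges >= 0)
  structure(list(max_terminal_loop = as.integer(max_terminal_loop),
                 min_paired_stem = as.integer(min_paired_stem),
                 max_mismatches = as.integer(max_mismatches),
                 max_asym_bulges = as.integer(max_asym_bulges)),
            class = "hairpin_criteria")
}

## per-column classes of an arm-vs-arm alignment; wobble (G:T) counts as
## paired in the RNA-hairpin context
stem_column_classes <- function(aln_left, aln_right) {
  l <- strsplit(aln_left, "", fixed = TRUE)[[1]]
  r <- strsplit(aln_right, "", fixed = TRUE)[[1]]
  if (length(l) != length(r))
    stop("arm alignment strings differ in length", call. = FALSE)
  gap <- l == "-" | r == "-"
  wc <- !gap & l != "N" & r != "N" & r == complement_chars(l)
  wob <- !gap & ((l == "G" & r == "T") | (l == "T" & r == "G"))
  cls <- rep("mismatch", length(l))
  cls[wc | wob] <- "paired"
  cls[gap] <- "gap"
  cls
}

#' Evaluate inverted repeats as hairpin precursor candidates
#'
#' Computes the structural metrics from the arm-vs-arm alignment: paired
#' columns (A:T, G:C, or G:T wobble), mismatched columns, bulges (maximal
#' runs of consecutive gap columns), and the terminal loop length, then
#' applies the filter rules.
#'
#' @param irs data.frame from [find_inverted_repeats()] (needs the
#'   `aln_left`/`aln_right` columns).
#' @param criteria a [hairpin_criteria()] object.
#' @return `irs` augmented with columns paired_len, mismatch_count,
#'   asym_bulge_count, and logical `passes`.
#' @export
evaluate_hairpin <- function(irs, criteria = hairpin_criteria()) {
  if (!all(c("aln_left", "aln_right") %in% names(irs)))
    stop("inverted repeats lack arm alignments", call. = FALSE)
  n <- nrow(irs)
  paired <- integer(n); mism <- integer(n); bulges <- integer(n)
  for (k in seq_len(n)) {
    cls <- stem_column_classes(irs$aln_left[k], irs$aln_right[k])
    paired[k] <- sum(cls == "paired")
    mism[k] <- sum(cls == "mismatch")
    runs <- rle(cls == "gap")
    bulges[k] <- sum(runs$values)
  }
  irs$paired_len <- paired
  irs$mismatch_count <- mism
  irs$asym_bulge_count <- bulges
  irs$passes <- irs$loop_len < criteria$max_terminal_loop &
    paired > criteria$min_paired_stem &
    mism <= criteria$max_mismatches &
    bulges <= criteria$max_asym_bulges
  irs
}

#' Expression of mapped sRNA over inverted-repeat arms
#'
#' Sums mapped read copies (within a size class, 21-24 nt by default)
#' overlapping either arm of each inverted repeat by at least 1 nt.
#'
#' @param irs data.frame from [find_inverted_repeats()].
#' @param mapped data.frame from [map_reads()].
#' @param size_range inclusive read-length bounds counted as expression.
#' @return numeric vector of read copies per inverted repeat.
#' @export
hairpin_expression <- function(irs, mapped, size_range = c(21L, 24L)) {
  n <- nrow(irs)
  out <- numeric(n)
  if (nrow(mapped) == 0L || n == 0L) return(out)
  len <- nchar(mapped$seq)
  sel <- len >= size_range[1] & len <= size_range[2]
  m <- mapped[sel, , drop = FALSE]
  for (k in seq_len(n)) {
    if (nrow(m) == 0L) next
    onseq <- m$seq_id == irs$seq_id[k]
    ov <- onseq & ((m$start <= irs$left_end[k] & m$end >= irs$left_start[k]) |
                     (m$start <= irs$right_end[k] & m$end >= irs$right_start[k]))
    out[k] <- sum(m$count[ov])
  }
  out
}

#' Screen inverted repeats for expressed hairpin precursors
#'
#' Ordered pipeline: the sRNA expression screen first (read copies over the
#' arms must reach `min_expression`), then the structural hairpin filter.
#' Retained candidates satisfy both.
#'
#' @param irs data.frame from [find_inverted_repeats()].
#' @param criteria a [hairpin_criteria()] object.
#' @param expression numeric vector of per-repeat read copies, e.g. from
#'   [hairpin_expression()]. Must have one value per row of `irs`.
#' @param min_expression minimum read copies for a repeat to count as
#'   expressed.
#' @return `irs` augmented with the structural metrics and logical columns
#'   `expressed`, `passes`, `retained`.
#' @export
screen_candidates <- function(irs, criteria = hairpin_criteria(),
                              expression, min_expression = 5) {
  if (length(expression) != nrow(irs))
    stop("expression track does not match inverted repeats (",
         length(expression), " values for ", nrow(irs), " repeats)",
         call. = FALSE)
  irs$expression <- as.numeric(expression)
  irs$expressed <- irs$expression >= min_expression
  irs <- evaluate_hairpin(irs, criteria)
  irs$retained <- irs$expressed & irs$passes
  irs
}

#' Export retained precursors as GFF3
#'
#' @param screened data.frame from [screen_candidates()].
#' @param path output path.
#' @param seq_lengths optional named lengths for bounds checking.
#' @return `path`, invisibly.
#' @export
write_precursor_gff3 <- function(screened, path, seq_lengths = NULL) {
  kept <- screened[screened$retained, , drop = FALSE]
  feats <- data.frame(seq_id = kept$seq_id, start = kept$left_start,
                      end = kept$right_end, strand = "+",
                      type = "sRNA_precursor", score = kept$score,
                      attributes = sprintf(
                        "ID=precursor%d;expression=%g;paired_len=%d",
                        seq_len(nrow(kept)), kept$expression, kept$paired_len))
  write_gff3(feats, path, seq_lengths)
}
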