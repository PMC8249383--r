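#' Scoring parameters for inverted-repeat detection
#'
#' Defaults are the einverted-style parameter set used for S-locus precursor
#' discovery: match +4, mismatch -4, gap -8 per gapped column (linear, not
#' affine), minimum alignment score 50, and a maximum repeat span (left arm
#' start to right arm end) of 350 nt.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap per-gapped-column score (negative).
#' @param min_score minimum reported alignment score.
#' @param max_span maximum span, left-arm start through right-arm end, in nt.
#' @return a list of class `ir_params`.
#' @export
ir_params <- function(match = 4L, mismatch = -4L, gap = -8L,
                      min_score = 50L, max_span = 350L) {
  stopifnot(match > 0, mismatch < 0, gap < 0, min_score > 0, max_span >= 2)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), min_score = as.integer(min_score),
                 max_span = as.integer(max_span)),
            class = "ir_params")
}

## greedy reduction of overlapping reports to local maxima:
## keep highest score; ties -> smaller span, then leftmost left arm,
## then leftmost right arm
select_ir_candidates <- function(df) {
  if (nrow(df) == 0L) return(df)
  df$span <- df$right_end - df$left_start + 1L
  ## drop exact duplicates (overlapping windows re-report the same repeat)
  key <- paste(df$left_start, df$left_end, df$right_start, df$right_end)
  df <- df[!duplicated(key), , drop = FALSE]
  ord <- order(-df$score, df$span, df$left_start, df$left_end, df$right_start)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  ks <- integer(0); ke <- integer(0)   # kept arm intervals
  for (k in seq_len(nrow(df))) {
    s <- c(df$left_start[k], df$right_start[k])
    e <- c(df$left_end[k], df$right_end[k])
    clash <- FALSE
    if (length(ks)) {
      for (a in 1:2) {
        if (any(s[a] <= ke & e[a] >= ks)) { clash <- TRUE; break }
      }
    }
    if (!clash) {
      keep[k] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  df[keep, , drop = FALSE]
}

#' Find inverted repeats in a locus sequence
#'
#' Detects inverted repeats by local alignment of the sequence against its
#' own reverse complement (banded by the span constraint), in the style of
#' EMBOSS einverted. Arm complementarity is strict Watson-Crick (A:T, G:C);
#' G:T counts as a mismatch here — wobble pairing enters only in the
#' RNA-context hairpin evaluation and target scoring. Overlapping reports are
#' reduced to local maxima (highest score; ties broken by smaller span, then
#' leftmost start).
#'
#' @param seq a single nucleotide string, or a one-element named vector as
#'   returned by [read_fasta()].
#' @param params an [ir_params()] object.
#' @param seq_id sequence label for the output (defaults to the name of
#'   `seq`, else "seq").
#' @return data.frame with columns seq_id, left_start, left_end, right_start,
#'   right_end, loop_len, span, score, aln_left, aln_right. The alignment
#'   strings are the two arms written so that column k of `aln_left` (5'->3')
#'   pairs with column k of `aln_right` (the right arm 3'->5'); `-` marks a
#'   gapped column. Ordered by (left_start, score desc).
#' @export
find_inverted_repeats <- function(seq, params = ir_params(), seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- unname(seq[[1]])
  stopifnot_scalar_seq(seq)
  seq <- normalize_residues(seq, "locus sequence")
  if (nchar(seq) < 2L) stop("sequence length must be >= 2", call. = FALSE)
  n <- nchar(seq)
  scan <- function(s) {
    .ir_scan_cpp(s, params$match, params$mismatch, params$gap,
                 params$min_score, params$max_span)
  }
  dedupe <- function(df) {
    df[!duplicated(paste(df$left_start, df$left_end, df$right_start,
                         df$right_end)), , drop = FALSE]
  }
  ## Iterative local-maximum selection: keep the top candidate, hard-mask
  ## its arm footprint, and rescan the affected region so lower-scoring
  ## alternatives sharing DP cells with the winner are recovered. This makes
  ## the reported set identical to a greedy reduction over the exhaustive
  ## arm-pair enumeration.
  work <- strsplit(seq, "", fixed = TRUE)[[1]]
  pool <- dedupe(scan(seq))
  kept <- list()
  ka_s <- integer(0); ka_e <- integer(0)
  repeat {
    if (nrow(pool) == 0L) break
    if (length(ka_s)) {
      ok <- vapply(seq_len(nrow(pool)), function(k) {
        !any((pool$left_start[k] <= ka_e & pool$left_end[k] >= ka_s) |
               (pool$right_start[k] <= ka_e & pool$right_end[k] >= ka_s))
      }, logical(1))
      pool <- pool[ok, , drop = FALSE]
      if (nrow(pool) == 0L) break
    }
    pool$span <- pool$right_end - pool$left_start + 1L
    best <- pool[order(-pool$score, pool$span, pool$left_start,
                       pool$left_end, pool$right_start)[1], , drop = FALSE]
    kept[[length(kept) + 1L]] <- best
    ka_s <- c(ka_s, best$left_start, best$right_start)
    ka_e <- c(ka_e, best$left_end, best$right_end)
    work[c(best$left_start:best$left_end,
           best$right_start:best$right_end)] <- "X"
    lo <- max(1L, best$left_start - params$max_span)
    hi <- min(n, best$right_end + params$max_span)
    pool <- pool[!(pool$left_start >= lo & pool$right_end <= hi), ,
                 drop = FALSE]
    if (hi - lo + 1L >= 2L) {
      res <- scan(paste(work[lo:hi], collapse = ""))
      if (nrow(res)) {
        res$left_start <- res$left_start + lo - 1L
        res$left_end <- res$left_end + lo - 1L
        res$right_start <- res$right_start + lo - 1L
        res$right_end <- res$right_end + lo - 1L
        pool <- dedupe(rbind(pool[, names(res)], res))
      }
    }
  }
  if (!length(kept)) return(ir_finalize(empty_ir_df(), seq_id))
  out <- do.call(rbind, kept)
  out$span <- out$right_end - out$left_start + 1L
  ir_finalize(out, seq_id)
}

empty_ir_df <- function() {
  data.frame(left_start = integer(0), left_end = integer(0),
             right_start = integer(0), right_end = integer(0),
             score = integer(0), span = integer(0),
             aln_left = character(0), aln_right = character(0))
}

ir_finalize <- function(df, seq_id) {
  if (nrow(df) == 0L) {
    return(data.frame(seq_id = character(0), left_start = integer(0),
                      left_end = integer(0), right_start = integer(0),
                      right_end = integer(0), loop_len = integer(0),
                      span = integer(0), score = integer(0),
                      aln_left = character(0), aln_right = character(0)))
  }
  df$loop_len <- df$right_start - df$left_end - 1L
  df$seq_id <- seq_id
  df <- df[order(df$left_start, -df$score), , drop = FALSE]
  rownames(df) <- NULL
  cols <- c("seq_id", "left_start", "left_end", "right_start", "right_end",
            "loop_len", "span", "score")
  df[, c(cols, intersect(c("aln_left", "aln_right"), names(df))), drop = FALSE]
}

#' Exhaustive inverted-repeat reference finder
#'
#' Independent reference implementation: enumerates every (left arm, right
#' arm) interval pair (arm length capped by `max_arm`), scores each with a
#' global alignment of the left arm against the reverse complement of the
#' right arm under the same linear scoring, and applies the same
#' local-maximum reduction as [find_inverted_repeats()]. Exponentially more
#' work than the scan — intended for verification on short sequences only.
#'
#' @inheritParams find_inverted_repeats
#' @param max_arm maximum arm length enumerated.
#' @return data.frame as [find_inverted_repeats()], without alignment strings.
#' @export
ir_bruteforce <- function(seq, params = ir_params(), seq_id = NULL,
                          max_arm = 20L) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- unname(seq[[1]])
  stopifnot_scalar_seq(seq)
  seq <- normalize_residues(seq, "locus sequence")
  raw <- .ir_enumerate_cpp(seq, params$match, params$mismatch, params$gap,
                           params$min_score, params$max_span,
                           as.integer(max_arm))
  out <- select_ir_candidates(raw)
  ir_finalize(out, seq_id)
}

#' Export inverted repeats as GFF3
#'
#' @param irs data.frame from [find_inverted_repeats()].
#' @param path output path.
#' @param seq_lengths optional named lengths for bounds checking.
#' @return `path`, invisibly.
#' @export
write_ir_gff3 <- function(irs, path, seq_lengths = NULL) {
  feats <- data.frame(seq_id = irs$seq_id, start = irs$left_start,
                      end = irs$right_end, strand = "+",
                      type = "inverted_repeat", score = irs$score,
                      attributes = sprintf(
                        "ID=ir%d;left_end=%d;right_start=%d",
                        seq_len(nrow(irs)), irs$left_end, irs$right_start))
  write_gff3(feats, path, seq_lengths)
}
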