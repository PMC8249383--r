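#' Filter and collapse small-RNA reads
#'
#' Clips a 3' adapter (detected by an exact match of at least 8 nt of the
#' adapter's prefix; the clipped read suffix must itself be a prefix of the
#' adapter), discards reads outside the length window, and collapses
#' identical sequences into (sequence, copy count) entries.
#'
#' @param reads data.frame with columns `seq` and `count`, e.g. from
#'   [read_srna_reads()].
#' @param adapter optional 3' adapter sequence.
#' @param min_len,max_len inclusive retained length bounds (nt).
#' @return data.frame with columns `seq`, `count` (one row per distinct
#'   sequence, ordered by sequence), with attributes `min_len`/`max_len`.
#' @export
filter_reads <- function(reads, adapter = NULL, min_len = 18L, max_len = 27L) {
  seqs <- normalize_residues(reads$seq, "read")
  counts <- if ("count" %in% names(reads)) as.integer(reads$count)
            else rep(1L, length(seqs))
  if (any(counts < 1L)) stop("read copy counts must be >= 1", call. = FALSE)
  if (!is.null(adapter) && nzchar(adapter)) {
    adapter <- normalize_residues(adapter, "adapter")
    if (nchar(adapter) < 8L)
      stop("adapter must be at least 8 nt for prefix matching", call. = FALSE)
    ad8 <- substr(adapter, 1L, 8L)
    for (i in seq_along(seqs)) {
      p <- regexpr(ad8, seqs[i], fixed = TRUE)
      if (p > 0L) {
        tail_seq <- substr(seqs[i], p, nchar(seqs[i]))
        if (tail_seq == substr(adapter, 1L, nchar(tail_seq)))
          seqs[i] <- substr(seqs[i], 1L, p - 1L)
      }
    }
  }
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  seqs <- seqs[keep]; counts <- counts[keep]
  if (!length(seqs)) {
    out <- data.frame(seq = character(0), count = integer(0))
    attr(out, "min_len") <- as.integer(min_len)
    attr(out, "max_len") <- as.integer(max_len)
    return(out)
  }
  agg <- tapply(counts, seqs, sum)
  out <- data.frame(seq = names(agg), count = as.integer(agg))
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_len") <- as.integer(min_len)
  attr(out, "max_len") <- as.integer(max_len)
  out
}

#' Map small-RNA reads to locus sequences
#'
#' Exact or 1-mismatch search of every read (and its reverse complement)
#' against every reference; all equally admissible placements are reported
#' and counted in `n_placements`.
#'
#' @param reads data.frame with columns `seq`, `count` (see [filter_reads()]).
#' @param refs named character vector of reference sequences.
#' @param max_mismatches allowed mismatches per placement (0 or 1).
#' @return data.frame with columns seq, count, seq_id, start, end, strand,
#'   n_placements, ordered by (seq, seq_id, start, strand).
#' @export
map_reads <- function(reads, refs, max_mismatches = 0L) {
  stopifnot(max_mismatches %in% c(0L, 1L))
  refs <- stats::setNames(normalize_residues(unname(unlist(refs)), "reference"),
                          names(refs))
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named", call. = FALSE)
  ref_dna <- lapply(refs, Biostrings::DNAString)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    cnt <- reads$count[i]
    hits <- list()
    for (id in names(ref_dna)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") rd else revcomp(rd)
        m <- Biostrings::matchPattern(pat, ref_dna[[id]],
                                      max.mismatch = max_mismatches)
        if (length(m)) {
          hits[[length(hits) + 1L]] <- data.frame(
            seq = rd, count = cnt, seq_id = id,
            start = BiocGenerics::start(m), end = BiocGenerics::end(m),
            strand = strand)
        }
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      h$n_placements <- nrow(h)
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows)) {
    return(data.frame(seq = character(0), count = integer(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_placements = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$seq, out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantify per-precursor sRNA expression
#'
#' Assigns mapped read copies to every precursor they overlap by at least
#' 1 nt. Multi-placement reads are down-weighted by 1/n_placements by
#' default; `multimapper = "unique"` drops them instead.
#'
#' @param mapped data.frame from [map_reads()].
#' @param precursors data.frame with columns `seq_id`, `start`, `end` and
#'   optionally `id`.
#' @param multimapper "weight" (1/n_placements) or "unique" (drop
#'   n_placements > 1).
#' @return list with `table` (precursor id, coordinates, total_count and
#'   per-length columns len_18..len_27) and `coverage` (per-precursor numeric
#'   vectors of weighted per-position depth).
#' @export
quantify <- function(mapped, precursors, multimapper = c("weight", "unique")) {
  multimapper <- match.arg(multimapper)
  ids <- if ("id" %in% names(precursors)) as.character(precursors$id)
         else sprintf("precursor%d", seq_len(nrow(precursors)))
  if (nrow(mapped) > 0L) {
    if (multimapper == "unique") {
      mapped <- mapped[mapped$n_placements == 1L, , drop = FALSE]
      w <- mapped$count
    } else {
      w <- mapped$count / mapped$n_placements
    }
  } else w <- numeric(0)
  lens <- 18:27
  tab <- data.frame(id = ids, seq_id = precursors$seq_id,
                    start = precursors$start, end = precursors$end,
                    total_count = 0)
  for (l in lens) tab[[sprintf("len_%d", l)]] <- 0
  cov <- vector("list", nrow(precursors))
  names(cov) <- ids
  for (k in seq_len(nrow(precursors))) {
    p_s <- precursors$start[k]; p_e <- precursors$end[k]
    cov_k <- numeric(p_e - p_s + 1L)
    if (nrow(mapped) > 0L) {
      ov <- mapped$seq_id == precursors$seq_id[k] &
        mapped$start <= p_e & mapped$end >= p_s
      if (any(ov)) {
        sub <- mapped[ov, , drop = FALSE]
        wk <- w[ov]
        tab$total_count[k] <- sum(wk)
        rl <- nchar(sub$seq)
        for (l in lens) {
          tab[[sprintf("len_%d", l)]][k] <- sum(wk[rl == l])
        }
        for (r in seq_len(nrow(sub))) {
          a <- max(sub$start[r], p_s) - p_s + 1L
          b <- min(sub$end[r], p_e) - p_s + 1L
          cov_k[a:b] <- cov_k[a:b] + wk[r]
        }
      }
    }
    cov[[k]] <- cov_k
  }
  list(table = tab, coverage = cov)
}

#' Most abundant mapped read over a precursor
#'
#' Picks, per precursor, the mapped read (within a size class) with the
#' highest copy count overlapping the precursor — the expressed-sRNA window
#' carried forward to target prediction. Ties break to the
#' lexicographically smallest sequence.
#'
#' @param mapped data.frame from [map_reads()].
#' @param precursor one row of a precursor data.frame (seq_id plus
#'   start/end, or left_start/right_end as in the screened repeat table).
#' @param size_range inclusive read-length bounds.
#' @return the read sequence, or NA if nothing overlaps.
#' @export
top_expressed_read <- function(mapped, precursor, size_range = c(21L, 24L)) {
  if (nrow(mapped) == 0L) return(NA_character_)
  p_start <- if ("start" %in% names(precursor)) precursor$start
             else precursor$left_start
  p_end <- if ("end" %in% names(precursor)) precursor$end
           else precursor$right_end
  len <- nchar(mapped$seq)
  ov <- mapped$seq_id == precursor$seq_id &
    mapped$start <= p_end & mapped$end >= p_start &
    len >= size_range[1] & len <= size_range[2]
  if (!any(ov)) return(NA_character_)
  sub <- mapped[ov, , drop = FALSE]
  per_seq <- tapply(sub$count, sub$seq, max)
  best <- names(per_seq)[order(-per_seq, names(per_seq))][1]
  best
}
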