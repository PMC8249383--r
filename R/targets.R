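#' Wobble-aware scoring scheme for sRNA-target affinity
#'
#' The modified Smith-Waterman scoring used for dominance-modifier target
#' prediction: match +1, mismatch -1, gap -2 per gapped column, G:U wobble
#' -0.5, with a hit cutoff of 18. Scores are half-integers; they are carried
#' internally as doubled integers so cutoff comparisons are exact.
#'
#' @param match,mismatch,gap,wobble column scores (multiples of 0.5).
#' @param cutoff minimum reported affinity.
#' @param comparator `">="` (default) or `">"` — whether a score exactly at
#'   the cutoff qualifies.
#' @return a list of class `wobble_scheme`.
#' @export
wobble_scheme <- function(match = 1, mismatch = -1, gap = -2, wobble = -0.5,
                          cutoff = 18, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  vals <- c(match, mismatch, gap, wobble, cutoff)
  if (any(vals * 2 != round(vals * 2)))
    stop("scores must be multiples of 0.5", call. = FALSE)
  if (match <= 0 || cutoff <= 0)
    stop("match and cutoff must be positive", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 wobble = wobble, cutoff = cutoff, comparator = comparator),
            class = "wobble_scheme")
}

#' Classify an sRNA/target base pair
#'
#' On the T-normalized alphabet: match for Watson-Crick complements, wobble
#' for G:U pairs (sRNA G against target T, or sRNA T against target G),
#' mismatch otherwise. N never matches or wobbles.
#'
#' @param srna_base,target_base vectors of single bases in \{A,C,G,T,N\}.
#' @return character vector in \{"match", "wobble", "mismatch"\}.
#' @export
pair_class <- function(srna_base, target_base) {
  srna_base <- toupper(srna_base); target_base <- toupper(target_base)
  ok <- srna_base %in% c(DNA_BASES, "N") & target_base %in% c(DNA_BASES, "N")
  if (!all(ok)) stop("non-nucleotide base in pair_class", call. = FALSE)
  n <- pmax(length(srna_base), length(target_base))
  srna_base <- rep_len(srna_base, n); target_base <- rep_len(target_base, n)
  out <- rep("mismatch", n)
  usable <- srna_base != "N" & target_base != "N"
  wc <- usable & target_base == complement_chars(srna_base)
  wob <- usable & ((srna_base == "G" & target_base == "T") |
                     (srna_base == "T" & target_base == "G"))
  out[wc] <- "match"
  out[wob] <- "wobble"
  out
}

## greedy per-strand reduction: best-scoring hit per overlapping cluster,
## ties -> fewer gaps, then leftmost target start
select_target_hits <- function(df) {
  if (nrow(df) == 0L) return(df)
  keep_all <- logical(nrow(df))
  for (std in unique(df$strand)) {
    idx <- which(df$strand == std)
    sub <- df[idx, , drop = FALSE]
    ord <- order(-sub$score, sub$n_gaps, sub$start, sub$end)
    ks <- integer(0); ke <- integer(0)
    for (k in ord) {
      if (!length(ks) || !any(sub$start[k] <= ke & sub$end[k] >= ks)) {
        keep_all[idx[k]] <- TRUE
        ks <- c(ks, sub$start[k]); ke <- c(ke, sub$end[k])
      }
    }
  }
  df[keep_all, , drop = FALSE]
}

#' Scan a locus for sRNA target sites
#'
#' Local alignment of the sRNA (5'->3') against the target transcript read
#' 3'->5', on both target strands, under the wobble-aware scheme. A hit on
#' the + strand means the sRNA hybridizes to the + strand transcript.
#' Overlapping local optima are reduced to the maximal-scoring hit per
#' cluster (ties: fewer gaps, then leftmost target start).
#'
#' @param srna sRNA sequence, 18-27 nt by default.
#' @param target a single nucleotide string or one-element named vector.
#' @param scheme a [wobble_scheme()] object.
#' @param srna_id,target_id labels for the output.
#' @param srna_len_bounds inclusive accepted sRNA length range.
#' @return data.frame with columns srna_id, seq_id, start, end, strand,
#'   score, n_gaps, pairing (per-column codes along the sRNA 5'->3':
#'   m = match, w = wobble, x = mismatch, g = gap).
#' @export
scan_targets <- function(srna, target, scheme = wobble_scheme(),
                         srna_id = "sRNA", target_id = NULL,
                         srna_len_bounds = c(18L, 27L)) {
  if (is.null(target_id))
    target_id <- if (!is.null(names(target))) names(target)[1] else "target"
  target <- unname(target[[1]])
  stopifnot_scalar_seq(target)
  srna <- normalize_residues(unname(srna[[1]]), "sRNA")
  target <- normalize_residues(target, "target")
  if (nchar(srna) < srna_len_bounds[1] || nchar(srna) > srna_len_bounds[2])
    stop(sprintf("sRNA length must be within %d-%d nt", srna_len_bounds[1],
                 srna_len_bounds[2]), call. = FALSE)
  m2 <- as.integer(scheme$match * 2); w2 <- as.integer(scheme$wobble * 2)
  x2 <- as.integer(scheme$mismatch * 2); g2 <- as.integer(scheme$gap * 2)
  cut2 <- as.integer(scheme$cutoff * 2)
  ## candidate floor: collect everything at >= cutoff, apply the comparator
  ## after cluster reduction
  L <- nchar(target)
  hits <- list()
  ## + strand: transcript 3'->5' is the reversed + strand
  plus <- .target_scan_cpp(srna, reverse_string(target), m2, w2, x2, g2, cut2)
  if (nrow(plus)) {
    plus$start <- L + 1L - plus$s_end
    plus$end <- L + 1L - plus$s_start
    plus$strand <- "+"
    hits[[length(hits) + 1L]] <- plus
  }
  ## - strand: transcript 3'->5' runs with ascending + coordinates,
  ## base-complemented
  minus <- .target_scan_cpp(srna, paste(complement_chars(
    strsplit(target, "", fixed = TRUE)[[1]]), collapse = ""),
    m2, w2, x2, g2, cut2)
  if (nrow(minus)) {
    minus$start <- minus$s_start
    minus$end <- minus$s_end
    minus$strand <- "-"
    hits[[length(hits) + 1L]] <- minus
  }
  proto <- data.frame(srna_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      n_gaps = integer(0), pairing = character(0))
  if (!length(hits)) return(proto)
  df <- do.call(rbind, hits)
  df$score <- df$score2 / 2
  df <- select_target_hits(df)
  if (scheme$comparator == ">")
    df <- df[df$score2 > cut2, , drop = FALSE]
  if (nrow(df) == 0L) return(proto)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  out <- data.frame(srna_id = srna_id, seq_id = target_id,
                    start = df$start, end = df$end, strand = df$strand,
                    score = df$score, n_gaps = df$n_gaps,
                    pairing = df$pairing)
  rownames(out) <- NULL
  out
}

#' Export target hits as GFF3
#'
#' @param hits data.frame from [scan_targets()].
#' @param path output path.
#' @param seq_lengths optional named lengths for bounds checking.
#' @return `path`, invisibly.
#' @export
write_target_gff3 <- function(hits, path, seq_lengths = NULL) {
  feats <- data.frame(seq_id = hits$seq_id, start = hits$start,
                      end = hits$end, strand = hits$strand,
                      type = "sRNA_target", score = hits$score,
                      attributes = sprintf("ID=target%d;srna=%s;pairing=%s",
                                           seq_len(nrow(hits)), hits$srna_id,
                                           hits$pairing))
  write_gff3(feats, path, seq_lengths)
}
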