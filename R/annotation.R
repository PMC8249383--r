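#' Call frameshift pseudogenization of a candidate CDS
#'
#' Globally aligns a candidate coding sequence against an intact reference
#' CDS (affine gaps, so a contiguous deletion is reported as one indel) and
#' reports every indel with its length and whether it disrupts the reading
#' frame (length not a multiple of 3). The candidate is a frameshift
#' pseudogene iff at least one frame-disrupting indel is present.
#'
#' @param candidate_cds,reference_cds nucleotide strings (or one-element
#'   named vectors). The reference length must be divisible by 3.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap costs (positive magnitudes).
#' @return list of class `gene_call` with elements status ("intact" or
#'   "frameshift_pseudogene"), indels (data.frame: position on the reference,
#'   length, type "insertion"/"deletion", frame_disrupting), and score.
#' @export
call_frameshifts <- function(candidate_cds, reference_cds,
                             match = 1, mismatch = -1,
                             gap_open = 5, gap_extend = 1) {
  cand <- normalize_residues(unname(candidate_cds[[1]]), "candidate CDS")
  ref <- normalize_residues(unname(reference_cds[[1]]), "reference CDS")
  if (!nzchar(cand) || !nzchar(ref))
    stop("empty sequence", call. = FALSE)
  if (nchar(ref) %% 3L != 0L)
    stop("reference CDS length must be divisible by 3", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(cand, ref, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  ## gaps in the aligned candidate are deletions relative to the reference;
  ## gaps in the aligned reference are insertions
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(sub != "-")
  indels <- list()
  r <- rle(paste0(ifelse(pat == "-", "D", "."), ifelse(sub == "-", "I", ".")))
  col <- 1L
  for (k in seq_along(r$lengths)) {
    v <- r$values[k]; len <- r$lengths[k]
    if (v == "D.") {
      indels[[length(indels) + 1L]] <-
        data.frame(position = ref_pos[col], length = len, type = "deletion")
    } else if (v == ".I") {
      pos <- if (col > 1L) ref_pos[col - 1L] + 1L else 1L
      indels[[length(indels) + 1L]] <-
        data.frame(position = pos, length = len, type = "insertion")
    }
    col <- col + len
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(position = integer(0), length = integer(0), type = character(0))
  indels$frame_disrupting <- indels$length %% 3L != 0L
  status <- if (any(indels$frame_disrupting)) "frameshift_pseudogene"
            else "intact"
  structure(list(status = status, indels = indels,
                 score = Biostrings::score(aln)),
            class = "gene_call")
}

#' @export
print.gene_call <- function(x, ...) {
  cat("Gene call:", x$status, "\n")
  if (nrow(x$indels)) {
    cat(sprintf("  %d indel(s):\n", nrow(x$indels)))
    print(x$indels, row.names = FALSE)
  } else cat("  no indels\n")
  invisible(x)
}

#' Spacing pattern for the conserved SCR cysteines
#'
#' SCR carries 8 conserved cysteine residues; candidates are windows of 8
#' cysteines in any reading frame whose 7 inter-cysteine gaps (intervening
#' residues) fall inside the spacing windows. The default windows, (2, 40)
#' residues each, are a tunable placeholder — the conservation criterion
#' fixes the cysteine count, not the spacings.
#'
#' @param n_cys number of cysteines (8).
#' @param spacing_windows list of `n_cys - 1` numeric pairs (min_gap,
#'   max_gap) in residues.
#' @return a list of class `cysteine_pattern`.
#' @export
cysteine_pattern <- function(n_cys = 8L,
                             spacing_windows = rep(list(c(2L, 40L)),
                                                   n_cys - 1L)) {
  stopifnot(n_cys >= 2L, length(spacing_windows) == n_cys - 1L)
  ok <- vapply(spacing_windows,
               function(w) length(w) == 2L && w[1] >= 0 && w[2] >= w[1],
               logical(1))
  if (!all(ok)) stop("invalid spacing windows", call. = FALSE)
  structure(list(n_cys = as.integer(n_cys),
                 spacing_windows = spacing_windows),
            class = "cysteine_pattern")
}

#' Scan all six reading frames for an SCR-like cysteine pattern
#'
#' Translates every frame on both strands and reports nucleotide intervals
#' spanning 8 consecutive cysteine occurrences whose spacings fit the
#' pattern, with no stop codon between the first and last cysteine.
#'
#' @param seq nucleotide string or one-element named vector.
#' @param pattern a [cysteine_pattern()] object.
#' @param seq_id label for the output.
#' @return data.frame with columns seq_id, start, end, strand, frame
#'   (0-2 within strand); empty if no candidate.
#' @export
scan_cysteine_pattern <- function(seq, pattern = cysteine_pattern(),
                                  seq_id = NULL) {
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  s <- normalize_residues(unname(seq[[1]]), "sequence")
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") s else revcomp(s)
    for (f in 0:2) {
      sub <- substr(src, f + 1L, f + 3L * ((nchar(src) - f) %/% 3L))
      if (nchar(sub) < 3L * pattern$n_cys) next
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")))
      ch <- strsplit(aa, "", fixed = TRUE)[[1]]
      cpos <- which(ch == "C")
      if (length(cpos) < pattern$n_cys) next
      for (i in seq_len(length(cpos) - pattern$n_cys + 1L)) {
        win <- cpos[i:(i + pattern$n_cys - 1L)]
        gaps <- diff(win) - 1L
        ok <- all(vapply(seq_along(gaps), function(k) {
          w <- pattern$spacing_windows[[k]]
          gaps[k] >= w[1] && gaps[k] <= w[2]
        }, logical(1)))
        if (!ok) next
        if (any(ch[win[1]:win[length(win)]] == "*")) next
        nt_s <- f + 3L * (win[1] - 1L) + 1L
        nt_e <- f + 3L * win[length(win)]
        if (strand == "-") {
          tmp <- nt_s
          nt_s <- L + 1L - nt_e
          nt_e <- L + 1L - tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          seq_id = seq_id, start = nt_s, end = nt_e, strand = strand,
          frame = f)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0)))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify S-haplotype presence from a depth profile
#'
#' Breadth is the fraction of positions at or above `min_depth`; evenness is
#' the fraction of positions within [0.25x, 4x] of the median depth. A
#' haplotype is called present when breadth reaches `breadth_threshold` —
#' the "broad and even coverage" criterion reduced to a numeric rule.
#'
#' @param depths numeric vector of per-position depths (length >= 1).
#' @param min_depth minimum depth for a position to count as covered.
#' @param breadth_threshold presence threshold on breadth.
#' @return list of class `coverage_call` with breadth, mean_depth, evenness,
#'   present.
#' @export
classify_coverage <- function(depths, min_depth = 1L,
                              breadth_threshold = 0.9) {
  depths <- as.numeric(depths)
  if (length(depths) < 1L) stop("empty depth profile", call. = FALSE)
  if (any(depths < 0)) stop("negative depth", call. = FALSE)
  breadth <- mean(depths >= min_depth)
  med <- stats::median(depths)
  evenness <- mean(depths >= 0.25 * med & depths <= 4 * med)
  structure(list(breadth = breadth, mean_depth = mean(depths),
                 evenness = evenness,
                 present = breadth >= breadth_threshold),
            class = "coverage_call")
}

#' Presence calls for a set of depth profiles
#'
#' @param depth_list named list of per-position depth vectors, e.g. from
#'   [read_depth_table()].
#' @inheritParams classify_coverage
#' @return data.frame with one row per sequence: seq_id, breadth,
#'   mean_depth, evenness, present.
#' @export
coverage_calls <- function(depth_list, min_depth = 1L,
                           breadth_threshold = 0.9) {
  rows <- lapply(names(depth_list), function(id) {
    cc <- classify_coverage(depth_list[[id]], min_depth, breadth_threshold)
    data.frame(seq_id = id, breadth = cc$breadth, mean_depth = cc$mean_depth,
               evenness = cc$evenness, present = cc$present)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
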