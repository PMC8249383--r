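#' Read locus sequences from a FASTA file
#'
#' Residues are normalized at ingest: lowercase is uppercased and U becomes T,
#' so DNA and RNA inputs share one alphabet. Only \{A,C,G,T,N\} (and U on
#' input) are accepted; anything else is a format error reporting the
#' offending line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the FASTA ids,
#'   first whitespace-delimited token of each header). Empty files yield an
#'   empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA format error at line %d: first non-blank line must start with '>'",
                 nonblank[1]), call. = FALSE)
  }
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop(sprintf("FASTA format error at line %d: empty header", i),
             call. = FALSE)
      }
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      body <- toupper(gsub("U", "T", toupper(ln), fixed = TRUE))
      if (grepl("[^ACGTN]", body)) {
        stop(sprintf("FASTA format error at line %d: non-nucleotide characters",
                     i), call. = FALSE)
      }
      seqs[cur] <- paste0(seqs[cur], body)
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first non-blank character ('>' for
#' FASTA, '@' for FASTQ). FASTQ quality strings are parsed but unused.
#'
#' @param path input path.
#' @return a read set: `data.frame(seq, count)` with one row per input read
#'   (count 1 each; use [filter_reads()] to collapse duplicates).
#' @export
read_srna_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) return(data.frame(seq = character(0), count = integer(0)))
  first <- substr(trimws(nonblank[1]), 1, 1)
  if (first == ">") {
    seqs <- unname(read_fasta(path))
  } else if (first == "@") {
    if (length(nonblank) %% 4L != 0L)
      stop("FASTQ format error: record count not a multiple of 4", call. = FALSE)
    seqs <- nonblank[seq(2L, length(nonblank), by = 4L)]
    seqs <- normalize_residues(seqs, "FASTQ read")
  } else {
    stop("unrecognized read file format (expected FASTA or FASTQ)", call. = FALSE)
  }
  data.frame(seq = seqs, count = rep(1L, length(seqs)))
}

#' Write features as GFF3
#'
#' Features are emitted with 1-based inclusive coordinates, sorted by
#' (seq_id, start); re-parsing with [read_gff3()] recovers the same intervals.
#'
#' @param features data.frame with columns `seq_id`, `start`, `end`,
#'   `strand`, `type`; optional `score` and `attributes`.
#' @param path output path.
#' @param seq_lengths optional named vector of sequence lengths used for
#'   bounds checking.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seq_lengths = NULL) {
  req <- c("seq_id", "start", "end", "strand", "type")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(features) > 0L) {
    if (any(features$start < 1L) || any(features$end < features$start))
      stop("invalid interval: need 1 <= start <= end", call. = FALSE)
    if (!is.null(seq_lengths)) {
      lens <- seq_lengths[as.character(features$seq_id)]
      if (any(!is.na(lens) & features$end > lens))
        stop("interval exceeds sequence length", call. = FALSE)
    }
    features <- features[order(features$seq_id, features$start), , drop = FALSE]
  }
  score <- if ("score" %in% names(features)) {
    ifelse(is.na(features$score), ".", format(features$score, trim = TRUE))
  } else rep(".", nrow(features))
  attrs <- if ("attributes" %in% names(features)) {
    ifelse(is.na(features$attributes) | !nzchar(features$attributes),
           ".", features$attributes)
  } else rep(".", nrow(features))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0L) {
    writeLines(paste(features$seq_id, "slocusmod", features$type,
                     features$start, features$end, score,
                     features$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file written by this package
#'
#' @param path input path.
#' @return data.frame with columns seq_id, type, start, end, score, strand,
#'   attributes.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  proto <- data.frame(seq_id = character(0), type = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), strand = character(0),
                      attributes = character(0))
  if (length(lines) == 0L) return(proto)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("GFF3 format error: expected 9 tab-separated columns", call. = FALSE)
  m <- do.call(rbind, f)
  data.frame(seq_id = m[, 1], type = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             score = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6]))),
             strand = m[, 7], attributes = m[, 9])
}

#' Read a samtools-depth-style table
#'
#' Three tab-separated columns: seq_id, 1-based position, depth. Positions
#' absent from the file get depth 0.
#'
#' @param path input path.
#' @param seq_lengths optional named integer vector; profiles are padded with
#'   zeros to these lengths. Without it, each profile runs to the largest
#'   position seen for that sequence.
#' @return named list of integer depth vectors (1-based positions).
#' @export
read_depth_table <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_lines <- length(readLines(path, warn = FALSE, n = 1L))
  tab <- if (n_lines == 0L) {
    data.frame(V1 = character(0), V2 = integer(0), V3 = character(0))
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "character"),
                      col.names = c("V1", "V2", "V3"))
  }
  depth_num <- suppressWarnings(as.numeric(tab$V3))
  if (nrow(tab) > 0L &&
      (anyNA(depth_num) || any(depth_num < 0) || any(depth_num != floor(depth_num))))
    stop("depth table format error: depth must be a non-negative integer",
         call. = FALSE)
  ids <- unique(c(tab$V1, names(seq_lengths)))
  out <- lapply(ids, function(id) {
    rows <- tab$V1 == id
    len <- if (!is.null(seq_lengths) && id %in% names(seq_lengths)) {
      as.integer(seq_lengths[[id]])
    } else if (any(rows)) max(tab$V2[rows]) else 0L
    d <- integer(len)
    if (any(rows)) {
      pos <- tab$V2[rows]
      if (any(pos < 1L | pos > len))
        stop("depth table position outside sequence bounds", call. = FALSE)
      d[pos] <- as.integer(depth_num[rows])
    }
    d
  })
  stats::setNames(out, ids)
}

#' Write a depth table in samtools-depth format
#'
#' Only non-zero positions are written.
#'
#' @param depths named list of integer depth vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(depths)) {
    d <- depths[[id]]
    nz <- which(d > 0L)
    if (length(nz))
      writeLines(paste(id, nz, d[nz], sep = "\t"), con)
  }
  invisible(path)
}
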