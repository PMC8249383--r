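# Independent reference implementations and fixture builders used across the
# suite. These deliberately avoid the package's scan/DP code paths.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A sequence with one planted inverted repeat whose flanks and innermost loop
# positions are self-paired (never Watson-Crick, never G:T), so the stem can
# neither creep outward nor into the loop. Returns the sequence and the
# planted arm coordinates.
planted_ir_seq <- function(arm_len, loop_len, flank = 30L) {
  arm <- random_seq(arm_len)
  loop <- strsplit(random_seq(loop_len), "")[[1]]
  for (d in seq_len(min(4L, loop_len %/% 2L)))
    loop[loop_len + 1L - d] <- loop[d]
  left_flank <- strsplit(random_seq(flank), "")[[1]]
  right_flank <- strsplit(random_seq(flank), "")[[1]]
  for (d in 1:4) right_flank[d] <- left_flank[flank + 1L - d]
  s <- paste0(paste(left_flank, collapse = ""), arm,
              paste(loop, collapse = ""), revcomp(arm),
              paste(right_flank, collapse = ""))
  list(seq = s,
       left_start = flank + 1L, left_end = flank + arm_len,
       right_start = flank + arm_len + loop_len + 1L,
       right_end = flank + 2L * arm_len + loop_len)
}

# Plain-R Smith-Waterman under the wobble scheme (doubled integer scores):
# the query base is the sRNA, the subject base the transcript base it pairs
# with. Returns the maximum local score (doubled).
sw_wobble_best2 <- function(q, s, m2 = 2L, w2 = -1L, x2 = -2L, g2 = -4L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0L, n + 1L, m + 1L)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cell <- if (qc[i] == "N" || sc[j] == "N") x2
        else if (sc[j] == comp[[qc[i]]]) m2
        else if ((qc[i] == "G" && sc[j] == "T") ||
                 (qc[i] == "T" && sc[j] == "G")) w2
        else x2
      H[i + 1L, j + 1L] <- max(0L, H[i, j] + cell,
                               H[i, j + 1L] + g2, H[i + 1L, j] + g2)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# best doubled affinity over both target strands
oracle_target_best2 <- function(srna, target) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  tch <- strsplit(target, "")[[1]]
  max(sw_wobble_best2(srna, paste(rev(tch), collapse = "")),
      sw_wobble_best2(srna, paste(comp[tch], collapse = "")))
}

# naive full-scan read placement oracle (exact matching, both strands)
oracle_map_read <- function(read, refs) {
  out <- list()
  for (id in names(refs)) {
    ref <- refs[[id]]
    L <- nchar(ref); l <- nchar(read)
    for (p in seq_len(L - l + 1L)) {
      sub <- substr(ref, p, p + l - 1L)
      if (sub == read)
        out[[length(out) + 1L]] <- data.frame(seq_id = id, start = p,
                                              end = p + l - 1L, strand = "+")
      if (sub == revcomp(read))
        out[[length(out) + 1L]] <- data.frame(seq_id = id, start = p,
                                              end = p + l - 1L, strand = "-")
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

ir_coord_cols <- c("left_start", "left_end", "right_start", "right_end",
                   "score")
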