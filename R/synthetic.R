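#' Configuration for the synthetic S-locus scenario
#'
#' Describes a pair of homeologous S-haplotypes: a B-like locus (gene order
#' U-box, mirS3, SCR, SRK, ARK3) carrying a planted hairpin precursor inside
#' mirS3 and a frameshift-deleted SCR, and an A-like locus carrying short
#' degenerate SCR-similarity fragments plus a planted target site of
#' designed affinity for the hairpin's 24-nt sRNA. Every generator call
#' draws from its own pseudo-random stream derived from (seed, operation
#' tag), so outputs are reproducible and independent across operations.
#'
#' @param seed integer seed.
#' @param locus_len haplotype length in nt.
#' @param base_composition probabilities over A,C,G,T for background
#'   sequence.
#' @param layout named list of gene intervals (each `c(start, end)`), in
#'   order u_box, mirs3, scr, srk, ark3.
#' @param hairpin list: arm_len, loop_len, n_mismatches, n_bulges.
#' @param scr_deletion_len deletion planted in the B SCR (0 = intact; 1 and
#'   31 reproduce the frame-disrupting cases).
#' @param target list: n_wobbles, n_mismatches, pos (target-site start on
#'   the A-like locus).
#' @param srna_len,srna_offset length of the designed sRNA and its offset
#'   within the hairpin's left arm.
#' @param srna_depth expected copy count per sampled read site.
#' @param srna_sites number of distinct read sites sampled over the arms.
#' @param background_reads number of single-copy background reads.
#' @param len_probs sampling probabilities for read lengths 21,22,23,24.
#' @param theta_true,n_samples,pop_len infinite-sites population parameters
#'   (per-site mutation parameter, sample size, locus length).
#' @param depth_mean mean per-position depth for present haplotypes.
#' @param flank_frac fraction of the locus covered at each end for absent
#'   haplotypes (conserved flanks).
#' @param n_decoys number of planted decoy inverted repeats that fail the
#'   hairpin rules.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, locus_len = 30000L,
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             layout = list(u_box = c(2000L, 3200L),
                                           mirs3 = c(5000L, 5800L),
                                           scr = c(8000L, 8400L),
                                           srk = c(12000L, 14500L),
                                           ark3 = c(20000L, 22000L)),
                             hairpin = list(arm_len = 60L, loop_len = 15L,
                                            n_mismatches = 2L, n_bulges = 1L),
                             scr_deletion_len = 1L,
                             target = list(n_wobbles = 2L, n_mismatches = 1L,
                                           pos = 9500L),
                             srna_len = 24L, srna_offset = 10L,
                             srna_depth = 20, srna_sites = 30L,
                             background_reads = 20L,
                             len_probs = c(0.15, 0.15, 0.2, 0.5),
                             theta_true = 0.001, n_samples = 4L,
                             pop_len = 25000L,
                             depth_mean = 20, flank_frac = 0.08,
                             n_decoys = 5L) {
  stopifnot(length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-9,
            n_samples >= 2L, srna_len >= 18L, srna_len <= 27L)
  starts <- vapply(layout, `[`, numeric(1), 1L)
  ends <- vapply(layout, `[`, numeric(1), 2L)
  if (any(starts >= ends) || any(ends > locus_len) ||
      any(diff(starts) <= 0) || any(utils::head(ends, -1) >= starts[-1]))
    stop("gene layout intervals must be ordered, non-overlapping, and fit the locus",
         call. = FALSE)
  if (hairpin$arm_len < cfg_min_arm(srna_len, srna_offset))
    stop("hairpin arm too short to carry the designed sRNA", call. = FALSE)
  structure(list(seed = as.integer(seed), locus_len = as.integer(locus_len),
                 base_composition = base_composition, layout = layout,
                 hairpin = hairpin,
                 scr_deletion_len = as.integer(scr_deletion_len),
                 target = target, srna_len = as.integer(srna_len),
                 srna_offset = as.integer(srna_offset),
                 srna_depth = srna_depth, srna_sites = as.integer(srna_sites),
                 background_reads = as.integer(background_reads),
                 len_probs = len_probs, theta_true = theta_true,
                 n_samples = as.integer(n_samples),
                 pop_len = as.integer(pop_len), depth_mean = depth_mean,
                 flank_frac = flank_frac, n_decoys = as.integer(n_decoys)),
            class = "synthetic_config")
}

cfg_min_arm <- function(srna_len, srna_offset) srna_offset + srna_len

random_bases <- function(n, comp) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = comp), collapse = "")
}

splice_in <- function(seq, at, insert) {
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

## reverse-translate an amino-acid string, choosing codons at random
reverse_translate <- function(aa, codon_map) {
  paste(vapply(strsplit(aa, "", fixed = TRUE)[[1]], function(a) {
    opts <- codon_map[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate the homeologous A-like / B-like haplotype pair
#'
#' Plants, by construction: a hairpin precursor inside the B-like mirS3
#' interval (arm mismatches and 1-nt asymmetric bulges on the right arm, so
#' the designed sRNA window on the left arm matches the locus exactly); a B
#' SCR coding sequence with the configured deletion relative to an intact
#' reference SCR carrying the 8-cysteine pattern; decoy inverted repeats
#' that violate the hairpin rules; degenerate SCR-similarity fragments on
#' the A-like locus; and a target site on the A-like locus whose designed
#' affinity for the sRNA is `srna_len - 1.5*n_wobbles - 2*n_mismatches`
#' (wobble and mismatch columns are kept interior so the designed alignment
#' is the local optimum).
#'
#' @param cfg a [synthetic_config()] object.
#' @return list with `haplotypes` (named character vector: A_hap, B_hap),
#'   `truth` (feature data.frame: seq_id, name, start, end, strand, note),
#'   `srna` (designed 24-nt sRNA), `scr_reference`/`scr_candidate`
#'   (intact and planted SCR CDS), and `designed_affinity`.
#' @export
make_haplotype_pair <- function(cfg) {
  comp <- cfg$base_composition
  feats <- list()
  add_feat <- function(seq_id, name, start, end, strand = "+", note = "") {
    feats[[length(feats) + 1L]] <<- data.frame(
      seq_id = seq_id, name = name, start = as.integer(start),
      end = as.integer(end), strand = strand, note = note)
  }

  ## intact reference SCR CDS with the 8-cysteine pattern
  scr <- with_stream(cfg$seed, "scr", {
    codon_map <- split(names(Biostrings::GENETIC_CODE),
                       unname(Biostrings::GENETIC_CODE))
    aa_pool <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), c("C", "*"))
    gaps <- sample(3:20, 7L, replace = TRUE)
    lead <- paste(sample(aa_pool, 9L, replace = TRUE), collapse = "")
    body <- "C"
    for (g in gaps) {
      body <- paste0(body,
                     paste(sample(aa_pool, g, replace = TRUE), collapse = ""),
                     "C")
    }
    tail_aa <- paste(sample(aa_pool, 6L, replace = TRUE), collapse = "")
    aa <- paste0("M", lead, body, tail_aa)
    paste0(reverse_translate(aa, codon_map), "TAA")
  })
  scr_cand <- scr
  if (cfg$scr_deletion_len > 0L) {
    del_at <- 100L
    scr_cand <- paste0(substr(scr, 1L, del_at - 1L),
                       substr(scr, del_at + cfg$scr_deletion_len, nchar(scr)))
  }

  ## hairpin: left arm + loop + modified reverse complement of the arm
  hp <- cfg$hairpin
  hairpin <- with_stream(cfg$seed, "hairpin", {
    arm <- random_bases(hp$arm_len, comp)
    armc <- strsplit(arm, "", fixed = TRUE)[[1]]
    rarm <- rev(complement_chars(armc))            # perfect 5'->3' right arm
    ## mismatch columns: set the right-arm partner to the left base itself
    ## (never Watson-Crick, never G:T); interior, away from the sRNA window
    usable <- setdiff(5:(hp$arm_len - 4L),
                      (cfg$srna_offset + 1L):(cfg$srna_offset + cfg$srna_len))
    mm_cols <- if (hp$n_mismatches > 0L) sort(sample(usable, hp$n_mismatches))
               else integer(0)
    for (k in mm_cols) rarm[hp$arm_len + 1L - k] <- armc[k]
    ## 1-nt asymmetric bulges: insert extra bases into the right arm
    if (hp$n_bulges > 0L) {
      bulge_at <- sort(sample(setdiff(usable, mm_cols), hp$n_bulges),
                       decreasing = TRUE)
      for (k in bulge_at) {
        ins_pos <- hp$arm_len + 1L - k
        extra <- sample(DNA_BASES, 1L)
        rarm <- append(rarm, extra, after = ins_pos)
      }
    }
    loop <- strsplit(random_bases(hp$loop_len, comp), "", fixed = TRUE)[[1]]
    ## make the innermost loop pairings mismatches so the stem cannot creep
    ## into the loop
    for (d in seq_len(min(4L, hp$loop_len %/% 2L)))
      loop[hp$loop_len + 1L - d] <- loop[d]
    list(arm = arm,
         seq = paste0(arm, paste(loop, collapse = ""),
                      paste(rarm, collapse = "")),
         mm_cols = mm_cols)
  })
  srna <- substr(hairpin$arm, cfg$srna_offset + 1L,
                 cfg$srna_offset + cfg$srna_len)

  ## B-like haplotype
  B <- with_stream(cfg$seed, "background_B",
                   random_bases(cfg$locus_len, comp))
  ly <- cfg$layout
  add_feat("B_hap", "U-box", ly$u_box[1], ly$u_box[2])
  add_feat("B_hap", "SRK", ly$srk[1], ly$srk[2])
  add_feat("B_hap", "ARK3", ly$ark3[1], ly$ark3[2])
  ## SCR candidate (same window as the reference; shorter if deleted)
  B <- splice_in(B, ly$scr[1],
                 paste0(scr_cand,
                        with_stream(cfg$seed, "scr_pad",
                                    random_bases(nchar(scr) - nchar(scr_cand),
                                                 comp))))
  add_feat("B_hap", "SCR", ly$scr[1], ly$scr[1] + nchar(scr_cand) - 1L,
           note = sprintf("deletion_len=%d", cfg$scr_deletion_len))
  ## hairpin inside mirS3
  hp_start <- ly$mirs3[1]
  B <- splice_in(B, hp_start, hairpin$seq)
  la_s <- hp_start; la_e <- hp_start + hp$arm_len - 1L
  ra_s <- la_e + hp$loop_len + 1L
  ra_e <- ra_s + hp$arm_len + hp$n_bulges - 1L
  ## pin down the hairpin flanks so the stem cannot extend outward
  Bch <- strsplit(B, "", fixed = TRUE)[[1]]
  for (d in 1:4) Bch[ra_e + d] <- Bch[la_s - d]
  B <- paste(Bch, collapse = "")
  add_feat("B_hap", "mirS3", ly$mirs3[1], ly$mirs3[2])
  add_feat("B_hap", "hairpin_left_arm", la_s, la_e)
  add_feat("B_hap", "hairpin_right_arm", ra_s, ra_e)
  add_feat("B_hap", "srna", la_s + cfg$srna_offset,
           la_s + cfg$srna_offset + cfg$srna_len - 1L, note = srna)
  ## decoy inverted repeats failing the hairpin rules (15-bp perfect arms,
  ## 50-nt loop: score 60 but stem <= 20 and loop >= 40)
  B <- with_stream(cfg$seed, "decoys", {
    s <- B
    for (k in seq_len(cfg$n_decoys)) {
      at <- 15500L + (k - 1L) * 500L
      arm <- random_bases(15L, comp)
      dec <- paste0(arm, random_bases(50L, comp), revcomp(arm))
      s <- splice_in(s, at, dec)
      add_feat("B_hap", sprintf("decoy_ir_%d", k), at, at + nchar(dec) - 1L)
    }
    s
  })

  ## A-like haplotype
  A <- with_stream(cfg$seed, "background_A",
                   random_bases(cfg$locus_len, comp))
  add_feat("A_hap", "U-box", ly$u_box[1], ly$u_box[2])
  add_feat("A_hap", "SRK_exon1", ly$srk[1], ly$srk[1] + 800L)
  add_feat("A_hap", "ARK3", ly$ark3[1], ly$ark3[2])
  A <- with_stream(cfg$seed, "scr_fragments", {
    s <- A
    for (k in 1:2) {
      at <- ly$scr[1] + (k - 1L) * 200L
      frag <- strsplit(substr(scr, 40L * k, 40L * k + 59L), "",
                       fixed = TRUE)[[1]]
      mut <- sample(length(frag), round(0.2 * length(frag)))
      frag[mut] <- sample(DNA_BASES, length(mut), replace = TRUE)
      s <- splice_in(s, at, paste(frag, collapse = ""))
      add_feat("A_hap", sprintf("scr_similarity_%d", k), at, at + 59L)
    }
    s
  })
  ## designed target site
  tg <- cfg$target
  n_w <- as.integer(tg$n_wobbles); n_m <- as.integer(tg$n_mismatches)
  affinity <- cfg$srna_len - 1.5 * n_w - 2 * n_m
  if (affinity > cfg$srna_len || n_w + n_m > cfg$srna_len)
    stop("infeasible target affinity", call. = FALSE)
  site <- with_stream(cfg$seed, "target_site", {
    q <- strsplit(srna, "", fixed = TRUE)[[1]]
    site <- rev(complement_chars(q))               # perfect complement
    interior <- 4:(cfg$srna_len - 3L)
    gt_pos <- intersect(interior, which(q %in% c("G", "T")))
    if (length(gt_pos) < n_w)
      stop("sRNA lacks interior G/T positions for the requested wobbles",
           call. = FALSE)
    w_cols <- if (n_w > 0L) sort(sample(gt_pos, n_w)) else integer(0)
    m_pool <- setdiff(interior, w_cols)
    m_cols <- if (n_m > 0L) sort(sample(m_pool, n_m)) else integer(0)
    for (i in w_cols)
      site[cfg$srna_len + 1L - i] <- if (q[i] == "G") "T" else "G"
    for (i in m_cols)
      site[cfg$srna_len + 1L - i] <- q[i]
    paste(site, collapse = "")
  })
  A <- splice_in(A, tg$pos, site)
  add_feat("A_hap", "target_site", tg$pos, tg$pos + cfg$srna_len - 1L,
           note = sprintf("designed_affinity=%g", affinity))

  truth <- do.call(rbind, feats)
  rownames(truth) <- NULL
  list(haplotypes = c(A_hap = A, B_hap = B), truth = truth, srna = srna,
       scr_reference = scr, scr_candidate = scr_cand,
       designed_affinity = affinity)
}

#' Sample small-RNA reads from a planted hairpin precursor
#'
#' The designed sRNA itself is always included at a boosted copy count
#' (Poisson with mean `3 * srna_depth`, plus one); the remaining
#' `srna_sites - 1` read sites start uniformly over the two arms with
#' lengths drawn from 21-24 nt under `len_probs` and copy counts
#' Poisson(`srna_depth`). `background_reads` single-copy reads of 18-27 nt
#' are scattered outside the precursor.
#'
#' @param cfg a [synthetic_config()] object.
#' @param haplotype the B-like sequence the precursor lives on.
#' @param arms data.frame with two rows (start, end): the arm intervals.
#' @param srna designed sRNA sequence, or NULL to skip the boosted read.
#' @return data.frame (seq, count) with attribute `expected_precursor_total`
#'   (the sampling model's expected total copies over the precursor).
#' @export
sample_srna_reads <- function(cfg, haplotype, arms, srna = NULL) {
  hap <- unname(haplotype[[1]])
  with_stream(cfg$seed, "srna_reads", {
    seqs <- character(0); counts <- integer(0)
    if (!is.null(srna)) {
      seqs <- srna
      counts <- stats::rpois(1L, 3 * cfg$srna_depth) + 1L
    }
    n_sites <- max(cfg$srna_sites - as.integer(!is.null(srna)), 0L)
    for (k in seq_len(n_sites)) {
      a <- sample.int(nrow(arms), 1L)
      len <- sample(21:24, 1L, prob = cfg$len_probs)
      lo <- arms$start[a]; hi <- arms$end[a] - len + 1L
      if (hi < lo) next
      st <- sample(lo:hi, 1L)
      cnt <- stats::rpois(1L, cfg$srna_depth)
      if (cnt > 0L) {
        seqs <- c(seqs, substr(hap, st, st + len - 1L))
        counts <- c(counts, cnt)
      }
    }
    span <- c(min(arms$start), max(arms$end))
    for (k in seq_len(cfg$background_reads)) {
      len <- sample(18:27, 1L)
      repeat {
        st <- sample.int(nchar(hap) - len + 1L, 1L)
        if (st + len - 1L < span[1] || st > span[2]) break
      }
      seqs <- c(seqs, substr(hap, st, st + len - 1L))
      counts <- c(counts, 1L)
    }
    out <- data.frame(seq = seqs, count = counts)
    attr(out, "expected_precursor_total") <-
      (cfg$srna_sites - as.integer(!is.null(srna))) * cfg$srna_depth +
      if (!is.null(srna)) 3 * cfg$srna_depth + 1 else 0
    out
  })
}

#' Simulate an infinite-sites population sample
#'
#' Draws S ~ Poisson(theta_true * a_n * L) segregating sites on a random
#' ancestral sequence; each site gets a derived allele carried by a
#' uniformly chosen proper, non-empty subset of the n samples. Under this
#' model E[theta_W] = theta_true.
#'
#' @param cfg a [synthetic_config()] object (fields theta_true, n_samples,
#'   pop_len).
#' @param replicate index mixed into the stream tag so replicate draws are
#'   independent.
#' @return named character vector of n aligned sequences.
#' @export
sample_population <- function(cfg, replicate = 1L) {
  n <- cfg$n_samples
  L <- cfg$pop_len
  with_stream(cfg$seed, paste0("population_", replicate), {
    anc <- strsplit(random_bases(L, cfg$base_composition), "",
                    fixed = TRUE)[[1]]
    a_n <- sum(1 / seq_len(n - 1L))
    S <- stats::rpois(1L, cfg$theta_true * a_n * L)
    S <- min(S, L)
    m <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
    if (S > 0L) {
      sites <- sample.int(L, S)
      for (s in sites) {
        k <- sample.int(n - 1L, 1L)              # derived-allele count
        carriers <- sample.int(n, k)
        m[carriers, s] <- sample(setdiff(DNA_BASES, anc[s]), 1L)
      }
    }
    stats::setNames(apply(m, 1L, paste, collapse = ""),
                    sprintf("hap%d", seq_len(n)))
  })
}

#' Simulate depth profiles for present/absent haplotypes
#'
#' Present haplotypes receive near-uniform Poisson(depth_mean) coverage;
#' absent haplotypes are covered only over conserved flank intervals
#' (`flank_frac` of the locus at each end), emulating cross-mapping from the
#' shared S-locus flanks.
#'
#' @param cfg a [synthetic_config()] object.
#' @param genotype "A_and_B" (both present) or "B_only" (A absent).
#' @return named list of integer depth vectors for A_hap and B_hap.
#' @export
make_depth_profile <- function(cfg, genotype = c("A_and_B", "B_only")) {
  genotype <- match.arg(genotype)
  L <- cfg$locus_len
  with_stream(cfg$seed, paste0("depth_", genotype), {
    present <- function() stats::rpois(L, cfg$depth_mean)
    absent <- function() {
      d <- integer(L)
      fl <- max(1L, round(cfg$flank_frac * L))
      d[1:fl] <- stats::rpois(fl, cfg$depth_mean)
      d[(L - fl + 1L):L] <- stats::rpois(fl, cfg$depth_mean)
      d
    }
    list(A_hap = if (genotype == "A_and_B") present() else absent(),
         B_hap = present())
  })
}

#' Generate a full synthetic scenario, optionally writing files
#'
#' Bundles [make_haplotype_pair()], [sample_srna_reads()],
#' [sample_population()] and [make_depth_profile()]; with `outdir` set,
#' writes haplotype FASTA, read FASTA, population alignment FASTA, a GFF3
#' truth table and depth TSVs.
#'
#' @param cfg a [synthetic_config()] object.
#' @param outdir optional output directory.
#' @return list with haplotypes, truth, srna, scr sequences, reads,
#'   population, depths.
#' @export
simulate_scenario <- function(cfg = synthetic_config(), outdir = NULL) {
  pair <- make_haplotype_pair(cfg)
  arms <- pair$truth[pair$truth$name %in% c("hairpin_left_arm",
                                            "hairpin_right_arm"), ]
  reads <- sample_srna_reads(cfg, pair$haplotypes["B_hap"], arms, pair$srna)
  pop <- sample_population(cfg)
  depths <- make_depth_profile(cfg, "A_and_B")
  out <- c(pair, list(reads = reads, population = pop, depths = depths))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(pair$haplotypes, file.path(outdir, "haplotypes.fasta"))
    expanded <- rep(reads$seq, reads$count)   # one record per copy
    write_fasta(stats::setNames(expanded,
                                sprintf("read%d", seq_along(expanded))),
                file.path(outdir, "srna_reads.fasta"))
    write_fasta(pop, file.path(outdir, "population.fasta"))
    write_fasta(c(SCR_reference = pair$scr_reference,
                  SCR_candidate = pair$scr_candidate),
                file.path(outdir, "scr.fasta"))
    tr <- pair$truth
    write_gff3(data.frame(seq_id = tr$seq_id, start = tr$start, end = tr$end,
                          strand = tr$strand, type = "region",
                          score = NA_real_,
                          attributes = sprintf("Name=%s;Note=%s", tr$name,
                                               tr$note)),
               file.path(outdir, "truth.gff3"))
    write_depth_table(depths, file.path(outdir, "depth.tsv"))
  }
  out
}
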