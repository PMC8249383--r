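test_that("identical seeds reproduce every generator output byte-for-byte", {
  cfg <- synthetic_config(seed = 21)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$reads, b$reads)
  expect_identical(a$population, b$population)
  expect_identical(a$depths, b$depths)
  # a different seed changes the background
  expect_false(identical(
    a$haplotypes, simulate_scenario(synthetic_config(seed = 22))$haplotypes))
})

test_that("planted features satisfy their stage rules by construction", {
  cfg <- synthetic_config(seed = 23)
  pair <- make_haplotype_pair(cfg)
  tr <- pair$truth
  arms <- tr[tr$name %in% c("hairpin_left_arm", "hairpin_right_arm"), ]
  irs <- find_inverted_repeats(pair$haplotypes["B_hap"])
  hp <- irs[irs$left_start == arms$start[1] & irs$right_end == arms$end[2], ]
  expect_identical(nrow(hp), 1L)
  ev <- evaluate_hairpin(hp)
  expect_true(ev$passes)
  expect_identical(ev$mismatch_count, cfg$hairpin$n_mismatches)
  expect_identical(ev$asym_bulge_count, cfg$hairpin$n_bulges)
  expect_identical(ev$loop_len, cfg$hairpin$loop_len)
  # sRNA is an exact substring of the left arm
  expect_identical(pair$srna,
                   unname(substr(pair$haplotypes["B_hap"],
                          arms$start[1] + cfg$srna_offset,
                          arms$start[1] + cfg$srna_offset + cfg$srna_len - 1L)))
})

test_that("designed target affinities are recovered, infeasible ones rejected", {
  cfg24 <- synthetic_config(seed = 24,
                            target = list(n_wobbles = 0L, n_mismatches = 0L,
                                          pos = 9500L))
  pair <- make_haplotype_pair(cfg24)
  expect_identical(pair$designed_affinity, 24)
  h <- scan_targets(pair$srna, pair$haplotypes["A_hap"])
  expect_identical(h$score, 24)
  expect_identical(h$start, 9500L)

  expect_error(make_haplotype_pair(
    synthetic_config(seed = 24,
                     target = list(n_wobbles = 0L, n_mismatches = 30L,
                                   pos = 9500L))),
    "infeasible|lacks")
})

test_that("read sampling follows its stated model", {
  cfg <- synthetic_config(seed = 25)
  pair <- make_haplotype_pair(cfg)
  arms <- pair$truth[pair$truth$name %in% c("hairpin_left_arm",
                                            "hairpin_right_arm"), ]
  # no signal, no background: empty
  cfg0 <- synthetic_config(seed = 25, srna_depth = 0, srna_sites = 0L,
                           background_reads = 0L)
  r0 <- sample_srna_reads(cfg0, pair$haplotypes["B_hap"], arms, srna = NULL)
  expect_identical(nrow(r0), 0L)

  # Poisson totals: observed precursor count within 3 sd of expectation
  reads <- sample_srna_reads(cfg, pair$haplotypes["B_hap"], arms, pair$srna)
  mapped <- map_reads(filter_reads(reads), pair$haplotypes["B_hap"])
  prec <- data.frame(id = "hp", seq_id = "B_hap", start = arms$start[1],
                     end = arms$end[2])
  q <- quantify(mapped, prec)
  expected <- attr(reads, "expected_precursor_total")
  expect_lt(abs(q$table$total_count - expected), 3 * sqrt(expected))
})

test_that("zero theta gives identical samples; depth profiles encode genotype", {
  cfg <- synthetic_config(seed = 26, theta_true = 0, pop_len = 3000L)
  aln <- sample_population(cfg)
  expect_identical(length(unique(unname(aln))), 1L)
  d <- diversity(aln)
  expect_identical(d$pi + d$theta_w, 0)

  both <- coverage_calls(make_depth_profile(cfg, "A_and_B"))
  expect_true(all(both$present))
  bonly <- coverage_calls(make_depth_profile(cfg, "B_only"))
  expect_identical(bonly$present[bonly$seq_id == "A_hap"], FALSE)
  expect_identical(bonly$present[bonly$seq_id == "B_hap"], TRUE)
  expect_lt(bonly$breadth[bonly$seq_id == "A_hap"], 0.9)
})

test_that("scenario files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 27, pop_len = 2000L)
  scen <- simulate_scenario(cfg, outdir = dir)
  haps <- read_fasta(file.path(dir, "haplotypes.fasta"))
  expect_identical(haps, scen$haplotypes)
  pop <- read_fasta(file.path(dir, "population.fasta"))
  expect_identical(pop, scen$population)
  depth <- read_depth_table(file.path(dir, "depth.tsv"),
                            vapply(scen$depths, length, 1L))
  expect_identical(depth, scen$depths)
  truth <- read_gff3(file.path(dir, "truth.gff3"))
  expect_identical(nrow(truth), nrow(scen$truth))
})
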