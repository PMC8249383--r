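test_that("pair classification follows Watson-Crick and G:U wobble rules", {
  expect_identical(pair_class("G", "C"), "match")
  expect_identical(pair_class("A", "T"), "match")
  expect_identical(pair_class("G", "T"), "wobble")
  expect_identical(pair_class("T", "G"), "wobble")
  expect_identical(pair_class("A", "A"), "mismatch")
  expect_identical(pair_class("N", "C"), "mismatch")  # N never pairs
  expect_identical(pair_class(c("G", "T", "A"), c("C", "G", "C")),
                   c("match", "wobble", "mismatch"))
  expect_error(pair_class("G", "Q"), "non-nucleotide")
})

test_that("a perfect complement scores the sRNA length at the planted site", {
  set.seed(51)
  srna <- random_seq(24)
  target <- paste0(random_seq(300), revcomp(srna), random_seq(200))
  hits <- scan_targets(srna, target)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$score, 24)
  expect_identical(hits$start, 301L)
  expect_identical(hits$end, 324L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$pairing, strrep("m", 24))
})

test_that("18 nt of perfect complementarity is the minimum hit", {
  set.seed(52)
  s17 <- random_seq(17)
  t17 <- paste0(random_seq(50), revcomp(s17), random_seq(50))
  expect_identical(nrow(scan_targets(s17, t17, srna_len_bounds = c(1, 27))),
                   0L)
  s18 <- random_seq(18)
  t18 <- paste0(random_seq(50), revcomp(s18), random_seq(50))
  h <- scan_targets(s18, t18)
  expect_identical(nrow(h), 1L)
  expect_identical(h$score, 18)
})

test_that("designed wobble/mismatch sites score by exact half-unit arithmetic", {
  # 21 matches + 2 wobbles + 1 mismatch = 21 - 1.0 - 1.0 = 19
  cfg <- synthetic_config(seed = 9,
                          target = list(n_wobbles = 2L, n_mismatches = 1L,
                                        pos = 9500L))
  pair <- make_haplotype_pair(cfg)
  expect_identical(pair$designed_affinity, 19)
  hits <- scan_targets(pair$srna, pair$haplotypes["A_hap"])
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$score, 19)
  expect_identical(hits$start, 9500L)
  tab <- table(strsplit(hits$pairing, "")[[1]])
  expect_identical(as.integer(tab[c("m", "w", "x")]), c(21L, 2L, 1L))
})

test_that("the cutoff comparator distinguishes >= 18 from > 18", {
  cfg <- synthetic_config(seed = 10,
                          target = list(n_wobbles = 4L, n_mismatches = 0L,
                                        pos = 9500L))
  pair <- make_haplotype_pair(cfg)    # affinity 24 - 6 = 18 exactly
  expect_identical(pair$designed_affinity, 18)
  ge <- scan_targets(pair$srna, pair$haplotypes["A_hap"],
                     wobble_scheme(comparator = ">="))
  gt <- scan_targets(pair$srna, pair$haplotypes["A_hap"],
                     wobble_scheme(comparator = ">"))
  expect_identical(nrow(ge), 1L)
  expect_identical(ge$score, 18)
  expect_identical(nrow(gt), 0L)
})

test_that("scanner matches the brute-force alignment oracle on small cases", {
  set.seed(53)
  sch <- wobble_scheme(cutoff = 0.5)
  for (r in 1:150) {
    q <- random_seq(sample(8:12, 1))
    t <- random_seq(sample(20:40, 1))
    hits <- scan_targets(q, t, sch, srna_len_bounds = c(1, 27))
    got2 <- if (nrow(hits)) as.integer(max(hits$score) * 2) else 0L
    expect_identical(got2, oracle_target_best2(q, t))
  }
})

test_that("no hit exceeds the sRNA length and revcomp mirrors hits", {
  set.seed(54)
  for (r in 1:10) {
    srna <- random_seq(24)
    target <- paste0(random_seq(150), revcomp(srna), random_seq(150))
    h <- scan_targets(srna, target, wobble_scheme(cutoff = 10))
    expect_true(all(h$score <= 24))
    hr <- scan_targets(srna, revcomp(target), wobble_scheme(cutoff = 10))
    L <- nchar(target)
    expect_identical(nrow(h), nrow(hr))
    expect_setequal(paste(L + 1L - hr$end, L + 1L - hr$start,
                          chartr("+-", "-+", hr$strand), hr$score),
                    paste(h$start, h$end, h$strand, h$score))
  }
})
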