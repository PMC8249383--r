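ref_cds <- function(seed = 5L) {
  make_haplotype_pair(synthetic_config(seed = seed))$scr_reference
}

test_that("frameshift calls classify deletions by frame disruption", {
  r <- ref_cds()
  expect_identical(call_frameshifts(r, r)$status, "intact")
  expect_identical(nrow(call_frameshifts(r, r)$indels), 0L)

  del <- function(at, len) paste0(substr(r, 1, at - 1),
                                  substr(r, at + len, nchar(r)))
  in_frame <- call_frameshifts(del(100, 3), r)
  expect_identical(in_frame$status, "intact")
  expect_identical(in_frame$indels$length, 3L)
  expect_false(in_frame$indels$frame_disrupting)

  one_bp <- call_frameshifts(del(100, 1), r)
  expect_identical(one_bp$status, "frameshift_pseudogene")
  expect_identical(one_bp$indels$length, 1L)

  # a contiguous 31-bp deletion is one indel under affine gaps
  big <- call_frameshifts(del(100, 31), r)
  expect_identical(big$status, "frameshift_pseudogene")
  expect_identical(nrow(big$indels), 1L)
  expect_identical(big$indels$length, 31L)
  expect_true(big$indels$frame_disrupting)

  expect_error(call_frameshifts("", r), "empty")
  expect_error(call_frameshifts(r, substr(r, 1, 100)), "divisible by 3")
})

test_that("frameshift status is invariant under shared flanking context", {
  set.seed(81)
  r <- ref_cds()
  flank5 <- random_seq(60); flank3 <- random_seq(60)
  del1 <- paste0(substr(r, 1, 99), substr(r, 101, nchar(r)))
  plain <- call_frameshifts(del1, r)
  # pad the reference to keep its length divisible by 3
  pad <- (3 - (nchar(flank5) + nchar(r) + nchar(flank3)) %% 3) %% 3
  flanked <- call_frameshifts(paste0(flank5, del1, flank3, strrep("A", pad)),
                              paste0(flank5, r, flank3, strrep("A", pad)))
  expect_identical(flanked$status, plain$status)
  expect_identical(flanked$indels$length, plain$indels$length)
})

test_that("the 8-cysteine scan finds planted SCR motifs on either strand", {
  set.seed(82)
  r <- ref_cds()
  bg <- random_seq(1500)
  planted <- paste0(substr(bg, 1, 700), r, substr(bg, 701, 1500))
  hits <- scan_cysteine_pattern(planted)
  scr_s <- 701L; scr_e <- 700L + nchar(r)
  expect_gt(nrow(hits), 0L)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start >= scr_s & plus$end <= scr_e))

  rc_hits <- scan_cysteine_pattern(revcomp(planted))
  minus <- rc_hits[rc_hits$strand == "-", ]
  L <- nchar(planted)
  expect_setequal(paste(L + 1L - minus$end, L + 1L - minus$start),
                  paste(plus$start, plus$end))

  no_c <- gsub("C", "A", gsub("G", "T", planted))  # no C or G: no Cys codon
  expect_identical(nrow(scan_cysteine_pattern(no_c)), 0L)
})

test_that("coverage classification follows breadth and evenness definitions", {
  uni <- classify_coverage(rep(10L, 100))
  expect_identical(uni$breadth, 1)
  expect_identical(uni$evenness, 1)
  expect_true(uni$present)

  zero <- classify_coverage(rep(0L, 100))
  expect_identical(zero$breadth, 0)
  expect_false(zero$present)

  # flank-only coverage stays below the presence threshold
  d <- c(rep(10L, 8), rep(0L, 84), rep(10L, 8))
  fl <- classify_coverage(d)
  expect_equal(fl$breadth, 0.16)
  expect_false(fl$present)
})

test_that("presence is monotone in per-position depth", {
  set.seed(83)
  d <- rpois(500, 1.2)
  base <- classify_coverage(d)
  more <- classify_coverage(d + rpois(500, 2))
  expect_gte(more$breadth, base$breadth)
  expect_true(!base$present || more$present)
})
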