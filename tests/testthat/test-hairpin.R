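# build a screened-shape IR row straight from arm alignment strings
ir_row <- function(aln_left, aln_right, loop_len, left_start = 101L) {
  l_len <- nchar(gsub("-", "", aln_left))
  r_len <- nchar(gsub("-", "", aln_right))
  left_end <- left_start + l_len - 1L
  right_start <- left_end + loop_len + 1L
  data.frame(seq_id = "s", left_start = left_start, left_end = left_end,
             right_start = right_start, right_end = right_start + r_len - 1L,
             loop_len = as.integer(loop_len),
             span = right_start + r_len - left_start,
             score = 999L, aln_left = aln_left, aln_right = aln_right)
}

perfect_stem <- function(n) {
  set.seed(n)
  arm <- random_seq(n)
  ir_row(arm, paste(slocusmod:::complement_chars(strsplit(arm, "")[[1]]),
                    collapse = ""), 10L)
}

test_that("hairpin metrics and rules follow the filter definition", {
  # perfect 25-bp stem, 10-nt loop: passes
  h <- evaluate_hairpin(perfect_stem(25L))
  expect_identical(h$paired_len, 25L)
  expect_identical(h$mismatch_count, 0L)
  expect_identical(h$asym_bulge_count, 0L)
  expect_true(h$passes)

  # loop bound is strict: 39 passes, 40 fails
  h39 <- perfect_stem(25L); h39$loop_len <- 39L
  h40 <- perfect_stem(25L); h40$loop_len <- 40L
  expect_true(evaluate_hairpin(h39)$passes)
  expect_false(evaluate_hairpin(h40)$passes)

  # stem bound is strict: 21 paired passes, exactly 20 fails
  expect_true(evaluate_hairpin(perfect_stem(21L))$passes)
  expect_false(evaluate_hairpin(perfect_stem(20L))$passes)
})

test_that("mismatch, wobble, and bulge columns are counted from the alignment", {
  # 22 columns, 5 of them self-paired (mismatches): fails the mismatch rule
  arm <- strsplit(random_seq(22), "")[[1]]
  partner <- slocusmod:::complement_chars(arm)
  partner[c(3, 7, 11, 15, 19)] <- arm[c(3, 7, 11, 15, 19)]
  h <- evaluate_hairpin(ir_row(paste(arm, collapse = ""),
                               paste(partner, collapse = ""), 10L))
  expect_identical(h$mismatch_count, 5L)
  expect_identical(h$paired_len, 17L)
  expect_false(h$passes)

  # G:T wobble counts as paired in the hairpin context
  h <- evaluate_hairpin(ir_row("GGGGGGGGGGGGGGGGGGGGG",
                               "TTTTTTTTTTTTTTTTTTTTT", 5L))
  expect_identical(h$paired_len, 21L)
  expect_true(h$passes)

  # 21 paired + 4 mismatches + 2 single-base bulges: passes all rules
  arm <- strsplit(random_seq(25), "")[[1]]
  partner <- slocusmod:::complement_chars(arm)
  partner[c(5, 9, 13, 17)] <- arm[c(5, 9, 13, 17)]     # 4 mismatches
  al <- append(arm, "-", after = 2L)                    # bulge in right arm
  pr <- append(partner, "A", after = 2L)
  al <- append(al, "C", after = 22L)                    # bulge in left arm
  pr <- append(pr, "-", after = 22L)
  h <- evaluate_hairpin(ir_row(paste(al, collapse = ""),
                               paste(pr, collapse = ""), 10L))
  expect_identical(h$paired_len, 21L)
  expect_identical(h$mismatch_count, 4L)
  expect_identical(h$asym_bulge_count, 2L)
  expect_true(h$passes)

  # a third bulge breaks the bulge rule
  al <- append(al, "-", after = 10L)
  pr <- append(pr, "G", after = 10L)
  h <- evaluate_hairpin(ir_row(paste(al, collapse = ""),
                               paste(pr, collapse = ""), 10L))
  expect_identical(h$asym_bulge_count, 3L)
  expect_false(h$passes)
})

test_that("screening requires expression and structure jointly", {
  good <- perfect_stem(25L)
  bad <- perfect_stem(25L); bad$loop_len <- 50L
  irs <- rbind(good, bad)
  sc <- screen_candidates(irs, hairpin_criteria(), expression = c(0, 100))
  expect_false(any(sc$retained))          # passing hairpin unexpressed,
  expect_identical(sc$expressed, c(FALSE, TRUE))
  expect_identical(sc$passes, c(TRUE, FALSE))

  sc2 <- screen_candidates(irs, hairpin_criteria(), expression = c(100, 100))
  expect_identical(sc2$retained, c(TRUE, FALSE))

  expect_error(screen_candidates(irs, hairpin_criteria(), expression = 1),
               "does not match")
})

test_that("tightening any single criterion never grows the retained set", {
  set.seed(71)
  irs <- do.call(rbind, lapply(1:12, function(k) {
    arm <- strsplit(random_seq(sample(18:30, 1)), "")[[1]]
    partner <- slocusmod:::complement_chars(arm)
    nmm <- sample(0:5, 1)
    if (nmm > 0) {
      at <- sample(seq_along(arm), nmm)
      partner[at] <- arm[at]
    }
    ir_row(paste(arm, collapse = ""), paste(partner, collapse = ""),
           sample(c(5L, 39L, 40L, 45L), 1))
  }))
  expr <- rep(100, nrow(irs))
  base <- screen_candidates(irs, hairpin_criteria(), expr)
  for (tight in list(hairpin_criteria(max_terminal_loop = 20L),
                     hairpin_criteria(min_paired_stem = 25L),
                     hairpin_criteria(max_mismatches = 1L),
                     hairpin_criteria(max_asym_bulges = 0L))) {
    tightened <- screen_candidates(irs, tight, expr)
    expect_true(all(which(tightened$retained) %in% which(base$retained)))
  }
})

test_that("hairpin metrics survive reverse-complementing the locus", {
  set.seed(72)
  pl <- planted_ir_seq(arm_len = 25L, loop_len = 12L)
  fwd <- evaluate_hairpin(find_inverted_repeats(pl$seq))
  rev <- evaluate_hairpin(find_inverted_repeats(revcomp(pl$seq)))
  expect_identical(nrow(fwd), 1L)
  cols <- c("loop_len", "paired_len", "mismatch_count", "asym_bulge_count",
            "passes")
  expect_identical(fwd[, cols], rev[, cols])
})
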