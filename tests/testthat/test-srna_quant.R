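test_that("read filtering clips adapters, bounds lengths, collapses copies", {
  adapter <- "AGATCGGAAGAGCACACGTCT"
  set.seed(41)
  insert <- random_seq(24)
  reads <- data.frame(
    seq = c(paste0(insert, substr(adapter, 1, 10)),  # adapter-bearing
            random_seq(17),                          # too short
            rep("ACGTACGTACGTACGTACGTA", 3)),        # identical triplet
    count = 1L)
  out <- filter_reads(reads, adapter = adapter)
  expect_true(insert %in% out$seq)
  expect_false(any(nchar(out$seq) < 18L | nchar(out$seq) > 27L))
  expect_identical(out$count[out$seq == "ACGTACGTACGTACGTACGTA"], 3L)

  # a read that is pure adapter collapses to nothing
  out2 <- filter_reads(data.frame(seq = adapter, count = 1L),
                       adapter = adapter)
  expect_identical(nrow(out2), 0L)
})

test_that("read mapping agrees with a naive full-scan oracle", {
  set.seed(42)
  refs <- c(r1 = random_seq(3000), r2 = random_seq(2000))
  reads <- data.frame(seq = c(substr(refs[1], 101, 124),
                              revcomp(substr(refs[2], 501, 522)),
                              random_seq(24)),
                      count = c(2L, 1L, 1L))
  mapped <- map_reads(reads, refs)
  for (rd in reads$seq) {
    want <- oracle_map_read(rd, refs)
    got <- mapped[mapped$seq == rd, c("seq_id", "start", "end", "strand")]
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- want[order(want$seq_id, want$start, want$strand), ]
      expect_equal(got, want, ignore_attr = TRUE)
      expect_true(all(mapped$n_placements[mapped$seq == rd] == nrow(want)))
    }
  }
})

test_that("a read planted twice reports both placements with n_placements 2", {
  set.seed(43)
  site <- random_seq(22)
  ref <- c(chr = paste0(random_seq(400), site, random_seq(300), site,
                        random_seq(200)))
  m <- map_reads(data.frame(seq = site, count = 5L), ref)
  expect_identical(nrow(m), 2L)
  expect_identical(m$start, c(401L, 723L))
  expect_true(all(m$n_placements == 2L))
})

test_that("one-mismatch mapping accepts near-exact placements", {
  set.seed(44)
  ref <- c(chr = random_seq(1500))
  site <- substr(ref, 701, 724)
  mut <- paste0(substr(site, 1, 11), "N", substr(site, 13, 24))
  mut <- sub("N", setdiff(c("A", "C", "G", "T"),
                          substr(site, 12, 12))[1], mut)
  expect_identical(nrow(map_reads(data.frame(seq = mut, count = 1L), ref,
                                  max_mismatches = 0L)), 0L)
  m1 <- map_reads(data.frame(seq = mut, count = 1L), ref, max_mismatches = 1L)
  expect_true(any(m1$start == 701L & m1$strand == "+"))
})

test_that("quantification assigns overlapping copies and size classes", {
  set.seed(45)
  ref <- c(chr = random_seq(1000))
  prec <- data.frame(id = "p1", seq_id = "chr", start = 401L, end = 520L)
  # 10 copies of a 24-nt read fully inside the precursor
  rd <- substr(ref, 451, 474)
  q <- quantify(map_reads(data.frame(seq = rd, count = 10L), ref), prec)
  expect_identical(q$table$total_count, 10)
  expect_identical(q$table$len_24, 10)
  expect_identical(sum(unlist(q$table[, sprintf("len_%d", 18:27)])), 10)
  expect_identical(q$coverage$p1[51:74], rep(10, 24))
  expect_identical(q$coverage$p1[1], 0)

  # nothing overlapping: zero
  far <- data.frame(id = "p2", seq_id = "chr", start = 901L, end = 950L)
  q0 <- quantify(map_reads(data.frame(seq = rd, count = 10L), ref), far)
  expect_identical(q0$table$total_count, 0)
})

test_that("disjoint precursors never double-count and multimappers down-weight", {
  set.seed(46)
  site <- random_seq(22)
  ref <- c(chr = paste0(random_seq(100), site, random_seq(300), site,
                        random_seq(100)))
  prec <- data.frame(id = c("a", "b"), seq_id = "chr",
                     start = c(81L, 401L), end = c(160L, 460L))
  mapped <- map_reads(data.frame(seq = site, count = 6L), ref)
  q <- quantify(mapped, prec)
  # each placement weighted 1/2: totals sum to the 6 input copies
  expect_equal(sum(q$table$total_count), 6)
  qu <- quantify(mapped, prec, multimapper = "unique")
  expect_equal(sum(qu$table$total_count), 0)
})
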