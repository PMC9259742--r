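test_that("expected errors sum per-base error probabilities", {
  expect_equal(expected_errors(rep(20, 10)), 0.1)
  expect_equal(expected_errors(0), 1.0)
  expect_equal(expected_errors(c(10, 20, 30)), 0.111)
  # string form agrees with numeric form
  q <- phred_string_for_test(c(10, 20, 30))
  expect_equal(expected_errors(q), 0.111)
})

test_that("identical fully-overlapping reads merge to a single read", {
  set.seed(1)
  s <- random_dna(50)
  m <- merge_pairs(s, revcomp(s), min_overlap = 10, max_overlap = 100)
  expect_true(m$merged)
  expect_identical(m$seq, s)
  expect_identical(m$overlap, 50L)
})

test_that("a planted exact overlap is found and is the global optimum", {
  set.seed(7)
  for (i in 1:25) {
    lf <- sample(40:120, 1)
    lr <- sample(40:120, 1)
    ov <- sample(20:min(lf, lr, 100), 1)
    p <- random_pair(lf, lr, ov)
    m <- merge_pairs(p$fwd, p$rev)
    o <- oracle_merge(p$fwd, p$rev)
    expect_true(m$merged)
    expect_identical(nchar(m$seq), o$merged_length)
    expect_identical(m$overlap, o$overlap)
    # the planted overlap is exact, so the chosen overlap has zero mismatches
    expect_identical(m$mismatches, 0L)
  }
})

test_that("overlap disagreements resolve to the higher-quality base, ties to N", {
  fwd <- "ACGTACGTAC"
  # full 10-bp overlap; reverse read disagrees at position 1 (A vs T)
  rev_frag <- "TCGTACGTAC"
  q_hi <- phred_string_for_test(rep(35, 10))
  q_lo <- phred_string_for_test(rep(20, 10))
  m <- merge_pairs(fwd, revcomp(rev_frag), fwd_qual = q_hi, rev_qual = q_lo,
                   min_overlap = 10, max_mismatch_density = 0.5)
  expect_identical(substr(m$seq, 1, 1), "A")
  m2 <- merge_pairs(fwd, revcomp(rev_frag), fwd_qual = q_lo, rev_qual = q_hi,
                    min_overlap = 10, max_mismatch_density = 0.5)
  expect_identical(substr(m2$seq, 1, 1), "T")
  m3 <- merge_pairs(fwd, revcomp(rev_frag), fwd_qual = q_hi, rev_qual = q_hi,
                    min_overlap = 10, max_mismatch_density = 0.5)
  expect_identical(substr(m3$seq, 1, 1), "N")
  # merged quality is the max of the two
  expect_identical(utf8ToInt(m$qual)[1] - 33L, 35L)
})

test_that("pairs with no acceptable overlap are rejected, empty reads error", {
  set.seed(2)
  a <- random_dna(60)
  b <- random_dna(60)
  m <- merge_pairs(a, b, max_mismatch_density = 0.05)
  # two unrelated random reads almost surely exceed a 5% density cap
  expect_false(m$merged)
  expect_error(merge_pairs("", "ACGT"), "empty read")
})

test_that("merge agrees with the exhaustive offset-search oracle", {
  set.seed(42)
  for (i in 1:60) {
    lf <- sample(30:200, 1)
    lr <- sample(30:200, 1)
    ov <- sample(12:min(lf, lr), 1)
    p <- random_pair(lf, lr, ov, n_mismatch = sample(0:2, 1))
    m <- merge_pairs(p$fwd, p$rev)
    o <- oracle_merge(p$fwd, p$rev)
    if (is.null(o)) {
      expect_false(m$merged)
    } else {
      expect_true(m$merged)
      expect_identical(m$overlap, o$overlap)
      expect_identical(m$mismatches, o$mismatches)
    }
  }
})

test_that("read filter applies inclusive maxee and closed length bounds", {
  reads <- data.frame(
    seq = c(strrep("A", 10), strrep("A", 10), strrep("A", 99), strrep("A", 100)),
    qual = c(
      phred_string_for_test(rep(20, 10)),   # EE = 0.1
      phred_string_for_test(rep(10, 10)),   # EE = 1.0, boundary: retained
      phred_string_for_test(rep(30, 99)),
      phred_string_for_test(rep(30, 100))
    ),
    stringsAsFactors = FALSE
  )
  out <- filter_reads(reads, maxee = 1, length_range = c(10, 10))
  expect_identical(nrow(out$retained), 2L)
  expect_setequal(out$rejected$reason, "length")
  # a 99-bp read is outside a [100, 122] amplicon window
  out2 <- filter_reads(reads[3:4, ], maxee = 1, length_range = c(100, 122))
  expect_identical(nrow(out2$retained), 1L)
  expect_identical(out2$rejected$reason, "length")
  expect_error(filter_reads(reads, length_range = c(10, 5)), "min > max")
})

test_that("read filter partitions its input", {
  set.seed(3)
  reads <- data.frame(
    seq = replicate(50, random_dna(sample(80:120, 1))),
    stringsAsFactors = FALSE
  )
  reads$qual <- vapply(seq_len(50), function(i) {
    phred_string_for_test(rep(sample(c(5, 30), 1), nchar(reads$seq[i])))
  }, character(1))
  out <- filter_reads(reads, maxee = 1, length_range = c(90, 110))
  expect_identical(nrow(out$retained) + nrow(out$rejected), nrow(reads))
  combined <- rbind(out$retained[, c("seq", "qual")], out$rejected[, c("seq", "qual")])
  expect_setequal(
    paste(combined$seq, combined$qual),
    paste(reads$seq, reads$qual)
  )
})

test_that("dereplication pools counts across samples and drops singletons", {
  reads <- data.frame(
    sample = c("A", "A", "A", "B", "B", "C"),
    seq = c("ACGT", "ACGT", "ACGT", "ACGT", "ACGT", "TTTT"),
    stringsAsFactors = FALSE
  )
  ot <- dereplicate(reads)
  expect_identical(nrow(ot$otus), 1L)
  expect_identical(ot$otus$total, 5L)
  expect_identical(
    ot$counts$count[order(ot$counts$sample)],
    c(3L, 2L)
  )
  expect_identical(attr(ot, "dropped")$seq, "TTTT")
  ot2 <- dereplicate(reads, remove_singletons = FALSE)
  expect_identical(nrow(ot2$otus), 2L)
})

test_that("dereplication conserves reads and is idempotent", {
  set.seed(9)
  reads <- data.frame(
    sample = sample(c("A", "B", "C"), 200, replace = TRUE),
    seq = replicate(200, random_dna(8)), # short, so duplicates arise
    stringsAsFactors = FALSE
  )
  ot <- dereplicate(reads)
  expect_identical(
    sum(ot$counts$count) + sum(attr(ot, "dropped")$total),
    nrow(reads)
  )
  # idempotence at count level: re-dereplicating the OTU table changes nothing
  again <- dereplicate(
    data.frame(sample = ot$counts$sample,
               seq = ot$otus$seq[match(ot$counts$otu_id, ot$otus$otu_id)],
               count = ot$counts$count),
    remove_singletons = TRUE
  )
  expect_equal(sum(again$counts$count), sum(ot$counts$count))
  expect_setequal(again$otus$seq, ot$otus$seq)
})

test_that("FASTQ round-trip preserves sequences, qualities and sample tokens", {
  reads <- data.frame(
    id = c("r1", "r2"), sample = c("S1", "S2"),
    seq = c("ACGTACGT", "TTGGCCAA"),
    qual = c("IIIIIIII", "33333333"),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(back$sample, reads$sample)
})
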