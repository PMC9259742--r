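test_that("zero divergence gives identical barcodes, targets land within 1 pp", {
  spec0 <- list(
    taxonomy = data.frame(
      species = c("A a", "B b"), genus = c("A", "B"),
      family = c("F", "F"), group = c("O", "O"), present = TRUE
    ),
    markers = data.frame(marker = "m", role = "prey", length = 120L),
    divergence = c(m = 0)
  )
  pool0 <- generate_reference_db(spec0, 1)
  expect_identical(pool0$refs$seq[1], pool0$refs$seq[2])

  spec10 <- spec0
  spec10$taxonomy <- data.frame(
    species = paste("Sp", 1:4), genus = paste("G", 1:4),
    family = "F", group = "O", present = TRUE
  )
  spec10$divergence <- c(m = 10)
  pool10 <- generate_reference_db(spec10, 1)
  m <- pairwise_identity(pool10, "m")
  off <- m[upper.tri(m)]
  expect_true(all(off >= 89 & off <= 91))
})

test_that("reference generation is deterministic and rejects unreachable targets", {
  spec <- default_pool_spec()
  a <- generate_reference_db(spec, 99)
  b <- generate_reference_db(spec, 99)
  expect_identical(a$refs, b$refs)
  c <- generate_reference_db(spec, 100)
  expect_false(identical(a$refs$seq, c$refs$seq))
  short <- list(
    taxonomy = data.frame(
      species = paste("Sp", 1:30), genus = paste("G", 1:30),
      family = "F", group = "O", present = TRUE
    ),
    markers = data.frame(marker = "m", role = "prey", length = 100L),
    divergence = c(m = 40)
  )
  expect_error(generate_reference_db(short, 1), "unreachable")
  bad <- short
  bad$divergence <- c(m = 60)
  expect_error(generate_reference_db(bad, 1), "\\[0, 50\\]")
})

test_that("full blocking leaves zero depositor reads on the prey marker", {
  pool <- generate_reference_db(default_pool_spec(), 2)
  design <- small_design(c(Touran = 4), budget = 5000, error_rate = 0)
  design$blocking_efficiency <- 1
  design$crosstalk_rate <- 0
  run <- simulate_scat_dataset(design, pool, 2)
  prey <- run$groups[run$groups$marker == "prey12S", ]
  for (i in seq_len(nrow(run$truth))) {
    dep_reads <- prey$count[prey$sample == run$truth$sample[i] &
                              prey$species == run$truth$depositor[i]]
    expect_identical(sum(dep_reads), 0L)
  }
})

test_that("zero crosstalk keeps every read in its source sample", {
  pool <- generate_reference_db(default_pool_spec(), 3)
  design <- small_design(c(Touran = 3), budget = 2000)
  design$crosstalk_rate <- 0
  run <- simulate_scat_dataset(design, pool, 3)
  expect_identical(run$groups$sample, run$groups$source)
})

test_that("realized crosstalk fraction is within 3 binomial SDs of nominal", {
  pool <- generate_reference_db(default_pool_spec(), 4)
  design <- small_design(c(Touran = 10, Yazd = 10), budget = 10000,
                         error_rate = 0)
  design$crosstalk_rate <- 0.01
  run <- simulate_scat_dataset(design, pool, 4)
  total <- sum(run$groups$count)
  moved <- sum(run$groups$count[run$groups$sample != run$groups$source])
  p_hat <- moved / total
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / total))
})

test_that("read budgets are conserved through crosstalk", {
  pool <- generate_reference_db(default_pool_spec(), 6)
  design <- small_design(c(Touran = 4), budget = 3000)
  design$crosstalk_rate <- 0.02
  run <- simulate_scat_dataset(design, pool, 6)
  # totals per (source sample, marker) equal the budget: reads move, never vanish
  per_source <- tapply(run$groups$count,
                       list(run$groups$source, run$groups$marker), sum)
  pred <- per_source[, "pred16S"]
  expect_true(all(pred == design$read_budget))
})

test_that("a fixed seed reproduces the simulated run bit-identically", {
  pool <- generate_reference_db(default_pool_spec(), 7)
  design <- small_design(c(Touran = 3), budget = 2000)
  r1 <- simulate_scat_dataset(design, pool, 7)
  r2 <- simulate_scat_dataset(design, pool, 7)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$groups, r2$groups)
  r3 <- simulate_scat_dataset(design, pool, 8)
  expect_false(identical(r1$groups, r3$groups))
})

test_that("simulator enforces its preconditions", {
  pool <- generate_reference_db(default_pool_spec(), 1)
  design <- small_design(c(Touran = 2))
  bad <- design
  bad$read_budget <- 0
  expect_error(simulate_scat_dataset(bad, pool, 1), "budget")
  bad <- design
  bad$crosstalk_rate <- 0.2
  expect_error(simulate_scat_dataset(bad, pool, 1), "crosstalk")
  bad <- design
  bad$diet_probs <- c("Ovis vignei" = 0.5, "Lepus capensis" = 0.4)
  expect_error(simulate_scat_dataset(bad, pool, 1), "sum to 1")
  empty_pool <- pool
  empty_pool$refs <- pool$refs[0, ]
  expect_error(simulate_scat_dataset(design, empty_pool, 1), "empty")
})

test_that("truth respects its invariants: diet non-empty, depositor excluded", {
  pool <- generate_reference_db(default_pool_spec(), 12)
  design <- small_design(c(Touran = 10, Miandasht = 10), budget = 1000,
                         error_rate = 0)
  run <- simulate_scat_dataset(design, pool, 12)
  diets <- strsplit(run$truth$diet, ";", fixed = TRUE)
  expect_true(all(lengths(diets) >= 1))
  expect_true(all(lengths(diets) <= 3))
  for (i in seq_len(nrow(run$truth))) {
    expect_false(run$truth$depositor[i] %in% diets[[i]])
  }
})

test_that("simulated reads carry the declared quality mix and marker lengths", {
  pool <- generate_reference_db(default_pool_spec(), 13)
  design <- small_design(c(Touran = 2), budget = 5000, error_rate = 0)
  run <- simulate_scat_dataset(design, pool, 13)
  g <- run$groups
  quals <- unique(c(g$fwd_qual, g$rev_qual))
  scores <- sort(unique(utf8ToInt(paste(quals, collapse = "")) - 33L))
  expect_setequal(scores, c(design$qual_low, design$qual_high))
  first_score <- utf8ToInt(paste0(substr(g$fwd_qual, 1, 1), collapse = "")) - 33L
  low <- sum(g$count[first_score == design$qual_low])
  p_low <- low / sum(g$count)
  expect_lt(abs(p_low - design$low_qual_fraction),
            3 * sqrt(design$low_qual_fraction / sum(g$count)) + 0.002)
  expect_true(all(nchar(g$fwd) == design$read_length))
})

test_that("FASTQ export expands weighted groups to the exact read count", {
  pool <- generate_reference_db(default_pool_spec(), 14)
  design <- small_design(c(Touran = 2), budget = 200, error_rate = 0.005)
  run <- simulate_scat_dataset(design, pool, 14)
  dir <- tempfile()
  paths <- write_run_fastq(run, dir)
  r1 <- read_fastq(paths[["prey12S"]][1])
  expect_identical(nrow(r1), sum(run$groups$count[run$groups$marker == "prey12S"]))
  expect_setequal(unique(r1$sample), unique(run$truth$sample))
})
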