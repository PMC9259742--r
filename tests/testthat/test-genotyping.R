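test_that("consensus rules accept het x2, hom x3, and shared-allele partials", {
  # heterozygote observed in two PCRs
  r <- reps_for(list(c(140, 144), c(140, 144), c(140, 140), NULL))
  cl <- consensus_locus(r$a1, r$a2)
  expect_identical(c(cl$a1, cl$a2), c(140L, 144L))
  expect_identical(cl$status, "called")
  # homozygote needs three
  r <- reps_for(list(c(140, 140), c(140, 140), c(140, 140), NULL))
  cl <- consensus_locus(r$a1, r$a2)
  expect_identical(c(cl$a1, cl$a2), c(140L, 140L))
  r <- reps_for(list(c(140, 140), c(140, 140), NULL, NULL))
  cl <- consensus_locus(r$a1, r$a2)
  expect_identical(cl$status, "partial") # two amplified replicates share 140
  expect_identical(cl$a1, 140L)
  expect_true(is.na(cl$a2))
  # exactly two amplified replicates sharing one allele -> partial
  r <- reps_for(list(c(140, 140), c(140, 144), NULL, NULL))
  cl <- consensus_locus(r$a1, r$a2)
  expect_identical(cl$status, "partial")
  expect_identical(cl$a1, 140L)
  # nothing qualifies
  r <- reps_for(list(c(140, 140), c(144, 144), NULL, NULL))
  expect_identical(consensus_locus(r$a1, r$a2)$status, "missing")
})

test_that("conflicting heterozygotes each seen twice give a flagged missing call", {
  r <- reps_for(list(c(140, 144), c(140, 144), c(140, 148), c(140, 148)))
  cl <- consensus_locus(r$a1, r$a2)
  expect_identical(cl$status, "missing")
  expect_true(cl$conflict)
})

test_that("consensus is invariant to replicate order", {
  set.seed(31)
  calls <- list(c(140, 144), c(140, 140), NULL, c(140, 144))
  base <- reps_for(calls)
  ref <- consensus_locus(base$a1, base$a2)
  for (i in 1:5) {
    p <- sample(4)
    r <- reps_for(calls[p])
    expect_identical(consensus_locus(r$a1, r$a2), ref)
  }
})

test_that("samples at exactly 70% screening success are rejected", {
  # 10 replicate x locus observations, 7 amplified: success 0.70, not > 0.70
  reps <- do.call(rbind, lapply(1:5, function(l) {
    reps_for(list(c(140, 144), if (l <= 3) NULL else c(140, 144)),
             locus = paste0("L", l))
  }))
  g <- consensus_genotype(reps, min_success = 0.70)
  expect_equal(g$success, 0.7)
  expect_false(g$accepted)
  reps2 <- reps
  reps2$a1[is.na(reps2$a1)][1] <- 140L
  reps2$a2[is.na(reps2$a2)][1] <- 144L
  expect_true(consensus_genotype(reps2, min_success = 0.70)$accepted)
})

test_that("identical genotypes merge, one-locus differences split", {
  truth <- simulate_individual_genotypes(2, seed = 3)$genotypes
  cons <- consensus_from_truth(
    truth,
    samples = data.frame(sample = c("A", "B", "C"),
                         individual = c("IND01", "IND01", "IND02"))
  )
  out <- match_individuals(cons)
  expect_identical(out$individual_id[out$sample == "A"],
                   out$individual_id[out$sample == "B"])
  expect_false(out$individual_id[out$sample == "C"] ==
                 out$individual_id[out$sample == "A"])
  # a single disagreeing locus splits at max_mismatch_loci = 0
  truth2 <- truth[truth$individual == "IND01", ]
  truth2$individual <- "IND01b"
  truth2$a1[1] <- truth2$a1[1] + 2L
  truth2$a2[1] <- max(truth2$a1[1], truth2$a2[1])
  cons2 <- consensus_from_truth(
    rbind(truth[truth$individual == "IND01", ], truth2),
    samples = data.frame(sample = c("A", "B"),
                         individual = c("IND01", "IND01b"))
  )
  out2 <- match_individuals(cons2)
  expect_identical(length(unique(out2$individual_id)), 2L)
  expect_warning(
    out3 <- match_individuals(cons2, max_mismatch_loci = 1),
    "near-matching"
  )
  expect_identical(length(unique(out3$individual_id)), 1L)
})

test_that("partial calls match any genotype containing the allele", {
  g1 <- consensus_from_truth(
    data.frame(individual = "I", locus = paste0("L", 1:12),
               a1 = 100L, a2 = 104L),
    samples = data.frame(sample = "A", individual = "I")
  )[[1]]
  g2 <- g1
  g2$sample <- "B"
  g2$calls$a2[1] <- NA_integer_ # partial (100, .) at L1
  out <- match_individuals(list(g1, g2))
  expect_identical(length(unique(out$individual_id)), 1L)
})

test_that("error rates are zero for perfect replicates and count false alleles", {
  truth <- simulate_individual_genotypes(4, seed = 8)$genotypes
  reps <- simulate_replicate_genotypes(truth, ado_rate = 0, fa_rate = 0,
                                       n_reps = 4, seed = 8)
  expect_true(all(!is.na(reps$a1))) # no dropout, no failures
  cons <- consensus_genotypes(reps)
  er <- genotyping_error_rates(reps, cons)
  expect_equal(er$ado, 0)
  expect_equal(er$fa, 0)
  # one planted false allele among homozygote replicates: FA = 1 / n_obs
  truth1 <- data.frame(individual = "I", locus = paste0("L", sprintf("%02d", 1:5)),
                       a1 = 120L, a2 = 120L)
  reps1 <- simulate_replicate_genotypes(truth1, 0, 0, n_reps = 10, seed = 1)
  reps1$a2[1] <- 130L
  cons1 <- consensus_from_truth(truth1, data.frame(sample = "I", individual = "I"))
  er1 <- genotyping_error_rates(reps1, cons1)
  expect_equal(er1$fa_trials, 50)
  expect_equal(er1$fa, 1 / 50)
})

test_that("nominal ADO and FA rates are recovered within 3 binomial SDs", {
  grid <- expand.grid(ado = c(0.1, 0.3), fa = c(0.01, 0.05))
  truth <- simulate_individual_genotypes(10, seed = 13)$genotypes
  for (i in seq_len(nrow(grid))) {
    reps <- simulate_replicate_genotypes(
      truth, grid$ado[i], grid$fa[i], n_reps = 6, seed = 100 + i
    )
    cons <- consensus_from_truth(truth)
    er <- genotyping_error_rates(reps, cons)
    sd_ado <- sqrt(grid$ado[i] * (1 - grid$ado[i]) / er$ado_trials)
    expect_lt(abs(er$ado - grid$ado[i]), 3 * sd_ado + 1e-12)
    sd_fa <- sqrt(grid$fa[i] * (1 - grid$fa[i]) / er$fa_trials)
    expect_lt(abs(er$fa - grid$fa[i]), 3 * sd_fa + 1e-12)
  }
})

test_that("heterozygote dropout produces single-allele replicates at 2p(1-p)", {
  truth <- data.frame(individual = "I", locus = "L01", a1 = 140L, a2 = 144L)
  reps <- simulate_replicate_genotypes(truth, ado_rate = 0.5, fa_rate = 0,
                                       n_reps = 10000, seed = 2)
  single <- !is.na(reps$a1) & reps$a1 == reps$a2
  p <- mean(single[!is.na(reps$a1)] )
  # among non-failed replicates: P(single) = 2*0.5*0.5 / (1 - 0.25)
  want <- 0.5 / 0.75
  n <- sum(!is.na(reps$a1))
  expect_lt(abs(p - want), 3 * sqrt(want * (1 - want) / n))
  # unconditional single-allele fraction: 2 * 0.5 * 0.5
  p_all <- mean(single)
  expect_lt(abs(p_all - 0.5), 3 * sqrt(0.5 * 0.5 / nrow(reps)))
})

test_that("PID and PIDsibs match closed forms and brute-force enumeration", {
  expect_equal(pid(c(0.5, 0.5))$overall, 0.375)
  expect_equal(pid_sibs(c(0.5, 0.5))$overall, 0.59375)
  expect_equal(pid(1)$overall, 1)
  expect_equal(pid_sibs(1)$overall, 1)
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p <- stats::rgamma(k, 1)
    p <- p / sum(p)
    expect_equal(pid(p)$overall, oracle_pid(p), tolerance = 1e-12)
    expect_equal(pid_sibs(p)$overall, oracle_pid_sibs(p), tolerance = 1e-12)
  }
})

test_that("PID invariants hold: 0 < PID <= PIDsibs <= 1, product decreasing", {
  set.seed(42)
  freqs <- lapply(1:8, function(i) {
    p <- stats::rgamma(sample(2:6, 1), 1)
    stats::setNames(p / sum(p), seq_along(p))
  })
  names(freqs) <- paste0("L", 1:8)
  a <- pid(freqs)
  b <- pid_sibs(freqs)
  expect_true(all(a$per_locus > 0))
  expect_true(all(a$per_locus <= b$per_locus + 1e-15))
  expect_true(all(b$per_locus <= 1))
  # multi-locus PID is non-increasing as loci are added
  cum <- cumprod(a$per_locus)
  expect_true(all(diff(cum) <= 1e-15))
  expect_error(pid(numeric(0)), "no alleles")
})

test_that("allele frequencies come from one genotype per individual and sum to 1", {
  sim <- simulate_individual_genotypes(6, seed = 9)
  cons <- consensus_from_truth(sim$genotypes)
  fr <- allele_frequencies(cons)
  expect_identical(length(fr), nrow(sim$loci))
  expect_true(all(abs(vapply(fr, sum, numeric(1)) - 1) < 1e-9))
})

test_that("replicate tables round-trip through CSV with empty-field missing alleles", {
  truth <- simulate_individual_genotypes(2, seed = 4)$genotypes
  reps <- simulate_replicate_genotypes(truth, 0.3, 0.05, n_reps = 4, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_replicates(reps, f)
  back <- read_replicates(f)
  expect_identical(back$a1, reps$a1)
  expect_identical(back$a2, reps$a2)
  expect_true(any(is.na(back$a1))) # failures encoded as empty fields
})
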