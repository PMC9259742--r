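test_that("hit filter keeps boundary query cover and masks absent taxa", {
  tax <- toy_taxonomy()
  hits <- data.frame(
    otu_id = "OTU_0001",
    subject_species = c("Sp01", "Sp02", "Sp04", "Sp05"),
    pident = c(100, 99, 100, 100),
    qcovs = c(98, 97.9, 100, 98.0),
    length = 100L, bitscore = 200,
    stringsAsFactors = FALSE
  )
  out <- filter_hits(hits, 98, tax)
  # qcov 98.0 retained (inclusive); 97.9 dropped; Sp04 absent from region
  expect_setequal(out$subject_species, c("Sp01", "Sp05"))
  # pure filter: idempotent and a subset preserving order
  expect_identical(filter_hits(out, 98, tax), out)
  expect_true(all(out$qcovs >= 98))
  bad <- hits
  bad$subject_species[1] <- "Nonexistent species"
  expect_error(filter_hits(bad, 98, tax), "database mismatch")
})

test_that("binning follows the unanimity cascade", {
  tax <- toy_taxonomy()
  th <- binning_thresholds(99, 99, 99, 99)
  one <- data.frame(otu_id = "o", subject_species = "Sp03", pident = 100,
                    qcovs = 100, length = 100L, bitscore = 200)
  expect_identical(bin_otu(one, th, tax),
                   list(rank = "species", taxon = "Sp03"))
  # two congeneric species above the species threshold escalate to genus
  cong <- data.frame(otu_id = "o", subject_species = c("Sp01", "Sp02"),
                     pident = c(99.5, 99.2), qcovs = 100, length = 100L,
                     bitscore = 200)
  expect_identical(bin_otu(cong, th, tax),
                   list(rank = "genus", taxon = "Gen01"))
  # all hits below every threshold: unassigned
  low <- data.frame(otu_id = "o", subject_species = c("Sp01", "Sp02"),
                    pident = c(97, 97), qcovs = 100, length = 100L,
                    bitscore = 200)
  expect_identical(bin_otu(low, th, tax)$rank, "unassigned")
  expect_identical(bin_otu(low[0, ], th, tax)$rank, "unassigned")
})

test_that("binning equals the most-specific-unanimous oracle on random hit sets", {
  tax <- toy_taxonomy()
  set.seed(11)
  for (i in 1:150) {
    th <- binning_thresholds(
      species = sample(95:100, 1), genus = sample(92:95, 1),
      family = sample(90:92, 1), above_family = sample(85:90, 1)
    )
    hits <- random_hits(sample(1:8, 1), tax)
    got <- bin_otu(hits, th, tax)
    want <- oracle_bin(hits, th, tax)
    expect_identical(got$rank, want$rank)
    if (got$rank != "unassigned") expect_identical(got$taxon, want$taxon)
  }
})

test_that("raising thresholds degrades lineage-unanimous hits monotonically", {
  # monotonicity holds when all hits share one lineage (the threshold-tuning
  # regime); conflicting hit sets can legitimately become *more* specific
  # when a raised threshold prunes the conflicting hit
  tax <- toy_taxonomy()
  rank_level <- c(species = 4, genus = 3, family = 2, above_family = 1,
                  unassigned = 0)
  set.seed(12)
  for (i in 1:40) {
    sp <- sample(tax$species, 1)
    hits <- random_hits(sample(1:6, 1), tax)
    hits$subject_species <- sp
    lo <- binning_thresholds(96, 94, 92, 90)
    hi <- binning_thresholds(99, 97, 95, 93)
    expect_lte(
      rank_level[[bin_otu(hits, hi, tax)$rank]],
      rank_level[[bin_otu(hits, lo, tax)$rank]]
    )
  }
})

test_that("pruning a conflicting hit by raising a threshold can sharpen the call", {
  tax <- toy_taxonomy()
  hits <- data.frame(
    otu_id = "o", subject_species = c("Sp01", "Sp03"),
    pident = c(96, 95), qcovs = 100, length = 100L, bitscore = 200
  )
  lo <- bin_otu(hits, binning_thresholds(95, 93, 91, 89), tax)
  hi <- bin_otu(hits, binning_thresholds(96, 93, 91, 89), tax)
  expect_false(lo$rank == "species") # Sp01 vs Sp03 conflict at 95
  expect_identical(hi$rank, "species") # Sp03 pruned at 96
  expect_identical(hi$taxon, "Sp01")
})

test_that("threshold selection separates within from among identities", {
  ident <- rbind(
    data.frame(rank = "species", taxon = "A", type = "within",
               identity = c(99.5, 99.8, 100)),
    data.frame(rank = "species", taxon = "A", type = "among",
               identity = c(95, 96.5, 97))
  )
  out <- select_thresholds(ident)
  expect_identical(out$thresholds$species, 98)
  expect_false(any(out$diagnostics$warning))
  expect_equal(out$diagnostics$min_within[out$diagnostics$rank == "species"], 99.5)
  expect_equal(out$diagnostics$max_among[out$diagnostics$rank == "species"], 97)
})

test_that("inseparable identity distributions raise the warning flag", {
  ident <- rbind(
    data.frame(rank = "species", taxon = "A", type = "within",
               identity = c(96, 97, 98)),
    data.frame(rank = "species", taxon = "A", type = "among",
               identity = c(96, 97, 98))
  )
  out <- select_thresholds(ident)
  expect_true(any(out$diagnostics$warning))
})

test_that("selected thresholds reproduce the 99% operating point and stay monotone", {
  # among-taxon identities reaching 98 at every rank force thresholds of 99
  ident <- do.call(rbind, lapply(
    c("species", "genus", "family", "above_family"),
    function(r) rbind(
      data.frame(rank = r, taxon = "A", type = "within", identity = c(99.5, 100)),
      data.frame(rank = r, taxon = "A", type = "among", identity = c(96, 98))
    )
  ))
  out <- select_thresholds(ident)
  expect_identical(
    unclass(out$thresholds)[c("species", "genus", "family", "above_family")],
    list(species = 99, genus = 99, family = 99, above_family = 99)
  )
  t <- out$thresholds
  expect_true(t$above_family <= t$family && t$family <= t$genus &&
                t$genus <= t$species)
})

test_that("threshold constructor rejects non-monotone or out-of-range values", {
  expect_error(binning_thresholds(98, 99, 99, 99), "must satisfy")
  expect_error(binning_thresholds(101, 99, 99, 99), "0, 100")
})

test_that("synthetic aligner reports Hamming identity and ranks hits", {
  refs <- data.frame(
    species = c("X", "Y"),
    seq = c("ACGTACGTAC", "ACGTACGTTT"),
    stringsAsFactors = FALSE
  )
  otus <- data.frame(otu_id = "OTU_0001", seq = "ACGTACGTAC",
                     stringsAsFactors = FALSE)
  hits <- align_otus(otus, refs)
  expect_equal(hits$pident[hits$subject_species == "X"], 100)
  expect_equal(hits$pident[hits$subject_species == "Y"], 80)
  expect_identical(hits$subject_species[1], "X")
})

test_that("tabular hit files round-trip through the reader", {
  hits <- data.frame(
    otu_id = "OTU_0001", subject_species = "Sp01", pident = 99.5,
    qcovs = 100, length = 100L, bitscore = 180.5, stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".tsv")
  utils::write.table(hits, f, sep = "\t", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  back <- read_hits(f)
  expect_equal(back$pident, 99.5)
  expect_identical(back$subject_species, "Sp01")
})
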