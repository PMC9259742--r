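# Shared fixtures: built in code, deterministic under fixed seeds.

phred_string_for_test <- function(scores) intToUtf8(scores + 33L)

# All n! permutations of 1..n (for exhaustive accumulation-curve averages).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# A 20-species toy taxonomy with congeneric and confamilial structure,
# used by the binning tests.
toy_taxonomy <- function() {
  data.frame(
    species = paste0("Sp", sprintf("%02d", 1:20)),
    genus = paste0("Gen", sprintf("%02d", rep(1:10, each = 2))),
    family = paste0("Fam", sprintf("%02d", rep(1:5, each = 4))),
    group = paste0("Ord", rep(1:2, each = 10)),
    present = rep(c(TRUE, TRUE, TRUE, FALSE), 5),
    stringsAsFactors = FALSE
  )
}

random_hits <- function(n, taxonomy, otu_id = "OTU_0001") {
  data.frame(
    otu_id = otu_id,
    subject_species = sample(taxonomy$species, n, replace = TRUE),
    pident = round(stats::runif(n, 85, 100), 1),
    qcovs = 100,
    length = 100L,
    bitscore = stats::runif(n, 100, 200),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random read pair with a planted true overlap and optional mismatches.
random_pair <- function(len_f, len_r, overlap, n_mismatch = 0) {
  amplicon <- random_dna(len_f + len_r - overlap)
  fwd <- substr(amplicon, 1, len_f)
  rev_fragment <- substr(amplicon, len_f - overlap + 1, len_f + len_r - overlap)
  if (n_mismatch > 0) {
    s <- strsplit(rev_fragment, "")[[1]]
    pos <- sample(seq_along(s), n_mismatch)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    rev_fragment <- paste(s, collapse = "")
  }
  list(fwd = fwd, rev = revcomp(rev_fragment), amplicon = amplicon)
}

# Small synthetic design for fast end-to-end tests.
small_design <- function(n = c(Touran = 3, Yazd = 3), budget = 20000,
                         error_rate = 0.001) {
  d <- default_study_design(n)
  d$read_budget <- budget
  d$error_rate <- error_rate
  d
}

rep_row <- function(sample, replicate, locus, a1, a2) {
  data.frame(
    sample = sample, replicate = replicate, locus = locus,
    a1 = a1, a2 = a2, stringsAsFactors = FALSE
  )
}

# Replicate table for one sample from a list of per-replicate calls,
# each call either c(a1, a2) or NULL for a failed amplification.
reps_for <- function(calls, locus = "L01", sample = "S1") {
  do.call(rbind, lapply(seq_along(calls), function(i) {
    a <- calls[[i]]
    if (is.null(a)) {
      rep_row(sample, i, locus, NA_integer_, NA_integer_)
    } else {
      rep_row(sample, i, locus, a[1], a[2])
    }
  }))
}
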