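# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exhaustive overlap search: best (lowest mismatch density, ties -> longest)
# ungapped overlap between fwd and the reverse complement of rev.
oracle_merge <- function(fwd, rev, min_overlap = 10, max_overlap = 100,
                         max_mismatch_density = 0.25) {
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", rev), "")[[1]]), collapse = "")
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rc, "")[[1]]
  nf <- length(f)
  nr <- length(r)
  best <- NULL
  for (o in seq_len(min(max_overlap, nf, nr))) {
    if (o < min_overlap) next
    mm <- sum(f[(nf - o + 1):nf] != r[1:o])
    cand <- list(overlap = o, mismatches = mm, density = mm / o)
    if (is.null(best) || cand$density < best$density ||
        (cand$density == best$density && cand$overlap > best$overlap)) {
      best <- cand
    }
  }
  if (is.null(best) || best$density > max_mismatch_density) return(NULL)
  best$merged_length <- nf + nr - best$overlap
  best
}

# Most-specific-unanimous binning oracle: enumerate every (rank, taxon)
# candidate and accept the most specific rank at which the above-threshold
# hits are unanimous.
oracle_bin <- function(hits, thresholds, taxonomy) {
  ranks <- c("species", "genus", "family", "above_family")
  cols <- c(species = "species", genus = "genus", family = "family",
            above_family = "group")
  for (rank in ranks) {
    t <- thresholds[[rank]]
    pass <- hits[hits$pident >= t, , drop = FALSE]
    if (!nrow(pass)) next
    taxa <- taxonomy[[cols[[rank]]]][match(pass$subject_species, taxonomy$species)]
    candidates <- unique(taxonomy[[cols[[rank]]]])
    valid <- Filter(function(tx) all(taxa == tx), candidates)
    if (length(valid) == 1L) return(list(rank = rank, taxon = valid[[1]]))
  }
  list(rank = "unassigned", taxon = NA_character_)
}

# Entry-wise crosstalk-filter predicate oracle.
oracle_crosstalk <- function(entries, taxon_frac, sample_frac, min_reads) {
  keep <- logical(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    tt <- sum(entries$reads[entries$taxon == entries$taxon[i]])
    st <- sum(entries$reads[entries$sample == entries$sample[i]])
    keep[i] <- entries$reads[i] >= taxon_frac * tt &&
      entries$reads[i] >= sample_frac * st &&
      entries$reads[i] >= min_reads
  }
  keep
}

# PID oracle: P(two random HWE genotypes identical) by enumerating all
# ordered-pair genotypes.
oracle_pid <- function(p) {
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      total <- total + pg^2
    }
  }
  total
}

# PIDsibs oracle: enumerate parental genotype pairs; a sib's genotype draws
# one allele from each parent uniformly; accumulate P(genotype | parents)^2.
oracle_pid_sibs <- function(p) {
  k <- length(p)
  geno <- expand.grid(a = seq_len(k), b = seq_len(k))
  gp <- p[geno$a] * p[geno$b] # ordered parental genotypes, HWE
  total <- 0
  for (m in seq_len(nrow(geno))) {
    for (f in seq_len(nrow(geno))) {
      # child genotype distribution: one allele from each parent
      probs <- new.env()
      for (am in c(geno$a[m], geno$b[m])) {
        for (af in c(geno$a[f], geno$b[f])) {
          key <- paste(sort(c(am, af)), collapse = "_")
          probs[[key]] <- (probs[[key]] %||% 0) + 0.25
        }
      }
      total <- total + gp[m] * gp[f] *
        sum(vapply(ls(probs), function(k2) probs[[k2]]^2, numeric(1)))
    }
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a
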