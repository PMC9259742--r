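#' Consensus call at one locus from replicate PCRs
#'
#' Multiple-tubes consensus under three fixed evidence rules, applied in
#' order: (1) a heterozygote is accepted when the identical allele pair was
#' observed in at least two independent PCRs; (2) a homozygote is accepted
#' when observed in at least three; (3) when exactly two replicates
#' amplified and they share one allele, that allele alone is accepted with
#' missing data for the second. Anything else is missing. Two *different*
#' heterozygotes each seen twice are contradictory evidence: the locus is
#' missing with the `conflict` flag set. Heterozygote evidence takes
#' precedence over homozygote evidence because dropout can fake a
#' homozygote but not a heterozygote. Replicates are order-free; a replicate
#' with a single observed peak is recorded as an apparent homozygote
#' `(a, a)`, as fragment analysis cannot distinguish the two.
#'
#' @param a1,a2 integer vectors of replicate allele calls (sorted so
#'   `a1 <= a2`); a failed amplification is `NA, NA`.
#' @return list `a1`, `a2` (NA when not called), `status` (`"called"`,
#'   `"partial"`, `"missing"`), `conflict` (logical).
#' @export
consensus_locus <- function(a1, a2) {
  stopifnot(length(a1) == length(a2))
  a1 <- as.integer(a1)
  a2 <- as.integer(a2)
  ok <- !is.na(a1) & !is.na(a2)
  bad <- xor(is.na(a1), is.na(a2))
  if (any(bad)) stop("replicate calls must have 0 or 2 alleles (use (a, a) for one peak)")
  a1s <- pmin(a1, a2)
  a2s <- pmax(a1, a2)
  het <- ok & a1s != a2s
  hom <- ok & a1s == a2s
  # rule 1: identical heterozygote in >= 2 replicates
  if (any(het)) {
    pairs <- paste(a1s[het], a2s[het])
    tab <- table(pairs)
    winners <- names(tab)[tab >= 2]
    if (length(winners) > 1L) {
      return(list(a1 = NA_integer_, a2 = NA_integer_, status = "missing", conflict = TRUE))
    }
    if (length(winners) == 1L) {
      al <- as.integer(strsplit(winners, " ")[[1]])
      return(list(a1 = al[1], a2 = al[2], status = "called", conflict = FALSE))
    }
  }
  # rule 2: homozygote in >= 3 replicates
  if (any(hom)) {
    tab <- table(a1s[hom])
    winners <- names(tab)[tab >= 3]
    if (length(winners) == 1L) {
      al <- as.integer(winners)
      return(list(a1 = al, a2 = al, status = "called", conflict = FALSE))
    }
  }
  # rule 3: exactly two amplified replicates sharing one allele
  if (sum(ok) == 2L) {
    w <- which(ok)
    shared <- intersect(unique(c(a1s[w[1]], a2s[w[1]])), unique(c(a1s[w[2]], a2s[w[2]])))
    if (length(shared) == 1L) {
      return(list(a1 = shared, a2 = NA_integer_, status = "partial", conflict = FALSE))
    }
  }
  list(a1 = NA_integer_, a2 = NA_integer_, status = "missing", conflict = FALSE)
}

#' Consensus multi-locus genotype for one sample
#'
#' Applies [consensus_locus()] at every locus of a sample's replicate table.
#' Samples are first screened on amplification success over a screening
#' panel (by default all loci): the fraction of non-failed replicate x locus
#' observations must exceed `min_success` (strictly; a sample at exactly the
#' threshold is rejected).
#'
#' @param replicates data frame `sample`, `replicate`, `locus`, `a1`, `a2`
#'   for one sample (failed amplification = both `NA`).
#' @param min_success screening success threshold (default 0.70, strict >).
#' @param screening_loci loci used for the quality screen (default: all).
#' @return a `consensus_genotype`: list with `sample`, `calls` (data frame
#'   `locus`, `a1`, `a2`, `status`, `conflict`), `n_loci_called` (loci with
#'   at least one accepted allele), `success` and `accepted`.
#' @export
consensus_genotype <- function(replicates, min_success = 0.70,
                               screening_loci = NULL) {
  stopifnot(all(c("sample", "replicate", "locus", "a1", "a2") %in% names(replicates)))
  sample <- unique(replicates$sample)
  stopifnot(length(sample) == 1L)
  screening_loci <- screening_loci %||% unique(replicates$locus)
  scr <- replicates[replicates$locus %in% screening_loci, , drop = FALSE]
  success <- mean(!is.na(scr$a1))
  loci <- unique(replicates$locus)
  calls <- do.call(rbind, lapply(loci, function(l) {
    d <- replicates[replicates$locus == l, , drop = FALSE]
    cl <- consensus_locus(d$a1, d$a2)
    data.frame(
      locus = l, a1 = cl$a1, a2 = cl$a2, status = cl$status,
      conflict = cl$conflict, stringsAsFactors = FALSE
    )
  }))
  rownames(calls) <- NULL
  structure(
    list(
      sample = sample,
      calls = calls,
      n_loci_called = sum(!is.na(calls$a1)),
      success = success,
      accepted = success > min_success
    ),
    class = "consensus_genotype"
  )
}

#' @export
print.consensus_genotype <- function(x, ...) {
  cat(sprintf(
    "consensus_genotype %s: %d/%d loci called (%s; screening success %.0f%%)\n",
    x$sample, x$n_loci_called, nrow(x$calls),
    if (x$accepted) "accepted" else "rejected", 100 * x$success
  ))
  invisible(x)
}

#' Consensus genotypes for every sample in a replicate table
#'
#' @param replicates data frame `sample`, `replicate`, `locus`, `a1`, `a2`.
#' @inheritParams consensus_genotype
#' @return list of `consensus_genotype` objects (accepted samples only when
#'   `drop_rejected`), named by sample.
#' @param drop_rejected drop samples failing the quality screen
#'   (default TRUE).
#' @export
consensus_genotypes <- function(replicates, min_success = 0.70,
                                screening_loci = NULL, drop_rejected = TRUE) {
  samples <- sort(unique(replicates$sample))
  out <- lapply(samples, function(s) {
    consensus_genotype(
      replicates[replicates$sample == s, , drop = FALSE],
      min_success = min_success, screening_loci = screening_loci
    )
  })
  names(out) <- samples
  if (drop_rejected) out <- out[vapply(out, `[[`, logical(1), "accepted")]
  out
}

# Do two locus calls disagree? Partial calls (a, NA) match any call
# containing a; two partials match when they share their allele.
locus_mismatch <- function(a1x, a2x, a1y, a2y) {
  px <- is.na(a2x)
  py <- is.na(a2y)
  if (!px && !py) return(!(a1x == a1y && a2x == a2y))
  if (px && py) return(a1x != a1y)
  if (px) return(!(a1x %in% c(a1y, a2y)))
  !(a1y %in% c(a1x, a2x))
}

#' Match consensus genotypes into individuals
#'
#' Samples whose genotypes agree at every commonly-called locus (allowing up
#' to `max_mismatch_loci` disagreements) are the same individual; the
#' transitive closure of this match relation defines the individuals.
#' Partial single-allele calls match any call containing that allele. Pairs
#' sharing fewer than `min_shared_loci` called loci are never merged.
#' Individual labels are assigned deterministically in sample-id order.
#'
#' @param genotypes list of `consensus_genotype` objects
#'   (e.g. [consensus_genotypes()]).
#' @param max_mismatch_loci tolerated disagreeing loci per pair (default 0).
#' @param min_loci_called genotypes with fewer called loci are excluded
#'   from matching (default 10).
#' @param min_shared_loci minimum commonly-called loci for a pair to be
#'   comparable (default 5).
#' @return data frame `sample`, `individual_id`, `n_loci_called`; samples
#'   excluded for too few called loci carry `NA` individual ids.
#' @export
match_individuals <- function(genotypes, max_mismatch_loci = 0,
                              min_loci_called = 10, min_shared_loci = 5) {
  samples <- vapply(genotypes, `[[`, character(1), "sample")
  ord <- order(samples)
  genotypes <- genotypes[ord]
  samples <- samples[ord]
  nl <- vapply(genotypes, `[[`, integer(1), "n_loci_called")
  usable <- nl >= min_loci_called
  idx <- which(usable)
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  merged_warning <- FALSE
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      gi <- genotypes[[idx[i]]]$calls
      gi <- gi[!is.na(gi$a1), , drop = FALSE]
      for (j in seq.int(i + 1, n)) {
        gj <- genotypes[[idx[j]]]$calls
        gj <- gj[!is.na(gj$a1), , drop = FALSE]
        common <- intersect(gi$locus, gj$locus)
        if (length(common) < min_shared_loci) next
        mi <- match(common, gi$locus)
        mj <- match(common, gj$locus)
        mm <- sum(vapply(seq_along(common), function(k) {
          locus_mismatch(gi$a1[mi[k]], gi$a2[mi[k]], gj$a1[mj[k]], gj$a2[mj[k]])
        }, logical(1)))
        if (mm <= max_mismatch_loci) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) {
            parent[max(ri, rj)] <- min(ri, rj)
            if (mm > 0) merged_warning <- TRUE
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- sprintf("IND%02d", match(roots, unique(roots)))
  out <- data.frame(
    sample = samples,
    individual_id = NA_character_,
    n_loci_called = nl,
    stringsAsFactors = FALSE
  )
  out$individual_id[idx] <- labels
  if (merged_warning) {
    warning("near-matching genotypes merged (max_mismatch_loci > 0); check transitivity")
  }
  rownames(out) <- NULL
  out
}

#' Estimate allelic dropout and false allele rates
#'
#' Error rates of the replicate PCRs against the accepted consensus.
#' Allelic dropout (ADO) is scored per allele at consensus-heterozygous
#' loci: each of the two consensus alleles of every replicate observation is
#' a trial, and a dropout is an absence of that allele from the replicate.
#' Replicates containing a false (non-consensus) allele are excluded from
#' dropout scoring, since a substitution masquerades as a dropout; fully
#' failed replicates count as double dropout. The false allele (FA) rate is
#' the fraction of non-failed replicate observations at fully-called
#' consensus loci that contain at least one allele absent from the
#' consensus.
#'
#' @param replicates data frame `sample`, `replicate`, `locus`, `a1`, `a2`.
#' @param genotypes list of accepted `consensus_genotype` objects.
#' @return list with `ado`, `fa` (overall rates; `NA` when undefined),
#'   `per_locus` (data frame `locus`, `ado`, `fa`), and the underlying
#'   counts `ado_events`, `ado_trials`, `fa_events`, `fa_trials`.
#' @export
genotyping_error_rates <- function(replicates, genotypes) {
  loci <- sort(unique(replicates$locus))
  acc <- matrix(0, nrow = length(loci), ncol = 4,
                dimnames = list(loci, c("ado_e", "ado_t", "fa_e", "fa_t")))
  for (g in genotypes) {
    reps <- replicates[replicates$sample == g$sample, , drop = FALSE]
    for (k in seq_len(nrow(g$calls))) {
      call <- g$calls[k, ]
      if (is.na(call$a1)) next
      full <- !is.na(call$a2)
      cons <- unique(c(call$a1, call$a2))
      cons <- cons[!is.na(cons)]
      d <- reps[reps$locus == call$locus, , drop = FALSE]
      for (r in seq_len(nrow(d))) {
        obs <- c(d$a1[r], d$a2[r])
        obs <- unique(obs[!is.na(obs)])
        failed <- length(obs) == 0L
        foreign <- length(setdiff(obs, cons)) > 0L
        if (full && !failed) {
          acc[call$locus, "fa_t"] <- acc[call$locus, "fa_t"] + 1
          if (foreign) acc[call$locus, "fa_e"] <- acc[call$locus, "fa_e"] + 1
        }
        het <- full && call$a1 != call$a2
        if (het && !foreign) {
          acc[call$locus, "ado_t"] <- acc[call$locus, "ado_t"] + 2
          acc[call$locus, "ado_e"] <- acc[call$locus, "ado_e"] + sum(!(cons %in% obs))
        }
      }
    }
  }
  per_locus <- data.frame(
    locus = rownames(acc),
    ado = ifelse(acc[, "ado_t"] > 0, acc[, "ado_e"] / acc[, "ado_t"], NA_real_),
    fa = ifelse(acc[, "fa_t"] > 0, acc[, "fa_e"] / acc[, "fa_t"], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(per_locus) <- NULL
  list(
    ado = if (sum(acc[, "ado_t"]) > 0) sum(acc[, "ado_e"]) / sum(acc[, "ado_t"]) else NA_real_,
    fa = if (sum(acc[, "fa_t"]) > 0) sum(acc[, "fa_e"]) / sum(acc[, "fa_t"]) else NA_real_,
    per_locus = per_locus,
    ado_events = sum(acc[, "ado_e"]), ado_trials = sum(acc[, "ado_t"]),
    fa_events = sum(acc[, "fa_e"]), fa_trials = sum(acc[, "fa_t"])
  )
}

#' Allele frequencies from one genotype per individual
#'
#' Counts alleles per locus over a set of genotypes, one per identified
#' individual (never per scat, to avoid pseudo-replication). Partial calls
#' contribute their single known allele once; missing loci contribute
#' nothing.
#'
#' @param genotypes list of `consensus_genotype` objects, or a data frame
#'   `locus`, `a1`, `a2` of genotypes stacked over individuals.
#' @return named list: per locus, a named numeric vector of allele
#'   frequencies summing to 1.
#' @export
allele_frequencies <- function(genotypes) {
  if (is.data.frame(genotypes)) {
    calls <- genotypes
  } else {
    calls <- do.call(rbind, lapply(genotypes, `[[`, "calls"))
  }
  calls <- calls[!is.na(calls$a1), , drop = FALSE]
  loci <- sort(unique(calls$locus))
  out <- lapply(loci, function(l) {
    d <- calls[calls$locus == l, , drop = FALSE]
    alleles <- c(d$a1, d$a2)
    alleles <- alleles[!is.na(alleles)]
    tab <- table(alleles)
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- names(tab)
    freqs
  })
  names(out) <- loci
  out
}

#' Probability of identity (PID) of a marker panel
#'
#' Probability that two individuals drawn at random from a population in
#' Hardy-Weinberg equilibrium share a multi-locus genotype by chance. Per
#' locus with allele frequencies `p`,
#' `PID = sum(p^4) + sum_{i<j} (2 p_i p_j)^2`; the multi-locus PID is the
#' product over loci.
#'
#' @param freqs per-locus allele frequencies, as returned by
#'   [allele_frequencies()] (a single numeric vector is treated as one
#'   locus).
#' @return list with `per_locus` (named numeric) and `overall` (product).
#' @export
#' @examples
#' pid(c(0.5, 0.5)) # one locus, two equifrequent alleles: 0.375
pid <- function(freqs) {
  if (is.numeric(freqs)) freqs <- list(locus = freqs)
  per <- vapply(freqs, function(p) {
    check_freqs(p)
    s <- sum(p^4)
    if (length(p) > 1) {
      ij <- utils::combn(length(p), 2)
      s <- s + sum((2 * p[ij[1, ]] * p[ij[2, ]])^2)
    }
    s
  }, numeric(1))
  list(per_locus = per, overall = prod(per))
}

#' Probability of identity among siblings (PIDsibs)
#'
#' The sibling analogue of [pid()]: the probability that two full siblings
#' share a genotype, the conservative upper bound used to judge whether a
#' panel can separate close relatives. Per locus,
#' `PIDsibs = 0.25 + 0.5 sum(p^2) + 0.5 (sum(p^2))^2 - 0.25 sum(p^4)`.
#'
#' @inheritParams pid
#' @return list with `per_locus` and `overall`.
#' @export
#' @examples
#' pid_sibs(c(0.5, 0.5)) # 0.59375
pid_sibs <- function(freqs) {
  if (is.numeric(freqs)) freqs <- list(locus = freqs)
  per <- vapply(freqs, function(p) {
    check_freqs(p)
    s2 <- sum(p^2)
    0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
  }, numeric(1))
  list(per_locus = per, overall = prod(per))
}

#' Wrap known true genotypes as consensus objects
#'
#' Builds `consensus_genotype` objects directly from a truth genotype table,
#' one per sample. Useful as the error-free reference when scoring
#' [genotyping_error_rates()] against a known truth: estimates referenced to
#' a consensus formed from the same few replicates are conditioned on those
#' replicates and biased downward, whereas truth-referenced estimates
#' converge to the generator's nominal rates.
#'
#' @param truth data frame `individual`, `locus`, `a1`, `a2`.
#' @param samples optional data frame `sample`, `individual` (default: one
#'   sample per individual).
#' @return named list of `consensus_genotype` objects.
#' @export
consensus_from_truth <- function(truth, samples = NULL) {
  if (is.null(samples)) {
    samples <- data.frame(
      sample = unique(truth$individual),
      individual = unique(truth$individual),
      stringsAsFactors = FALSE
    )
  }
  out <- lapply(seq_len(nrow(samples)), function(i) {
    g <- truth[truth$individual == samples$individual[i], , drop = FALSE]
    calls <- data.frame(
      locus = g$locus, a1 = pmin(g$a1, g$a2), a2 = pmax(g$a1, g$a2),
      status = "called", conflict = FALSE, stringsAsFactors = FALSE
    )
    structure(
      list(
        sample = samples$sample[i], calls = calls,
        n_loci_called = nrow(calls), success = 1, accepted = TRUE
      ),
      class = "consensus_genotype"
    )
  })
  names(out) <- samples$sample
  out
}

#' Score consensus genotypes against known truth
#'
#' Fraction of fully-called consensus loci whose allele pair equals the true
#' genotype, pooled over samples.
#'
#' @param genotypes list of `consensus_genotype` objects.
#' @param truth data frame `individual`, `locus`, `a1`, `a2`.
#' @param samples data frame `sample`, `individual` mapping.
#' @return list with `accuracy`, `n_called`, `n_correct`.
#' @export
consensus_accuracy <- function(genotypes, truth, samples) {
  n_called <- 0L
  n_correct <- 0L
  for (g in genotypes) {
    ind <- samples$individual[match(g$sample, samples$sample)]
    tg <- truth[truth$individual == ind, , drop = FALSE]
    full <- g$calls[!is.na(g$calls$a1) & !is.na(g$calls$a2), , drop = FALSE]
    m <- match(full$locus, tg$locus)
    n_called <- n_called + nrow(full)
    n_correct <- n_correct + sum(
      full$a1 == pmin(tg$a1[m], tg$a2[m]) & full$a2 == pmax(tg$a1[m], tg$a2[m])
    )
  }
  list(
    accuracy = if (n_called) n_correct / n_called else NA_real_,
    n_called = n_called, n_correct = n_correct
  )
}

check_freqs <- function(p) {
  if (!length(p)) stop("locus with no alleles")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  invisible(p)
}

#' Read / write replicate genotype tables
#'
#' CSV layout: `sample`, `replicate`, `locus`, `a1`, `a2`; a missing allele
#' is an empty field, a failed amplification has both allele fields empty.
#'
#' @param path CSV path.
#' @return data frame (`read_replicates`) or `path` invisibly
#'   (`write_replicates`).
#' @export
read_replicates <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$a1 <- suppressWarnings(as.integer(x$a1))
  x$a2 <- suppressWarnings(as.integer(x$a2))
  x
}

#' @rdname read_replicates
#' @param replicates replicate table to write.
#' @export
write_replicates <- function(replicates, path) {
  utils::write.csv(replicates, path, row.names = FALSE, na = "")
  invisible(path)
}
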