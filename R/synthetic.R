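#' Default species pool specification
#'
#' The study-conditions species pool: the predator community and food-item
#' species of the central-Iran cheetah range, wild/domestic sheep and goat
#' counterparts, plus two extralimital congeners (flagged absent) to
#' exercise geographic masking. Three markers are declared: a mammal-generic
#' predator marker, a prey marker on which wild and domestic Ovis (and
#' Capra) are indistinguishable (shared clade), and a D-loop-style
#' wild/domestic marker carried only by Ovis and Capra.
#'
#' @return a pool specification list with `taxonomy`, `markers`,
#'   `divergence` and `clades` entries, suitable for
#'   [generate_reference_db()].
#' @export
default_pool_spec <- function() {
  taxonomy <- data.frame(
    species = c(
      "Acinonyx jubatus", "Caracal caracal", "Vulpes vulpes", "Canis lupus",
      "Hyaena hyaena", "Hystrix indica",
      "Ovis vignei", "Ovis aries", "Capra aegagrus", "Capra hircus",
      "Gazella subgutturosa", "Gazella bennettii", "Camelus dromedarius",
      "Sus scrofa", "Lepus capensis", "Meriones meridianus", "Mus musculus",
      "Gazella dorcas", "Lepus europaeus"
    ),
    genus = c(
      "Acinonyx", "Caracal", "Vulpes", "Canis", "Hyaena", "Hystrix",
      "Ovis", "Ovis", "Capra", "Capra", "Gazella", "Gazella", "Camelus",
      "Sus", "Lepus", "Meriones", "Mus", "Gazella", "Lepus"
    ),
    family = c(
      "Felidae", "Felidae", "Canidae", "Canidae", "Hyaenidae", "Hystricidae",
      "Bovidae", "Bovidae", "Bovidae", "Bovidae", "Bovidae", "Bovidae",
      "Camelidae", "Suidae", "Leporidae", "Muridae", "Muridae",
      "Bovidae", "Leporidae"
    ),
    group = c(
      "Carnivora", "Carnivora", "Carnivora", "Carnivora", "Carnivora",
      "Rodentia", "Artiodactyla", "Artiodactyla", "Artiodactyla",
      "Artiodactyla", "Artiodactyla", "Artiodactyla", "Artiodactyla",
      "Artiodactyla", "Lagomorpha", "Rodentia", "Rodentia",
      "Artiodactyla", "Lagomorpha"
    ),
    present = c(rep(TRUE, 17), FALSE, FALSE),
    domestication = c(
      rep(NA, 6),
      "wild", "domestic", "wild", "domestic",
      rep(NA, 7), NA, NA
    ),
    stringsAsFactors = FALSE
  )
  markers <- data.frame(
    marker = c("pred16S", "prey12S", "dloop"),
    role = c("predator", "prey", "wild_domestic"),
    length = c(120L, 110L, 110L),
    stringsAsFactors = FALSE
  )
  # on the prey marker wild/domestic congeners share a clade (identical
  # barcode), so binning escalates to genus and the D-loop marker resolves
  clades <- taxonomy$species
  names(clades) <- taxonomy$species
  prey_clades <- clades
  prey_clades[c("Ovis vignei", "Ovis aries")] <- "Ovis"
  prey_clades[c("Capra aegagrus", "Capra hircus")] <- "Capra"
  wd_species <- taxonomy$species[!is.na(taxonomy$domestication)]
  list(
    taxonomy = taxonomy,
    markers = markers,
    divergence = c(pred16S = 10, prey12S = 10, dloop = 10),
    clades = list(pred16S = clades, prey12S = prey_clades,
                  dloop = clades[wd_species]),
    marker_species = list(
      pred16S = taxonomy$species,
      prey12S = taxonomy$species,
      dloop = wd_species
    )
  )
}

#' Generate a concrete reference database from a pool specification
#'
#' Generates one barcode per (marker, species) by mutating a random marker
#' ancestor: each clade receives an exact number of substitutions
#' `k = round(length * divergence / 200)` at clade-private sites, so any two
#' clades differ at exactly `2k` sites and the realized pairwise divergence
#' lands within one percentage point of the target for sequences of 100 bp
#' or more. Species sharing a clade share a barcode (within-clade divergence
#' 0). Deterministic for a fixed seed. When the sequence is too short to
#' host disjoint site sets for all clades the divergence target is
#' unreachable and an error is raised.
#'
#' @param pool_spec a specification as from [default_pool_spec()]:
#'   `taxonomy`, `markers` (`marker`, `role`, `length`), `divergence`
#'   (named percent per marker, in `[0, 50]`), optional `clades` (named
#'   species->clade vector per marker) and `marker_species` (species
#'   declared per marker).
#' @param seed integer seed.
#' @return a `species_pool`: list with `taxonomy`, `markers`, `refs`
#'   (data frame `marker`, `species`, `clade`, `seq`).
#' @export
generate_reference_db <- function(pool_spec, seed) {
  taxonomy <- taxonomy_table(pool_spec$taxonomy)
  markers <- pool_spec$markers
  if (any(pool_spec$divergence < 0 | pool_spec$divergence > 50)) {
    stop("divergence targets must be in [0, 50] percent")
  }
  refs <- do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
    mk <- markers$marker[i]
    L <- markers$length[i]
    d <- pool_spec$divergence[[mk]]
    species <- pool_spec$marker_species[[mk]] %||% taxonomy$species
    clades <- pool_spec$clades[[mk]]
    if (is.null(clades)) {
      clades <- species
      names(clades) <- species
    }
    clades <- clades[species]
    uclades <- unique(clades)
    k <- round(L * d / 200)
    if (length(uclades) * k > L) {
      stop(sprintf(
        "marker %s: divergence target %g%% unreachable for %d clades at %d bp",
        mk, d, length(uclades), L
      ))
    }
    with_seed(derive_seed(seed, paste0("refdb/", mk)), {
      bases <- c("A", "C", "G", "T")
      ancestor <- sample(bases, L, replace = TRUE)
      sites <- if (k > 0) sample.int(L, length(uclades) * k) else integer(0)
      clade_seq <- vapply(seq_along(uclades), function(ci) {
        s <- ancestor
        if (k > 0) {
          own <- sites[seq.int((ci - 1) * k + 1, ci * k)]
          for (pos in own) s[pos] <- sample(setdiff(bases, s[pos]), 1)
        }
        paste(s, collapse = "")
      }, character(1))
      names(clade_seq) <- uclades
      data.frame(
        marker = mk, species = species, clade = unname(clades),
        seq = unname(clade_seq[clades]), stringsAsFactors = FALSE
      )
    })
  }))
  rownames(refs) <- NULL
  structure(
    list(taxonomy = taxonomy, markers = markers, refs = refs),
    class = "species_pool"
  )
}

#' @export
print.species_pool <- function(x, ...) {
  cat(sprintf(
    "species_pool: %d species (%d present), markers: %s\n",
    nrow(x$taxonomy), sum(x$taxonomy$present),
    paste(sprintf("%s (%d bp, %s)", x$markers$marker, x$markers$length,
                  x$markers$role), collapse = ", ")
  ))
  invisible(x)
}

#' Pairwise percent identity of reference barcodes
#'
#' @param pool a `species_pool`.
#' @param marker marker name.
#' @return symmetric matrix of percent identities between the marker's
#'   clade barcodes.
#' @export
pairwise_identity <- function(pool, marker) {
  refs <- pool$refs[pool$refs$marker == marker, , drop = FALSE]
  refs <- refs[!duplicated(refs$clade), , drop = FALSE]
  n <- nrow(refs)
  m <- matrix(100, n, n, dimnames = list(refs$clade, refs$clade))
  ints <- lapply(refs$seq, utf8ToInt)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        m[i, j] <- m[j, i] <- 100 * mean(ints[[i]] == ints[[j]])
      }
    }
  }
  m
}

#' Wild/domestic label reference database for the D-loop marker
#'
#' Re-labels the D-loop reference entries as `"<genus> wild"` /
#' `"<genus> domestic"` and builds the matching label taxonomy, so the same
#' [bin_otu()] machinery performs wild/domestic assignment.
#'
#' @param pool a `species_pool`.
#' @param marker the wild/domestic marker name (default the pool's
#'   `wild_domestic` role marker).
#' @return list with `refs` (data frame `species` = label, `seq`) and
#'   `taxonomy` (a label [taxonomy_table()]).
#' @export
wild_domestic_reference <- function(pool, marker = NULL) {
  marker <- marker %||% pool$markers$marker[pool$markers$role == "wild_domestic"][1]
  refs <- pool$refs[pool$refs$marker == marker, , drop = FALSE]
  tx <- pool$taxonomy[match(refs$species, pool$taxonomy$species), ]
  if (anyNA(tx$domestication)) {
    stop("wild/domestic marker species need domestication labels")
  }
  label <- paste(tx$genus, tx$domestication)
  lab_refs <- data.frame(species = label, seq = refs$seq, stringsAsFactors = FALSE)
  lab_tax <- data.frame(
    species = label, genus = tx$genus, family = tx$family, group = tx$group,
    present = TRUE, domestication = tx$domestication, stringsAsFactors = FALSE
  )
  lab_tax <- lab_tax[!duplicated(lab_tax$species), ]
  lab_refs <- lab_refs[!duplicated(lab_refs$species), ]
  list(refs = lab_refs, taxonomy = taxonomy_table(lab_tax))
}

#' Default study design for the synthetic scat survey
#'
#' Study-conditions defaults for [simulate_scat_dataset()]: four survey
#' regions, depositor composition following the observed depositor mix, a
#' food-item composition following the observed regional diets (1-2 items
#' per scat averaging 1.2), a read budget of 1e5 read pairs per sample and
#' marker, 0.1% between-sample crosstalk and 90% blocking-primer
#' suppression of depositor template on the prey marker.
#'
#' @param n_samples_per_area named integer vector (defaults to 10 per
#'   region).
#' @return a design list.
#' @export
default_study_design <- function(n_samples_per_area = c(
                                   Touran = 10, Miandasht = 10,
                                   Naybandan = 10, Yazd = 10
                                 )) {
  depositor <- c(
    "Acinonyx jubatus" = 0.4, "Vulpes vulpes" = 0.25, "Canis lupus" = 0.15,
    "Caracal caracal" = 0.1, "Hyaena hyaena" = 0.05, "Hystrix indica" = 0.05
  )
  diet <- c(
    "Ovis vignei" = 0.45, "Capra aegagrus" = 0.2, "Lepus capensis" = 0.15,
    "Gazella subgutturosa" = 0.08, "Sus scrofa" = 0.05,
    "Camelus dromedarius" = 0.05, "Meriones meridianus" = 0.02
  )
  list(
    areas = data.frame(
      area = names(n_samples_per_area),
      n_samples = as.integer(n_samples_per_area),
      stringsAsFactors = FALSE
    ),
    depositor_probs = depositor,
    diet_probs = diet,
    n_items_probs = c(`1` = 0.8, `2` = 0.2),
    read_budget = 1e5,
    error_rate = 0.001,
    crosstalk_rate = 0.001,
    blocking_efficiency = 0.9,
    low_qual_fraction = 0.01,
    qual_high = 30L,
    qual_low = 10L,
    read_length = 75L,
    n_individuals = 14L
  )
}

area_probs <- function(p, area) {
  if (is.list(p) && !is.data.frame(p)) p <- p[[area]] %||% p[["default"]] %||% stop("no probabilities for area ", area)
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1 (area ", area, ")")
  p
}

#' Simulate a ground-truthed scat metabarcoding dataset
#'
#' Generates, per scat sample: a depositor and 1-3 food items drawn from the
#' design's composition probabilities; predator-marker read pairs from the
#' depositor; prey-marker read pairs drawn multinomially over the diet
#' species plus residual depositor template at `(1 - blocking_efficiency)`
#' weight; wild/domestic-marker read pairs for Ovis/Capra items. Per-base
#' substitution errors occur at `error_rate`; a `low_qual_fraction` of reads
#' carries constant low Phred scores (to exercise the expected-error
#' filter), the rest constant high scores. Crosstalk then re-assigns each
#' read to a uniformly random other sample with probability
#' `crosstalk_rate`, preserving total read counts. Reads are carried as
#' weighted read groups (unique pair x count); [as_read_pairs()] or
#' [write_run_fastq()] expand them to individual records.
#'
#' @param design a design list, see [default_study_design()].
#' @param pool a `species_pool` from [generate_reference_db()].
#' @param seed integer seed; the run is reproducible given (design, seed).
#' @return a `scat_run`: list with `truth` (one row per sample: `sample`,
#'   `area`, `depositor`, `diet` (semicolon-separated), `individual_id`,
#'   `sex`, `read_budget`), `groups` (weighted read-pair groups with truth
#'   `species` and `source` sample), `design`, `seed`.
#' @export
simulate_scat_dataset <- function(design, pool, seed) {
  if (!nrow(pool$refs)) stop("empty species pool")
  if (design$read_budget < 1) stop("read budget must be >= 1")
  if (design$crosstalk_rate < 0 || design$crosstalk_rate > 0.05) {
    stop("crosstalk_rate must be in [0, 0.05]")
  }
  stopifnot(design$blocking_efficiency >= 0, design$blocking_efficiency <= 1)

  areas <- design$areas
  samples <- do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
    data.frame(
      sample = sprintf("%s_S%03d", areas$area[i], seq_len(areas$n_samples[i])),
      area = areas$area[i], stringsAsFactors = FALSE
    )
  }))

  # individuals: identities and sexes for the focal-predator samples
  n_ind <- design$n_individuals %||% 14L
  ind_ids <- sprintf("IND%02d", seq_len(n_ind))
  ind_sex <- with_seed(
    derive_seed(seed, "individuals"),
    sample(c("F", "M"), n_ind, replace = TRUE, prob = c(0.25, 0.75))
  )

  truth <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    a <- samples$area[i]
    with_seed(derive_seed(seed, paste0("truth/", s)), {
      dep_p <- area_probs(design$depositor_probs, a)
      dep <- sample(names(dep_p), 1, prob = dep_p)
      diet_p <- area_probs(design$diet_probs, a)
      diet_p <- diet_p[names(diet_p) != dep]
      diet_p <- diet_p / sum(diet_p)
      n_items <- as.integer(sample(
        names(design$n_items_probs), 1,
        prob = design$n_items_probs
      ))
      n_items <- min(n_items, length(diet_p))
      diet <- sample(names(diet_p), n_items, prob = diet_p)
      focal <- dep == "Acinonyx jubatus"
      ind <- if (focal) sample(ind_ids, 1) else NA_character_
      data.frame(
        sample = s, area = a, depositor = dep,
        diet = paste(sort(diet), collapse = ";"),
        individual_id = ind,
        sex = if (focal) ind_sex[match(ind, ind_ids)] else NA_character_,
        read_budget = design$read_budget,
        stringsAsFactors = FALSE
      )
    })
  }))

  markers <- pool$markers
  wd_species <- pool$taxonomy$species[!is.na(pool$taxonomy$domestication)]
  ref_seq <- function(marker, species) {
    pool$refs$seq[pool$refs$marker == marker & pool$refs$species == species]
  }

  # per-sample per-marker template composition, multinomial over weights
  groups <- list()
  for (i in seq_len(nrow(truth))) {
    s <- truth$sample[i]
    diet <- strsplit(truth$diet[i], ";", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(markers))) {
      mk <- markers$marker[j]
      role <- markers$role[j]
      w <- switch(role,
        predator = stats::setNames(1, truth$depositor[i]),
        prey = c(
          stats::setNames(rep(1, length(diet)), diet),
          stats::setNames(1 - design$blocking_efficiency, truth$depositor[i])
        ),
        wild_domestic = {
          sp <- intersect(diet, wd_species)
          if (!length(sp)) NULL else stats::setNames(rep(1, length(sp)), sp)
        }
      )
      w <- w[w > 0]
      if (is.null(w) || !length(w)) next
      counts <- with_seed(
        derive_seed(seed, paste0("reads/", s, "/", mk)),
        as.integer(stats::rmultinom(1, design$read_budget, w))
      )
      for (k in seq_along(w)) {
        if (counts[k] == 0) next
        groups[[length(groups) + 1L]] <- make_read_groups(
          sample = s, marker = mk, species = names(w)[k],
          template = ref_seq(mk, names(w)[k]), count = counts[k],
          design = design,
          seed = derive_seed(seed, paste0("err/", s, "/", mk, "/", names(w)[k]))
        )
      }
    }
  }
  groups <- do.call(rbind, groups)
  groups$source <- groups$sample

  groups <- apply_crosstalk(
    groups, samples$sample, design$crosstalk_rate,
    derive_seed(seed, "crosstalk")
  )

  structure(
    list(truth = truth, groups = groups, samples = samples,
         design = design, pool = pool, seed = seed),
    class = "scat_run"
  )
}

# Split `count` template copies into weighted read-pair groups:
# error-free vs substitution-bearing amplicons, high vs low quality.
make_read_groups <- function(sample, marker, species, template, count,
                             design, seed) {
  L <- nchar(template)
  rl <- min(design$read_length, L)
  e <- design$error_rate
  with_seed(seed, {
    n_err <- if (e > 0) stats::rbinom(1, count, 1 - (1 - e)^L) else 0L
    variants <- rep(template, 1)
    vcounts <- count - n_err
    if (n_err > 0) {
      bases <- c("A", "C", "G", "T")
      err_seqs <- vapply(seq_len(n_err), function(z) {
        k <- max(1L, stats::rbinom(1, L, e))
        pos <- sample.int(L, k)
        sv <- strsplit(template, "")[[1]]
        for (p in pos) sv[p] <- sample(setdiff(bases, sv[p]), 1)
        paste(sv, collapse = "")
      }, character(1))
      tab <- table(err_seqs)
      variants <- c(variants, names(tab))
      vcounts <- c(vcounts, as.integer(tab))
    }
    keep <- vcounts > 0
    variants <- variants[keep]
    vcounts <- vcounts[keep]
    # low-quality subset per variant
    n_low <- stats::rbinom(length(vcounts), vcounts, design$low_qual_fraction)
    qh <- phred_string(rep(design$qual_high, rl))
    ql <- phred_string(rep(design$qual_low, rl))
    rows <- list()
    for (v in seq_along(variants)) {
      fwd <- substr(variants[v], 1, rl)
      rev <- revcomp(substr(variants[v], L - rl + 1, L))
      for (q in c("high", "low")) {
        n <- if (q == "high") vcounts[v] - n_low[v] else n_low[v]
        if (n == 0) next
        qual <- if (q == "high") qh else ql
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample, marker = marker, species = species,
          amplicon = variants[v], fwd = fwd, rev = rev,
          fwd_qual = qual, rev_qual = qual, count = n,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

# Re-assign each read to a uniformly random other sample with probability
# `rate`, preserving totals (reads move between samples, never vanish).
apply_crosstalk <- function(groups, all_samples, rate, seed) {
  if (rate == 0 || !nrow(groups)) return(groups)
  with_seed(seed, {
    moved_rows <- list()
    for (i in seq_len(nrow(groups))) {
      n_move <- stats::rbinom(1, groups$count[i], rate)
      if (n_move == 0) next
      others <- setdiff(all_samples, groups$sample[i])
      dest <- as.integer(stats::rmultinom(1, n_move, rep(1, length(others))))
      for (d in which(dest > 0)) {
        row <- groups[i, , drop = FALSE]
        row$sample <- others[d]
        row$count <- dest[d]
        moved_rows[[length(moved_rows) + 1L]] <- row
      }
      groups$count[i] <- groups$count[i] - n_move
    }
    groups <- groups[groups$count > 0, , drop = FALSE]
    if (length(moved_rows)) groups <- rbind(groups, do.call(rbind, moved_rows))
    rownames(groups) <- NULL
    groups
  })
}

#' @export
print.scat_run <- function(x, ...) {
  cat(sprintf(
    "scat_run: %d samples in %d areas, %d read groups (%d read pairs), seed %d\n",
    nrow(x$truth), length(unique(x$truth$area)), nrow(x$groups),
    sum(x$groups$count), x$seed
  ))
  invisible(x)
}

#' Expand a simulated run's read groups to individual read pairs
#'
#' @param run a `scat_run`.
#' @param marker optional marker filter.
#' @return data frame with one row per read pair (`id`, `sample`, `marker`,
#'   `fwd`, `rev`, `fwd_qual`, `rev_qual`, `source`).
#' @export
as_read_pairs <- function(run, marker = NULL) {
  g <- run$groups
  if (!is.null(marker)) g <- g[g$marker == marker, , drop = FALSE]
  idx <- rep(seq_len(nrow(g)), g$count)
  out <- g[idx, c("sample", "marker", "fwd", "rev", "fwd_qual", "rev_qual", "source")]
  out$id <- sprintf("%s_read_%07d", out$marker, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("id", "sample", "marker", "fwd", "rev", "fwd_qual", "rev_qual", "source")]
}

#' Write a simulated run as paired FASTQ plus truth CSV
#'
#' One R1/R2 FASTQ pair per marker (Phred+33, sample identity as a
#' `sample=<id>` header token) and the truth table as CSV.
#'
#' @param run a `scat_run`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_run_fastq <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (mk in unique(run$groups$marker)) {
    reads <- as_read_pairs(run, mk)
    r1 <- file.path(dir, paste0(mk, "_R1.fastq"))
    r2 <- file.path(dir, paste0(mk, "_R2.fastq"))
    write_fastq(
      data.frame(id = reads$id, sample = reads$sample, seq = reads$fwd,
                 qual = reads$fwd_qual), r1
    )
    write_fastq(
      data.frame(id = reads$id, sample = reads$sample, seq = reads$rev,
                 qual = reads$rev_qual), r2
    )
    paths[[mk]] <- c(r1, r2)
  }
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(run$truth, truth_path, row.names = FALSE, na = "")
  paths$truth <- truth_path
  invisible(paths)
}

#' Default microsatellite locus panel
#'
#' A 21-locus dinucleotide panel in the style of domestic-cat microsatellite
#' multiplexes: per locus, an integer fragment-size allele range.
#'
#' @param n_loci number of loci (default 21).
#' @return data frame `locus`, `min_allele`, `n_alleles`, `step`.
#' @export
default_loci <- function(n_loci = 21) {
  i <- seq_len(n_loci)
  data.frame(
    locus = sprintf("L%02d", i),
    min_allele = 100L + 4L * i,
    n_alleles = 4L + (i %% 5L),
    step = 2L,
    stringsAsFactors = FALSE
  )
}

locus_allele_range <- function(loci, locus) {
  r <- loci[loci$locus == locus, , drop = FALSE]
  if (!nrow(r) || r$n_alleles < 1) stop("locus with no declared allele range: ", locus)
  seq(r$min_allele, by = r$step, length.out = r$n_alleles)
}

#' Simulate true multi-locus genotypes for a set of individuals
#'
#' Allele frequencies per locus are drawn from a flat Dirichlet; genotypes
#' are drawn under Hardy-Weinberg equilibrium.
#'
#' @param n_individuals number of individuals (default 14).
#' @param loci a locus panel from [default_loci()].
#' @param seed integer seed.
#' @return list with `genotypes` (data frame `individual`, `locus`, `a1`,
#'   `a2` with `a1 <= a2`), `freqs` (per-locus allele frequencies) and
#'   `loci`.
#' @export
simulate_individual_genotypes <- function(n_individuals = 14,
                                          loci = default_loci(), seed = 1) {
  with_seed(derive_seed(seed, "truth_genotypes"), {
    inds <- sprintf("IND%02d", seq_len(n_individuals))
    freqs <- lapply(loci$locus, function(l) {
      alleles <- locus_allele_range(loci, l)
      w <- stats::rgamma(length(alleles), 1)
      stats::setNames(w / sum(w), alleles)
    })
    names(freqs) <- loci$locus
    rows <- list()
    for (ind in inds) {
      for (l in loci$locus) {
        a <- sort(sample(
          as.integer(names(freqs[[l]])), 2,
          replace = TRUE, prob = freqs[[l]]
        ))
        rows[[length(rows) + 1L]] <- data.frame(
          individual = ind, locus = l, a1 = a[1], a2 = a[2],
          stringsAsFactors = FALSE
        )
      }
    }
    list(genotypes = do.call(rbind, rows), freqs = freqs, loci = loci)
  })
}

#' Simulate replicate PCR genotype tables with dropout and false alleles
#'
#' Emulates the multiple-tubes design: per sample, `n_reps` independent
#' replicates of every locus. In each replicate of a heterozygous locus,
#' each true allele drops independently with probability `ado_rate`; with
#' probability `fa_rate` one uniformly chosen surviving allele is replaced
#' by a false allele drawn uniformly from the locus's declared allele range
#' excluding the true alleles. A replicate with no surviving allele is a
#' failed amplification; a single surviving allele is recorded as an
#' apparent homozygote.
#'
#' @param truth truth genotypes: data frame `individual`, `locus`, `a1`,
#'   `a2` (e.g. `simulate_individual_genotypes()$genotypes`).
#' @param ado_rate,fa_rate error probabilities in `[0, 1)`.
#' @param n_reps replicates per sample (default 4, the study design).
#' @param seed integer seed.
#' @param samples optional data frame `sample`, `individual` mapping scat
#'   samples to individuals (default: one sample per individual).
#' @param loci locus panel with allele ranges (default [default_loci()]).
#' @return replicate table: data frame `sample`, `replicate`, `locus`,
#'   `a1`, `a2` (`NA`s for failed amplification).
#' @export
simulate_replicate_genotypes <- function(truth, ado_rate, fa_rate,
                                         n_reps = 4, seed = 1,
                                         samples = NULL,
                                         loci = default_loci()) {
  stopifnot(ado_rate >= 0, ado_rate < 1, fa_rate >= 0, fa_rate < 1, n_reps >= 1)
  if (is.null(samples)) {
    samples <- data.frame(
      sample = unique(truth$individual),
      individual = unique(truth$individual),
      stringsAsFactors = FALSE
    )
  }
  ranges <- lapply(unique(truth$locus), function(l) locus_allele_range(loci, l))
  names(ranges) <- unique(truth$locus)
  rows <- vector("list", nrow(samples) * n_reps * length(unique(truth$locus)))
  ri <- 0L
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    g <- truth[truth$individual == samples$individual[i], , drop = FALSE]
    with_seed(derive_seed(seed, paste0("reps/", s)), {
      for (rep_i in seq_len(n_reps)) {
        for (k in seq_len(nrow(g))) {
          a <- c(g$a1[k], g$a2[k])
          obs <- a
          if (a[1] != a[2]) obs <- a[stats::runif(2) >= ado_rate]
          if (length(obs) && stats::runif(1) < fa_rate) {
            false_pool <- setdiff(ranges[[g$locus[k]]], a)
            if (length(false_pool)) {
              obs[sample.int(length(obs), 1)] <-
                false_pool[sample.int(length(false_pool), 1)]
            }
          }
          call <- if (!length(obs)) {
            c(NA_integer_, NA_integer_)
          } else if (length(obs) == 1L) {
            c(obs, obs)
          } else {
            sort(obs)
          }
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            sample = s, replicate = rep_i, locus = g$locus[k],
            a1 = call[1], a2 = call[2], stringsAsFactors = FALSE
          )
        }
      }
    })
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}
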