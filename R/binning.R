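#' Per-rank percent-identity binning thresholds
#'
#' Container for the four inclusive percent-identity thresholds used by
#' [bin_otu()]. The thresholds must be monotone in rank specificity:
#' `above_family <= family <= genus <= species`. The pipeline default is 99
#' at every rank, the operating point at which congeneric reference entries
#' stop being falsely merged for the markers this pipeline targets.
#'
#' @param species,genus,family,above_family percent identities in `[0, 100]`.
#' @return a `binning_thresholds` list.
#' @export
binning_thresholds <- function(species = 99, genus = 99, family = 99,
                               above_family = 99) {
  t <- list(
    species = species, genus = genus, family = family,
    above_family = above_family
  )
  v <- unlist(t)
  if (any(v < 0 | v > 100)) stop("thresholds must be in [0, 100]")
  if (!(above_family <= family && family <= genus && genus <= species)) {
    stop("thresholds must satisfy above_family <= family <= genus <= species")
  }
  structure(t, class = "binning_thresholds")
}

#' Validate and normalise a taxonomy table
#'
#' The taxonomy is a flat species table with full lineages, a regional
#' presence flag (geographic allow-list) and an optional domestication label
#' for wild/domestic disambiguation. Lineages must be consistent: one genus
#' per species and one family per genus.
#'
#' @param taxonomy data frame with columns `species`, `genus`, `family`,
#'   `group` (above-family), `present` (logical), and optionally
#'   `domestication` (`"wild"`, `"domestic"` or `NA`).
#' @return the validated data frame.
#' @export
taxonomy_table <- function(taxonomy) {
  need <- c("species", "genus", "family", "group", "present")
  if (!all(need %in% names(taxonomy))) {
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(taxonomy$species)) stop("duplicated species in taxonomy")
  if (any(!stats::complete.cases(taxonomy[, c("species", "genus", "family", "group")]))) {
    stop("every species needs a complete lineage")
  }
  gf <- unique(taxonomy[, c("genus", "family")])
  if (anyDuplicated(gf$genus)) stop("lineage inconsistency: a genus maps to several families")
  if (is.null(taxonomy$domestication)) taxonomy$domestication <- NA_character_
  taxonomy
}

#' Filter alignment hits on query cover and regional presence
#'
#' Keeps hits with `query_cover >= min_query_cover` (inclusive) whose subject
#' species is flagged present in the study region; hits to absent taxa are
#' masked out before binning. Input order is preserved, making this a pure,
#' idempotent filter. A hit to a species absent from the taxonomy table is a
#' reference-database mismatch and raises an error.
#'
#' @param hits data frame with columns `otu_id`, `subject_species`,
#'   `pident`, `qcovs` (and typically `length`, `bitscore`).
#' @param min_query_cover minimum query cover percent (default 98).
#' @param taxonomy a [taxonomy_table()].
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_query_cover = 98, taxonomy) {
  taxonomy <- taxonomy_table(taxonomy)
  unknown <- setdiff(hits$subject_species, taxonomy$species)
  if (length(unknown)) {
    stop(
      "hits to species absent from taxonomy (database mismatch): ",
      paste(unknown, collapse = ", ")
    )
  }
  present <- taxonomy$present[match(hits$subject_species, taxonomy$species)]
  keep <- hits$qcovs >= min_query_cover & present
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place one OTU in a taxonomic bin
#'
#' Threshold/LCA binning with unanimity semantics: at each rank, from species
#' downwards in specificity, the hits at or above that rank's identity
#' threshold are examined; the OTU is assigned at the first rank where all
#' such hits agree on a single taxon. Conflicting equal-identity species
#' therefore escalate to their shared genus (and so on); when no rank is
#' unanimous, or when the hit list is empty, the OTU is unassigned.
#'
#' @param hits alignment hits for one OTU, already passed through
#'   [filter_hits()].
#' @param thresholds a [binning_thresholds()].
#' @param taxonomy a [taxonomy_table()].
#' @return list with `rank` (`"species"`, `"genus"`, `"family"`,
#'   `"above_family"` or `"unassigned"`) and `taxon` (`NA` when unassigned).
#' @export
bin_otu <- function(hits, thresholds = binning_thresholds(), taxonomy) {
  taxonomy <- taxonomy_table(taxonomy)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(rank = "unassigned", taxon = NA_character_))
  }
  idx <- match(hits$subject_species, taxonomy$species)
  if (anyNA(idx)) stop("hits to species absent from taxonomy")
  lineage <- list(
    species = taxonomy$species[idx],
    genus = taxonomy$genus[idx],
    family = taxonomy$family[idx],
    above_family = taxonomy$group[idx]
  )
  tmin <- c(
    species = thresholds$species, genus = thresholds$genus,
    family = thresholds$family, above_family = thresholds$above_family
  )
  for (rank in names(tmin)) {
    pass <- hits$pident >= tmin[[rank]]
    if (!any(pass)) next
    taxa <- unique(lineage[[rank]][pass])
    if (length(taxa) == 1L) return(list(rank = rank, taxon = taxa))
  }
  list(rank = "unassigned", taxon = NA_character_)
}

#' Bin every OTU in a hit table
#'
#' @param hits alignment hits for any number of OTUs (column `otu_id`),
#'   already filtered with [filter_hits()].
#' @param thresholds a [binning_thresholds()].
#' @param taxonomy a [taxonomy_table()].
#' @param otu_ids optional OTU ids to report (defaults to those present in
#'   `hits`); ids without hits come back unassigned.
#' @return data frame `otu_id`, `rank`, `taxon`.
#' @export
bin_otus <- function(hits, thresholds = binning_thresholds(), taxonomy,
                     otu_ids = NULL) {
  taxonomy <- taxonomy_table(taxonomy)
  otu_ids <- otu_ids %||% unique(hits$otu_id)
  res <- lapply(otu_ids, function(id) {
    bin_otu(hits[hits$otu_id == id, , drop = FALSE], thresholds, taxonomy)
  })
  data.frame(
    otu_id = otu_ids,
    rank = vapply(res, `[[`, character(1), "rank"),
    taxon = vapply(res, function(r) as.character(r$taxon), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Select per-rank identity thresholds from labelled identity distributions
#'
#' Data-driven threshold choice: for each rank, the smallest integer
#' threshold `t` such that the fraction of among-taxon identity observations
#' at or above `t` is at most `tolerance` (default 0, i.e. no among-taxon
#' pair may reach the threshold). Rank monotonicity
#' (`above_family <= family <= genus <= species`) is then enforced by raising
#' higher-rank thresholds to the running maximum, which can only reduce the
#' among-taxon false-merge fraction further. The diagnostic table reports,
#' per rank and taxon, the minimum within-taxon and maximum among-taxon
#' identity, and a `warning` flag whenever the chosen threshold would also
#' exclude some within-taxon pairs (inseparable distributions).
#'
#' @param identities data frame with columns `rank` (`species`, `genus`,
#'   `family`, `above_family`), `taxon`, `type` (`"within"` or `"among"`) and
#'   `identity` (percent).
#' @param tolerance maximum tolerated among-taxon fraction at or above the
#'   threshold (default 0).
#' @return list with `thresholds` (a [binning_thresholds()]) and
#'   `diagnostics` (data frame `rank`, `taxon`, `min_within`, `max_among`,
#'   `warning`).
#' @export
select_thresholds <- function(identities, tolerance = 0) {
  stopifnot(all(c("rank", "taxon", "type", "identity") %in% names(identities)))
  ranks <- c("above_family", "family", "genus", "species")
  pick <- function(among) {
    for (t in 0:100) {
      if (mean(among >= t) <= tolerance) return(t)
    }
    100L
  }
  th <- vapply(ranks, function(r) {
    d <- identities[identities$rank == r, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    among <- d$identity[d$type == "among"]
    if (!length(among)) return(0)
    pick(among)
  }, numeric(1))
  # absent ranks inherit the nearest computed threshold below them
  for (i in seq_along(th)) if (is.na(th[i])) th[i] <- if (i > 1) th[i - 1] else 0
  th <- cummax(th) # enforce above_family <= family <= genus <= species
  thresholds <- binning_thresholds(
    species = th[["species"]], genus = th[["genus"]],
    family = th[["family"]], above_family = th[["above_family"]]
  )
  diag <- do.call(rbind, lapply(ranks, function(r) {
    d <- identities[identities$rank == r, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    taxa <- sort(unique(d$taxon))
    do.call(rbind, lapply(taxa, function(tx) {
      w <- d$identity[d$taxon == tx & d$type == "within"]
      a <- d$identity[d$taxon == tx & d$type == "among"]
      data.frame(
        rank = r, taxon = tx,
        min_within = if (length(w)) min(w) else NA_real_,
        max_among = if (length(a)) max(a) else NA_real_,
        warning = length(w) > 0 && any(w < th[[r]]),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(diag) <- NULL
  list(thresholds = thresholds, diagnostics = diag)
}

#' Compute alignment hits of OTU sequences against a reference database
#'
#' Produces the tabular hit input consumed by [filter_hits()]/[bin_otus()]
#' directly in R, for the fully offline synthetic path: each OTU is compared
#' against every reference sequence. Equal-length pairs are
#' scored by Hamming identity (the synthetic error model is
#' substitution-only); unequal lengths fall back to a global pairwise
#' alignment. Query cover is 100 for full-length comparisons, matching the
#' relaxed-gap full-length alignments the downstream filter expects. The
#' top `max_hits` hits per OTU by identity are returned.
#'
#' @param otus data frame with columns `otu_id`, `seq` (e.g.
#'   `dereplicate()$otus`).
#' @param refs data frame with columns `species`, `seq` for one marker.
#' @param max_hits hits kept per OTU (default 100).
#' @return data frame `otu_id`, `subject_species`, `pident`, `qcovs`,
#'   `length`, `bitscore`.
#' @export
align_otus <- function(otus, refs, max_hits = 100) {
  stopifnot(nrow(refs) > 0)
  out <- lapply(seq_len(nrow(otus)), function(i) {
    q <- otus$seq[i]
    nq <- nchar(q)
    qi <- utf8ToInt(q)
    pid <- numeric(nrow(refs))
    alen <- integer(nrow(refs))
    for (j in seq_len(nrow(refs))) {
      s <- refs$seq[j]
      if (nchar(s) == nq) {
        m <- sum(qi == utf8ToInt(s))
        pid[j] <- 100 * m / nq
        alen[j] <- nq
      } else {
        pa <- Biostrings::pairwiseAlignment(q, s, type = "global")
        pid[j] <- Biostrings::pid(pa)
        alen[j] <- Biostrings::nchar(pa)
      }
    }
    ord <- order(-pid, refs$species)[seq_len(min(max_hits, nrow(refs)))]
    data.frame(
      otu_id = otus$otu_id[i],
      subject_species = refs$species[ord],
      pident = pid[ord],
      qcovs = 100,
      length = alen[ord],
      bitscore = 2 * pid[ord] * alen[ord] / 100,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read BLAST-style tabular hits
#'
#' Six-plus-column tab-separated hits: `qseqid`, `sseqid` (taxon name),
#' `pident`, `qcovs`, `length`, `bitscore`.
#'
#' @param path TSV path (no header).
#' @return data frame with standardised column names (`otu_id`,
#'   `subject_species`, `pident`, `qcovs`, `length`, `bitscore`).
#' @export
read_hits <- function(path) {
  x <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE, quote = "",
    col.names = c("otu_id", "subject_species", "pident", "qcovs", "length", "bitscore")
  )
  x
}
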