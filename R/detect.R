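#' Assemble a sample x taxon detection matrix
#'
#' Joins per-OTU taxonomic assignments onto per-sample OTU counts and sums
#' reads per (sample, taxon). Unassigned OTUs are dropped. The result is the
#' long-form substrate of all downstream filtering: one row per (sample,
#' taxon) with a positive read count.
#'
#' @param otu_table a [dereplicate()] result.
#' @param assignments data frame `otu_id`, `rank`, `taxon` from
#'   [bin_otus()].
#' @param marker optional marker label (defaults to the OTU table's).
#' @return a `detection_matrix`: data frame `sample`, `taxon`, `rank`,
#'   `reads`.
#' @export
detection_matrix <- function(otu_table, assignments, marker = NULL) {
  counts <- otu_table$counts
  m <- match(counts$otu_id, assignments$otu_id)
  counts$taxon <- assignments$taxon[m]
  counts$rank <- assignments$rank[m]
  counts <- counts[!is.na(counts$taxon) & counts$rank != "unassigned", , drop = FALSE]
  if (nrow(counts)) {
    agg <- stats::aggregate(count ~ sample + taxon + rank, data = counts, FUN = sum)
  } else {
    agg <- data.frame(
      sample = character(0), taxon = character(0),
      rank = character(0), count = integer(0)
    )
  }
  names(agg)[names(agg) == "count"] <- "reads"
  agg <- agg[order(agg$sample, agg$taxon), c("sample", "taxon", "rank", "reads")]
  rownames(agg) <- NULL
  structure(agg, marker = marker %||% otu_table$marker, class = c("detection_matrix", "data.frame"))
}

#' Build a detection matrix from a long count table
#'
#' @param entries data frame `sample`, `taxon`, `reads` and optionally
#'   `rank` (defaults to `"species"`).
#' @param marker optional marker label.
#' @return a `detection_matrix`.
#' @export
as_detection_matrix <- function(entries, marker = NA_character_) {
  stopifnot(all(c("sample", "taxon", "reads") %in% names(entries)))
  if (is.null(entries$rank)) entries$rank <- rep("species", nrow(entries))
  if (anyDuplicated(entries[, c("sample", "taxon")])) {
    stop("one entry per (sample, taxon) required")
  }
  if (any(entries$reads < 1)) stop("read counts must be positive")
  entries <- entries[order(entries$sample, entries$taxon),
                     c("sample", "taxon", "rank", "reads"), drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, marker = marker, class = c("detection_matrix", "data.frame"))
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf(
    "detection_matrix (%s): %d entries, %d samples, %d taxa, %d reads\n",
    attr(x, "marker") %||% "unknown marker", nrow(x),
    length(unique(x$sample)), length(unique(x$taxon)), sum(x$reads)
  ))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Remove crosstalk and spurious detections
#'
#' Single-pass screening of a detection matrix against three predicates, all
#' evaluated on the totals of the *input* matrix (no iterative
#' recomputation): an entry is kept iff its read count is at least
#' `taxon_frac` of the total reads of its taxon, at least `sample_frac` of
#' the total reads of its sample, and at least `min_reads`. The defaults
#' (0.1%, 0.1%, 40 reads) are the pipeline's tag-jumping screen; an entry of
#' exactly `min_reads` reads is kept (detections *below* the floor are
#' discarded).
#'
#' @param matrix a `detection_matrix`.
#' @param taxon_frac,sample_frac relative-abundance floors in `[0, 1)`.
#' @param min_reads absolute read floor (default 40).
#' @return the filtered `detection_matrix`; removed entries, with
#'   comma-separated reason codes (`taxon_frac|sample_frac|min_reads`), are
#'   attached as the `"removal_log"` attribute.
#' @export
filter_crosstalk <- function(matrix, taxon_frac = 0.001, sample_frac = 0.001,
                             min_reads = 40) {
  stopifnot(taxon_frac >= 0, taxon_frac < 1, sample_frac >= 0, sample_frac < 1)
  if (nrow(matrix) == 0L) {
    attr(matrix, "removal_log") <- cbind(as.data.frame(matrix), reason = character(0))
    return(matrix)
  }
  taxon_tot <- tapply(matrix$reads, matrix$taxon, sum)
  sample_tot <- tapply(matrix$reads, matrix$sample, sum)
  ok_taxon <- matrix$reads >= taxon_frac * taxon_tot[matrix$taxon]
  ok_sample <- matrix$reads >= sample_frac * sample_tot[matrix$sample]
  ok_min <- matrix$reads >= min_reads
  keep <- ok_taxon & ok_sample & ok_min
  reason <- character(nrow(matrix))
  reason[!ok_taxon] <- "taxon_frac"
  reason[!ok_sample] <- paste0(ifelse(nzchar(reason[!ok_sample]), paste0(reason[!ok_sample], ","), ""), "sample_frac")
  reason[!ok_min] <- paste0(ifelse(nzchar(reason[!ok_min]), paste0(reason[!ok_min], ","), ""), "min_reads")
  removed <- cbind(as.data.frame(matrix)[!keep, , drop = FALSE], reason = reason[!keep])
  rownames(removed) <- NULL
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out,
    marker = attr(matrix, "marker"),
    class = c("detection_matrix", "data.frame")
  )
  attr(out, "removal_log") <- removed
  out
}

#' Default predator allow-list for depositor calling
#'
#' Predator taxa (and the ranks they may be reported at) eligible as scat
#' depositors; non-listed mammals surviving on the predator marker are
#' logged, not called. The default mirrors the predator community of the
#' cheetah-range survey bundled as the worked example: the carnivores plus
#' the Indian crested porcupine, and the family/order fallbacks the marker
#' cannot always resolve beyond.
#'
#' @return character vector of taxa.
#' @export
default_predator_allowlist <- function() {
  c(
    "Acinonyx jubatus", "Vulpes vulpes", "Canis lupus", "Caracal caracal",
    "Hystrix indica", "Hyaena hyaena",
    "Acinonyx", "Vulpes", "Canis", "Caracal", "Hystrix", "Hyaena",
    "Felidae", "Canidae", "Hyaenidae", "Hystricidae", "Carnivora"
  )
}

#' Call the scat depositor per sample
#'
#' On the crosstalk-filtered predator-marker matrix, the depositor of each
#' sample is the allow-listed taxon with the maximum surviving read count
#' (ties broken alphabetically for determinism). Family-rank detections
#' (e.g. `Felidae`) are legitimate calls when binning could not resolve
#' further. Samples with no surviving allow-listed detection are
#' unidentified (`NA`).
#'
#' @param matrix a crosstalk-filtered `detection_matrix` (predator marker).
#' @param allowlist eligible depositor taxa
#'   (default [default_predator_allowlist()]).
#' @param samples optional character vector of all sample ids to report
#'   (samples absent from the matrix come back unidentified).
#' @return data frame `sample`, `depositor` (`NA` = unidentified), `rank`,
#'   `reads`; surviving non-listed detections are attached as the
#'   `"unlisted"` attribute.
#' @export
call_depositor <- function(matrix, allowlist = default_predator_allowlist(),
                           samples = NULL) {
  samples <- samples %||% sort(unique(matrix$sample))
  df <- as.data.frame(matrix)
  listed <- df[df$taxon %in% allowlist, , drop = FALSE]
  unlisted <- df[!(df$taxon %in% allowlist), , drop = FALSE]
  out <- do.call(rbind, lapply(samples, function(s) {
    d <- listed[listed$sample == s, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(
        sample = s, depositor = NA_character_, rank = NA_character_,
        reads = NA_integer_, stringsAsFactors = FALSE
      ))
    }
    d <- d[order(-d$reads, d$taxon), , drop = FALSE]
    data.frame(
      sample = s, depositor = d$taxon[1], rank = d$rank[1], reads = d$reads[1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "unlisted") <- unlisted
  out
}

#' Call diet items per sample
#'
#' On the crosstalk-filtered prey-marker matrix, the diet of a sample is the
#' set of surviving taxa minus the sample's depositor: residual predator
#' reads that escaped the blocking primer are self-detections, not food.
#' When the depositor was only resolved to family rank, taxa of that family
#' are masked likewise; an explicit extra mask can be supplied. Read counts
#' are retained for downstream low-read exclusion.
#'
#' @param matrix a crosstalk-filtered `detection_matrix` (prey marker).
#' @param depositors data frame `sample`, `depositor`, `rank` from
#'   [call_depositor()].
#' @param taxonomy a [taxonomy_table()] (used to mask the depositor's
#'   lineage: its species, genus entry and, for family-rank depositors, all
#'   members of the family).
#' @param mask optional character vector of additional taxa never reported
#'   as food.
#' @return long data frame `sample`, `taxon`, `rank`, `reads` (samples with
#'   no surviving food item are simply absent).
#' @export
call_diet <- function(matrix, depositors, taxonomy, mask = character(0)) {
  taxonomy <- taxonomy_table(taxonomy)
  df <- as.data.frame(matrix)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- df$sample[i]
    dep <- depositors$depositor[match(s, depositors$sample)]
    masked <- mask
    if (length(dep) == 1L && !is.na(dep)) {
      masked <- c(masked, dep)
      dep_rank <- depositors$rank[match(s, depositors$sample)]
      if (identical(dep_rank, "family")) {
        fam_sp <- taxonomy$species[taxonomy$family == dep]
        fam_gen <- unique(taxonomy$genus[taxonomy$family == dep])
        masked <- c(masked, fam_sp, fam_gen)
      } else if (dep %in% taxonomy$species) {
        # residual depositor reads may have binned only to genus
        masked <- c(masked, taxonomy$genus[match(dep, taxonomy$species)])
      }
    }
    keep[i] <- !(df$taxon[i] %in% masked)
  }
  out <- df[keep, c("sample", "taxon", "rank", "reads"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve wild vs domestic status of Ovis and Capra food items
#'
#' The prey marker cannot separate wild from domestic sheep and goats; a
#' D-loop marker binned against a database whose entries are labelled
#' `"Ovis wild"`, `"Ovis domestic"`, `"Capra wild"` and `"Capra domestic"`
#' does. Each Ovis/Capra food item is re-labelled by its sample's surviving
#' D-loop detections: `wild`, `domestic`, `conflict` (both labels survive;
#' both reported, flagged) or `unresolved` (no surviving D-loop detection).
#'
#' @param matrix a crosstalk-filtered `detection_matrix` whose taxa are the
#'   four wild/domestic labels (D-loop marker).
#' @param diet long diet table from [call_diet()].
#' @param taxonomy a [taxonomy_table()] (to map food items to their genus).
#' @return data frame `sample`, `taxon`, `genus`, `status`.
#' @export
resolve_wild_domestic <- function(matrix, diet, taxonomy) {
  taxonomy <- taxonomy_table(taxonomy)
  df <- as.data.frame(matrix)
  genus_of <- function(taxon) {
    if (taxon %in% taxonomy$species) return(taxonomy$genus[match(taxon, taxonomy$species)])
    if (taxon %in% taxonomy$genus) return(taxon)
    NA_character_
  }
  rows <- lapply(seq_len(nrow(diet)), function(i) {
    g <- genus_of(diet$taxon[i])
    if (is.na(g) || !(g %in% c("Ovis", "Capra"))) return(NULL)
    s <- diet$sample[i]
    labs <- df$taxon[df$sample == s & df$taxon %in% paste(g, c("wild", "domestic"))]
    status <- if (!length(labs)) {
      "unresolved"
    } else if (length(labs) == 2L) {
      "conflict"
    } else if (grepl("wild$", labs)) "wild" else "domestic"
    data.frame(
      sample = s, taxon = diet$taxon[i], genus = g, status = status,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      sample = character(0), taxon = character(0), genus = character(0),
      status = character(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Assemble per-scat records
#'
#' One row per collected sample: area, depositor call, diet items (semicolon
#' separated, wild/domestic-resolved items labelled `taxon (wild)` etc.),
#' and, when genotyping results are supplied, individual id and sex.
#'
#' @param samples data frame `sample`, `area` for every collected sample.
#' @param depositors [call_depositor()] output.
#' @param diet [call_diet()] output.
#' @param wild_domestic optional [resolve_wild_domestic()] output.
#' @param individuals optional data frame `sample`, `individual_id`, `sex`.
#' @return data frame of scat records (class `scat_records`), with the long
#'   diet table attached as attribute `"diet"`.
#' @export
assemble_scat_records <- function(samples, depositors, diet,
                                  wild_domestic = NULL, individuals = NULL) {
  stopifnot(all(c("sample", "area") %in% names(samples)))
  lab <- diet
  if (!is.null(wild_domestic) && nrow(wild_domestic)) {
    key <- paste(lab$sample, lab$taxon)
    wkey <- paste(wild_domestic$sample, wild_domestic$taxon)
    st <- wild_domestic$status[match(key, wkey)]
    lab$taxon <- ifelse(
      !is.na(st) & st %in% c("wild", "domestic"),
      paste0(lab$taxon, " (", st, ")"),
      lab$taxon
    )
  }
  items <- vapply(samples$sample, function(s) {
    paste(sort(lab$taxon[lab$sample == s]), collapse = ";")
  }, character(1))
  out <- data.frame(
    sample = samples$sample,
    area = samples$area,
    depositor = depositors$depositor[match(samples$sample, depositors$sample)],
    depositor_rank = depositors$rank[match(samples$sample, depositors$sample)],
    diet_items = items,
    stringsAsFactors = FALSE
  )
  if (!is.null(individuals)) {
    m <- match(samples$sample, individuals$sample)
    out$individual_id <- individuals$individual_id[m]
    out$sex <- individuals$sex[m]
  }
  rownames(out) <- NULL
  diet_long <- diet
  diet_long$area <- samples$area[match(diet_long$sample, samples$sample)]
  structure(out, diet = diet_long, class = c("scat_records", "data.frame"))
}
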