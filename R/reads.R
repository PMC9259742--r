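#' Expected number of sequencing errors in a read
#'
#' The expected-error (maxEE) statistic: the sum of per-base error
#' probabilities `10^(-Q/10)` over the read's Phred scores. Ten bases at Q20
#' give 0.1 expected errors; a single Q0 base gives 1.
#'
#' @param quals either a numeric vector of Phred scores for one read, or a
#'   character vector of Phred+33 quality strings (one element per read).
#' @return numeric vector of expected error counts (length 1 for a numeric
#'   input, one value per string otherwise).
#' @export
#' @examples
#' expected_errors(rep(20, 10)) # 0.1
#' expected_errors("III")       # three Q40 bases
expected_errors <- function(quals) {
  if (is.character(quals)) {
    vapply(
      quals,
      function(q) sum(10^(-(utf8ToInt(q) - 33) / 10)),
      numeric(1),
      USE.NAMES = FALSE
    )
  } else {
    if (any(quals < 0)) stop("Phred scores must be non-negative")
    sum(10^(-quals / 10))
  }
}

#' Merge a read pair by best ungapped overlap
#'
#' Aligns the forward read against the reverse complement of the reverse read
#' at every candidate overlap length in `[min_overlap, max_overlap]` and keeps
#' the overlap with the lowest mismatch density (ties broken towards the
#' longer overlap). Overlap disagreements are resolved towards the
#' higher-quality base; when both bases have equal quality the merged base is
#' `N`. Merged quality is the maximum of the two qualities. The pair is
#' rejected when no overlap meets the mismatch-density cap. Only
#' "innie" overlaps (merged length at least as long as either read) are
#' considered: amplicons shorter than a single read are outside the model.
#'
#' @param fwd,rev forward and reverse read sequences; `rev` in sequencing
#'   orientation (it is reverse-complemented internally).
#' @param fwd_qual,rev_qual optional Phred+33 quality strings matching the
#'   reads; when omitted all bases are treated as equal quality Q30.
#' @param min_overlap,max_overlap overlap length bounds (defaults 10 and 100,
#'   mirroring common paired-end merger settings for short amplicons).
#' @param max_mismatch_density maximum fraction of mismatching positions
#'   tolerated in the chosen overlap (default 0.25).
#' @return a list with elements `merged` (logical), and when merged: `seq`,
#'   `qual`, `overlap`, `mismatches`; when rejected: `reason`.
#' @export
merge_pairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                        min_overlap = 10, max_overlap = 100,
                        max_mismatch_density = 0.25) {
  if (!nzchar(fwd) || !nzchar(rev)) stop("empty read")
  nf <- nchar(fwd)
  nr <- nchar(rev)
  if (is.null(fwd_qual)) fwd_qual <- phred_string(rep(30L, nf))
  if (is.null(rev_qual)) rev_qual <- phred_string(rep(30L, nr))
  stopifnot(nchar(fwd_qual) == nf, nchar(rev_qual) == nr)

  f <- utf8ToInt(fwd)
  fq <- phred_scores(fwd_qual)
  rc <- utf8ToInt(revcomp(rev))
  rq <- rev(phred_scores(rev_qual))

  omax <- min(max_overlap, nf, nr)
  if (omax < min_overlap) {
    return(list(merged = FALSE, reason = "no_overlap_in_range"))
  }
  best_o <- NA_integer_
  best_density <- Inf
  best_mm <- NA_integer_
  for (o in seq.int(min_overlap, omax)) {
    mm <- sum(f[(nf - o + 1):nf] != rc[1:o])
    dens <- mm / o
    # strictly-lower density wins; equal density prefers the longer overlap
    if (dens < best_density || (dens == best_density && !is.na(best_o) && o > best_o)) {
      best_density <- dens
      best_o <- o
      best_mm <- mm
    }
  }
  if (best_density > max_mismatch_density) {
    return(list(merged = FALSE, reason = "mismatch_density"))
  }
  o <- best_o
  fo <- (nf - o + 1):nf
  f_ov <- f[fo]
  fq_ov <- fq[fo]
  r_ov <- rc[1:o]
  rq_ov <- rq[1:o]
  base <- ifelse(fq_ov >= rq_ov, f_ov, r_ov)
  disagree <- f_ov != r_ov
  base[disagree & fq_ov == rq_ov] <- utf8ToInt("N")
  qual <- pmax(fq_ov, rq_ov)
  seq_out <- intToUtf8(c(f[seq_len(nf - o)], base, rc[seq.int(o + 1, length.out = nr - o)]))
  qual_out <- phred_string(c(fq[seq_len(nf - o)], qual, rq[seq.int(o + 1, length.out = nr - o)]))
  list(merged = TRUE, seq = seq_out, qual = qual_out, overlap = o, mismatches = best_mm)
}

#' Merge paired read groups
#'
#' Applies [merge_pairs()] to a table of (possibly weighted) read pairs.
#' Identical pairs are merged once and their counts carried through, so
#' deeply duplicated amplicon data costs one merge per unique pair.
#'
#' @param pairs data frame with columns `fwd`, `rev` and optionally
#'   `fwd_qual`, `rev_qual`, `count` (default 1) plus any carry-through
#'   columns (e.g. `sample`, `marker`).
#' @param ... passed to [merge_pairs()].
#' @return list with `merged` (input rows that merged, with `seq` and `qual`
#'   columns added) and `rejected` (rows that failed, with `reason`).
#' @export
merge_read_groups <- function(pairs, ...) {
  stopifnot(all(c("fwd", "rev") %in% names(pairs)))
  if (is.null(pairs$count)) pairs$count <- 1L
  if (is.null(pairs$fwd_qual)) pairs$fwd_qual <- NA_character_
  if (is.null(pairs$rev_qual)) pairs$rev_qual <- NA_character_
  key <- paste(pairs$fwd, pairs$rev, pairs$fwd_qual, pairs$rev_qual, sep = "\r")
  uk <- !duplicated(key)
  res <- lapply(which(uk), function(i) {
    merge_pairs(
      pairs$fwd[i], pairs$rev[i],
      if (is.na(pairs$fwd_qual[i])) NULL else pairs$fwd_qual[i],
      if (is.na(pairs$rev_qual[i])) NULL else pairs$rev_qual[i],
      ...
    )
  })
  names(res) <- key[uk]
  res <- res[key]
  ok <- vapply(res, function(r) r$merged, logical(1))
  merged <- pairs[ok, , drop = FALSE]
  if (any(ok)) {
    merged$seq <- vapply(res[ok], `[[`, character(1), "seq")
    merged$qual <- vapply(res[ok], `[[`, character(1), "qual")
  } else {
    merged$seq <- character(0)
    merged$qual <- character(0)
  }
  rejected <- pairs[!ok, , drop = FALSE]
  rejected$reason <- if (any(!ok)) {
    vapply(res[!ok], `[[`, character(1), "reason")
  } else {
    character(0)
  }
  rownames(merged) <- NULL
  rownames(rejected) <- NULL
  list(merged = merged, rejected = rejected)
}

#' Filter reads on expected errors and length
#'
#' Retains reads whose expected error count is at most `maxee` (inclusive,
#' the usual quality-filter convention) and whose length lies in the closed
#' interval `length_range`. Every input row ends up in exactly one of the two
#' outputs; rejected rows carry the first failing reason (`length`, then
#' `maxee`).
#'
#' @param reads data frame with columns `seq`, `qual` (Phred+33) and any
#'   carry-through columns (`count`, `sample`, ...).
#' @param maxee maximum expected errors (default 1).
#' @param length_range integer vector `c(min, max)`; closed interval.
#' @return list with data frames `retained` and `rejected` (the latter with a
#'   `reason` column).
#' @export
filter_reads <- function(reads, maxee = 1, length_range) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  stopifnot(length(length_range) == 2L)
  if (length_range[1] > length_range[2]) stop("length_range: min > max")
  len <- nchar(reads$seq)
  ee <- expected_errors(reads$qual)
  bad_len <- len < length_range[1] | len > length_range[2]
  bad_ee <- ee > maxee
  keep <- !bad_len & !bad_ee
  rejected <- reads[!keep, , drop = FALSE]
  rejected$reason <- ifelse(bad_len[!keep], "length", "maxee")
  retained <- reads[keep, , drop = FALSE]
  rownames(retained) <- NULL
  rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Dereplicate reads to zero-radius OTUs
#'
#' Exact-sequence dereplication pooled across samples, preserving per-sample
#' counts. OTUs whose total count across all samples is 1 (singletons) are
#' dropped when `remove_singletons` is set; the dropped rows are attached as
#' the `"dropped"` attribute so read-count conservation can be audited.
#'
#' @param reads data frame with columns `sample`, `seq` and optionally
#'   `count` (default 1).
#' @param remove_singletons drop OTUs with pooled total count <= 1
#'   (default TRUE).
#' @param marker optional marker label stored on the result.
#' @return an `otu_table`: list with `otus` (data frame `otu_id`, `seq`,
#'   `total`) and `counts` (long data frame `otu_id`, `sample`, `count`).
#' @export
dereplicate <- function(reads, remove_singletons = TRUE, marker = NA_character_) {
  stopifnot(all(c("sample", "seq") %in% names(reads)))
  if (is.null(reads$count)) reads$count <- 1L
  stopifnot(all(reads$count >= 0))
  counts <- stats::aggregate(count ~ seq + sample, data = reads, FUN = sum)
  totals <- stats::aggregate(count ~ seq, data = counts, FUN = sum)
  names(totals)[2] <- "total"
  # deterministic OTU order: by decreasing abundance, then sequence
  totals <- totals[order(-totals$total, totals$seq), , drop = FALSE]
  singleton <- totals$total <= 1
  dropped <- totals[remove_singletons & singleton, , drop = FALSE]
  if (remove_singletons) totals <- totals[!singleton, , drop = FALSE]
  totals$otu_id <- sprintf("OTU_%04d", seq_len(nrow(totals)))
  counts <- counts[counts$seq %in% totals$seq, , drop = FALSE]
  counts$otu_id <- totals$otu_id[match(counts$seq, totals$seq)]
  counts <- counts[order(counts$otu_id, counts$sample), c("otu_id", "sample", "count")]
  otus <- totals[, c("otu_id", "seq", "total")]
  rownames(otus) <- NULL
  rownames(counts) <- NULL
  structure(
    list(otus = otus, counts = counts, marker = marker),
    dropped = dropped,
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(
    sprintf(
      "otu_table: %d OTUs x %d samples (%s), %d reads\n",
      nrow(x$otus), length(unique(x$counts$sample)),
      ifelse(is.na(x$marker), "unknown marker", x$marker),
      sum(x$counts$count)
    )
  )
  invisible(x)
}

#' Read a paired or single FASTQ file
#'
#' Thin wrapper over Biostrings FASTQ input. Sample identity travels in the
#' read header as a `sample=<id>` token (sequencer-side demultiplexing is out
#' of scope); it is parsed into a `sample` column when present.
#'
#' @param path FASTQ file path.
#' @return data frame with columns `id`, `sample`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that (empty) metadata columns are dropped; harmless here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- names(x)
  sample <- sub(".*sample=([^ ;]+).*", "\\1", ids)
  sample[!grepl("sample=", ids)] <- NA_character_
  data.frame(
    id = sub(" .*", "", ids),
    sample = sample,
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns `seq`, `qual`, and optionally `id`
#'   and `sample` (encoded as a `sample=<id>` header token).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  ids <- reads$id %||% sprintf("read_%06d", seq_len(n))
  if (!is.null(reads$sample)) ids <- paste0(ids, " sample=", reads$sample)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write OTU representative sequences as FASTA
#'
#' Headers carry the OTU id and pooled total count (`>OTU_0001;size=123`).
#'
#' @param otu_table an [dereplicate()] result.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_otu_fasta <- function(otu_table, path) {
  x <- Biostrings::DNAStringSet(otu_table$otus$seq)
  names(x) <- sprintf("%s;size=%d", otu_table$otus$otu_id, otu_table$otus$total)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
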