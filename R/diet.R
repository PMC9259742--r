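#' Build a regional diet table from scat-level food items
#'
#' Tabulates, per region, the number of diet-positive scats and the number
#' of scats containing each food item. Each item detected in a scat counts
#' as a single predatory event, so a region's occurrence total is the sum of
#' its per-item scat counts. Scats with no diet item never enter the
#' denominators; a scat with an unknown (missing) region is an error.
#'
#' @param diet long data frame `sample`, `area`, `item` (one row per
#'   detected food item per scat; duplicates are counted once), or a
#'   `scat_records` object from [assemble_scat_records()] (its attached diet
#'   table is used, with wild/domestic labels folded into the item name).
#' @return a `diet_table`: list with `scats` (data frame `region`,
#'   `n_scats`) and `items` (data frame `region`, `item`, `n`).
#' @export
build_diet_table <- function(diet) {
  if (inherits(diet, "scat_records")) {
    d <- attr(diet, "diet")
    diet <- data.frame(
      sample = d$sample, area = d$area, item = d$taxon,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("sample", "area", "item") %in% names(diet)))
  if (anyNA(diet$area)) stop("scat with unknown region")
  diet <- unique(diet[, c("sample", "area", "item")])
  scats <- stats::aggregate(
    sample ~ area,
    data = unique(diet[, c("sample", "area")]), FUN = length
  )
  names(scats) <- c("region", "n_scats")
  items <- stats::aggregate(sample ~ area + item, data = diet, FUN = length)
  names(items) <- c("region", "item", "n")
  items <- items[order(items$region, -items$n, items$item), ]
  scats <- scats[order(scats$region), ]
  rownames(items) <- NULL
  rownames(scats) <- NULL
  structure(list(scats = scats, items = items), class = "diet_table")
}

#' Build a diet table directly from printed per-region counts
#'
#' Reconstructs a scat-level layout consistent with published per-region
#' counts (number of diet-positive scats per region; number of scats
#' containing each item) and feeds it through [build_diet_table()]. Item
#' occurrences are dealt to scats round-robin, which reproduces the counts
#' exactly whenever each item's count does not exceed the region's scat
#' count.
#'
#' @param items data frame `region`, `item`, `n` (scats containing item).
#' @param scats data frame `region`, `n_scats`.
#' @return a `diet_table`.
#' @export
diet_table_from_counts <- function(items, scats) {
  long <- expand_diet_counts(items, scats)
  dt <- build_diet_table(long)
  stopifnot(identical(
    dt$scats$n_scats,
    scats$n_scats[match(dt$scats$region, scats$region)]
  ))
  dt
}

#' @rdname diet_table_from_counts
#' @export
expand_diet_counts <- function(items, scats) {
  stopifnot(all(c("region", "item", "n") %in% names(items)))
  stopifnot(all(c("region", "n_scats") %in% names(scats)))
  rows <- lapply(seq_len(nrow(scats)), function(i) {
    region <- scats$region[i]
    S <- scats$n_scats[i]
    it <- items[items$region == region, , drop = FALSE]
    if (any(it$n > S)) stop("item count exceeds region scat count")
    if (sum(it$n) < S) stop("fewer occurrences than scats in ", region)
    it <- it[order(-it$n, it$item), , drop = FALSE]
    ptr <- 0L
    do.call(rbind, lapply(seq_len(nrow(it)), function(j) {
      idx <- ((ptr + seq_len(it$n[j]) - 1L) %% S) + 1L
      ptr <<- ptr + it$n[j]
      data.frame(
        sample = sprintf("%s_%03d", region, idx),
        area = region, item = it$item[j], stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.diet_table <- function(x, ...) {
  cat(sprintf(
    "diet_table: %d regions, %d scats, %d occurrences, %d items\n",
    nrow(x$scats), sum(x$scats$n_scats), sum(x$items$n),
    length(unique(x$items$item))
  ))
  invisible(x)
}

#' Exclude rare or low-read food items
#'
#' Removes items observed in fewer than `min_scats` scats in total across
#' regions (strictly below: an item in exactly `min_scats` scats is
#' retained), plus any caller-flagged low-read items (there is no automatic
#' read-based cutoff; field contamination judgement is the caller's).
#' Denominators (occurrence totals) shrink accordingly in later
#' [rfo()]/[fo()] calls; the excluded rows are attached as `"excluded"`.
#'
#' @param table a `diet_table`.
#' @param min_scats minimum total scat count to retain an item (default 3).
#' @param low_read_items character vector of items flagged low-read.
#' @return the reduced `diet_table`.
#' @export
apply_exclusions <- function(table, min_scats = 3, low_read_items = character(0)) {
  tot <- tapply(table$items$n, table$items$item, sum)
  drop_items <- names(tot)[tot < min_scats]
  drop_items <- union(drop_items, low_read_items)
  excluded <- table$items[table$items$item %in% drop_items, , drop = FALSE]
  table$items <- table$items[!(table$items$item %in% drop_items), , drop = FALSE]
  rownames(table$items) <- NULL
  attr(table, "excluded") <- excluded
  table
}

region_items <- function(table, region) {
  if (identical(region, "total")) {
    agg <- stats::aggregate(n ~ item, data = table$items, FUN = sum)
  } else {
    agg <- table$items[table$items$region == region, c("item", "n"), drop = FALSE]
  }
  agg[order(-agg$n, agg$item), , drop = FALSE]
}

region_scats <- function(table, region) {
  if (identical(region, "total")) {
    sum(table$scats$n_scats)
  } else {
    s <- table$scats$n_scats[table$scats$region == region]
    if (!length(s)) stop("unknown region: ", region)
    s
  }
}

#' Relative frequency of occurrence (RFO)
#'
#' A food item's occurrences as a percentage of all food-item occurrences in
#' a region: `RFO(item) = 100 * occurrences(item) / total occurrences`.
#' Full precision is kept in `rfo`; `rfo_rounded` applies the terminal
#' half-away-from-zero rounding used for report output.
#'
#' @param table a `diet_table`.
#' @param region a region name or `"total"` for the pooled study area.
#' @return data frame `item`, `n`, `rfo`, `rfo_rounded`.
#' @export
rfo <- function(table, region = "total") {
  it <- region_items(table, region)
  total <- sum(it$n)
  if (total == 0) stop("no occurrences in region: ", region)
  out <- data.frame(
    item = it$item, n = it$n,
    rfo = 100 * it$n / total,
    stringsAsFactors = FALSE
  )
  out$rfo_rounded <- round_half_up(out$rfo)
  rownames(out) <- NULL
  out
}

#' Frequency of occurrence (FO)
#'
#' Percentage of diet-positive scats containing an item:
#' `FO(item) = 100 * scats containing item / scats with diet` in the region.
#'
#' @inheritParams rfo
#' @return data frame `item`, `n`, `fo`, `fo_rounded`.
#' @export
fo <- function(table, region = "total") {
  it <- region_items(table, region)
  n_scats <- region_scats(table, region)
  if (n_scats == 0) stop("no scats in region: ", region)
  out <- data.frame(
    item = it$item, n = it$n,
    fo = 100 * it$n / n_scats,
    stringsAsFactors = FALSE
  )
  out$fo_rounded <- round_half_up(out$fo)
  rownames(out) <- NULL
  out
}

#' Mean number of food items per scat
#'
#' @inheritParams rfo
#' @param digits decimals for the rounded value (default 1).
#' @return list with `value` (full precision) and `rounded`.
#' @export
items_per_scat <- function(table, region = "total", digits = 1) {
  v <- sum(region_items(table, region)$n) / region_scats(table, region)
  list(value = v, rounded = round_half_up(v, digits))
}

#' Food-item accumulation curve
#'
#' Mean (and SD) number of distinct food items observed in the first `k`
#' scats of a region, over random permutations of scat order, for
#' `k = 1 .. n_scats`. Deterministic for a fixed seed.
#'
#' @param diet long data frame `sample`, `area`, `item` (as for
#'   [build_diet_table()]) or a `scat_records` object.
#' @param region region name.
#' @param n_permutations number of random scat orders (default 100).
#' @param seed integer seed.
#' @return data frame `region`, `k`, `mean`, `sd`.
#' @export
accumulation_curve <- function(diet, region, n_permutations = 100, seed = 1) {
  if (inherits(diet, "scat_records")) {
    d <- attr(diet, "diet")
    diet <- data.frame(sample = d$sample, area = d$area, item = d$taxon)
  }
  diet <- diet[diet$area == region, , drop = FALSE]
  if (!nrow(diet)) stop("no scats in region: ", region)
  sets <- split(diet$item, diet$sample)
  n <- length(sets)
  acc <- matrix(NA_real_, nrow = n_permutations, ncol = n)
  with_seed(derive_seed(seed, paste0("accumulation/", region)), {
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      seen <- character(0)
      for (k in seq_len(n)) {
        seen <- union(seen, sets[[ord[k]]])
        acc[p, k] <- length(seen)
      }
    }
  })
  data.frame(
    region = region,
    k = seq_len(n),
    mean = colMeans(acc),
    sd = apply(acc, 2, stats::sd)
  )
}

#' Summarise scat depositors per region
#'
#' Counts and percentages of depositor calls per region and in total, the
#' report-table view of [call_depositor()] output. Percentages are of the
#' region's *collected* samples (unidentified scats included in the
#' denominator and reported as their own row), with terminal
#' half-away-from-zero rounding.
#'
#' @param calls data frame `sample`, `area`, `depositor` (`NA` =
#'   unidentified), e.g. scat records.
#' @return data frame `region`, `depositor`, `n`, `pct`, `pct_rounded`,
#'   ordered by total abundance; includes `region = "total"` rows.
#' @export
summarize_depositors <- function(calls) {
  stopifnot(all(c("sample", "area", "depositor") %in% names(calls)))
  calls$depositor[is.na(calls$depositor)] <- "Unidentified"
  areas <- sort(unique(calls$area))
  n_area <- table(calls$area)
  taxa_tot <- sort(table(calls$depositor), decreasing = TRUE)
  taxa <- names(taxa_tot)
  rows <- list()
  for (region in c("total", areas)) {
    sub <- if (region == "total") calls else calls[calls$area == region, , drop = FALSE]
    denom <- nrow(sub)
    for (tx in taxa) {
      n <- sum(sub$depositor == tx)
      if (n == 0 && region != "total") next
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, depositor = tx, n = n,
        pct = 100 * n / denom, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$pct_rounded <- round_half_up(out$pct)
  rownames(out) <- NULL
  out
}
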