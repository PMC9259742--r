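#' Assemble a pipeline configuration
#'
#' Collects every stage's tunables with the pipeline defaults: inclusive
#' per-rank identity thresholds of 99, a 98% query-cover floor, the
#' 0.1%/0.1%/40-read crosstalk screen, the >70% genotyping quality screen
#' and the three-scat reporting floor. The input is either a synthetic
#' design (`design`, run through [simulate_scat_dataset()]) or file paths
#' (`input`: per-marker paired FASTQ plus reference FASTA, a taxonomy CSV,
#' optionally a replicate-genotype CSV). Paths are validated before any
#' compute.
#'
#' @param seed integer seed for every stochastic component.
#' @param design synthetic design list (see [default_study_design()]), or
#'   `NULL` when `input` is given.
#' @param pool_spec pool specification for the synthetic path (default
#'   [default_pool_spec()]).
#' @param input named list of file inputs: `markers` (data frame `marker`,
#'   `role`, `length`, `r1`, `r2`, `refs`), `taxonomy` (CSV path),
#'   `replicates` (optional CSV path).
#' @param thresholds list: `species`, `genus`, `family`, `above_family`,
#'   `min_query_cover`.
#' @param crosstalk list: `taxon_frac`, `sample_frac`, `min_reads`.
#' @param merge list: `min_overlap`, `max_overlap`, `max_mismatch_density`.
#' @param filter list: `maxee` and per-marker length slack `length_slack`
#'   (retained lengths are `marker length +- length_slack`).
#' @param genotyping list: `min_success`, `max_mismatch_loci`,
#'   `min_loci_called`, `n_reps`, `ado_rate`, `fa_rate` (the last three
#'   drive replicate simulation on the synthetic path).
#' @param diet list: `min_scats`, `low_read_items`, `n_permutations`.
#' @param output_dir optional directory for report CSVs and the manifest.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            design = default_study_design(),
                            pool_spec = default_pool_spec(),
                            input = NULL,
                            thresholds = list(),
                            crosstalk = list(),
                            merge = list(),
                            filter = list(),
                            genotyping = list(),
                            diet = list(),
                            output_dir = NULL) {
  defaults <- function(x, d) utils::modifyList(d, x)
  cfg <- list(
    seed = as.integer(seed),
    design = design,
    pool_spec = pool_spec,
    input = input,
    thresholds = defaults(thresholds, list(
      species = 99, genus = 99, family = 99, above_family = 99,
      min_query_cover = 98
    )),
    crosstalk = defaults(crosstalk, list(
      taxon_frac = 0.001, sample_frac = 0.001, min_reads = 40
    )),
    merge = defaults(merge, list(
      min_overlap = 10, max_overlap = 100, max_mismatch_density = 0.25
    )),
    filter = defaults(filter, list(maxee = 1, length_slack = 0)),
    genotyping = defaults(genotyping, list(
      min_success = 0.70, max_mismatch_loci = 0, min_loci_called = 10,
      n_reps = 4, ado_rate = 0.2, fa_rate = 0.02,
      target = "Acinonyx jubatus"
    )),
    diet = defaults(diet, list(
      min_scats = 3, low_read_items = character(0), n_permutations = 100
    )),
    output_dir = output_dir
  )
  if (!is.null(input)) {
    paths <- c(input$markers$r1, input$markers$r2, input$markers$refs,
               input$taxonomy, input$replicates)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("config validation: missing input path(s): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (`seed`, `thresholds`, `crosstalk`, `input`, ...).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$input$markers)) {
    args$input$markers <- as.data.frame(args$input$markers, stringsAsFactors = FALSE)
  }
  do.call(pipeline_config, args)
}

process_marker <- function(pairs, marker_len, refs, taxonomy, cfg) {
  counts_in <- sum(pairs$count)
  m <- merge_read_groups(
    pairs,
    min_overlap = cfg$merge$min_overlap,
    max_overlap = cfg$merge$max_overlap,
    max_mismatch_density = cfg$merge$max_mismatch_density
  )
  stopifnot(sum(m$merged$count) + sum(m$rejected$count) == counts_in)
  f <- filter_reads(
    m$merged,
    maxee = cfg$filter$maxee,
    length_range = c(marker_len - cfg$filter$length_slack,
                     marker_len + cfg$filter$length_slack)
  )
  stopifnot(sum(f$retained$count) + sum(f$rejected$count) == sum(m$merged$count))
  ot <- dereplicate(f$retained, remove_singletons = TRUE)
  stopifnot(
    sum(ot$counts$count) + sum(attr(ot, "dropped")$total) == sum(f$retained$count)
  )
  hits <- if (nrow(ot$otus)) align_otus(ot$otus, refs) else
    data.frame(otu_id = character(0), subject_species = character(0),
               pident = numeric(0), qcovs = numeric(0),
               length = integer(0), bitscore = numeric(0))
  fh <- filter_hits(hits, cfg$thresholds$min_query_cover, taxonomy)
  th <- binning_thresholds(
    species = cfg$thresholds$species, genus = cfg$thresholds$genus,
    family = cfg$thresholds$family, above_family = cfg$thresholds$above_family
  )
  asn <- bin_otus(fh, th, taxonomy, otu_ids = ot$otus$otu_id)
  dm <- detection_matrix(ot, asn)
  dm_f <- filter_crosstalk(
    dm,
    taxon_frac = cfg$crosstalk$taxon_frac,
    sample_frac = cfg$crosstalk$sample_frac,
    min_reads = cfg$crosstalk$min_reads
  )
  list(
    otus = ot, assignments = asn, matrix = dm_f,
    counts = list(
      input_pairs = counts_in, merged = sum(m$merged$count),
      merge_rejected = sum(m$rejected$count),
      filtered = sum(f$retained$count),
      filter_rejected = sum(f$rejected$count),
      in_otus = sum(ot$counts$count),
      singletons_dropped = sum(attr(ot, "dropped")$total),
      detections = nrow(dm), detections_kept = nrow(dm_f),
      detections_removed = nrow(attr(dm_f, "removal_log"))
    )
  )
}

#' Run the full scat metabarcoding pipeline
#'
#' Executes reads -> merge -> expected-error/length filter -> zero-radius
#' OTUs -> taxonomic binning -> crosstalk filtering -> depositor / diet /
#' wild-domestic calls -> (genotyping and individual matching) -> diet and
#' depositor summaries, with per-stage record-count conservation enforced
#' and a provenance manifest. Identical configuration and seed give
#' identical output.
#'
#' @param config a [pipeline_config()] (or a YAML path readable by
#'   [read_pipeline_config()]).
#' @return list with `records` (scat records), `diet_table`, `summaries`
#'   (`depositors`, `rfo`, `fo` per region and total), `genotyping`
#'   (consensus genotypes, individuals, error rates, PID), `markers`
#'   (per-marker OTU/assignment/detection objects), `truth` (synthetic path
#'   only) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (is.null(config$input)) {
    pool <- generate_reference_db(config$pool_spec, seed)
    run <- simulate_scat_dataset(config$design, pool, seed)
    taxonomy <- pool$taxonomy
    markers <- pool$markers
    groups <- run$groups
    truth <- run$truth
    samples <- run$samples
  } else {
    run <- NULL
    truth <- NULL
    markers <- config$input$markers
    taxonomy <- taxonomy_table(
      utils::read.csv(config$input$taxonomy, stringsAsFactors = FALSE)
    )
    groups <- do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
      r1 <- read_fastq(markers$r1[i])
      r2 <- read_fastq(markers$r2[i])
      stopifnot(identical(r1$id, r2$id))
      data.frame(
        sample = r1$sample, marker = markers$marker[i],
        fwd = r1$seq, rev = r2$seq,
        fwd_qual = r1$qual, rev_qual = r2$qual,
        count = 1L, source = r1$sample, stringsAsFactors = FALSE
      )
    }))
    samples <- unique(data.frame(
      sample = groups$sample,
      area = sub("_S?[0-9]+$", "", groups$sample),
      stringsAsFactors = FALSE
    ))
    pool <- NULL
  }

  marker_results <- list()
  for (i in seq_len(nrow(markers))) {
    mk <- markers$marker[i]
    role <- markers$role[i]
    pairs <- groups[groups$marker == mk, , drop = FALSE]
    if (!nrow(pairs)) next
    if (role == "wild_domestic") {
      if (!is.null(pool)) {
        wd <- wild_domestic_reference(pool, mk)
        refs <- wd$refs
        tax <- wd$taxonomy
      } else {
        refs <- read_ref_fasta(markers$refs[i])
        tax <- taxonomy
      }
    } else {
      refs <- if (!is.null(pool)) {
        pool$refs[pool$refs$marker == mk, c("species", "seq")]
      } else {
        read_ref_fasta(markers$refs[i])
      }
      tax <- taxonomy
    }
    marker_results[[mk]] <- process_marker(
      pairs, markers$length[i], refs, tax, config
    )
  }

  role_of <- function(role) markers$marker[markers$role == role][1]
  dm_pred <- marker_results[[role_of("predator")]]$matrix
  dm_prey <- marker_results[[role_of("prey")]]$matrix
  dm_wd <- if (!is.na(role_of("wild_domestic")) &&
               !is.null(marker_results[[role_of("wild_domestic")]])) {
    marker_results[[role_of("wild_domestic")]]$matrix
  }

  depositors <- call_depositor(dm_pred, samples = samples$sample)
  diet <- call_diet(dm_prey, depositors, taxonomy)
  wd <- if (!is.null(dm_wd)) resolve_wild_domestic(dm_wd, diet, taxonomy)

  genotyping <- NULL
  if (!is.null(truth)) {
    gt_samples <- depositors$sample[
      !is.na(depositors$depositor) &
        depositors$depositor == config$genotyping$target
    ]
    inds <- truth$individual_id[match(gt_samples, truth$sample)]
    keep <- !is.na(inds)
    gt_samples <- gt_samples[keep]
    inds <- inds[keep]
    if (length(gt_samples)) {
      tg <- simulate_individual_genotypes(
        n_individuals = config$design$n_individuals %||% 14,
        seed = seed
      )
      reps <- simulate_replicate_genotypes(
        tg$genotypes,
        ado_rate = config$genotyping$ado_rate,
        fa_rate = config$genotyping$fa_rate,
        n_reps = config$genotyping$n_reps,
        seed = seed,
        samples = data.frame(sample = gt_samples, individual = inds)
      )
      cons <- consensus_genotypes(reps, min_success = config$genotyping$min_success)
      indiv <- if (length(cons)) {
        match_individuals(
          cons,
          max_mismatch_loci = config$genotyping$max_mismatch_loci,
          min_loci_called = config$genotyping$min_loci_called
        )
      }
      freqs <- if (length(cons) && !is.null(indiv)) {
        first <- cons[match(unique(indiv$individual_id[!is.na(indiv$individual_id)]),
                            indiv$individual_id)]
        allele_frequencies(first)
      }
      genotyping <- list(
        replicates = reps, consensus = cons, individuals = indiv,
        error_rates = if (length(cons)) genotyping_error_rates(reps, cons),
        pid = if (!is.null(freqs)) pid(freqs)$overall,
        pid_sibs = if (!is.null(freqs)) pid_sibs(freqs)$overall
      )
    }
  }

  indiv_df <- if (!is.null(genotyping$individuals)) {
    data.frame(
      sample = genotyping$individuals$sample,
      individual_id = genotyping$individuals$individual_id,
      sex = if (!is.null(truth)) {
        truth$sex[match(genotyping$individuals$sample, truth$sample)]
      } else {
        NA_character_
      },
      stringsAsFactors = FALSE
    )
  }
  records <- assemble_scat_records(samples, depositors, diet, wd, indiv_df)

  dt <- build_diet_table(records)
  dt_kept <- apply_exclusions(
    dt,
    min_scats = config$diet$min_scats,
    low_read_items = config$diet$low_read_items
  )
  dep_calls <- data.frame(
    sample = records$sample, area = records$area,
    depositor = records$depositor, stringsAsFactors = FALSE
  )
  regions <- c("total", sort(unique(records$area)))
  summaries <- list(
    depositors = summarize_depositors(dep_calls),
    rfo = lapply(stats::setNames(regions, regions), function(r) {
      tryCatch(rfo(dt_kept, r), error = function(e) NULL)
    }),
    fo = lapply(stats::setNames(regions, regions), function(r) {
      tryCatch(fo(dt_kept, r), error = function(e) NULL)
    })
  )

  stage_counts <- lapply(marker_results, `[[`, "counts")
  manifest <- list(
    package = as.character(utils::packageVersion("scatdiet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = config_hash(config),
    n_samples = nrow(samples),
    stage_counts = stage_counts,
    n_records = nrow(records),
    n_diet_scats = sum(dt$scats$n_scats)
  )

  result <- list(
    records = records, diet_table = dt, diet_table_excluded = dt_kept,
    summaries = summaries, genotyping = genotyping,
    markers = marker_results, depositors = depositors, diet = diet,
    wild_domestic = wd, truth = truth, samples = samples,
    taxonomy = taxonomy, manifest = manifest
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config$output_dir)
  result
}

config_hash <- function(config) {
  config$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

read_ref_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(
    species = gsub("_", " ", sub(" .*", "", names(x))),
    seq = as.character(x), stringsAsFactors = FALSE
  )
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$records, file.path(dir, "scat_records.csv"), row.names = FALSE, na = "")
  utils::write.csv(result$summaries$depositors, file.path(dir, "depositor_summary.csv"), row.names = FALSE)
  rfo_all <- do.call(rbind, lapply(names(result$summaries$rfo), function(r) {
    x <- result$summaries$rfo[[r]]
    if (is.null(x) || nrow(x) == 0) return(NULL)
    cbind(region = r, x)
  }))
  if (!is.null(rfo_all)) utils::write.csv(rfo_all, file.path(dir, "rfo.csv"), row.names = FALSE)
  fo_all <- do.call(rbind, lapply(names(result$summaries$fo), function(r) {
    x <- result$summaries$fo[[r]]
    if (is.null(x) || nrow(x) == 0) return(NULL)
    cbind(region = r, x)
  }))
  if (!is.null(fo_all)) utils::write.csv(fo_all, file.path(dir, "fo.csv"), row.names = FALSE)
  for (mk in names(result$markers)) {
    log <- attr(result$markers[[mk]]$matrix, "removal_log")
    utils::write.csv(log, file.path(dir, paste0("removed_", mk, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    result$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Score truth recovery of a synthetic pipeline run
#'
#' Compares called depositors and food items against the simulator's truth.
#' A truth food item is recovered when the called items contain the species
#' itself, or its genus with a matching wild/domestic resolution (wild and
#' domestic congeners are indistinguishable on the prey marker by design).
#'
#' @param result a [run_pipeline()] result from the synthetic path.
#' @return list with `depositor_recovery`, `diet_recovery` (fractions),
#'   `n_samples`, `n_truth_items` and per-sample detail data frame.
#' @export
recovery_report <- function(result) {
  truth <- result$truth
  if (is.null(truth)) stop("recovery_report needs a synthetic-path result")
  taxonomy <- result$taxonomy
  diet <- result$diet
  wd <- result$wild_domestic
  dep_ok <- result$depositors$depositor[match(truth$sample, result$depositors$sample)] ==
    truth$depositor
  dep_ok[is.na(dep_ok)] <- FALSE
  items_recovered <- 0L
  items_total <- 0L
  detail <- list()
  for (i in seq_len(nrow(truth))) {
    s <- truth$sample[i]
    t_items <- strsplit(truth$diet[i], ";", fixed = TRUE)[[1]]
    called <- diet$taxon[diet$sample == s]
    for (it in t_items) {
      items_total <- items_total + 1L
      ok <- it %in% called
      if (!ok) {
        # genus-level call resolved by the wild/domestic marker
        g <- taxonomy$genus[match(it, taxonomy$species)]
        dom <- taxonomy$domestication[match(it, taxonomy$species)]
        if (!is.na(g) && g %in% called && !is.null(wd)) {
          st <- wd$status[wd$sample == s & wd$taxon == g]
          ok <- length(st) == 1L && !is.na(dom) && identical(st, dom)
        }
      }
      if (ok) items_recovered <- items_recovered + 1L
      detail[[length(detail) + 1L]] <- data.frame(
        sample = s, item = it, recovered = ok, stringsAsFactors = FALSE
      )
    }
  }
  list(
    depositor_recovery = mean(dep_ok),
    diet_recovery = items_recovered / items_total,
    n_samples = nrow(truth),
    n_truth_items = items_total,
    detail = do.call(rbind, detail)
  )
}
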