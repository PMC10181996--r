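#' Read and validate a pipeline configuration
#'
#' YAML layout:
#' ```yaml
#' seed: 20260929          # required
#' out_dir: results
#' synth:                  # overrides for synth_config(); 'preset' picks
#'   preset: compromised   # compromised | healthy | custom
#'   noise_sd_bp: 2
#' protocol: {type: loo}   # or {type: split, ratio: 0.8}
#' feature_sets: [combined, pat, morphology]
#' families: [lasso_en, boosted_trees, svr, ann, lstm]
#' targets: [sbp, dbp, map]
#' ```
#'
#' A missing seed is an error: every stochastic stage in the pipeline is
#' seeded from this value.
#'
#' @param path YAML file path.
#' @return A validated list of class `bp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) bp_abort("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) bp_abort("config must set an integer 'seed'")
  if (!is.numeric(raw$seed) || raw$seed != round(raw$seed)) {
    bp_abort("config 'seed' must be an integer")
  }
  raw$seed <- as.integer(raw$seed)
  raw$out_dir <- raw$out_dir %||% "results"
  synth <- raw$synth %||% list()
  preset <- synth$preset %||% "compromised"
  if (!preset %in% c("compromised", "healthy", "custom")) {
    bp_abort("synth preset must be compromised, healthy or custom")
  }
  synth$preset <- NULL
  maker <- switch(preset, compromised = synth_config_compromised,
                  healthy = synth_config_healthy, custom = synth_config)
  raw$synth_config <- do.call(maker, c(list(seed = raw$seed), synth))
  raw$protocol <- raw$protocol %||% list(type = "loo")
  if (!(raw$protocol$type %||% "loo") %in% c("loo", "split")) {
    bp_abort("protocol type must be loo or split")
  }
  if (identical(raw$protocol$type, "split")) raw$protocol$seed <- raw$seed
  raw$feature_sets <- unlist(raw$feature_sets %||% c("combined", "pat", "morphology"))
  raw$families <- unlist(raw$families %||% bp_families)
  raw$targets <- unlist(raw$targets %||% c("sbp", "dbp", "map"))
  bad <- setdiff(raw$families, bp_families)
  if (length(bad) > 0L) bp_abort("unknown families: ", paste(bad, collapse = ", "))
  for (fs in raw$feature_sets) feature_set_columns(fs)
  structure(raw, class = "bp_pipeline_config")
}

#' Write / read a waveform record on disk
#'
#' The on-disk container is a plain-text pair: `<path>.csv` with one column
#' per channel (`ecg`, `ppg1`, optionally `ppg2`, `abp`) and `<path>.json`
#' with the sampling rate and subject metadata.
#'
#' @param record A [waveform_record()].
#' @param path Base path without extension.
#' @return `write_waveform_record`: `path`, invisibly.
#'   `read_waveform_record`: a `waveform_record`.
#' @export
write_waveform_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  sig <- c(list(ecg = record$ecg),
           stats::setNames(record$ppg, paste0("ppg", seq_along(record$ppg))))
  if (!is.null(record$abp)) sig$abp <- record$abp
  readr::write_csv(tibble::as_tibble(sig), paste0(path, ".csv"))
  jsonlite::write_json(list(fs = record$fs, meta = record$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_waveform_record
#' @export
read_waveform_record <- function(path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    bp_abort("waveform record needs both ", csv, " and ", js)
  }
  sig <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  hdr <- jsonlite::read_json(js, simplifyVector = TRUE)
  ppg_cols <- grep("^ppg[0-9]+$", names(sig), value = TRUE)
  if (!"ecg" %in% names(sig) || length(ppg_cols) == 0L) {
    bp_abort("record csv must contain ecg and ppg1 columns")
  }
  waveform_record(
    ecg = sig$ecg, ppg = lapply(ppg_cols, function(cl) sig[[cl]]),
    fs = hdr$fs, abp = if ("abp" %in% names(sig)) sig$abp,
    meta = as.list(hdr$meta)
  )
}

#' Pipeline stage: synthesize data
#'
#' Generates the configured synthetic cohort's feature table (and ground
#' truth) and writes both as CSV under `out_dir`.
#'
#' @param config A `bp_pipeline_config`.
#' @param write_records Also render and write the first `write_records`
#'   waveform records (0 = none).
#' @return The `synth_feature_table`, invisibly; files
#'   `features.csv`, `truth.csv` (and `records/record_###.{csv,json}`).
#' @export
pipeline_synth <- function(config, write_records = 0L) {
  stopifnot(inherits(config, "bp_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- generate_feature_table(config$synth_config)
  save_table(tab, file.path(config$out_dir, "features.csv"))
  readr::write_csv(tab$truth, file.path(config$out_dir, "truth.csv"))
  if (write_records > 0L) {
    rec_dir <- file.path(config$out_dir, "records")
    dir.create(rec_dir, showWarnings = FALSE)
    cohort <- synthesize_cohort(config$synth_config)
    for (i in seq_len(min(write_records, length(cohort$records)))) {
      write_waveform_record(cohort$records[[i]],
                            file.path(rec_dir, sprintf("record_%03d", i)))
    }
  }
  invisible(tab)
}

#' Pipeline stage: extract features from waveform records
#'
#' @param records A directory of records written by [write_waveform_record()],
#'   or a list of `waveform_record` objects.
#' @param out Optional CSV path for the extracted table.
#' @return Tibble of extracted feature rows.
#' @export
pipeline_extract <- function(records, out = NULL) {
  if (is.character(records)) {
    bases <- sub("\\.csv$", "", list.files(records, pattern = "\\.csv$",
                                           full.names = TRUE))
    if (length(bases) == 0L) bp_abort("no records found in ", records)
    records <- lapply(bases, read_waveform_record)
  }
  rows <- lapply(records, extract_record_features)
  tab <- dplyr::bind_rows(rows)
  if (!is.null(out)) save_table(tab, out)
  tab
}

#' Pipeline stage: evaluate the method-by-feature-set grid
#'
#' @param dataset Feature table (tibble, `synth_feature_table`, or a CSV
#'   path loadable by [load_table()]).
#' @param config A `bp_pipeline_config`.
#' @return The `bp_protocol_result`; `summary.csv` and `errors.csv` are
#'   written under `out_dir`.
#' @export
pipeline_evaluate <- function(dataset, config) {
  stopifnot(inherits(config, "bp_pipeline_config"))
  if (is.character(dataset)) dataset <- load_table(dataset)
  if (inherits(dataset, "synth_feature_table")) dataset <- dataset$features
  missing <- setdiff(bp_feature_schema(), names(dataset))
  if (length(missing) > 0L) {
    bp_abort("feature table schema violation; missing columns: ",
             paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- full_protocol(dataset, protocol = config$protocol,
                       families = config$families,
                       feature_sets = config$feature_sets,
                       targets = config$targets)
  readr::write_csv(res$summaries, file.path(config$out_dir, "summary.csv"))
  readr::write_csv(res$errors, file.path(config$out_dir, "errors.csv"))
  res
}

#' Pipeline stage: statistical comparison report
#'
#' @param result A `bp_protocol_result` (or the `errors.csv` written by
#'   [pipeline_evaluate()]).
#' @param config A `bp_pipeline_config`.
#' @return Named list of [stat_report()]s, one per target;
#'   `stats_<target>.json` files are written under `out_dir`.
#' @export
pipeline_compare <- function(result, config) {
  stopifnot(inherits(config, "bp_pipeline_config"))
  errors <- if (inherits(result, "bp_protocol_result")) result$errors
            else readr::read_csv(result, show_col_types = FALSE, progress = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(stats::setNames(config$targets, config$targets), function(tgt) {
    rep <- stat_report(errors, target = tgt)
    jsonlite::write_json(
      lapply(unclass(rep), function(x) as.data.frame(x)),
      file.path(config$out_dir, paste0("stats_", tgt, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    rep
  })
  reports
}

#' Pipeline stage: consolidated report
#'
#' Collects the evaluation grid, IEC census and Bland-Altman data for the
#' combined feature set into one JSON plus per-target Bland-Altman CSVs.
#'
#' @param result A `bp_protocol_result`.
#' @param dataset The evaluated feature table (for Bland-Altman truths).
#' @param config A `bp_pipeline_config`.
#' @return The report list, invisibly; writes `report.json` and
#'   `bland_altman_<target>.csv`.
#' @export
pipeline_report <- function(result, dataset, config) {
  stopifnot(inherits(result, "bp_protocol_result"),
            inherits(config, "bp_pipeline_config"))
  if (inherits(dataset, "synth_feature_table")) dataset <- dataset$features
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$summaries
  report <- list(
    n_cells = nrow(s),
    iec = list(bias_pass = sum(s$bias_pass), sd_pass = sum(s$sd_pass),
               overall = sum(s$overall)),
    summaries = as.data.frame(s)
  )
  for (tgt in intersect(config$targets, unique(result$errors$target))) {
    err <- result$errors
    err <- err[err$target == tgt & err$feature_set == "combined", ]
    if (nrow(err) == 0L) next
    truth_col <- paste0(tgt, "_mmhg")
    ba_rows <- lapply(split(err, err$method), function(e) {
      truths <- dataset[[truth_col]][e$row]
      ba <- bland_altman(truths + e$error, truths)
      tibble::tibble(method = e$method[1], mean = ba$points$mean,
                     difference = ba$points$difference,
                     lower = ba$lower, upper = ba$upper)
    })
    readr::write_csv(dplyr::bind_rows(ba_rows),
                     file.path(config$out_dir, paste0("bland_altman_", tgt, ".csv")))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
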