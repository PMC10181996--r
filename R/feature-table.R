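#' Feature-table column schema
#'
#' Canonical column order for persisted feature tables. Units are encoded in
#' the names: seconds (`_s`), bpm, arbitrary PPG units (`_au`), years, cm,
#' kg, degrees Celsius and mmHg. `sex` is coded 0/1 (1 = male).
#'
#' @return Character vector of column names.
#' @export
bp_feature_schema <- function() {
  c("subject_id", "cohort",
    "pat_s", "ptt_s", "pulse_rate_bpm",
    "tc_s", "ts_s", "td_s",
    "vp_au", "vs_au", "dvs_au_per_s", "vd_au", "dvd_au_per_s",
    "age_y", "sex", "waist_cm", "weight_kg", "temp_c",
    "sbp_mmhg", "dbp_mmhg", "map_mmhg")
}

label_columns <- function() c("sbp_mmhg", "dbp_mmhg", "map_mmhg")

#' Save a feature table as CSV
#'
#' @param dataset Tibble/data frame with the [bp_feature_schema()] columns
#'   (extra columns are preserved), or a `synth_feature_table` whose
#'   `features` element is written.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_table <- function(dataset, path) {
  if (inherits(dataset, "synth_feature_table")) dataset <- dataset$features
  missing <- setdiff(bp_feature_schema(), names(dataset))
  if (length(missing) > 0L) {
    bp_abort("dataset is missing schema columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(dataset), bp_feature_schema())
  dataset <- dataset[, c(bp_feature_schema(), extra)]
  readr::write_csv(dataset, path)
  invisible(path)
}

#' Load a feature table from CSV
#'
#' Validates the schema: all canonical columns must be present and numeric
#' columns must parse as numeric. Unknown extra columns are preserved with a
#' warning.
#'
#' @param path CSV path written by [save_table()] (or matching the schema).
#' @return A tibble with the schema columns first.
#' @export
load_table <- function(path) {
  if (!file.exists(path)) bp_abort("no such file: ", path)
  num_spec <- stats::setNames(
    rep(list(readr::col_double()),
        length(setdiff(bp_feature_schema(), c("subject_id", "cohort")))),
    setdiff(bp_feature_schema(), c("subject_id", "cohort")))
  dataset <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = do.call(readr::cols,
                        c(list(subject_id = readr::col_character(),
                               cohort = readr::col_character()), num_spec))))
  prob <- readr::problems(dataset)
  if (nrow(prob) > 0L) {
    bp_abort("non-numeric values in columns: ",
             paste(unique(names(dataset)[unique(prob$col)]), collapse = ", "))
  }
  missing <- setdiff(bp_feature_schema(), names(dataset))
  if (length(missing) > 0L) {
    bp_abort("feature table schema violation; missing columns: ",
             paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(bp_feature_schema(), c("subject_id", "cohort"))
  bad <- num_cols[!vapply(dataset[num_cols], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    bp_abort("non-numeric values in columns: ", paste(bad, collapse = ", "))
  }
  extra <- setdiff(names(dataset), bp_feature_schema())
  if (length(extra) > 0L) {
    bp_warn("unknown columns preserved: ", paste(extra, collapse = ", "))
  }
  dataset[, c(bp_feature_schema(), extra)]
}

#' Columns of a named feature-set view
#'
#' The `combined` set holds all 12 model inputs used for the ICU-style
#' cohort: the two temporal components (PAT, pulse rate), the two
#' demographic components (age, sex) and the eight morphology features. The
#' `pat` and `morphology` subsets keep the demographics so each view is a
#' self-contained predictor set. `healthy7` is the wrist-watch view: PTT,
#' pulse rate and five demographics.
#'
#' @param id One of `"combined"`, `"pat"`, `"morphology"`, `"healthy7"`.
#' @return Ordered character vector of feature column names.
#' @export
feature_set_columns <- function(id) {
  morph <- c("tc_s", "ts_s", "td_s", "vp_au", "vs_au", "dvs_au_per_s",
             "vd_au", "dvd_au_per_s")
  switch(match.arg(id, c("combined", "pat", "morphology", "healthy7")),
    combined = c("pat_s", "pulse_rate_bpm", "age_y", "sex", morph),
    pat = c("pat_s", "pulse_rate_bpm", "age_y", "sex"),
    morphology = c(morph, "age_y", "sex"),
    healthy7 = c("ptt_s", "pulse_rate_bpm", "waist_cm", "weight_kg", "sex",
                 "temp_c", "age_y")
  )
}

#' Select a feature-set view as a model matrix plus labels
#'
#' @param dataset Feature table (tibble) or `synth_feature_table`.
#' @param id Feature-set id, see [feature_set_columns()].
#' @param target Optional label: `"sbp"`, `"dbp"` or `"map"`. When given,
#'   `y` is that label vector; otherwise `y` is a tibble of all three.
#' @return List with `x` (numeric matrix, one column per feature), `y`,
#'   and `feature_set`.
#' @export
select_feature_set <- function(dataset, id, target = NULL) {
  if (inherits(dataset, "synth_feature_table")) dataset <- dataset$features
  cols <- feature_set_columns(id)
  missing <- setdiff(cols, names(dataset))
  if (length(missing) > 0L) {
    bp_abort("feature set '", id, "' needs missing columns: ",
             paste(missing, collapse = ", "))
  }
  x <- as.matrix(dataset[, cols])
  storage.mode(x) <- "double"
  if (anyNA(x)) bp_abort("missing values in feature set '", id, "'")
  lab <- dataset[, intersect(label_columns(), names(dataset))]
  if (!is.null(target)) {
    target <- match.arg(target, c("sbp", "dbp", "map"))
    col <- paste0(target, "_mmhg")
    if (!col %in% names(dataset)) bp_abort("missing label column ", col)
    y <- dataset[[col]]
    if (anyNA(y)) bp_abort("missing values in label ", col)
  } else {
    y <- lab
  }
  list(x = x, y = y, feature_set = id)
}
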