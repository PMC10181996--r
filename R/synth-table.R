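runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# Subject-level physiology + demographics. Assumes the RNG state is already
# set by the caller when reproducibility is wanted.
sample_population_impl <- function(config) {
  n <- config$n_subjects
  dem <- config$demographics
  if (n == 0L) {
    return(tibble::tibble(
      subject_id = character(0), sex = integer(0), age_y = numeric(0),
      waist_cm = numeric(0), weight_kg = numeric(0), temp_c = numeric(0),
      hr_bpm = numeric(0), ptt_s = numeric(0), pir = numeric(0),
      alpha = numeric(0), ts_frac = numeric(0), vp_au = numeric(0)
    ))
  }
  sex <- stats::rbinom(n, 1L, dem$p_male)  # 1 = male, 0 = female
  old <- stats::rbinom(n, 1L, dem$p_old) == 1L
  age <- ifelse(old, runif_range(n, dem$age_old), runif_range(n, dem$age_young))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = as.integer(sex),
    age_y = round(age),
    waist_cm = round(runif_range(n, dem$waist), 1),
    weight_kg = round(runif_range(n, dem$weight), 1),
    temp_c = round(runif_range(n, dem$temp), 1),
    hr_bpm = runif_range(n, config$heart_rate_range),
    ptt_s = runif_range(n, config$ptt_range),
    pir = runif_range(n, config$pir_range),
    alpha = runif_range(n, config$alpha_range),
    ts_frac = runif_range(n, config$ts_frac_range),
    vp_au = runif_range(n, config$vp_range)
  )
}

#' Sample a synthetic subject population
#'
#' Draws one row of subject-level parameters (demographics plus baseline
#' physiology) per subject from the distributions in `config`. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config A [synth_config()]; `seed` must be set.
#' @return A tibble with one row per subject.
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_subjects > 0L && is.null(config$seed)) {
    bp_abort("config$seed must be set for sample_population")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sample_population_impl(config)
}

# clamp per-record jitter draws back into the configured range
jitter_in_range <- function(x, range, rel = 0.05) {
  sd <- rel * (range[2] - range[1])
  pmin(range[2], pmax(range[1], x + stats::rnorm(length(x), 0, sd)))
}

#' Generate a synthetic feature table with ground truth
#'
#' Produces one feature row per record. Per-record timing and morphology
#' parameters jitter around subject baselines; labels are generated through
#' the closed-form hemodynamic model: DBP is affine in the log of the drive
#' term `PEP/(PIR*PTT^2)` times the Womersley factor, pulse pressure is
#' proportional to the same drive, SBP = PP + DBP, and MAP is the (2*DBP +
#' SBP)/3 weighted mean of the (noisy) pair, so the MAP identity holds
#' exactly in every row. Independent Gaussian noise of SD `noise_sd_bp` is
#' added to DBP and SBP.
#'
#' Morphology features are derived from the sampled pulse shape: `Tc = 60/HR`,
#' `Ts = ts_frac * Tc`, `Td = Tc - Ts`, and the four volume features by their
#' defining formulas (`Vs = Vp*Ts/Tc`, `dVs = Vp/Ts`, `Vd = Vp*Td/Tc`,
#' `dVd = Vp/Td`).
#'
#' @param config A [synth_config()]; `seed` must be set.
#' @return A list of class `synth_feature_table` with elements
#'   `features` (tibble in the [bp_feature_schema()] column layout) and
#'   `truth` (tibble of latent per-record parameters, including the
#'   `log_drive` regressor and noiseless labels `sbp0`/`dbp0`/`map0`).
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(config$seed)) bp_abort("config$seed must be set for generate_feature_table")
  set.seed(config$seed)
  pop <- sample_population_impl(config)
  counts <- config$records_per_subject
  idx <- rep(seq_len(config$n_subjects), counts)
  n <- length(idx)
  sub <- pop[idx, ]

  hr <- jitter_in_range(sub$hr_bpm, config$heart_rate_range)
  ptt <- jitter_in_range(sub$ptt_s, config$ptt_range)
  pir <- jitter_in_range(sub$pir, config$pir_range)
  alpha <- jitter_in_range(sub$alpha, config$alpha_range)
  ts_frac <- jitter_in_range(sub$ts_frac, config$ts_frac_range)
  vp <- jitter_in_range(sub$vp_au, config$vp_range)
  pep <- rep(config$pat_offset, n)
  pat <- ptt + pep

  drive <- (pep / (pir * ptt^2)) * womersley_factor(alpha)
  log_drive <- log(drive)
  dbp0 <- config$a_dbp * log_drive + config$b_dbp
  pp <- config$k_pp * drive
  sbp0 <- pp + dbp0
  map0 <- (2 * dbp0 + sbp0) / 3

  eps_d <- stats::rnorm(n, 0, config$noise_sd_bp)
  eps_s <- stats::rnorm(n, 0, config$noise_sd_bp)
  dbp <- dbp0 + eps_d
  sbp <- pp + dbp + eps_s
  map <- (2 * dbp + sbp) / 3

  tc <- 60 / hr
  ts <- ts_frac * tc
  td <- tc - ts

  record <- stats::ave(idx, idx, FUN = seq_along)
  features <- tibble::tibble(
    subject_id = sub$subject_id,
    cohort = config$cohort,
    pat_s = pat,
    ptt_s = if (config$dual_ppg) ptt else NA_real_,
    pulse_rate_bpm = hr,
    tc_s = tc, ts_s = ts, td_s = td,
    vp_au = vp,
    vs_au = vp * ts / tc,
    dvs_au_per_s = vp / ts,
    vd_au = vp * td / tc,
    dvd_au_per_s = vp / td,
    age_y = sub$age_y, sex = sub$sex,
    waist_cm = sub$waist_cm, weight_kg = sub$weight_kg, temp_c = sub$temp_c,
    sbp_mmhg = sbp, dbp_mmhg = dbp, map_mmhg = map
  )
  truth <- tibble::tibble(
    subject_id = sub$subject_id, record = record,
    pat = pat, ptt = ptt, pep = pep, pir = pir, alpha = alpha,
    hr = hr, tc = tc, ts = ts, td = td, vp = vp,
    drive = drive, log_drive = log_drive, pp = pp,
    sbp0 = sbp0, dbp0 = dbp0, map0 = map0,
    sbp = sbp, dbp = dbp, map = map
  )
  structure(list(features = features, truth = truth, config = config),
            class = "synth_feature_table")
}

#' @export
print.synth_feature_table <- function(x, ...) {
  cat("<synth_feature_table> ", nrow(x$features), " records, ",
      length(unique(x$features$subject_id)), " subjects, cohort '",
      x$config$cohort, "'\n", sep = "")
  invisible(x)
}
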