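#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic data module: cohort layout, sampling,
#' pulse timing, the hemodynamic constants that turn timing into labels,
#' pulse-wave morphology ranges, noise levels and demographic distributions.
#' Subject-level parameters are drawn uniformly from the configured ranges and
#' per-record values jitter around them, so repeated records from one subject
#' are correlated, as in repeated clinical feature sets.
#'
#' Default ranges are chosen so generated labels land in a realistic
#' dysregulated-adult envelope (roughly SBP 90-180, DBP 50-110 mmHg).
#'
#' @param n_subjects Number of subjects.
#' @param records_per_subject Integer scalar or vector (length `n_subjects`)
#'   of records per subject, each in 1..5.
#' @param fs Sampling rate in Hz (125 emulates ICU monitor exports; 400 the
#'   wrist-watch recordings).
#' @param duration Record length in seconds; must cover at least 7 beats.
#' @param heart_rate_range Heart-rate range in bpm.
#' @param ptt_range Pulse-transit-time range in seconds.
#' @param pat_offset Pre-ejection-period surrogate (s): `PAT = PTT + pat_offset`.
#' @param pir_range Pulse-intensity-ratio range (dimensionless).
#' @param alpha_range Womersley-number range.
#' @param k_pp,a_dbp,b_dbp Hemodynamic constants, see [hemo_params()].
#' @param ts_frac_range Range of the systolic-rise fraction `Ts/Tc` (0-1).
#' @param vp_range Range of PPG pulse amplitude `Vp` (arbitrary units).
#' @param noise_sd_signal Waveform noise SD as a fraction of the per-record
#'   pulse amplitude (0.02 = 2 % amplitude noise on ECG/PPG/ABP channels).
#' @param noise_sd_bp Label noise SD in mmHg added to DBP and SBP.
#' @param dual_ppg If `TRUE`, records carry a second (distal) PPG channel
#'   delayed by `ppg_transit_delay`.
#' @param ppg_transit_delay Proximal-to-distal PPG delay in seconds.
#' @param demographics List with `p_male`, `p_old`, `age_young`, `age_old`,
#'   `waist`, `weight`, `temp` (ranges in cm, kg, deg C).
#' @param cohort Cohort tag: `"synthetic"`, `"compromised"` or `"healthy"`.
#' @param seed Integer seed; required by the generator entry points.
#' @return An object of class `synth_config` (named list).
#' @seealso [synth_config_compromised()], [synth_config_healthy()],
#'   [generate_feature_table()], [synthesize_record()]
#' @export
synth_config <- function(n_subjects = 31,
                         records_per_subject = 4,
                         fs = 125,
                         duration = 10,
                         heart_rate_range = c(60, 100),
                         ptt_range = c(0.16, 0.26),
                         pat_offset = 0.08,
                         pir_range = c(1.5, 2.5),
                         alpha_range = c(2.5, 3.5),
                         k_pp = 24, a_dbp = 22, b_dbp = 78,
                         ts_frac_range = c(0.25, 0.40),
                         vp_range = c(0.8, 1.6),
                         noise_sd_signal = 0.02,
                         noise_sd_bp = 2,
                         dual_ppg = FALSE,
                         ppg_transit_delay = 0.005,
                         demographics = list(
                           p_male = 0.6, p_old = 0.92,
                           age_young = c(20, 40), age_old = c(41, 90),
                           waist = c(70, 115), weight = c(50, 110),
                           temp = c(36, 37.5)
                         ),
                         cohort = "synthetic",
                         seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 0 || n_subjects != round(n_subjects)) {
    bp_abort("n_subjects must be a non-negative integer")
  }
  n_subjects <- as.integer(n_subjects)
  if (length(records_per_subject) == 1L) {
    records_per_subject <- rep(as.integer(records_per_subject), n_subjects)
  }
  if (n_subjects > 0L) {
    if (length(records_per_subject) != n_subjects ||
        any(records_per_subject < 1L) || any(records_per_subject > 5L)) {
      bp_abort("records_per_subject must be in 1..5 per subject")
    }
  } else {
    records_per_subject <- integer(0)
  }
  check_number(fs, "fs", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_range(heart_rate_range, "heart_rate_range")
  check_range(ptt_range, "ptt_range")
  check_number(pat_offset, "pat_offset", positive = TRUE)
  check_range(pir_range, "pir_range")
  check_range(alpha_range, "alpha_range")
  if (alpha_range[1] <= 0.56 / sqrt(2)) bp_abort("alpha_range must exceed 0.56/sqrt(2)")
  check_range(ts_frac_range, "ts_frac_range")
  if (ts_frac_range[2] >= 1) bp_abort("ts_frac_range must lie strictly inside (0, 1)")
  check_range(vp_range, "vp_range")
  check_number(noise_sd_signal, "noise_sd_signal")
  check_number(noise_sd_bp, "noise_sd_bp")
  if (noise_sd_signal < 0 || noise_sd_bp < 0) bp_abort("noise SDs must be >= 0")
  check_number(ppg_transit_delay, "ppg_transit_delay", positive = TRUE)
  if (!is.list(demographics) ||
      !all(c("p_male", "p_old", "age_young", "age_old", "waist", "weight", "temp")
           %in% names(demographics))) {
    bp_abort("demographics must list p_male, p_old, age_young, age_old, waist, weight, temp")
  }
  if (demographics$p_male < 0 || demographics$p_male > 1 ||
      demographics$p_old < 0 || demographics$p_old > 1) {
    bp_abort("demographic probabilities must be in [0, 1]")
  }
  cohort <- match.arg(cohort, c("synthetic", "compromised", "healthy"))
  if (!is.null(seed)) {
    if (!is.numeric(seed) || seed != round(seed)) bp_abort("seed must be an integer")
    seed <- as.integer(seed)
  }
  structure(
    list(n_subjects = n_subjects, records_per_subject = records_per_subject,
         fs = fs, duration = duration, heart_rate_range = heart_rate_range,
         ptt_range = ptt_range, pat_offset = pat_offset, pir_range = pir_range,
         alpha_range = alpha_range, k_pp = k_pp, a_dbp = a_dbp, b_dbp = b_dbp,
         ts_frac_range = ts_frac_range, vp_range = vp_range,
         noise_sd_signal = noise_sd_signal, noise_sd_bp = noise_sd_bp,
         dual_ppg = dual_ppg, ppg_transit_delay = ppg_transit_delay,
         demographics = demographics, cohort = cohort, seed = seed),
    class = "synth_config"
  )
}

#' Preset: hemodynamically compromised ICU-style cohort
#'
#' 31 subjects with up to five repeated feature sets each, allocated so the
#' cohort totals 126 records; single finger-style PPG at 125 Hz,
#' predominantly older subjects.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_compromised <- function(seed = NULL, ...) {
  counts <- rep(4L, 31)
  counts[1:2] <- 5L  # 29*4 + 2*5 = 126 records
  synth_config(
    n_subjects = 31, records_per_subject = counts, fs = 125,
    cohort = "compromised",
    demographics = list(p_male = 0.6, p_old = 0.92,
                        age_young = c(20, 40), age_old = c(41, 90),
                        waist = c(70, 115), weight = c(50, 110),
                        temp = c(36, 37.5)),
    seed = seed, ...
  )
}

#' Preset: healthy wrist-watch cohort
#'
#' 23 healthy subjects, one feature set each, dual red/infrared PPG at 400 Hz
#' with waist, weight and temperature demographics.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_healthy <- function(seed = NULL, ...) {
  synth_config(
    n_subjects = 23, records_per_subject = 1, fs = 400, dual_ppg = TRUE,
    cohort = "healthy",
    demographics = list(p_male = 0.52, p_old = 0.52,
                        age_young = c(20, 40), age_old = c(41, 75),
                        waist = c(65, 105), weight = c(50, 100),
                        temp = c(36, 37.2)),
    seed = seed, ...
  )
}
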