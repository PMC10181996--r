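#' Pulse arrival time over a clean window
#'
#' Mean over the window cycles of the R-peak-to-PPG-peak interval. Any
#' non-positive per-cycle interval indicates mis-paired fiducials and is an
#' error.
#'
#' @param r_peaks R-peak positions, aligned cycle-wise with `ppg_peaks`.
#' @param ppg_peaks PPG pulse-peak positions (may be fractional).
#' @param window Cycle indices from [select_clean_window()].
#' @param fs Sampling rate (Hz).
#' @return PAT in seconds.
#' @export
compute_pat <- function(r_peaks, ppg_peaks, window, fs) {
  check_number(fs, "fs", positive = TRUE)
  if (length(window) < 1L || max(window) > length(r_peaks) ||
      max(window) > length(ppg_peaks)) {
    bp_abort("window indexes cycles outside the fiducial set")
  }
  gaps <- (ppg_peaks[window] - r_peaks[window]) / fs
  if (any(gaps <= 0)) {
    bp_abort("non-positive R-to-PPG interval in window: mis-paired fiducials")
  }
  mean(gaps)
}

#' Pulse transit time between two PPG sites
#'
#' Mean over the window cycles of the proximal-to-distal pulse-peak delay.
#'
#' @param prox_peaks Proximal PPG peak positions.
#' @param dist_peaks Distal PPG peak positions, aligned cycle-wise.
#' @param window Cycle indices.
#' @param fs Sampling rate (Hz).
#' @return PTT in seconds (> 0).
#' @export
compute_ptt <- function(prox_peaks, dist_peaks, window, fs) {
  check_number(fs, "fs", positive = TRUE)
  if (length(window) < 1L || max(window) > length(prox_peaks) ||
      max(window) > length(dist_peaks)) {
    bp_abort("window indexes cycles outside the fiducial set")
  }
  gaps <- (dist_peaks[window] - prox_peaks[window]) / fs
  if (any(gaps <= 0)) {
    bp_abort("non-positive proximal-to-distal transit: degenerate or mis-paired peaks")
  }
  mean(gaps)
}

#' Pulse-wave morphology features over a clean window
#'
#' Per cycle, `Ts` is foot-to-peak time, `Td` peak-to-next-foot time,
#' `Tc = Ts + Td`, and `Vp` the foot-to-peak amplitude difference. The
#' primitives are averaged over the window and the four volume features are
#' derived from the averages (`Vs = Vp*Ts/Tc`, `dVs = Vp/Ts`, `Vd = Vp*Td/Tc`,
#' `dVd = Vp/Td`), so the defining identities hold exactly on every returned
#' row.
#'
#' @param fiducials A `ppg_fiducials` object.
#' @param window Cycle indices from [select_clean_window()].
#' @param fs Sampling rate (Hz).
#' @return Named list: `tc`, `ts`, `td` (s), `vp`, `vs`, `vd` (a.u.),
#'   `dvs`, `dvd` (a.u./s).
#' @export
compute_morphology <- function(fiducials, window, fs) {
  stopifnot(inherits(fiducials, "ppg_fiducials"))
  check_number(fs, "fs", positive = TRUE)
  if (max(window) + 1L > length(fiducials$feet)) {
    bp_abort("window cycles need a following foot; window exceeds fiducial set")
  }
  ts_i <- (fiducials$peaks[window] - fiducials$feet[window]) / fs
  td_i <- (fiducials$feet[window + 1L] - fiducials$peaks[window]) / fs
  vp_i <- fiducials$peak_values[window] - fiducials$foot_levels[window]
  if (any(ts_i <= 0) || any(td_i <= 0) || any(vp_i <= 0)) {
    bp_abort("non-positive Ts, Td or Vp in window")
  }
  ts <- mean(ts_i); td <- mean(td_i); vp <- mean(vp_i)
  tc <- ts + td
  list(tc = tc, ts = ts, td = td, vp = vp,
       vs = vp * ts / tc, dvs = vp / ts,
       vd = vp * td / tc, dvd = vp / td)
}

#' Pulse rate from window cycle times
#'
#' @param tc Per-cycle durations in seconds (the window's cycle lengths).
#' @return Pulse rate in bpm: `60 / mean(tc)`.
#' @export
compute_pulse_rate <- function(tc) {
  if (length(tc) < 1L || any(!is.finite(tc)) || any(tc <= 0)) {
    bp_abort("cycle times must be positive and finite")
  }
  60 / mean(tc)
}

#' Reference blood pressure averaged over the window
#'
#' Systolic pressure is the mean of the per-cycle arterial-pressure maxima,
#' diastolic the mean of the per-cycle minima, and MAP their (2*DBP + SBP)/3
#' combination.
#'
#' @param abp Arterial pressure vector (mmHg); errors if `NULL`.
#' @param fiducials A `ppg_fiducials` object defining cycle boundaries.
#' @param window Cycle indices.
#' @param fs Sampling rate (Hz).
#' @return Named list `sbp`, `dbp`, `map` (mmHg).
#' @export
average_reference_bp <- function(abp, fiducials, window, fs) {
  if (is.null(abp)) bp_abort("record has no arterial-pressure channel")
  stopifnot(inherits(fiducials, "ppg_fiducials"))
  if (max(window) + 1L > length(fiducials$feet)) {
    bp_abort("window cycles need a following foot; window exceeds fiducial set")
  }
  maxima <- minima <- numeric(length(window))
  for (j in seq_along(window)) {
    k <- window[j]
    span <- max(1L, floor(fiducials$feet[k])):min(length(abp), ceiling(fiducials$feet[k + 1L]) - 1L)
    maxima[j] <- max(abp[span])
    minima[j] <- min(abp[span])
  }
  sbp <- mean(maxima); dbp <- mean(minima)
  list(sbp = sbp, dbp = dbp, map = map_from_sbp_dbp(sbp, dbp))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    bp_abort("extract_record_features [", stage, "]: ", conditionMessage(e))
  })
}

#' Extract the full feature row from one waveform record
#'
#' Composes R-peak detection, PPG fiducial detection, clean-window selection,
#' PAT/PTT/pulse-rate/morphology computation and reference-label averaging,
#' then attaches the record's demographic metadata. Errors from any stage are
#' re-raised with the stage name.
#'
#' PTT is present only for dual-PPG records; reference labels only when the
#' record carries an arterial-pressure channel.
#'
#' @param record A [waveform_record()].
#' @param k Window length in cycles (default 5).
#' @param cv_len,cv_amp Clean-window CV thresholds, see [select_clean_window()].
#' @return One-row tibble in the [bp_feature_schema()] column layout.
#' @export
extract_record_features <- function(record, k = 5, cv_len = 0.10, cv_amp = 0.20) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$fs
  r_peaks <- with_stage("detect_r_peaks", detect_r_peaks(record$ecg, fs))
  fid <- with_stage("detect_ppg_fiducials",
                    detect_ppg_fiducials(record$ppg[[1]], fs, r_peaks))
  window <- with_stage("select_clean_window",
                       select_clean_window(fid, k = k, cv_len = cv_len, cv_amp = cv_amp))
  pat <- with_stage("compute_pat",
                    compute_pat(fid$r_peaks, fid$peaks, window, fs))
  morph <- with_stage("compute_morphology", compute_morphology(fid, window, fs))
  lens <- diff(fid$feet)
  rate <- with_stage("compute_pulse_rate", compute_pulse_rate(lens[window] / fs))

  ptt <- NA_real_
  if (length(record$ppg) == 2L) {
    fid2 <- with_stage("detect_ppg_fiducials(distal)",
                       detect_ppg_fiducials(record$ppg[[2]], fs, r_peaks))
    common <- intersect(fid$r_peaks, fid2$r_peaks)
    i1 <- match(common, fid$r_peaks)
    i2 <- match(common, fid2$r_peaks)
    win_r <- fid$r_peaks[window]
    sel <- match(win_r, common)
    if (any(is.na(sel))) {
      bp_abort("extract_record_features [compute_ptt]: distal fiducials missing in window")
    }
    ptt <- with_stage("compute_ptt",
                      compute_ptt(fid$peaks[i1][sel], fid2$peaks[i2][sel],
                                  seq_along(sel), fs))
  }

  labels <- list(sbp = NA_real_, dbp = NA_real_, map = NA_real_)
  if (!is.null(record$abp)) {
    labels <- with_stage("average_reference_bp",
                         average_reference_bp(record$abp, fid, window, fs))
  }

  meta <- record$meta
  tibble::tibble(
    subject_id = meta$subject_id %||% NA_character_,
    cohort = meta$cohort %||% "synthetic",
    pat_s = pat,
    ptt_s = ptt,
    pulse_rate_bpm = rate,
    tc_s = morph$tc, ts_s = morph$ts, td_s = morph$td,
    vp_au = morph$vp, vs_au = morph$vs, dvs_au_per_s = morph$dvs,
    vd_au = morph$vd, dvd_au_per_s = morph$dvd,
    age_y = meta$age_y %||% NA_real_,
    sex = meta$sex %||% NA_real_,
    waist_cm = meta$waist_cm %||% NA_real_,
    weight_kg = meta$weight_kg %||% NA_real_,
    temp_c = meta$temp_c %||% NA_real_,
    sbp_mmhg = labels$sbp, dbp_mmhg = labels$dbp, map_mmhg = labels$map
  )
}
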