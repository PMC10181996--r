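#' Waveform record container
#'
#' Synchronized single-record container for an ECG channel, one or two PPG
#' channels and an optional arterial-pressure channel, all sampled at `fs`.
#' All channels must have equal length and finite samples. Sample indices are
#' 1-based throughout the package; index `i` corresponds to time
#' `(i - 1) / fs` seconds.
#'
#' @param ecg Numeric vector (a.u. or mV).
#' @param ppg A numeric vector or list of 1-2 numeric vectors (a.u.);
#'   channel 1 is proximal, channel 2 distal.
#' @param fs Sampling rate (Hz).
#' @param abp Optional arterial pressure vector (mmHg).
#' @param meta Named list of subject metadata (`age_y`, `sex`, optionally
#'   `waist_cm`, `weight_kg`, `temp_c`, `subject_id`, `cohort`).
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(ecg, ppg, fs, abp = NULL, meta = list()) {
  if (is.numeric(ppg)) ppg <- list(ppg)
  if (!is.list(ppg) || length(ppg) < 1L || length(ppg) > 2L) {
    bp_abort("ppg must be one or two numeric channels")
  }
  check_number(fs, "fs", positive = TRUE)
  n <- length(ecg)
  lens <- c(n, vapply(ppg, length, 1L), if (!is.null(abp)) length(abp))
  if (length(unique(lens)) != 1L) bp_abort("all channels must have equal length")
  chans <- c(list(ecg), ppg, if (!is.null(abp)) list(abp))
  if (any(!vapply(chans, function(ch) all(is.finite(ch)), logical(1)))) {
    bp_abort("all samples must be finite")
  }
  structure(list(ecg = ecg, ppg = ppg, abp = abp, fs = fs, meta = meta),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record> ", length(x$ecg), " samples @ ", x$fs, " Hz, ",
      length(x$ppg), " PPG channel(s)",
      if (!is.null(x$abp)) ", ABP" else "", "\n", sep = "")
  invisible(x)
}

#' Single-beat PPG pulse template
#'
#' One stylized PPG beat on the sample grid: a monotone quarter-sine rise
#' from 0 to `vp` over the systolic time `ts` (sharp foot, smooth peak),
#' followed by a monotone Gaussian-tapered decay toward 0 over the diastolic
#' time `td`. The vector has length `round(fs*(ts+td))` and its maximum `vp`
#' falls exactly at 1-based index `round(fs*ts) + 1`.
#'
#' @param ts Systolic rise time (s, > 0).
#' @param td Diastolic decay time (s, > 0).
#' @param vp Pulse amplitude (a.u., >= 0).
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of samples.
#' @export
ppg_beat_template <- function(ts, td, vp, fs) {
  check_number(ts, "ts", positive = TRUE)
  check_number(td, "td", positive = TRUE)
  check_number(vp, "vp")
  check_number(fs, "fs", positive = TRUE)
  if (vp < 0) bp_abort("vp must be >= 0")
  len <- round(fs * (ts + td))
  if (len < 4) bp_abort("fs*(ts+td) must cover at least 4 samples")
  i_peak <- round(fs * ts)
  if (i_peak < 1 || i_peak > len - 2) {
    bp_abort("ts and td must each span at least one sample at this fs")
  }
  i <- 0:(len - 1L)
  out <- numeric(len)
  rise <- i <= i_peak
  out[rise] <- vp * sin(pi * i[rise] / (2 * i_peak))
  # Gaussian-tapered decay, shifted and rescaled to land exactly on 0 at the
  # cycle end so consecutive beats tile without a baseline step
  tau <- (len - i_peak) / 2.45
  e0 <- exp(-2.45^2)
  out[!rise] <- vp * (exp(-((i[!rise] - i_peak) / tau)^2) - e0) / (1 - e0)
  out
}

#' Synthesize a waveform record from subject parameters
#'
#' Builds an ECG channel of narrow stylized R spikes at the configured beat
#' period, a PPG channel of [ppg_beat_template()] pulses whose peaks lag each
#' R spike by the pulse arrival time, optionally a second PPG channel delayed
#' by `config$ppg_transit_delay`, and an arterial-pressure channel
#' oscillating between DBP (at each pulse foot) and SBP (at each pulse peak)
#' with the same beat timing. Independent Gaussian noise of SD
#' `config$noise_sd_signal * amplitude` is added per channel.
#'
#' Beat timing is laid out on the integer sample grid with a constant period
#' of `round(fs * 60/hr)` samples, so with zero noise the fiducial-derived
#' features match the parameters to sub-sample accuracy.
#'
#' @param params Named list or one-row data frame of per-record parameters:
#'   `hr` (bpm), `ts_frac`, `vp`, `pat` (s), `sbp`, `dbp` (mmHg), and
#'   optionally demographic fields copied into the record metadata.
#' @param config A [synth_config()]; `fs`, `duration`, `noise_sd_signal`,
#'   `dual_ppg` and `ppg_transit_delay` are honoured.
#' @return A `waveform_record` with the generating parameters attached as
#'   attribute `"truth"`.
#' @export
synthesize_record <- function(params, config) {
  stopifnot(inherits(config, "synth_config"))
  params <- as.list(params)
  for (f in c("hr", "ts_frac", "vp", "pat", "sbp", "dbp")) {
    if (is.null(params[[f]])) bp_abort("params$", f, " is required")
  }
  fs <- config$fs
  n_samp <- round(config$duration * fs)
  tc <- 60 / params$hr
  ts <- params$ts_frac * tc
  td <- tc - ts
  beat <- ppg_beat_template(ts, td, params$vp, fs)
  period <- length(beat)
  i_peak <- round(fs * ts)
  pat_samp <- round(fs * params$pat)

  # first foot placed so the first R spike stays inside the record
  i0 <- max(round(0.1 * fs), pat_samp - i_peak + round(0.05 * fs)) + 1L
  n_beats <- floor((n_samp - i0 - period + 1) / period) + 1L
  if (n_beats < 7L) {
    bp_abort("duration too short: need at least 7 beats, got ", max(n_beats, 0))
  }
  feet <- i0 + period * (0:(n_beats - 1L))
  r_peaks <- feet + i_peak - pat_samp

  ecg <- numeric(n_samp)
  ecg[r_peaks] <- 1
  ecg[r_peaks - 1L] <- pmax(ecg[r_peaks - 1L], 0.3)
  ecg[r_peaks + 1L] <- pmax(ecg[r_peaks + 1L], 0.3)

  ppg1 <- numeric(n_samp)
  shape <- beat / max(params$vp, .Machine$double.eps)  # unit-amplitude beat
  abp <- rep(params$dbp, n_samp)
  pp <- params$sbp - params$dbp
  if (pp <= 0) bp_abort("sbp must exceed dbp")
  for (f in feet) {
    span <- f:(f + period - 1L)
    ppg1[span] <- beat
    abp[span] <- params$dbp + pp * shape
  }

  ppg <- list(ppg1)
  if (isTRUE(config$dual_ppg)) {
    d <- round(fs * config$ppg_transit_delay)
    ppg2 <- numeric(n_samp)
    src <- seq_len(n_samp - d)
    ppg2[src + d] <- ppg1[src]
    ppg <- list(ppg1, ppg2)
  }

  sd_sig <- config$noise_sd_signal
  if (sd_sig > 0) {
    ecg <- ecg + stats::rnorm(n_samp, 0, sd_sig)
    ppg <- lapply(ppg, function(ch) ch + stats::rnorm(n_samp, 0, sd_sig * params$vp))
    abp <- abp + stats::rnorm(n_samp, 0, sd_sig * pp)
  }

  meta_fields <- c("subject_id", "cohort", "age_y", "sex", "waist_cm",
                   "weight_kg", "temp_c")
  meta <- params[intersect(meta_fields, names(params))]
  rec <- waveform_record(ecg, ppg, fs, abp = abp, meta = meta)
  attr(rec, "truth") <- list(
    hr = params$hr, tc = tc, ts = ts, td = td, vp = params$vp,
    pat = params$pat, sbp = params$sbp, dbp = params$dbp,
    map = (2 * params$dbp + params$sbp) / 3,
    r_peaks = r_peaks, feet = feet, peaks = feet + i_peak
  )
  rec
}

#' Synthesize a cohort of waveform records
#'
#' Draws a population and per-record parameters exactly as
#' [generate_feature_table()] does, then renders each record's waveforms with
#' [synthesize_record()]. Deterministic under `config$seed`.
#'
#' @param config A [synth_config()] with `seed` set.
#' @return List with `records` (list of `waveform_record`) and `truth`
#'   (tibble, one row per record).
#' @export
synthesize_cohort <- function(config) {
  tab <- generate_feature_table(config)
  truth <- tab$truth
  feats <- tab$features
  records <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    params <- list(
      hr = truth$hr[i], ts_frac = truth$ts[i] / truth$tc[i], vp = truth$vp[i],
      pat = truth$pat[i], sbp = truth$sbp[i], dbp = truth$dbp[i],
      subject_id = feats$subject_id[i], cohort = feats$cohort[i],
      age_y = feats$age_y[i], sex = feats$sex[i],
      waist_cm = feats$waist_cm[i], weight_kg = feats$weight_kg[i],
      temp_c = feats$temp_c[i]
    )
    records[[i]] <- synthesize_record(params, config)
  }
  list(records = records, truth = truth)
}
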