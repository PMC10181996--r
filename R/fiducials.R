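#' Detect ECG R peaks
#'
#' Adaptive-threshold peak picking: candidate local maxima above a fraction
#' of the robust signal maximum (0.995 quantile), then a refractory rule that
#' keeps the tallest candidate within any refractory window. Indices are
#' 1-based sample positions, sorted and unique.
#'
#' @param ecg Numeric ECG vector (any units); at least 2 s of signal.
#' @param fs Sampling rate (Hz).
#' @param threshold_frac Detection threshold as a fraction of the robust
#'   maximum (default 0.5).
#' @param refractory Minimum peak separation in seconds (default 0.25).
#' @return Integer vector of R-peak sample indices.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.5, refractory = 0.25) {
  check_number(fs, "fs", positive = TRUE)
  n <- length(ecg)
  if (n < 2 * fs) bp_abort("detect_r_peaks needs at least 2 s of signal")
  if (!all(is.finite(ecg))) bp_abort("ecg contains non-finite samples")
  if (stats::sd(ecg) == 0) bp_abort("flat ECG signal: no peaks detectable")
  # robust max: median of per-second block maxima, so neither a single
  # artifact spike nor sparse beats distort the detection threshold
  blocks <- split(ecg, ceiling(seq_along(ecg) / fs))
  robust_max <- stats::median(vapply(blocks, max, numeric(1)))
  thr <- threshold_frac * robust_max
  if (robust_max <= 0 || thr <= stats::median(ecg)) {
    bp_abort("ECG has no prominent positive peaks above the adaptive threshold")
  }
  core <- 2:(n - 1L)
  cand <- core[ecg[core] >= ecg[core - 1L] & ecg[core] > ecg[core + 1L] &
                 ecg[core] > thr]
  if (length(cand) == 0L) bp_abort("no R-peak candidates above threshold")
  # refractory: accept candidates tallest-first, reject those too close
  ord <- cand[order(ecg[cand], decreasing = TRUE)]
  min_gap <- round(refractory * fs)
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(unique(keep))
}

#' Detect PPG feet and peaks per cardiac cycle
#'
#' For each R peak, locates the following PPG pulse peak and the preceding
#' pulse foot. The signal is smoothed with a short moving average
#' (width ~40 ms). The peak is the in-window maximum of the smoothed signal,
#' refined to sub-sample position and amplitude by a local quadratic fit with
#' a correction for the moving-average bias. The foot is located by the
#' intersecting-tangent construction: the tangent at the steepest upstroke
#' point is intersected with the level of the preceding diastolic minimum —
#' which reduces to that minimum's position for a clean corner foot, but is
#' far more stable under noise than a raw argmin.
#'
#' Cycles whose search windows fall outside the record are dropped; the
#' number dropped is attached as attribute `"dropped"` and reported with a
#' warning when positive.
#'
#' @param ppg Numeric PPG vector.
#' @param fs Sampling rate (Hz).
#' @param r_peaks Integer vector of R-peak indices (non-empty).
#' @param refine Refine fiducials against a beat-averaged ensemble template
#'   when at least five cycles are available (default `TRUE`).
#' @return A list of class `ppg_fiducials`: `feet`, `peaks` (possibly
#'   fractional 1-based positions), `foot_levels`, `peak_values` (smoothed,
#'   bias-corrected amplitudes) and `r_peaks` (the R peaks each cycle was
#'   anchored to).
#' @export
detect_ppg_fiducials <- function(ppg, fs, r_peaks, refine = TRUE) {
  check_number(fs, "fs", positive = TRUE)
  if (length(r_peaks) == 0L) bp_abort("r_peaks must be non-empty")
  n <- length(ppg)
  if (!all(is.finite(ppg))) bp_abort("ppg contains non-finite samples")
  if (stats::sd(ppg) == 0) {
    bp_warn("constant PPG signal: no fiducials resolvable")
    out <- list(feet = numeric(0), peaks = numeric(0), foot_levels = numeric(0),
                peak_values = numeric(0), r_peaks = integer(0))
    attr(out, "dropped") <- length(r_peaks)
    return(structure(out, class = "ppg_fiducials"))
  }

  sm <- pulse_smoothers(ppg, fs)
  rr <- if (length(r_peaks) > 1L) stats::median(diff(r_peaks)) else round(0.8 * fs)

  feet <- peaks <- foot_levels <- peak_values <- numeric(0)
  kept_r <- integer(0)
  dropped <- 0L
  for (r in r_peaks) {
    lo <- r + 1L
    hi <- min(n, r + round(0.9 * rr))
    m <- if (hi - lo >= 4L) measure_pulse(sm, lo, hi, rr) else NULL
    if (is.null(m)) { dropped <- dropped + 1L; next }
    feet <- c(feet, m$foot); peaks <- c(peaks, m$peak)
    foot_levels <- c(foot_levels, m$level); peak_values <- c(peak_values, m$value)
    kept_r <- c(kept_r, r)
  }
  if (refine && length(feet) >= 5L) {
    ref <- refine_by_ensemble(ppg, fs, feet, peaks, foot_levels, peak_values, rr)
    if (!is.null(ref)) {
      feet <- ref$feet; peaks <- ref$peaks
      foot_levels <- ref$foot_levels; peak_values <- ref$peak_values
    }
  }
  if (dropped > 0L) {
    bp_warn(dropped, " cardiac cycle(s) dropped: fiducials unresolvable")
  }
  out <- list(feet = feet, peaks = peaks, foot_levels = foot_levels,
              peak_values = peak_values, r_peaks = kept_r)
  attr(out, "dropped") <- dropped
  structure(out, class = "ppg_fiducials")
}

# light and heavy moving-average copies plus window bookkeeping
pulse_smoothers <- function(x, fs, w = NULL) {
  w <- w %||% max(3L, round(0.04 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  wa <- w + 2L
  list(x = x, n = length(x), fs = fs,
       w = w, h = (w - 1L) %/% 2L,
       wa = wa, ha = (wa - 1L) %/% 2L,
       s = moving_average(x, w), sa = moving_average(x, wa))
}

# One pulse between `lo` and `hi`: peak apex (cubic + fixed-centre quadratic
# refinement with moving-average bias correction), steepest-rise tangent foot,
# and the diastolic baseline level. Returns NULL when unresolvable.
measure_pulse <- function(sm, lo, hi, rr) {
  s <- sm$s; sa <- sm$sa; n <- sm$n
  h <- sm$h; ha <- sm$ha; w <- sm$w; wa <- sm$wa
  seg <- lo:hi
  p_int <- seg[which.max(sa[seg])]
  u_lo <- max(1L, p_int - round(0.6 * rr))
  if (p_int - u_lo < 3L) return(NULL)
  ds <- diff(s[u_lo:p_int])
  u <- u_lo + which.max(ds) - 1L
  # cubic fit sized by the rise length: the cubic term absorbs rise/decay
  # curvature asymmetry that would bias a symmetric parabola on flat summits
  wfit <- min(16L, max(ha + 2L, round(0.35 * (p_int - u))))
  fit_lo <- max(1L, p_int - wfit)
  fit_hi <- min(n, p_int + wfit)
  dx <- (fit_lo:fit_hi) - p_int
  cc <- tryCatch(stats::lm.fit(cbind(1, dx, dx^2, dx^3), sa[fit_lo:fit_hi])$coefficients,
                 error = function(e) NULL)
  p_pos <- p_int
  if (!is.null(cc) && all(is.finite(cc))) {
    disc <- (2 * cc[3])^2 - 12 * cc[4] * cc[2]
    vx <- NA_real_
    if (abs(cc[4]) > 1e-12 && disc >= 0) {
      roots <- (-2 * cc[3] + c(-1, 1) * sqrt(disc)) / (6 * cc[4])
      roots <- roots[2 * cc[3] + 6 * cc[4] * roots < 0]  # local maxima only
      if (length(roots) > 0) vx <- roots[which.min(abs(roots))]
    }
    if (!is.finite(vx) && cc[3] < 0) vx <- -cc[2] / (2 * cc[3])
    if (is.finite(vx)) p_pos <- p_int + max(-wfit + 1, min(wfit - 1, vx))
  }
  # second pass at the fixed rough centre (no argmax selection, so noise
  # cannot drag the apex): fit the moving-average-smoothed image of a
  # two-limb parabola (shared value and tangent at the centre, different
  # curvatures per limb). Because the basis is pre-smoothed, the smoother
  # contributes no apex bias; the apex comes from the unsmoothed model.
  # Second pass at a fixed centre (no argmax selection, so noise cannot
  # drag the apex): two parabolic limbs with a shared tangent, observed
  # through the moving average (pre-smoothed basis, so the smoother adds no
  # apex bias). The model pins the curvature junction at the window centre,
  # so the fit is recentred on its own apex until the two agree; the window
  # widens with the rise length so flat summits gain averaging.
  wfit2 <- min(14L, max(ha + 3L, round(0.3 * (p_int - u))))
  kk <- -ha:ha
  c0 <- round(p_pos)
  for (iter in 1:3) {
    r_lo <- max(1L, c0 - wfit2)
    r_hi <- min(n, c0 + wfit2)
    dx2 <- (r_lo:r_hi) - c0
    B3 <- vapply(dx2, function(x) mean(pmin(x + kk, 0)^2), numeric(1))
    B4 <- vapply(dx2, function(x) mean(pmax(x + kk, 0)^2), numeric(1))
    c2 <- tryCatch(stats::lm.fit(cbind(1, dx2, B3, B4), sa[r_lo:r_hi])$coefficients,
                   error = function(e) NULL)
    if (!is.null(c2) && all(is.finite(c2)) && c2[3] < 0 && c2[4] < 0) {
      apex <- if (c2[2] > 0) -c2[2] / (2 * c2[4]) else -c2[2] / (2 * c2[3])
      p_pos <- c0 + max(-3, min(3, apex))
    } else {
      cq <- tryCatch(stats::lm.fit(cbind(1, dx2, dx2^2), sa[r_lo:r_hi])$coefficients,
                     error = function(e) NULL)
      if (!is.null(cq) && is.finite(cq[3]) && cq[3] < 0) {
        p_pos <- c0 + max(-3, min(3, -cq[2] / (2 * cq[3])))
      }
      break
    }
    if (round(p_pos) == c0) break
    c0 <- round(p_pos)
  }
  # peak amplitude from the heavy copy, vertex value corrected for the blur
  fa_lo <- max(1L, p_int - ha - 3L)
  fa_hi <- min(n, p_int + ha + 3L)
  dxa <- (fa_lo:fa_hi) - p_int
  ca <- tryCatch(stats::lm.fit(cbind(1, dxa, dxa^2), sa[fa_lo:fa_hi])$coefficients,
                 error = function(e) NULL)
  if (is.null(ca) || !is.finite(ca[3]) || ca[3] >= 0) {
    p_val <- sa[p_int]
  } else {
    vxa <- max(-ha, min(ha, -ca[2] / (2 * ca[3])))
    p_val <- ca[1] + ca[2] * vxa + ca[3] * vxa^2 - ca[3] * (wa^2 - 1) / 12
  }
  slope <- mean(ds[pmax(1L, which.max(ds) - 1L):pmin(length(ds), which.max(ds) + 1L)])
  if (slope <= 0) return(NULL)
  # diastolic baseline, two steps: a provisional smoothed minimum anchors the
  # tangent foot; the final level is a short tail mean strictly before the
  # foot, where neither the upstroke nor argmin selection can leak in
  base_seg <- u_lo:u
  i_min <- base_seg[which.min(sa[base_seg])]
  lvl0 <- mean(sa[max(u_lo, i_min - 1L):min(u, i_min + 1L)])
  f_pos <- u - (s[u] - lvl0) / slope
  f_pos <- max(u_lo, min(u, f_pos))
  if (f_pos >= p_pos) return(NULL)
  fi <- floor(f_pos)
  f_level <- if (fi - 3L >= u_lo) mean(s[(fi - 3L):(fi - 1L)]) else lvl0
  list(foot = f_pos, peak = p_pos, level = f_level, value = p_val)
}

# Ensemble (beat-average) refinement: align the rough cycles, average them
# into a low-noise template, measure the fiducials once on the template, and
# carry per-cycle positions/amplitudes back through cross-correlation lags
# and least-squares gains. Falls back to the rough estimates (returns NULL)
# when the template cannot be built or measured.
refine_by_ensemble <- function(ppg, fs, feet, peaks, foot_levels, peak_values, rr) {
  n <- length(ppg)
  P <- round(stats::median(diff(feet)))
  if (!is.finite(P) || P < 8L) return(NULL)
  pad <- max(4L, round(0.2 * P))
  len <- P + 2L * pad
  starts <- round(feet) - pad
  valid <- which(starts >= 1L & starts + len - 1L <= n)
  if (length(valid) < 3L) return(NULL)
  cyc <- t(vapply(starts[valid], function(a) ppg[a:(a + len - 1L)], numeric(len)))
  ens <- colMeans(cyc)

  # the ensemble is nearly noise-free (averaged over all cycles), so it is
  # measured with the narrowest smoother to keep the fiducial bias minimal
  esm <- pulse_smoothers(ens, fs, w = 3L)
  me <- measure_pulse(esm, pad + 1L, min(len, pad + round(0.9 * P)), rr)
  if (is.null(me)) return(NULL)

  core <- (pad %/% 2 + 4L):(len - pad %/% 2 - 4L)
  e_core <- ens[core] - mean(ens[core])
  lags <- -3L:3L
  for (j in seq_along(valid)) {
    k <- valid[j]
    xk <- cyc[j, ]
    cors <- vapply(lags, function(d) {
      sum((xk[core] - mean(xk[core])) * (ens[core - d] - mean(ens[core - d])))
    }, numeric(1))
    bi <- which.max(cors)
    lag <- lags[bi]
    if (bi > 1L && bi < length(lags)) {
      den <- cors[bi - 1L] - 2 * cors[bi] + cors[bi + 1L]
      if (is.finite(den) && den < 0) {
        lag <- lag + max(-0.5, min(0.5, 0.5 * (cors[bi - 1L] - cors[bi + 1L]) / den))
      }
    }
    # amplitude gain from the informative (high-swing) samples only
    wgt <- which(abs(e_core) > 0.5 * stats::sd(e_core))
    if (length(wgt) < 8L) wgt <- seq_along(e_core)
    fit <- stats::lm.fit(cbind(1, e_core[wgt]), xk[core][wgt])
    gain <- fit$coefficients[2]
    offset <- fit$coefficients[1]
    if (!is.finite(gain) || gain <= 0) next
    base <- starts[k] - 1L
    feet[k] <- base + me$foot + lag
    peaks[k] <- base + me$peak + lag
    foot_levels[k] <- offset + gain * me$level
    peak_values[k] <- offset + gain * me$value
  }
  list(feet = feet, peaks = peaks, foot_levels = foot_levels,
       peak_values = peak_values)
}

#' Select a clean run of consecutive cardiac cycles
#'
#' Automated surrogate for visual selection of an artefact-free segment: the
#' first run of `k` consecutive complete cycles whose cycle lengths have a
#' coefficient of variation below `cv_len` and whose pulse amplitudes have a
#' CV below `cv_amp`. Deterministic.
#'
#' @param fiducials A `ppg_fiducials` object (cycle `j` spans foot `j` to
#'   foot `j + 1`, so `length(feet) - 1` complete cycles are available).
#' @param k Number of cycles in the window (default 5).
#' @param cv_len Cycle-length CV threshold (default 0.10).
#' @param cv_amp Amplitude CV threshold (default 0.20).
#' @return Integer vector of `k` consecutive cycle indices.
#' @export
select_clean_window <- function(fiducials, k = 5, cv_len = 0.10, cv_amp = 0.20) {
  stopifnot(inherits(fiducials, "ppg_fiducials"))
  n_cyc <- length(fiducials$feet) - 1L
  if (n_cyc < k) {
    bp_abort("need at least ", k, " complete cycles, found ", max(n_cyc, 0))
  }
  lens <- diff(fiducials$feet)
  amps <- (fiducials$peak_values - fiducials$foot_levels)[seq_len(n_cyc)]
  cv <- function(x) stats::sd(x) / mean(x)
  diags <- character(0)
  for (i in seq_len(n_cyc - k + 1L)) {
    run <- i:(i + k - 1L)
    cl <- cv(lens[run]); ca <- cv(amps[run])
    if (is.finite(cl) && is.finite(ca) && cl < cv_len && ca < cv_amp) return(run)
    diags <- c(diags, sprintf("run %d: length CV %.3f, amplitude CV %.3f", i, cl, ca))
  }
  bp_abort("no run of ", k, " clean cycles found:\n  ",
           paste(diags, collapse = "\n  "))
}
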