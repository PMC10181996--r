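test_that("R-peak detection finds spikes and rejects flat signals", {
  ecg <- numeric(1200)
  ecg[c(100, 500, 900)] <- 1
  ecg[c(99, 101, 499, 501, 899, 901)] <- 0.3
  expect_equal(detect_r_peaks(ecg, fs = 400), c(100, 500, 900))

  # oracle = generator truth, small additive noise
  set.seed(42)
  noisy <- ecg + rnorm(1200, 0, 0.01)
  expect_equal(detect_r_peaks(noisy, fs = 400), c(100, 500, 900))

  expect_error(detect_r_peaks(numeric(1200), fs = 400), "flat")
  expect_error(detect_r_peaks(numeric(100), fs = 400), "2 s")
  # refractory rule collapses twin spikes
  ecg2 <- numeric(1200)
  ecg2[c(100, 110, 500)] <- c(1, 0.9, 1)
  expect_equal(detect_r_peaks(ecg2, fs = 400), c(100, 500))
})

test_that("PPG fiducials sit within a sample of generator truth", {
  rec <- clean_record(seed = 3, noise = 0)
  tr <- attr(rec, "truth")
  fid <- detect_ppg_fiducials(rec$ppg[[1]], rec$fs, tr$r_peaks)
  common <- seq_len(min(length(fid$peaks), length(tr$peaks)))
  m <- match(fid$r_peaks, tr$r_peaks)
  expect_true(all(abs(fid$peaks - tr$peaks[m]) <= 1.5))
  expect_true(all(abs(fid$feet - tr$feet[m]) <= 1.5))

  # small noise: still within ~1 sample
  rec <- clean_record(seed = 3, noise = 0.01)
  fid2 <- detect_ppg_fiducials(rec$ppg[[1]], rec$fs, tr$r_peaks)
  m2 <- match(fid2$r_peaks, tr$r_peaks)
  expect_true(mean(abs(fid2$peaks - tr$peaks[m2])) <= 1.5)

  expect_warning(fid3 <- detect_ppg_fiducials(rep(1, 1000), 125, c(100, 300)),
                 "constant")
  expect_length(fid3$feet, 0)
})

test_that("clean-window selection is deterministic and scans for quality", {
  rec <- clean_record(seed = 5, noise = 0)
  tr <- attr(rec, "truth")
  fid <- detect_ppg_fiducials(rec$ppg[[1]], rec$fs, tr$r_peaks)
  expect_equal(select_clean_window(fid), 1:5)

  # corrupt the amplitude of cycle 3: first qualifying run starts after it
  fid_bad <- fid
  fid_bad$peak_values[3] <- fid_bad$peak_values[3] * 3
  win <- select_clean_window(fid_bad)
  expect_equal(win, 4:8)
  # brute-force scan oracle: every earlier run violates the amplitude CV
  amps <- (fid_bad$peak_values - fid_bad$foot_levels)
  for (i in 1:3) {
    expect_gte(sd(amps[i:(i + 4)]) / mean(amps[i:(i + 4)]), 0.20)
  }

  fid_short <- fid
  for (f in c("feet", "peaks", "foot_levels", "peak_values", "r_peaks")) {
    fid_short[[f]] <- fid_short[[f]][1:5]
  }
  expect_error(select_clean_window(fid_short), "at least 5")
})

test_that("PAT and PTT are window means with sign guards", {
  r <- c(400, 800, 1200, 1600, 2000)
  expect_equal(compute_pat(r, r + 100, 1:5, fs = 400), 0.25)
  expect_equal(compute_pat(r, r + c(99, 100, 101, 100, 100), 1:5, fs = 400), 0.25)
  bad <- r + 100; bad[3] <- r[3] - 5
  expect_error(compute_pat(r, bad, 1:5, fs = 400), "non-positive")

  prox <- c(100, 500, 900, 1300, 1700)
  expect_equal(compute_ptt(prox, prox + 2, 1:5, fs = 400), 0.005)
  expect_equal(compute_ptt(prox, prox + c(1, 2, 3, 2, 2), 1:5, fs = 400), 0.005)
  expect_error(compute_ptt(prox, prox, 1:5, fs = 400), "transit")
})

test_that("morphology features follow their defining formulas", {
  # triangular pulse oracle: Tc = 1 s, peak at 0.3 s, Vp = 2
  fid <- structure(list(feet = c(1, 101, 201, 301, 401, 501),
                        peaks = c(31, 131, 231, 331, 431),
                        foot_levels = rep(0, 5),
                        peak_values = rep(2, 5),
                        r_peaks = c(11, 111, 211, 311, 411)),
                   class = "ppg_fiducials")
  m <- compute_morphology(fid, 1:5, fs = 100)
  expect_equal(m$ts, 0.3)
  expect_equal(m$td, 0.7)
  expect_equal(m$tc, 1.0)
  expect_equal(m$vp, 2)
  expect_equal(m$vs, 0.6)
  expect_equal(m$dvs, 6.667, tolerance = 1e-3)
  expect_equal(m$vd, 1.4)
  expect_equal(m$dvd, 2.857, tolerance = 1e-3)

  # symmetry: Ts = Td implies Vs = Vd = Vp/2
  fid$peaks <- fid$feet[1:5] + 50
  ms <- compute_morphology(fid, 1:5, fs = 100)
  expect_equal(ms$vs, ms$vd)
  expect_equal(ms$vs, ms$vp / 2)

  fid$peaks <- fid$feet[1:5] - 1
  expect_error(compute_morphology(fid, 1:5, fs = 100), "non-positive")
})

test_that("pulse rate and reference pressures average over the window", {
  expect_equal(compute_pulse_rate(1.0), 60)
  expect_equal(compute_pulse_rate(0.5), 120)
  expect_equal(compute_pulse_rate(c(1.0, 1.0, 1.0, 0.9, 1.1)), 60)
  expect_error(compute_pulse_rate(c(1, -1)), "positive")

  fid <- structure(list(feet = seq(1, 601, by = 100),
                        peaks = seq(31, 531, by = 100),
                        foot_levels = rep(0, 6), peak_values = rep(1, 6),
                        r_peaks = seq(11, 511, by = 100)),
                   class = "ppg_fiducials")
  abp <- rep(80, 700)
  peak_idx <- fid$peaks[1:5]
  maxima <- c(118, 119, 120, 121, 122)
  abp[peak_idx] <- maxima
  ref <- average_reference_bp(abp, fid, 1:5, fs = 100)
  expect_equal(ref$sbp, 120)
  expect_equal(ref$dbp, 80)
  expect_equal(ref$map, (2 * 80 + 120) / 3)
  expect_error(average_reference_bp(NULL, fid, 1:5, 100), "arterial")
})

test_that("record extraction reproduces generator truth end to end", {
  fs <- 125
  rec <- clean_record(seed = 8, noise = 0)
  tr <- attr(rec, "truth")
  f <- extract_record_features(rec)
  expect_lte(abs(f$pat_s - tr$pat) * fs, 1)
  expect_lte(abs(f$ts_s - tr$ts) * fs, 2)
  expect_lte(abs(f$td_s - tr$td) * fs, 2)
  expect_lte(abs(f$tc_s - tr$tc) * fs, 2)
  expect_lte(abs(f$vp_au - tr$vp) / tr$vp, 0.01)
  # zero noise: the reference pressures are recovered exactly
  expect_equal(f$sbp_mmhg, tr$sbp, tolerance = 1e-9)
  expect_equal(f$dbp_mmhg, tr$dbp, tolerance = 1e-9)
  expect_equal(f$map_mmhg, tr$map, tolerance = 1e-9)

  # identities hold on the extracted row
  expect_equal(f$tc_s, f$ts_s + f$td_s, tolerance = 1e-12)
  expect_equal(f$vs_au + f$vd_au, f$vp_au, tolerance = 1e-12)
  expect_equal(f$dvs_au_per_s, f$vp_au / f$ts_s, tolerance = 1e-12)

  # determinism: identical record, identical features
  expect_identical(f, extract_record_features(rec))

  # without ABP: features present, labels absent
  rec_no_abp <- rec
  rec_no_abp$abp <- NULL
  f2 <- extract_record_features(rec_no_abp)
  expect_true(is.na(f2$sbp_mmhg) && is.na(f2$dbp_mmhg) && is.na(f2$map_mmhg))
  expect_false(is.na(f2$pat_s))
  # single PPG channel: ptt absent, pat present
  expect_true(is.na(f$ptt_s))
  expect_false(is.na(f$pat_s))
})

test_that("dual-PPG records yield a positive transit time", {
  cfg <- synth_config(n_subjects = 1, records_per_subject = 1, seed = 4,
                      dual_ppg = TRUE, ppg_transit_delay = 0.01, fs = 400,
                      noise_sd_signal = 0)
  rec <- synthesize_record(list(hr = 70, ts_frac = 0.3, vp = 1, pat = 0.25,
                                sbp = 120, dbp = 80), cfg)
  f <- extract_record_features(rec)
  expect_equal(f$ptt_s, 0.01, tolerance = 1.5 / 400)
})
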