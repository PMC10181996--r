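test_that("population sampling is deterministic and matches its distributions", {
  cfg <- synth_config(n_subjects = 0, seed = 1)
  expect_equal(nrow(sample_population(cfg)), 0)

  cfg <- synth_config(n_subjects = 31, seed = 11)
  pop1 <- sample_population(cfg)
  pop2 <- sample_population(cfg)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 31)

  # binomial oracle: male fraction within 3 SE of the configured probability
  cfg <- synth_config(n_subjects = 10000, seed = 5,
                      demographics = list(p_male = 0.6, p_old = 0.9,
                                          age_young = c(20, 40), age_old = c(41, 90),
                                          waist = c(70, 115), weight = c(50, 110),
                                          temp = c(36, 37.5)))
  pop <- sample_population(cfg)
  se <- sqrt(0.6 * 0.4 / 10000)
  expect_lt(abs(mean(pop$sex) - 0.6), 3 * se)
  expect_error(sample_population(synth_config(n_subjects = 3)), "seed")
})

test_that("feature tables honour the generative label model", {
  # zero label noise: the MAP identity holds exactly in every row
  tab <- generate_feature_table(small_config(seed = 2, n = 40, noise_sd_bp = 0))
  f <- tab$features
  expect_equal(f$map_mmhg, (2 * f$dbp_mmhg + f$sbp_mmhg) / 3, tolerance = 1e-12)
  expect_true(all(f$dbp_mmhg < f$map_mmhg & f$map_mmhg < f$sbp_mmhg))
  expect_equal(tab$truth$sbp0 - tab$truth$dbp0, tab$truth$pp, tolerance = 1e-10)

  # degenerate ranges: all rows identical
  tab <- generate_feature_table(synth_config(
    n_subjects = 5, records_per_subject = 1, seed = 3, noise_sd_bp = 0,
    heart_rate_range = c(70, 70), ptt_range = c(0.2, 0.2),
    pir_range = c(2, 2), alpha_range = c(3, 3),
    ts_frac_range = c(0.3, 0.3), vp_range = c(1, 1)))
  num <- dplyr::select(tab$features, -subject_id, -cohort, -age_y, -sex,
                       -waist_cm, -weight_kg, -temp_c)
  expect_true(all(vapply(num, function(col) length(unique(col)) == 1L, logical(1))))

  # the model implies SBP decreases in PTT, hence in PAT
  tab <- generate_feature_table(small_config(seed = 4, n = 500))
  expect_lt(cor(tab$features$pat_s, tab$features$sbp_mmhg), 0)

  # determinism under a fixed seed
  t1 <- generate_feature_table(small_config(seed = 9, n = 20))
  t2 <- generate_feature_table(small_config(seed = 9, n = 20))
  expect_identical(t1$features, t2$features)
})

test_that("labels land in a plausible adult envelope and noise perturbs them", {
  tab <- generate_feature_table(synth_config_compromised(seed = 6))
  f <- tab$features
  expect_equal(nrow(f), 126)
  expect_equal(length(unique(f$subject_id)), 31)
  expect_true(all(f$sbp_mmhg > 75 & f$sbp_mmhg < 190))
  expect_true(all(f$dbp_mmhg > 45 & f$dbp_mmhg < 115))
  expect_equal(sd(f$dbp_mmhg - tab$truth$dbp0), 2, tolerance = 0.5)
})

test_that("beat template has the documented geometry", {
  v <- ppg_beat_template(ts = 0.3, td = 0.7, vp = 2, fs = 100)
  expect_length(v, 100)
  expect_equal(max(v), 2)
  expect_equal(which.max(v), 31)  # round(fs*ts) samples after the onset
  expect_equal(v[1], 0)
  # monotone rise then monotone decay
  expect_true(all(diff(v[1:31]) > 0))
  expect_true(all(diff(v[31:100]) < 0))
  expect_true(all(ppg_beat_template(0.3, 0.7, 0, 100) == 0))
  expect_error(ppg_beat_template(-0.1, 0.7, 1, 100), "ts")
  expect_error(ppg_beat_template(0.01, 0.01, 1, 100), "4 samples")

  # roundtrip oracle: foot/peak positions recover Ts within one sample
  # (interior cycles; the very first beat starts at the signal edge and has
  # no diastolic tail to anchor its foot)
  fs <- 100
  train <- rep(ppg_beat_template(0.3, 0.7, 2, fs), 10)
  r_peaks <- round(seq(5, length.out = 9, by = fs))
  fid <- detect_ppg_fiducials(train, fs, r_peaks + 20)
  ts_hat <- (fid$peaks - fid$feet) / fs
  expect_true(all(abs(ts_hat[-1] - 0.3) <= 1 / fs))
})

test_that("synthesized records align PPG peaks at PAT after each R spike", {
  rec <- clean_record(pat = 0.25, fs = 400, noise = 0)
  tr <- attr(rec, "truth")
  expect_equal(tr$peaks - tr$r_peaks, rep(100, length(tr$peaks)))
  expect_s3_class(rec, "waveform_record")
  # byte-identical regeneration under the same seed
  rec2 <- clean_record(pat = 0.25, fs = 400, noise = 0)
  expect_identical(rec$ppg, rec2$ppg)
  # ABP oscillates exactly between the configured pressures
  expect_equal(max(rec$abp), tr$sbp)
  expect_equal(min(rec$abp), tr$dbp)
  # too short for the required beats
  cfg <- synth_config(n_subjects = 1, records_per_subject = 1, duration = 3, seed = 1)
  expect_error(synthesize_record(list(hr = 60, ts_frac = 0.3, vp = 1, pat = 0.25,
                                      sbp = 120, dbp = 80), cfg),
               "7 beats")
})

test_that("dual-PPG records carry a delayed distal channel", {
  cfg <- synth_config(n_subjects = 1, records_per_subject = 1, seed = 2,
                      dual_ppg = TRUE, ppg_transit_delay = 0.005, fs = 400,
                      noise_sd_signal = 0)
  rec <- synthesize_record(list(hr = 70, ts_frac = 0.3, vp = 1, pat = 0.25,
                                sbp = 120, dbp = 80), cfg)
  expect_length(rec$ppg, 2)
  d <- round(400 * 0.005)
  n <- length(rec$ppg[[1]])
  expect_equal(rec$ppg[[2]][(d + 1):n], rec$ppg[[1]][1:(n - d)])
})
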