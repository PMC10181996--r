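# shared fixtures: small, seeded synthetic configurations

small_config <- function(seed = 1, n = 6, noise_sd_signal = 0, ...) {
  synth_config(n_subjects = n, records_per_subject = 1,
               noise_sd_signal = noise_sd_signal, seed = seed, ...)
}

# one clean record plus its ground truth
clean_record <- function(seed = 1, hr = 72, ts_frac = 0.3, vp = 1.2,
                         pat = 0.28, sbp = 120, dbp = 80, noise = 0, ...) {
  cfg <- synth_config(n_subjects = 1, records_per_subject = 1,
                      noise_sd_signal = noise, seed = seed, ...)
  set.seed(seed)
  synthesize_record(list(hr = hr, ts_frac = ts_frac, vp = vp, pat = pat,
                         sbp = sbp, dbp = dbp), cfg)
}

# tiny feature table with a strong linear feature-label link, for model tests
linear_table <- function(n = 60, noise = 0, seed = 1) {
  set.seed(seed)
  x1 <- runif(n, -1, 1)
  x2 <- runif(n, -1, 1)
  y <- 100 + 12 * x1 - 5 * x2 + rnorm(n, 0, noise)
  tibble::tibble(pat_s = x1, pulse_rate_bpm = x2, age_y = 50, sex = 1,
                 sbp_mmhg = y, dbp_mmhg = y - 40, map_mmhg = (2 * (y - 40) + y) / 3)
}

cheap_specs <- function(family, target) {
  switch(family,
    lasso_en = model_spec("lasso_en", alpha = 0.6),
    boosted_trees = model_spec("boosted_trees", splits = 20, cycles = 50),
    svr = model_spec("svr", box = 10, kernel_scale = 1),
    ann = model_spec("ann", epochs = 60),
    lstm = model_spec("lstm", epochs = 40, hidden = 20)
  )
}
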