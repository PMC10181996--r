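#' Leave-one-out estimation errors
#'
#' For each row, trains on the remaining rows and predicts the held-out row;
#' the returned vector holds `estimate - truth` per row. The training sizes
#' are attached as attribute `"train_n"`.
#'
#' @param spec A [model_spec()].
#' @param dataset Feature table (tibble or `synth_feature_table`).
#' @param feature_set Feature-set id.
#' @param target `"sbp"`, `"dbp"` or `"map"`.
#' @return Numeric vector of signed errors (mmHg), length `nrow(dataset)`.
#' @export
loo_errors <- function(spec, dataset, feature_set, target) {
  sel <- select_feature_set(dataset, feature_set, target)
  n <- nrow(sel$x)
  if (n < 3L) bp_abort("leave-one-out needs at least 3 rows")
  errs <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_model(spec, sel$x[-i, , drop = FALSE], sel$y[-i]),
                    error = function(e) {
                      bp_abort("fold ", i, ": ", conditionMessage(e))
                    })
    errs[i] <- predict(fit, sel$x[i, , drop = FALSE]) - sel$y[i]
  }
  attr(errs, "train_n") <- rep(n - 1L, n)
  errs
}

#' Holdout-split estimation errors
#'
#' Deterministic train/test split under `seed`; errors are computed on the
#' held-out rows only. The training-set fraction is restricted to the two
#' benchmark ratios unless `allow_any_ratio` is set.
#'
#' @param spec A [model_spec()].
#' @param dataset Feature table.
#' @param feature_set Feature-set id.
#' @param target `"sbp"`, `"dbp"` or `"map"`.
#' @param ratio Training fraction, 0.8 or 0.7.
#' @param seed Integer seed for the split.
#' @param allow_any_ratio Permit ratios outside `{0.8, 0.7}`.
#' @return Numeric vector of signed test errors (mmHg); test-row indices
#'   attached as attribute `"test_idx"`.
#' @export
holdout_errors <- function(spec, dataset, feature_set, target, ratio = 0.8,
                           seed = 1L, allow_any_ratio = FALSE) {
  if (!allow_any_ratio && !isTRUE(all.equal(ratio, 0.8)) &&
      !isTRUE(all.equal(ratio, 0.7))) {
    bp_abort("ratio must be 0.8 or 0.7 (set allow_any_ratio to override)")
  }
  sel <- select_feature_set(dataset, feature_set, target)
  n <- nrow(sel$x)
  n_train <- floor(ratio * n)
  if (n_train < 2L || n_train >= n) bp_abort("split leaves no usable train/test rows")
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)
  fit <- fit_model(spec, sel$x[train, , drop = FALSE], sel$y[train])
  errs <- predict(fit, sel$x[test, , drop = FALSE]) - sel$y[test]
  attr(errs, "test_idx") <- test
  errs
}

# dispatch helper shared with select_hyperparameters
protocol_errors <- function(spec, dataset, feature_set, target, protocol) {
  type <- protocol$type %||% "loo"
  if (type == "loo") {
    loo_errors(spec, dataset, feature_set, target)
  } else if (type == "split") {
    holdout_errors(spec, dataset, feature_set, target,
                   ratio = protocol$ratio %||% 0.8,
                   seed = protocol$seed %||% 1L,
                   allow_any_ratio = isTRUE(protocol$allow_any_ratio))
  } else {
    bp_abort("unknown protocol type '", type, "'")
  }
}

#' Summarize signed estimation errors
#'
#' Bias is the mean signed error, SD the sample standard deviation (n - 1
#' denominator) and the 95 % confidence interval uses the normal quantile:
#' `bias +/- 1.96 * sd / sqrt(n)`.
#'
#' @param errors Numeric vector of signed errors (mmHg), length >= 2.
#' @param target Optional target label stored in the summary.
#' @return One-row tibble: `target`, `n`, `bias`, `sd`, `mean_abs_error`,
#'   `ci_low`, `ci_high`.
#' @export
summarize_errors <- function(errors, target = NA_character_) {
  errors <- as.numeric(errors)
  n <- length(errors)
  if (n < 2L) bp_abort("need at least 2 errors to summarize")
  if (any(!is.finite(errors))) bp_abort("errors must be finite")
  bias <- mean(errors)
  sd <- stats::sd(errors)
  half <- 1.96 * sd / sqrt(n)
  tibble::tibble(target = target, n = n, bias = bias, sd = sd,
                 mean_abs_error = mean(abs(errors)),
                 ci_low = bias - half, ci_high = bias + half)
}

#' 95 % confidence interval from summary statistics
#'
#' Normal-quantile interval `mu +/- 1.96 * sd / sqrt(n)`, rounded to two
#' decimals (half away from zero) for report output.
#'
#' @param mu Mean signed error (mmHg).
#' @param sd Error standard deviation (mmHg, >= 0).
#' @param n Number of observations (>= 2).
#' @return Numeric `c(low, high)`.
#' @export
ci_from_summary <- function(mu, sd, n) {
  check_number(mu, "mu"); check_number(sd, "sd")
  if (sd < 0) bp_abort("sd must be >= 0")
  if (!is_number(n) || n < 2 || n != round(n)) bp_abort("n must be an integer >= 2")
  half <- 1.96 * sd / sqrt(n)
  round_half_away(c(mu - half, mu + half), 2)
}

#' Grade an error summary against IEC 80601-2-30 criterion 1
#'
#' The automated-sphygmomanometer accuracy criterion: mean error within
#' +/- 5 mmHg and error standard deviation at most 8 mmHg. Comparisons are
#' inclusive.
#'
#' @param bias Mean signed error (mmHg), or a one-row summary tibble from
#'   [summarize_errors()] (then `sd` is taken from it).
#' @param sd Error standard deviation (mmHg).
#' @return List: `bias_pass`, `sd_pass`, `overall`.
#' @export
iec_grade <- function(bias, sd = NULL) {
  if (is.data.frame(bias)) {
    sd <- bias$sd[1]
    bias <- bias$bias[1]
  }
  check_number(bias, "bias"); check_number(sd, "sd")
  bias_pass <- abs(bias) <= 5
  sd_pass <- sd <= 8
  list(bias_pass = bias_pass, sd_pass = sd_pass,
       overall = bias_pass && sd_pass)
}

#' Bland-Altman agreement analysis
#'
#' Pairwise means and differences with limits of agreement at the mean
#' difference +/- 2 standard deviations of the differences.
#'
#' @param estimates Numeric vector of estimated pressures (mmHg).
#' @param truths Numeric vector of reference pressures, same length (>= 2).
#' @return List: `points` (tibble with `mean`, `difference`), `mean_diff`,
#'   `sd_diff`, `lower`, `upper`.
#' @export
bland_altman <- function(estimates, truths) {
  if (length(estimates) != length(truths)) bp_abort("length mismatch")
  if (length(estimates) < 2L) bp_abort("need at least 2 pairs")
  d <- estimates - truths
  m <- (estimates + truths) / 2
  md <- mean(d); sdd <- stats::sd(d)
  list(points = tibble::tibble(mean = m, difference = d),
       mean_diff = md, sd_diff = sdd,
       lower = md - 2 * sdd, upper = md + 2 * sdd)
}

#' Run the full method-by-feature-set evaluation grid
#'
#' Evaluates every (family, feature set, target) cell — by default the five
#' regression families, the three ICU-style feature sets and the three
#' pressure targets, i.e. 45 cells — under one protocol, and summarizes and
#' grades each cell.
#'
#' @param dataset Feature table.
#' @param specs Either `NULL` (use [benchmark_selected_spec()] per cell), a
#'   function `(family, target) -> model_spec`, or a named list of specs
#'   keyed `"family.target"`.
#' @param protocol `list(type = "loo")` (default) or
#'   `list(type = "split", ratio = , seed = )`.
#' @param families Families to include.
#' @param feature_sets Feature-set ids to include.
#' @param targets Targets to include.
#' @return Object of class `bp_protocol_result`: list with `summaries`
#'   (tibble, one row per cell with bias/SD/CI and IEC flags) and `errors`
#'   (long tibble of per-fold signed errors for the statistical comparisons).
#' @export
full_protocol <- function(dataset, specs = NULL, protocol = list(type = "loo"),
                          families = bp_families,
                          feature_sets = c("combined", "pat", "morphology"),
                          targets = c("sbp", "dbp", "map")) {
  get_spec <- function(family, target) {
    if (is.null(specs)) return(benchmark_selected_spec(family, target))
    if (is.function(specs)) return(specs(family, target))
    key <- paste(family, target, sep = ".")
    if (!key %in% names(specs)) bp_abort("specs has no entry '", key, "'")
    specs[[key]]
  }
  summaries <- list()
  errors <- list()
  for (fam in families) for (fset in feature_sets) for (tgt in targets) {
    cell <- paste(fam, fset, tgt, sep = ".")
    errs <- tryCatch(
      protocol_errors(get_spec(fam, tgt), dataset, fset, tgt, protocol),
      error = function(e) {
        bp_warn("cell ", cell, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(errs)) next
    s <- summarize_errors(errs, target = tgt)
    g <- iec_grade(s$bias, s$sd)
    summaries[[cell]] <- tibble::tibble(
      method = fam, feature_set = fset, target = tgt,
      n = s$n, bias = s$bias, sd = s$sd, mean_abs_error = s$mean_abs_error,
      ci_low = s$ci_low, ci_high = s$ci_high,
      bias_pass = g$bias_pass, sd_pass = g$sd_pass, overall = g$overall
    )
    errors[[cell]] <- tibble::tibble(
      method = fam, feature_set = fset, target = tgt,
      fold = seq_along(errs),
      row = (attr(errs, "test_idx") %||% seq_along(errs)),
      error = as.numeric(errs)
    )
  }
  structure(list(summaries = dplyr::bind_rows(summaries),
                 errors = dplyr::bind_rows(errors),
                 protocol = protocol),
            class = "bp_protocol_result")
}

#' @export
print.bp_protocol_result <- function(x, ...) {
  cat("<bp_protocol_result> ", nrow(x$summaries), " cells, protocol ",
      x$protocol$type %||% "loo", "\n", sep = "")
  print(x$summaries, n = 10)
  invisible(x)
}
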