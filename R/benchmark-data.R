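#' Published benchmark error summaries
#'
#' Reference fixture: the leave-one-out error summaries (mean signed error,
#' error SD and printed 95 % confidence bounds, all in mmHg) reported by a
#' published cuffless blood-pressure benchmark for five regression methods.
#' The healthy cohort (n = 23 wrist-watch recordings) was evaluated on the
#' seven-feature PTT view; the hemodynamically compromised ICU cohort
#' (n = 126 records from 31 subjects) on the combined, PAT and morphology
#' feature sets. Used by the tests and the acceptance script to exercise
#' [ci_from_summary()] and [iec_grade()] against independently published
#' numbers; none of these values feed any model fit.
#'
#' @return Tibble with columns `cohort`, `feature_set`, `method`, `target`,
#'   `n`, `bias`, `sd`, `ci_low_printed`, `ci_high_printed`.
#' @export
benchmark_error_summaries <- function() {
  methods <- c("lasso_en", "boosted_trees", "svr", "ann", "lstm")
  block <- function(cohort, feature_set, target, n, bias, sd, lo, hi) {
    tibble::tibble(cohort = cohort, feature_set = feature_set,
                   method = methods, target = target, n = n,
                   bias = bias, sd = sd,
                   ci_low_printed = lo, ci_high_printed = hi)
  }
  dplyr::bind_rows(
    # healthy cohort, PTT/demographics view, n = 23
    block("healthy", "healthy7", "map", 23,
          c(-0.18, 0.27, -2.18, -0.21, -10.15),
          c(11.51, 9.51, 9.26, 10.15, 10.61),
          c(-4.88, -3.62, -5.97, -4.36, -14.49),
          c(4.53, 4.16, 1.60, 3.94, -5.82)),
    block("healthy", "healthy7", "sbp", 23,
          c(1.77, -0.65, 3.44, 1.27, 10.63),
          c(22.46, 15.28, 13.56, 19.62, 19.37),
          c(-7.41, -6.89, -2.10, -6.75, 2.71),
          c(10.95, 5.59, 8.98, 9.29, 18.55)),
    block("healthy", "healthy7", "dbp", 23,
          c(-0.62, -0.08, 1.56, -0.31, 9.92),
          c(7.64, 7.49, 8.62, 8.76, 13.51),
          c(-3.74, -3.14, -1.96, -3.89, 4.40),
          c(2.50, 2.98, 5.08, 3.27, 15.44)),
    # compromised cohort, combined feature set, n = 126
    block("compromised", "combined", "map", 126,
          c(0.03, 0.76, 0.75, 1.17, 2.25),
          c(11.89, 8.84, 10.56, 11.12, 13.39),
          c(-2.05, -0.78, -1.09, -0.77, -0.09),
          c(2.11, 2.30, 2.59, 3.11, 4.59)),
    block("compromised", "combined", "sbp", 126,
          c(-0.14, 1.38, 0.43, 1.65, 3.78),
          c(18.31, 15.12, 17.70, 21.62, 21.82),
          c(-3.34, -1.26, -2.66, -2.13, -0.03),
          c(3.06, 4.02, 3.52, 5.43, 7.59)),
    block("compromised", "combined", "dbp", 126,
          c(0.03, 0.45, 0.91, -0.93, 1.49),
          c(8.97, 7.53, 7.32, 9.23, 9.17),
          c(-1.53, -0.86, -0.37, -2.54, -0.11),
          c(1.60, 1.76, 2.19, 0.68, 3.09)),
    # compromised cohort, PAT feature set
    block("compromised", "pat", "map", 126,
          c(0.00, -0.08, 0.95, -0.26, 2.32),
          c(12.67, 6.57, 9.72, 8.07, 13.46),
          c(-2.21, -1.23, -0.74, -1.67, -0.03),
          c(2.21, 1.07, 2.65, 1.15, 4.67)),
    block("compromised", "pat", "sbp", 126,
          c(0.00, -0.52, 0.63, -1.52, 4.13),
          c(20.80, 15.40, 16.44, 18.12, 22.03),
          c(-3.63, -3.21, -2.24, -4.68, 0.28),
          c(3.63, 2.17, 3.50, 1.64, 7.98)),
    block("compromised", "pat", "dbp", 126,
          c(0.00, 0.14, 1.09, 0.37, 1.42),
          c(9.03, 4.51, 6.69, 5.92, 9.18),
          c(-1.58, -0.65, -0.08, -0.66, -0.18),
          c(1.58, 0.93, 2.26, 1.40, 3.02)),
    # compromised cohort, morphology feature set
    block("compromised", "morphology", "map", 126,
          c(0.09, -0.14, 0.89, -0.94, 1.36),
          c(12.46, 8.55, 10.11, 11.41, 13.10),
          c(-2.08, -1.63, -0.87, -2.93, -0.93),
          c(2.27, 1.35, 2.66, 1.05, 3.65)),
    block("compromised", "morphology", "sbp", 126,
          c(-0.11, 0.09, 0.57, 2.49, 4.00),
          c(18.83, 17.51, 17.24, 24.22, 21.99),
          c(-3.39, -2.97, -2.44, -1.74, 0.16),
          c(3.18, 3.15, 3.58, 6.72, 7.84)),
    block("compromised", "morphology", "dbp", 126,
          c(-0.14, 0.05, 1.01, 0.65, 0.045),
          c(8.80, 7.61, 7.35, 11.55, 8.66),
          c(-1.68, -1.28, -0.27, -1.37, -1.47),
          c(1.40, 1.38, 2.30, 2.67, 1.56))
  )
}
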