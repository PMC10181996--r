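check_errors_df <- function(errors_df, target = NULL) {
  need <- c("method", "feature_set", "error")
  missing <- setdiff(need, names(errors_df))
  if (length(missing) > 0L) {
    bp_abort("errors data needs columns: ", paste(missing, collapse = ", "))
  }
  if (!is.null(target) && "target" %in% names(errors_df)) {
    errors_df <- errors_df[errors_df$target == target, ]
  }
  if (nrow(errors_df) == 0L) bp_abort("no error observations for this target")
  counts <- table(errors_df$feature_set, errors_df$method)
  if (any(counts < 2)) bp_abort("every feature_set x method cell needs >= 2 observations")
  errors_df
}

anova_rows <- function(df, value_col) {
  df$feature_set <- factor(df$feature_set)
  df$method <- factor(df$method)
  # single-level factors drop out of the model (one-factor layouts are
  # legitimate, e.g. when only one feature set is under test)
  terms <- c(
    if (nlevels(df$feature_set) > 1L) "feature_set",
    if (nlevels(df$method) > 1L) "method"
  )
  if (length(terms) == 0L) bp_abort("need at least one factor with 2+ levels")
  if (length(terms) == 2L) terms <- c(terms, "feature_set:method")
  if (stats::var(df[[value_col]]) == 0) {
    # a constant response carries no evidence either way: report null F
    d1 <- c(nlevels(df$feature_set) - 1L, nlevels(df$method) - 1L,
            (nlevels(df$feature_set) - 1L) * (nlevels(df$method) - 1L))
    d1[d1 == 0L] <- NA_real_
    used <- sum(d1, na.rm = TRUE) + 1L
    return(tibble::tibble(factor = c("feature", "method", "interaction"),
                          df1 = d1, df2 = nrow(df) - used,
                          statistic = ifelse(is.na(d1), NA_real_, 0),
                          p = ifelse(is.na(d1), NA_real_, 1)))
  }
  fit <- stats::aov(stats::reformulate(terms, response = value_col), data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  df_res <- tab[rn == "Residuals", "Df"]
  cell <- function(name, col) {
    i <- which(rn == name)
    if (length(i) == 1L) tab[i, col] else NA_real_
  }
  tibble::tibble(
    factor = c("feature", "method", "interaction"),
    df1 = c(cell("feature_set", "Df"), cell("method", "Df"),
            cell("feature_set:method", "Df")),
    df2 = rep(df_res, 3),
    statistic = c(cell("feature_set", "F value"), cell("method", "F value"),
                  cell("feature_set:method", "F value")),
    p = c(cell("feature_set", "Pr(>F)"), cell("method", "Pr(>F)"),
          cell("feature_set:method", "Pr(>F)"))
  )
}

#' Two-way ANOVA on signed estimation errors
#'
#' Classical two-factor analysis of variance of the signed errors over
#' feature set and method (balanced by construction when every cell comes
#' from the same protocol), with the feature, method and interaction F tests.
#'
#' @param errors_df Long tibble with columns `method`, `feature_set`,
#'   `error` (and optionally `target`).
#' @param target Optional target filter when `errors_df` has a `target`
#'   column.
#' @return Tibble with rows `feature`, `method`, `interaction` and columns
#'   `df1`, `df2`, `statistic`, `p`.
#' @export
two_way_anova <- function(errors_df, target = NULL) {
  df <- check_errors_df(errors_df, target)
  anova_rows(df, "error")
}

#' Two-way Levene test on absolute deviations
#'
#' Classic mean-centered Levene's test generalized to two factors: signed
#' errors are replaced by absolute deviations from their cell mean and a
#' two-way ANOVA is run on the deviations. On a single-factor layout this
#' reduces exactly to the standard Levene test.
#'
#' @inheritParams two_way_anova
#' @param center `"mean"` (classic Levene) or `"median"` (Brown-Forsythe).
#' @return Tibble as in [two_way_anova()].
#' @export
levene_two_way <- function(errors_df, target = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  df <- check_errors_df(errors_df, target)
  ctr <- if (center == "mean") mean else stats::median
  df <- dplyr::mutate(dplyr::group_by(df, .data$feature_set, .data$method),
                      abs_dev = abs(.data$error - ctr(.data$error)))
  df <- dplyr::ungroup(df)
  anova_rows(as.data.frame(df), "abs_dev")
}

#' Post hoc pairwise comparisons with Holm correction
#'
#' All unordered pairs of methods, compared within one pressure target. For
#' `measure = "mean"` each pair is tested with a two-group one-way F test on
#' the signed errors (equivalent to the squared pooled t statistic),
#' restricted by default to the `combined` feature set. For
#' `measure = "absolute"` each pair is tested with a two-sample t test on
#' the mean-centered absolute deviations (the Levene deviations), either
#' within one feature set or across all method-by-feature-set combinations
#' (`by_cell = TRUE`). P values are Holm-adjusted within the call family.
#'
#' @inheritParams two_way_anova
#' @param measure `"mean"` or `"absolute"`.
#' @param feature_set Feature set to restrict to (default `"combined"` —
#'   ignored when `by_cell` is `TRUE`).
#' @param by_cell Compare all method x feature-set cells instead of methods
#'   within one feature set.
#' @param alpha Significance level applied to adjusted p values.
#' @return Tibble with one row per pair: groups, statistic, `df1`/`df2`,
#'   raw and Holm-adjusted p, `significant`, and `winner` (the group with
#'   the smaller mean of the measure; `NA` when not significant).
#' @export
posthoc_pairwise <- function(errors_df, measure = c("mean", "absolute"),
                             target = NULL, feature_set = "combined",
                             by_cell = FALSE, alpha = 0.05) {
  measure <- match.arg(measure)
  df <- check_errors_df(errors_df, target)
  if (measure == "absolute") {
    df <- dplyr::mutate(dplyr::group_by(df, .data$feature_set, .data$method),
                        value = abs(.data$error - mean(.data$error)))
    df <- dplyr::ungroup(df)
  } else {
    df$value <- df$error
  }
  if (by_cell) {
    df$group <- paste(df$method, df$feature_set, sep = " | ")
  } else {
    df <- df[df$feature_set == feature_set, ]
    if (nrow(df) == 0L) bp_abort("no observations in feature set '", feature_set, "'")
    df$group <- df$method
  }
  groups <- unique(df$group)
  if (length(groups) < 2L) bp_abort("need at least 2 groups for post hoc comparisons")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- df$value[df$group == pr[1]]
    b <- df$value[df$group == pr[2]]
    if (length(a) < 2L || length(b) < 2L) {
      bp_abort("fewer than 2 observations in a group")
    }
    if (measure == "mean") {
      fit <- stats::oneway.test(value ~ group, data = df[df$group %in% pr, ],
                                var.equal = TRUE)
      stat <- unname(fit$statistic); d1 <- unname(fit$parameter[1])
      d2 <- unname(fit$parameter[2]); p <- fit$p.value
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      stat <- unname(tt$statistic); d1 <- 1
      d2 <- unname(tt$parameter); p <- tt$p.value
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2], statistic = stat,
                   df1 = d1, df2 = d2, p = p,
                   mean1 = mean(a), mean2 = mean(b))
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- holm_adjust(out$p)
  out$significant <- out$p_holm <= alpha
  out$winner <- ifelse(out$significant,
                       ifelse(out$mean1 <= out$mean2, out$group1, out$group2),
                       NA_character_)
  out$pair <- paste(out$group1, "vs", out$group2)
  out[, c("pair", "group1", "group2", "statistic", "df1", "df2",
          "p", "p_holm", "significant", "winner")]
}

#' Bonferroni-Holm adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, capped at 1,
#' order-preserving with the input.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    bp_abort("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Full statistical comparison report for one target
#'
#' Bundles the two-way ANOVA on signed errors, the two-way Levene test on
#' absolute deviations, and the Holm-corrected post hoc families for both
#' measures.
#'
#' @inheritParams two_way_anova
#' @param posthoc_feature_set Feature set used for the mean-error post hocs.
#' @return List of class `bp_stat_report`: `anova`, `levene`,
#'   `posthoc_mean`, `posthoc_absolute`.
#' @export
stat_report <- function(errors_df, target = NULL, posthoc_feature_set = "combined") {
  list2 <- list(
    anova = two_way_anova(errors_df, target),
    levene = levene_two_way(errors_df, target),
    posthoc_mean = posthoc_pairwise(errors_df, "mean", target,
                                    feature_set = posthoc_feature_set),
    posthoc_absolute = posthoc_pairwise(errors_df, "absolute", target,
                                        by_cell = TRUE)
  )
  structure(list2, class = "bp_stat_report")
}
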