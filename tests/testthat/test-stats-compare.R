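make_errors <- function(fun, methods = paste0("m", 1:5),
                        fsets = c("combined", "pat", "morphology"), n = 10) {
  out <- list()
  for (m in methods) for (f in fsets) {
    out[[paste(m, f)]] <- tibble::tibble(method = m, feature_set = f,
                                         error = fun(m, f, n))
  }
  dplyr::bind_rows(out)
}

test_that("two-way ANOVA has the design degrees of freedom and null behaviour", {
  # identical cell populations: zero between-cell variance
  df <- make_errors(function(m, f, n) c(-1, 0, 1, 2, -2, 0, 1, -1, 0.5, -0.5))
  a <- two_way_anova(df)
  expect_equal(a$factor, c("feature", "method", "interaction"))
  expect_equal(a$df1, c(2, 4, 8))
  expect_equal(a$df2, rep(150 - 15, 3))
  expect_equal(a$statistic, rep(0, 3), tolerance = 1e-10)
  expect_equal(a$p, rep(1, 3), tolerance = 1e-10)

  # two-group one-factor reduction: F equals the squared pooled t statistic
  set.seed(4)
  df2 <- tibble::tibble(method = rep(c("a", "b"), each = 20),
                        feature_set = "combined", error = rnorm(40, rep(c(0, 1), each = 20)))
  a2 <- two_way_anova(df2)
  tt <- t.test(error ~ method, data = df2, var.equal = TRUE)
  expect_equal(a2$statistic[a2$factor == "method"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_error(two_way_anova(df2[c(1, 2, 21), ]), ">= 2")
})

test_that("two-way Levene reduces to the reference one-factor Levene", {
  skip_if_not_installed("car")
  df <- tibble::tibble(method = "m1", feature_set = rep(c("a", "b", "c"), each = 30),
                       error = rnorm(90, 0, rep(c(1, 2, 5), each = 30)))
  lv <- levene_two_way(df)
  ref <- car::leveneTest(error ~ factor(feature_set), data = df, center = mean)
  expect_equal(lv$statistic[lv$factor == "feature"], ref[1, "F value"],
               tolerance = 1e-10)
  expect_equal(lv$p[lv$factor == "feature"], ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("Levene detects gross spread differences and ignores equal spread", {
  df_eq <- tibble::tibble(method = rep(c("a", "b"), each = 2),
                          feature_set = "combined", error = c(-1, 1, -1, 1))
  lv <- levene_two_way(df_eq)
  row <- lv[lv$factor == "method", ]
  expect_equal(row$statistic, 0, tolerance = 1e-12)
  expect_equal(row$p, 1, tolerance = 1e-12)

  set.seed(5)
  df_sp <- tibble::tibble(method = rep(c("a", "b"), each = 50),
                          feature_set = "combined",
                          error = c(rnorm(50, 0, 1), rnorm(50, 0, 10)))
  lv2 <- levene_two_way(df_sp)
  expect_lt(lv2$p[lv2$factor == "method"], 0.001)
})

test_that("post hoc pairwise tests emit all pairs with Holm-corrected winners", {
  set.seed(6)
  # five null groups: nothing significant
  df0 <- make_errors(function(m, f, n) rnorm(n), n = 20)
  ph0 <- posthoc_pairwise(df0, "mean")
  expect_equal(nrow(ph0), choose(5, 2))
  expect_false(any(ph0$significant))
  expect_true(all(is.na(ph0$winner)))

  # one shifted group: exactly its four pairs are significant
  set.seed(7)
  df1 <- make_errors(function(m, f, n) {
    rnorm(n, mean = if (m == "m3") 10 else 0, sd = 1)
  }, n = 50)
  ph1 <- posthoc_pairwise(df1, "mean")
  sig <- ph1[ph1$significant, ]
  expect_equal(nrow(sig), 4)
  expect_true(all(sig$group1 == "m3" | sig$group2 == "m3"))
  # winner is the group with the smaller mean error
  expect_true(all(sig$winner != "m3"))

  # absolute measure with one high-variance group, compared across all cells
  set.seed(8)
  df2 <- make_errors(function(m, f, n) {
    rnorm(n, 0, if (m == "m2" && f == "combined") 12 else 1)
  }, n = 40)
  ph2 <- posthoc_pairwise(df2, "absolute", by_cell = TRUE)
  expect_equal(nrow(ph2), choose(15, 2))
  noisy_sig <- ph2$significant &
    (ph2$group1 == "m2 | combined" | ph2$group2 == "m2 | combined")
  expect_equal(sum(noisy_sig), 14)
  expect_false(any(ph2$significant & !noisy_sig))
})

test_that("Holm adjustment matches the step-down construction", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # never decreases, capped at one, order-preserving with the input ranks
  set.seed(9)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("stat_report bundles the factor tests and both post hoc families", {
  set.seed(10)
  df <- make_errors(function(m, f, n) rnorm(n), n = 8)
  df$target <- "dbp"
  rep <- stat_report(df, target = "dbp")
  expect_s3_class(rep, "bp_stat_report")
  expect_equal(nrow(rep$anova), 3)
  expect_equal(nrow(rep$levene), 3)
  expect_equal(nrow(rep$posthoc_mean), 10)
  expect_equal(nrow(rep$posthoc_absolute), choose(15, 2))
})
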