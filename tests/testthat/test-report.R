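test_that("distribution comparison reports percentage-point differences", {
  config <- tiny_config()
  d <- tiny_dataset(trow("A", "left", "yes", 5), trow("A", "left", "no", 5))
  same <- compare_distributions(d, d, "outcome", config)
  expect_equal(same$abs_diff, rep(0, 3L))
  expect_equal(sum(same$freq_before), 100)

  kept <- d[d$outcome == "yes", ]
  halved <- compare_distributions(d, kept, "outcome", config)
  expect_equal(halved$abs_diff[halved$value %in% c("yes", "no")], c(50, 50))
  expect_error(compare_distributions(d, kept, "nope", config), "unknown variable")
  expect_error(compare_distributions(d, d[0, ], "outcome", config), "non-empty")
})

test_that("the case fatality rate counts the dead branch of the hierarchy", {
  config <- leoss_config()
  d <- simulate_primary(30, seed = 3)
  d$`Last known patient status` <- "alive-recovered"
  expect_equal(case_fatality_rate(d, config), 0)

  d4 <- d[1:4, ]
  d4$`Last known patient status` <- c("dead-covid", "alive-recovered",
                                      "alive-not-recovered", "alive-recovered")
  expect_equal(case_fatality_rate(d4, config), 25)
  # numerator configurable to COVID-attributed deaths only
  d4$`Last known patient status`[2L] <- "dead-other"
  expect_equal(case_fatality_rate(d4, config), 50)
  expect_equal(case_fatality_rate(d4, config, dead_values = "dead-covid"), 25)
  expect_error(case_fatality_rate(d4[0, ], config), "empty")
})

test_that("the age-death log odds ratio matches its closed form and a logistic fit", {
  config <- leoss_config()
  build <- function(a, b, c, d) {
    n <- a + b + c + d
    base <- simulate_primary(n, seed = 1)
    base$`Age at diagnosis` <- rep(c("56-65", "26-35"), c(a + b, c + d))
    base$`Last known patient status` <- c(rep("dead-covid", a), rep("alive-recovered", b),
                                          rep("dead-covid", c), rep("alive-recovered", d))
    base
  }
  expect_equal(log_odds_death_by_age(build(10, 10, 10, 10), config)$coefficient, 0)
  expect_equal(log_odds_death_by_age(build(20, 5, 5, 20), config)$coefficient, log(16))

  # no deaths at all: the coefficient is undefined, not an error
  res <- log_odds_death_by_age(build(0, 20, 0, 20), config)
  expect_false(res$defined)
  expect_true(is.na(res$coefficient))

  # closed form ln(ad/bc) == iteratively fitted univariate logistic slope
  set.seed(77)
  for (trial in 1:20) {
    cells <- sample(1:30, 4L, replace = TRUE)
    d <- build(cells[1], cells[2], cells[3], cells[4])
    closed <- log_odds_death_by_age(d, config)$coefficient
    old <- d$`Age at diagnosis` == "56-65"
    dead <- d$`Last known patient status` == "dead-covid"
    fitted <- stats::glm(dead ~ old, family = stats::binomial())
    expect_equal(closed, unname(stats::coef(fitted)["oldTRUE"]), tolerance = 1e-6)
  }
})

test_that("quality reports assemble bias, risk and suppression consistently", {
  config <- leoss_config()
  d <- simulate_primary(1200, seed = 21)
  res <- anonymize(d, config)
  report <- quality_report(d, res$released, config)

  expect_equal(report$suppressed_fraction,
               length(res$suppressed_ids) / nrow(d))
  # frequencies sum to 100% per variable on both sides
  for (cmp in report$comparisons) {
    expect_equal(sum(cmp$freq_before), 100, tolerance = 1e-6)
    expect_equal(sum(cmp$freq_after), 100, tolerance = 1e-6)
  }
  # the clinical average is over the non-key variables only
  clinical <- setdiff(names(report$comparisons), config$key_vars)
  expect_equal(report$mean_abs_diff_clinical,
               mean(unlist(lapply(report$comparisons[clinical], `[[`, "abs_diff"))))
  # engine post-condition surfaces in the report
  expect_lte(report$risk_after$highest, 1 / config$k)
  expect_equal(report$cfr_diff, report$cfr_after - report$cfr_before)

  g <- glance(report)
  expect_equal(g$n_after, nrow(res$released))
  expect_s3_class(tidy(report), "tbl_df")

  # zero-bias report when nothing is suppressed
  trivial <- quality_report(d, d, config)
  expect_equal(trivial$suppressed_fraction, 0)
  expect_equal(trivial$mean_abs_diff_all, 0)
  expect_equal(trivial$cfr_diff, 0)

  # serialized report is valid JSON and carries no record-level data
  path <- withr::local_tempfile(fileext = ".json")
  write_report(report, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$summary$n_before, nrow(d))
  expect_false("record_id" %in% names(parsed$frequencies))

  expect_error(quality_report(res$released, d, config), "subset")
})

test_that("an empty release yields a flagged, total-loss report", {
  config <- leoss_config()
  d <- simulate_primary(40, seed = 4)
  res <- anonymize(d, config)  # far too small: everything suppressed
  expect_equal(nrow(res$released), 0L)
  report <- quality_report(d, res$released, config)
  expect_equal(report$suppressed_fraction, 1)
  expect_true(is.na(report$cfr_after))
  expect_equal(nrow(tidy(report)), 0L)
})

test_that("release trends tabulate suppression and CFR bias over growth", {
  config <- leoss_config()
  series <- simulate_growth_series(c(200, 800), seed = 13)
  trend <- release_trend(series, config)
  expect_equal(trend$size, c(200L, 800L))
  expect_true(all(trend$suppressed_fraction >= 0 & trend$suppressed_fraction <= 1))
  # empty-release convention: bias degrades to the primary CFR
  empty_rows <- is.na(trend$cfr_released)
  expect_equal(trend$cfr_abs_bias[empty_rows], trend$cfr_primary[empty_rows])
  ok <- !empty_rows
  expect_equal(trend$cfr_abs_bias[ok],
               abs(trend$cfr_released[ok] - trend$cfr_primary[ok]))
})

test_that("plot builders return ggplot objects", {
  config <- leoss_config()
  d <- simulate_primary(600, seed = 31)
  res <- anonymize(d, config)
  expect_s3_class(autoplot(res), "ggplot")
  report <- quality_report(d, res$released, config)
  expect_s3_class(autoplot(report, variables = "Last known patient status"), "ggplot")
  trend <- release_trend(simulate_growth_series(c(200, 600), seed = 2), config)
  expect_s3_class(plot_release_trend(trend), "ggplot")
})
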