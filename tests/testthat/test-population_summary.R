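test_that("weighted_mean_se handles degenerate and hand-computed cases", {
  # zero variance
  expect_equal(weighted_mean_se(rep(17.2, 5), c(1, 2, 3, 4, 5)),
               c(mean = 17.2, se = 0))
  # single observation convention
  expect_equal(weighted_mean_se(42), c(mean = 42, se = 0))
  # {1,2,3}, unit weights: mean 2, se = sqrt(((1-2)^2+(3-2)^2)/9) = sqrt(2)/3
  expect_equal(weighted_mean_se(c(1, 2, 3)),
               c(mean = 2, se = sqrt(2) / 3))
  expect_error(weighted_mean_se(numeric(0)), "at least one")
  expect_error(weighted_mean_se(1:3, c(1, -1, 1)), "positive")
})

test_that("weighted mean follows the design-based estimator on unequal weights", {
  x <- c(10, 20, 30)
  w <- c(1, 2, 3)
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum(w^2 * (x - m)^2) / sum(w)^2)
  expect_equal(weighted_mean_se(x, w), c(mean = m, se = se))
})

test_that("percent_reaching covers boundary and closed-form cases", {
  expect_equal(percent_reaching(c(31, 35), threshold = 30),
               c(pct = 100, se = 0))
  expect_equal(percent_reaching(c(10, 20), threshold = 30),
               c(pct = 0, se = 0))
  # 50 of 100 above: pct 50, se = 100*sqrt(0.25/100) = 5
  vals <- c(rep(31, 50), rep(29, 50))
  expect_equal(percent_reaching(vals, threshold = 30),
               c(pct = 50, se = 5))
  # ties count as reaching
  expect_equal(percent_reaching(30, threshold = 30)[["pct"]], 100)
  expect_error(percent_reaching(numeric(0), threshold = 30), "at least one")
  expect_error(percent_reaching(1, threshold = 0), "threshold")
})

test_that("ages map to the five report bands with half-open boundaries", {
  expect_equal(as.character(age_band(2.0)), "Pre-school (1.5-3 years)")
  expect_equal(as.character(age_band(19.0)), "Adults (19-65 years)")
  expect_equal(as.character(age_band(66.0)), "Older Adults (>65 years)")
  # boundary years fall in the upper band
  expect_equal(as.character(age_band(c(4, 11, 65.9))),
               c("Junior School (4-10 years)", "Adolescents (11-18 years)",
                 "Adults (19-65 years)"))
  expect_error(age_band(1.0), "1.5")
  # exhaustive and disjoint over the supported range
  ages <- seq(1.5, 100, by = 0.25)
  expect_false(any(is.na(age_band(ages))))
})

test_that("the default recommendation schedule covers all ages and is overridable", {
  sched <- recommendation_schedule()
  expect_equal(threshold_for_age(c(2, 7, 12, 16, 40, 80), sched),
               c(15, 20, 25, 30, 30, 30))
  custom <- recommendation_schedule(data.frame(
    age_lower = 1.5, age_upper = Inf, threshold_g_per_day = 30
  ))
  expect_equal(threshold_for_age(c(2, 40), custom), c(30, 30))
  expect_error(recommendation_schedule(data.frame(
    age_lower = c(1.5, 10), age_upper = c(12, Inf),
    threshold_g_per_day = c(15, 30)
  )), "overlap")
})

test_that("summary rows match Table-2 shape and identity scenario collapses columns", {
  d <- make_random_dataset(n = 40, seed = 8)
  res <- compute_intakes(d, identity_scenario())
  s <- summarize_population(d, res)
  expect_equal(s$group_label,
               c("Male", "Female",
                 "Pre-school (1.5-3 years)", "Junior School (4-10 years)",
                 "Adolescents (11-18 years)", "Adults (19-65 years)",
                 "Older Adults (>65 years)"))
  expect_equal(s$current_mean, s$scenario_mean)
  expect_equal(s$current_pct, s$scenario_pct)
  # sexes partition the roster
  expect_equal(sum(s$n[s$group_type == "sex"]), nrow(d$participants))
  expect_equal(sum(s$n[s$group_type == "age"]), nrow(d$participants))
})

test_that("a group of males all at 31 g/day reaches 100% under the 30 g threshold", {
  d <- fibre_dataset(
    participants = tibble::tibble(
      participant_id = c("m1", "m2", "f1"),
      sex = c("male", "male", "female"),
      age_years = c(30, 40, 35),
      survey_weight = 1, diary_days = 1L
    ),
    entries = tibble::tibble(
      participant_id = c("m1", "m2", "f1"), day_index = 1L,
      food_code = "X", amount_g = c(3100, 3100, 1000)
    ),
    foods = tibble::tibble(food_code = "X", description = "x",
                           fibre_g_per_100g = 1, category = "other")
  )
  res <- compute_intakes(d, higher_fibre_scenario())
  s <- suppressWarnings(summarize_population(d, res))
  expect_equal(s$current_pct[s$group_label == "Male"], 100)
  expect_equal(s$current_pct_se[s$group_label == "Male"], 0)
  expect_equal(s$current_pct[s$group_label == "Female"], 0)
})

test_that("every summary cell equals an independent group-by-group recomputation", {
  d <- make_random_dataset(n = 60, n_entries_per = 6, seed = 21)
  res <- compute_intakes(d, higher_fibre_scenario())
  for (weighted in c(FALSE, TRUE)) {
    s <- summarize_population(d, res, weighted = weighted)
    joined <- merge(as.data.frame(d$participants), as.data.frame(res),
                    by = "participant_id")
    joined$w <- if (weighted) joined$survey_weight else 1
    joined$thr <- threshold_for_age(joined$age_years)
    groups <- list(
      Male = joined$sex == "male",
      Female = joined$sex == "female",
      `Adults (19-65 years)` = joined$age_years >= 19 & joined$age_years < 66
    )
    for (g in names(groups)) {
      sub <- joined[groups[[g]], ]
      row <- s[s$group_label == g, ]
      if (nrow(sub) == 0) next
      m <- sum(sub$w * sub$baseline_g_per_day) / sum(sub$w)
      expect_equal(row$current_mean, m, tolerance = 1e-12)
      expect_equal(row$current_se,
                   sqrt(sum(sub$w^2 * (sub$baseline_g_per_day - m)^2) /
                          sum(sub$w)^2),
                   tolerance = 1e-12)
      pr <- sum(sub$w * (sub$scenario_g_per_day >= sub$thr)) / sum(sub$w)
      expect_equal(row$scenario_pct, 100 * pr, tolerance = 1e-12)
      expect_equal(row$scenario_pct_se,
                   100 * sqrt(pr * (1 - pr) * sum(sub$w^2) / sum(sub$w)^2),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted estimators reduce to unweighted ones under unit weights", {
  d <- make_random_dataset(n = 30, seed = 13)
  d$participants$survey_weight <- 1
  res <- compute_intakes(d, higher_fibre_scenario())
  expect_equal(summarize_population(d, res, weighted = TRUE),
               summarize_population(d, res, weighted = FALSE))
})

test_that("percent reaching is monotone under fibre-raising scenarios", {
  for (seed in 1:3) {
    d <- make_random_dataset(n = 50, seed = seed)
    res <- compute_intakes(d, higher_fibre_scenario())
    s <- suppressWarnings(summarize_population(d, res))
    ok <- !is.na(s$current_pct)
    expect_true(all(s$scenario_pct[ok] >= s$current_pct[ok]))
    expect_true(all(s$scenario_mean[ok] >= s$current_mean[ok]))
  }
})

test_that("group mean shift equals the group-weighted mean of per-person deltas", {
  d <- make_random_dataset(n = 40, seed = 31)
  res <- compute_intakes(d, higher_fibre_scenario())
  s <- suppressWarnings(summarize_population(d, res, weighted = TRUE))
  joined <- merge(as.data.frame(d$participants), as.data.frame(res),
                  by = "participant_id")
  males <- joined[joined$sex == "male", ]
  expect_equal(
    s$scenario_mean[s$group_label == "Male"] -
      s$current_mean[s$group_label == "Male"],
    sum(males$survey_weight * males$delta_g_per_day) /
      sum(males$survey_weight),
    tolerance = 1e-12
  )
})

test_that("an empty group yields n = 0 with missing statistics and a warning", {
  d <- make_toy_dataset()  # ages 34 and 7: three age bands are empty
  res <- compute_intakes(d, higher_fibre_scenario())
  w <- capture_warnings(s <- summarize_population(d, res))
  expect_length(w, 3)  # three of the five age bands are empty
  expect_match(w, "no members", all = TRUE)
  empty <- s[s$group_label == "Pre-school (1.5-3 years)", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$current_mean))
})

test_that("rendered report matches the summary after 1-decimal rounding", {
  d <- make_random_dataset(n = 50, seed = 17)
  res <- compute_intakes(d, higher_fibre_scenario())
  s <- summarize_population(d, res)
  lines <- render_summary(s)
  male <- grep("^Male ", lines, value = TRUE)
  expect_match(male, sprintf("%.1f \\(%.1f\\)",
                             s$current_mean[s$group_label == "Male"],
                             s$current_se[s$group_label == "Male"]))
  expect_match(male, sprintf("%.1f \\(%.1f\\)",
                             s$scenario_pct[s$group_label == "Male"],
                             s$scenario_pct_se[s$group_label == "Male"]))
  # layout: a Gender block, an Age block, five age rows
  expect_equal(sum(grepl("^Gender", lines)), 1)
  expect_equal(sum(grepl("^Age", lines)), 1)
  expect_equal(sum(grepl("years\\)", lines)), 5)
})
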