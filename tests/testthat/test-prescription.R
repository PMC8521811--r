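test_that("activity status uses the 0 / 150 / 300 min per week bands", {
  expect_equal(classify_activity_status(0), "inactive")
  expect_equal(classify_activity_status(1), "somewhat_active")
  expect_equal(classify_activity_status(149), "somewhat_active")
  expect_equal(classify_activity_status(150), "moderately_active")
  expect_equal(classify_activity_status(299), "moderately_active")
  expect_equal(classify_activity_status(300), "active")
  expect_error(classify_activity_status(-5), "non-negative")
})

test_that("MET intensity bands are light <3, moderate 3-<6, vigorous >=6", {
  expect_equal(classify_intensity(2.5), "light")
  expect_equal(classify_intensity(3.0), "moderate")
  expect_equal(classify_intensity(5.9), "moderate")
  expect_equal(classify_intensity(6.0), "vigorous")
  expect_equal(classify_intensity(6.5), "vigorous")
  expect_error(classify_intensity(0), "positive")
})

test_that("shipped activity menu is label-consistent and tag-filterable", {
  menu <- load_activity_menu()
  expect_gt(nrow(menu), 10)
  for (i in seq_len(nrow(menu))) {
    expect_equal(menu$intensity[i], classify_intensity(menu$met[i]),
                 label = menu$name[i])
  }
  inland <- load_activity_menu(exclude_tags = "coastal")
  expect_false("surfing" %in% inland$name)
  expect_true("surfing" %in% menu$name)
})

test_that("default dose matrix respects the severe-obese starting-dose ordering", {
  mat <- load_dose_matrix()
  so <- mat$severe_obese$inactive
  ow <- mat$overweight$inactive
  expect_lt(so$minutes, ow$minutes)
  expect_lte(so$sessions, ow$sessions)
  for (ws in c("overweight", "obese", "severe_obese")) {
    for (as_ in c("inactive", "somewhat_active", "moderately_active", "active")) {
      expect_gt(mat[[ws]][[as_]]$minutes, 0)
      expect_gt(mat[[ws]][[as_]]$sessions, 0)
    }
  }
})

test_that("a user-supplied matrix violating the ordering is rejected at load", {
  mat <- yaml::read_yaml(system.file("extdata", "dose_matrix_default.yaml",
                                     package = "cvhrx"))
  mat$severe_obese$inactive$minutes <- 60
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(mat, path)
  expect_error(load_dose_matrix(path), "ordering")
})

test_that("weekly goals follow the +10% geometric progression with rounding", {
  plan <- generate_pa_plan("overweight", "inactive", "dancing",
                           progression = progression_config(
                             horizon_weeks = 4,
                             weekly_cap_min_per_week = 1e6))
  # hand multiplication from the default 30 min x 3/wk starting cell
  expect_equal(plan$weeks$minutes_per_week, c(90.0, 99.0, 108.9, 119.8))

  # closed-form oracle d_1 * r^(w-1) to within cumulative rounding
  long <- generate_pa_plan("obese", "somewhat_active", "hiking",
                           progression = progression_config(
                             horizon_weeks = 12,
                             weekly_cap_min_per_week = 1e6))
  d1 <- long$weeks$minutes_per_week[1]
  closed <- d1 * 1.1^(0:11)
  expect_equal(long$weeks$minutes_per_week, closed, tolerance = 1e-3)
  expect_true(all(diff(long$weeks$minutes_per_week) > 0))
})

test_that("the weekly cap truncates the progression and r = 1 holds steady", {
  capped <- generate_pa_plan("overweight", "active", "soccer (casual)",
                             progression = progression_config(
                               horizon_weeks = 12,
                               weekly_cap_min_per_week = 300))
  expect_true(all(capped$weeks$minutes_per_week <= 300))
  expect_equal(max(capped$weeks$minutes_per_week), 300)
  expect_true(all(diff(capped$weeks$minutes_per_week) >= 0))

  flat <- generate_pa_plan("obese", "inactive", "yoga",
                           progression = progression_config(
                             weekly_multiplier = 1.0, horizon_weeks = 6))
  expect_true(all(flat$weeks$minutes_per_week ==
                    flat$weeks$minutes_per_week[1]))
  expect_error(generate_pa_plan("overweight", "inactive", character()),
               "at least one")
})

test_that("severely obese inactive patients start lower than overweight inactive", {
  so <- generate_pa_plan("severe_obese", "inactive", "brisk walking")
  ow <- generate_pa_plan("overweight", "inactive", "brisk walking")
  expect_lt(so$weeks$minutes_per_week[1], ow$weeks$minutes_per_week[1])
  expect_lte(so$sessions_per_week, ow$sessions_per_week)
})

test_that("problem behaviors are flagged iff the screener answer is unhealthy", {
  all_healthy <- diet_survey(TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_length(flag_problem_behaviors(all_healthy), 0)
  veg_no <- diet_survey(TRUE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(flag_problem_behaviors(veg_no), "vegetable")
  none_healthy <- diet_survey(FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(flag_problem_behaviors(none_healthy),
               c("fruit", "vegetable", "whole_grains", "ssb", "snacking"))
  expect_error(diet_survey(TRUE, NA, TRUE, TRUE, TRUE), "TRUE/FALSE")
})

test_that("recommendation count equals flag count over all 32 flag sets", {
  lib <- load_food_lists()
  behaviors <- c("fruit", "vegetable", "whole_grains", "ssb", "snacking")
  for (mask in 0:31) {
    flags <- behaviors[bitwAnd(mask, 2^(0:4)) > 0]
    recs <- generate_diet_recs(flags, lib)
    expect_length(recs, length(flags))
    expect_setequal(vapply(recs, `[[`, character(1), "behavior"), flags)
    for (r in recs) {
      expect_named(r$food_lists, c("green", "yellow", "red"))
      expect_true(all(lengths(r$food_lists) > 0))
    }
  }
})

test_that("max_behaviors focuses on the first flags in survey order", {
  recs <- generate_diet_recs(c("snacking", "fruit", "ssb"), max_behaviors = 2)
  expect_equal(vapply(recs, `[[`, character(1), "behavior"),
               c("fruit", "ssb"))
  expect_error(generate_diet_recs("dessert"), "unknown behaviors")
})
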