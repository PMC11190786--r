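test_that("arithmetic estimates follow the duration rule", {
  tbl <- make_visits(start_time = c("2024-01-01 06:00:00", "2024-01-01 12:00:00",
                                    "2024-01-01 18:00:00"),
                     duration = c(3.5, 2.5, 0.5),
                     ch4 = c(160, 150, 60))
  est <- function(rule) arithmetic_estimates(tbl, "ch4", rule)$estimate
  expect_equal(est(duration_rule(3)), 160)
  expect_equal(est(duration_rule(2)), 155)
  expect_equal(est(rule_all_visits()), mean(c(160, 150, 60)), tolerance = 1e-9)
  expect_equal(arithmetic_estimates(tbl, "ch4", duration_rule(2))$n_visits, 2)
})

test_that("animals without qualifying visits are omitted and listed", {
  tbl <- make_visits(animal_id = c("A1", "A2"), duration = c(4, 1))
  est <- arithmetic_estimates(tbl, "ch4", duration_rule(3))
  expect_equal(est$animal_id, "A1")
  expect_equal(attr(est, "omitted"), "A2")
})

test_that("time-bin averaging weights occupied bins equally", {
  # bin [0,3): one visit at 100; bin [12,15): three visits 200, 200, 260
  tbl <- make_visits(start_time = c("2024-01-01 01:00:00", "2024-01-01 12:30:00",
                                    "2024-01-01 13:00:00", "2024-01-01 14:00:00"),
                     ch4 = c(100, 200, 200, 260))
  tb <- time_bin_estimates(tbl, "ch4", rule_all_visits())
  expect_equal(tb$estimate, (100 + 220) / 2)
  expect_equal(tb$n_bins_occupied, 2)
  expect_equal(arithmetic_estimates(tbl, "ch4", rule_all_visits())$estimate, 190)
})

test_that("time-bin equals arithmetic when visits collapse to one bin or are balanced", {
  one_bin <- make_visits(start_time = c("2024-01-01 08:05:00", "2024-01-01 08:40:00"),
                         ch4 = c(140, 180))
  expect_equal(time_bin_estimates(one_bin, "ch4", rule_all_visits())$estimate,
               arithmetic_estimates(one_bin, "ch4", rule_all_visits())$estimate)

  # identical values replicated once per bin across all 8 bins
  balanced <- make_visits(
    start_time = sprintf("2024-01-01 %02d:30:00", seq(1, 23, by = 3)),
    ch4 = rep(150, 8))
  expect_equal(time_bin_estimates(balanced, "ch4", rule_all_visits())$estimate,
               arithmetic_estimates(balanced, "ch4", rule_all_visits())$estimate)
})

test_that("method_difference is signed and scaled by the reference mean", {
  a <- tibble::tibble(animal_id = c("A1", "A2"), estimate = c(10, 20))
  expect_equal(method_difference(a, a), list(mean_diff = 0, percent = 0, n_pairs = 2))

  b <- tibble::tibble(animal_id = c("A1", "A2"), estimate = c(12, 18))
  md <- method_difference(a, b)
  expect_equal(md$mean_diff, 0)
  expect_equal(md$percent, 0)

  a2 <- tibble::tibble(animal_id = c("A1", "A2"), estimate = c(11, 21))
  md2 <- method_difference(a2, b)
  expect_equal(md2$mean_diff, 1)
  expect_equal(md2$percent, 100 * 1 / 15, tolerance = 1e-9)

  expect_error(method_difference(a, tibble::tibble(animal_id = "Z", estimate = 1)),
               "no animals in common")
})

test_that("estimates stay within qualifying visit bounds and counts are monotone in the rule", {
  ch <- generate_cohort(small_config(), seed = 3)
  tbl <- run_qc(ch$visits)$table
  rules <- list(duration_rule(3), duration_rule(2), duration_rule(1), rule_all_visits())
  prev <- NULL
  for (rule in rules) {
    est <- arithmetic_estimates(tbl, "ch4", rule)
    for (i in seq_len(nrow(est))) {
      vals <- tbl$ch4_gpd[tbl$animal_id == est$animal_id[i] &
                            tbl$duration_min >= rule$lower &
                            tbl$duration_min < rule$upper]
      expect_gte(est$estimate[i], min(vals))
      expect_lte(est$estimate[i], max(vals))
    }
    if (!is.null(prev)) {
      joined <- dplyr::inner_join(prev, est, by = "animal_id",
                                  suffix = c("_strict", "_relaxed"))
      expect_true(all(joined$n_visits_relaxed >= joined$n_visits_strict))
    }
    prev <- est
  }
})

test_that("duration rules and bin schemes validate their invariants", {
  expect_error(duration_rule(3, 2))
  r <- duration_rule(1, 2)
  expect_equal(r$kind, "range")
  expect_equal(duration_rule(3)$kind, "threshold")
  expect_error(time_bin_scheme(c(0, 3, 2, 24)))
  expect_error(time_bin_scheme(c(1, 24)))
  expect_equal(time_bin_scheme()$n_bins, 8)
})
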