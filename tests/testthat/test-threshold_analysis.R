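# Two small synthetic "experiments" with disjoint animal ids.
two_experiment_table <- function(seed = 5) {
  a <- generate_cohort(small_config(), seed = seed)$visits
  b <- generate_cohort(small_config(), seed = seed + 100)$visits
  a$experiment_id <- "E1"
  b$experiment_id <- "E2"
  b$animal_id <- sub("^A", "B", b$animal_id)
  visit_table(dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b)))
}

test_that("relaxing the threshold never shrinks visit counts nor lengthens mean duration", {
  tbl <- run_qc(generate_cohort(small_config(), seed = 21)$visits)$table
  desc <- descriptive_by_threshold(tbl)
  nv <- desc[desc$metric == "n_visits", ]
  dur <- desc[desc$metric == "duration", ]
  order_lab <- c(">=3 min", ">=2 min", ">=1 min", "all")
  for (e in unique(nv$experiment_id)) {
    expect_true(all(diff(nv$mean[match(order_lab, nv$rule[nv$experiment_id == e])]) >= 0))
    expect_true(all(diff(dur$mean[match(order_lab, dur$rule[dur$experiment_id == e])]) <= 0))
  }
})

test_that("a single animal with one visit reports an undefined SD", {
  desc <- descriptive_by_threshold(make_visits(), rules = list(duration_rule(3)))
  expect_true(all(is.na(desc$sd)))
  expect_equal(unique(desc$n_animals), 1)
})

test_that("with a degenerate generator the descriptive gas means equal the truth", {
  ch <- generate_cohort(exact_config(), seed = 9)
  desc <- descriptive_by_threshold(ch$visits, rules = list(duration_rule(3)))
  expect_equal(desc$mean[desc$metric == "ch4"], mean(ch$truth$ch4), tolerance = 1e-12)
  expect_equal(desc$mean[desc$metric == "co2"], mean(ch$truth$co2), tolerance = 1e-12)
})

test_that("the gold rule agrees perfectly with itself and pooling concatenates pairs", {
  tbl <- run_qc(two_experiment_table())$table
  agr <- agreement_by_threshold(tbl, rules = list(duration_rule(3), duration_rule(1)))
  self <- agr[agr$rule == ">=3 min", ]
  expect_true(all(abs(self$ccc - 1) < 1e-12))
  expect_true(all(self$rmse_pct < 1e-9))

  pooled <- agr[agr$experiment_id == "pooled" & agr$rule == ">=1 min", ]
  per_exp <- agr[agr$experiment_id != "pooled" & agr$rule == ">=1 min", ]
  for (g in unique(pooled$gas)) {
    expect_equal(pooled$n_pairs[pooled$gas == g],
                 sum(per_exp$n_pairs[per_exp$gas == g]))
  }
})

test_that("the seven duration ranges partition the visits", {
  tbl <- make_visits(animal_id = paste0("A", 1:7),
                     duration = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5))
  rep <- duration_range_report(tbl)
  counts <- rep$descriptive[rep$descriptive$metric == "n_visits", ]
  expect_equal(nrow(counts), 7)
  expect_true(all(counts$mean == 1))

  # counts over a cohort sum to the all-visits count
  big <- run_qc(generate_cohort(small_config(), seed = 2)$visits)$table
  rep2 <- duration_range_report(big)
  nv <- rep2$descriptive[rep2$descriptive$metric == "n_visits", ]
  expect_equal(sum(nv$mean * nv$n_animals), nrow(big))
})

test_that("a range reproducing the gold set agrees perfectly", {
  # all visits in [3, 4): the [3,4) range estimate equals the gold standard
  tbl <- make_visits(animal_id = rep(paste0("A", 1:4), each = 3),
                     duration = rep(c(3.1, 3.5, 3.9), 4),
                     ch4 = rnorm(12, 150, 20))
  rep <- duration_range_report(tbl)
  cell <- rep$agreement[rep$agreement$range == "[3,4) min" &
                          rep$agreement$gas == "ch4", ]
  expect_equal(cell$ccc, 1)
  expect_equal(cell$rmse_pct, 0)
})

test_that("ranges overlapping are rejected and sparse ranges are omitted with a note", {
  expect_error(duration_range_report(make_visits(),
                                     ranges = list(duration_rule(0, 2),
                                                   duration_rule(1, 3))),
               "overlap")
  rep <- duration_range_report(make_visits(animal_id = c("A1", "A2", "A3"),
                                           duration = c(3.5, 3.6, 3.7)))
  expect_true(any(grepl("fewer than 3 pairs", attr(rep, "omitted_cells"))))
})

test_that("percent differences reproduce the published cross-experiment arithmetic", {
  visits_ge2 <- c(77.6, 64.1, 67.4, 173.3)
  visits_ge3 <- c(61.1, 49.1, 51.3, 144.0)
  pd <- percent_difference_summary(visits_ge2, visits_ge3,
                                   labels = c("beck2018", "beck2019",
                                              "thompson", "proctor"))
  expect_equal(unname(round(pd$per_group, 1)), c(27.0, 30.5, 31.4, 20.3))
  expect_equal(pd$mean, 27.3, tolerance = 0.05)

  same <- percent_difference_summary(visits_ge3, visits_ge3)
  expect_true(all(same$per_group == 0))
  expect_error(percent_difference_summary(1, 0), "zero reference")
})

test_that("study-day arithmetic rounds up to whole days", {
  expect_equal(study_days_required(30, 1.5)$days, 20)
  d <- study_days_required(30, 2.4)
  expect_equal(d$days_raw, 12.5)
  expect_equal(d$days, 13)
  d2 <- study_days_required(40, 2.7)
  expect_equal(d2$days_raw, 40 / 2.7, tolerance = 1e-12)
  expect_equal(d2$days, 15)
  expect_error(study_days_required(30, 0), "positive")
})
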