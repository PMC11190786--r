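test_that("write then read round-trips records, including missing gas values", {
  tbl <- make_visits(animal_id = c("A1", "A1", "A2"),
                     start_time = c("2024-01-01 06:30:00", "2024-01-01 15:00:00",
                                    "2024-01-02 07:45:30"),
                     duration = c(3.25, 4.5, 0.75),
                     co2 = c(9123.456789, 8000.1, 7500),
                     ch4 = c(150.5, NA, 120))
  path <- withr::local_tempfile(fileext = ".csv")
  write_visit_table(tbl, path)
  back <- read_visit_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$animal_id, tbl$animal_id)
  expect_equal(back$start_time, tbl$start_time)
  expect_equal(back$duration_min, tbl$duration_min, tolerance = 1e-9)
  expect_equal(back$co2_gpd, tbl$co2_gpd, tolerance = 1e-9)
  expect_true(is.na(back$ch4_gpd[2]))
})

test_that("malformed rows are rejected with diagnostics, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "animal_id,experiment_id,start_time,duration_min,airflow_lps,co2_gpd,o2_gpd,ch4_gpd",
    "A1,E1,2024-01-01T08:00:00,3.5,30,9000,6000,150",
    "A1,E1,not-a-time,3.5,30,9000,6000,150",
    "A2,E1,2024-01-01T09:00:00,0,30,9000,6000,150"
  ), path)
  expect_warning(tbl <- read_visit_table(path), "rejected")
  expect_equal(nrow(tbl), 1)
  diag <- attr(tbl, "diagnostics")
  expect_equal(diag$row, c(2, 3))
  expect_match(diag$problem[1], "start_time")
  expect_match(diag$problem[2], "duration")
})

test_that("reader errors on missing files, missing columns and all-bad rows", {
  expect_error(read_visit_table(file.path(tempdir(), "nope.csv")), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,start_time", "A1,2024-01-01T00:00:00"), path)
  expect_error(read_visit_table(path), "missing columns")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "animal_id,experiment_id,start_time,duration_min,airflow_lps,co2_gpd,o2_gpd,ch4_gpd",
    "A1,E1,2024-01-01T08:00:00,0,30,9000,6000,150"
  ), path2)
  expect_error(suppressWarnings(read_visit_table(path2)), "no valid rows")
})

test_that("a schema mapping renames vendor columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "RFID,experiment_id,start_time,GoodDuration,airflow_lps,co2_gpd,o2_gpd,ch4_gpd",
    "A1,E1,2024-01-01T08:00:00,3.5,30,9000,6000,150"
  ), path)
  tbl <- read_visit_table(path, schema = c(animal_id = "RFID",
                                           duration_min = "GoodDuration"))
  expect_equal(tbl$animal_id, "A1")
  expect_equal(tbl$duration_min, 3.5)
  expect_error(read_visit_table(path, schema = c(animal_id = "NoSuchCol")),
               "absent")
})

test_that("visit table invariants are enforced at construction", {
  expect_error(make_visits(duration = c(3, 0)), "positive")
  expect_error(make_visits(airflow = -1), "nonnegative")
  expect_error(
    visit_table(tibble::tibble(
      animal_id = c("A1", "A1"), experiment_id = c("E1", "E2"),
      start_time = rep("2024-01-01 08:00:00", 2), duration_min = c(3, 3),
      airflow_lps = c(30, 30), co2_gpd = c(1, 1), o2_gpd = c(1, 1),
      ch4_gpd = c(1, 1))),
    "more than one experiment")
  expect_error(write_visit_table(make_visits()[0, ], tempfile()), "empty")
})

test_that("per-animal summary uses the inclusive calendar-day span", {
  one_day <- make_visits(start_time = paste0("2024-01-01 ", c("06", "10", "15", "20"), ":00:00"))
  s <- per_animal_summary(one_day)
  expect_equal(s$observation_days, 1)
  expect_equal(s$visits_per_day, 4)

  # 30 visits spread from Jan 1 to Jan 20 -> 20 d span, 1.5 visits/d
  days <- sort(c(1, 20, sample(rep(1:20, 2), 28)))
  span <- make_visits(start_time = sprintf("2024-01-%02d 08:00:00", days))
  s2 <- per_animal_summary(span)
  expect_equal(s2$n_visits, 30)
  expect_equal(s2$observation_days, 20)
  expect_equal(s2$visits_per_day, 1.5)
})

test_that("per-animal visit counts are conserved across animals", {
  tbl <- make_visits(animal_id = rep(c("A1", "A2"), c(3, 5)))
  s <- per_animal_summary(tbl)
  expect_equal(nrow(s), 2)
  expect_equal(sum(s$n_visits), nrow(tbl))
  expect_equal(sort(s$n_visits), c(3, 5))
})
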