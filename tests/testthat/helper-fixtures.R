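# Small in-code fixtures used across the suite.

make_visits <- function(animal_id = "A1", experiment_id = "E1",
                        start_time = "2024-01-01 08:00:00",
                        duration = 3.5, airflow = 30,
                        co2 = 9000, o2 = 6000, ch4 = 150) {
  n <- max(lengths(list(animal_id, experiment_id, start_time, duration,
                        airflow, co2, o2, ch4)))
  visit_table(tibble::tibble(
    animal_id = rep_len(animal_id, n),
    experiment_id = rep_len(experiment_id, n),
    start_time = rep_len(start_time, n),
    duration_min = rep_len(duration, n),
    airflow_lps = rep_len(airflow, n),
    co2_gpd = rep_len(co2, n),
    o2_gpd = rep_len(o2, n),
    ch4_gpd = rep_len(ch4, n)
  ))
}

# Ten-record QC fixture with hand-enumerated violations:
# rows 1-3 low airflow (row 2 also carries a CH4 violation, claimed by
# the airflow stage), row 4 a CH4 ceiling violation at adequate airflow,
# rows 5 and 6 boundary records (airflow exactly 26, CH4 exactly 500)
# that must be kept, rows 7-10 clean.
qc_fixture <- function() {
  make_visits(
    animal_id = paste0("A", 1:10),
    airflow = c(25, 20, 25.5, 30, 26, 30, 28, 31, 29, 30),
    ch4 = c(150, 600, 140, 500.1, 155, 500, 160, 145, 150, 148)
  )
}

# A small fast cohort configuration for unit tests.
small_config <- function(...) {
  args <- utils::modifyList(list(n_animals = 8, study_days = 12), list(...))
  do.call(cohort_config, args)
}

# Generator with all stochastic distortions switched off: observations
# equal the animal's true fluxes exactly.
exact_config <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 8, study_days = 12, noise_cv = 0,
         bias_curve = zero_bias_curve(),
         low_airflow_rate = 0, extreme_flux_rate = 0),
    list(...))
  do.call(cohort_config, args)
}

all_gas_arithmetic <- function(table, rule) {
  dplyr::bind_rows(lapply(c("co2", "o2", "ch4"), function(g) {
    arithmetic_estimates(table, g, rule)
  }))
}
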