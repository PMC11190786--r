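# Helpers shared by the threshold and range reports -------------------------

# Per-animal estimates for every gas under one rule, stacked long.
all_gas_estimates <- function(table, rule) {
  dplyr::bind_rows(lapply(names(GAS_COLS), function(g) {
    arithmetic_estimates(table, g, rule)
  }))
}

mean_sd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)

# Animal observation spans from the FULL table (an animal's observation
# period does not depend on the duration rule in force).
animal_spans <- function(table) {
  s <- per_animal_summary(table)
  setNames(s$observation_days, s$animal_id)
}

#' Descriptive statistics by visit-duration threshold
#'
#' For each experiment and duration rule: the cross-animal mean and SD of
#' per-animal visit duration, visits per day, qualifying visit count, and
#' per-gas flux estimates. The SD is the between-animal SD of per-animal
#' values. Visits-per-day denominators use each animal's inclusive
#' calendar-day span over all of its visits, so the denominator is the
#' same for every rule.
#'
#' @param table a QC-filtered [visit_table()].
#' @param rules list of [duration_rule()] objects; defaults to the
#'   conventional thresholds (>=3, >=2, >=1 min, all visits).
#' @return tibble with columns `experiment_id`, `rule`, `metric`,
#'   `n_animals`, `mean`, `sd`. Cells with zero qualifying visits are
#'   omitted (noted in the `omitted_cells` attribute).
#' @export
descriptive_by_threshold <- function(table,
                                     rules = list(duration_rule(3), duration_rule(2),
                                                  duration_rule(1), rule_all_visits())) {
  spans <- animal_spans(table)
  rows <- list()
  omitted <- character()
  for (rule in rules) {
    q <- table[rule_qualifies(table$duration_min, rule), ]
    for (exp_id in unique(table$experiment_id)) {
      qe <- q[q$experiment_id == exp_id, ]
      if (nrow(qe) == 0) {
        omitted <- c(omitted, sprintf("%s / %s: no qualifying visits", exp_id, rule$label))
        next
      }
      per_animal <- dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(qe), .data$animal_id),
        duration = mean(.data$duration_min),
        n_visits = dplyr::n(),
        co2 = mean(.data$co2_gpd, na.rm = TRUE),
        o2 = mean(.data$o2_gpd, na.rm = TRUE),
        ch4 = mean(.data$ch4_gpd, na.rm = TRUE),
        .groups = "drop"
      )
      per_animal$visits_per_day <- per_animal$n_visits / spans[per_animal$animal_id]
      for (metric in c("duration", "visits_per_day", "n_visits", "co2", "o2", "ch4")) {
        ms <- mean_sd(per_animal[[metric]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          experiment_id = exp_id, rule = rule$label, metric = metric,
          n_animals = nrow(per_animal), mean = ms[["mean"]], sd = ms[["sd"]]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "omitted_cells") <- omitted
  out
}

#' Agreement with the gold standard by visit-duration threshold
#'
#' Per experiment, gas and candidate rule: agreement statistics of the
#' candidate rule's per-animal estimates against the same experiment's
#' gold-standard estimates (all visits >= 3 min). With `pooled = TRUE`
#' an additional set of rows concatenates the animal-level estimate
#' pairs of all experiments into one unweighted comparison.
#'
#' @inheritParams descriptive_by_threshold
#' @param gold_rule the gold-standard rule (default >= 3 min).
#' @param pooled also report the pooled (all experiments concatenated)
#'   comparison.
#' @return tibble with columns `experiment_id` (or `"pooled"`), `rule`,
#'   `gas`, `r`, `Cb`, `ccc`, `rmse_pct`, `n_pairs`, `n_dropped`. Cells
#'   with fewer than 3 pairable animals are omitted (noted in the
#'   `omitted_cells` attribute).
#' @export
agreement_by_threshold <- function(table,
                                   rules = list(duration_rule(3), duration_rule(2),
                                                duration_rule(1), rule_all_visits()),
                                   gold_rule = duration_rule(3), pooled = TRUE) {
  rows <- list()
  omitted <- character()
  exps <- unique(table$experiment_id)
  for (gas in names(GAS_COLS)) {
    gold_all <- arithmetic_estimates(table, gas, gold_rule)
    for (rule in rules) {
      cand_all <- arithmetic_estimates(table, gas, rule)
      units <- lapply(exps, function(e) {
        list(id = e,
             cand = cand_all[cand_all$experiment_id == e, ],
             gold = gold_all[gold_all$experiment_id == e, ])
      })
      if (pooled && length(exps) > 1) {
        units <- c(units, list(list(id = "pooled", cand = cand_all, gold = gold_all)))
      }
      for (u in units) {
        stats <- tryCatch(compare_estimates(u$cand, u$gold), error = function(e) NULL)
        if (is.null(stats)) {
          omitted <- c(omitted, sprintf("%s / %s / %s: fewer than 3 pairs",
                                        u$id, rule$label, gas))
          next
        }
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(experiment_id = u$id, rule = rule$label, gas = gas), stats
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "omitted_cells") <- omitted
  out
}

#' Descriptive and agreement report by visit-duration range
#'
#' Stratifies visits into disjoint duration ranges (default: the seven
#' conventional ranges partitioning (0, Inf)), reports per-range
#' cross-animal descriptive statistics, and compares each range's
#' per-animal estimates against the gold standard (all visits >= 3 min,
#' pooled across experiments). Animals absent from a range are excluded
#' from that range's comparison.
#'
#' @inheritParams descriptive_by_threshold
#' @param ranges list of disjoint [duration_rule()] range objects.
#' @return list with `descriptive` (tibble: `range`, `metric`,
#'   `n_animals`, `mean`, `sd`) and `agreement` (tibble: `range`, `gas`,
#'   `r`, `Cb`, `ccc`, `rmse_pct`, `n_pairs`, `n_dropped`); ranges with
#'   fewer than 3 represented animals have their agreement rows omitted
#'   with a note in the `omitted_cells` attribute.
#' @export
duration_range_report <- function(table, ranges = default_duration_ranges()) {
  # ranges must be disjoint
  lows <- vapply(ranges, `[[`, numeric(1), "lower")
  ups <- vapply(ranges, `[[`, numeric(1), "upper")
  ord <- order(lows)
  if (any(ups[ord][-length(ord)] > lows[ord][-1])) stop("ranges overlap")

  desc_rows <- list()
  agree_rows <- list()
  omitted <- character()
  gold <- lapply(setNames(names(GAS_COLS), names(GAS_COLS)), function(g) {
    arithmetic_estimates(table, g, duration_rule(3))
  })
  for (rule in ranges) {
    q <- table[rule_qualifies(table$duration_min, rule), ]
    if (nrow(q) > 0) {
      per_animal <- dplyr::summarise(
        dplyr::group_by(tibble::as_tibble(q), .data$animal_id),
        n_visits = dplyr::n(),
        duration = mean(.data$duration_min),
        co2 = mean(.data$co2_gpd, na.rm = TRUE),
        o2 = mean(.data$o2_gpd, na.rm = TRUE),
        ch4 = mean(.data$ch4_gpd, na.rm = TRUE),
        .groups = "drop"
      )
      for (metric in c("n_visits", "duration", "co2", "o2", "ch4")) {
        ms <- mean_sd(per_animal[[metric]])
        desc_rows[[length(desc_rows) + 1]] <- tibble::tibble(
          range = rule$label, metric = metric, n_animals = nrow(per_animal),
          mean = ms[["mean"]], sd = ms[["sd"]]
        )
      }
    }
    for (gas in names(GAS_COLS)) {
      cand <- arithmetic_estimates(table, gas, rule)
      stats <- tryCatch(compare_estimates(cand, gold[[gas]]), error = function(e) NULL)
      if (is.null(stats)) {
        omitted <- c(omitted, sprintf("%s / %s: fewer than 3 pairs", rule$label, gas))
        next
      }
      agree_rows[[length(agree_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(range = rule$label, gas = gas), stats
      )
    }
  }
  out <- list(descriptive = dplyr::bind_rows(desc_rows),
              agreement = dplyr::bind_rows(agree_rows))
  attr(out, "omitted_cells") <- omitted
  out
}

#' Per-group percent differences and their cross-group average
#'
#' Computes `(a - b) / b * 100` per group (sign preserved) and the
#' unweighted mean across groups. This is the arithmetic behind
#' cross-experiment summaries such as "relaxing the threshold increased
#' visits per animal by x% on average".
#'
#' @param a numeric vector of group values (e.g. one value per
#'   experiment).
#' @param b numeric reference values, same length and order as `a`; all
#'   nonzero.
#' @param labels optional group labels.
#' @return list with `per_group` (named numeric vector of percent
#'   differences) and `mean` (unweighted mean percent difference).
#' @export
percent_difference_summary <- function(a, b, labels = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (any(b == 0)) stop("zero reference value")
  pct <- 100 * (a - b) / b
  if (!is.null(labels)) names(pct) <- labels
  list(per_group = pct, mean = mean(pct))
}

#' Study days required to accumulate a visit quota
#'
#' How long an experiment must run for an animal visiting at a given
#' daily rate to accumulate `n_required` qualifying visits. Reported raw
#' and rounded up to whole days.
#'
#' @param n_required number of qualifying visits needed per animal.
#' @param visits_per_day qualifying visits per day (positive).
#' @return list with `days_raw` and `days` (= `ceiling(days_raw)`).
#' @export
study_days_required <- function(n_required, visits_per_day) {
  if (any(visits_per_day <= 0)) stop("visits_per_day must be positive")
  raw <- n_required / visits_per_day
  list(days_raw = raw, days = ceiling(raw))
}

#' Headline percentages derived from the published summary tables
#'
#' Recomputes, from the published per-threshold and per-range summary
#' statistics shipped with the package, the cross-experiment headline
#' percentages: visit-count gains from relaxing the threshold, the
#' shortfall of the all-visits flux estimates relative to >= 3 min, the
#' pooled per-range flux shortfalls relative to >= 3 min, and the
#' study-day arithmetic for 30-visit (>= 3 min) and 40-visit (>= 2 min)
#' quotas.
#'
#' @return named list of computed quantities (see source for the keys).
#' @export
reference_derived_percentages <- function() {
  thr <- reference_threshold_stats()
  rng <- reference_range_stats()
  pick <- function(metric, rule) {
    x <- thr[thr$metric == metric & thr$rule == rule, ]
    setNames(x$mean, x$experiment)
  }
  rpick <- function(metric, range) {
    rng$mean[rng$metric == metric & rng$range == range]
  }
  out <- list()
  # visit-count gain of relaxed thresholds over >=3 min, per experiment
  for (rule in c("ge2", "ge1", "all")) {
    out[[paste0("visits_gain_", rule, "_pct")]] <-
      percent_difference_summary(pick("n_visits", rule), pick("n_visits", "ge3"),
                                 labels = names(pick("n_visits", "ge3")))
  }
  # >=3 min flux estimates relative to the all-visits estimates
  for (gas in c("co2", "o2", "ch4")) {
    out[[paste0(gas, "_ge3_vs_all_pct")]] <-
      percent_difference_summary(pick(gas, "ge3"), pick(gas, "all"),
                                 labels = names(pick(gas, "ge3")))
  }
  # pooled per-range shortfalls vs the >=3 min gold column
  for (gas in c("co2", "o2", "ch4")) {
    for (range in c("lt1", "r12", "r23", "r34", "r45", "r56", "ge6")) {
      out[[paste0(gas, "_range_", range, "_pct")]] <-
        percent_difference_summary(rpick(gas, range), rpick(gas, "ge3"))$mean
    }
  }
  # study-day arithmetic: grazing rates (lowest visit rate among the
  # grazing experiments) and the feedlot experiment, at the 30-visit
  # (>=3 min) and 40-visit (>=2 min) quotas
  vpd_ge3 <- pick("visits_per_day", "ge3")
  vpd_ge2 <- pick("visits_per_day", "ge2")
  out$study_days_ge3 <- lapply(vpd_ge3, function(v) study_days_required(30, v))
  out$study_days_ge2 <- lapply(vpd_ge2, function(v) study_days_required(40, v))
  # average relative increase in study days from moving to the 2-min
  # threshold quota (raw days, unweighted across experiments)
  incr <- 100 * (40 / vpd_ge2 - 30 / vpd_ge3) / (30 / vpd_ge3)
  out$study_days_increase_ge2_pct <- list(per_group = incr, mean = mean(incr))
  out
}
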