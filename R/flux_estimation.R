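#' Visit-duration rules
#'
#' A duration rule selects the spot samples that enter a per-animal
#' average: either a threshold (at least `lower` minutes, no upper limit)
#' or a half-open range `[lower, upper)`. The conventional candidates are
#' thresholds of 3, 2 and 1 min and "all visits" (threshold 0), with the
#' mean over all visits of at least 3 min serving as the gold standard.
#'
#' @param lower inclusive lower bound, minutes.
#' @param upper exclusive upper bound, minutes; `Inf` for a threshold rule.
#' @return list of class `duration_rule` with fields `kind`
#'   (`"threshold"` or `"range"`), `lower`, `upper` and a display `label`.
#' @export
duration_rule <- function(lower, upper = Inf) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  kind <- if (is.infinite(upper)) "threshold" else "range"
  label <- if (is.infinite(upper)) {
    if (lower <= 0) "all" else sprintf(">=%g min", lower)
  } else {
    sprintf("[%g,%g) min", lower, upper)
  }
  structure(list(kind = kind, lower = lower, upper = upper, label = label),
            class = "duration_rule")
}

#' @rdname duration_rule
#' @export
rule_all_visits <- function() duration_rule(0)

#' @export
print.duration_rule <- function(x, ...) {
  cat("<duration_rule> ", x$label, "\n", sep = "")
  invisible(x)
}

# Logical vector: which durations satisfy the rule.
rule_qualifies <- function(duration, rule) {
  duration >= rule$lower & duration < rule$upper
}

# The seven conventional duration ranges: <1, [1,2), ..., [5,6), >=6 min.
# They partition (0, Inf), so every visit falls in exactly one.
#' Default duration-range partition
#'
#' @return list of seven [duration_rule()] objects: `<1`, `[1,2)`,
#'   `[2,3)`, `[3,4)`, `[4,5)`, `[5,6)` and `>=6` minutes.
#' @export
default_duration_ranges <- function() {
  breaks <- c(0, 1, 2, 3, 4, 5, 6, Inf)
  lapply(seq_len(7), function(i) duration_rule(breaks[i], breaks[i + 1]))
}

#' Time-of-day binning scheme
#'
#' Bins must partition the clock day `[0, 24)` with half-open intervals.
#' The default is eight 3-h bins starting at midnight.
#'
#' @param breaks increasing numeric vector of bin boundaries in hours,
#'   starting at 0 and ending at 24.
#' @return list of class `time_bin_scheme`.
#' @export
time_bin_scheme <- function(breaks = seq(0, 24, by = 3)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2,
            breaks[1] == 0, breaks[length(breaks)] == 24,
            all(diff(breaks) > 0))
  structure(list(breaks = breaks, n_bins = length(breaks) - 1),
            class = "time_bin_scheme")
}

# Filter a visit table to records qualifying under `rule` that carry the
# requested gas.
qualifying_visits <- function(table, gas, rule) {
  col <- gas_column(gas)
  keep <- rule_qualifies(table$duration_min, rule) & !is.na(table[[col]])
  table[keep, ]
}

#' Per-animal flux estimates by arithmetic averaging
#'
#' The daily flux estimate for one gas is the arithmetic mean of the gas
#' values over an animal's qualifying visits. Animals with zero
#' qualifying visits are omitted from the result and listed in the
#' `omitted` attribute.
#'
#' @param table a QC-filtered [visit_table()].
#' @param gas `"co2"`, `"o2"` or `"ch4"`.
#' @param rule a [duration_rule()].
#' @return tibble with columns `animal_id`, `experiment_id`, `gas`,
#'   `estimate` (g/d), `n_visits`, `rule`, `method`; attribute `omitted`
#'   holds the ids of animals with no qualifying visit.
#' @export
arithmetic_estimates <- function(table, gas, rule = duration_rule(3)) {
  gas <- match.arg(gas, names(GAS_COLS))
  col <- gas_column(gas)
  q <- qualifying_visits(table, gas, rule)
  est <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(q), .data$animal_id, .data$experiment_id),
    gas = gas,
    estimate = mean(.data[[col]]),
    n_visits = dplyr::n(),
    .groups = "drop"
  )
  est$rule <- rule$label
  est$method <- "arithmetic"
  attr(est, "omitted") <- setdiff(unique(table$animal_id), est$animal_id)
  est
}

#' Per-animal flux estimates by time-bin averaging
#'
#' Qualifying visits are assigned to time-of-day bins by their start
#' time's clock hour; the within-bin mean is computed, and the daily
#' estimate is the unweighted mean of the means of occupied bins (empty
#' bins are excluded rather than imputed). This weights the day uniformly
#' across occupied bins, at the cost of letting sparsely visited bins
#' carry as much weight as dense ones; `n_bins_occupied` is reported so
#' users can filter.
#'
#' @inheritParams arithmetic_estimates
#' @param scheme a [time_bin_scheme()].
#' @return tibble as [arithmetic_estimates()] plus `n_bins_occupied`;
#'   `method` is `"time_bin"`.
#' @export
time_bin_estimates <- function(table, gas, rule = duration_rule(3),
                               scheme = time_bin_scheme()) {
  gas <- match.arg(gas, names(GAS_COLS))
  col <- gas_column(gas)
  q <- qualifying_visits(table, gas, rule)
  bin <- findInterval(hour_of_day(q$start_time), scheme$breaks,
                      rightmost.closed = FALSE)
  q$`..bin` <- bin
  per_bin <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(q), .data$animal_id, .data$experiment_id,
                    .data$`..bin`),
    bin_mean = mean(.data[[col]]),
    bin_n = dplyr::n(),
    .groups = "drop_last"
  )
  est <- dplyr::summarise(
    per_bin,
    gas = gas,
    estimate = mean(.data$bin_mean),
    n_visits = sum(.data$bin_n),
    n_bins_occupied = dplyr::n(),
    .groups = "drop"
  )
  est$rule <- rule$label
  est$method <- "time_bin"
  attr(est, "omitted") <- setdiff(unique(table$animal_id), est$animal_id)
  est[c("animal_id", "experiment_id", "gas", "estimate", "n_visits",
        "n_bins_occupied", "rule", "method")]
}

#' Mean difference between two sets of per-animal estimates
#'
#' Signed mean of the per-animal differences `a - b`, paired by
#' `animal_id`, with the percent expressed against the mean of `b`.
#'
#' @param a,b estimate tibbles (as returned by [arithmetic_estimates()] or
#'   [time_bin_estimates()]) for the same gas.
#' @return list with `mean_diff` (g/d), `percent` (% of `b`'s mean) and
#'   `n_pairs`.
#' @export
method_difference <- function(a, b) {
  pairs <- dplyr::inner_join(
    a[c("animal_id", "estimate")], b[c("animal_id", "estimate")],
    by = "animal_id", suffix = c("_a", "_b")
  )
  if (nrow(pairs) == 0) stop("no animals in common between the two estimate sets")
  mean_diff <- mean(pairs$estimate_a - pairs$estimate_b)
  list(mean_diff = mean_diff,
       percent = 100 * mean_diff / mean(pairs$estimate_b),
       n_pairs = nrow(pairs))
}
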