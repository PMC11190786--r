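#' Design of the random visit-subsampling experiment
#'
#' The subsampling experiment asks: under a given visit-duration
#' threshold, how many visits per animal are needed before the
#' per-animal flux estimate agrees "excellently" (CCC at or above
#' `ccc_cut`) with the gold standard (the mean of ALL of the animal's
#' QC-passed visits >= 3 min)? For every (threshold x visit count)
#' combination, each animal's estimate is recomputed from a uniform
#' random subset of exactly `n` qualifying visits drawn without
#' replacement, and agreement across animals is measured; replicates of
#' the draw stabilise the CCC.
#'
#' Eligibility defaults to the largest grid value so the animal set is
#' constant across the whole grid; set `eligibility` lower to trade a
#' varying animal set for wider inclusion.
#'
#' @param thresholds numeric vector of minimum visit durations (minutes)
#'   to compare, each used as a threshold rule.
#' @param n_grid strictly increasing visit counts (all >= 2).
#' @param replicates random subsample draws per grid cell (>= 1; use 1
#'   for a single-draw design).
#' @param seed integer seed controlling the whole experiment.
#' @param eligibility minimum qualifying visits an animal must have under
#'   a threshold to enter that threshold's comparisons.
#' @param ccc_cut CCC value taken as excellent agreement.
#' @return list of class `subsampling_design`.
#' @export
subsampling_design <- function(thresholds = c(3, 2, 1),
                               n_grid = seq(5, 60, by = 5),
                               replicates = 100,
                               seed = 1L,
                               eligibility = max(n_grid),
                               ccc_cut = 0.90) {
  stopifnot(length(n_grid) >= 1, all(n_grid >= 2), all(diff(n_grid) > 0),
            replicates >= 1, ccc_cut > 0, ccc_cut <= 1)
  structure(list(thresholds = thresholds, n_grid = as.integer(n_grid),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 eligibility = as.integer(eligibility), ccc_cut = ccc_cut),
            class = "subsampling_design")
}

#' Animals with enough qualifying visits
#'
#' @param table a QC-filtered [visit_table()].
#' @param threshold a [duration_rule()] (or a number, taken as a
#'   threshold in minutes).
#' @param min_visits minimum qualifying visit count.
#' @return character vector of eligible `animal_id`s.
#' @export
eligible_animals <- function(table, threshold, min_visits) {
  if (is.numeric(threshold)) threshold <- duration_rule(threshold)
  q <- table[rule_qualifies(table$duration_min, threshold), ]
  counts <- table(q$animal_id)
  names(counts)[counts >= min_visits]
}

# Per-animal matrices of qualifying gas values under a threshold rule,
# for fast repeated subsampling. Returns a named list of (m x 3)
# matrices with columns co2, o2, ch4.
qualifying_matrices <- function(table, rule, animals) {
  out <- vector("list", length(animals))
  names(out) <- animals
  q <- table[rule_qualifies(table$duration_min, rule), ]
  for (a in animals) {
    qa <- q[q$animal_id == a, ]
    out[[a]] <- cbind(co2 = qa$co2_gpd, o2 = qa$o2_gpd, ch4 = qa$ch4_gpd)
  }
  out
}

#' Subsampled per-animal estimates for all gases
#'
#' Draws, for each included animal, a uniform random subset of exactly
#' `n` qualifying visits without replacement and returns the arithmetic
#' mean per gas. Every included animal must have at least `n` qualifying
#' visits.
#'
#' @inheritParams eligible_animals
#' @param n number of visits to draw per animal.
#' @param animals animal ids to include; defaults to all animals with at
#'   least `n` qualifying visits.
#' @return tibble with columns `animal_id`, `co2`, `o2`, `ch4`,
#'   `n_visits`. Uses the current RNG state; seed it for reproducibility.
#' @export
subsample_estimates <- function(table, threshold, n, animals = NULL) {
  if (is.numeric(threshold)) threshold <- duration_rule(threshold)
  if (is.null(animals)) animals <- eligible_animals(table, threshold, n)
  mats <- qualifying_matrices(table, threshold, animals)
  short <- vapply(mats, nrow, integer(1)) < n
  if (any(short)) {
    stop("animal(s) with fewer than n qualifying visits: ",
         paste(names(mats)[short], collapse = ", "))
  }
  est <- t(vapply(mats, function(m) {
    idx <- sample.int(nrow(m), n)
    colMeans(m[idx, , drop = FALSE])
  }, numeric(3)))
  tibble::tibble(animal_id = names(mats), co2 = unname(est[, 1]),
                 o2 = unname(est[, 2]), ch4 = unname(est[, 3]), n_visits = n)
}

#' Run the full subsampling grid
#'
#' For every (threshold x n x replicate) cell, subsamples each eligible
#' animal's qualifying visits, computes per-animal estimates for all
#' three gases, and measures agreement with the gold standard. The gold
#' standard per animal is the arithmetic mean of ALL its >= 3-min
#' QC-passed visits and is never subsampled, so it is identical across
#' all grid cells. One constant animal set is used for the whole
#' experiment: animals eligible under EVERY threshold (and with gold
#' visits), so comparisons between thresholds are over the same animals.
#' Per-cell RNG seeds are derived once from the design seed, making
#' every cell independently reproducible; cells at the same
#' (n, replicate) share their seed across thresholds (common random
#' numbers), so between-threshold contrasts are not blurred by
#' independent sampling noise.
#'
#' @param table a QC-filtered [visit_table()].
#' @param design a [subsampling_design()].
#' @return list of class `subsampling_result` with elements `results`
#'   (long tibble: `gas`, `threshold`, `n`, `replicate`, `r`, `Cb`,
#'   `ccc`, `rmse_pct`, `n_pairs`, `mean_estimate`), `decisions` (from
#'   [minimum_visits()]), `gold` (per-animal gold estimates), `eligible`
#'   (the shared animal set) and `design`.
#' @export
run_grid <- function(table, design = subsampling_design()) {
  gold_rule <- duration_rule(3)
  thr_rules <- lapply(design$thresholds, duration_rule)
  thr_labels <- vapply(thr_rules, `[[`, character(1), "label")

  # constant animal set: supports the largest n under every threshold
  # AND has gold visits
  gold_tbl <- table[rule_qualifies(table$duration_min, gold_rule), ]
  shared <- unique(gold_tbl$animal_id)
  for (r in thr_rules) {
    shared <- intersect(shared, eligible_animals(table, r, design$eligibility))
  }
  if (length(shared) < 3) {
    stop("fewer than 3 animals eligible under every threshold")
  }
  eligible <- sort(shared)

  gold_est <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(gold_tbl), .data$animal_id),
    co2 = mean(.data$co2_gpd, na.rm = TRUE),
    o2 = mean(.data$o2_gpd, na.rm = TRUE),
    ch4 = mean(.data$ch4_gpd, na.rm = TRUE),
    .groups = "drop"
  )
  gold_vec <- list(
    co2 = setNames(gold_est$co2, gold_est$animal_id),
    o2 = setNames(gold_est$o2, gold_est$animal_id),
    ch4 = setNames(gold_est$ch4, gold_est$animal_id)
  )

  n_shared_cells <- length(design$n_grid) * design$replicates
  set.seed(design$seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_shared_cells),
                       nrow = length(design$n_grid))

  animals <- eligible
  golds <- lapply(gold_vec, function(g) g[animals])
  n_rows <- n_shared_cells * length(thr_rules) * 3
  col_gas <- character(n_rows)
  col_thr <- character(n_rows)
  col_n <- integer(n_rows)
  col_rep <- integer(n_rows)
  col_r <- col_cb <- col_ccc <- col_rmse <- col_meanest <- numeric(n_rows)
  gases <- c("co2", "o2", "ch4")
  ri <- 0L
  for (ti in seq_along(thr_rules)) {
    rule <- thr_rules[[ti]]
    mats <- qualifying_matrices(table, rule, animals)
    for (ni in seq_along(design$n_grid)) {
      n <- design$n_grid[ni]
      for (rep_k in seq_len(design$replicates)) {
        set.seed(cell_seeds[ni, rep_k])
        est <- matrix(0, nrow = length(animals), ncol = 3)
        for (ai in seq_along(animals)) {
          m <- mats[[ai]]
          idx <- sample.int(nrow(m), n)
          est[ai, ] <- colMeans(m[idx, , drop = FALSE])
        }
        for (gi in seq_len(3)) {
          cc <- lin_ccc(est[, gi], golds[[gases[gi]]])
          ri <- ri + 1L
          col_gas[ri] <- gases[gi]
          col_thr[ri] <- thr_labels[ti]
          col_n[ri] <- n
          col_rep[ri] <- rep_k
          col_r[ri] <- cc$r
          col_cb[ri] <- cc$Cb
          col_ccc[ri] <- cc$ccc
          col_rmse[ri] <- rmse_percent(est[, gi], golds[[gases[gi]]])
          col_meanest[ri] <- mean(est[, gi])
        }
      }
    }
  }

  results <- tibble::tibble(
    gas = col_gas, threshold = col_thr, n = col_n, replicate = col_rep,
    r = col_r, Cb = col_cb, ccc = col_ccc, rmse_pct = col_rmse,
    n_pairs = length(animals), mean_estimate = col_meanest
  )
  out <- list(results = results,
              decisions = minimum_visits(results, design$ccc_cut),
              gold = gold_est, eligible = eligible, design = design)
  class(out) <- "subsampling_result"
  out
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat("<subsampling_result> ", nrow(x$results), " cells (",
      length(unique(x$results$threshold)), " thresholds x ",
      length(unique(x$results$n)), " visit counts x ",
      max(x$results$replicate), " replicates)\n", sep = "")
  print(x$decisions)
  invisible(x)
}

#' Minimum visits achieving the concordance target
#'
#' For each (gas x threshold), averages CCC over replicates at each `n`
#' and reports the smallest `n` whose replicate-mean CCC reaches
#' `ccc_cut` (first-crossing rule). Sequences whose replicate-mean CCC is
#' not non-decreasing in `n` are flagged via `monotone = FALSE`.
#'
#' @param results the `results` tibble of a [run_grid()] output (or a
#'   `subsampling_result`).
#' @param ccc_cut CCC value taken as excellent agreement.
#' @return tibble with columns `gas`, `threshold`, `n_min` (`NA` when
#'   the cut is never reached), `reached`, `monotone`.
#' @export
minimum_visits <- function(results, ccc_cut = 0.90) {
  if (inherits(results, "subsampling_result")) results <- results$results
  means <- dplyr::summarise(
    dplyr::group_by(results, .data$gas, .data$threshold, .data$n),
    mean_ccc = mean(.data$ccc), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(means, .data$gas, .data$threshold),
    n_min = {
      o <- order(.data$n)
      hit <- which(.data$mean_ccc[o] >= ccc_cut)
      if (length(hit)) .data$n[o][hit[1]] else NA_integer_
    },
    reached = !is.na(.data$n_min),
    monotone = all(diff(.data$mean_ccc[order(.data$n)]) >= -1e-12),
    .groups = "drop"
  )
}
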