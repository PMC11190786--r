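#' Pearson correlation (precision component)
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return the product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y)
  cor(x, y)
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired vectors")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the vectors")
  invisible(TRUE)
}

#' Lin's concordance correlation coefficient
#'
#' Computes agreement between paired measurements as
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2}}
#' using population (divide-by-n) variances and covariance, which is
#' Lin's original estimator. The CCC factors into a precision component
#' (Pearson's r) and an accuracy component, the bias correction factor
#' \eqn{C_b = CCC / r}, which penalises location and scale shifts;
#' \eqn{C_b} is reported as `NA` when `r` is within 1e-12 of zero.
#'
#' @inheritParams pearson_r
#' @return list with elements `r`, `Cb` and `ccc`.
#' @export
lin_ccc <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  dy <- y - my
  sx2 <- sum(dx * dx) / n
  sy2 <- sum(dy * dy) / n
  sxy <- sum(dx * dy) / n
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  Cb <- if (abs(r) < 1e-12) NA_real_ else ccc / r
  list(r = r, Cb = Cb, ccc = ccc)
}

#' RMSE as a percent of the gold-standard mean
#'
#' @param candidate,gold paired numeric vectors; `mean(gold)` must be
#'   nonzero.
#' @return `sqrt(mean((candidate - gold)^2)) / mean(gold) * 100`.
#' @export
rmse_percent <- function(candidate, gold) {
  if (length(candidate) != length(gold)) stop("vectors must have equal length")
  if (anyNA(candidate) || anyNA(gold)) stop("missing values in paired vectors")
  g <- mean(gold)
  if (g == 0) stop("gold-standard mean is zero")
  100 * sqrt(mean((candidate - gold)^2)) / g
}

#' Compare candidate estimates against a gold standard
#'
#' Pairs two per-animal estimate sets by `animal_id` (animals present on
#' only one side are dropped and counted) and computes the full agreement
#' battery: Pearson r (precision), bias correction factor Cb (accuracy),
#' Lin's CCC (agreement) and RMSE as a percent of the gold-standard mean.
#'
#' @param candidate,gold estimate tibbles for the same gas, with columns
#'   `animal_id` and `estimate`.
#' @return one-row tibble: `r`, `Cb`, `ccc`, `rmse_pct`, `n_pairs`,
#'   `n_dropped`.
#' @export
compare_estimates <- function(candidate, gold) {
  if ("gas" %in% names(candidate) && "gas" %in% names(gold)) {
    if (!identical(unique(candidate$gas), unique(gold$gas))) {
      stop("candidate and gold estimates are for different gases")
    }
  }
  pairs <- dplyr::inner_join(
    candidate[c("animal_id", "estimate")], gold[c("animal_id", "estimate")],
    by = "animal_id", suffix = c("_cand", "_gold")
  )
  n_dropped <- length(union(candidate$animal_id, gold$animal_id)) - nrow(pairs)
  if (nrow(pairs) < 3) stop("fewer than 3 pairable animals")
  cc <- lin_ccc(pairs$estimate_cand, pairs$estimate_gold)
  tibble::tibble(
    r = cc$r, Cb = cc$Cb, ccc = cc$ccc,
    rmse_pct = rmse_percent(pairs$estimate_cand, pairs$estimate_gold),
    n_pairs = nrow(pairs), n_dropped = n_dropped
  )
}
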