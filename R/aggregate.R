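# Aggregation of per-person Bayes factors for one fixed comparison into the
# P-population summaries:
#   P-BF   product of the P individual Bayes factors
#   gP-BF  geometric mean, the expected BF for a next sampled person
#   ER     evidence rate: proportion of individual BFs on the same side of 1
#          as the gP-BF (homogeneity)
#   SR     stability rate: proportion of individual BFs strictly more extreme
#          than the gP-BF on its side (skewness / influential cases)
# Indicator counts use strict inequalities; a BF exactly equal to 1 (or to
# the gP-BF) counts for neither side.  When gP-BF is exactly 1 the ER and SR
# are undefined and returned as NA.

check_bf_vector <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("need at least one Bayes factor (P >= 1)",
                          call. = FALSE)
  if (any(is.na(x)) || any(x < 0)) {
    stop("Bayes factors must be non-negative and non-missing", call. = FALSE)
  }
  x
}

#' Product of individual Bayes factors (P-BF)
#'
#' The P-population Bayes factor for "the hypothesis holds for every person",
#' computed in log space.  Any individual Bayes factor of 0 annihilates the
#' product.  Note that the P-BF grows (or shrinks) with P even when each
#' person contributes the same evidence.
#'
#' @param x Numeric vector of `P` per-person Bayes factors for one fixed
#'   comparison.
#' @return A single number.
#' @export
p_bf <- function(x) {
  x <- check_bf_vector(x)
  if (any(x == 0)) return(0)
  exp(sum(log(x)))
}

#' Geometric mean of individual Bayes factors (gP-BF)
#'
#' The P-th root of the P-BF: the "average" relative evidence per person,
#' independent of P, interpretable as the Bayes factor expected for the
#' (P+1)-st person sampled from the same population.
#'
#' @inheritParams p_bf
#' @return A single number; 0 when any individual Bayes factor is 0.
#' @export
gp_bf <- function(x) {
  x <- check_bf_vector(x)
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Evidence rate (ER)
#'
#' Consistency of the preferred hypothesis across persons: the proportion of
#' individual Bayes factors on the same side of 1 as the gP-BF.  Strict
#' inequalities; undefined (NA) when `gp` equals 1 exactly.
#'
#' @inheritParams p_bf
#' @param gp The gP-BF that fixes which side is counted; defaults to
#'   `gp_bf(x)`.  Supplying it explicitly supports censored inputs where the
#'   side is known from a published gP-BF but not computable from bounds.
#' @return Proportion in `[0, 1]`, or `NA` when `gp == 1`.
#' @export
evidence_rate <- function(x, gp = gp_bf(x)) {
  x <- check_bf_vector(x)
  if (gp == 1) return(NA_real_)
  if (gp > 1) mean(x > 1) else mean(x < 1)
}

#' Stability rate (SR)
#'
#' Skewness of the individual Bayes factors around the gP-BF: the proportion
#' strictly more extreme than the gP-BF on its side.  Values near .5 indicate
#' an even spread; small values flag a gP-BF driven by a minority of extreme
#' persons.  Strict inequalities; undefined (NA) when `gp` equals 1 exactly.
#'
#' @inheritParams evidence_rate
#' @return Proportion in `[0, 1]`, or `NA` when `gp == 1`.
#' @export
stability_rate <- function(x, gp = gp_bf(x)) {
  x <- check_bf_vector(x)
  if (gp == 1) return(NA_real_)
  if (gp > 1) mean(x > gp) else mean(x < gp)
}

#' Aggregate per-person Bayes factors over persons, per comparison
#'
#' Computes P-BF, gP-BF, ER and SR for each comparison present in the data.
#' Comparisons are never mixed: the gP-BF of "m versus unconstrained" cannot
#' be translated into "m versus complement", so each is aggregated from its
#' own per-person Bayes factors.
#'
#' Censored published Bayes factors (e.g. printed as "< 0.01") are accepted
#' via the `censor` column (`"lt"` marks `bf` as an upper bound).  The gP-BF
#' is then computed from the bound value and flagged: it is an upper bound
#' on the true gP-BF, and its side (above/below 1) may differ from the side
#' of the true gP-BF.
#'
#' @param data Data frame with columns `comparison`, `bf` and optionally
#'   `person` and `censor` — e.g. the output of [bf_long()] or a CSV of
#'   published per-person Bayes factors.
#' @param gp_override Optional named vector mapping comparison tags to a
#'   known gP-BF used as the side-defining reference for ER and SR (for
#'   censored tables whose true gP-BF is published but not computable from
#'   the bounds).
#' @return A tibble of class `nof1_aggregate`: one row per comparison with
#'   `comparison`, `n` (P), `p_bf`, `gp_bf`, `er`, `sr` and flag columns
#'   `any_zero`, `censored`, `undefined` (gP-BF exactly 1).
#' @examples
#' set1 <- tibble::tibble(comparison = "Hm_vs_u", bf = c(9, 7.11))
#' aggregate_bf(set1)
#' @export
aggregate_bf <- function(data, gp_override = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("no Bayes factors to aggregate", call. = FALSE)
  if (!all(c("comparison", "bf") %in% names(data))) {
    stop("`data` needs columns `comparison` and `bf`", call. = FALSE)
  }
  if (!"censor" %in% names(data)) data$censor <- NA_character_
  out <- data |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      n = dplyr::n(),
      p_bf = p_bf(.data$bf),
      gp_bf = gp_bf(.data$bf),
      any_zero = any(.data$bf == 0),
      censored = any(!is.na(.data$censor) & .data$censor != ""),
      bfs = list(.data$bf),
      .groups = "drop"
    )
  gp_side <- out$gp_bf
  if (!is.null(gp_override)) {
    idx <- match(out$comparison, names(gp_override))
    gp_side <- ifelse(is.na(idx), gp_side, gp_override[idx])
  }
  out$er <- purrr::map2_dbl(out$bfs, gp_side, ~ evidence_rate(.x, gp = .y))
  out$sr <- purrr::map2_dbl(out$bfs, gp_side, ~ stability_rate(.x, gp = .y))
  out$undefined <- gp_side == 1
  out <- dplyr::select(out, "comparison", "n", "p_bf", "gp_bf", "er", "sr",
                       "any_zero", "censored", "undefined")
  class(out) <- c("nof1_aggregate", class(out))
  out
}

#' @export
print.nof1_aggregate <- function(x, ...) {
  cat("# P-population aggregation of per-person Bayes factors\n")
  print(round_bf_cols(tibble::as_tibble(x)), ...)
  if (any(x$censored)) {
    cat("# Note: comparisons with censored inputs report gP-BF computed\n",
        "# from bound values; treat those gP-BF as upper bounds\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nof1_aggregate <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.nof1_aggregate <- function(x, ...) {
  tibble::tibble(n_comparisons = nrow(x), n_persons = max(x$n),
                 any_zero = any(x$any_zero), any_censored = any(x$censored))
}

#' @exportS3Method ggplot2::autoplot
autoplot.nof1_aggregate <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$gp_bf)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("ER %.2f\nSR %.2f", .data$er, .data$sr)),
      vjust = -0.2, size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "gP-BF (log scale)")
}
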