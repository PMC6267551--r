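# Complexity, fit and Bayes factors for one person.
#
# Complexity c_m is the proportion of the uniform encompassing prior in
# agreement with H_m; fit f_m is the proportion of the unconstrained
# posterior in agreement with H_m.  BF_mu = f_m / c_m; the pairwise and
# complement Bayes factors derive from it.  All hypotheses in a set are
# evaluated against one shared prior pool and one shared posterior pool per
# person, which makes the pairwise ratio identity exact and cuts Monte Carlo
# noise.

mc_estimate <- function(value, n_draws, analytic = NA_real_) {
  structure(
    list(value = value,
         std_error = sqrt(value * (1 - value) / n_draws),
         n_draws = n_draws,
         analytic = analytic),
    class = "nof1_mc"
  )
}

#' @export
print.nof1_mc <- function(x, ...) {
  cat(sprintf("<nof1_mc> %.4f (MC se %.2g, N = %g)", x$value, x$std_error,
              x$n_draws))
  if (!is.na(x$analytic)) cat(sprintf(", analytic %.6g", x$analytic))
  cat("\n")
  invisible(x)
}

mc_value <- function(x) if (inherits(x, "nof1_mc")) x$value else as.numeric(x)
mc_se <- function(x) if (inherits(x, "nof1_mc")) x$std_error else 0

# Proportion of a pool inside the hypothesis region.  The complement is
# scored as 1 minus the informative proportion on the same pool, which
# assigns (probability-zero) boundary hits to the complement and guarantees
# fit + complement fit = 1 on shared pools.
prop_in_region <- function(h, pool) {
  margins <- pool %*% t(h$matrix)
  p_in <- mean(rowSums(margins > 0) == ncol(margins))
  if (h$kind == "informative") p_in else 1 - p_in
}

#' Estimate the complexity of a hypothesis
#'
#' Monte Carlo estimate of the proportion of the uniform encompassing prior
#' satisfying the hypothesis' constraints.  For a complete simple ordering of
#' all `J` conditions the exact value `1/J!` is attached alongside the
#' estimate (field `analytic`).
#'
#' @param h An informative or complement `nof1_hypothesis`.
#' @param n_draws Prior pool size N (default `1e5`).
#' @param seed Optional integer seed.
#' @param pool Optional pre-sampled prior pool (an `n x J` matrix), e.g. to
#'   share one pool across all hypotheses of a set.
#' @return An `nof1_mc` estimate: `value`, `std_error`, `n_draws`,
#'   `analytic`.
#' @export
estimate_complexity <- function(h, n_draws = 1e5, seed = NULL, pool = NULL) {
  stopifnot(inherits(h, "nof1_hypothesis"))
  if (h$kind == "unconstrained") {
    return(mc_estimate(1, n_draws, analytic = 1))
  }
  if (is.null(pool)) {
    pool <- sample_product(uniform_prior(h$layout), n_draws, seed)
  }
  mc_estimate(prop_in_region(h, pool), nrow(pool),
              analytic = analytic_complexity(h))
}

#' Estimate the fit of a hypothesis
#'
#' Monte Carlo estimate of the proportion of the unconstrained posterior
#' satisfying the hypothesis' constraints.  The complement's fit is computed
#' on the same pool as one minus the informative fit.
#'
#' @param h An informative or complement `nof1_hypothesis`.
#' @param posterior An `nof1_beta_product` from [posterior_update()].
#' @param n_draws Posterior pool size N (default `1e5`).
#' @param seed Optional integer seed.
#' @param pool Optional pre-sampled posterior pool.
#' @return An `nof1_mc` estimate.
#' @export
estimate_fit <- function(h, posterior, n_draws = 1e5, seed = NULL,
                         pool = NULL) {
  stopifnot(inherits(h, "nof1_hypothesis"))
  if (h$kind == "unconstrained") return(mc_estimate(1, n_draws, analytic = 1))
  if (is.null(pool)) pool <- sample_product(posterior, n_draws, seed)
  mc_estimate(prop_in_region(h, pool), nrow(pool))
}

propagate_se <- function(value, dfd, se_f, dcd, se_c) {
  sqrt((dfd * se_f)^2 + (dcd * se_c)^2)
}

#' Bayes factor of a hypothesis against the unconstrained hypothesis
#'
#' `BF_mu = f_m / c_m`: the change in relative belief for `H_m` versus `H_u`
#' caused by the data.  By construction it ranges from 0 to `1/c_m`.
#'
#' @param fit,complexity `nof1_mc` estimates (or bare numbers).
#' @return The Bayes factor, with the propagated Monte Carlo standard error
#'   in attribute `"se"`.
#' @export
bf_vs_unconstrained <- function(fit, complexity) {
  f <- mc_value(fit); cc <- mc_value(complexity)
  if (cc == 0) {
    stop("complexity estimate is 0: the hypothesis region was never hit at ",
         "this pool size; increase the number of draws", call. = FALSE)
  }
  value <- f / cc
  se <- propagate_se(value, 1 / cc, mc_se(fit), f / cc^2, mc_se(complexity))
  structure(value, se = se)
}

#' Bayes factor of a hypothesis against its complement
#'
#' `(f/c) / ((1-f)/(1-c))`: does the data support `H_m` or "not `H_m`"?
#' Unlike `BF_mu`, this ratio ranges from 0 to infinity, which makes it the
#' natural yardstick for whether the best hypothesis is also a *good* one.
#'
#' @param fit,complexity `nof1_mc` estimates (or bare numbers) for the
#'   informative hypothesis.
#' @return The Bayes factor with attribute `"se"`.  `fit = 1` returns `Inf`
#'   with a warning (the complement was never hit at this pool size);
#'   `fit = 0` returns 0.
#' @export
bf_vs_complement <- function(fit, complexity) {
  f <- mc_value(fit); cc <- mc_value(complexity)
  if (cc <= 0 || cc >= 1) {
    stop("complexity must lie strictly between 0 and 1 for a complement ",
         "Bayes factor", call. = FALSE)
  }
  if (f == 1) {
    warning("fit estimate is exactly 1 at this pool size; the complement ",
            "Bayes factor is reported as Inf", call. = FALSE)
    return(structure(Inf, se = NA_real_))
  }
  if (f == 0) return(structure(0, se = 0))
  value <- (f / cc) / ((1 - f) / (1 - cc))
  dgdf <- (1 - cc) / (cc * (1 - f)^2)
  dgdc <- -(f / (1 - f)) / cc^2
  structure(value, se = propagate_se(value, dgdf, mc_se(fit), dgdc,
                                     mc_se(complexity)))
}

#' Pairwise Bayes factor between two informative hypotheses
#'
#' `BF_mm' = BF_mu / BF_m'u`, the ratio of the two marginal likelihoods.
#'
#' @param bf_mu,bf_mprime_u Bayes factors of `m` and `m'` versus the
#'   unconstrained hypothesis.
#' @return The pairwise Bayes factor (a bare number).
#' @export
bf_pairwise <- function(bf_mu, bf_mprime_u) {
  a <- as.numeric(bf_mu); b <- as.numeric(bf_mprime_u)
  if (b == 0) {
    warning("denominator Bayes factor is 0; pairwise Bayes factor reported ",
            "as Inf", call. = FALSE)
    return(Inf)
  }
  a / b
}

#' Select the best hypothesis for one person
#'
#' A hypothesis `m` is called best when its Bayes factor versus every other
#' hypothesis is at least `max(M - 1, 2)`, which guarantees a posterior
#' probability of at least .5 for `m` under equal prior probabilities.  The
#' threshold is one reasonable strategy, not a law, and can be overridden.
#'
#' @param bf_u Named vector of the `M` per-hypothesis Bayes factors versus
#'   the unconstrained hypothesis for one person.
#' @param threshold Decision threshold; defaults to `max(M - 1, 2)`.
#' @return A list with `best` (label, or `NA` when no hypothesis clears the
#'   threshold) and `threshold`.
#' @export
select_best <- function(bf_u, threshold = NULL) {
  m <- length(bf_u)
  if (m < 2) {
    return(list(best = NA_character_, threshold = NA_real_))
  }
  threshold <- threshold %||% max(m - 1, 2)
  labels <- names(bf_u) %||% paste0("H", seq_len(m))
  top <- which.max(bf_u)
  others <- bf_u[-top]
  ok <- all(bf_u[top] >= threshold * others)
  list(best = if (ok) labels[top] else NA_character_, threshold = threshold)
}

# ---------------------------------------------------------------------------
# Per-person evaluation over a data frame of counts
# ---------------------------------------------------------------------------

find_person_column <- function(data, layout) {
  candidates <- c("person_id", "person", "id")
  hit <- intersect(candidates, names(data))
  if (length(hit) > 0) return(hit[1])
  first <- names(data)[1]
  if (first %in% layout$conditions) {
    stop("no person identifier column found (expected 'person_id', ",
         "'person' or 'id', or a non-condition first column)", call. = FALSE)
  }
  first
}

#' Evaluate a set of informative hypotheses for every person
#'
#' For each person: the posterior over the `J` success probabilities is a
#' product of independent Betas; the fit of every hypothesis is estimated on
#' one shared posterior pool, complexities on one shared prior pool, and the
#' three Bayes factor families (versus unconstrained, versus complement,
#' pairwise) are formed.  The best-hypothesis decision rule is applied per
#' person.
#'
#' @param data Data frame with one row per person: a person identifier
#'   column (`person_id`, `person`, `id`, or the first column) and one
#'   integer count column per condition of the layout.
#' @param hypotheses An [hypothesis_set()] (or a single parsed hypothesis).
#' @param n_draws Pool size per person (and for the shared prior pool);
#'   default `1e5`.  Estimates carry MC standard errors `sqrt(p(1-p)/N)`.
#' @param seed Optional root seed; per-person child streams are derived
#'   deterministically from it.
#' @param threshold Decision threshold override for [select_best()].
#'
#' @return A tibble of class `nof1_eval` with one row per person x
#'   hypothesis: `person`, `hypothesis`, `complexity`, `complexity_se`,
#'   `fit`, `fit_se`, `bf_u` (vs unconstrained), `bf_u_se`, `bf_c` (vs
#'   complement).  Attributes: `pairwise` (long tibble of pairwise BFs),
#'   `decisions` (per-person best hypothesis and threshold), `meta`.
#'   [tidy()], [glance()] and [autoplot()] methods are available.
#' @examples
#' lay <- condition_layout(c("c1", "c2", "c3", "c4"), 7)
#' hs <- hypothesis_set(H1 = "c1 > c2 > c3 > c4",
#'                      H2 = "(c1 + c2)/2 > (c3 + c4)/2", layout = lay)
#' counts <- tibble::tibble(person_id = 1, c1 = 7, c2 = 5, c3 = 4, c4 = 1)
#' evaluate_hypotheses(counts, hs, n_draws = 2e4, seed = 1)
#' @export
evaluate_hypotheses <- function(data, hypotheses, n_draws = 1e5, seed = NULL,
                                threshold = NULL) {
  if (inherits(hypotheses, "nof1_hypothesis")) {
    hypotheses <- hypothesis_set(hypotheses)
  }
  stopifnot(inherits(hypotheses, "nof1_hset"))
  layout <- hypotheses$layout
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop("`data` has no persons", call. = FALSE)
  person_col <- find_person_column(data, layout)
  missing_cond <- setdiff(layout$conditions, names(data))
  if (length(missing_cond) > 0) {
    stop("missing condition column(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  persons <- data[[person_col]]
  if (anyDuplicated(persons)) {
    stop("duplicate person identifiers in `data`", call. = FALSE)
  }

  hyps <- hypotheses$hypotheses
  labels <- names(hyps)
  m <- length(hyps)
  seeds <- child_seeds(seed, nrow(data) + 1L)

  prior_pool <- sample_product(uniform_prior(layout), n_draws,
                               seeds[[1]])
  complexities <- lapply(hyps, estimate_complexity, pool = prior_pool)

  rows <- vector("list", nrow(data))
  pairwise_rows <- vector("list", nrow(data))
  decisions <- vector("list", nrow(data))
  prior <- uniform_prior(layout)
  for (i in seq_len(nrow(data))) {
    x <- unlist(data[i, layout$conditions])
    post <- posterior_update(prior, x)
    pool <- sample_product(post, n_draws, seeds[[i + 1L]])
    fits <- lapply(hyps, estimate_fit, posterior = post, pool = pool)
    bfu <- purrr::map2(fits, complexities, bf_vs_unconstrained)
    bfc <- purrr::map2(fits, complexities, bf_vs_complement)
    rows[[i]] <- tibble::tibble(
      person = persons[i],
      hypothesis = labels,
      complexity = unname(vapply(complexities, mc_value, numeric(1))),
      complexity_se = unname(vapply(complexities, mc_se, numeric(1))),
      fit = unname(vapply(fits, mc_value, numeric(1))),
      fit_se = unname(vapply(fits, mc_se, numeric(1))),
      bf_u = unname(vapply(bfu, as.numeric, numeric(1))),
      bf_u_se = unname(vapply(bfu, function(b) attr(b, "se"), numeric(1))),
      bf_c = unname(vapply(bfc, as.numeric, numeric(1)))
    )
    bfu_num <- stats::setNames(vapply(bfu, as.numeric, numeric(1)), labels)
    grid <- expand.grid(hypothesis = labels, vs = labels,
                        stringsAsFactors = FALSE)
    if (m > 1) grid <- grid[grid$hypothesis != grid$vs, , drop = FALSE]
    pairwise_rows[[i]] <- tibble::tibble(
      person = persons[i],
      hypothesis = grid$hypothesis,
      vs = grid$vs,
      bf = unname(bfu_num[grid$hypothesis] / bfu_num[grid$vs])
    )
    dec <- select_best(bfu_num, threshold)
    decisions[[i]] <- tibble::tibble(person = persons[i], best = dec$best,
                                     threshold = dec$threshold)
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "pairwise") <- dplyr::bind_rows(pairwise_rows)
  attr(out, "decisions") <- dplyr::bind_rows(decisions)
  attr(out, "meta") <- list(n_draws = n_draws, seed = seed, layout = layout,
                            labels = labels)
  class(out) <- c("nof1_eval", class(out))
  out
}

#' @export
print.nof1_eval <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("# Per-person evaluation of", length(meta$labels),
      "informative hypotheses (N =", format(meta$n_draws, big.mark = ","),
      "draws per pool)\n")
  print(round_bf_cols(tibble::as_tibble(x)), ...)
  dec <- attr(x, "decisions")
  sel <- dec$best[!is.na(dec$best)]
  cat("# Decision rule (threshold ",
      format(dec$threshold[1]), "): ", sum(!is.na(dec$best)), " of ",
      nrow(dec), " person(s) with a best hypothesis",
      if (length(sel)) paste0(" (", paste(unique(sel), collapse = ", "), ")"),
      "\n", sep = "")
  if (any(x$fit == 0)) {
    cat("# Note: zero fit estimates are at the pool resolution limit (1/N)\n")
  }
  invisible(x)
}

# human-readable rounding only; stored values keep full precision
round_bf_cols <- function(tbl) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double),
                                   ~ round(.x, 2)))
}

#' Long table of per-person Bayes factors
#'
#' Reshapes an evaluation into one row per person and comparison, the input
#' format of [aggregate_bf()].  Comparison tags are `"<m>_vs_u"`,
#' `"<m>_vs_c"` and `"<m>_vs_<m'>"`.
#'
#' @param x An `nof1_eval` from [evaluate_hypotheses()].
#' @param families Which Bayes factor families to include.
#' @return Tibble with columns `person`, `comparison`, `bf`.
#' @export
bf_long <- function(x, families = c("unconstrained", "complement",
                                    "pairwise")) {
  stopifnot(inherits(x, "nof1_eval"))
  families <- match.arg(families, several.ok = TRUE)
  out <- list()
  tbl <- tibble::as_tibble(x)
  if ("unconstrained" %in% families) {
    out$u <- dplyr::transmute(tbl, person = .data$person,
                              comparison = paste0(.data$hypothesis, "_vs_u"),
                              bf = .data$bf_u)
  }
  if ("complement" %in% families) {
    out$c <- dplyr::transmute(tbl, person = .data$person,
                              comparison = paste0(.data$hypothesis, "_vs_c"),
                              bf = .data$bf_c)
  }
  if ("pairwise" %in% families) {
    pw <- attr(x, "pairwise")
    out$p <- dplyr::transmute(pw, person = .data$person,
                              comparison = paste0(.data$hypothesis, "_vs_",
                                                  .data$vs),
                              bf = .data$bf)
  }
  dplyr::bind_rows(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.nof1_eval <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dec <- attr(x, "decisions")
  dplyr::left_join(out, dec, by = "person")
}

#' @exportS3Method generics::glance
glance.nof1_eval <- function(x, ...) {
  meta <- attr(x, "meta")
  dec <- attr(x, "decisions")
  tibble::tibble(
    n_persons = nrow(dec),
    n_hypotheses = length(meta$labels),
    n_draws = meta$n_draws,
    n_selected = sum(!is.na(dec$best)),
    threshold = dec$threshold[1]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.nof1_eval <- function(object, families = c("unconstrained",
                                                    "complement"), ...) {
  df <- bf_long(object, families = families)
  df$family <- ifelse(grepl("_vs_u$", df$comparison), "vs unconstrained",
                      ifelse(grepl("_vs_c$", df$comparison), "vs complement",
                             "pairwise"))
  df$hypothesis <- sub("_vs_.*$", "", df$comparison)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$person), y = .data$bf,
                                   colour = .data$hypothesis)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "person", y = "Bayes factor (log scale)",
                  colour = "hypothesis")
}
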