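# Simulation-based design (sensitivity) analysis: for candidate numbers of
# persons P and replications R, estimate the sampling distribution of gP-BF,
# ER and SR under three generating P-populations — the hypothesis true for
# everyone, false for everyone (complement), or true for a theta-mixture.
#
# Algorithm (two stages):
#   1. surrogate: draw `size` within-person parameter vectors pi from the
#      uniform prior truncated to the population's region, sample counts
#      x ~ Binomial(R, pi), and compute each person's Bayes factor, giving a
#      surrogate for the infinite P-population;
#   2. bootstrap: for each P, resample `sets` groups of size P with
#      replacement from the surrogate and summarise gP-BF, ER and SR by
#      percentiles (default 2.5 / 50 / 97.5).

# chain of condition indices (largest ... smallest) when the matrix is a
# complete simple ordering, else NULL
full_ordering_chain <- function(m) {
  if (!is_full_ordering(m)) return(NULL)
  j <- ncol(m)
  succ <- rep(NA_integer_, j)
  indeg <- rep(0L, j)
  for (r in seq_len(nrow(m))) {
    pos <- which(m[r, ] == 1)
    neg <- which(m[r, ] == -1)
    succ[pos] <- neg
    indeg[neg] <- indeg[neg] + 1L
  }
  chain <- integer(j)
  cur <- which(indeg == 0L & !is.na(succ))
  for (k in seq_len(j)) {
    chain[k] <- cur
    cur <- succ[cur]
  }
  chain
}

# uses the ambient RNG stream; callers seed
sample_region <- function(h, n, mode, theta = 0.5, max_draws = 1e7) {
  j <- n_conditions(h$layout)
  if (mode == "mixture") {
    u <- stats::runif(n)
    k <- sum(u <= theta)
    out <- matrix(NA_real_, n, j)
    if (k > 0) {
      out[u <= theta, ] <- sample_region(h, k, "under_h",
                                         max_draws = max_draws)
    }
    if (k < n) {
      out[u > theta, ] <- sample_region(h, n - k, "under_complement",
                                        max_draws = max_draws)
    }
    colnames(out) <- h$layout$conditions
    return(out)
  }
  target <- if (mode == "under_h") h else complement_of(h)
  chain <- full_ordering_chain(h$matrix)
  if (mode == "under_h" && !is.null(chain)) {
    # exchangeability shortcut for complete orderings: sort J iid uniforms
    # into the required order; acceptance-free even at complexity 1/J!
    u <- matrix(stats::runif(n * j), n, j)
    s <- t(apply(u, 1L, sort, decreasing = TRUE))
    out <- matrix(NA_real_, n, j)
    out[, chain] <- s
    colnames(out) <- h$layout$conditions
    return(out)
  }
  # batched rejection sampling from the uniform prior
  got <- 0L
  used <- 0
  acc <- max(analytic_complexity(target), 0.05, na.rm = TRUE)
  out <- matrix(NA_real_, n, j)
  while (got < n) {
    batch <- min(ceiling((n - got) / acc * 1.2) + 100L, 1e6L)
    if (used + batch > max_draws) {
      stop("rejection budget exhausted sampling the truncated prior ",
           sprintf("(estimated acceptance rate %.2g after %d draws)",
                   got / max(used, 1), as.integer(used)), call. = FALSE)
    }
    cand <- matrix(stats::runif(batch * j), batch, j)
    keep <- satisfies(target, cand)
    used <- used + batch
    k <- sum(keep)
    if (k > 0) {
      take <- min(k, n - got)
      out[(got + 1L):(got + take), ] <- cand[which(keep)[seq_len(take)], ,
                                             drop = FALSE]
      got <- got + take
    }
    acc <- max((got + 1) / used, 1e-6)
  }
  colnames(out) <- h$layout$conditions
  out
}

#' Sample within-person parameter vectors from a generating P-population
#'
#' Draws success-probability vectors from the uniform encompassing prior
#' truncated to the hypothesis' region (`mode = "under_h"`), to its
#' complement (`"under_complement"`), or from a mixture where each person is
#' truncated to the hypothesis with probability `theta` and to the
#' complement otherwise.  Complete simple orderings are sampled
#' acceptance-free by sorting iid uniforms (valid by exchangeability);
#' other regions use batched rejection sampling.
#'
#' @param h An informative `nof1_hypothesis`.
#' @param n Number of vectors to draw.
#' @param mode `"under_h"`, `"under_complement"` or `"mixture"`.
#' @param theta Mixture proportion of persons adhering to the hypothesis
#'   (mixture mode only, default .5).
#' @param seed Optional integer seed.
#' @param max_draws Total rejection-candidate budget before erroring with an
#'   acceptance-rate estimate.
#' @return An `n x J` matrix of probabilities, columns named by condition.
#' @export
sample_wp_population <- function(h, n = 1, mode = c("under_h",
                                                    "under_complement",
                                                    "mixture"),
                                 theta = 0.5, seed = NULL, max_draws = 1e7) {
  stopifnot(inherits(h, "nof1_hypothesis"), h$kind == "informative")
  mode <- match.arg(mode)
  if (mode == "mixture" && (theta < 0 || theta > 1)) {
    stop("`theta` must lie in [0, 1]", call. = FALSE)
  }
  with_seed_maybe(seed, sample_region(h, n, mode, theta, max_draws))
}

#' Build a surrogate P-population of per-person Bayes factors
#'
#' Stage one of the design analysis: draws `size` persons from the
#' generating population, samples their counts at `R` replications, and
#' computes each person's Bayes factor for the configured comparison from a
#' posterior pool of `n_draws`.  The resulting set stands in for the
#' infinite P-population in the bootstrap stage.
#'
#' @inheritParams sample_wp_population
#' @param r Number of replications per condition used when sampling counts
#'   (overrides the layout's `R`); default the layout's `R`.
#' @param size Surrogate size (default 10000, as in the two-stage
#'   algorithm's reference setting).
#' @param n_draws Posterior pool size per person (default `1e5`).
#' @param comparison `"complement"` (default; the focal comparison for
#'   design) or `"unconstrained"`.
#' @return A tibble with columns `person`, `fit`, `bf`; attributes `pi`
#'   (true parameter matrix), `x` (count matrix) and `meta`.
#' @export
build_surrogate <- function(h, mode = c("under_h", "under_complement",
                                        "mixture"),
                            theta = 0.5, r = NULL, size = 10000,
                            n_draws = 1e5, seed = NULL,
                            comparison = c("complement", "unconstrained")) {
  stopifnot(inherits(h, "nof1_hypothesis"), h$kind == "informative")
  mode <- match.arg(mode)
  comparison <- match.arg(comparison)
  layout <- h$layout
  if (!is.null(r)) layout$replications <- as.integer(r)
  h <- new_hypothesis(h$label, h$kind, h$matrix, layout, h$text)
  j <- n_conditions(layout)
  rr <- layout$replications

  with_seed_maybe(seed, {
    pis <- sample_region(h, size, mode, theta)
    x <- matrix(stats::rbinom(size * j, rr, pis), size, j)
    cc <- analytic_complexity(h)
    if (is.na(cc)) {
      prior_pool <- sample_product(uniform_prior(layout), n_draws)
      cc <- prop_in_region(h, prior_pool)
      if (cc == 0 || cc == 1) {
        stop("prior pool of ", n_draws, " draws cannot resolve the ",
             "complexity of ", h$label, "; increase `n_draws`",
             call. = FALSE)
      }
    }
    tmat <- t(h$matrix)
    k <- ncol(tmat)
    fits <- numeric(size)
    for (i in seq_len(size)) {
      a <- x[i, ] + 1
      b <- rr - x[i, ] + 1
      pool <- matrix(stats::rbeta(n_draws * j, rep(a, each = n_draws),
                                  rep(b, each = n_draws)),
                     nrow = n_draws, ncol = j)
      fits[i] <- mean(rowSums((pool %*% tmat) > 0) == k)
    }
    bf <- if (comparison == "unconstrained") {
      fits / cc
    } else {
      (fits / cc) / ((1 - fits) / (1 - cc))
    }
    bf[fits == 1 & comparison == "complement"] <- Inf
    out <- tibble::tibble(person = seq_len(size), fit = fits, bf = bf)
    attr(out, "pi") <- pis
    attr(out, "x") <- x
    attr(out, "meta") <- list(mode = mode, theta = theta, r = rr,
                              n_draws = n_draws, comparison = comparison,
                              complexity = cc, hypothesis = h$label)
    out
  })
}

#' Bootstrap percentile summary of gP-BF, ER and SR for a sample size P
#'
#' Stage two of the design analysis: resamples `sets` groups of `p` persons
#' with replacement from a surrogate pool of per-person Bayes factors,
#' computes gP-BF, ER and SR for each group, and summarises each statistic
#' by percentiles.  Resamples with gP-BF exactly 1 leave ER and SR undefined;
#' they are excluded from the percentiles and counted in `undefined_rate`.
#'
#' @param bf Numeric vector of surrogate per-person Bayes factors (or the
#'   tibble from [build_surrogate()]).
#' @param p Number of persons per resampled set.
#' @param sets Number of bootstrap resamples (default 1000).
#' @param probs Percentile levels (default `c(.025, .5, .975)`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `statistic` (`gp_bf`, `er`, `sr`),
#'   `percentile`, `value`, `undefined_rate`.
#' @export
bootstrap_design <- function(bf, p, sets = 1000,
                             probs = c(0.025, 0.5, 0.975), seed = NULL) {
  if (is.data.frame(bf)) bf <- bf$bf
  bf <- check_bf_vector(bf)
  p <- as.integer(p)
  sets <- as.integer(sets)
  if (p < 1L || sets < 1L) stop("`p` and `sets` must be >= 1", call. = FALSE)
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("`probs` must lie strictly in (0, 1)", call. = FALSE)
  }
  with_seed_maybe(seed, {
    idx <- matrix(sample.int(length(bf), sets * p, replace = TRUE), sets, p)
    bfm <- matrix(bf[idx], sets, p)
    lg <- suppressWarnings(log(bfm))      # log(0) = -Inf annihilates the mean
    gp <- exp(rowMeans(lg))
    gp[apply(bfm, 1L, function(z) any(z == 0))] <- 0
    er <- ifelse(gp > 1, rowMeans(bfm > 1),
                 ifelse(gp < 1, rowMeans(bfm < 1), NA_real_))
    # gp recycles along rows of the sets x p matrix (column-major)
    sr <- ifelse(gp > 1, rowMeans(bfm > gp),
                 ifelse(gp < 1, rowMeans(bfm < gp), NA_real_))
    stats_list <- list(gp_bf = gp, er = er, sr = sr)
    purrr::imap_dfr(stats_list, function(v, nm) {
      tibble::tibble(
        statistic = nm,
        percentile = probs * 100,
        value = unname(stats::quantile(v, probs, na.rm = TRUE)),
        undefined_rate = mean(is.na(v))
      )
    })
  })
}

#' Configuration for a design analysis
#'
#' @param hypothesis An informative `nof1_hypothesis` (its layout supplies
#'   `J`; its `R` is overridden by `r_grid`).
#' @param r_grid,p_grid Candidate numbers of replications and persons.
#' @param modes Generating populations to simulate.
#' @param theta Mixture proportion (default .5).
#' @param surrogate_size Surrogate P-population size per (mode, R) cell
#'   (default 10000; reduce for desk-scale runs).
#' @param n_boot Bootstrap resamples per (mode, R, P) cell (default 1000).
#' @param n_draws Per-person posterior pool size (default `1e5`).
#' @param probs Percentiles reported (default 2.5 / 50 / 97.5).
#' @param comparison Bayes factor compared per person; `"complement"`
#'   (default) or `"unconstrained"`.
#' @param er_target Desired median evidence rate (default .9).
#' @param sr_margin Acceptable margin of the median stability rate around .5
#'   (default .1).
#' @param seed Optional root seed; every (mode, R) cell gets a derived
#'   child seed.
#' @return An object of class `nof1_design_config`.
#' @export
design_config <- function(hypothesis, r_grid, p_grid,
                          modes = c("under_h", "under_complement", "mixture"),
                          theta = 0.5, surrogate_size = 10000, n_boot = 1000,
                          n_draws = 1e5, probs = c(0.025, 0.5, 0.975),
                          comparison = c("complement", "unconstrained"),
                          er_target = 0.9, sr_margin = 0.1, seed = NULL) {
  stopifnot(inherits(hypothesis, "nof1_hypothesis"),
            hypothesis$kind == "informative")
  modes <- match.arg(modes, several.ok = TRUE)
  comparison <- match.arg(comparison)
  if (length(r_grid) == 0 || length(p_grid) == 0) {
    stop("`r_grid` and `p_grid` must be non-empty", call. = FALSE)
  }
  if (surrogate_size < max(p_grid)) {
    stop("`surrogate_size` must be at least max(p_grid)", call. = FALSE)
  }
  structure(
    list(hypothesis = hypothesis, r_grid = as.integer(r_grid),
         p_grid = as.integer(p_grid), modes = modes, theta = theta,
         surrogate_size = as.integer(surrogate_size),
         n_boot = as.integer(n_boot), n_draws = as.integer(n_draws),
         probs = probs, comparison = comparison, er_target = er_target,
         sr_margin = sr_margin, seed = seed),
    class = "nof1_design_config"
  )
}

#' Run the full two-stage design analysis over the (population, R, P) grid
#'
#' For every generating population and every `R`, one surrogate
#' P-population of per-person Bayes factors is built and then reused for
#' every `P` in the bootstrap stage (resampling with replacement), exactly
#' as the two-stage algorithm prescribes.  Medians are flagged against the
#' configured desiderata: evidence rate at least `er_target` and stability
#' rate within `sr_margin` of .5 (no gP-BF threshold is imposed — how much
#' average evidence suffices is left to the user).
#'
#' @param config An [design_config()].
#' @return A tibble of class `nof1_design` in long format: `population`,
#'   `r`, `p`, `statistic`, `percentile`, `value`, `undefined_rate`,
#'   `meets_target` (`NA` except for median ER/SR rows).  [autoplot()]
#'   draws median lines with percentile ribbons.
#' @export
run_design <- function(config) {
  stopifnot(inherits(config, "nof1_design_config"))
  cells <- expand.grid(mode = config$modes, r = config$r_grid,
                       stringsAsFactors = FALSE)
  seeds <- child_seeds(config$seed, nrow(cells) * (1 + length(config$p_grid)))
  si <- 0L
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    si <- si + 1L
    surr <- build_surrogate(
      config$hypothesis, mode = cells$mode[ci], theta = config$theta,
      r = cells$r[ci], size = config$surrogate_size,
      n_draws = config$n_draws, seed = seeds[[si]],
      comparison = config$comparison
    )
    per_p <- vector("list", length(config$p_grid))
    for (pi in seq_along(config$p_grid)) {
      si <- si + 1L
      bt <- bootstrap_design(surr$bf, p = config$p_grid[pi],
                             sets = config$n_boot, probs = config$probs,
                             seed = seeds[[si]])
      bt$population <- cells$mode[ci]
      bt$r <- cells$r[ci]
      bt$p <- config$p_grid[pi]
      per_p[[pi]] <- bt
    }
    out[[ci]] <- dplyr::bind_rows(per_p)
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::select(res, "population", "r", "p", "statistic",
                       "percentile", "value", "undefined_rate")
  res$meets_target <- NA
  med <- res$percentile == 50
  res$meets_target[med & res$statistic == "er"] <-
    res$value[med & res$statistic == "er"] >= config$er_target
  res$meets_target[med & res$statistic == "sr"] <-
    abs(res$value[med & res$statistic == "sr"] - 0.5) <= config$sr_margin
  attr(res, "config") <- config
  class(res) <- c("nof1_design", class(res))
  res
}

#' @export
print.nof1_design <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("# Design analysis:", cfg$hypothesis$label, "vs", cfg$comparison,
      "| surrogate", cfg$surrogate_size, "x", cfg$n_boot, "bootstrap sets\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nof1_design <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.nof1_design <- function(x, ...) {
  cfg <- attr(x, "config")
  med <- x[x$percentile == 50, ]
  tibble::tibble(
    n_cells = nrow(unique(x[, c("population", "r", "p")])),
    surrogate_size = cfg$surrogate_size,
    n_boot = cfg$n_boot,
    n_draws = cfg$n_draws,
    prop_er_ok = mean(med$meets_target[med$statistic == "er"]),
    prop_sr_ok = mean(med$meets_target[med$statistic == "sr"])
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.nof1_design <- function(object, ...) {
  df <- tibble::as_tibble(object)
  probs <- sort(unique(df$percentile))
  lo <- probs[1]; hi <- probs[length(probs)]
  wide <- tidyr::pivot_wider(df,
                             id_cols = c("population", "r", "p", "statistic"),
                             names_from = "percentile", values_from = "value",
                             names_prefix = "q")
  names(wide)[names(wide) == paste0("q", lo)] <- "lower"
  names(wide)[names(wide) == paste0("q", hi)] <- "upper"
  names(wide)[names(wide) == "q50"] <- "median"
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$p, y = .data$median,
                                     colour = factor(.data$r),
                                     fill = factor(.data$r))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(statistic ~ population, scales = "free_y") +
    ggplot2::labs(x = "number of persons P", y = NULL,
                  colour = "R", fill = "R")
}
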