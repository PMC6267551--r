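# Conjugate Beta-binomial machinery.  Prior and posterior over the success
# probabilities factor into J independent Beta laws, so pools of draws are
# sampled directly (no MCMC needed) and every proportion estimated from a
# pool carries the exact Monte Carlo standard error sqrt(p (1 - p) / N).

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

# Deterministic child seeds (below 2^31) derived from one root seed, so that
# per-person / per-purpose streams are reproducible and independent.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(withr::with_seed(as.integer(seed),
                           sample.int(2147483646L, n, replace = FALSE)))
}

#' Uniform encompassing prior over success probabilities
#'
#' The prior under the unconstrained hypothesis is a product of `J`
#' independent Beta(1, 1) laws, i.e. uniform on the unit cube.  With
#' alpha = beta = 1 the prior is unbiased over all hypotheses in an
#' equivalent set (e.g. the `J!` complete orderings).
#'
#' @param layout A [condition_layout()].
#' @return An object of class `nof1_beta_product` with fields `alpha`,
#'   `beta` (length-`J` vectors) and the layout.
#' @export
uniform_prior <- function(layout) {
  stopifnot(inherits(layout, "nof1_layout"))
  j <- n_conditions(layout)
  new_beta_product(rep(1, j), rep(1, j), layout)
}

new_beta_product <- function(alpha, beta, layout) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("Beta parameters must be strictly positive", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 layout = layout),
            class = "nof1_beta_product")
}

#' @export
print.nof1_beta_product <- function(x, ...) {
  cat("<nof1_beta_product> J =", length(x$alpha), "independent Beta laws\n")
  print(tibble::tibble(condition = x$layout$conditions,
                       alpha = x$alpha, beta = x$beta,
                       mean = x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Conjugate posterior update from one person's counts
#'
#' Component-wise `alpha_1 = x_j + alpha_0` and `beta_1 = (R - x_j) + beta_0`,
#' the standard Beta-binomial update; with the uniform prior the posterior is
#' determined by the data alone.
#'
#' @param prior An `nof1_beta_product`, typically [uniform_prior()].
#' @param successes Integer vector of `J` success counts in `0..R`, ordered
#'   as the layout's conditions (or named by them).
#' @return An `nof1_beta_product` holding the posterior.
#' @examples
#' lay <- condition_layout(c("c1", "c2", "c3", "c4"), 7)
#' posterior_update(uniform_prior(lay), c(7, 5, 4, 1))
#' @export
posterior_update <- function(prior, successes) {
  stopifnot(inherits(prior, "nof1_beta_product"))
  layout <- prior$layout
  successes <- check_counts(successes, layout)
  new_beta_product(successes + prior$alpha,
                   (layout$replications - successes) + prior$beta,
                   layout)
}

check_counts <- function(successes, layout) {
  j <- n_conditions(layout)
  if (!is.null(names(successes)) &&
      all(layout$conditions %in% names(successes))) {
    successes <- successes[layout$conditions]
  }
  if (length(successes) != j) {
    stop("expected J = ", j, " success counts, got ", length(successes),
         call. = FALSE)
  }
  if (any(is.na(successes)) || any(successes != round(successes))) {
    stop("success counts must be integers", call. = FALSE)
  }
  r <- layout$replications
  if (any(successes < 0) || any(successes > r)) {
    bad <- which(successes < 0 | successes > r)[1]
    stop("success count out of range [0, R = ", r, "] in condition '",
         layout$conditions[bad], "'", call. = FALSE)
  }
  as.numeric(successes)
}

#' Sample a pool of success-probability vectors
#'
#' Draws an `n x J` pool with column `j` distributed Beta(alpha_j, beta_j),
#' columns independent.  Reproducible given `seed`.
#'
#' @param bp An `nof1_beta_product` (prior or posterior).
#' @param n Number of draws (pool size N).
#' @param seed Optional integer seed; the sampler is seeded locally and the
#'   caller's RNG state is untouched.
#' @return An `n x J` numeric matrix with columns named by condition.
#' @export
sample_product <- function(bp, n, seed = NULL) {
  stopifnot(inherits(bp, "nof1_beta_product"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  j <- length(bp$alpha)
  draws <- with_seed_maybe(seed, {
    matrix(stats::rbeta(n * j, rep(bp$alpha, each = n), rep(bp$beta, each = n)),
           nrow = n, ncol = j)
  })
  colnames(draws) <- bp$layout$conditions
  draws
}

#' Simulate binomial counts for one person
#'
#' Given a true success-probability vector, draws `x_j ~ Binomial(R, pi_j)`
#' independently per condition — the generative model of a within-person
#' population.
#'
#' @param pi Numeric vector of `J` probabilities in `[0, 1]`.
#' @param layout A [condition_layout()] supplying `R` (and `J`).
#' @param seed Optional integer seed.
#' @return Integer vector of `J` success counts named by condition.
#' @export
simulate_counts <- function(pi, layout, seed = NULL) {
  stopifnot(inherits(layout, "nof1_layout"))
  j <- n_conditions(layout)
  if (length(pi) != j) {
    stop("`pi` must have length J = ", j, call. = FALSE)
  }
  if (any(pi < 0) || any(pi > 1) || any(is.na(pi))) {
    stop("success probabilities must lie in [0, 1]", call. = FALSE)
  }
  x <- with_seed_maybe(seed, stats::rbinom(j, layout$replications, pi))
  stats::setNames(as.integer(x), layout$conditions)
}
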