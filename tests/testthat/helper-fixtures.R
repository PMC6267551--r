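# Shared layouts, hypothesis sets and independent oracles used across tests.

lay4 <- function(r = 7) condition_layout(c("c1", "c2", "c3", "c4"), r)
lay2 <- function(r = 7) condition_layout(c("c1", "c2"), r)
lay8 <- function(r = 7) condition_layout(paste0("c", 1:8), r)

h_full4 <- function(r = 7) {
  parse_hypothesis("c1 > c2 > c3 > c4", lay4(r), label = "H1")
}
h_avg4 <- function(r = 7) {
  parse_hypothesis("(c1 + c2)/2 > (c3 + c4)/2", lay4(r), label = "H2")
}
hset4 <- function(r = 7) {
  hypothesis_set(H1 = "c1 > c2 > c3 > c4",
                 H2 = "(c1 + c2)/2 > (c3 + c4)/2",
                 layout = lay4(r))
}
h_full8 <- function(r = 7) {
  parse_hypothesis(paste(paste0("c", 1:8), collapse = " > "), lay8(r),
                   label = "H1")
}

# Independent oracle for the two-condition ordering probability
# P(X > Y) with X ~ Beta(a1, b1), Y ~ Beta(a2, b2), by deterministic
# numerical integration of P(Y < t) against the density of X.
p_beta_greater <- function(a1, b1, a2, b2) {
  stats::integrate(function(t) stats::pbeta(t, a2, b2) *
                     stats::dbeta(t, a1, b1),
                   0, 1, rel.tol = 1e-10)$value
}

# all 24 complete orderings of four conditions as constraint strings
orderings4 <- function() {
  perms <- list()
  for (p in asplit(as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4)), 1)) {
    if (length(unique(p)) == 4) perms[[length(perms) + 1L]] <- p
  }
  vapply(perms, function(p) paste(paste0("c", p), collapse = " > "),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
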