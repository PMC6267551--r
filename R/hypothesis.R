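#' Define the experimental layout of a within-subject N-of-1 study
#'
#' A layout records the `J` named experimental conditions a person is exposed
#' to and the number of replications `R` (dichotomous trials) performed in
#' each condition.  All hypotheses, counts and pools in the package refer to
#' one layout.
#'
#' @param conditions Character vector of `J >= 2` unique, non-empty condition
#'   labels.  Labels may contain hyphens (e.g. `"hr-sup-li"`); the hypothesis
#'   parser matches them greedily.
#' @param replications Positive integer `R`, the number of trials per
#'   condition (constant over conditions and persons).
#'
#' @return An object of class `nof1_layout`.
#' @examples
#' condition_layout(c("c1", "c2", "c3", "c4"), replications = 7)
#' @export
condition_layout <- function(conditions, replications) {
  conditions <- as.character(conditions)
  if (length(conditions) < 2) {
    stop("a layout needs at least two conditions (J >= 2)", call. = FALSE)
  }
  if (anyDuplicated(conditions) || any(!nzchar(conditions))) {
    stop("condition names must be unique and non-empty", call. = FALSE)
  }
  replications <- as.integer(replications)
  if (length(replications) != 1L || is.na(replications) || replications < 1L) {
    stop("`replications` must be a single positive integer", call. = FALSE)
  }
  structure(
    list(conditions = conditions, replications = replications),
    class = "nof1_layout"
  )
}

#' @export
print.nof1_layout <- function(x, ...) {
  cat("<nof1_layout> J =", length(x$conditions),
      "conditions, R =", x$replications, "replications\n")
  cat(" ", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

n_conditions <- function(layout) length(layout$conditions)

# ---------------------------------------------------------------------------
# Constraint mini-language
#
#   term  := condition | "(" expr ")" | number "*" term
#   expr  := term { ("+" | "-") term } [ "/" number ]
#   chain := expr { (">" | "<") expr }       (single direction per chain)
#   text  := chain { (";" | ",") chain }     (separators impose no constraint)
#
# Every adjacent pair of a chain becomes one row of the constraint matrix
# r with r %*% pi > 0.  Chains are expanded to adjacent pairs only
# (a > b > c gives exactly the two rows a - b and b - c).
# ---------------------------------------------------------------------------

tokenize_constraints <- function(text, conditions) {
  # Condition names are matched greedily (longest first) so labels containing
  # hyphens are not split into subtraction.
  by_len <- conditions[order(nchar(conditions), decreasing = TRUE)]
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    matched <- FALSE
    for (nm in by_len) {
      len <- nchar(nm)
      if (substr(text, i, i + len - 1L) == nm) {
        nxt <- substr(text, i + len, i + len)
        if (!grepl("^[A-Za-z0-9_.]$", nxt)) {
          tokens[[length(tokens) + 1L]] <- list(type = "name", value = nm)
          i <- i + len
          matched <- TRUE
          break
        }
      }
    }
    if (matched) next
    if (ch %in% c("+", "-", "/", "*", "(", ")", ">", "<", ";", ",")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch)
      i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    if (grepl("^[0-9.]$", ch)) {
      m <- regmatches(rest, regexpr("^[0-9]*\\.?[0-9]+", rest))
      tokens[[length(tokens) + 1L]] <- list(type = "num",
                                            value = as.numeric(m))
      i <- i + nchar(m)
      next
    }
    bad <- regmatches(rest, regexpr("^[^[:space:]+*/()><;,-]+", rest))
    stop("unknown token '", bad, "' in constraint string (not a condition ",
         "name of this layout)", call. = FALSE)
  }
  tokens
}

# Recursive-descent evaluation of one side of an inequality into a
# coefficient vector over the layout's conditions.  `state` is an environment
# carrying the token stream and cursor.
parse_side <- function(tokens, conditions) {
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  peek <- function() {
    if (state$pos > length(state$tokens)) NULL else state$tokens[[state$pos]]
  }
  advance <- function() {
    tok <- peek()
    state$pos <- state$pos + 1L
    tok
  }
  expect_num <- function(what) {
    tok <- advance()
    if (is.null(tok) || tok$type != "num") {
      stop("malformed arithmetic: expected a number after '", what, "'",
           call. = FALSE)
    }
    tok$value
  }
  # values are lists: either a scalar or a coefficient vector
  val_scalar <- function(x) list(kind = "scalar", x = x)
  val_coef <- function(x) list(kind = "coef", x = x)

  parse_primary <- function() {
    tok <- advance()
    if (is.null(tok)) stop("empty term in constraint string", call. = FALSE)
    if (tok$type == "name") {
      coef <- as.numeric(conditions == tok$value)
      return(val_coef(coef))
    }
    if (tok$type == "num") {
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "*") {
        advance()
        p <- parse_primary()
        if (p$kind == "scalar") return(val_scalar(tok$value * p$x))
        return(val_coef(tok$value * p$x))
      }
      return(val_scalar(tok$value))
    }
    if (tok$type == "(") {
      inner <- parse_expr()
      close <- advance()
      if (is.null(close) || close$type != ")") {
        stop("malformed arithmetic: unbalanced parenthesis", call. = FALSE)
      }
      return(inner)
    }
    stop("malformed arithmetic near '", tok$value, "'", call. = FALSE)
  }

  parse_term <- function() {
    v <- parse_primary()
    repeat {
      nxt <- peek()
      if (is.null(nxt) || !(nxt$type %in% c("/", "*"))) break
      advance()
      d <- expect_num(nxt$type)
      if (nxt$type == "/") {
        if (d == 0) stop("division by zero in constraint term", call. = FALSE)
        v$x <- v$x / d
      } else {
        v$x <- v$x * d
      }
    }
    v
  }

  parse_expr <- function() {
    v <- parse_term()
    repeat {
      nxt <- peek()
      if (is.null(nxt) || !(nxt$type %in% c("+", "-"))) break
      advance()
      w <- parse_term()
      if (v$kind == "scalar" && w$kind == "scalar") {
        v$x <- if (nxt$type == "+") v$x + w$x else v$x - w$x
      } else {
        a <- if (v$kind == "coef") v$x else rep(v$x, length(conditions))
        b <- if (w$kind == "coef") w$x else rep(w$x, length(conditions))
        if (v$kind == "scalar" || w$kind == "scalar") {
          stop("constants may only appear as multipliers or divisors, not ",
               "as standalone terms", call. = FALSE)
        }
        v <- val_coef(if (nxt$type == "+") a + b else a - b)
      }
    }
    v
  }

  out <- parse_expr()
  if (state$pos <= length(tokens)) {
    stop("malformed arithmetic near '", tokens[[state$pos]]$value, "'",
         call. = FALSE)
  }
  if (out$kind != "coef") {
    stop("a constraint term must reference at least one condition",
         call. = FALSE)
  }
  out$x
}

#' Parse an informative hypothesis from a constraint string
#'
#' Translates expectations written with `>` and `<` on condition success
#' probabilities into a constraint matrix \eqn{R_m} with one row per adjacent
#' inequality, encoding the hypothesis \eqn{H_m: R_m \pi > 0}.  Terms may be
#' condition names, sums/differences of conditions, and explicitly divided
#' averages such as `(a + b)/2`.  Chains expand to adjacent pairs only:
#' `"a > b > c"` yields the two rows `a - b` and `b - c`.  `;` (or `,`)
#' separates independent constraint groups; no constraint is imposed across
#' groups.
#'
#' @param text Constraint string, e.g. `"c1 > c2 > c3 > c4"` or
#'   `"(c1 + c2)/2 > (c3 + c4)/2"`.
#' @param layout A [condition_layout()].
#' @param label Optional hypothesis label; defaults to the text itself.
#'
#' @return An object of class `nof1_hypothesis` with `kind = "informative"`
#'   and a `K x J` constraint matrix.
#' @examples
#' lay <- condition_layout(c("c1", "c2", "c3", "c4"), 7)
#' parse_hypothesis("c1 > c2 > c3 > c4", lay, label = "H1")
#' parse_hypothesis("(c1 + c2)/2 > (c3 + c4)/2", lay, label = "H2")
#' @export
parse_hypothesis <- function(text, layout, label = NULL) {
  stopifnot(inherits(layout, "nof1_layout"))
  conditions <- layout$conditions
  tokens <- tokenize_constraints(text, conditions)
  if (length(tokens) == 0L) {
    stop("empty constraint string", call. = FALSE)
  }
  types <- vapply(tokens, function(t) t$type, character(1))
  if (sum(types == "(") != sum(types == ")")) {
    stop("malformed arithmetic: unbalanced parenthesis", call. = FALSE)
  }

  # split on top-level ';' and ',' into independent groups
  depth <- 0L
  group_id <- integer(length(tokens))
  g <- 1L
  keep <- logical(length(tokens))
  for (i in seq_along(tokens)) {
    t <- tokens[[i]]$type
    if (t == "(") depth <- depth + 1L
    if (t == ")") depth <- depth - 1L
    if (depth == 0L && t %in% c(";", ",")) {
      g <- g + 1L
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
    }
    group_id[i] <- g
  }

  rows <- list()
  for (gi in unique(group_id)) {
    gtok <- tokens[group_id == gi & keep]
    if (length(gtok) == 0L) {
      stop("empty chain between separators in constraint string",
           call. = FALSE)
    }
    # split the chain on top-level relations
    depth <- 0L
    sides <- list()
    rels <- character()
    cur <- list()
    for (tok in gtok) {
      if (tok$type == "(") depth <- depth + 1L
      if (tok$type == ")") depth <- depth - 1L
      if (depth == 0L && tok$type %in% c(">", "<")) {
        sides[[length(sides) + 1L]] <- cur
        rels <- c(rels, tok$type)
        cur <- list()
      } else {
        cur[[length(cur) + 1L]] <- tok
      }
    }
    sides[[length(sides) + 1L]] <- cur
    if (any(lengths(sides) == 0L)) {
      stop("empty chain: missing term beside '>' or '<'", call. = FALSE)
    }
    if (length(rels) == 0L) next  # bare term list, no constraint
    if (length(unique(rels)) > 1L) {
      stop("mixed-direction chain: use a single direction per chain or ",
           "separate chains with ';'", call. = FALSE)
    }
    coefs <- lapply(sides, parse_side, conditions = conditions)
    for (k in seq_along(rels)) {
      row <- if (rels[k] == ">") {
        coefs[[k]] - coefs[[k + 1L]]
      } else {
        coefs[[k + 1L]] - coefs[[k]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    stop("constraint string imposes no constraints (empty chain)",
         call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- conditions
  if (any(rowSums(abs(mat)) == 0)) {
    stop("degenerate constraint: a row reduced to all zeros (both sides ",
         "of an inequality are identical)", call. = FALSE)
  }
  new_hypothesis(label = label %||% text, kind = "informative",
                 matrix = mat, layout = layout, text = text)
}

new_hypothesis <- function(label, kind, matrix, layout, text = NULL) {
  structure(
    list(label = label, kind = kind, matrix = matrix, layout = layout,
         text = text),
    class = "nof1_hypothesis"
  )
}

#' @export
print.nof1_hypothesis <- function(x, ...) {
  cat("<nof1_hypothesis> ", x$label, " (", x$kind, ")\n", sep = "")
  if (!is.null(x$text)) cat("  ", x$text, "\n", sep = "")
  if (!is.null(x$matrix)) {
    cat("  constraint matrix (", nrow(x$matrix), " x ", ncol(x$matrix),
        "):\n", sep = "")
    print(unname(x$matrix))
  }
  invisible(x)
}

#' Complement of an informative hypothesis
#'
#' The complement states that \eqn{H_m} is *not* true: at least one of its
#' row inequalities is violated.  The constraint matrix of the negated
#' informative hypothesis is stored on the complement for membership tests.
#'
#' @param h An informative `nof1_hypothesis`.
#' @return An `nof1_hypothesis` with `kind = "complement"`.
#' @export
complement_of <- function(h) {
  stopifnot(inherits(h, "nof1_hypothesis"))
  if (h$kind != "informative") {
    stop("only an informative hypothesis has a complement (got kind '",
         h$kind, "')", call. = FALSE)
  }
  new_hypothesis(label = paste0("not ", h$label), kind = "complement",
                 matrix = h$matrix, layout = h$layout, text = h$text)
}

#' The unconstrained (encompassing) hypothesis
#'
#' \eqn{H_u} leaves every success probability free; it is the reference
#' against which complexity and fit are defined.
#'
#' @param layout A [condition_layout()].
#' @return An `nof1_hypothesis` with `kind = "unconstrained"` and no matrix.
#' @export
unconstrained_hypothesis <- function(layout) {
  stopifnot(inherits(layout, "nof1_layout"))
  new_hypothesis(label = "Hu", kind = "unconstrained", matrix = NULL,
                 layout = layout)
}

#' Membership of parameter vectors in a hypothesis region
#'
#' Evaluates, for each row of `pi` (draws of the success-probability vector),
#' whether it lies in the hypothesis region.  Inequalities are strict: an
#' informative hypothesis requires every row product `r %*% pi` to be `> 0`,
#' its complement requires at least one row product `< 0`.  A draw on the
#' boundary (some row product exactly 0, a probability-zero event under
#' continuous Betas) belongs to neither.
#'
#' @param h An `nof1_hypothesis`.
#' @param pi Numeric vector of length `J`, or an `n x J` matrix of draws.
#' @return Logical vector with one entry per draw.
#' @export
satisfies <- function(h, pi) {
  stopifnot(inherits(h, "nof1_hypothesis"))
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1L)
  if (ncol(pi) != n_conditions(h$layout)) {
    stop("`pi` must have J = ", n_conditions(h$layout), " columns",
         call. = FALSE)
  }
  if (h$kind == "unconstrained") return(rep(TRUE, nrow(pi)))
  margins <- pi %*% t(h$matrix)
  if (h$kind == "informative") {
    rowSums(margins > 0) == ncol(margins)
  } else {
    rowSums(margins < 0) > 0
  }
}

#' Bundle competing informative hypotheses that share one layout
#'
#' @param ... Named constraint strings, or `nof1_hypothesis` objects.
#' @param layout A [condition_layout()]; required when strings are given.
#' @return An object of class `nof1_hset`: an ordered list of `M >= 1`
#'   informative hypotheses with unique labels.
#' @examples
#' lay <- condition_layout(c("c1", "c2", "c3", "c4"), 7)
#' hypothesis_set(H1 = "c1 > c2 > c3 > c4",
#'                H2 = "(c1 + c2)/2 > (c3 + c4)/2", layout = lay)
#' @export
hypothesis_set <- function(..., layout = NULL) {
  args <- list(...)
  if (length(args) == 0L) {
    stop("a hypothesis set needs at least one hypothesis (M >= 1)",
         call. = FALSE)
  }
  hyps <- vector("list", length(args))
  labels <- names(args) %||% rep("", length(args))
  for (i in seq_along(args)) {
    a <- args[[i]]
    if (inherits(a, "nof1_hypothesis")) {
      if (a$kind != "informative") {
        stop("hypothesis sets hold informative hypotheses only", call. = FALSE)
      }
      hyps[[i]] <- a
    } else if (is.character(a) && length(a) == 1L) {
      if (is.null(layout)) {
        stop("`layout` is required when hypotheses are given as strings",
             call. = FALSE)
      }
      lab <- if (nzchar(labels[i])) labels[i] else paste0("H", i)
      hyps[[i]] <- parse_hypothesis(a, layout, label = lab)
    } else {
      stop("hypotheses must be constraint strings or nof1_hypothesis objects",
           call. = FALSE)
    }
    if (nzchar(labels[i])) hyps[[i]]$label <- labels[i]
  }
  labs <- vapply(hyps, function(h) h$label, character(1))
  if (anyDuplicated(labs)) {
    stop("hypothesis labels must be unique", call. = FALSE)
  }
  lay <- hyps[[1]]$layout
  same <- vapply(hyps, function(h) identical(h$layout$conditions,
                                             lay$conditions), logical(1))
  if (!all(same)) {
    stop("all hypotheses in a set must share one condition layout",
         call. = FALSE)
  }
  structure(list(hypotheses = stats::setNames(hyps, labs), layout = lay),
            class = "nof1_hset")
}

#' @export
print.nof1_hset <- function(x, ...) {
  cat("<nof1_hset> M =", length(x$hypotheses), "informative hypotheses, J =",
      n_conditions(x$layout), "conditions\n")
  for (h in x$hypotheses) {
    cat("  ", h$label, ": ", h$text %||% "<matrix>", "\n", sep = "")
  }
  invisible(x)
}

#' Diagnostics for a constraint matrix
#'
#' Reports the row count, duplicate or proportional rows, and all-zero rows.
#' The matrix is never modified; this is a reporting aid for hand-built
#' matrices.
#'
#' @param m Numeric constraint matrix (K x J), or an `nof1_hypothesis`.
#' @return A tibble with one row per check: `check`, `ok`, `detail`.
#' @export
validate_constraints <- function(m) {
  if (inherits(m, "nof1_hypothesis")) m <- m$matrix
  m <- as.matrix(m)
  k <- nrow(m)
  zero_rows <- which(rowSums(abs(m)) == 0)
  # proportional (incl. duplicate) row pairs: compare unit-normalized rows
  prop_pairs <- character()
  if (k >= 2) {
    norms <- sqrt(rowSums(m^2))
    unit <- m / ifelse(norms == 0, 1, norms)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (norms[i] > 0 && norms[j] > 0 &&
            (max(abs(unit[i, ] - unit[j, ])) < 1e-12 ||
             max(abs(unit[i, ] + unit[j, ])) < 1e-12)) {
          prop_pairs <- c(prop_pairs, paste0(i, "~", j))
        }
      }
    }
  }
  tibble::tibble(
    check = c("rows", "no_zero_rows", "no_proportional_rows"),
    ok = c(k >= 1, length(zero_rows) == 0, length(prop_pairs) == 0),
    detail = c(
      paste0("K = ", k),
      if (length(zero_rows)) {
        paste0("all-zero row(s): ", paste(zero_rows, collapse = ", "))
      } else "none",
      if (length(prop_pairs)) {
        paste0("proportional row pair(s): ", paste(prop_pairs, collapse = ", "))
      } else "none"
    )
  )
}

# Is the matrix a complete simple ordering of all J conditions?
# (J-1 rows, each with a single +1 and a single -1, forming one chain that
# visits every condition).  For such hypotheses the prior complexity is
# exactly 1/J! by exchangeability of the uniform prior.
is_full_ordering <- function(m) {
  m <- as.matrix(m)
  j <- ncol(m)
  if (nrow(m) != j - 1L) return(FALSE)
  edges <- matrix(NA_integer_, nrow(m), 2)
  for (r in seq_len(nrow(m))) {
    pos <- which(m[r, ] == 1)
    neg <- which(m[r, ] == -1)
    if (length(pos) != 1L || length(neg) != 1L ||
        sum(m[r, ] != 0) != 2L) {
      return(FALSE)
    }
    edges[r, ] <- c(pos, neg)
  }
  # must form a single path: follow successor links from the unique source
  succ <- rep(NA_integer_, j)
  indeg <- rep(0L, j)
  for (r in seq_len(nrow(edges))) {
    if (!is.na(succ[edges[r, 1]])) return(FALSE)  # branching
    succ[edges[r, 1]] <- edges[r, 2]
    indeg[edges[r, 2]] <- indeg[edges[r, 2]] + 1L
  }
  if (any(indeg > 1L)) return(FALSE)
  start <- which(indeg == 0L & !is.na(succ))
  if (length(start) != 1L) return(FALSE)
  seen <- integer()
  cur <- start
  while (!is.na(cur)) {
    if (cur %in% seen) return(FALSE)
    seen <- c(seen, cur)
    cur <- if (is.na(succ[cur])) NA_integer_ else succ[cur]
  }
  length(seen) == j
}

#' Analytic prior complexity, where available
#'
#' For a complete simple ordering of all `J` conditions the complexity under
#' the exchangeable uniform prior is exactly `1/J!` (and `1 - 1/J!` for its
#' complement).  For other constraint structures no closed form is attached
#' and `NA` is returned.
#'
#' @param h An `nof1_hypothesis`.
#' @return A number, or `NA` if no analytic value is available.
#' @export
analytic_complexity <- function(h) {
  stopifnot(inherits(h, "nof1_hypothesis"))
  if (h$kind == "unconstrained") return(1)
  if (!is_full_ordering(h$matrix)) return(NA_real_)
  j <- n_conditions(h$layout)
  if (h$kind == "informative") 1 / factorial(j) else 1 - 1 / factorial(j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
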