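# File I/O and bundled worked-example fixtures.
#
# Counts files are wide CSV: header `person_id,<cond1>,...,<condJ>`, one row
# per person; R is supplied by the layout / hypothesis config (constant over
# conditions and persons).  Hypothesis configs are YAML: condition names,
# replications, and a map label -> constraint string (or explicit matrix as
# a list of rows).

#' Read a wide counts CSV
#'
#' @param path Path to a CSV with a person identifier column and one integer
#'   count column per condition.
#' @param layout A [condition_layout()] used for validation (condition
#'   columns present, counts integers in `0..R`, person ids unique).
#' @return A tibble of validated persons in file order.
#' @export
read_counts <- function(path, layout) {
  stopifnot(inherits(layout, "nof1_layout"))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(data) == 0) {
    stop("counts file '", path, "' has no data rows", call. = FALSE)
  }
  person_col <- find_person_column(data, layout)
  missing_cond <- setdiff(layout$conditions, names(data))
  if (length(missing_cond) > 0) {
    stop("counts file is missing condition column(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data[[person_col]])) {
    stop("duplicate person ids in counts file", call. = FALSE)
  }
  for (cond in layout$conditions) {
    v <- data[[cond]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
      stop("non-integer count in column '", cond, "'", call. = FALSE)
    }
    bad <- which(v < 0 | v > layout$replications)
    if (length(bad) > 0) {
      stop("count out of range [0, R = ", layout$replications,
           "] at row ", bad[1], ", column '", cond, "' (value ", v[bad[1]],
           ")", call. = FALSE)
    }
  }
  data
}

#' Read a hypothesis configuration (YAML)
#'
#' The file holds `conditions`, `replications`, and `hypotheses`: a map from
#' label to constraint string, or to an explicit constraint matrix given as
#' a list of coefficient rows.
#'
#' @param path Path to the YAML file.
#' @return An [hypothesis_set()].
#' @export
read_hypotheses <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$conditions) || is.null(cfg$replications) ||
      is.null(cfg$hypotheses)) {
    stop("hypothesis config needs `conditions`, `replications` and ",
         "`hypotheses`", call. = FALSE)
  }
  layout <- condition_layout(unlist(cfg$conditions), cfg$replications)
  hyps <- list()
  for (lab in names(cfg$hypotheses)) {
    spec <- cfg$hypotheses[[lab]]
    if (is.character(spec) && length(spec) == 1L) {
      hyps[[lab]] <- spec
    } else if (is.list(spec)) {
      mat <- do.call(rbind, lapply(spec, as.numeric))
      if (ncol(mat) != n_conditions(layout)) {
        stop("matrix for hypothesis '", lab, "' must have J = ",
             n_conditions(layout), " columns", call. = FALSE)
      }
      colnames(mat) <- layout$conditions
      hyps[[lab]] <- new_hypothesis(lab, "informative", mat, layout)
    } else {
      stop("hypothesis '", lab, "' must be a constraint string or a list ",
           "of coefficient rows", call. = FALSE)
    }
  }
  do.call(hypothesis_set, c(hyps, list(layout = layout)))
}

#' Write analysis results to disk
#'
#' `format = "csv"` writes the machine-readable table at full precision
#' (round-trips through [readr::read_csv()]); `format = "txt"` writes a
#' human-readable summary rounded to two decimals, table style.
#'
#' @param results A tibble from [evaluate_hypotheses()], [aggregate_bf()],
#'   [run_design()] or [bf_long()].
#' @param path Output file path.
#' @param format `"csv"` (default) or `"txt"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  tbl <- tibble::as_tibble(results)
  if (nrow(tbl) == 0) {
    warning("writing an empty results table (header only)", call. = FALSE)
  }
  if (format == "csv") {
    readr::write_csv(tbl, path, progress = FALSE)
  } else {
    lines <- utils::capture.output(print(round_bf_cols(tbl), n = Inf,
                                         width = 200))
    writeLines(lines, path)
  }
  invisible(path)
}

fixture_names <- c("table1", "table1_hypotheses", "table2", "table3",
                   "table4_gp")

#' Bundled worked-example fixtures
#'
#' Published worked examples shipped with the package: `"table1"` — three
#' hypothetical N = 1 persons (J = 4, R = 7, counts (7,5,4,1), (7,2,5,1),
#' (3,4,6,1)); `"table1_hypotheses"` — the matching hypothesis set (a full
#' ordering and an averages hypothesis); `"table2"` — 26 persons' published
#' Bayes factors for four hypotheses versus the unconstrained hypothesis and
#' versus their complements, with censor flags on entries printed as
#' "< 0.01"; `"table3"` — seven hypothetical sets of individual Bayes
#' factors used to illustrate aggregation; `"table4_gp"` — the published
#' gP-BF values for the table2 data (side references for ER/SR when the
#' censored columns only bound the gP-BF).
#'
#' @param name One of `"table1"`, `"table1_hypotheses"`, `"table2"`,
#'   `"table3"`, `"table4_gp"`.
#' @return A tibble, or an [hypothesis_set()] for `"table1_hypotheses"`.
#' @export
nof1_fixture <- function(name = fixture_names) {
  name <- match.arg(name)
  if (name == "table1_hypotheses") {
    return(read_hypotheses(system.file("extdata", "table1_hypotheses.yaml",
                                       package = "nof1bf", mustWork = TRUE)))
  }
  file <- paste0(switch(name, table1 = "table1_counts",
                        table2 = "table2_bf", table3 = "table3_bf",
                        table4_gp = "table4_gp"), ".csv")
  readr::read_csv(system.file("extdata", file, package = "nof1bf",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Write fixture files to a directory
#'
#' Materialises a named fixture as files for use with the command-line
#' front end: `"table1"` writes the counts CSV plus the matching hypothesis
#' YAML; `"table2"` / `"table3"` write the Bayes factor CSVs.
#'
#' @param name Fixture name, as in [nof1_fixture()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
generate_fixture <- function(name = fixture_names, dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- switch(name,
                table1 = c("table1_counts.csv", "table1_hypotheses.yaml"),
                table1_hypotheses = "table1_hypotheses.yaml",
                table2 = "table2_bf.csv",
                table3 = "table3_bf.csv",
                table4_gp = "table4_gp.csv")
  paths <- character(length(src))
  for (i in seq_along(src)) {
    from <- system.file("extdata", src[i], package = "nof1bf",
                        mustWork = TRUE)
    paths[i] <- file.path(dir, src[i])
    file.copy(from, paths[i], overwrite = TRUE)
  }
  invisible(paths)
}
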