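## Delimited-text input/output: survey microdata, benchmark tables, weight
## vectors, and the structured run summary written by the command line
## interface. Comma is the default delimiter; tab is accepted.

.read_delim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read survey microdata from a delimited text file
#'
#' Expects a header with at least `unit_id` and `weight` columns; `psu_id`
#' is used when present. Remaining columns become benchmark variables:
#' numeric columns are treated as continuous, everything else as
#' categorical (override with `categorical`).
#'
#' @param path file path (comma- or tab-delimited, sniffed from the header).
#' @param sep optional explicit field separator.
#' @param categorical character vector of column names to force categorical
#'   even if numeric-looking.
#' @return A [sample_data()] object.
#' @export
read_sample <- function(path, sep = NULL, categorical = character(0)) {
  df <- .read_delim(path, sep)
  for (required in c("unit_id", "weight")) {
    if (!required %in% names(df)) {
      stop("sample file ", path, ": missing required column '", required, "'")
    }
  }
  for (cn in intersect(categorical, names(df))) {
    df[[cn]] <- as.character(df[[cn]])
  }
  sample_data(df)
}

#' Write survey microdata
#'
#' Inverse of [read_sample()]; numeric values keep full round-trip
#' precision.
#'
#' @param sample a [sample_data()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @export
write_sample <- function(sample, path, sep = ",") {
  stopifnot(inherits(sample, "sample_data"))
  df <- data.frame(unit_id = sample$unit_id, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(sample$psu_id)) df$psu_id <- sample$psu_id
  df$weight <- sample$d
  for (cn in names(sample$variables)) df[[cn]] <- sample$variables[[cn]]
  .write_delim(df, path, sep)
  invisible(path)
}

.write_delim <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    df[[cn]] <- vapply(df[[cn]], function(x) {
      if (is.na(x)) return("NA")
      if (!is.finite(x)) return(as.character(x))
      if (x == round(x) && abs(x) < 2^53) return(format(x, scientific = FALSE))
      sprintf("%.17g", x)
    }, character(1))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a benchmark table from a delimited text file
#'
#' One row per constraint: columns `variables` (`;`-joined names, `*` for
#' the all-units constraint), `categories` (`;`-joined labels, empty for
#' continuous), `total`, and optional `exact` (0/1), `r`, `v`, `eps_cap`.
#'
#' @inheritParams read_sample
#' @return A [benchmark_spec()].
#' @export
read_benchmarks <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  if (!nrow(df)) stop("benchmark file ", path, ": no constraints (p >= 1)")
  for (required in c("variables", "total")) {
    if (!required %in% names(df)) {
      stop("benchmark file ", path, ": missing column '", required, "'")
    }
  }
  if (any(!is.finite(df$total) | df$total < 0)) {
    stop("benchmark file ", path, ": totals must be finite and nonnegative")
  }
  cats <- if ("categories" %in% names(df)) {
    out <- as.character(df$categories)
    out[!nzchar(trimws(out)) | is.na(out)] <- NA_character_
    out
  } else NA_character_
  benchmark_spec(
    variables = df$variables, categories = cats, total = df$total,
    exact = if ("exact" %in% names(df)) df$exact %in% c(1, "1", TRUE, "TRUE")
      else FALSE,
    r = if ("r" %in% names(df)) df$r else 1,
    v = if ("v" %in% names(df)) df$v else NA_real_,
    eps_cap = if ("eps_cap" %in% names(df)) df$eps_cap else NA_real_)
}

#' Write a benchmark table
#' @param spec a [benchmark_spec()].
#' @inheritParams write_sample
#' @export
write_benchmarks <- function(spec, path, sep = ",") {
  stopifnot(inherits(spec, "benchmark_spec"))
  df <- as.data.frame(spec)
  df$exact <- as.integer(df$exact)
  .write_delim(df, path, sep)
  invisible(path)
}

#' Write calibrated weights
#'
#' Two columns, `unit_id` and `weight`, at full round-trip precision.
#'
#' @param w weight vector.
#' @param unit_id unit identifiers (same length).
#' @inheritParams write_sample
#' @export
write_weights <- function(w, unit_id, path, sep = ",") {
  stopifnot(length(w) == length(unit_id))
  .write_delim(data.frame(unit_id = unit_id, weight = w), path, sep)
  invisible(path)
}

#' Write a scenario to a directory of delimited files
#'
#' Emits `sample.csv`, `benchmarks.csv` (broad exact rows first, then the
#' fine inexact rows) and `validation.csv` so the command-line interface
#' can run end-to-end on generated data.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample(scenario$sample, file.path(dir, "sample.csv"))
  write_benchmarks(c(scenario$broad_benchmarks, scenario$fine_benchmarks),
                   file.path(dir, "benchmarks.csv"))
  .write_delim(scenario$validation_table, file.path(dir, "validation.csv"))
  invisible(dir)
}

#' Write the structured run summary
#'
#' Single JSON file per run: schema version, configuration echo, and every
#' solver decision (branch, budgets, tolerances, seeds) for audit.
#'
#' @param summary named list.
#' @param path output path.
#' @export
write_run_summary <- function(summary, path) {
  summary <- c(list(schema_version = 1L), summary)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
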