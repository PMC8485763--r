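## Delimited-table I/O with row-level validation.  Tables are tab-separated
## with a header row; numeric columns may use comma digit grouping
## ("9,280,000"), which is stripped on read.

read_table_checked <- function(path, columns, delim = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = delim, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(columns), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  if (!nrow(df)) {
    warning(sprintf("%s: empty table", path))
    return(df)
  }
  for (col in names(columns)) {
    spec <- columns[[col]]
    v <- df[[col]]
    if (spec$type == "numeric") {
      v <- suppressWarnings(as.numeric(gsub(",", "", trimws(as.character(v)))))
      bad <- which(is.na(v))
      if (length(bad))
        stop(sprintf("%s: line %d, column '%s': not a number", path,
                     bad[1L] + 1L, col))
      if (!is.null(spec$min) && any(v < spec$min))
        stop(sprintf("%s: line %d, column '%s': value below %g", path,
                     which(v < spec$min)[1L] + 1L, col, spec$min))
      if (isTRUE(spec$integer) && any(abs(v - round(v)) > 1e-8))
        stop(sprintf("%s: line %d, column '%s': not an integer", path,
                     which(abs(v - round(v)) > 1e-8)[1L] + 1L, col))
      df[[col]] <- v
    } else {
      df[[col]] <- as.character(v)
    }
  }
  df
}

#' Read per-culture fluctuation-assay counts
#'
#' Tab-separated file with header and columns `label` (experiment/strain)
#' and `count` (resistant colonies per culture, non-negative integer).
#' Validation failures are reported with file and line number.
#'
#' @param path file path.
#' @return data frame with columns `label`, `count`.
#' @export
read_fluctuation_counts <- function(path) {
  read_table_checked(path, list(
    label = list(type = "character"),
    count = list(type = "numeric", min = 0, integer = TRUE)))
}

#' Read per-experiment metadata (plating fraction and population size)
#'
#' Columns: `label`, `epsilon` (plating fraction in (0, 1]) and `Nt`
#' (final cells per culture).
#'
#' @param path file path.
#' @return data frame with columns `label`, `epsilon`, `Nt`.
#' @export
read_experiment_meta <- function(path) {
  df <- read_table_checked(path, list(
    label = list(type = "character"),
    epsilon = list(type = "numeric", min = 0),
    Nt = list(type = "numeric", min = 1)))
  if (nrow(df) && any(df$epsilon > 1 | df$epsilon <= 0))
    stop(sprintf("%s: epsilon must be in (0, 1]", path))
  df
}

#' Read gel lane profiles from a long-format table
#'
#' Columns: `lane`, `distance`, `intensity`, and optionally `rnhB`
#' (`wt`/`drnhB`) and `dnaE`.  Rows are grouped by `lane` into
#' [lane_profile()] objects (distances sorted increasing).
#'
#' @param path file path.
#' @return named list of [lane_profile()] objects.
#' @export
read_lane_profiles <- function(path) {
  df <- read_table_checked(path, list(
    lane = list(type = "character"),
    distance = list(type = "numeric"),
    intensity = list(type = "numeric", min = 0)))
  lanes <- split(df, df$lane)
  lapply(lanes, function(d) {
    d <- d[order(d$distance), ]
    lane_profile(d$distance, d$intensity, label = d$lane[1L],
                 rnhB = if ("rnhB" %in% names(d)) d$rnhB[1L] else "wt",
                 dnaE = if ("dnaE" %in% names(d)) d$dnaE[1L] else "dnaE_wt")
  })
}

#' Read a substitution-call table
#'
#' Columns: `isolate`, `position` (1-based), `ref`, `alt` (single bases).
#'
#' @param path file path.
#' @return data frame of calls.
#' @export
read_substitution_calls <- function(path) {
  df <- read_table_checked(path, list(
    isolate = list(type = "character"),
    position = list(type = "numeric", min = 1, integer = TRUE),
    ref = list(type = "character"),
    alt = list(type = "character")))
  if (nrow(df)) {
    df$position <- as.integer(df$position)
    df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
    bad <- which(!(df$ref %in% c("A", "C", "G", "T")) |
                 !(df$alt %in% c("A", "C", "G", "T")) | df$ref == df$alt)
    if (length(bad))
      stop(sprintf("%s: line %d: invalid substitution (%s>%s)", path,
                   bad[1L] + 1L, df$ref[bad[1L]], df$alt[bad[1L]]))
  }
  df
}

#' Read isolate sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet`, returning plain named
#' character strings ready for [call_substitutions()].
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_isolate_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a data frame as a tab-separated table
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics with an optional two-sample t test
#'
#' Mean and standard error (or standard deviation) of a sample, optionally
#' with an unpaired two-tailed t test (Welch or pooled-variance) against a
#' second sample.
#'
#' @param samples numeric vector (n >= 1; n >= 2 for SEM or a test).
#' @param test_against optional second sample.
#' @param error `"sem"` or `"sd"`.
#' @param test `"welch"` or `"pooled"`.
#' @return list with `mean`, `sem` or `sd`, `n`, and (when `test_against`
#'   is given) `t`, `df`, `p`.
#' @export
descriptive_stats <- function(samples, test_against = NULL,
                              error = c("sem", "sd"),
                              test = c("welch", "pooled")) {
  error <- match.arg(error); test <- match.arg(test)
  if (!length(samples)) stop("`samples` must be non-empty")
  n <- length(samples)
  out <- list(mean = mean(samples), n = n)
  if (n >= 2L) {
    s <- sd(samples)
    out[[error]] <- if (error == "sem") s / sqrt(n) else s
  } else if (!is.null(test_against) || error == "sem") {
    stop("need >= 2 observations for SEM or a test")
  }
  if (!is.null(test_against)) {
    if (length(test_against) < 2L)
      stop("need >= 2 observations in `test_against`")
    tt <- t.test(samples, test_against, var.equal = (test == "pooled"))
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  out
}

#' Write a machine-readable run manifest
#'
#' Records inputs, parameters, seed and package version for a pipeline run
#' so deterministic stages can be reproduced byte for byte.
#'
#' @param path output JSON path.
#' @param stage pipeline stage name.
#' @param inputs named list/vector of input file paths.
#' @param params named list of stage parameters.
#' @param seed integer seed or `NULL` for deterministic stages.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, inputs = list(),
                               params = list(), seed = NULL) {
  manifest <- list(stage = stage,
                   package = "replifid",
                   version = as.character(packageVersion("replifid")),
                   inputs = inputs, params = params,
                   seed = seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
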