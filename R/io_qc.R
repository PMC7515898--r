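#' Cohort tables of pyrosequencing methylation
#'
#' A cohort table is a `data.frame` with one row per individual and columns
#' `sample_id`, `age`, `study`, `cpg1`..`cpg7` (methylation percentages on the
#' 0--100 scale, `NA` for missing measurements) plus an optional `role` column
#' (`training`, `testing`, `independent` or `unassigned`). The constructor
#' validates the invariants: unique sample ids, non-negative ages, methylation
#' within \[0, 100\].
#'
#' @param df data.frame with the columns above.
#' @param role role assigned to the whole table; overrides any `role` column
#'   when given.
#' @return A `cohort_table` (classed data.frame).
#' @export
cohort_table <- function(df, role = NULL) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "age", "study", CPG_COLS)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$study <- as.character(df$study)
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age < 0))
    stop("age must be non-negative and non-missing")
  if (anyDuplicated(df$sample_id))
    stop("sample_ids must be unique within a cohort table")
  for (cc in CPG_COLS) {
    v <- as.numeric(df[[cc]])
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad) > 0L)
      stop(sprintf("methylation outside [0,100] in column %s, row %d (value %g)",
                   cc, bad[1L], v[bad[1L]]))
    df[[cc]] <- v
  }
  if (!is.null(role)) {
    role <- match.arg(role, c("unassigned", "training", "testing", "independent"))
    df$role <- role
  } else if (is.null(df$role)) {
    df$role <- "unassigned"
  }
  rownames(df) <- NULL
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Extract the n x 7 methylation matrix from a cohort table
#'
#' @param table cohort_table.
#' @return Numeric matrix with columns `cpg1`..`cpg7` and rownames taken from
#'   `sample_id`.
#' @export
meth_matrix <- function(table) {
  m <- as.matrix(table[, CPG_COLS, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

#' Read a methylation table from CSV or TSV
#'
#' Expected header (case-insensitive): `sample_id`, `age`, `study`,
#' `cpg1`..`cpg7`, optionally `role`. Missing methylation values are encoded
#' as empty fields or `NA`. Methylation is accepted on the percent (0--100)
#' scale; a file whose methylation values all lie in \[0, 1\] is rejected as a
#' probable fraction-scale file unless `rescale_fractions = TRUE`, in which
#' case values are multiplied by 100.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param rescale_fractions multiply 0--1 fraction-scale methylation by 100
#'   instead of rejecting it.
#' @return A [cohort_table()].
#' @export
read_methylation_table <- function(path, dialect = c("csv", "tsv"),
                                   rescale_fractions = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  names(df) <- tolower(names(df))
  required <- c("sample_id", "age", "study", CPG_COLS)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
  mm <- as.matrix(df[, CPG_COLS])
  storage.mode(mm) <- "double"
  obs <- mm[!is.na(mm)]
  if (length(obs) > 0L && all(obs <= 1)) {
    if (!rescale_fractions)
      stop("all methylation values are <= 1: this looks like a 0-1 fraction ",
           "scale; pass rescale_fractions = TRUE to rescale to percent")
    df[CPG_COLS] <- as.data.frame(mm * 100)
  }
  cohort_table(df)
}

#' Apply the cohort quality-control exclusions
#'
#' Removes (1) every sample named in `outlier_ids` (the CpG7-outlier list;
#' the published analysis excluded 73 such samples from one source study) and
#' (2) every sample with at least one missing methylation value among the 7
#' CpGs. Unknown outlier ids produce a warning and are ignored.
#'
#' @param table cohort_table.
#' @param outlier_ids character vector of sample ids to exclude (may be empty).
#' @return A list with `table` (the retained samples) and `report`, an
#'   `exclusion_report` with fields `excluded_outliers`, `excluded_missing`,
#'   `n_input`, `n_retained`.
#' @export
apply_exclusions <- function(table, outlier_ids = character()) {
  stopifnot(inherits(table, "cohort_table"))
  outlier_ids <- as.character(outlier_ids)
  unknown <- setdiff(outlier_ids, table$sample_id)
  if (length(unknown) > 0L) {
    warning("ignoring ", length(unknown), " unknown outlier id(s): ",
            paste(head(unknown, 5L), collapse = ", "))
    outlier_ids <- setdiff(outlier_ids, unknown)
  }
  n_input <- nrow(table)
  is_outlier <- table$sample_id %in% outlier_ids
  has_missing <- apply(is.na(meth_matrix(table)), 1L, any)
  excluded_outliers <- table$sample_id[is_outlier]
  excluded_missing <- table$sample_id[!is_outlier & has_missing]
  keep <- !is_outlier & !has_missing
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(
    list(excluded_outliers = excluded_outliers,
         excluded_missing = excluded_missing,
         n_input = n_input,
         n_retained = nrow(out)),
    class = "exclusion_report")
  stopifnot(report$n_retained ==
              n_input - length(excluded_outliers) - length(excluded_missing))
  list(table = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d input, %d retained (%d CpG7 outliers, %d with missing values)\n",
              x$n_input, x$n_retained,
              length(x$excluded_outliers), length(x$excluded_missing)))
  invisible(x)
}

#' Flag candidate CpG7 outliers (exploratory helper)
#'
#' The published exclusion of CpG7 outliers is given only as an id list; no
#' numeric rule is stated. This helper flags, for exploration only, samples
#' whose CpG7 methylation lies more than `k` robust SDs *below* a running
#' median of CpG7 against age. It is never applied automatically.
#'
#' @param table cohort_table with no missing cpg7 values among flag candidates.
#' @param k robust-SD multiplier (default 3).
#' @return Character vector of candidate sample ids.
#' @export
flag_cpg7_outliers <- function(table, k = 3) {
  ok <- !is.na(table$cpg7)
  ord <- order(table$age[ok])
  x <- table$cpg7[ok][ord]
  n <- length(x)
  if (n < 7L) return(character())
  win <- min(2L * (n %/% 10L) + 1L, n - (1L - n %% 2L))
  win <- max(win, 7L)
  if (win %% 2L == 0L) win <- win + 1L
  med <- runmed(x, k = min(win, if (n %% 2L == 1L) n else n - 1L))
  resid <- x - med
  s <- mad(resid)
  if (s == 0) return(character())
  flagged <- resid < -k * s
  table$sample_id[ok][ord][flagged]
}

#' Split a cohort into training and testing sets
#'
#' Random disjoint partition, reproducible under `seed`. The published pooled
#' cohort of 1,413 samples was split into 1,028 training and 385 testing
#' individuals; the split seed is unpublished, so it is a required argument
#' here. Alternatively a pre-assigned `role` column can be honoured via
#' [split_by_role()].
#'
#' @param table cohort_table.
#' @param n_training number of training samples, strictly between 0 and
#'   `nrow(table)`.
#' @param seed integer seed.
#' @return List with `training` and `testing` cohort tables.
#' @export
random_split <- function(table, n_training, seed) {
  stopifnot(inherits(table, "cohort_table"))
  n <- nrow(table)
  if (!is.numeric(n_training) || length(n_training) != 1L ||
      n_training <= 0 || n_training >= n)
    stop("n_training must satisfy 0 < n_training < n_samples (", n, ")")
  rng <- local_rng(seed)
  idx <- sample.int(n, size = as.integer(n_training))
  training <- table[sort(idx), , drop = FALSE]
  testing <- table[-sort(idx), , drop = FALSE]
  training$role <- "training"
  testing$role <- "testing"
  rownames(training) <- rownames(testing) <- NULL
  list(training = training, testing = testing)
}

#' Split a cohort by a pre-assigned role column
#'
#' @param table cohort_table whose `role` column contains `training` and
#'   `testing` labels (e.g. read from a published split assignment).
#' @return List with `training` and `testing` cohort tables.
#' @export
split_by_role <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (!all(c("training", "testing") %in% table$role))
    stop("role column must contain both 'training' and 'testing'")
  list(training = table[table$role == "training", , drop = FALSE],
       testing = table[table$role == "testing", , drop = FALSE])
}

#' Write per-sample age predictions to CSV
#'
#' @param table cohort_table.
#' @param predictions numeric vector of predicted ages, one per sample, in
#'   table order.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(table, predictions, path) {
  stopifnot(inherits(table, "cohort_table"))
  if (length(predictions) != nrow(table))
    stop("length mismatch: ", nrow(table), " samples but ",
         length(predictions), " predictions")
  out <- data.frame(sample_id = table$sample_id,
                    age = table$age,
                    predicted_age = as.numeric(predictions),
                    residual = as.numeric(predictions) - table$age)
  write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions CSV written by [write_predictions()]
#'
#' @param path file path.
#' @return data.frame with columns sample_id, age, predicted_age, residual.
#' @export
read_predictions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "age", "predicted_age", "residual") %in% names(df)))
  df
}

#' Read an exclusion id list (one sample_id per line)
#'
#' @param path plain-text file, one id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of ids.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

## Seed handling: all package randomness flows through named seeds; the
## caller's global RNG stream is restored on exit.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) stop("a seed is required")
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  restore <- if (has_seed) {
    old <- get(".Random.seed", globalenv())
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}
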