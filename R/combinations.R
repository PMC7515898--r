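#' Predictor combinations over the CpG panel
#'
#' A predictor combination is a non-empty subset of variables from one of two
#' scopes: `"cpg7"` (the 7 CpG methylation values; subsets of 1..7) or
#' `"mqr14"` (multiple quadratic regression: the 7 methylation values plus
#' their 7 squares, encoded as variable ids 1..14 where id `i + 7` is CpG i
#' squared). Each combination has a canonical human-readable label such as
#' `"CpG_2-3,5-7"` or `"CpG_4-6 & CpG_2^2-4^2,6^2-7^2"`, which is a bijection
#' with the variable set (see [parse_combination_label()]).
#'
#' @param scope `"cpg7"` or `"mqr14"`.
#' @param variables integer vector of unique variable ids (1..7 for cpg7,
#'   1..14 for mqr14).
#' @return A `predictor_combination` object.
#' @export
predictor_combination <- function(scope = c("cpg7", "mqr14"), variables) {
  scope <- match.arg(scope)
  variables <- sort(unique(as.integer(variables)))
  max_id <- if (scope == "cpg7") 7L else 14L
  if (length(variables) == 0L) stop("combination must be non-empty")
  if (any(variables < 1L | variables > max_id))
    stop("variable ids must lie in 1..", max_id, " for scope ", scope)
  structure(list(scope = scope, variables = variables,
                 label = combination_label(scope, variables)),
            class = "predictor_combination")
}

## Compress sorted integers into a "1-3,5" run string.
compress_runs <- function(ids) {
  if (length(ids) == 0L) return("")
  breaks <- c(0L, which(diff(ids) != 1L), length(ids))
  parts <- vapply(seq_len(length(breaks) - 1L), function(j) {
    run <- ids[(breaks[j] + 1L):breaks[j + 1L]]
    if (length(run) == 1L) as.character(run)
    else paste0(run[1L], "-", run[length(run)])
  }, "")
  paste(parts, collapse = ",")
}

expand_runs <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1L]]
  unlist(lapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
    if (length(ab) == 1L) ab else seq(ab[1L], ab[2L])
  }))
}

combination_label <- function(scope, variables) {
  lin <- variables[variables <= 7L]
  sq <- variables[variables > 7L] - 7L
  lin_part <- if (length(lin) > 0L) paste0("CpG_", compress_runs(lin)) else ""
  sq_part <- if (length(sq) > 0L) {
    paste0("CpG_", gsub("(\\d+)", "\\1^2", compress_runs(sq)))
  } else ""
  if (nzchar(lin_part) && nzchar(sq_part)) paste(lin_part, "&", sq_part)
  else paste0(lin_part, sq_part)
}

#' Parse a canonical combination label back to a combination
#'
#' @param label label produced by [predictor_combination()].
#' @param scope scope to parse under; squared terms require `"mqr14"`.
#' @return A [predictor_combination()].
#' @export
parse_combination_label <- function(label, scope = c("cpg7", "mqr14")) {
  scope <- match.arg(scope)
  halves <- strsplit(label, " & ", fixed = TRUE)[[1L]]
  vars <- integer()
  for (h in halves) {
    if (!grepl("^CpG_", h)) stop("unparseable combination label: ", label)
    body <- sub("^CpG_", "", h)
    if (grepl("^", body, fixed = TRUE)) {
      ids <- expand_runs(gsub("\\^2", "", body))
      vars <- c(vars, ids + 7L)
    } else {
      vars <- c(vars, expand_runs(body))
    }
  }
  predictor_combination(scope, vars)
}

#' @export
print.predictor_combination <- function(x, ...) {
  cat(sprintf("<%s combination> %s (%d variable%s)\n", x$scope, x$label,
              length(x$variables), if (length(x$variables) > 1L) "s" else ""))
  invisible(x)
}

#' Enumerate every non-empty predictor combination of a scope
#'
#' All `2^p - 1` non-empty subsets, in deterministic order: by subset size,
#' then lexicographically within a size. The 7-CpG scope yields 127
#' combinations; the 14-variable quadratic-regression scope yields 16,383 —
#' with the four other 7-CpG families this gives the full complement of
#' 16,383 + 5 x 127 = 17,018 candidate models.
#'
#' @param scope `"cpg7"` or `"mqr14"`.
#' @return List of [predictor_combination()] objects.
#' @export
enumerate_combinations <- function(scope = c("cpg7", "mqr14")) {
  scope <- match.arg(scope)
  p <- if (scope == "cpg7") 7L else 14L
  out <- vector("list", 2L^p - 1L)
  k <- 0L
  for (size in seq_len(p)) {
    sets <- combn(p, size, simplify = FALSE)
    for (s in sets) {
      k <- k + 1L
      out[[k]] <- predictor_combination(scope, s)
    }
  }
  out
}

## Design column name for a variable id.
var_name <- function(id) {
  ifelse(id <= 7L, paste0("cpg", id), paste0("cpg", id - 7L, "_sq"))
}

#' Expand a cohort table into a design matrix for a combination
#'
#' Column j holds the methylation of the j-th variable of the combination:
#' the raw percentage for a linear variable, its square for a squared
#' (quadratic-regression) variable. Ages are returned aligned by row.
#'
#' @param table cohort_table with no missing values among the combination's
#'   CpGs.
#' @param combination [predictor_combination()].
#' @return List with `X` (n x k numeric matrix, named columns) and `age`.
#' @export
expand_design <- function(table, combination) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(combination, "predictor_combination"))
  mm <- meth_matrix(table)
  cpgs <- ifelse(combination$variables <= 7L, combination$variables,
                 combination$variables - 7L)
  na_hit <- which(is.na(mm[, unique(cpgs), drop = FALSE]), arr.ind = TRUE)
  if (nrow(na_hit) > 0L) {
    cpg_used <- unique(cpgs)[na_hit[1L, 2L]]
    stop(sprintf("missing methylation for sample %s at cpg%d",
                 table$sample_id[na_hit[1L, 1L]], cpg_used))
  }
  X <- sapply(combination$variables, function(id) {
    col <- mm[, if (id <= 7L) id else id - 7L]
    if (id <= 7L) col else col^2
  })
  X <- matrix(X, nrow = nrow(table),
              dimnames = list(table$sample_id,
                              var_name(combination$variables)))
  list(X = X, age = table$age)
}
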