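#' Fit one (family, combination) model and evaluate it on both sets
#'
#' Dispatcher used by the exhaustive search. The direct-regression families
#' fit on the training set and predict both sets; the imputation family
#' (`mmda`) pools the two sets per its contract.
#'
#' @param training,testing cohort_tables.
#' @param spec [model_spec()].
#' @param combination [predictor_combination()].
#' @return List: `record` (one-row data.frame of metrics), `model` (a
#'   fitted_model, or NULL for the imputation family), `predictions`
#'   (testing-set predicted ages).
#' @export
fit_and_evaluate <- function(training, testing, spec, combination) {
  res <- fit_eval_core(training, testing, spec, combination)
  record <- as.data.frame(res$values, stringsAsFactors = FALSE)
  list(record = record, model = res$model, predictions = res$predictions)
}

## Core of one search cell, returning the record as a flat list (the
## exhaustive search assembles 16k+ of these, so no per-fit data.frame).
## `cache` optionally holds the full expanded designs of both sets so the
## 16,383-combination scope only subsets columns per fit.
fit_eval_core <- function(training, testing, spec, combination,
                          cache = NULL) {
  if (spec$family == "mmda") {
    res <- mmda_predict_age(training, testing, combination, spec)
    pred_tr <- res$fitted_training
    pred_te <- res$predicted
    model <- NULL
  } else {
    if (is.null(cache)) {
      d <- expand_design(training, combination)
      Xtr <- d$X
      Xte <- NULL
    } else {
      idx <- combination$variables
      Xtr <- cache$Xtr[, idx, drop = FALSE]
      Xte <- cache$Xte[, idx, drop = FALSE]
      d <- list(age = cache$age_tr)
    }
    model <- switch(spec$family,
      zp1_mlr = ,
      mqr = fit_linear_family(Xtr, d$age, spec, combination),
      svm_r = , svm_l = , svm_p = fit_svm(Xtr, d$age, spec, combination),
      gbr = fit_gbr(Xtr, d$age, spec, combination),
      stop("unknown family ", spec$family))
    if (is.null(cache)) {
      pred_tr <- predict(model, training)
      pred_te <- predict(model, testing)
    } else {
      pred_tr <- unname(predict_design(model, Xtr))
      pred_te <- unname(predict_design(model, Xte))
    }
  }
  mtr <- metric_set(pred_tr, training$age)
  mte <- metric_set(pred_te, testing$age)
  values <- list(
    family = spec$family, label = combination$label,
    scope = combination$scope, n_vars = length(combination$variables),
    r_train = mtr$pearson_r, mad_train = mtr$mad, rmse_train = mtr$rmse,
    r_test = mte$pearson_r, mad_test = mte$mad, rmse_test = mte$rmse,
    n_train = mtr$n, n_test = mte$n,
    hyper = hyper_fingerprint(spec), failed = FALSE, reason = "")
  list(values = values, model = model, predictions = pred_te)
}

hyper_fingerprint <- function(spec) {
  keep <- setdiff(names(spec), c("family", "injected_coef"))
  vals <- vapply(keep, function(k) {
    v <- spec[[k]]
    if (is.null(v)) "auto" else paste(format(v, digits = 6), collapse = "|")
  }, "")
  paste(paste0(keep, "=", vals), collapse = ";")
}

## Scope a family searches over: quadratic regression uses the 14-variable
## scope, every other family the 7-CpG scope.
family_scope <- function(family) if (family == "mqr") "mqr14" else "cpg7"

#' Default six-family search plan
#'
#' The published procedure: quadratic regression over the 14-variable scope
#' (16,383 combinations) and five further families over the 7-CpG scope
#' (5 x 127), totalling 17,018 candidate models. The two-CpG linear baseline
#' is evaluated separately (it is one fixed combination, not searched).
#'
#' @param ... per-family [model_spec()] overrides, named by family.
#' @return Named list of model_specs.
#' @export
default_search_families <- function(...) {
  over <- list(...)
  fams <- c("mqr", "svm_r", "svm_l", "svm_p", "gbr", "mmda")
  specs <- lapply(fams, function(f) over[[f]] %||% model_spec(f))
  names(specs) <- fams
  specs
}

#' Exhaustively search every (family, combination) model
#'
#' Fits and evaluates every combination of each family's scope on the
#' training set and reports MAD, RMSE and Pearson R on both the training and
#' testing sets. Individual fit failures are recorded (flagged rows) without
#' stopping the search. When `checkpoint_dir` is given, completed families
#' are written to `<dir>/search_<family>.csv` and re-runs skip them.
#'
#' @param training,testing disjoint, QC'd cohort_tables.
#' @param families named list of [model_spec()]s (default the six-family
#'   plan of [default_search_families()]).
#' @param checkpoint_dir optional directory for resumable checkpoints.
#' @param verbose print per-family progress.
#' @return A `search_records` data.frame, one row per (family, combination).
#' @export
run_exhaustive_search <- function(training, testing,
                                  families = default_search_families(),
                                  checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(training, "cohort_table"),
            inherits(testing, "cohort_table"))
  if (length(intersect(training$sample_id, testing$sample_id)) > 0L)
    stop("training and testing sets must be disjoint")
  if (is.null(names(families)))
    names(families) <- vapply(families, `[[`, "", "family")
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  out <- vector("list", length(families))
  for (fi in seq_along(families)) {
    spec <- families[[fi]]
    fam <- spec$family
    ckpt <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, paste0("search_", names(families)[fi], ".csv"))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      if (verbose) message("resume: skipping completed family ", fam)
      out[[fi]] <- read.csv(ckpt, stringsAsFactors = FALSE,
                            colClasses = c(reason = "character"))
      next
    }
    combos <- enumerate_combinations(family_scope(fam))
    if (verbose)
      message(sprintf("family %s: %d combinations", fam, length(combos)))
    cache <- if (fam != "mmda") {
      full <- predictor_combination(family_scope(fam),
                                    seq_len(if (fam == "mqr") 14L else 7L))
      dtr <- expand_design(training, full)
      dte <- expand_design(testing, full)
      list(Xtr = dtr$X, Xte = dte$X, age_tr = dtr$age)
    }
    recs <- vector("list", length(combos))
    hyper <- hyper_fingerprint(spec)
    for (ci in seq_along(combos)) {
      recs[[ci]] <- tryCatch(
        fit_eval_core(training, testing, spec, combos[[ci]], cache)$values,
        error = function(e) {
          comb <- combos[[ci]]
          list(family = fam, label = comb$label, scope = comb$scope,
               n_vars = length(comb$variables),
               r_train = NA_real_, mad_train = NA_real_, rmse_train = NA_real_,
               r_test = NA_real_, mad_test = NA_real_, rmse_test = NA_real_,
               n_train = NA_integer_, n_test = NA_integer_, hyper = hyper,
               failed = TRUE, reason = conditionMessage(e))
        })
      if (verbose && ci %% 1000L == 0L)
        message(sprintf("  %s: %d/%d", fam, ci, length(combos)))
    }
    cols <- names(recs[[1L]])
    out[[fi]] <- as.data.frame(
      setNames(lapply(cols, function(cn)
        unlist(lapply(recs, `[[`, cn), use.names = FALSE)), cols),
      stringsAsFactors = FALSE)
    if (!is.null(ckpt)) write.csv(out[[fi]], ckpt, row.names = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- unique(c("search_records", class(res)))
  res
}

#' Select the best combination of a family
#'
#' Minimal MAD on the chosen reference set; ties are broken first by fewer
#' variables, then by lexicographic label, so selection is deterministic and
#' invariant to record order. The caller must name the reference set
#' explicitly — selecting on the testing set is the published "V" reading
#' and is a deliberate, visible choice, never a silent default.
#'
#' @param records search_records data.frame.
#' @param family family to select within.
#' @param reference `"training"` or `"testing"`.
#' @return The winning record (one-row data.frame).
#' @export
select_best_combination <- function(records, family,
                                    reference = c("training", "testing")) {
  reference <- match.arg(reference)
  sub <- records[records$family == family & !records$failed, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no successful records for family ", family)
  madcol <- if (reference == "training") "mad_train" else "mad_test"
  ord <- order(sub[[madcol]], sub$n_vars, sub$label, method = "radix")
  sub[ord[1L], , drop = FALSE]
}

#' Table-style per-family summary of a search
#'
#' One row per family and reference set (training-selected "T" and
#' testing-selected "V"), mirroring the published results layout.
#'
#' @param records search_records.
#' @return data.frame with columns family, reference, label, n_vars and the
#'   six metrics.
#' @export
summarize_search <- function(records) {
  fams <- unique(records$family)
  rows <- list()
  for (fam in fams) {
    for (ref in c("training", "testing")) {
      best <- select_best_combination(records, fam, ref)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(reference = if (ref == "training") "T" else "V"),
        best[, c("family", "label", "n_vars", "r_train", "mad_train",
                 "rmse_train", "r_test", "mad_test", "rmse_test")])
    }
  }
  out <- do.call(rbind, rows)
  out[, c("family", "reference", "label", "n_vars", "r_train", "mad_train",
          "rmse_train", "r_test", "mad_test", "rmse_test")]
}

#' Average the predictions of several fitted models
#'
#' Unweighted per-sample mean of the member predictions: the multi-model
#' averaging step that can slightly improve accuracy when member errors are
#' not perfectly correlated.
#'
#' @param models non-empty list of fitted_models (all able to predict on
#'   `table`).
#' @param table cohort_table.
#' @param clip optional prediction clipping passed to each member.
#' @return Numeric vector of averaged predicted ages.
#' @export
average_model_predictions <- function(models, table, clip = NULL) {
  if (length(models) == 0L) stop("need at least one model")
  preds <- vapply(models, function(m) predict(m, table, clip = clip),
                  numeric(nrow(table)))
  preds <- matrix(preds, nrow = nrow(table))
  rowMeans(preds)
}
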