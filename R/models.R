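#' Model family specifications
#'
#' Families: `zp1_mlr` (the published two-CpG multiple-linear-regression
#' baseline, CpG5 + CpG7, refit on the active training set by default),
#' `mqr` (ordinary least squares over any subset of the 14
#' quadratic-regression variables), `svm_r`/`svm_l`/`svm_p`
#' (epsilon-insensitive support-vector regression with radial, linear or
#' polynomial kernel), `gbr` (gradient-boosted regression trees) and `mmda`
#' (age imputation via iterative PCA; see [mmda_impute()]).
#'
#' Hyperparameters were not published, so the defaults are standard and
#' declared rather than hidden: SVR epsilon 0.1, radial/polynomial kernel
#' coefficient `1/k` on standardized features, polynomial degree 3, and a
#' cost chosen per fit by the Cherkassky--Ma heuristic
#' `C = max(|mean(y) + 3 sd(y)|, |mean(y) - 3 sd(y)|)` from the training
#' ages (`cost = NULL`; a fixed SVR default of 1 over-regularizes a response
#' spanning 0--91 years and makes the radial family uncompetitive, which
#' contradicts the behaviour the model families are meant to reproduce --
#' pass an explicit `cost` to override); GBR 500 trees, learning rate 0.1,
#' depth 3; mMDA 2 components with ridge-type shrinkage. Feature
#' standardization is applied for the SVM families only (kernels are
#' scale-sensitive) and the constants are stored in every fitted model.
#'
#' @param family one of `"zp1_mlr"`, `"mqr"`, `"svm_r"`, `"svm_l"`,
#'   `"svm_p"`, `"gbr"`, `"mmda"`.
#' @param ... family-specific hyperparameter overrides (see Details).
#' @return A `model_spec` list with all hyperparameters filled in.
#' @export
model_spec <- function(family = c("zp1_mlr", "mqr", "svm_r", "svm_l", "svm_p",
                                  "gbr", "mmda"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    zp1_mlr = list(allow_rank_deficient = FALSE, injected_coef = NULL),
    mqr = list(allow_rank_deficient = FALSE),
    svm_r = list(cost = NULL, epsilon = 0.1, gamma = NULL, standardize = TRUE,
                 max_iter = 200000L, tol = 1e-3),
    svm_l = list(cost = NULL, epsilon = 0.1, standardize = TRUE,
                 max_iter = 200000L, tol = 1e-3),
    svm_p = list(cost = NULL, epsilon = 0.1, gamma = NULL, degree = 3L,
                 coef0 = 1, standardize = TRUE, max_iter = 200000L,
                 tol = 1e-3),
    gbr = list(n_trees = 500L, learning_rate = 0.1, max_depth = 3L,
               min_node = 10L, seed = 1L),
    mmda = list(ncp = 2L, regularization = "ridge-shrinkage", tol = 1e-6,
                max_iter = 1000L, scale_columns = TRUE))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  spec <- modifyList(defaults, over)
  spec$family <- family
  structure(spec, class = "model_spec")
}

## Cheap numeric fingerprint of the training data for provenance.
training_fingerprint <- function(X, age, seed = NA_integer_) {
  list(n = nrow(X), k = ncol(X), seed = seed,
       checksum = sum(X) + 7 * sum(age) + 0.13 * sum(X * X))
}

new_fitted_model <- function(family, spec, combination, parameters,
                             scaling = NULL, fingerprint = NULL) {
  structure(list(family = family, spec = spec, combination = combination,
                 parameters = parameters, scaling = scaling,
                 fingerprint = fingerprint),
            class = c(paste0("fitted_", family, "_model"), "fitted_model"))
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted %s model> combination %s, trained on n = %d\n",
              x$family, x$combination$label, x$fingerprint$n))
  invisible(x)
}

#' Fit the ordinary-least-squares families (Z-P1 baseline and MQR)
#'
#' Both the two-CpG linear baseline and multiple quadratic regression are
#' ordinary least squares on an intercept-augmented design. The solve is
#' QR-based; a rank-deficient design raises an error naming the aliased
#' columns unless `spec$allow_rank_deficient` requests the minimum-norm
#' solution. For the baseline, externally published coefficients can be
#' injected via `spec$injected_coef` (named vector `(Intercept)`, `cpg5`,
#' `cpg7`), in which case no fitting occurs.
#'
#' @param X n x k design matrix (no intercept column).
#' @param age numeric response (years).
#' @param spec [model_spec()] with family `"mqr"` or `"zp1_mlr"`.
#' @param combination the [predictor_combination()] the design came from.
#' @return A `fitted_model` whose parameters hold `coef` (intercept first)
#'   and the training residuals.
#' @export
fit_linear_family <- function(X, age, spec = model_spec("mqr"),
                              combination = NULL) {
  stopifnot(spec$family %in% c("mqr", "zp1_mlr"))
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(age) != n) stop("length mismatch between design and age")
  if (!is.null(spec$injected_coef)) {
    cf <- spec$injected_coef
    stopifnot(length(cf) == k + 1L)
    fitted <- drop(cbind(1, X) %*% cf)
    return(new_fitted_model(spec$family, spec, combination,
                            list(coef = cf, residuals = age - fitted,
                                 fitted = fitted, injected = TRUE),
                            fingerprint = training_fingerprint(X, age)))
  }
  if (n <= k) stop("need n > k observations for least squares")
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(Xi, age)
  if (fit$rank < ncol(Xi)) {
    aliased <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (!isTRUE(spec$allow_rank_deficient))
      stop("rank-deficient design (collinear variables: ",
           paste(aliased, collapse = ", "),
           "); remove collinear variables or set allow_rank_deficient")
    ## minimum-norm solution via the pseudo-inverse
    sv <- svd(Xi)
    pos <- sv$d > max(dim(Xi)) * .Machine$double.eps * sv$d[1L]
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], age)) / sv$d[pos])
    cf <- drop(cf)
    names(cf) <- colnames(Xi)
    fitted <- drop(Xi %*% cf)
    return(new_fitted_model(spec$family, spec, combination,
                            list(coef = cf, residuals = age - fitted,
                                 fitted = fitted, min_norm = TRUE),
                            fingerprint = training_fingerprint(X, age)))
  }
  cf <- fit$coefficients
  fitted <- drop(Xi %*% cf)
  new_fitted_model(spec$family, spec, combination,
                   list(coef = cf, residuals = age - fitted, fitted = fitted),
                   fingerprint = training_fingerprint(X, age))
}

#' Fit the published-style two-CpG linear baseline on a cohort
#'
#' Convenience wrapper: builds the CpG5 + CpG7 linear design and routes to
#' [fit_linear_family()].
#'
#' @param training cohort_table.
#' @param spec [model_spec()] of family `"zp1_mlr"`.
#' @return fitted_model.
#' @export
fit_zp1_baseline <- function(training, spec = model_spec("zp1_mlr")) {
  comb <- predictor_combination("cpg7", c(5L, 7L))
  d <- expand_design(training, comb)
  fit_linear_family(d$X, d$age, spec = spec, combination = comb)
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  if (any(scl == 0))
    stop("zero-variance feature with standardization on: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, scaling) {
  if (is.null(scaling)) return(X)
  sweep(sweep(X, 2L, scaling$center), 2L, scaling$scale, "/")
}

#' Fit epsilon-insensitive support-vector regression
#'
#' Solves the SVR dual by sequential minimal optimization (an in-package C++
#' solver; no external SVM library is required). Features are standardized by
#' default (constants learned on the training data and stored in the model).
#' The radial kernel is `exp(-gamma * ||u - v||^2)` and the polynomial kernel
#' `(gamma * u.v + coef0)^degree`; `gamma` defaults to `1 / (k * mean feature
#' variance)`, i.e. `1/k` after standardization. Deterministic given data and
#' hyperparameters.
#'
#' @inheritParams fit_linear_family
#' @param spec [model_spec()] with family `"svm_r"`, `"svm_l"` or `"svm_p"`.
#' @return fitted_model holding dual coefficients, intercept and the support
#'   vectors.
#' @export
fit_svm <- function(X, age, spec = model_spec("svm_r"), combination = NULL) {
  stopifnot(spec$family %in% c("svm_r", "svm_l", "svm_p"))
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (length(age) != nrow(X)) stop("length mismatch between design and age")
  scaling <- if (isTRUE(spec$standardize)) standardize_fit(X) else NULL
  Xs <- standardize_apply(X, scaling)
  kernel <- switch(spec$family, svm_l = 0L, svm_p = 1L, svm_r = 2L)
  ## Cherkassky-Ma cost heuristic: scales the epsilon-SVR capacity to the
  ## spread of the response, here ages spanning several decades
  cost <- spec$cost %||% max(abs(mean(age) + 3 * sd(age)),
                             abs(mean(age) - 3 * sd(age)))
  gamma <- spec$gamma %||% (1 / (ncol(X) * mean(apply(Xs, 2L, var))))
  degree <- spec$degree %||% 3L
  coef0 <- spec$coef0 %||% 0
  sol <- svr_smo_cpp(Xs, as.numeric(age), as.numeric(cost),
                     as.numeric(spec$epsilon), kernel, as.numeric(gamma),
                     as.integer(degree), as.numeric(coef0),
                     as.numeric(spec$tol), as.integer(spec$max_iter))
  keep <- abs(sol$beta) > 1e-12
  params <- list(beta = sol$beta[keep], b = sol$b,
                 SV = Xs[keep, , drop = FALSE],
                 kernel = kernel, cost = cost, gamma = gamma,
                 degree = degree, coef0 = coef0,
                 iterations = sol$iterations, converged = sol$converged)
  new_fitted_model(spec$family, spec, combination, params, scaling = scaling,
                   fingerprint = training_fingerprint(X, age))
}

#' Fit gradient-boosted regression trees
#'
#' Squared-error gradient boosting: each iteration fits an exact greedy
#' depth-limited regression tree (in-package C++) to the current residuals
#' and adds it with shrinkage `learning_rate`. `max_depth = 0` yields a
#' root-only tree, i.e. the training-mean predictor. Fully deterministic
#' under the spec's seed (no stochastic subsampling by default).
#'
#' @inheritParams fit_linear_family
#' @param spec [model_spec()] with family `"gbr"`.
#' @return fitted_model holding the flattened tree ensemble.
#' @export
fit_gbr <- function(X, age, spec = model_spec("gbr"), combination = NULL) {
  stopifnot(spec$family == "gbr")
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (length(age) != nrow(X)) stop("length mismatch between design and age")
  if (spec$n_trees < 1L) stop("n_trees must be positive")
  if (spec$max_depth < 0L) stop("max_depth must be >= 0")
  ens <- gbr_fit_cpp(X, as.numeric(age), as.integer(spec$n_trees),
                     as.numeric(spec$learning_rate),
                     as.integer(spec$max_depth), as.integer(spec$min_node))
  params <- list(ensemble = ens, n_trees = spec$n_trees,
                 learning_rate = spec$learning_rate)
  new_fitted_model("gbr", spec, combination, params,
                   fingerprint = training_fingerprint(X, age,
                                                      seed = spec$seed))
}

#' Predict ages with a fitted model
#'
#' Applies the stored standardization (if any) and the family's prediction
#' function. `newdata` may be a cohort_table (the model's combination is
#' expanded automatically) or a design matrix already in combination order.
#' Predictions can optionally be clipped to a plausible age range; clipping
#' is off by default.
#'
#' @param object fitted_model.
#' @param newdata cohort_table or numeric design matrix.
#' @param clip optional `c(lo, hi)` bounds for the predictions.
#' @param ... unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.fitted_model <- function(object, newdata, clip = NULL, ...) {
  X <- if (inherits(newdata, "cohort_table")) {
    if (is.null(object$combination))
      stop("model carries no combination; supply a design matrix")
    expand_design(newdata, object$combination)$X
  } else as.matrix(newdata)
  pred <- unname(predict_design(object, X))
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1L] <= clip[2L])
    pred <- pmin(pmax(pred, clip[1L]), clip[2L])
  }
  pred
}

predict_design <- function(model, X) {
  switch(model$family,
    mqr = ,
    zp1_mlr = drop(cbind(1, X) %*% model$parameters$coef),
    svm_r = ,
    svm_l = ,
    svm_p = {
      Xs <- standardize_apply(X, model$scaling)
      p <- model$parameters
      drop(svr_predict_cpp(p$SV, p$beta, p$b, Xs, p$kernel, p$gamma,
                           as.integer(p$degree), p$coef0))
    },
    gbr = drop(gbr_predict_cpp(model$parameters$ensemble, as.matrix(X))),
    stop("no direct prediction for family ", model$family))
}

#' Serialize and restore a fitted model
#'
#' The archive is self-describing plain JSON: family, spec, combination
#' label, parameters, standardization constants and training fingerprint. A
#' restored model predicts without access to the training data.
#'
#' @param model fitted_model.
#' @param path file path (.json).
#' @return `path` invisibly; `load_model()` returns the fitted_model.
#' @export
save_model <- function(model, path) {
  payload <- list(
    family = model$family,
    spec = unclass(model$spec),
    combination = if (is.null(model$combination)) NULL else
      list(scope = model$combination$scope,
           variables = model$combination$variables),
    parameters = model$parameters,
    scaling = model$scaling,
    fingerprint = model$fingerprint)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  comb <- if (!is.null(p$combination))
    predictor_combination(p$combination$scope, p$combination$variables)
  spec <- p$spec
  class(spec) <- "model_spec"
  params <- p$parameters
  for (fld in c("coef", "beta", "residuals", "fitted"))
    if (!is.null(params[[fld]])) params[[fld]] <- as.numeric(params[[fld]])
  if (!is.null(params$coef) && !is.null(p$parameters$coef))
    names(params$coef) <- names(p$parameters$coef)
  if (!is.null(params$SV)) params$SV <- as.matrix(params$SV)
  if (!is.null(params$ensemble)) {
    ens <- as.matrix(params$ensemble)
    attr(ens, "tree_nodes") <- (nrow(ens) - 1L) %/% params$n_trees
    attr(ens, "learning_rate") <- params$learning_rate
    params$ensemble <- ens
  }
  scaling <- if (!is.null(p$scaling))
    list(center = as.numeric(p$scaling$center),
         scale = as.numeric(p$scaling$scale))
  new_fitted_model(p$family, spec, comb, params, scaling = scaling,
                   fingerprint = p$fingerprint)
}
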