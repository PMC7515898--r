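#' Build the joint methylation + age imputation matrix
#'
#' The age-imputation family pools the training and testing samples into one
#' matrix whose columns are the combination's CpG variables plus a final
#' `age` column; the age cells of the testing rows are the missing cells to
#' impute. Methylation cells are never missing (QC guarantees this upstream).
#'
#' @param training cohort_table with known ages.
#' @param testing cohort_table whose ages are treated as missing.
#' @param combination [predictor_combination()] over the cpg7 scope.
#' @return List with `M` (matrix, last column `age`, testing-row ages set to
#'   `NA`), `mask` (logical matrix, TRUE at missing cells), `is_testing`
#'   (logical row index) and `true_age` (testing ages, kept only for
#'   evaluation by the caller).
#' @export
mmda_matrix <- function(training, testing, combination) {
  dtr <- expand_design(training, combination)
  dte <- expand_design(testing, combination)
  M <- rbind(cbind(dtr$X, age = dtr$age),
             cbind(dte$X, age = NA_real_))
  mask <- is.na(M)
  list(M = M, mask = mask,
       is_testing = c(rep(FALSE, nrow(dtr$X)), rep(TRUE, nrow(dte$X))),
       true_age = dte$age)
}

#' Impute missing cells by regularized iterative PCA
#'
#' The iterative principal-component imputation behind the age-as-missing-
#' value family: (1) missing cells are initialized with column means of the
#' observed cells; (2) columns are centered (and optionally scaled) with
#' constants fixed from the observed cells; (3) the completed matrix is
#' approximated by its rank-`ncp` truncated SVD, with ridge-type shrinkage of
#' the singular values when `regularization = "ridge-shrinkage"` (each
#' retained singular value d_l is damped by `max(0, 1 - s2*(n-1)/d_l^2)`
#' where `s2` is the mean trailing eigenvalue, the usual noise-variance
#' estimate); (4) only the missing cells are overwritten by the
#' reconstruction; (5) steps 3--4 iterate until the imputed cells change by
#' less than `tol` (root-mean-square) or `max_iter` is reached. For
#' `regularization = "none"` this is the classical EM / hard-impute scheme
#' whose observed-cell reconstruction objective is non-increasing; the
#' objective trace is returned so callers can assert it.
#'
#' @param M numeric matrix with `NA` at the cells to impute.
#' @param ncp number of components, `1 <= ncp < min(n - 1, k)`.
#' @param regularization `"ridge-shrinkage"` or `"none"`.
#' @param tol convergence threshold (> 0) on the RMS change of imputed cells.
#' @param max_iter maximum iterations (>= 1).
#' @param scale_columns scale columns to unit observed-cell SD.
#' @return List: `completed` (matrix with imputed cells filled, observed
#'   cells untouched), `iterations`, `converged`, `objective` (per-iteration
#'   observed-cell squared reconstruction error), `final_change`.
#' @export
mmda_impute <- function(M, ncp = 2L, regularization = c("ridge-shrinkage", "none"),
                        tol = 1e-6, max_iter = 1000L, scale_columns = TRUE) {
  regularization <- match.arg(regularization)
  stopifnot(is.matrix(M), tol > 0, max_iter >= 1L)
  n <- nrow(M); k <- ncol(M)
  if (ncp < 1L || ncp >= min(n - 1L, k))
    stop("ncp must satisfy 1 <= ncp < min(n - 1, k)")
  mask <- is.na(M)
  if (!any(mask))
    return(list(completed = M, fitted = M, iterations = 0L, converged = TRUE,
                objective = numeric(), final_change = 0))
  if (all(mask[, k])) stop("no observed cells in column ", k)

  ## scales are fixed from the observed cells; column centers are
  ## re-estimated each iteration (colMeans-then-SVD is the exact joint
  ## minimizer over mean + rank-ncp fits, so the EM monotonicity argument
  ## applies and an exactly low-rank completion is a true fixed point)
  scl <- if (scale_columns) {
    s <- apply(M, 2L, sd, na.rm = TRUE)
    s[s == 0] <- 1
    s
  } else rep(1, k)
  Y <- sweep(M, 2L, scl, "/")
  init <- colMeans(Y, na.rm = TRUE)
  Y[mask] <- matrix(init, n, k, byrow = TRUE)[mask]

  objective <- numeric(0)
  converged <- FALSE
  change <- Inf
  iter <- 0L
  fit <- Y
  while (iter < max_iter) {
    iter <- iter + 1L
    ctr <- colMeans(Y)
    Z <- sweep(Y, 2L, ctr)
    sv <- svd(Z)
    d <- sv$d
    dr <- d[seq_len(ncp)]
    if (regularization == "ridge-shrinkage" && length(d) > ncp) {
      s2 <- mean(d[(ncp + 1L):length(d)]^2) / (n - 1)
      dr <- dr * pmax(0, 1 - s2 * (n - 1) / dr^2)
    }
    recon <- sv$u[, seq_len(ncp), drop = FALSE] %*%
      (dr * t(sv$v[, seq_len(ncp), drop = FALSE]))
    fit <- sweep(recon, 2L, ctr, "+")
    objective <- c(objective, sum((Y[!mask] - fit[!mask])^2))
    new_vals <- fit[mask]
    change <- sqrt(mean((new_vals - Y[mask])^2))
    Y[mask] <- new_vals
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("mmda_impute did not converge in ", max_iter,
            " iterations (last change ", signif(change, 3), ")")
  completed <- sweep(Y, 2L, scl, "*")
  completed[!mask] <- M[!mask]  # observed cells are never modified
  fitted <- sweep(fit, 2L, scl, "*")
  dimnames(completed) <- dimnames(M)
  dimnames(fitted) <- dimnames(M)
  list(completed = completed, fitted = fitted, iterations = iter,
       converged = converged, objective = objective, final_change = change)
}

#' Predict testing-set ages by joint-matrix imputation
#'
#' High-level wrapper for the imputation family: builds the pooled matrix via
#' [mmda_matrix()], imputes the testing-row age cells with [mmda_impute()],
#' and also returns the reconstructed (fitted) ages of the training rows for
#' training-set metrics.
#'
#' @inheritParams mmda_matrix
#' @param spec [model_spec()] of family `"mmda"`.
#' @return List: `predicted` (testing ages, table order), `fitted_training`
#'   (rank-`ncp` reconstruction of the observed training ages),
#'   `diagnostics` (iterations, convergence, ncp).
#' @export
mmda_predict_age <- function(training, testing, combination,
                             spec = model_spec("mmda")) {
  mm <- mmda_matrix(training, testing, combination)
  ## small combinations admit fewer components than the configured default:
  ## clamp to the feasible range (a 1-CpG matrix has 2 columns -> ncp = 1)
  ncp_max <- min(nrow(mm$M) - 2L, ncol(mm$M) - 1L)
  spec$ncp <- min(spec$ncp, ncp_max)
  res <- mmda_impute(mm$M, ncp = spec$ncp,
                     regularization = spec$regularization, tol = spec$tol,
                     max_iter = spec$max_iter,
                     scale_columns = spec$scale_columns)
  k <- ncol(mm$M)
  list(predicted = res$completed[mm$is_testing, k],
       fitted_training = res$fitted[!mm$is_testing, k],
       diagnostics = list(iterations = res$iterations,
                          converged = res$converged, ncp = spec$ncp,
                          final_change = res$final_change))
}

#' Choose the number of components by cross-validated masking
#'
#' Randomly masks observed age cells in `folds` folds, imputes them at each
#' candidate `ncp`, and returns the candidate minimizing imputation RMSE,
#' with ties (within numerical noise) broken toward the smallest ncp.
#' Deterministic under `seed`. A single candidate is returned without CV.
#'
#' @param M matrix as in [mmda_impute()] (age in the last column; `NA` at
#'   genuinely missing cells).
#' @param candidate_ncps integer candidates.
#' @param folds number of CV folds.
#' @param seed integer seed.
#' @param ... passed on to [mmda_impute()].
#' @return The selected ncp (integer), with attribute `"cv_rmse"`.
#' @export
select_ncp <- function(M, candidate_ncps, folds = 5L, seed = 1L, ...) {
  candidate_ncps <- as.integer(candidate_ncps)
  stopifnot(length(candidate_ncps) >= 1L)
  if (length(candidate_ncps) == 1L) return(candidate_ncps)
  k <- ncol(M)
  obs_age <- which(!is.na(M[, k]))
  if (length(obs_age) < folds)
    stop("fewer observed ages (", length(obs_age), ") than folds (", folds, ")")
  local_rng(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_age)))
  errs <- matrix(NA_real_, length(candidate_ncps), folds)
  for (ci in seq_along(candidate_ncps)) {
    for (f in seq_len(folds)) {
      hold <- obs_age[fold_of == f]
      Mf <- M
      Mf[hold, k] <- NA
      res <- mmda_impute(Mf, ncp = candidate_ncps[ci], ...)
      errs[ci, f] <- sqrt(mean((res$completed[hold, k] - M[hold, k])^2))
    }
  }
  cv <- rowMeans(errs)
  ## parsimony tie-break: the smallest ncp within numerical noise of the
  ## minimum CV error wins (exactly low-rank data ties all adequate ncps)
  tol_tie <- max(1e-8, 1e-6 * min(cv))
  best <- min(candidate_ncps[cv <= min(cv) + tol_tie])
  attr(best, "cv_rmse") <- setNames(cv, candidate_ncps)
  best
}
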