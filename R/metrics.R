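#' Accuracy metrics for age prediction
#'
#' The primary accuracy metric is the mean absolute deviation (MAD) between
#' predicted and chronological age in years, complemented by the root mean
#' square error (RMSE) and the Pearson product-moment correlation. By the
#' power-mean inequality `rmse >= mad >= 0` always holds.
#'
#' @param predicted,observed numeric vectors of equal nonzero length (years).
#' @return A scalar (years for MAD/RMSE, dimensionless in \[-1, 1\] for the
#'   correlation).
#' @export
compute_mad <- function(predicted, observed) {
  check_lengths(predicted, observed)
  mean(abs(predicted - observed))
}

#' @rdname compute_mad
#' @export
compute_rmse <- function(predicted, observed) {
  check_lengths(predicted, observed)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname compute_mad
#' @param x,y numeric vectors, `n >= 2`, both with nonzero variance.
#' @export
compute_pearson_r <- function(x, y) {
  check_lengths(x, y)
  if (length(x) < 2L) stop("need n >= 2 for a correlation")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance input")
  cor(x, y)
}

check_lengths <- function(a, b) {
  if (length(a) == 0L || length(a) != length(b))
    stop("predicted and observed must have equal nonzero length (",
         length(a), " vs ", length(b), ")")
  invisible(TRUE)
}

#' Bundle the three accuracy metrics
#'
#' @param predicted,observed numeric vectors of predicted and chronological
#'   ages.
#' @return A `metric_set` list: `pearson_r`, `mad`, `rmse`, `n`. The
#'   `rmse >= mad` invariant is asserted.
#' @export
metric_set <- function(predicted, observed) {
  m <- compute_mad(predicted, observed)
  r <- compute_rmse(predicted, observed)
  stopifnot(r >= m - 1e-12, m >= 0)
  structure(list(pearson_r = compute_pearson_r(predicted, observed),
                 mad = m, rmse = r, n = length(observed)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R = %.4f, MAD = %.3f y, RMSE = %.3f y (n = %d)\n",
              x$pearson_r, x$mad, x$rmse, x$n))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing design column j on all other
#' columns (with intercept). A perfectly collinear column yields `Inf`
#' rather than an error. Values above `threshold` (10 by convention) flag
#' multicollinearity; the search pipeline diagnoses but never corrects it,
#' since only predictions (not coefficient interpretation) are of interest.
#'
#' @param X numeric matrix with at least 2 columns and `n > k` rows.
#' @param threshold flagging threshold.
#' @return Named numeric vector of VIFs with attribute `"flagged"` (names of
#'   columns whose VIF exceeds the threshold).
#' @export
compute_vif <- function(X, threshold = 10) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 2L) stop("need at least 2 columns")
  if (nrow(X) <= k) stop("need n > k rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  vif <- vapply(seq_len(k), function(j) {
    yj <- X[, j]
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), yj)
    tss <- sum((yj - mean(yj))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)
  attr(vif, "flagged") <- names(vif)[vif > threshold]
  vif
}
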