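# --- linear family ---------------------------------------------------------

test_that("least squares matches an independent normal-equations oracle", {
  set.seed(21)
  for (trial in 1:20) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    y <- rnorm(20)
    fit <- fit_linear_family(X, y)
    Xi <- cbind(1, X)
    oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)  # textbook normal equations
    expect_equal(unname(fit$parameters$coef), drop(oracle), tolerance = 1e-8)
  }
})

test_that("noiseless linear data is interpolated exactly", {
  m5 <- seq(10, 60, length.out = 12)
  age <- 2 + 0.3 * m5
  fit <- fit_linear_family(cbind(cpg5 = m5), age)
  expect_equal(unname(fit$parameters$coef), c(2, 0.3), tolerance = 1e-10)
  expect_equal(max(abs(fit$parameters$residuals)), 0, tolerance = 1e-10)
})

test_that("rank deficiency errors unless minimum-norm is requested", {
  X <- cbind(a = rnorm(15), b = 0)
  X[, 2] <- X[, 1]           # duplicated column
  y <- rnorm(15)
  expect_error(fit_linear_family(X, y), "rank-deficient")
  fit <- fit_linear_family(X, y, model_spec("mqr", allow_rank_deficient = TRUE))
  expect_true(fit$parameters$min_norm)
  # minimum-norm fit still reproduces the projection of y
  qr1 <- fit_linear_family(X[, 1, drop = FALSE], y)
  expect_equal(unname(fit$parameters$fitted),
               unname(qr1$parameters$fitted), tolerance = 1e-8)
  expect_error(fit_linear_family(X[1:2, ], y[1:2]), "n > k")
})

test_that("least-squares residuals are orthogonal to every design column", {
  set.seed(22)
  X <- matrix(runif(30 * 4, 0, 100), 30, 4)
  y <- runif(30, 0, 91)
  fit <- fit_linear_family(X, y)
  r <- fit$parameters$residuals
  expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-7)
})

test_that("coefficient injection bypasses fitting (published-baseline path)", {
  tab <- random_cohort(10, seed = 31)
  spec <- model_spec("zp1_mlr", injected_coef =
                       c(`(Intercept)` = -10, cpg5 = 0.5, cpg7 = 0.9))
  fit <- fit_zp1_baseline(tab, spec)
  expect_true(fit$parameters$injected)
  pred <- predict(fit, tab)
  expect_equal(pred, -10 + 0.5 * tab$cpg5 + 0.9 * tab$cpg7, tolerance = 1e-12)
})

test_that("linear predictions are affine in the design", {
  set.seed(23)
  X <- matrix(runif(25 * 2, 10, 80), 25, 2)
  y <- runif(25, 0, 91)
  fit <- fit_linear_family(X, y)
  Xnew <- matrix(runif(10 * 2, 10, 80), 10, 2)
  p1 <- predict(fit, Xnew)
  cf <- fit$parameters$coef
  expect_equal(p1, drop(cbind(1, Xnew) %*% cf), tolerance = 1e-12)
})

# --- support-vector regression ---------------------------------------------

# Independent oracle: solve the epsilon-SVR dual as a box-constrained QP in
# the 2n (alpha, alpha*) variables with quadprog, then read off beta and the
# intercept from the free support vectors.
svr_qp_oracle <- function(X, y, C, eps, kfun) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- kfun(X[i, ], X[j, ])
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-7, 2 * n)
  d <- c(y - eps, -y - eps)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)$solution
  beta <- sol[1:n] - sol[(n + 1):(2 * n)]
  u <- drop(K %*% beta)
  free_a <- which(sol[1:n] > 1e-3 & sol[1:n] < C - 1e-3)
  free_s <- which(sol[(n + 1):(2 * n)] > 1e-3 & sol[(n + 1):(2 * n)] < C - 1e-3)
  # jitter distorts a few duals, so take the median of the KKT candidates
  b <- median(c(y[free_a] - eps - u[free_a], y[free_s] + eps - u[free_s]))
  list(beta = beta, b = b, u = u)
}

test_that("SMO solution matches the quadprog dual oracle", {
  set.seed(41)
  n <- 18
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- X[, 1] - 2 * X[, 2] + 0.3 * rnorm(n)
  cases <- list(
    list(fam = "svm_l", kfun = function(u, v) sum(u * v)),
    list(fam = "svm_r", kfun = function(u, v) exp(-0.5 * sum((u - v)^2))))
  for (cs in cases) {
    spec <- model_spec(cs$fam, cost = 1, standardize = FALSE, tol = 1e-8,
                       max_iter = 1000000L)
    if (cs$fam == "svm_r") spec$gamma <- 0.5
    fit <- fit_svm(X, y, spec)
    oracle <- svr_qp_oracle(X, y, C = 1, eps = 0.1, cs$kfun)
    pred_pkg <- predict(fit, X)
    pred_orc <- oracle$u + oracle$b
    expect_equal(pred_pkg, pred_orc, tolerance = 1e-4)
  }
})

test_that("linear SVR on noiseless linear data stays inside the epsilon tube", {
  set.seed(42)
  X <- matrix(runif(40, 0, 80), 40, 1)
  y <- 5 + 0.8 * drop(X)
  fit <- fit_svm(X, y, model_spec("svm_l", epsilon = 0.05, cost = 100))
  mad_train <- compute_mad(predict(fit, X), y)
  expect_lt(mad_train, 0.05)
})

test_that("radial SVR achieves high training correlation on a paper-like cohort", {
  sp <- paperlike_split(n = 1000, seed = 51, n_training = 700)
  comb <- predictor_combination("cpg7", c(2, 3, 5, 6, 7))
  d <- expand_design(sp$training, comb)
  fit <- fit_svm(d$X, d$age, model_spec("svm_r"), comb)
  expect_gt(compute_pearson_r(predict(fit, sp$training), sp$training$age), 0.9)
})

test_that("SVR standardization constants live in the model and errors are typed", {
  set.seed(43)
  X <- cbind(a = rnorm(20), b = rep(3, 20))   # zero-variance feature
  expect_error(fit_svm(X, rnorm(20), model_spec("svm_l")), "zero-variance")
  X2 <- matrix(rnorm(40), 20, 2)
  fit <- fit_svm(X2, rnorm(20), model_spec("svm_r"))
  expect_named(fit$scaling, c("center", "scale"))
})

test_that("stored SVR models predict bit-identically across two loads", {
  sp <- paperlike_split(n = 120, seed = 52, n_training = 90)
  comb <- predictor_combination("cpg7", c(5, 6, 7))
  d <- expand_design(sp$training, comb)
  fit <- fit_svm(d$X, d$age, model_spec("svm_r"), comb)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_model(fit, p1)
  save_model(fit, p2)
  m1 <- load_model(p1)
  m2 <- load_model(p2)
  expect_identical(predict(m1, sp$training), predict(m2, sp$training))
  expect_equal(predict(m1, sp$training), predict(fit, sp$training),
               tolerance = 1e-12)
})

# --- gradient-boosted trees -------------------------------------------------

test_that("a single depth-0 tree predicts the training mean everywhere", {
  set.seed(61)
  X <- matrix(runif(30, 0, 100), 30, 1)
  y <- runif(30, 0, 91)
  fit <- fit_gbr(X, y, model_spec("gbr", n_trees = 1L, max_depth = 0L,
                                  learning_rate = 1))
  expect_equal(predict(fit, matrix(c(0, 50, 100), 3, 1)),
               rep(mean(y), 3), tolerance = 1e-10)
})

test_that("boosting overfits training relative to testing on noisy data", {
  sp <- paperlike_split(n = 600, seed = 62, n_training = 400)
  comb <- predictor_combination("cpg7", 1:7)
  d <- expand_design(sp$training, comb)
  fit <- fit_gbr(d$X, d$age, model_spec("gbr"), comb)
  mad_train <- compute_mad(predict(fit, sp$training), sp$training$age)
  mad_test <- compute_mad(predict(fit, sp$testing), sp$testing$age)
  expect_lt(mad_train, mad_test)
  # the training/testing gap is surfaced in search records, not hidden
  rec <- fit_and_evaluate(sp$training, sp$testing, model_spec("gbr"), comb)
  expect_equal(rec$record$mad_train, mad_train, tolerance = 1e-10)
  expect_equal(rec$record$mad_test, mad_test, tolerance = 1e-10)
})

test_that("boosting is deterministic and reduces training error with depth", {
  set.seed(63)
  X <- matrix(runif(200 * 2, 0, 100), 200, 2)
  y <- 0.5 * X[, 1] + 0.002 * X[, 2]^2 + rnorm(200, 0, 2)
  f1 <- fit_gbr(X, y, model_spec("gbr", n_trees = 100L))
  f2 <- fit_gbr(X, y, model_spec("gbr", n_trees = 100L))
  expect_identical(predict(f1, X), predict(f2, X))
  shallow <- fit_gbr(X, y, model_spec("gbr", n_trees = 20L, max_depth = 1L))
  deep <- fit_gbr(X, y, model_spec("gbr", n_trees = 20L, max_depth = 3L))
  expect_lt(compute_mad(predict(deep, X), y),
            compute_mad(predict(shallow, X), y))
  expect_error(fit_gbr(X, y, model_spec("gbr", n_trees = 0L)), "positive")
})

test_that("GBR models survive serialization", {
  set.seed(64)
  X <- matrix(runif(50 * 2, 0, 100), 50, 2)
  y <- runif(50, 0, 91)
  fit <- fit_gbr(X, y, model_spec("gbr", n_trees = 25L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  expect_equal(predict(load_model(path), X), predict(fit, X),
               tolerance = 1e-12)
})

# --- shared model behaviour --------------------------------------------------

test_that("prediction clipping clamps out-of-scale values", {
  fit <- fit_linear_family(cbind(x = c(1, 2, 3, 4)), c(1, 2, 3, 4) * -2)
  raw <- predict(fit, cbind(x = c(2, 10)))
  expect_lt(raw[1], 0)
  clipped <- predict(fit, cbind(x = c(2, 10)), clip = c(0, 120))
  expect_equal(clipped[1], 0)
})

test_that("identical data and spec give identical serialized models", {
  sp <- paperlike_split(n = 100, seed = 71, n_training = 80)
  comb <- predictor_combination("cpg7", c(6, 7))
  d <- expand_design(sp$training, comb)
  for (builder in list(
    function() fit_linear_family(d$X, d$age, combination = comb),
    function() fit_svm(d$X, d$age, model_spec("svm_l"), comb),
    function() fit_gbr(d$X, d$age, model_spec("gbr", n_trees = 10L), comb))) {
    pa <- withr::local_tempfile(fileext = ".json")
    pb <- withr::local_tempfile(fileext = ".json")
    save_model(builder(), pa)
    save_model(builder(), pb)
    expect_identical(readLines(pa), readLines(pb))
  }
})

test_that("parameter recovery: MQR recovers noiseless quadratic curves", {
  cfg <- synthetic_config(n_samples = 80, shared_factor_sd = 0,
                          residual_sd = 0, seed = 72)
  co <- generate_cohort(cfg)
  X <- cbind(age = co$age, age2 = co$age^2)
  for (i in c(2, 6)) {
    cf <- unname(fit_linear_family(X, meth_matrix(co)[, i])$parameters$coef)
    truth <- c(cfg$curve_a[i], cfg$curve_b[i], cfg$curve_c[i])
    expect_lt(max(abs(cf - truth) / abs(truth)), 1e-6)
  }
})
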