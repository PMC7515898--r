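test_that("noiseless generation lies exactly on the mean curves", {
  cfg <- synthetic_config(n_samples = 50, shared_factor_sd = 0,
                          residual_sd = 0, seed = 1)
  co <- generate_cohort(cfg)
  mm <- meth_matrix(co)
  for (i in 1:7) {
    expected <- cfg$curve_a[i] + cfg$curve_b[i] * co$age +
      cfg$curve_c[i] * co$age^2
    expect_equal(unname(mm[, i]), expected, tolerance = 1e-12)
  }
  # noiseless regression recovers the curve coefficients to machine precision
  X <- cbind(age = co$age, age2 = co$age^2)
  for (i in 1:7) {
    cf <- unname(fit_linear_family(X, mm[, i])$parameters$coef)
    expect_equal(cf, c(cfg$curve_a[i], cfg$curve_b[i], cfg$curve_c[i]),
                 tolerance = 1e-8)
  }
})

test_that("config validation rejects degenerate inputs", {
  expect_error(synthetic_config(residual_sd = -1), "negative SD")
  expect_error(synthetic_config(pcr_sd = -0.1), "negative SD")
  expect_error(synthetic_config(n_samples = 0), "n_samples")
  expect_error(synthetic_config(age_range = c(5, 2)), "age_range")
  # degenerate (min == max) age range is allowed
  cfg <- synthetic_config(n_samples = 5, age_range = c(40, 40), seed = 1)
  expect_equal(unique(generate_cohort(cfg)$age), 40)
})

test_that("shared factor induces the closed-form inter-CpG correlation", {
  # at fixed age the only variance sources are the shared factor and the
  # residual: corr = shared_var / (shared_var + resid_var)
  cfg <- synthetic_config(n_samples = 2000, age_range = c(40, 40),
                          shared_factor_sd = 6, residual_sd = 2, seed = 8)
  mm <- meth_matrix(generate_cohort(cfg))
  expected <- 6^2 / (6^2 + 2^2)  # 0.9
  cors <- cor(mm)[upper.tri(diag(7))]
  expect_true(all(cors > 0.7))
  expect_equal(mean(cors), expected, tolerance = 0.03)
})

test_that("batch offsets shift study means by the configured amount", {
  off <- c(5, 5, 5, 0, 0, 0, 0)
  cfg <- synthetic_config(n_samples = 4000, batch_offsets =
                            list(independent = off),
                          study_weights = c(reference = 1, independent = 1),
                          seed = 9)
  co <- generate_cohort(cfg)
  mm <- meth_matrix(co)
  # compare age-adjusted means via the known curves (ages differ by study
  # draw, so regress out the curve first)
  for (i in c(1, 4)) {
    curve <- cfg$curve_a[i] + cfg$curve_b[i] * co$age + cfg$curve_c[i] * co$age^2
    dev <- mm[, i] - curve
    diffm <- mean(dev[co$study == "independent"]) -
      mean(dev[co$study == "reference"])
    expect_equal(diffm, off[i], tolerance = 0.5)
  }
})

test_that("generation is deterministic under the config seed", {
  cfg <- synthetic_config(n_samples = 30, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  co <- generate_cohort(cfg)
  expect_identical(generate_replicate_grids(co, cfg),
                   generate_replicate_grids(co, cfg))
})

test_that("replicate grids have the nested variance structure", {
  cfg <- synthetic_config(n_samples = 1000, pcr_sd = 2, psq_sd = 1, seed = 10)
  co <- generate_cohort(cfg)
  grids <- generate_replicate_grids(co, cfg)
  expect_equal(nrow(grids), 6000L)
  wide <- function(cell) {
    sub <- grids[paste0(grids$pcr, grids$psq) == cell, ]
    sub$cpg6[match(co$sample_id, sub$sample_id)]
  }
  same_pcr <- cor(wide("A1"), wide("A2"))
  cross_pcr <- cor(wide("A1"), wide("B1"))
  expect_gt(same_pcr, cross_pcr)
  # closed-form variance-component correlations
  lat <- var(co$cpg6)
  expect_equal(same_pcr, (lat + 4) / (lat + 4 + 1), tolerance = 0.02)
  expect_equal(cross_pcr, lat / (lat + 4 + 1), tolerance = 0.02)
})

test_that("noiseless replicate grids collapse to the cohort value", {
  cfg <- synthetic_config(n_samples = 20, pcr_sd = 0, psq_sd = 0, seed = 11)
  co <- generate_cohort(cfg)
  grids <- generate_replicate_grids(co, cfg)
  for (cell in split(grids, paste0(grids$pcr, grids$psq)))
    expect_equal(unname(as.matrix(cell[match(co$sample_id, cell$sample_id),
                                       paste0("cpg", 1:7)])),
                 unname(meth_matrix(co)), tolerance = 1e-12)
})

test_that("all emitted values respect [0,100] under extreme offsets", {
  for (sgn in c(-1, 1)) {
    cfg <- synthetic_config(n_samples = 200, batch_offsets =
                              list(test = rep(sgn * 500, 7)),
                            study_weights = c(test = 1),
                            pcr_sd = 30, psq_sd = 30, seed = 12)
    co <- generate_cohort(cfg)
    mm <- meth_matrix(co)
    expect_true(all(mm >= 0 & mm <= 100))
    gr <- generate_replicate_grids(co, cfg)
    gm <- as.matrix(gr[, paste0("cpg", 1:7)])
    expect_true(all(gm >= 0 & gm <= 100))
  }
})

test_that("larger cohorts estimate correlations more precisely", {
  # SE of the age-methylation correlation shrinks with n
  reps <- function(n) {
    vapply(1:8, function(s) {
      cfg <- synthetic_config(n_samples = n, seed = 100 + s)
      co <- generate_cohort(cfg)
      cor(co$age, co$cpg6)
    }, 0)
  }
  expect_lt(sd(reps(800)), sd(reps(50)))
})

test_that("default_paper_like_config is stable and satisfies its contract", {
  expect_identical(default_paper_like_config(seed = 1),
                   default_paper_like_config(seed = 1))
  cfg <- default_paper_like_config()
  # curves stay within [0,100] at the age extremes
  for (y in c(0, 91)) {
    vals <- cfg$curve_a + cfg$curve_b * y + cfg$curve_c * y^2
    expect_true(all(vals >= 0 & vals <= 100))
  }
  # monotone increasing on [0, 91]
  ygrid <- seq(0, 91, by = 0.5)
  for (i in 1:7) {
    curve <- cfg$curve_a[i] + cfg$curve_b[i] * ygrid + cfg$curve_c[i] * ygrid^2
    expect_true(all(diff(curve) > 0))
  }
  co <- generate_cohort(cfg)
  rr <- vapply(1:7, function(i) cor(co$age, meth_matrix(co)[, i]), 0)
  expect_gt(min(rr), 0.7)
})

test_that("synthetic config round-trips through the key-value file", {
  cfg <- synthetic_config(n_samples = 77, age_range = c(3, 88),
                          shared_factor_sd = 2.5,
                          batch_offsets = list(labX = c(1:6, 0.5)),
                          seed = 99)
  path <- withr::local_tempfile(fileext = ".txt")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back, cfg, tolerance = 1e-12)
})

test_that("replicate table round-trips through CSV", {
  cfg <- synthetic_config(n_samples = 5, seed = 13)
  co <- generate_cohort(cfg)
  grids <- generate_replicate_grids(co, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_replicate_table(grids, path)
  back <- read_replicate_table(path)
  expect_equal(as.data.frame(back), as.data.frame(grids), tolerance = 1e-12)
})
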