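#' Configuration of the synthetic pyrosequencing cohort generator
#'
#' The generator emulates the statistical structure of the pooled blood
#' pyrosequencing cohorts: per-CpG mean methylation following a quadratic
#' curve in age, `a_i + b_i*y + c_i*y^2`, a latent per-sample factor shared by
#' all 7 CpGs (driving the high inter-CpG correlation seen in real data),
#' independent per-CpG residual noise, per-study additive batch offsets, and a
#' 3-PCR x 2-PSQ technical-replicate hierarchy in which a per-PCR random
#' effect makes same-PCR replicates correlate more strongly than cross-PCR
#' replicates. All methylation is on the percent (0--100) scale and clipped to
#' that range after all additive terms.
#'
#' @param n_samples number of individuals.
#' @param age_range ages are drawn uniformly from `[min, max]` years; a
#'   degenerate range (min == max) is allowed.
#' @param curve_a,curve_b,curve_c length-7 numeric vectors: intercept, linear
#'   and quadratic coefficients of the per-CpG mean curves (percent, percent
#'   per year, percent per year squared).
#' @param shared_factor_sd SD (percent) of the latent per-sample factor added
#'   to every CpG with loading 1.
#' @param residual_sd SD (percent) of the independent per-CpG noise.
#' @param batch_offsets named list mapping study label to a length-7 numeric
#'   vector of additive shifts (percent); studies absent from the list get
#'   zero offset.
#' @param study_weights named numeric vector of study sampling proportions
#'   (normalized internally).
#' @param pcr_sd SD (percent) of the per-PCR random effect.
#' @param psq_sd SD (percent) of the per-pyrosequencing-run noise.
#' @param seed integer seed; mandatory for generation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 1000L,
                             age_range = c(0, 91),
                             curve_a = NULL, curve_b = NULL, curve_c = NULL,
                             shared_factor_sd = 3,
                             residual_sd = 1.8,
                             batch_offsets = list(),
                             study_weights = c(bekaert = 206, zbiec = 420,
                                               park = 765, cho = 100),
                             pcr_sd = 1.5,
                             psq_sd = 1.0,
                             seed = NULL) {
  dflt <- default_mean_curves()
  curve_a <- curve_a %||% dflt$a
  curve_b <- curve_b %||% dflt$b
  curve_c <- curve_c %||% dflt$c
  stopifnot(length(curve_a) == N_CPG, length(curve_b) == N_CPG,
            length(curve_c) == N_CPG)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (length(age_range) != 2L || age_range[2L] < age_range[1L] ||
      any(age_range < 0))
    stop("age_range must be a non-negative [min, max] with max >= min")
  sds <- c(shared_factor_sd = shared_factor_sd, residual_sd = residual_sd,
           pcr_sd = pcr_sd, psq_sd = psq_sd)
  if (any(sds < 0)) stop("negative SD: ", names(sds)[which(sds < 0)[1L]])
  if (is.null(names(study_weights)) || any(study_weights < 0) ||
      sum(study_weights) <= 0)
    stop("study_weights must be a named non-negative vector with positive sum")
  for (st in names(batch_offsets))
    stopifnot(length(batch_offsets[[st]]) == N_CPG)
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 curve_a = curve_a, curve_b = curve_b, curve_c = curve_c,
                 shared_factor_sd = shared_factor_sd,
                 residual_sd = residual_sd,
                 batch_offsets = batch_offsets,
                 study_weights = study_weights / sum(study_weights),
                 pcr_sd = pcr_sd, psq_sd = psq_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synthetic_config")
}

## Mean curves chosen once to mimic the assay: methylation low in newborns
## (~5-15%), rising steeply and slightly super-linearly, reaching ~55-80% by
## age 91 so that clipping at 100 is never active for realistic noise levels.
## Monotone on [0, 91] since b_i + 2 c_i y > 0 there for all i.
default_mean_curves <- function() {
  list(a = c(6, 8, 10, 12, 14, 7, 16),
       b = c(0.62, 0.55, 0.50, 0.48, 0.55, 0.70, 0.45),
       c = c(0.0016, 0.0014, 0.0012, 0.0010, 0.0012, 0.0018, 0.0008))
}

#' Default cohort configuration with realistic age-methylation structure
#'
#' Returns a fully documented configuration whose noiseless mean curves are
#' increasing on \[0, 91\] years and whose generated cohorts show
#' age-methylation Pearson correlations above 0.7 at every CpG (the
#' qualitative behaviour of the real pooled data) for n = 1,000.
#'
#' @param seed integer seed stored in the config.
#' @return A [synthetic_config()].
#' @export
default_paper_like_config <- function(seed = 20200924L) {
  synthetic_config(n_samples = 1000L, seed = seed)
}

#' Generate a synthetic cohort
#'
#' Per sample: age is uniform on `age_range`; the latent methylation of CpG i
#' is `clip(a_i + b_i*y + c_i*y^2 + shared factor + batch offset + residual
#' noise, 0, 100)`; this is also the per-sample latent value around which
#' [generate_replicate_grids()] draws technical replicates, so replicate
#' averaging converges to the cohort value.
#'
#' @param config [synthetic_config()] with a non-NULL seed.
#' @param study study label for all samples, or NULL to sample labels from
#'   `config$study_weights`.
#' @param role role recorded on the returned table.
#' @param id_prefix prefix for generated sample ids.
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(config, study = NULL, role = "unassigned",
                            id_prefix = "S") {
  stopifnot(inherits(config, "synthetic_config"))
  local_rng(config$seed)
  n <- config$n_samples
  age <- runif(n, config$age_range[1L], config$age_range[2L])
  studies <- if (is.null(study)) {
    sample(names(config$study_weights), n, replace = TRUE,
           prob = config$study_weights)
  } else rep_len(study, n)
  mean_curve <- outer(rep(1, n), config$curve_a) +
    outer(age, config$curve_b) + outer(age^2, config$curve_c)
  shared <- rnorm(n, 0, config$shared_factor_sd)
  resid <- matrix(rnorm(n * N_CPG, 0, config$residual_sd), n, N_CPG)
  offs <- matrix(0, n, N_CPG)
  for (st in names(config$batch_offsets)) {
    hit <- studies == st
    if (any(hit))
      offs[hit, ] <- matrix(config$batch_offsets[[st]], sum(hit), N_CPG,
                            byrow = TRUE)
  }
  latent <- pmin(pmax(mean_curve + shared + offs + resid, 0), 100)
  df <- data.frame(sample_id = sprintf("%s%04d", id_prefix, seq_len(n)),
                   age = age, study = studies, stringsAsFactors = FALSE)
  df[CPG_COLS] <- as.data.frame(latent)
  cohort_table(df, role = role)
}

#' Generate 3-PCR x 2-PSQ technical-replicate grids for a cohort
#'
#' Each sample is measured in 6 cells: 3 PCR reactions (A, B, C), each
#' pyrosequenced twice (runs 1, 2). A cell value is the sample's latent
#' methylation plus a per-PCR random effect (shared by the two PSQ runs of
#' that PCR) plus independent per-PSQ noise, clipped to \[0, 100\]. Same-PCR
#' replicate pairs therefore correlate more strongly than cross-PCR pairs
#' whenever `pcr_sd > 0`.
#'
#' @param cohort cohort_table; its observed methylation plays the latent
#'   role (the cohort-level value is the per-sample latent methylation, so
#'   replicate averaging converges to it).
#' @param config [synthetic_config()] supplying `pcr_sd`, `psq_sd`; the seed
#'   used is `seed + 1` so grids are reproducible yet distinct from the
#'   cohort draw.
#' @return A `replicate_table`: long data.frame with columns `sample_id`,
#'   `pcr` (A/B/C), `psq` (1/2), `cpg1`..`cpg7`; 6 rows per sample.
#' @export
generate_replicate_grids <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(config, "synthetic_config"))
  latent <- meth_matrix(cohort)
  n <- nrow(cohort)
  local_rng(config$seed + 1L)
  pcr_levels <- c("A", "B", "C")
  cells <- expand.grid(pcr = pcr_levels, psq = c(1L, 2L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$pcr, cells$psq), ]
  ## per (sample, pcr, cpg) effect shared by both PSQ runs of that PCR
  pcr_eff <- array(rnorm(n * 3L * N_CPG, 0, config$pcr_sd),
                   dim = c(n, 3L, N_CPG))
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    p <- match(cells$pcr[ci], pcr_levels)
    psq_noise <- matrix(rnorm(n * N_CPG, 0, config$psq_sd), n, N_CPG)
    vals <- pmin(pmax(latent + pcr_eff[, p, ] + psq_noise, 0), 100)
    d <- data.frame(sample_id = cohort$sample_id, pcr = cells$pcr[ci],
                    psq = cells$psq[ci], stringsAsFactors = FALSE)
    d[CPG_COLS] <- as.data.frame(vals)
    rows[[ci]] <- d
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$sample_id, cohort$sample_id), out$pcr, out$psq), ]
  rownames(out) <- NULL
  class(out) <- unique(c("replicate_table", class(out)))
  out
}

#' Serialize / read a synthetic config as a flat key-value file
#'
#' Vector-valued fields are comma-joined; batch offsets are stored as
#' `batch_offset.<study>` keys. The schema round-trips through
#' [read_synthetic_config()].
#'
#' @param config [synthetic_config()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  num <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  kv <- c(n_samples = num(config$n_samples),
          age_range = num(config$age_range),
          curve_a = num(config$curve_a), curve_b = num(config$curve_b),
          curve_c = num(config$curve_c),
          shared_factor_sd = num(config$shared_factor_sd),
          residual_sd = num(config$residual_sd),
          pcr_sd = num(config$pcr_sd), psq_sd = num(config$psq_sd),
          study_weights = paste(names(config$study_weights),
                                format(config$study_weights, digits = 17,
                                       trim = TRUE),
                                sep = ":", collapse = ","),
          seed = if (is.null(config$seed)) "" else num(config$seed))
  for (st in names(config$batch_offsets))
    kv[paste0("batch_offset.", st)] <- num(config$batch_offsets[[st]])
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @param path path to a key-value file written by [write_synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", "")
  names(vals) <- trimws(keys)
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1L]])
  sw <- strsplit(strsplit(vals[["study_weights"]], ",")[[1L]], ":")
  study_weights <- setNames(as.numeric(vapply(sw, `[[`, "", 2L)),
                            vapply(sw, `[[`, "", 1L))
  bo_keys <- grep("^batch_offset\\.", names(vals), value = TRUE)
  batch_offsets <- setNames(lapply(bo_keys, nums),
                            sub("^batch_offset\\.", "", bo_keys))
  synthetic_config(
    n_samples = nums("n_samples"), age_range = nums("age_range"),
    curve_a = nums("curve_a"), curve_b = nums("curve_b"),
    curve_c = nums("curve_c"),
    shared_factor_sd = nums("shared_factor_sd"),
    residual_sd = nums("residual_sd"),
    batch_offsets = batch_offsets, study_weights = study_weights,
    pcr_sd = nums("pcr_sd"), psq_sd = nums("psq_sd"),
    seed = if (nzchar(vals[["seed"]])) nums("seed") else NULL)
}

#' Write / read the long replicate table CSV
#'
#' Columns: `sample_id`, `pcr`, `psq`, `cpg1`..`cpg7`.
#'
#' @param grids replicate_table from [generate_replicate_grids()].
#' @param path file path.
#' @export
write_replicate_table <- function(grids, path) {
  write.csv(format(grids, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_replicate_table
#' @export
read_replicate_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pcr", "psq", CPG_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("malformed replicate table: missing ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$pcr <- as.character(df$pcr)
  df$psq <- as.integer(df$psq)
  class(df) <- unique(c("replicate_table", class(df)))
  df
}
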