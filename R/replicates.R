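#' The five technical-replicate schemes on the 3-PCR x 2-PSQ grid
#'
#' Each sample of the independent set is measured in six cells: PCR reactions
#' A, B, C, each pyrosequenced twice. Five replicate schemes select and
#' average cells before prediction: a single measurement (S1), the two PSQ
#' runs of one PCR (S2 same-PCR), one PSQ run from each of two PCRs (S2
#' cross-PCR), one PSQ run from each of the three PCRs (S3), and all six
#' cells (S6). Measurement counts are 1, 2, 2, 3 and 6.
#'
#' @return data.frame with `scheme_id`, `n_measurements`, `description`.
#' @export
replicate_schemes <- function() {
  data.frame(
    scheme_id = c("S1_1pcr1psq", "S2_1pcr2psq", "S2_2pcr1psq",
                  "S3_3pcr1psq", "S6_3pcr2psq"),
    n_measurements = c(1L, 2L, 2L, 3L, 6L),
    description = c("1 PCR and 1 PSQ/PCR (1 replicate)",
                    "1 PCR and 2 PSQ/PCR (2 replicates)",
                    "2 PCR and 1 PSQ/PCR (2 replicates)",
                    "3 PCR and 1 PSQ/PCR (3 replicates)",
                    "3 PCR and 2 PSQ/PCR (6 replicates)"),
    stringsAsFactors = FALSE)
}

## All symmetric cell choices of a scheme, as lists of (pcr, psq) pairs.
## Cells are labelled "A1".."C2".
scheme_cell_choices <- function(scheme_id) {
  pcrs <- c("A", "B", "C")
  cell <- function(p, q) paste0(p, q)
  switch(scheme_id,
    S1_1pcr1psq = {
      ch <- list()
      for (p in pcrs) for (q in 1:2) ch[[length(ch) + 1L]] <- cell(p, q)
      ch
    },
    S2_1pcr2psq = lapply(pcrs, function(p) c(cell(p, 1), cell(p, 2))),
    S2_2pcr1psq = {
      ch <- list()
      for (pp in list(c("A", "B"), c("A", "C"), c("B", "C")))
        for (q1 in 1:2) for (q2 in 1:2)
          ch[[length(ch) + 1L]] <- c(cell(pp[1], q1), cell(pp[2], q2))
      ch
    },
    S3_3pcr1psq = {
      ch <- list()
      for (q1 in 1:2) for (q2 in 1:2) for (q3 in 1:2)
        ch[[length(ch) + 1L]] <- c(cell("A", q1), cell("B", q2), cell("C", q3))
      ch
    },
    S6_3pcr2psq = list(as.vector(outer(pcrs, 1:2, cell))),
    stop("unknown scheme_id: ", scheme_id))
}

## Reshape a long replicate table into an array [sample, cell, cpg], erroring
## on incomplete grids.
replicate_array <- function(grids, sample_ids) {
  cells <- c("A1", "A2", "B1", "B2", "C1", "C2")
  key <- paste0(grids$pcr, grids$psq)
  arr <- array(NA_real_, dim = c(length(sample_ids), 6L, N_CPG),
               dimnames = list(sample_ids, cells, CPG_COLS))
  gi <- match(paste(grids$sample_id, key),
              as.vector(outer(sample_ids, cells, paste)))
  if (anyNA(gi)) stop("replicate table contains unknown sample/cell rows")
  mm <- as.matrix(grids[, CPG_COLS])
  for (j in seq_len(N_CPG)) {
    slice <- matrix(NA_real_, length(sample_ids), 6L)
    slice[gi] <- mm[, j]
    arr[, , j] <- slice
  }
  missing_cells <- which(is.na(arr[, , 1L]), arr.ind = TRUE)
  if (nrow(missing_cells) > 0L)
    stop("incomplete replicate grid: sample ",
         sample_ids[missing_cells[1L, 1L]], " is missing cell ",
         cells[missing_cells[1L, 2L]])
  arr
}

#' Evaluate a model under a technical-replicate scheme
#'
#' Per sample, methylation is averaged per CpG across the scheme's selected
#' cells, then predicted once (averaging measurements before prediction, not
#' predictions). For schemes that do not use all six cells, `assignment`
#' controls the cell choice: `"exhaustive_mean"` evaluates every symmetric
#' choice and averages the resulting metrics; `"random"` picks one choice
#' per sample under `seed` (the design used for scatterplot-style output).
#'
#' @param grids replicate_table covering all of `ages`' samples with all six
#'   cells.
#' @param model fitted_model (its combination names the CpGs used).
#' @param ages named numeric vector (or cohort_table) of chronological ages
#'   for the samples to evaluate.
#' @param scheme_id one of `replicate_schemes()$scheme_id`.
#' @param assignment `"exhaustive_mean"` or `"random"`.
#' @param seed seed for `assignment = "random"`.
#' @param clip optional prediction clipping.
#' @return A [metric_set()] (for `exhaustive_mean`, the choice-averaged
#'   metrics, with attribute `"n_choices"`).
#' @export
evaluate_replicate_scheme <- function(grids, model, ages,
                                      scheme_id = "S6_3pcr2psq",
                                      assignment = c("exhaustive_mean",
                                                     "random"),
                                      seed = 1L, clip = NULL) {
  assignment <- match.arg(assignment)
  if (inherits(ages, "cohort_table"))
    ages <- setNames(ages$age, ages$sample_id)
  stopifnot(!is.null(names(ages)))
  arr <- replicate_array(grids, names(ages))
  choices <- scheme_cell_choices(scheme_id)

  predict_cells <- function(cell_sets) {
    ## cell_sets: list per sample, or a single set reused for all samples
    n <- length(ages)
    meth <- matrix(NA_real_, n, N_CPG, dimnames = list(names(ages), CPG_COLS))
    for (i in seq_len(n)) {
      cs <- if (is.list(cell_sets)) cell_sets[[i]] else cell_sets
      sub <- arr[i, cs, , drop = FALSE]
      meth[i, ] <- apply(sub, 3L, mean)
    }
    tab <- data.frame(sample_id = names(ages), age = ages, study = "replicate",
                      stringsAsFactors = FALSE)
    tab[CPG_COLS] <- as.data.frame(meth)
    predict(model, cohort_table(tab), clip = clip)
  }

  if (assignment == "random") {
    local_rng(seed)
    pick <- sample.int(length(choices), length(ages), replace = TRUE)
    pred <- predict_cells(lapply(pick, function(j) choices[[j]]))
    return(metric_set(pred, ages))
  }
  per_choice <- lapply(choices, function(cs) metric_set(predict_cells(cs), ages))
  avg <- function(fld) mean(vapply(per_choice, `[[`, 0, fld))
  out <- structure(list(pearson_r = avg("pearson_r"), mad = avg("mad"),
                        rmse = avg("rmse"), n = length(ages)),
                   class = "metric_set")
  attr(out, "n_choices") <- length(choices)
  out
}

#' Evaluate a model under all five replicate schemes
#'
#' @inheritParams evaluate_replicate_scheme
#' @return data.frame with one row per scheme: scheme_id, n_measurements,
#'   pearson_r, mad, rmse.
#' @export
evaluate_all_schemes <- function(grids, model, ages,
                                 assignment = "exhaustive_mean", seed = 1L,
                                 clip = NULL) {
  sch <- replicate_schemes()
  res <- lapply(sch$scheme_id, function(s)
    evaluate_replicate_scheme(grids, model, ages, s, assignment, seed, clip))
  cbind(sch[, c("scheme_id", "n_measurements")],
        data.frame(pearson_r = vapply(res, `[[`, 0, "pearson_r"),
                   mad = vapply(res, `[[`, 0, "mad"),
                   rmse = vapply(res, `[[`, 0, "rmse")))
}
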