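# Fixtures are built in code; nothing is read from disk.

# Minimal hand-written cohort data.frame (3 samples, complete).
tiny_cohort_df <- function() {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   age = c(10, 40, 70),
                   study = "test",
                   stringsAsFactors = FALSE)
  for (i in 1:7) df[[paste0("cpg", i)]] <- c(10, 30, 50) + i
  df
}

# Random valid cohort of n samples; prob_missing gives per-cell NA chance.
random_cohort <- function(n, seed, prob_missing = 0, studies = "test") {
  set.seed(seed)
  df <- data.frame(sample_id = sprintf("r%03d", seq_len(n)),
                   age = runif(n, 0, 91),
                   study = sample(studies, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  for (i in 1:7) {
    v <- runif(n, 5, 95)
    if (prob_missing > 0) v[runif(n) < prob_missing] <- NA
    df[[paste0("cpg", i)]] <- v
  }
  cohort_table(df)
}

# Paper-like noisy cohort split used across model tests.
paperlike_split <- function(n = 500, seed = 11, n_training = 350) {
  cfg <- synthetic_config(n_samples = n, seed = seed)
  random_split(generate_cohort(cfg), n_training, seed = seed + 1L)
}
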