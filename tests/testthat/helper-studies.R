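# Shared fixtures: the two bundled datasets and random study generators.

testosterone_table <- function() {
  read_long_table(system.file("extdata", "testosterone.csv",
                              package = "mimvar"),
                  control = "Non-smokers")
}

blood_counts_table <- function() {
  read_long_table(system.file("extdata", "blood_counts.csv",
                              package = "mimvar"),
                  control = "Control")
}

testosterone_study <- function() as_study(summarize_groups(testosterone_table()))
blood_counts_study <- function() as_study(summarize_groups(blood_counts_table()))

# Random study with positive variances; equal_sizes forces a common
# treatment sample size so Spurrier applies.
random_study <- function(k = sample(1:5, 1), equal_sizes = FALSE,
                         min_n = 3, max_n = 30) {
  n0 <- sample(min_n:max_n, 1)
  ns <- if (equal_sizes) rep(sample(min_n:max_n, 1), k)
        else sample(min_n:max_n, k, replace = TRUE)
  ctrl <- group_summary("ctrl", n0, rchisq(1, 3) + 0.05)
  trts <- lapply(seq_len(k), function(i)
    group_summary(paste0("t", i), ns[i], rchisq(1, 3) + 0.05))
  study_summary(ctrl, trts)
}
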