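# Shared fixtures: small cohorts and worlds built in code.

# A small two-group cohort (subs + unsubs) for pipeline tests.
small_deaf_design <- function(n_per_group = 4L, response = 0.19,
                              renditions = 120L, n_stim = 8L) {
  c(
    lapply(seq_len(n_per_group), function(i) {
      bird_params(sprintf("s%02d", i), "subs",
                  if (i %% 2 == 1L) "high" else "low",
                  response_per_day = response,
                  renditions_per_day_mean = renditions,
                  n_stimulus_days = n_stim)
    }),
    lapply(seq_len(n_per_group), function(i) {
      bird_params(sprintf("u%02d", i), "unsubs", "none",
                  renditions_per_day_mean = renditions,
                  n_stimulus_days = n_stim)
    })
  )
}

# Hand-built daily summary row.
summary_row <- function(mean_pitch, var_pitch, day = 1L, n = 10L) {
  list(bird_id = "x", day = day, mean_pitch = mean_pitch,
       var_pitch = var_pitch, n = n)
}

# Single-bird summaries with prescribed day means (constant variance),
# for criteria / change-window tests. Variance chosen so that one unit of
# mean difference equals `dprime_per_unit` d-prime.
summaries_from_means <- function(means, n_baseline, sd = 1) {
  n <- length(means)
  data.frame(
    bird_id = "x", day = seq_len(n), mean_pitch = means,
    var_pitch = sd^2, n = 100L, cv = 100 * sd / means, contingency = 0,
    group = "subs", target_side = "high",
    phase = rep(c("baseline", "stimulus"), c(n_baseline, n - n_baseline)),
    dprime_prev = c(NA, diff(means) / sd)
  )
}
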