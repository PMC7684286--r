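test_that("daily summaries reproduce hand-computed moments", {
  tab <- data.frame(bird_id = "b", day = c(1, 1, 1, 2, 2),
                    pitch_hz = c(100, 100, 100, 99, 101), stimulus = FALSE)
  ds <- daily_summaries(tab)
  expect_equal(ds$mean_pitch, c(100, 100))
  expect_equal(ds$var_pitch, c(0, 2))
  expect_equal(ds$cv, c(0, 100 * sqrt(2) / 100), tolerance = 1e-12)
  expect_equal(ds$n, c(3L, 2L))
  expect_true(is.na(ds$dprime_prev[1]))
  expect_equal(ds$dprime_prev[2], (100 - 100) / sqrt(0.5 * (0 + 2)))
})

test_that("contingency is the stimulus fraction and min_count filters days", {
  tab <- data.frame(bird_id = "b", day = rep(1:2, c(4, 2)),
                    pitch_hz = 700, stimulus = c(TRUE, TRUE, FALSE, FALSE,
                                                 TRUE, FALSE))
  ds <- daily_summaries(tab)
  expect_equal(ds$contingency, c(0.5, 0.5))
  expect_equal(nrow(daily_summaries(tab, min_count = 3)), 1L)
  expect_error(daily_summaries(tab[0, ]))
})

test_that("dprime matches direct arithmetic and is antisymmetric and scale-free", {
  a <- summary_row(800, 100)
  b <- summary_row(805, 300)
  expect_equal(dprime(a, b), 5 / sqrt(0.5 * 400), tolerance = 1e-12)
  expect_equal(round(dprime(a, b), 4), 0.3536)
  expect_equal(dprime(a, a), 0)
  set.seed(3)
  for (i in 1:25) {
    mi <- runif(1, 600, 900); mj <- runif(1, 600, 900)
    vi <- runif(1, 1, 400); vj <- runif(1, 1, 400)
    d <- dprime_values(mi, vi, mj, vj)
    expect_equal(dprime_values(mj, vj, mi, vi), -d)
    c_ <- runif(1, 0.1, 10) # rescaling all pitches by c scales sd by c too
    expect_equal(dprime_values(c_ * mi, c_^2 * vi, c_ * mj, c_^2 * vj), d,
                 tolerance = 1e-9)
  }
  expect_error(dprime(summary_row(1, 0), summary_row(2, 0)), "zero")
})

test_that("average daily change handles constant, linear and stochastic series", {
  s <- summaries_from_means(rep(750, 10), n_baseline = 5)
  expect_equal(average_daily_change(s, "stimulus"), 0)
  expect_equal(average_daily_change(s, "baseline"), 0)
  # exactly +0.2 d-prime per day during the stimulus phase
  means <- c(rep(750, 5), 750 + cumsum(rep(0.2, 5)))
  s2 <- summaries_from_means(means, n_baseline = 5)
  expect_equal(average_daily_change(s2, "stimulus"), 0.2, tolerance = 1e-12)
  # generator ground truth: injected 0.19 d-prime/day
  b <- simulate_bird(bird_params("g", "subs", "high", response_per_day = 0.19,
                                 renditions_per_day_mean = 400,
                                 n_stimulus_days = 12, seed = 11))
  ch <- average_daily_change(daily_summaries(b), "stimulus")
  expect_equal(ch, 0.19, tolerance = 0.06)
})

test_that("direction and magnitude flip together under mirroring", {
  means <- c(rep(750, 5), 750 + cumsum(rep(0.3, 6)))
  up <- summaries_from_means(means, n_baseline = 5)
  res_up <- direction_and_magnitude(up)
  expect_identical(res_up$delta, 1)
  expect_gt(res_up$magnitude, 0)
  mirrored <- summaries_from_means(2 * 750 - means, n_baseline = 5)
  res_dn <- direction_and_magnitude(mirrored)
  expect_identical(res_dn$delta, -1)
  expect_equal(res_dn$magnitude, res_up$magnitude, tolerance = 1e-12)
  flat <- summaries_from_means(rep(750, 10), n_baseline = 5)
  expect_warning(res0 <- direction_and_magnitude(flat), "direction")
  expect_identical(res0$delta, 1)
})

test_that("paradigm criteria implement the strict 0.5 / 2.5 d-prime rules", {
  flat <- summaries_from_means(rep(750, 5), n_baseline = 5)
  expect_identical(paradigm_criteria(flat, "baseline"), "start_ok")
  # exactly |d'| = 0.5 across 5 days: strict inequality, keep waiting
  edge <- summaries_from_means(c(750, 750, 750, 750, 750.5), n_baseline = 5)
  expect_identical(paradigm_criteria(edge, "baseline"), "continue")
  just_under <- summaries_from_means(c(750, 750, 750, 750, 750.4999),
                                     n_baseline = 5)
  expect_identical(paradigm_criteria(just_under, "baseline"), "start_ok")
  # cumulative 3 d-prime shift vs baseline ends the paradigm
  shift <- summaries_from_means(c(rep(750, 5), 750.6, 751.2, 751.8, 752.4, 753),
                                n_baseline = 5)
  expect_identical(paradigm_criteria(shift, "stimulus"), "end_shift")
  # drifted then stabilized near zero
  stable <- summaries_from_means(c(rep(750, 5), 751, 751.2, rep(751.3, 5)),
                                 n_baseline = 5)
  expect_identical(paradigm_criteria(stable, "stimulus"), "end_stable")
  expect_error(paradigm_criteria(flat[1:4, ], "baseline"), "5")
})

test_that("pitch-trace d-prime localizes injected shifts in syllable time", {
  set.seed(9)
  n_t <- 60L
  base <- matrix(rnorm(80 * n_t, 0, 1), 80)
  expect_equal(max(abs(pitch_trace_dprime(base, base))), 0)
  # global +1 sd shift: flat curve near 1
  shifted <- base + 1
  curve <- pitch_trace_dprime(base, shifted)
  expect_true(all(abs(curve - 1) < 0.5))
  expect_equal(mean(curve), 1, tolerance = 0.05)
  # shift confined to a 16-sample band: curve peaks inside the band
  band <- 20:35
  local <- matrix(rnorm(80 * n_t, 0, 1), 80)
  local[, band] <- local[, band] + 2
  curve2 <- pitch_trace_dprime(base, local)
  expect_true(which.max(curve2) %in% band)
  expect_lt(max(abs(curve2[-band])), max(curve2[band]))
  # flipping makes downward learners comparable
  expect_equal(pitch_trace_dprime(base, shifted, flip = TRUE), -curve)
  expect_error(pitch_trace_dprime(base, base[, 1:10]), "misaligned")
})

test_that("time-shuffled traces stay within a permutation-derived flatness bound", {
  set.seed(31)
  n_r <- 60L; n_t <- 40L
  a <- matrix(rnorm(n_r * n_t), n_r)
  b <- matrix(rnorm(n_r * n_t), n_r)
  shuffled <- b[, sample(n_t)]
  observed <- max(abs(pitch_trace_dprime(a, shuffled)))
  null_max <- replicate(200, {
    pool <- rbind(a, b)
    pick <- sample(2 * n_r, n_r)
    max(abs(pitch_trace_dprime(pool[pick, ], pool[-pick, ])))
  })
  expect_lt(observed, quantile(null_max, 0.99) + 0.2)
})

test_that("binomial direction probabilities match exhaustive enumeration", {
  expect_equal(binomial_direction_prob(10, 10, "one_sided"), 1 / 1024)
  expect_equal(binomial_direction_prob(5, 10, "two_sided"), 1)
  # brute force over all 2^10 outcomes
  outcomes <- expand.grid(rep(list(0:1), 10))
  k_up <- rowSums(outcomes)
  for (k in c(6, 8, 9, 10)) {
    expect_equal(binomial_direction_prob(k, 10, "one_sided"),
                 mean(k_up >= k), tolerance = 1e-12)
    expect_equal(binomial_direction_prob(k, 10, "two_sided"),
                 mean(k_up >= k | k_up <= 10 - k), tolerance = 1e-12)
    expect_equal(binomial_direction_prob(k, 10, "point"),
                 mean(k_up == k), tolerance = 1e-12)
  }
  # the 9-of-10 case under all conventions (the often-quoted <1% bound
  # only holds for the one-sided 10-of-10 tail)
  expect_equal(binomial_direction_prob(9, 10, "one_sided"), 11 / 1024)
  expect_equal(binomial_direction_prob(9, 10, "two_sided"), 22 / 1024)
})
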