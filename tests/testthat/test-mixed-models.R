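test_that("pitch change table partitions observations into the three indicator sets", {
  tab <- simulate_cohort(small_deaf_design(n_per_group = 2L), seed = 3)
  ch <- pitch_change_table(daily_summaries(tab))
  # each observation activates at most one indicator
  active <- (ch$bsl != 0) + (ch$ctrl != 0) + (ch$stim != 0)
  expect_true(all(active <= 1))
  # straddle rows (baseline -> first stimulus day) carry all-zero indicators
  straddle <- ch$day == 7 & ch$group == "subs"
  expect_true(all(active[straddle] == 0))
  # subs birds never activate ctrl; unsubs never activate stim
  expect_true(all(ch$ctrl[ch$group == "subs"] == 0))
  expect_true(all(ch$stim[ch$group == "unsubs"] == 0))
  # sign of the stimulus indicator follows the target side
  sides <- tab$target_side[match(ch$bird_id, tab$bird_id)]
  expect_true(all(ch$stim[sides == "high"] >= 0))
  expect_true(all(ch$stim[sides == "low"] <= 0))
})

test_that("the daily-change model recovers injected effects", {
  design <- small_deaf_design(n_per_group = 5L, response = 0.19)
  fit <- fit_pitch_lmm(pitch_change_table(daily_summaries(
    simulate_cohort(design, seed = 17))))
  co <- fit$coef
  expect_identical(co$term, c("bsl", "ctrl", "stim"))
  d <- co[co$term == "stim", ]
  expect_lt(abs(d$estimate - 0.19), 3 * d$se)
  expect_lt(d$p, 0.001)
  expect_equal(co$df[1], fit$n_obs - 3)
  b <- co[co$term == "bsl", ]
  expect_lt(abs(b$estimate), 3 * b$se)
})

test_that("degenerate and invariance cases behave", {
  ch <- data.frame(bird_id = rep(c("a", "b"), each = 6),
                   group = rep(c("subs", "unsubs"), each = 6),
                   day = rep(2:7, 2), dprime = 0,
                   bsl = rep(c(1, 1, 0, 0, 0, 0), 2),
                   ctrl = c(rep(0, 6), c(0, 0, 0, 1, 1, 1)),
                   stim = c(c(0, 0, 0, 1, 1, 1), rep(0, 6)))
  fit0 <- fit_pitch_lmm(ch)
  expect_true(all(fit0$coef$estimate == 0))
  # estimates invariant to bird relabeling
  tab <- simulate_cohort(small_deaf_design(n_per_group = 3L), seed = 21)
  ch1 <- pitch_change_table(daily_summaries(tab))
  ch2 <- ch1
  relabel <- setNames(sample(unique(ch1$bird_id)), unique(ch1$bird_id))
  ch2$bird_id <- unname(relabel[ch2$bird_id])
  expect_equal(fit_pitch_lmm(ch1)$coef$estimate,
               fit_pitch_lmm(ch2)$coef$estimate, tolerance = 1e-6)
  # all birds in one group is a singular design
  expect_error(fit_pitch_lmm(ch1[ch1$stim == 0 & ch1$group == "unsubs", ]),
               "singular")
})

test_that("with zero random-effect variance the ML fit equals OLS", {
  tab <- simulate_cohort(small_deaf_design(n_per_group = 4L), seed = 33)
  ch <- pitch_change_table(daily_summaries(tab))
  fit <- fit_pitch_lmm(ch)
  ols <- lm(dprime ~ 0 + bsl + ctrl + stim, data = ch)
  # the generator has no between-bird effect heterogeneity, so the random
  # intercept collapses and fixed effects coincide with least squares
  expect_lt(fit$random_sd, 0.02)
  expect_equal(fit$coef$estimate, unname(coef(ols)), tolerance = 1e-3)
})

test_that("collapsing baseline and control drift leaves the stimulus term stable", {
  tab <- simulate_cohort(small_deaf_design(n_per_group = 5L), seed = 41)
  ch <- pitch_change_table(daily_summaries(tab))
  full <- fit_pitch_lmm(ch)
  red <- fit_pitch_lmm(ch, reduced = TRUE)
  d_full <- full$coef[full$coef$term == "stim", ]
  d_red <- red$coef[red$coef$term == "stim", ]
  expect_identical(sign(d_full$estimate), sign(d_red$estimate))
  expect_identical(d_full$p < 0.05, d_red$p < 0.05)
  expect_equal(d_red$estimate, d_full$estimate, tolerance = 0.05)
})

test_that("singing-rate model isolates the deafening-by-stimulus interaction", {
  # constant response across all birds: only the offset survives
  rates <- expand.grid(bird_id = sprintf("b%02d", 1:12), day = 1:3)
  rates$deaf <- as.numeric(as.integer(factor(rates$bird_id)) %% 2 == 0)
  rates$lo <- as.numeric(as.integer(factor(rates$bird_id)) %% 4 < 2)
  rates$deaf_lo <- rates$deaf * rates$lo
  rates$rate <- 1.3
  fit <- fit_singing_lmm(rates)
  expect_equal(fit$coef$estimate[fit$coef$term == "(Intercept)"], 1.3)
  expect_true(all(abs(fit$coef$estimate[-1]) < 1e-10))
  # interaction-only effect is recovered with a near-zero main stimulus term
  set.seed(13)
  rates$rate <- 1 + 0.5 * rates$deaf_lo + rnorm(nrow(rates), 0, 0.12)
  fit2 <- fit_singing_lmm(rates)
  d <- fit2$coef[fit2$coef$term == "deaf_lo", ]
  b <- fit2$coef[fit2$coef$term == "lo", ]
  expect_lt(abs(d$estimate - 0.5), 3 * d$se)
  expect_lt(d$p, 0.01)
  expect_lt(abs(b$estimate), 3 * b$se)
  expect_error(fit_singing_lmm(rates[rates$deaf == 1, ]), "factor level")
})

test_that("full synthetic cohort shows the singing-rate valence signature", {
  tab <- simulate_cohort(study_design(n_subs = 6, n_unsubs = 6, n_lo = 6,
                                      n_nolo = 6, n_subs_rand = 0), seed = 19)
  fit <- fit_singing_lmm(singing_rate_table(tab))
  d <- fit$coef[fit$coef$term == "deaf_lo", ]
  expect_gt(d$estimate, 0) # substitution boosts singing only in deaf birds
  expect_lt(d$p, 0.05)
})

test_that("per-bird t-test matches the closed-form pooled statistic", {
  x <- c(0.31, 0.05, 0.17, 0.26, -0.02, 0.15)
  y <- c(0.02, -0.08, 0.06, -0.01, 0.04, -0.03, 0.02, 0.05)
  res <- per_bird_test(x, y)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, nx + ny - 2)
  expect_equal(res$p, 2 * pt(-abs(t_hand), nx + ny - 2), tolerance = 1e-12)
  same <- per_bird_test(x, x)
  expect_false(same$significant)
  expect_equal(same$p, 1)
})

test_that("random pairings quantify robustness of the population comparison", {
  set.seed(2)
  treated_vals <- lapply(1:5, function(i) rnorm(8, 0.3, 0.05))
  control_vals <- lapply(1:5, function(i) rnorm(8, 0.0, 0.05))
  names(treated_vals) <- paste0("t", 1:5)
  names(control_vals) <- paste0("c", 1:5)
  test_fn <- function(pairs) {
    x <- unlist(treated_vals[pairs$treated])
    y <- unlist(control_vals[pairs$control])
    per_bird_test(x, y)$significant
  }
  # strong effect, unconstrained: every replicate significant
  res <- random_pairings(paste0("t", 1:5), paste0("c", 1:5), test_fn,
                         n_replicates = 200, seed = 4)
  expect_equal(res$fraction_significant, 1)
  # null cohort: significant fraction near alpha
  null_vals <- lapply(1:10, function(i) rnorm(30, 0, 0.05))
  names(null_vals) <- c(paste0("t", 1:5), paste0("c", 1:5))
  null_fn <- function(pairs) {
    per_bird_test(unlist(null_vals[pairs$treated]),
                  unlist(null_vals[pairs$control]))$significant
  }
  res_null <- random_pairings(paste0("t", 1:5), paste0("c", 1:5), null_fn,
                              n_replicates = 400, seed = 8)
  expect_lt(res_null$fraction_significant, 0.2)
  # a single feasible matching makes all replicates identical
  feas <- diag(5) == 1
  seen <- new.env(); seen$pairs <- list()
  once_fn <- function(pairs) {
    seen$pairs[[length(seen$pairs) + 1L]] <- pairs[order(pairs$treated), ]
    TRUE
  }
  random_pairings(paste0("t", 1:5), paste0("c", 1:5), once_fn,
                  feasible = feas, n_replicates = 20, seed = 1)
  expect_true(all(vapply(seen$pairs, identical, logical(1), seen$pairs[[1]])))
  # infeasible constraints are rejected
  bad <- matrix(TRUE, 5, 5); bad[, 3] <- FALSE
  expect_error(random_pairings(paste0("t", 1:5), paste0("c", 1:5), once_fn,
                               feasible = bad), "infeasible")
  # surplus controls are all used, each treated bird at least once
  res_s <- random_pairings(paste0("t", 1:3), paste0("c", 1:5), function(pairs) {
    expect_equal(sort(unique(pairs$control)), paste0("c", 1:5))
    expect_true(all(paste0("t", 1:3) %in% pairs$treated))
    TRUE
  }, n_replicates = 5, seed = 3)
  expect_equal(res_s$fraction_significant, 1)
})
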