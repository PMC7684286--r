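test_that("theta estimates interpolate between prior and empirical frequencies", {
  expect_equal(estimate_theta(c(0, 0)), c(0.5, 0.5))
  expect_equal(estimate_theta(c(3, 1)), c(4 / 6, 2 / 6))
  big <- estimate_theta(c(3e6, 1e6))
  expect_equal(big, c(0.75, 0.25), tolerance = 1e-5)
  expect_equal(sum(estimate_theta(c(2, 0, 7), 0.5)), 1)
  expect_error(estimate_theta(c(0, 0), 0), "pseudocount")
})

test_that("the manipulation bonus is the KL impact with the deaf closed form", {
  expect_equal(manipulation_bonus(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(manipulation_bonus(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-15)
  expect_equal(manipulation_bonus(c(1, 0), c(1, 0)), 0)
  expect_error(manipulation_bonus(c(0.5, 0.5), c(1, 0)), "infinite")
  expect_identical(manipulation_bonus(c(0.5, 0.5), c(1, 0),
                                      allow_infinite = TRUE), Inf)
  # deaf equivalence: full KL equals -log theta(on) on the binary alphabet
  for (p_on in seq(0.02, 1, by = 0.02)) {
    expect_equal(manipulation_bonus(c(1, 0), c(p_on, 1 - p_on)),
                 -log(p_on), tolerance = 1e-12)
  }
})

test_that("exploration bonus is positive, monotone in counts and vanishing", {
  expect_gt(exploration_bonus(c(1, 1)), exploration_bonus(c(10, 10)))
  expect_lt(exploration_bonus(c(1e6, 1e6)), 1e-5)
  # zero counts maximize the bonus over count configurations
  e0 <- exploration_bonus(c(0, 0, 0))
  set.seed(4)
  for (i in 1:30) {
    cts <- rpois(3, sample(1:20, 1))
    expect_lte(exploration_bonus(cts), e0 + 1e-12)
  }
  # closed form agrees with a direct posterior-predictive KL computation
  kl_dirichlet <- function(a, b) {
    lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
      sum((a - b) * (digamma(a) - digamma(sum(a))))
  }
  for (cts in list(c(0, 0), c(3, 1), c(2, 5, 9), c(10, 0, 0, 4))) {
    alpha <- cts + 1
    pred <- alpha / sum(alpha)
    direct <- sum(vapply(seq_along(alpha), function(k) {
      a2 <- alpha; a2[k] <- a2[k] + 1
      pred[k] * kl_dirichlet(a2, alpha)
    }, numeric(1)))
    expect_equal(exploration_bonus(cts, 1), direct, tolerance = 1e-12)
  }
})

test_that("total reward composes the components and rejects positive punishment", {
  expect_equal(total_reward(0.1, log(2), FALSE, -0.2), 0.1 + log(2))
  expect_equal(total_reward(0, log(2), TRUE, -0.2), log(2) - 0.2,
               tolerance = 1e-15)
  expect_equal(total_reward(0, 0, FALSE, 0), 0)
  expect_error(total_reward(0, 0, TRUE, 0.1), "punishment")
})

test_that("the sensory model anchors unseen actions to the baseline", {
  m <- sensory_model(3, 2, theta0 = c(1, 0), lambda = 0.005)
  expect_equal(sensory_theta(m, 1), c(1, 0))
  expect_equal(manipulation_bonus(c(1, 0), sensory_theta(m, 1)), 0)
  # after consistent light-off observations the impact approaches its cap
  for (i in 1:50) record_observation(m, 2, 2L)
  expect_equal(manipulation_bonus(c(1, 0), sensory_theta(m, 2)),
               -log(0.005), tolerance = 1e-12)
  # mixed outcomes: impact depends on frequencies, not on visit count
  for (i in 1:10) record_observation(m, 3, c(1L, 2L)[1 + i %% 2])
  theta10 <- sensory_theta(m, 3)
  for (i in 1:90) record_observation(m, 3, c(1L, 2L)[1 + i %% 2])
  expect_equal(sensory_theta(m, 3), theta10, tolerance = 1e-12)
  expect_equal(manipulation_bonus(c(1, 0), sensory_theta(m, 3)),
               -log(0.005 + 0.995 * 0.5), tolerance = 1e-12)
})

test_that("under random 50% delivery no action beats the log 2 impact bound", {
  # asymptotic impact of any deterministic policy over the 18 actions when
  # light-off is an independent fair coin: every action's outcome
  # distribution is (1/2, 1/2), so M -> -log(1/2 + lambda/2) <= log 2
  lambda <- 0.005
  m_asym <- manipulation_bonus(c(1, 0), (1 - lambda) * c(0.5, 0.5) +
                                 lambda * c(1, 0))
  expect_lte(m_asym, log(2))
  expect_equal(m_asym, log(2), tolerance = 0.01)
  # policy grid: feed each of the 18 deterministic action choices a long
  # fair-coin outcome stream; no action's estimated impact exceeds the bound
  set.seed(23)
  m <- sensory_model(18, 2, theta0 = c(1, 0), lambda = lambda)
  m_hat <- vapply(1:18, function(a) {
    obs <- 1L + rbinom(4000, 1, 0.5)
    for (o in obs) record_observation(m, a, o)
    manipulation_bonus(c(1, 0), sensory_theta(m, a))
  }, numeric(1))
  expect_true(all(abs(m_hat - log(2)) < 0.06)) # binomial sampling noise
  expect_lte(mean(m_hat), log(2) + 0.01)
  # while a contingent action can exceed it
  expect_gt(manipulation_bonus(c(1, 0), (1 - lambda) * c(0, 1) +
                                 lambda * c(1, 0)), log(2))
})
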