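#' Dirichlet-smoothed distribution estimate
#'
#' Laplace-style estimator of a categorical distribution from counts:
#' `(count + pseudocount) / (total + pseudocount * alphabet)`. With
#' pseudocount 1 this is the classical add-one rule; as counts grow the
#' estimate converges to the empirical frequencies.
#'
#' @param counts Nonnegative count vector (one entry per symbol).
#' @param pseudocount Per-symbol pseudocount (default 1).
#' @return Probability vector of the same length.
#' @examples
#' estimate_theta(c(3, 1)) # 4/6, 2/6
#' @export
estimate_theta <- function(counts, pseudocount = 1) {
  stopifnot(length(counts) >= 1L, all(counts >= 0), pseudocount >= 0)
  if (pseudocount == 0 && sum(counts) == 0) {
    stop("all-zero counts need a positive pseudocount")
  }
  (counts + pseudocount) / (sum(counts) + pseudocount * length(counts))
}

#' Manipulation (impact) bonus
#'
#' The impact of an action is the Kullback-Leibler divergence (in nats)
#' between the estimated sensory distribution without acting and the
#' distribution following the action:
#' \deqn{M_j = D_{KL}(\hat\vartheta_0 \,\|\, \hat\vartheta_j).}
#' For a deaf bird the observation is binary (light on/off) and the
#' no-action distribution puts all mass on "on", so the bonus reduces
#' exactly to the Shannon surprise of light-on,
#' \eqn{M_j = -\log \hat\vartheta_j(\mathrm{on})}: an action is the more
#' impactful the more reliably it extinguishes the light. The largest
#' achievable impact under random 50% delivery is \eqn{\log 2}.
#'
#' @param theta0 No-action sensory distribution.
#' @param thetaj Sensory distribution following the action.
#' @param allow_infinite If `FALSE` (default), mass of `theta0` on a zero of
#'   `thetaj` raises an error instead of returning `Inf`.
#' @return KL divergence in nats (>= 0).
#' @examples
#' manipulation_bonus(c(1, 0), c(0.5, 0.5)) # log 2
#' @export
manipulation_bonus <- function(theta0, thetaj, allow_infinite = FALSE) {
  stopifnot(length(theta0) == length(thetaj),
            abs(sum(theta0) - 1) < 1e-9, abs(sum(thetaj) - 1) < 1e-9,
            all(theta0 >= 0), all(thetaj >= 0))
  sup <- theta0 > 0
  if (any(thetaj[sup] == 0)) {
    if (!allow_infinite) {
      stop("infinite impact: no-action distribution has mass where the ",
           "action distribution has none")
    }
    return(Inf)
  }
  sum(theta0[sup] * (log(theta0[sup]) - log(thetaj[sup])))
}

#' Exploration bonus (expected information gain)
#'
#' The Bayesian expected information gain about an action's sensory-outcome
#' distribution from one more observation, under a Dirichlet model with the
#' given per-symbol pseudocount: the posterior-predictive-weighted KL
#' divergence between the updated and current Dirichlet posteriors. In
#' closed form, with \eqn{\alpha_k = n_k + \mathrm{pc}} and
#' \eqn{A = \sum_k \alpha_k},
#' \deqn{E = \sum_k \frac{\alpha_k}{A}\left[\log A - \log\alpha_k
#'   + \psi(\alpha_k + 1) - \psi(A + 1)\right].}
#' The bonus is strictly positive, decreases as counts accumulate and
#' vanishes in the large-count limit — the knowledge-seeking drive saturates
#' with experience.
#'
#' @param counts Observation counts for the action (one entry per symbol).
#' @param pseudocount Per-symbol Dirichlet pseudocount.
#' @return Expected information gain in nats.
#' @examples
#' exploration_bonus(c(0, 0)) > exploration_bonus(c(10, 10))
#' @export
exploration_bonus <- function(counts, pseudocount = 1) {
  stopifnot(length(counts) >= 1L, all(counts >= 0), pseudocount > 0)
  alpha <- counts + pseudocount
  A <- sum(alpha)
  p <- alpha / A
  sum(p * (log(A) - log(alpha) + digamma(alpha + 1) - digamma(A + 1)))
}

#' Total reward of one action
#'
#' The agent's reward sums the exploration bonus, the manipulation bonus and
#' an extrinsic punishment delivered only on light-off events:
#' \eqn{R = E + M + r\,\mathbb{1}\{\mathrm{LO}\}} with \eqn{r \le 0}.
#'
#' @param exploration,manipulation Bonus components in nats (>= 0).
#' @param lo_flag Whether this step triggered light-off.
#' @param r_per_lo Extrinsic reinforcement per light-off event (<= 0).
#' @return Total reward in nats.
#' @examples
#' total_reward(0, log(2), TRUE, -0.2) # log 2 - 0.2
#' @export
total_reward <- function(exploration, manipulation, lo_flag, r_per_lo) {
  stopifnot(exploration >= 0, manipulation >= 0)
  if (r_per_lo > 0) stop("r_per_lo must be <= 0 (punishment)")
  exploration + manipulation + if (isTRUE(lo_flag)) r_per_lo else 0
}

#' Sensory model of an agent
#'
#' Tracks, per action, the counts of observed sensory symbols and estimates
#' each action's outcome distribution by shrinking the empirical frequencies
#' toward the no-action baseline distribution:
#' \deqn{\hat\vartheta_j = (1-\lambda)\,f_j + \lambda\,\hat\vartheta_0,}
#' with \eqn{\hat\vartheta_j = \hat\vartheta_0} before the first
#' observation. The anchor weight \eqn{\lambda} bounds the manipulation
#' bonus at \eqn{-\log\lambda} and makes an action's estimated impact depend
#' on the observed outcome frequencies, not on how often the action happens
#' to have been tried. The exploration bonus uses a Dirichlet model on the
#' raw counts with a Perks prior (total pseudocount mass 1 spread over the
#' alphabet) so that its magnitude is comparable across observation
#' alphabets of different size.
#'
#' @param n_actions Number of actions.
#' @param alphabet_size Number of observation symbols.
#' @param theta0 No-action baseline distribution over the alphabet.
#' @param lambda Shrinkage weight toward the baseline (default 0.005).
#' @param e_pseudocount Per-symbol pseudocount of the exploration bonus
#'   (default `1 / alphabet_size`, the Perks prior).
#' @return An environment of class `sensory_model` with fields `counts`
#'   (`n_actions` x `alphabet_size`), `theta0`, `lambda`, `e_pseudocount`.
#' @export
sensory_model <- function(n_actions, alphabet_size, theta0,
                          lambda = 0.005,
                          e_pseudocount = 1 / alphabet_size) {
  stopifnot(length(theta0) == alphabet_size,
            abs(sum(theta0) - 1) < 1e-9,
            lambda > 0, lambda < 1, e_pseudocount > 0)
  model <- new.env(parent = emptyenv())
  model$counts <- matrix(0, n_actions, alphabet_size)
  model$theta0 <- theta0
  model$lambda <- lambda
  model$e_pseudocount <- e_pseudocount
  class(model) <- "sensory_model"
  model
}

#' @rdname sensory_model
#' @param model A `sensory_model`.
#' @param action Action id.
#' @return `sensory_theta()`: the action's estimated outcome distribution.
#' @export
sensory_theta <- function(model, action) {
  cts <- model$counts[action, ]
  n <- sum(cts)
  if (n == 0) return(model$theta0)
  (1 - model$lambda) * cts / n + model$lambda * model$theta0
}

#' @rdname sensory_model
#' @param observation Observed symbol index.
#' @export
record_observation <- function(model, action, observation) {
  model$counts[action, observation] <- model$counts[action, observation] + 1
  invisible(model)
}
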