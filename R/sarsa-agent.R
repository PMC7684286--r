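#' Agent configuration
#'
#' Settings of the tabular SARSA agent that sings syllables in a
#' [syllable_world()] and maximizes the total reward
#' \eqn{R = E + M + r} (exploration bonus + manipulation bonus + extrinsic
#' punishment per light-off).
#'
#' @param learning_rate SARSA step size in (0, 1].
#' @param discount Within-syllable discount factor in \[0, 1\] (episodes —
#'   syllables — are independent).
#' @param epsilon Epsilon-greedy exploration rate in \[0, 1\].
#' @param r_per_lo Extrinsic reinforcement per light-off event (<= 0).
#' @param modality `"deaf"` (binary light observation) or `"hearing"` (full
#'   sensory state observation).
#' @param ablate_manipulation If `TRUE`, the manipulation bonus is forced to
#'   zero in the reward (the M = 0 ablation); the sensory model is still
#'   updated so that ablated and full runs share their random streams.
#' @param n_trials Number of syllables sung.
#' @param seed Optional seed for the run.
#' @param lambda Shrinkage weight of the sensory estimator (see
#'   [sensory_model()]).
#' @param e_pseudocount Pseudocount of the exploration bonus; default
#'   `1 / alphabet_size` (Perks prior).
#' @param converged_fraction Final fraction of trials treated as converged
#'   behavior when summarizing contingency, motivation and reward prediction
#'   errors (default 0.2).
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(learning_rate = 0.1, discount = 0.9, epsilon = 0.1,
                         r_per_lo = 0, modality = c("deaf", "hearing"),
                         ablate_manipulation = FALSE, n_trials = 2000L,
                         seed = NULL, lambda = 0.005, e_pseudocount = NULL,
                         converged_fraction = 0.2) {
  modality <- match.arg(modality)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            discount >= 0, discount <= 1,
            epsilon >= 0, epsilon <= 1,
            r_per_lo <= 0, n_trials >= 1,
            converged_fraction > 0, converged_fraction <= 1)
  structure(list(learning_rate = learning_rate, discount = discount,
                 epsilon = epsilon, r_per_lo = r_per_lo, modality = modality,
                 ablate_manipulation = isTRUE(ablate_manipulation),
                 n_trials = as.integer(n_trials), seed = seed,
                 lambda = lambda, e_pseudocount = e_pseudocount,
                 converged_fraction = converged_fraction),
            class = "agent_config")
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the action with the maximal Q value
#' (uniform tie-break), otherwise a uniform random action.
#'
#' @param q_row Numeric vector of Q values over the available actions.
#' @param epsilon Exploration rate.
#' @return The selected action index.
#' @export
select_action <- function(q_row, epsilon = 0) {
  n <- length(q_row)
  if (n == 0L) stop("empty Q row")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    return(sample.int(n, 1L))
  }
  best <- which(q_row == max(q_row))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' One SARSA update
#'
#' The on-policy temporal-difference update: the prediction error is
#' \eqn{\delta = R + \gamma Q(s', a') - Q(s, a)} (with \eqn{Q(s', a') = 0}
#' at the terminal note) and \eqn{Q(s, a)} moves by \eqn{\alpha\delta}.
#'
#' @param q Q matrix (states x actions).
#' @param s,a Current state and action indices.
#' @param reward Reward received.
#' @param s_next,a_next Next state and action (`NA` at episode end).
#' @param alpha Learning rate.
#' @param gamma Discount factor.
#' @return List with the updated `q` and the prediction error `delta`.
#' @export
sarsa_step <- function(q, s, a, reward, s_next, a_next, alpha, gamma) {
  q_next <- if (is.na(s_next) || is.na(a_next)) 0 else q[s_next, a_next]
  delta <- reward + gamma * q_next - q[s, a]
  q[s, a] <- q[s, a] + alpha * delta
  list(q = q, delta = delta)
}

#' Run a SARSA agent in a syllable world
#'
#' Simulates `n_trials` syllables. Each trial is one episode over the notes:
#' the agent picks a variant per note (epsilon-greedy on its Q table), the
#' world emits a sensory state, the reward components are computed from the
#' agent's current sensory model (exploration bonus from the Dirichlet
#' counts, manipulation bonus as the KL impact of the action against the
#' no-action baseline, extrinsic `r_per_lo` on light-off), the model counts
#' are updated, and Q is updated by SARSA. Deaf agents observe only the
#' light channel; hearing agents observe the emitted sensory state.
#'
#' @param world A [syllable_world()].
#' @param config An [agent_config()].
#' @param keep_trace If `TRUE`, return the full per-step trace (trial, note,
#'   action, state, lo, E, M, r, R, rpe); disable for large sweeps.
#' @return List of class `agent_run` with elements `q` (notes x variants),
#'   `visits` (same shape, counted over the converged window), `contingency`
#'   (fraction of converged-window trials with at least one light-off),
#'   `motivation` (visit-weighted mean Q over the converged window, see
#'   [motivation_index()]), `mean_manipulation` (mean per-step M over the
#'   converged window), `trial_lo` (logical per trial), `config`, `world`,
#'   and `trace` (data.frame or `NULL`).
#' @examples
#' w <- syllable_world()
#' run <- run_agent(w, agent_config(modality = "deaf", n_trials = 200, seed = 1))
#' run$contingency
#' @export
run_agent <- function(world, config, keep_trace = FALSE) {
  stopifnot(inherits(world, "syllable_world"), inherits(config, "agent_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_notes <- world$n_notes
  n_var <- world$n_variants
  n_actions <- world$n_actions
  n_trials <- config$n_trials
  deaf <- config$modality == "deaf"
  k_alpha <- if (deaf) 2L else world$n_states + 1L
  theta0 <- if (deaf) c(1, 0) else c(rep(0, world$n_states), 1)
  s0 <- if (deaf) 1L else world$n_states + 1L # the baseline's support symbol
  pc <- if (is.null(config$e_pseudocount)) 1 / k_alpha else config$e_pseudocount
  lambda <- config$lambda
  alpha_lr <- config$learning_rate
  gamma <- config$discount
  eps <- config$epsilon
  r_lo <- config$r_per_lo
  ablate <- config$ablate_manipulation

  counts <- matrix(0, n_actions, k_alpha)
  # cached per-action reward components, refreshed after each observation
  e_zero <- exploration_bonus(numeric(k_alpha), pc)
  e_cur <- rep(e_zero, n_actions)
  m_cur <- rep(0, n_actions) # theta_hat = theta0 before any observation
  q <- matrix(0, n_notes, n_var)

  # precomputed sampling tables for the emission rows
  emis_cum <- t(apply(world$emission, 1L, cumsum))

  trial_lo <- logical(n_trials)
  conv_start <- n_trials - floor(config$converged_fraction * n_trials) + 1L
  visits <- matrix(0, n_notes, n_var)
  motiv_sum <- 0; motiv_n <- 0L
  m_sum <- 0; m_n <- 0L

  if (keep_trace) {
    n_rows <- n_trials * n_notes
    tr <- list(trial = integer(n_rows), note = integer(n_rows),
               action = integer(n_rows), state = integer(n_rows),
               lo = logical(n_rows), E = numeric(n_rows), M = numeric(n_rows),
               r = numeric(n_rows), R = numeric(n_rows), rpe = numeric(n_rows))
    row <- 0L
  }

  for (t in seq_len(n_trials)) {
    forced_lo <- if (world$lo_mode == "random") stats::runif(1) < 0.5 else FALSE
    any_lo <- FALSE
    variant <- select_action(q[1L, ], eps)
    for (note in seq_len(n_notes)) {
      a <- (note - 1L) * n_var + variant
      # emit a sensory state from the action's row
      u <- stats::runif(1)
      state <- which(emis_cum[a, ] >= u)[1L]
      lo <- switch(world$lo_mode,
                   state = state %in% world$lo_states,
                   random = forced_lo, none = FALSE)
      any_lo <- any_lo || lo
      obs <- if (deaf) (if (lo) 2L else 1L) else state

      e_j <- e_cur[a]
      m_j <- m_cur[a]
      reward <- e_j + (if (ablate) 0 else m_j) + (if (lo) r_lo else 0)

      # update the sensory model and refresh the action's cached bonuses
      counts[a, obs] <- counts[a, obs] + 1
      cts <- counts[a, ]
      e_cur[a] <- exploration_bonus(cts, pc)
      m_cur[a] <- -log((1 - lambda) * cts[s0] / sum(cts) + lambda * theta0[s0])

      # choose the next note's variant (SARSA is on-policy)
      if (note < n_notes) {
        next_variant <- select_action(q[note + 1L, ], eps)
        q_next <- q[note + 1L, next_variant]
      } else {
        next_variant <- NA_integer_
        q_next <- 0
      }
      delta <- reward + gamma * q_next - q[note, variant]
      q[note, variant] <- q[note, variant] + alpha_lr * delta

      if (keep_trace) {
        row <- row + 1L
        tr$trial[row] <- t; tr$note[row] <- note; tr$action[row] <- a
        tr$state[row] <- state; tr$lo[row] <- lo
        tr$E[row] <- e_j; tr$M[row] <- m_j
        tr$r[row] <- if (lo) r_lo else 0
        tr$R[row] <- reward; tr$rpe[row] <- delta
      }
      if (t >= conv_start) {
        visits[note, variant] <- visits[note, variant] + 1
        motiv_sum <- motiv_sum + q[note, variant]
        motiv_n <- motiv_n + 1L
        m_sum <- m_sum + m_j; m_n <- m_n + 1L
      }
      variant <- next_variant
    }
    trial_lo[t] <- any_lo
  }

  structure(list(
    q = q, visits = visits,
    contingency = mean(trial_lo[conv_start:n_trials]),
    motivation = motiv_sum / motiv_n,
    mean_manipulation = m_sum / m_n,
    trial_lo = trial_lo, config = config, world = world,
    trace = if (keep_trace) as.data.frame(tr) else NULL
  ), class = "agent_run")
}

#' @export
print.agent_run <- function(x, ...) {
  cat("SARSA agent run:", x$config$n_trials, "trials,",
      x$config$modality, "modality, r per LO =", x$config$r_per_lo,
      if (x$config$ablate_manipulation) "(M ablated)" else "", "\n")
  cat("Converged-window contingency:", format(x$contingency, digits = 3),
      "| motivation index:", format(x$motivation, digits = 3), "\n")
  invisible(x)
}

#' Motivation index of a Q table
#'
#' The visit-weighted mean Q value: the expected total reward of the
#' state-action pairs the agent actually experiences under its current
#' policy. Visit weighting (rather than a uniform average over the table)
#' keeps unvisited state-actions from diluting the index.
#'
#' @param q Q matrix (notes x variants).
#' @param visits Matrix of visit counts with the same shape.
#' @return The weighted mean Q value (arbitrary units).
#' @examples
#' motivation_index(matrix(2, 1, 3), matrix(1, 1, 3)) # 2
#' @export
motivation_index <- function(q, visits) {
  stopifnot(all(dim(q) == dim(visits)), all(visits >= 0))
  if (sum(visits) == 0) stop("empty visit set")
  sum(q * visits) / sum(visits)
}

#' Reward-prediction-error summary at one note
#'
#' Splits the converged-window prediction errors at a given note into
#' reinforced trials (light-off delivered at that note) and escape trials
#' (no light-off), and returns the mean error of each class. In a converged
#' punished agent the reinforced-trial mean is negative (worse than
#' expected) and the escape-trial mean positive (relief), mirroring
#' dopaminergic firing on hit versus escape trials. By default only trials
#' whose chosen action can trigger light-off (nonzero emission mass on the
#' light-off states) enter the summary, matching analyses restricted to
#' targeted renditions.
#'
#' @param run An [run_agent()] result with a trace (`keep_trace = TRUE`).
#' @param note Note position to summarize (default 2).
#' @param targeted_only Restrict to actions with nonzero light-off
#'   probability (default `TRUE`).
#' @return List with `mean_rpe_reinforced`, `mean_rpe_escape`,
#'   `n_reinforced`, `n_escape`.
#' @export
rpe_summary <- function(run, note = 2L, targeted_only = TRUE) {
  stopifnot(inherits(run, "agent_run"))
  if (is.null(run$trace)) stop("run has no trace; rerun with keep_trace = TRUE")
  tr <- run$trace
  conv_start <- run$config$n_trials -
    floor(run$config$converged_fraction * run$config$n_trials) + 1L
  sel <- tr$note == note & tr$trial >= conv_start
  if (targeted_only) sel <- sel & run$world$p_lo[tr$action] > 0
  hit <- sel & tr$lo
  esc <- sel & !tr$lo
  if (!any(hit) || !any(esc)) {
    stop("need both reinforced and escape trials at note ", note)
  }
  list(mean_rpe_reinforced = mean(tr$rpe[hit]),
       mean_rpe_escape = mean(tr$rpe[esc]),
       n_reinforced = sum(hit), n_escape = sum(esc))
}
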