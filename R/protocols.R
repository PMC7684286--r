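#' Default reinforcement-per-LO grid
#'
#' Eight log-spaced negative reinforcement magnitudes from 0.01 to 2 nats
#' per light-off event.
#'
#' @param n Number of grid points.
#' @param from,to Magnitude range (positive; returned negated).
#' @return Decreasing vector of negative r values.
#' @export
default_r_grid <- function(n = 8L, from = 0.01, to = 2) {
  -exp(seq(log(from), log(to), length.out = n))
}

#' Reinforcement sweep over simulated cohorts
#'
#' For every value of the extrinsic reinforcement `r` per light-off, runs a
#' cohort of agents per modality (deaf, hearing, and optionally deaf with
#' the manipulation bonus ablated) for `n_trials` syllables each and records
#' the converged-window light-off contingency and motivation index. Matched
#' control agents — an identical world in which the light never goes off,
#' the unsubstituted/no-LO condition — provide the motivation baselines; they
#' experience no reinforcement, so one control cohort per modality serves
#' the whole grid.
#'
#' @param r_grid Vector of reinforcement values (<= 0, at least 3).
#' @param n_agents_per_cell Agents per (modality, r) cell (>= 2; the
#'   paradigm's default is 20).
#' @param modalities Character vector among `"deaf"`, `"hearing"`,
#'   `"deaf_ablated"`.
#' @param seed Master seed; each agent gets a derived counter seed.
#' @param n_trials Trials per agent.
#' @param world A [syllable_world()] (default world if omitted).
#' @return List of class `reinforcement_sweep` with `cells` (data.frame:
#'   modality, r, mean/sd contingency, mean/sd motivation, n_agents) and
#'   `controls` (data.frame: modality, mean/sd motivation).
#' @export
sweep_reinforcement <- function(r_grid = default_r_grid(),
                                n_agents_per_cell = 20L,
                                modalities = c("deaf", "hearing", "deaf_ablated"),
                                seed = 1L, n_trials = 2000L,
                                world = syllable_world()) {
  stopifnot(length(r_grid) >= 3L, all(r_grid <= 0), n_agents_per_cell >= 2L)
  modalities <- match.arg(modalities, several.ok = TRUE)
  seed <- as.integer(seed)

  run_cell <- function(modality, r, cell_index, w) {
    base_modality <- if (modality == "deaf_ablated") "deaf" else modality
    cont <- numeric(n_agents_per_cell)
    motiv <- numeric(n_agents_per_cell)
    for (i in seq_len(n_agents_per_cell)) {
      cfg <- agent_config(
        modality = base_modality, r_per_lo = r, n_trials = n_trials,
        ablate_manipulation = modality == "deaf_ablated",
        seed = seed + 10000L * cell_index + i
      )
      run <- run_agent(w, cfg)
      cont[i] <- run$contingency
      motiv[i] <- run$motivation
    }
    data.frame(modality = modality, r = r,
               mean_contingency = mean(cont), sd_contingency = stats::sd(cont),
               mean_motivation = mean(motiv), sd_motivation = stats::sd(motiv),
               n_agents = n_agents_per_cell, stringsAsFactors = FALSE)
  }

  cell_index <- 0L
  cells <- list()
  for (m in modalities) {
    for (r in r_grid) {
      cell_index <- cell_index + 1L
      cells[[cell_index]] <- run_cell(m, r, cell_index, world)
    }
  }
  cells <- do.call(rbind, cells)

  control_world <- syllable_world(
    n_notes = world$n_notes, n_variants = world$n_variants,
    kernel = world$emission[2, 1:3] / sum(world$emission[2, 1:3]),
    lo_mode = "none"
  )
  ctrl_modalities <- unique(ifelse(modalities == "deaf_ablated", "deaf", modalities))
  controls <- do.call(rbind, lapply(seq_along(ctrl_modalities), function(k) {
    m <- ctrl_modalities[k]
    cell <- run_cell(m, 0, 1000L + k, control_world)
    data.frame(modality = m, mean_motivation = cell$mean_motivation,
               sd_motivation = cell$sd_motivation,
               n_agents = n_agents_per_cell, stringsAsFactors = FALSE)
  }))

  structure(list(cells = cells, controls = controls, r_grid = sort(r_grid),
                 n_trials = n_trials, seed = seed),
            class = "reinforcement_sweep")
}

#' @export
print.reinforcement_sweep <- function(x, ...) {
  cat("Reinforcement sweep:", length(x$r_grid), "r values,",
      x$n_trials, "trials/agent\n")
  print(x$cells, digits = 3)
  cat("Controls (no light-off):\n")
  print(x$controls, digits = 3)
  invisible(x)
}

#' Plausible reinforcement-per-LO region
#'
#' The contiguous sub-interval of the r grid on which the simulated cohorts
#' jointly reproduce the observed pattern: deaf contingency above 50%,
#' hearing contingency below 50%, deaf motivation above its no-stimulus
#' control and hearing motivation below its control. Returns the longest
#' contiguous run of r values satisfying the conjunction.
#'
#' @param sweep A [sweep_reinforcement()] result including both `"deaf"` and
#'   `"hearing"` modalities.
#' @return List with `r_values` (the region, possibly empty), `r_range`, and
#'   `table` (per-r condition breakdown).
#' @export
plausible_region <- function(sweep) {
  stopifnot(inherits(sweep, "reinforcement_sweep"))
  cells <- sweep$cells
  need <- c("deaf", "hearing")
  if (!all(need %in% cells$modality)) {
    stop("sweep must include deaf and hearing modalities")
  }
  deaf <- cells[cells$modality == "deaf", ]
  hear <- cells[cells$modality == "hearing", ]
  deaf <- deaf[order(deaf$r), ]; hear <- hear[order(hear$r), ]
  ctrl <- sweep$controls
  deaf_ctrl <- ctrl$mean_motivation[ctrl$modality == "deaf"]
  hear_ctrl <- ctrl$mean_motivation[ctrl$modality == "hearing"]

  tab <- data.frame(
    r = deaf$r,
    deaf_above_chance = deaf$mean_contingency > 0.5,
    hearing_below_chance = hear$mean_contingency[match(deaf$r, hear$r)] < 0.5,
    deaf_motivated = deaf$mean_motivation > deaf_ctrl,
    hearing_demotivated =
      hear$mean_motivation[match(deaf$r, hear$r)] < hear_ctrl
  )
  tab$all <- tab$deaf_above_chance & tab$hearing_below_chance &
    tab$deaf_motivated & tab$hearing_demotivated

  # longest contiguous run of TRUE
  runs <- rle(tab$all)
  if (!any(runs$values)) {
    return(list(r_values = numeric(0), r_range = c(NA_real_, NA_real_), table = tab))
  }
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  hi <- cumsum(runs$lengths)[best]
  lo <- hi - runs$lengths[best] + 1L
  r_vals <- tab$r[lo:hi]
  list(r_values = r_vals, r_range = range(r_vals), table = tab)
}

#' Random 50% light-off protocol
#'
#' Runs deaf agents in a world that delivers light-off on a fair coin per
#' syllable, independent of the agent's actions. Because no action predicts
#' the stimulus, every action's outcome distribution converges to
#' (on: 1/2, off: 1/2) and the achievable impact saturates at log 2 —
#' strictly less than what a contingent (substituted) agent can reach — and
#' the light-off contingency is pinned at 50%.
#'
#' @param n_agents Number of agents.
#' @param n_trials Trials per agent.
#' @param seed Master seed.
#' @param r_per_lo Extrinsic reinforcement per light-off (default 0).
#' @return List with `mean_manipulation` (mean converged-window per-step M),
#'   `contingency` (mean converged-window light-off fraction) and the
#'   per-agent values.
#' @export
subs_rand_run <- function(n_agents = 5L, n_trials = 10000L, seed = 1L,
                          r_per_lo = 0) {
  world <- syllable_world(lo_mode = "random")
  m_vals <- numeric(n_agents)
  cont <- numeric(n_agents)
  for (i in seq_len(n_agents)) {
    cfg <- agent_config(modality = "deaf", r_per_lo = r_per_lo,
                        n_trials = n_trials, seed = as.integer(seed) + i)
    run <- run_agent(world, cfg)
    m_vals[i] <- run$mean_manipulation
    cont[i] <- run$contingency
  }
  list(mean_manipulation = mean(m_vals), contingency = mean(cont),
       per_agent_manipulation = m_vals, per_agent_contingency = cont)
}
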