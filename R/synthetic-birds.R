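#' Parameters of one synthetic bird
#'
#' Describes one bird's generative model: Gaussian within-day pitch
#' distribution with a slowly drifting mean, an additive reinforcement-driven
#' mean shift during the stimulus phase, and Poisson daily rendition counts
#' with a multiplicative trend. Effects are expressed in d-prime units per day
#' (multiples of the within-day standard deviation), matching how the
#' paradigm's outcomes are reported.
#'
#' @param bird_id Bird label (unique within a cohort).
#' @param group One of `"subs"` (deaf, substituted), `"unsubs"` (deaf
#'   control), `"LO"` (hearing, light-off), `"noLO"` (hearing control),
#'   `"subs_rand"` (deaf, random 50% stimulus).
#' @param target_side `"high"`, `"low"` or `"none"`: which side of the
#'   threshold triggers the stimulus (`"none"` for controls and random
#'   delivery).
#' @param baseline_mean_pitch Baseline mean pitch in Hz.
#' @param baseline_sd Within-day pitch standard deviation in Hz (constant
#'   across days; the default gives a coefficient of variation of 1%).
#' @param drift_per_day Spontaneous drift of the day mean, d-prime units/day.
#' @param response_per_day Reinforcement-driven shift of the day mean during
#'   the stimulus phase, d-prime units/day; positive values shift toward the
#'   stimulus zone (up for `"high"`, down for `"low"` birds), negative values
#'   away from it.
#' @param renditions_per_day_mean Expected renditions per day (Poisson,
#'   floored at 1).
#' @param singing_trend Multiplicative trend of the expected daily rendition
#'   count, fraction per day (e.g. 0.02 for +2%/day).
#' @param n_baseline_days,n_stimulus_days Number of baseline and stimulus
#'   days; at least 5 baseline days are required (the paradigm's start
#'   criterion inspects the last five).
#' @param seed Optional per-bird seed; when `NULL`, [simulate_cohort()]
#'   derives one from its master seed.
#' @return An object of class `bird_params`.
#' @export
bird_params <- function(bird_id,
                        group = c("subs", "unsubs", "LO", "noLO", "subs_rand"),
                        target_side = c("high", "low", "none"),
                        baseline_mean_pitch = 750,
                        baseline_sd = 7.5,
                        drift_per_day = 0,
                        response_per_day = 0,
                        renditions_per_day_mean = 150,
                        singing_trend = 0,
                        n_baseline_days = 6L,
                        n_stimulus_days = 11L,
                        seed = NULL) {
  group <- match.arg(group)
  target_side <- match.arg(target_side)
  stopifnot(baseline_sd > 0,
            renditions_per_day_mean >= 1,
            n_baseline_days >= 5L,
            n_stimulus_days >= 0L)
  if (group %in% c("subs", "LO") && target_side == "none") {
    stop("treated (", group, ") birds need target_side 'high' or 'low'")
  }
  if (group %in% c("unsubs", "noLO", "subs_rand") && target_side != "none") {
    stop(group, " birds must have target_side 'none'")
  }
  structure(
    list(bird_id = as.character(bird_id), group = group,
         target_side = target_side,
         baseline_mean_pitch = baseline_mean_pitch,
         baseline_sd = baseline_sd,
         drift_per_day = drift_per_day,
         response_per_day = response_per_day,
         renditions_per_day_mean = renditions_per_day_mean,
         singing_trend = singing_trend,
         n_baseline_days = as.integer(n_baseline_days),
         n_stimulus_days = as.integer(n_stimulus_days),
         seed = seed),
    class = "bird_params"
  )
}

# Direction multiplier toward the stimulus zone.
zone_direction <- function(target_side) {
  switch(target_side, high = 1, low = -1, none = 0)
}

#' Simulate one bird's rendition table
#'
#' Baseline days draw renditions i.i.d. from
#' \eqn{N(\mu_0 + \sigma\,\mathrm{drift}\,(d-1),\ \sigma^2)}. On stimulus
#' days the mean additionally shifts by `response_per_day` d-prime units per
#' stimulus day, signed toward the stimulus zone. Stimulus flags are set per
#' rendition by the closed-loop controller: each stimulus-day morning the
#' threshold resets to the previous day's median pitch, and a rendition
#' triggers when its pitch lies beyond the threshold on the bird's target
#' side (for `subs_rand` birds, a fair coin per rendition regardless of
#' pitch). Control birds (`unsubs`, `noLO`) never receive stimuli but keep
#' the same phase structure for time-matched analyses.
#'
#' @param params A [bird_params()] object.
#' @param controller Optional [threshold_controller()]; defaults to one
#'   matching the bird's target side (`"random"` for `subs_rand`). Supplying
#'   a controller whose side conflicts with `params$target_side` is an error.
#' @return A rendition table: `bird_id`, `group`, `target_side`, `phase`,
#'   `day`, `rendition`, `pitch_hz`, `stimulus`.
#' @examples
#' tab <- simulate_bird(bird_params("b1", "subs", "high",
#'                                  response_per_day = 0.19, seed = 1))
#' head(tab)
#' @export
simulate_bird <- function(params, controller = NULL) {
  stopifnot(inherits(params, "bird_params"))
  treated <- params$group %in% c("subs", "LO")
  random_stim <- params$group == "subs_rand"
  if (is.null(controller)) {
    controller <- if (random_stim) {
      threshold_controller("random")
    } else if (treated) {
      threshold_controller(params$target_side)
    } else {
      NULL
    }
  } else {
    want <- if (random_stim) "random" else params$target_side
    if (treated && controller$side != want) {
      stop("controller side '", controller$side,
           "' conflicts with target_side '", params$target_side, "'")
    }
    if (random_stim && controller$side != "random") {
      stop("subs_rand birds need a 'random' controller")
    }
  }
  if (!is.null(params$seed)) set.seed(params$seed)

  n_days <- params$n_baseline_days + params$n_stimulus_days
  dir <- zone_direction(params$target_side)
  sd0 <- params$baseline_sd
  rows <- vector("list", n_days)
  prev_pitches <- NULL

  for (d in seq_len(n_days)) {
    in_stim <- d > params$n_baseline_days
    stim_days <- if (in_stim) d - params$n_baseline_days else 0L
    mu <- params$baseline_mean_pitch +
      sd0 * (params$drift_per_day * (d - 1L) +
               dir * params$response_per_day * stim_days)
    lambda <- params$renditions_per_day_mean *
      (1 + params$singing_trend)^(d - 1L)
    n_r <- max(1L, stats::rpois(1L, max(lambda, 0)))
    pitch <- stats::rnorm(n_r, mu, sd0)

    stim <- rep(FALSE, n_r)
    if (in_stim && (treated || random_stim)) {
      controller <- update_threshold(controller, prev_pitches)
      stim <- stimulus_flags(controller, pitch)
    }
    rows[[d]] <- data.frame(
      bird_id = params$bird_id, group = params$group,
      target_side = params$target_side,
      phase = if (in_stim) "stimulus" else "baseline",
      day = d, rendition = seq_len(n_r),
      pitch_hz = pitch, stimulus = stim,
      stringsAsFactors = FALSE
    )
    prev_pitches <- pitch
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of birds
#'
#' Concatenates [simulate_bird()] tables for a list of [bird_params()]. Birds
#' without their own seed get one derived from the master seed plus their
#' position in the design (a counter split), so appending birds to a design
#' does not perturb the tables of earlier birds.
#'
#' @param design A list of [bird_params()] with unique `bird_id`s.
#' @param seed Master seed (integer).
#' @return A rendition table covering all birds (see [simulate_bird()]).
#' @export
simulate_cohort <- function(design, seed = 1L) {
  stopifnot(is.list(design), length(design) > 0L)
  ids <- vapply(design, function(p) p$bird_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate bird_id in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tabs <- lapply(seq_along(design), function(i) {
    p <- design[[i]]
    if (is.null(p$seed)) p$seed <- as.integer(seed) + i
    simulate_bird(p)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Default study design for all five cohorts
#'
#' Returns a list of [bird_params()] mirroring the reference experiment's
#' group sizes and reported effect sizes: 10 deaf substituted birds (5 high-
#' and 5 low-pitch targets, response +0.19 d-prime/day toward the stimulus
#' zone), 12 deaf controls, 12 hearing light-off birds (6/6 split, response
#' -0.08 d-prime/day, i.e. away from the zone), 12 hearing controls and 2
#' deaf birds with random 50% stimulus delivery. Singing-rate trends
#' reproduce the reported last-three-day changes (about +25% in substituted
#' deaf birds, -34% in deaf controls, -9% in hearing light-off birds, +8% in
#' hearing controls).
#'
#' @param n_subs,n_unsubs,n_lo,n_nolo,n_subs_rand Group sizes.
#' @param subs_response,lo_response Stimulus-phase responses in d-prime/day
#'   (signed toward the stimulus zone).
#' @return A list of [bird_params()].
#' @export
study_design <- function(n_subs = 10L, n_unsubs = 12L, n_lo = 12L,
                         n_nolo = 12L, n_subs_rand = 2L,
                         subs_response = 0.19, lo_response = -0.08) {
  design <- list()
  add <- function(design, n, prefix, group, response, trend) {
    for (i in seq_len(n)) {
      side <- if (group %in% c("subs", "LO")) {
        if (i <= ceiling(n / 2)) "high" else "low"
      } else "none"
      design[[length(design) + 1L]] <- bird_params(
        bird_id = sprintf("%s%02d", prefix, i), group = group,
        target_side = side, response_per_day = response,
        singing_trend = trend
      )
    }
    design
  }
  # Daily multiplicative trends chosen so that the last-3-day singing rates,
  # relative to the last-3-baseline-day mean, land near the reported changes.
  design <- add(design, n_subs, "subs", "subs", subs_response, 0.022)
  design <- add(design, n_unsubs, "unsubs", "unsubs", 0, -0.038)
  design <- add(design, n_lo, "lo", "LO", lo_response, -0.009)
  design <- add(design, n_nolo, "nolo", "noLO", 0, 0.007)
  design <- add(design, n_subs_rand, "srand", "subs_rand", 0, -0.06)
  design
}
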