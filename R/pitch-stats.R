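#' Per bird-day pitch summaries
#'
#' Collapses a rendition table (one row per syllable rendition) to one row per
#' bird and day: mean pitch, sample variance, rendition count, coefficient of
#' variation (in percent of the mean) and the stimulus contingency (fraction
#' of renditions that triggered the stimulus). Group metadata and, when
#' present, the experimental phase are carried along.
#'
#' @param table A rendition table as returned by [simulate_cohort()] or
#'   [read_renditions()]: columns `bird_id`, `day`, `pitch_hz`, `stimulus`,
#'   optionally `group`, `target_side`, `phase`.
#' @param min_count Days with fewer renditions are dropped (default 1, i.e.
#'   keep everything; cross-bird comparisons in the paradigm use 100).
#' @return A data.frame with columns `bird_id`, (`group`, `target_side`,
#'   `phase`,) `day`, `mean_pitch`, `var_pitch`, `n`, `cv`, `contingency` and
#'   `dprime_prev` (the d-prime between the previous and this day, `NA` on
#'   each bird's first day).
#' @examples
#' tab <- data.frame(bird_id = "b1", day = c(1, 1, 2, 2),
#'                   pitch_hz = c(99, 101, 100, 104), stimulus = FALSE)
#' daily_summaries(tab)
#' @export
daily_summaries <- function(table, min_count = 1L) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  req <- c("bird_id", "day", "pitch_hz")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0L) {
    stop("rendition table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(table$stimulus)) table$stimulus <- FALSE
  meta_cols <- intersect(c("group", "target_side", "phase"), names(table))

  key <- interaction(table$bird_id, table$day, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  rows <- lapply(idx, function(sel) {
    p <- table$pitch_hz[sel]
    m <- mean(p)
    v <- if (length(p) > 1L) stats::var(p) else 0
    out <- data.frame(
      bird_id = table$bird_id[sel[1L]], day = table$day[sel[1L]],
      mean_pitch = m, var_pitch = v, n = length(p),
      cv = 100 * sqrt(v) / m,
      contingency = mean(table$stimulus[sel]),
      stringsAsFactors = FALSE
    )
    for (mc in meta_cols) out[[mc]] <- table[[mc]][sel[1L]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bird_id, out$day), , drop = FALSE]
  out <- out[out$n >= min_count, , drop = FALSE]

  out$dprime_prev <- NA_real_
  for (b in unique(out$bird_id)) {
    idx <- which(out$bird_id == b)
    if (length(idx) < 2L) next
    for (k in 2L:length(idx)) {
      i <- idx[k - 1L]; j <- idx[k]
      if (out$day[j] == out$day[i] + 1L &&
          out$var_pitch[i] + out$var_pitch[j] > 0) {
        out$dprime_prev[j] <- dprime_values(
          out$mean_pitch[i], out$var_pitch[i],
          out$mean_pitch[j], out$var_pitch[j]
        )
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' d-prime between two days' pitch distributions
#'
#' The standardized pitch change between days \eqn{i} and \eqn{j}:
#' \deqn{d'_{i,j} = \frac{\bar p_j - \bar p_i}{\sqrt{\tfrac12(\sigma_i^2 + \sigma_j^2)}}}
#' where \eqn{\bar p} are day-mean pitches and \eqn{\sigma^2} the day pitch
#' variances. Antisymmetric in its arguments and invariant to rescaling all
#' pitches by a common positive factor.
#'
#' @param summary_i,summary_j Single rows of a [daily_summaries()] table (or
#'   any list with `mean_pitch` and `var_pitch`).
#' @return The dimensionless d-prime value.
#' @examples
#' a <- list(mean_pitch = 800, var_pitch = 100)
#' b <- list(mean_pitch = 805, var_pitch = 300)
#' dprime(a, b) # 0.3536
#' @export
dprime <- function(summary_i, summary_j) {
  dprime_values(summary_i$mean_pitch, summary_i$var_pitch,
                summary_j$mean_pitch, summary_j$var_pitch)
}

#' @rdname dprime
#' @param mean_i,var_i,mean_j,var_j Day means and variances given directly.
#' @export
dprime_values <- function(mean_i, var_i, mean_j, var_j) {
  pooled <- 0.5 * (var_i + var_j)
  if (any(pooled <= 0)) {
    stop("d-prime undefined: both day variances are zero")
  }
  (mean_j - mean_i) / sqrt(pooled)
}

#' Average daily pitch change over a window
#'
#' Mean of consecutive-day d-prime values \eqn{\langle d'_{i-1,i}\rangle}
#' over either the stimulus (LO) window — all stimulus days starting from the
#' second — or the baseline window, the last 4 baseline days.
#'
#' @param summaries A [daily_summaries()] table for one bird, with a `phase`
#'   column (`"baseline"`/`"stimulus"`).
#' @param window `"stimulus"` or `"baseline"`.
#' @return Mean daily change in d-prime per day.
#' @export
average_daily_change <- function(summaries, window = c("stimulus", "baseline")) {
  window <- match.arg(window)
  stopifnot("phase" %in% names(summaries))
  if (length(unique(summaries$bird_id)) != 1L) {
    stop("average_daily_change expects summaries of a single bird")
  }
  summaries <- summaries[order(summaries$day), , drop = FALSE]
  if (window == "stimulus") {
    days <- summaries$day[summaries$phase == "stimulus"]
    # changes with both end points in the window: from the second stimulus day
    use <- summaries$phase == "stimulus" & summaries$day %in% days[-1L]
  } else {
    bdays <- summaries$day[summaries$phase == "baseline"]
    if (length(bdays) < 2L) stop("baseline window shorter than 2 days")
    last4 <- utils::tail(bdays, 4L)
    use <- summaries$day %in% last4 & !is.na(summaries$dprime_prev)
  }
  vals <- summaries$dprime_prev[use]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 1L) stop("window shorter than 2 summarized days")
  mean(vals)
}

#' Direction and aligned magnitude of the pitch response
#'
#' The global direction of pitch change is \eqn{\delta = \mathrm{sign}(d'_{b,l})}
#' with \eqn{b} the last baseline day and \eqn{l} the last stimulus day; the
#' aligned magnitude is \eqn{\bar a' = \delta\,\langle d'_{i-1,i}\rangle_i}
#' over the stimulus window, so that a consistent shift always yields a
#' positive magnitude irrespective of its direction.
#'
#' @param summaries A single-bird [daily_summaries()] table with `phase`.
#' @param b,l Day indices of the last baseline and last stimulus day; default
#'   to the phase boundaries found in `summaries`.
#' @return A list with elements `delta` (-1 or +1) and `magnitude`.
#' @export
direction_and_magnitude <- function(summaries, b = NULL, l = NULL) {
  stopifnot("phase" %in% names(summaries))
  summaries <- summaries[order(summaries$day), , drop = FALSE]
  if (is.null(b)) b <- max(summaries$day[summaries$phase == "baseline"])
  if (is.null(l)) l <- max(summaries$day[summaries$phase == "stimulus"])
  if (!(b < l)) stop("last baseline day must precede last stimulus day")
  si <- summaries[summaries$day == b, ]
  sj <- summaries[summaries$day == l, ]
  if (nrow(si) != 1L || nrow(sj) != 1L) stop("days ", b, " and ", l, " must be summarized")
  d_bl <- dprime(si, sj)
  delta <- sign(d_bl)
  if (delta == 0) {
    warning("zero net pitch change between days ", b, " and ", l,
            "; direction set to +1")
    delta <- 1
  }
  list(delta = delta,
       magnitude = delta * average_daily_change(summaries, "stimulus"))
}

#' Start / end criteria of the reinforcement paradigm
#'
#' During baseline, reinforcement may start once singing is stable:
#' \eqn{|d'_{i-4,i}| < 0.5} over the last five baseline days (strict
#' inequality). During the stimulus phase the paradigm ends either when the
#' cumulative shift relative to the last baseline day exceeds 2.5 d-prime
#' (`"end_shift"`) or when the pitch stabilizes, \eqn{|d'_{i-4,i}| < 0.5}
#' (`"end_stable"`); otherwise it continues.
#'
#' @param summaries Single-bird [daily_summaries()] table ordered by day; the
#'   last row is "today" (day \eqn{i}).
#' @param phase `"baseline"` or `"stimulus"`: which rule set applies.
#' @param baseline_day For the stimulus phase, the last baseline day used as
#'   reference for the cumulative shift (defaults to the last `phase ==
#'   "baseline"` day in `summaries`).
#' @return One of `"continue"`, `"start_ok"`, `"end_shift"`, `"end_stable"`.
#' @export
paradigm_criteria <- function(summaries, phase = c("baseline", "stimulus"),
                              baseline_day = NULL) {
  phase <- match.arg(phase)
  summaries <- summaries[order(summaries$day), , drop = FALSE]
  n <- nrow(summaries)
  if (n < 5L) stop("criteria need at least 5 consecutive summarized days")
  i <- summaries[n, ]
  i4 <- summaries[n - 4L, ]
  if (i$day - i4$day != 4L) stop("criteria need 5 consecutive days")
  stab <- abs(dprime(i4, i)) < 0.5

  if (phase == "baseline") {
    return(if (stab) "start_ok" else "continue")
  }
  if (is.null(baseline_day)) {
    if (!"phase" %in% names(summaries)) stop("need a phase column or baseline_day")
    baseline_day <- max(summaries$day[summaries$phase == "baseline"])
  }
  b <- summaries[summaries$day == baseline_day, ]
  if (nrow(b) != 1L) stop("baseline day ", baseline_day, " not summarized")
  if (abs(dprime(b, i)) > 2.5) return("end_shift")
  if (stab) return("end_stable")
  "continue"
}

#' Within-syllable pitch-trace d-prime curve
#'
#' Compares two days' distributions of within-syllable pitch traces (sampled
#' on a common 1-ms grid aligned to the stimulus window onset) time point by
#' time point, returning a d-prime curve over syllable time. Used to localize
#' where in the syllable the adaptive pitch change occurred.
#'
#' @param traces_day_a,traces_day_b Numeric matrices, one row per rendition,
#'   one column per time sample; both days must share the sampling grid.
#' @param flip If `TRUE`, the curve is sign-flipped (used before averaging
#'   birds that decreased pitch, so that adaptive changes are positive).
#' @return Numeric vector of d-prime values, one per time sample.
#' @export
pitch_trace_dprime <- function(traces_day_a, traces_day_b, flip = FALSE) {
  stopifnot(is.matrix(traces_day_a), is.matrix(traces_day_b))
  if (ncol(traces_day_a) != ncol(traces_day_b)) {
    stop("trace grids misaligned: ", ncol(traces_day_a), " vs ",
         ncol(traces_day_b), " time samples")
  }
  ma <- colMeans(traces_day_a)
  mb <- colMeans(traces_day_b)
  va <- apply(traces_day_a, 2L, stats::var)
  vb <- apply(traces_day_b, 2L, stats::var)
  pooled <- 0.5 * (va + vb)
  if (any(pooled <= 0)) stop("zero pooled variance at some time sample")
  curve <- (mb - ma) / sqrt(pooled)
  if (flip) -curve else curve
}

#' Binomial probability of a shared drift direction
#'
#' Probability, under a fair-coin null (each bird drifts up or down with
#' probability 1/2 independently), of observing at least `k` of `n` birds
#' drifting in the same direction. The tail convention is explicit because
#' the bound depends on it: `"one_sided"` is \eqn{P(X \ge k)} for a
#' pre-specified direction; `"two_sided"` additionally counts the mirror tail
#' \eqn{P(X \le n-k)} (the usual choice when the common direction is not
#' fixed in advance); `"point"` is the exact probability \eqn{P(X = k)}.
#'
#' @param k Number of birds drifting in the majority direction.
#' @param n Number of birds.
#' @param tail Tail convention, see above.
#' @return The exact binomial probability.
#' @examples
#' binomial_direction_prob(10, 10, "one_sided") # 1/1024
#' binomial_direction_prob(9, 10, "two_sided")  # ~0.0215
#' @export
binomial_direction_prob <- function(k, n, tail = c("two_sided", "one_sided", "point")) {
  tail <- match.arg(tail)
  stopifnot(k >= 0, k <= n, n >= 1)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE) # P(X >= k)
  switch(tail,
    one_sided = upper,
    two_sided = min(1, upper + stats::pbinom(n - k, n, 0.5)),
    point = stats::dbinom(k, n, 0.5)
  )
}
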