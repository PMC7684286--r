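#' Long table of daily pitch changes with model indicators
#'
#' Builds the observation table for [fit_pitch_lmm()] from per-day summaries:
#' one row per bird and consecutive-day pair \eqn{(i-1, i)} with the d-prime
#' change and the three design indicators of the daily-change model —
#' `bsl` (1 when day \eqn{i} lies in baseline), `ctrl` (1 in control birds
#' when both days are post-baseline) and `stim` (+1/-1 in treated birds when
#' both days carry the stimulus, signed by the target side: +1 high, -1 low).
#' Changes straddling the phase boundary carry all-zero indicators.
#'
#' @param summaries A [daily_summaries()] table with `group`, `target_side`
#'   and `phase` columns (several birds).
#' @return A data.frame with `bird_id`, `group`, `day`, `dprime`, `bsl`,
#'   `ctrl`, `stim`.
#' @export
pitch_change_table <- function(summaries) {
  need <- c("bird_id", "group", "target_side", "phase", "day", "dprime_prev")
  stopifnot(all(need %in% names(summaries)))
  s <- summaries[!is.na(summaries$dprime_prev), , drop = FALSE]
  s <- s[order(s$bird_id, s$day), , drop = FALSE]

  prev_phase <- rep(NA_character_, nrow(s))
  for (r in seq_len(nrow(s))) {
    m <- summaries$bird_id == s$bird_id[r] & summaries$day == s$day[r] - 1L
    prev_phase[r] <- summaries$phase[m][1L]
  }
  treated <- s$group %in% c("subs", "LO")
  control <- s$group %in% c("unsubs", "noLO")
  side_sign <- ifelse(s$target_side == "high", 1,
                      ifelse(s$target_side == "low", -1, 0))
  data.frame(
    bird_id = s$bird_id, group = s$group, day = s$day,
    dprime = s$dprime_prev,
    bsl = as.numeric(s$phase == "baseline"),
    ctrl = as.numeric(control & s$phase == "stimulus" &
                        prev_phase == "stimulus"),
    stim = side_sign * as.numeric(treated & s$phase == "stimulus" &
                                    prev_phase == "stimulus"),
    stringsAsFactors = FALSE
  )
}

# Shared fixed-effect report: residual df convention, Wald t intervals.
lmm_coef_table <- function(est, se, df) {
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df)
  half <- stats::qt(0.975, df) * se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(t), df = df, p = unname(p),
             ci_lo = unname(est - half), ci_hi = unname(est + half),
             stringsAsFactors = FALSE)
}

fit_indicator_lmm <- function(data, formula, terms) {
  y <- stats::model.response(stats::model.frame(
    stats::as.formula(paste(deparse(formula[[2]]), "~ 1")), data))
  fixed_only <- stats::as.formula(
    paste(deparse(formula[[2]]), "~",
          paste(c("0"[attr(terms, "no_intercept")], terms), collapse = " + ")))
  fit <- if (stats::var(y) == 0) {
    simpleError("degenerate constant response")
  } else {
    tryCatch(
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) e
    )
  }
  if (inherits(fit, "error")) {
    # degenerate response (e.g. all-zero changes): ML estimates reduce to OLS
    ols <- stats::lm(fixed_only, data = data)
    est <- stats::coef(ols)
    se <- sqrt(diag(suppressWarnings(stats::vcov(ols))))
    se[!is.finite(se)] <- 0
    df <- nrow(data) - length(est)
    return(list(coef = lmm_coef_table(est, se, df), fit = ols,
                random_sd = 0, n_obs = nrow(data)))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(data) - length(est)
  list(coef = lmm_coef_table(est, se, df), fit = fit,
       random_sd = sqrt(unlist(lme4::VarCorr(fit))[[1L]]),
       n_obs = nrow(data))
}

#' Mixed model of daily pitch change
#'
#' Fits the daily-change model
#' \deqn{d'^j_{i-1,i} = b\,\vartheta_i + a\,\theta_i + d\,\varphi_i + r_j}
#' by maximum likelihood with a Gaussian random intercept \eqn{r_j} per bird
#' and no global intercept: `b` is the daily change during baseline, `a` the
#' post-baseline drift in control birds and `d` the stimulus-driven change in
#' the direction of increasing stimulus rate. Inference uses the residual
#' degrees-of-freedom convention (observations minus fixed effects).
#'
#' @param changes A [pitch_change_table()] (or any data.frame with columns
#'   `bird_id`, `dprime`, `bsl`, `ctrl`, `stim`).
#' @param reduced If `TRUE`, collapse `bsl` and `ctrl` into a single
#'   spontaneous-drift term (robustness variant).
#' @return An object of class `pitch_lmm_fit`: list with `coef` (term table:
#'   estimate, se, t, df, p, Wald 95% CI), `random_sd`, `n_obs` and the
#'   underlying `lme4` fit.
#' @examples
#' design <- study_design(n_subs = 4, n_unsubs = 4, n_lo = 0, n_nolo = 0,
#'                        n_subs_rand = 0)
#' tab <- simulate_cohort(design, seed = 7)
#' fit <- fit_pitch_lmm(pitch_change_table(daily_summaries(tab)))
#' fit$coef
#' @export
fit_pitch_lmm <- function(changes, reduced = FALSE) {
  stopifnot(all(c("bird_id", "dprime", "bsl", "ctrl", "stim") %in% names(changes)))
  if (all(changes$stim == 0)) {
    stop("singular design: no treated (stim != 0) observations")
  }
  if (reduced) {
    changes$drift <- pmax(changes$bsl, changes$ctrl)
    terms <- c("drift", "stim")
    formula <- dprime ~ 0 + drift + stim + (1 | bird_id)
  } else {
    terms <- c("bsl", "ctrl", "stim")
    formula <- dprime ~ 0 + bsl + ctrl + stim + (1 | bird_id)
  }
  attr(terms, "no_intercept") <- TRUE
  out <- fit_indicator_lmm(changes, formula, terms)
  structure(c(out, list(reduced = reduced)), class = "pitch_lmm_fit")
}

#' @export
print.pitch_lmm_fit <- function(x, ...) {
  cat("Daily pitch change mixed model (ML,", x$n_obs, "observations)\n")
  print(x$coef, digits = 3)
  cat("Random intercept sd:", format(x$random_sd, digits = 3), "\n")
  invisible(x)
}

#' Relative singing rates for the singing-rate model
#'
#' Per bird, the relative singing rate on each of the last `last_n` stimulus-
#' phase days: daily rendition count divided by the mean count over the last
#' `last_n` baseline days. Adds the deafness/stimulus indicator columns used
#' by [fit_singing_lmm()].
#'
#' @param table A rendition table with `phase` (several birds).
#' @param last_n Number of days at each end (default 3).
#' @return Data.frame with `bird_id`, `day`, `rate`, `deaf`, `lo`, `deaf_lo`.
#' @export
singing_rate_table <- function(table, last_n = 3L) {
  stopifnot(all(c("bird_id", "group", "phase", "day") %in% names(table)))
  rows <- lapply(split(table, table$bird_id), function(tb) {
    counts <- stats::aggregate(list(n = tb$day), by = list(day = tb$day), FUN = length)
    phase <- tb$phase[match(counts$day, tb$day)]
    bdays <- utils::tail(sort(counts$day[phase == "baseline"]), last_n)
    sdays <- utils::tail(sort(counts$day[phase == "stimulus"]), last_n)
    if (length(bdays) < 1L || length(sdays) < 1L) return(NULL)
    base_mean <- mean(counts$n[counts$day %in% bdays])
    g <- tb$group[1L]
    data.frame(
      bird_id = tb$bird_id[1L], group = g, day = sdays,
      rate = counts$n[match(sdays, counts$day)] / base_mean,
      deaf = as.numeric(g %in% c("subs", "unsubs", "subs_rand")),
      lo = as.numeric(g %in% c("subs", "LO", "subs_rand")),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$deaf_lo <- out$deaf * out$lo
  rownames(out) <- NULL
  out
}

#' Mixed model of relative singing rate
#'
#' Fits \deqn{n^j_i = c + a\,\alpha_j + b\,\beta_j + d\,\gamma_j + r_j}
#' where \eqn{\alpha_j} indicates deafness, \eqn{\beta_j} stimulus exposure
#' and \eqn{\gamma_j = \alpha_j \beta_j} their interaction, with a Gaussian
#' random intercept per bird (ML fit). A significant interaction `d` means
#' the stimulus affects deaf and hearing birds differently.
#'
#' @param rates A [singing_rate_table()] (columns `bird_id`, `rate`, `deaf`,
#'   `lo`, `deaf_lo`).
#' @return Object of class `singing_lmm_fit`, structured as
#'   [fit_pitch_lmm()]'s result.
#' @export
fit_singing_lmm <- function(rates) {
  stopifnot(all(c("bird_id", "rate", "deaf", "lo", "deaf_lo") %in% names(rates)))
  if (length(unique(rates$deaf)) < 2L || length(unique(rates$lo)) < 2L) {
    stop("missing factor level: need both deaf/hearing and exposed/control birds")
  }
  terms <- c("(Intercept)", "deaf", "lo", "deaf_lo")
  attr(terms, "no_intercept") <- FALSE
  out <- fit_indicator_lmm(
    rates, rate ~ deaf + lo + deaf_lo + (1 | bird_id),
    structure(c("deaf", "lo", "deaf_lo"), no_intercept = FALSE)
  )
  structure(out, class = "singing_lmm_fit")
}

#' @export
print.singing_lmm_fit <- function(x, ...) {
  cat("Relative singing rate mixed model (ML,", x$n_obs, "observations)\n")
  print(x$coef, digits = 3)
  cat("Random intercept sd:", format(x$random_sd, digits = 3), "\n")
  invisible(x)
}

#' Per-bird test of a pitch response against matched controls
#'
#' Compares one treated bird's daily pitch changes during the stimulus period
#' with daily changes of control birds in time-matched windows, using a
#' pooled-variance two-sample two-tailed t-test at alpha = 0.05 without
#' multiple-comparison correction.
#'
#' @param treated_changes Numeric vector of the treated bird's daily d-prime
#'   changes during the stimulus period.
#' @param control_changes Numeric vector of control daily changes from
#'   time-matched windows.
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
per_bird_test <- function(treated_changes, control_changes, alpha = 0.05) {
  stopifnot(length(treated_changes) >= 2L, length(control_changes) >= 2L)
  ht <- stats::t.test(treated_changes, control_changes, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

#' Random-pairing robustness of a matched-control comparison
#'
#' Repeats a treated-vs-control comparison over many random control
#' assignments to verify that a significance call does not hinge on one
#' arbitrary pairing. Each replicate builds a pairing under a feasibility
#' constraint (only time-matchable pairs are permitted), scarcity first: the
#' control bird with the fewest permissible partners is matched first, each
#' time uniformly among its remaining feasible partners. When controls
#' outnumber treated birds, every treated bird first receives a distinct
#' control and leftover controls are then assigned to random treated birds
#' (so all controls contribute). The supplied test is evaluated once per
#' replicate.
#'
#' @param treated_ids,control_ids Character vectors of bird ids.
#' @param feasible Logical matrix `length(treated_ids)` x
#'   `length(control_ids)` (dimnames optional) marking permissible pairs;
#'   default all `TRUE`.
#' @param n_replicates Number of random pairings (default 1000).
#' @param seed Master seed; replicate `r` uses the derived seed `seed + r`.
#' @param test_fn Function taking a data.frame with columns `treated` and
#'   `control` (one row per pair) and returning `TRUE` if the comparison is
#'   significant.
#' @return List with `fraction_significant`, `n_replicates`, and `pairings`
#'   (the first replicate's pairing, for reporting).
#' @export
random_pairings <- function(treated_ids, control_ids, test_fn,
                            feasible = NULL, n_replicates = 1000L,
                            seed = 1L) {
  nt <- length(treated_ids); nc <- length(control_ids)
  stopifnot(nt >= 1L, nc >= 1L, is.function(test_fn))
  if (is.null(feasible)) feasible <- matrix(TRUE, nt, nc)
  stopifnot(dim(feasible) == c(nt, nc))
  if (any(colSums(feasible) == 0L) || any(rowSums(feasible) == 0L)) {
    stop("infeasible constraint matrix: some bird has no permissible partner")
  }

  draw_pairing <- function() {
    if (nc <= nt) {
      # match scarce controls first, each to a random remaining treated bird
      taken <- rep(FALSE, nt)
      pairs <- data.frame(treated = character(0), control = character(0))
      for (ci in order(colSums(feasible))) {
        cand <- which(feasible[, ci] & !taken)
        if (length(cand) == 0L) return(NULL) # dead end; resample
        ti <- if (length(cand) == 1L) cand else sample(cand, 1L)
        taken[ti] <- TRUE
        pairs <- rbind(pairs, data.frame(treated = treated_ids[ti],
                                         control = control_ids[ci]))
      }
      pairs
    } else {
      # controls outnumber treated: distinct control per treated bird first
      taken <- rep(FALSE, nc)
      pairs <- data.frame(treated = character(0), control = character(0))
      for (ti in order(rowSums(feasible))) {
        cand <- which(feasible[ti, ] & !taken)
        if (length(cand) == 0L) return(NULL)
        ci <- if (length(cand) == 1L) cand else sample(cand, 1L)
        taken[ci] <- TRUE
        pairs <- rbind(pairs, data.frame(treated = treated_ids[ti],
                                         control = control_ids[ci]))
      }
      for (ci in which(!taken)) {
        cand <- which(feasible[, ci])
        ti <- if (length(cand) == 1L) cand else sample(cand, 1L)
        pairs <- rbind(pairs, data.frame(treated = treated_ids[ti],
                                         control = control_ids[ci]))
      }
      pairs
    }
  }

  sig <- logical(n_replicates)
  first <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + r)
    pairs <- NULL
    tries <- 0L
    while (is.null(pairs)) {
      pairs <- draw_pairing()
      tries <- tries + 1L
      if (tries > 100L) stop("could not find a feasible pairing in 100 attempts")
    }
    if (r == 1L) first <- pairs
    sig[r] <- isTRUE(test_fn(pairs))
  }
  list(fraction_significant = mean(sig), n_replicates = n_replicates,
       pairings = first)
}
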