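#' Discrete syllable-production world
#'
#' A generative environment for one song syllable composed of `n_notes`
#' consecutive notes, each offering `n_variants` action variants. Every
#' action has a home sensory state (actions map to contiguous state blocks,
#' note by note) and stochastically emits one of three adjacent sensory
#' states centred on its home state; a designated subset of states triggers
#' the light-off stimulus. Edge actions concentrate the out-of-range
#' neighbour's mass on the next state inward, so every emission row has
#' exactly three nonzero entries. A distinguished "silence" observation with
#' the light on stands for the sensory state without acting, which pins the
#' no-action light-off probability to zero.
#'
#' @param n_notes Number of notes per syllable (default 3).
#' @param n_variants Action variants per note (default 6).
#' @param lo_states Integer set of light-off-triggering sensory states
#'   (default 13:16, overlapping the territory of notes 2 and 3).
#' @param kernel Length-3 emission kernel over (state below home, home
#'   state, state above home); must sum to 1 and be strictly positive.
#' @param lo_mode `"state"`: light-off whenever the emitted state is in
#'   `lo_states`. `"random"`: light-off on a fair coin per syllable,
#'   independent of actions (the random-delivery protocol). `"none"`: the
#'   light never goes off (control world).
#' @return Object of class `syllable_world` with the emission matrix
#'   (`n_actions` x `n_states`), note/variant bookkeeping and observation
#'   alphabets for both modalities.
#' @examples
#' w <- syllable_world()
#' dim(w$emission) # 18 actions x 18 states
#' @export
syllable_world <- function(n_notes = 3L, n_variants = 6L,
                           lo_states = 13:16,
                           kernel = c(0.25, 0.5, 0.25),
                           lo_mode = c("state", "random", "none")) {
  lo_mode <- match.arg(lo_mode)
  n_notes <- as.integer(n_notes); n_variants <- as.integer(n_variants)
  stopifnot(n_notes >= 1L, n_variants >= 1L, length(kernel) == 3L)
  if (abs(sum(kernel) - 1) > 1e-9) stop("emission kernel must sum to 1 (tol 1e-9)")
  if (any(kernel <= 0)) stop("emission kernel entries must be positive")
  n_states <- n_notes * n_variants
  n_actions <- n_states
  if (lo_mode == "state") {
    lo_states <- as.integer(lo_states)
    if (length(lo_states) == 0L) stop("lo_states must be nonempty (use lo_mode = 'none')")
    if (any(lo_states < 1L | lo_states > n_states)) stop("lo_states out of range")
    if (length(unique(lo_states)) >= n_states) stop("lo_states must be a strict subset")
  } else {
    lo_states <- integer(0)
  }

  emission <- matrix(0, n_actions, n_states)
  for (a in seq_len(n_actions)) {
    home <- a
    support <- (home - 1L):(home + 1L)
    w <- kernel
    # fold out-of-range mass onto the next state inward
    if (support[1L] < 1L) { support <- home:(home + 2L); w <- c(kernel[2L], kernel[1L], kernel[3L]) }
    if (support[3L] > n_states) { support <- (home - 2L):home; w <- c(kernel[1L], kernel[3L], kernel[2L]) }
    emission[a, support] <- w
  }
  stopifnot(all(abs(rowSums(emission) - 1) < 1e-9))

  structure(list(
    n_notes = n_notes, n_variants = n_variants, n_states = n_states,
    n_actions = n_actions, emission = emission, lo_states = lo_states,
    lo_mode = lo_mode,
    # per-action probability that the emitted state triggers light-off
    p_lo = if (lo_mode == "state") {
      rowSums(emission[, lo_states, drop = FALSE])
    } else if (lo_mode == "random") {
      rep(0.5, n_actions)
    } else {
      rep(0, n_actions)
    },
    # observation alphabets: deaf birds see only the light; hearing birds
    # see the full sensory state, plus the no-action "silence" symbol
    deaf_alphabet = c("on", "off"),
    hearing_alphabet = c(paste0("s", seq_len(n_states)), "silence")
  ), class = "syllable_world")
}

#' @export
print.syllable_world <- function(x, ...) {
  cat("Syllable world:", x$n_notes, "notes x", x$n_variants, "variants,",
      x$n_states, "sensory states; light-off mode:", x$lo_mode)
  if (x$lo_mode == "state") {
    cat(" (states", paste(range(x$lo_states), collapse = "-"), ")")
  }
  cat("\n")
  invisible(x)
}

#' Action bookkeeping
#'
#' Actions are indexed 1..`n_actions` in note-major order: action
#' `(note - 1) * n_variants + variant`.
#'
#' @param world A [syllable_world()].
#' @param note Note position (1-based).
#' @param variant Variant within the note (1-based).
#' @return `action_index()` the flat action id; `action_note()` /
#'   `action_variant()` the inverse mapping.
#' @export
action_index <- function(world, note, variant) {
  stopifnot(note >= 1L, note <= world$n_notes,
            variant >= 1L, variant <= world$n_variants)
  (note - 1L) * world$n_variants + variant
}

#' @rdname action_index
#' @param action Flat action id.
#' @export
action_note <- function(world, action) (action - 1L) %/% world$n_variants + 1L

#' @rdname action_index
#' @export
action_variant <- function(world, action) (action - 1L) %% world$n_variants + 1L

#' Emit one sensory step
#'
#' Samples the sensory state produced by an action, determines the light-off
#' flag and returns the modality-dependent observation symbol: hearing birds
#' observe the full sensory state, deaf birds only the binary light channel.
#' In `"random"` light-off mode the flag is supplied per syllable by the
#' caller (`forced_lo`), independent of the action.
#'
#' @param world A [syllable_world()].
#' @param action Flat action id (must belong to the current note).
#' @param note Current note position.
#' @param modality `"deaf"` or `"hearing"`.
#' @param forced_lo For `lo_mode = "random"` worlds: the syllable's coin-flip
#'   light-off outcome.
#' @return List with `state`, `lo` (logical) and `observation` (index into
#'   the modality's alphabet).
#' @export
emit_step <- function(world, action, note, modality = c("deaf", "hearing"),
                      forced_lo = NA) {
  modality <- match.arg(modality)
  if (action_note(world, action) != note) {
    stop("action ", action, " does not belong to note ", note)
  }
  row <- world$emission[action, ]
  state <- sample.int(world$n_states, 1L, prob = row)
  lo <- switch(world$lo_mode,
    state = state %in% world$lo_states,
    random = isTRUE(forced_lo),
    none = FALSE
  )
  observation <- if (modality == "deaf") {
    if (lo) 2L else 1L # off / on
  } else {
    state # silence (symbol n_states + 1) never follows an action
  }
  list(state = state, lo = lo, observation = observation)
}
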