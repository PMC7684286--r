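#' Adaptive light-off threshold controller
#'
#' The operant paradigm resets the pitch threshold every morning to the median
#' pitch of all (uncurated) renditions produced on the previous day, so that
#' the neutral expectation of the stimulus contingency is 50% each day. A
#' controller carries the delivery side and the current threshold;
#' [update_threshold()] performs the morning reset and [stimulus_flags()]
#' evaluates which renditions trigger the stimulus.
#'
#' @param side One of `"high"` (stimulus when pitch exceeds the threshold),
#'   `"low"` (stimulus when pitch falls below it) or `"random"` (stimulus on a
#'   fair coin flip per rendition, independent of pitch).
#' @param threshold Initial threshold in Hz (`NA` until first update).
#' @param carry_forward If `TRUE` (default), a day without data (e.g. a
#'   recording crash) leaves the previous threshold in place instead of
#'   failing.
#'
#' @return An object of class `threshold_controller`.
#' @examples
#' ctrl <- threshold_controller("high")
#' ctrl <- update_threshold(ctrl, c(740, 750, 760))
#' current_threshold(ctrl) # 750
#' stimulus_flags(ctrl, c(745, 755))
#' @seealso [simulate_bird()] which closes the loop between generator and
#'   controller.
#' @export
threshold_controller <- function(side = c("high", "low", "random"),
                                 threshold = NA_real_,
                                 carry_forward = TRUE) {
  side <- match.arg(side)
  stopifnot(is.logical(carry_forward), length(carry_forward) == 1L)
  structure(
    list(side = side, threshold = as.numeric(threshold),
         carry_forward = carry_forward),
    class = "threshold_controller"
  )
}

#' @export
print.threshold_controller <- function(x, ...) {
  cat("Threshold controller: side =", x$side,
      "| threshold =", format(x$threshold),
      "Hz | carry_forward =", x$carry_forward, "\n")
  invisible(x)
}

#' Morning threshold update
#'
#' Sets the controller threshold to the median of the previous day's pitches.
#' The median of an even number of renditions is the mean of the two central
#' order statistics. With no data, the previous threshold is carried forward
#' when `carry_forward` is set (mirroring crash days in the paradigm) and an
#' error is raised otherwise.
#'
#' @param controller A [threshold_controller()].
#' @param pitches_yesterday Numeric vector of yesterday's (uncurated) pitch
#'   values in Hz; may be empty.
#' @return The updated controller.
#' @export
update_threshold <- function(controller, pitches_yesterday) {
  stopifnot(inherits(controller, "threshold_controller"))
  pitches_yesterday <- pitches_yesterday[!is.na(pitches_yesterday)]
  if (length(pitches_yesterday) == 0L) {
    if (!controller$carry_forward || is.na(controller$threshold)) {
      stop("no pitch data for threshold update and no threshold to carry forward")
    }
    return(controller)
  }
  controller$threshold <- stats::median(pitches_yesterday)
  controller
}

#' @rdname update_threshold
#' @export
current_threshold <- function(controller) {
  stopifnot(inherits(controller, "threshold_controller"))
  controller$threshold
}

#' Evaluate which renditions trigger the stimulus
#'
#' For a `"high"` controller a rendition triggers on `pitch > threshold`, for
#' `"low"` on `pitch < threshold`; equality never triggers. A `"random"`
#' controller ignores pitch and flips a fair coin per rendition (uses the
#' current RNG stream).
#'
#' @param controller A [threshold_controller()].
#' @param pitches Numeric vector of pitch values in Hz.
#' @return Logical vector, one flag per rendition.
#' @export
stimulus_flags <- function(controller, pitches) {
  stopifnot(inherits(controller, "threshold_controller"))
  if (controller$side == "random") {
    return(stats::runif(length(pitches)) < 0.5)
  }
  if (is.na(controller$threshold)) {
    stop("controller threshold not set; call update_threshold() first")
  }
  switch(controller$side,
    high = pitches > controller$threshold,
    low  = pitches < controller$threshold
  )
}
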