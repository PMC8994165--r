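# The 4-2 dB staircase and the Full Threshold procedure built on it.
#
# Steps are 4 dB up to and including the move made at the first response
# reversal, 2 dB afterwards; the procedure terminates at the second
# reversal with the midpoint of the last-seen and last-not-seen levels as
# the estimate. A level pinned at the dynamic-range bound on two
# consecutive presentations terminates early with the bound as estimate.

#' Create a 4-2 staircase state
#'
#' @param start starting level in dB.
#' @param floor_db,ceiling_db dynamic range bounds.
#' @return an object of class `staircase_state`.
#' @export
staircase_create <- function(start, floor_db = 0, ceiling_db = 40) {
  if (start < floor_db || start > ceiling_db)
    stop_perisim("start level outside the dynamic range")
  structure(list(current_level = start, floor_db = floor_db,
                 ceiling_db = ceiling_db, reversals = 0L,
                 last_response = NA, last_seen_level = NA_real_,
                 last_not_seen_level = NA_real_,
                 history = data.frame(level = numeric(0), seen = logical(0)),
                 finished = FALSE, pinned = FALSE, estimate = NA_real_),
            class = "staircase_state")
}

#' Update a 4-2 staircase with a response
#'
#' A seen response moves to a dimmer (higher-dB) level, a not-seen response
#' to a brighter one. The step is 4 dB while no reversal has yet occurred
#' at response time, 2 dB afterwards; the second reversal terminates the
#' staircase with estimate = midpoint of the bracketing last-seen /
#' last-not-seen pair. If the next level is clamped at a range bound while
#' the current level already sits on that bound, the staircase terminates
#' pinned with estimate = bound.
#'
#' @param state a `staircase_state`, not finished.
#' @param seen logical response to the current level.
#' @return the updated state.
#' @examples
#' s <- staircase_create(25)
#' for (r in c(TRUE, TRUE, FALSE, FALSE, TRUE)) s <- staircase_update(s, r)
#' staircase_estimate(s)  # 28
#' @export
staircase_update <- function(state, seen) {
  if (state$finished)
    stop_perisim("staircase already finished", class = "staircase_state_error")
  lev <- state$current_level
  state$history <- rbind(state$history, data.frame(level = lev, seen = seen))
  if (seen) state$last_seen_level <- lev else state$last_not_seen_level <- lev
  reversal <- !is.na(state$last_response) && (seen != state$last_response)
  step <- if (state$reversals == 0L) 4 else 2
  if (reversal) state$reversals <- state$reversals + 1L
  state$last_response <- seen
  if (state$reversals >= 2L) {
    state$finished <- TRUE
    state$estimate <- (state$last_seen_level + state$last_not_seen_level) / 2
    return(state)
  }
  nxt <- clamp(if (seen) lev + step else lev - step,
               state$floor_db, state$ceiling_db)
  if (nxt == lev && (lev == state$floor_db || lev == state$ceiling_db)) {
    state$finished <- TRUE
    state$pinned <- TRUE
    state$estimate <- lev
    return(state)
  }
  state$current_level <- nxt
  state
}

#' Terminal 4-2 staircase estimate
#'
#' @param state a finished (or running) `staircase_state`.
#' @return estimate in dB (`NA` while running).
#' @export
staircase_estimate <- function(state) state$estimate

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("4-2 staircase: level %g dB, %d reversal(s), %d trial(s)%s%s\n",
              x$current_level, x$reversals, nrow(x$history),
              if (x$finished) sprintf(", finished (estimate %g dB)", x$estimate) else "",
              if (x$pinned) " [pinned]" else ""))
  invisible(x)
}

#' Full Threshold procedure
#'
#' Runs one 4-2 staircase from `start`; if the resulting estimate differs
#' from the start by 4 dB or more, a second staircase is run starting at the
#' first estimate and its result is returned. All trials from both
#' staircases are logged.
#'
#' @param start starting level in dB.
#' @param responder a function `f(level)` returning `TRUE` (seen) or
#'   `FALSE`.
#' @param floor_db,ceiling_db dynamic range.
#' @param retest_delta retest criterion in dB (default 4).
#' @return list with `estimate`, `trials` (data frame: level, seen, stage),
#'   `retested`, `pinned`.
#' @export
full_threshold_run <- function(start, responder, floor_db = 0,
                               ceiling_db = 40, retest_delta = 4) {
  run_one <- function(s0) {
    st <- staircase_create(s0, floor_db, ceiling_db)
    while (!st$finished) st <- staircase_update(st, responder(st$current_level))
    st
  }
  st1 <- run_one(start)
  trials <- cbind(st1$history, stage = 1L)
  retested <- abs(st1$estimate - start) >= retest_delta
  if (retested) {
    st2 <- run_one(clamp(st1$estimate, floor_db, ceiling_db))
    trials <- rbind(trials, cbind(st2$history, stage = 2L))
    return(list(estimate = st2$estimate, trials = trials, retested = TRUE,
                pinned = st2$pinned))
  }
  list(estimate = st1$estimate, trials = trials, retested = FALSE,
       pinned = st1$pinned)
}
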