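# The machine contract: initialize / query / set background / present /
# close, backed by a simulated observer. The observer answers each static
# stimulus through a frequency-of-seeing (FoS) psychometric model, so whole
# test procedures can be developed and validated without a physical
# perimeter.

#' Probability that a stimulus is reported seen
#'
#' Cumulative-Gaussian frequency-of-seeing model on the dB scale:
#' \deqn{P(seen) = fp + (1 - fp - fn)\,\Phi\left(\frac{t - l}{\sigma}\right)}
#' where `l` is the stimulus level (dB attenuation: larger = dimmer), `t`
#' the observer's threshold, and `sigma` the FoS spread. `fp` and `fn` set
#' the lower and upper asymptotes: a blind observer still responds at rate
#' `fp`, a perfectly visible stimulus is missed at rate `fn`. The function
#' is non-increasing in `level` and non-decreasing in `threshold`.
#'
#' @param level stimulus level in dB attenuation.
#' @param threshold observer threshold in dB.
#' @param fos_sd FoS spread in dB (> 0).
#' @param fp false-positive rate in `[0, 1)`.
#' @param fn false-negative rate in `[0, 1)`.
#' @return probability of a "seen" response; vectorized over all arguments.
#' @examples
#' prob_seen(level = 25, threshold = 25, fos_sd = 2)  # 0.5
#' @export
prob_seen <- function(level, threshold, fos_sd, fp = 0, fn = 0) {
  if (any(fos_sd <= 0)) stop_perisim("fos_sd must be positive")
  if (any(fp < 0 | fp >= 1) || any(fn < 0 | fn >= 1) || any(fp + fn >= 1))
    stop_perisim("fp and fn must be in [0, 1) with fp + fn < 1")
  fp + (1 - fp - fn) * stats::pnorm((threshold - level) / fos_sd)
}

#' Define a simulated observer
#'
#' The simulation's ground truth: one true threshold per grid location plus
#' the FoS spread, response-error rates and a Gaussian response-time model.
#'
#' @param thresholds numeric vector of true thresholds (dB), one per grid
#'   location; `NA` allowed only at blind-spot locations.
#' @param fos_sd FoS spread in dB.
#' @param fp,fn false-positive / false-negative rates (`fp + fn < 1`).
#' @param rt_mean,rt_sd response-time mean and sd in ms.
#' @return an object of class `sim_observer`.
#' @export
sim_observer <- function(thresholds, fos_sd = 1, fp = 0.03, fn = 0.03,
                         rt_mean = 400, rt_sd = 60) {
  if (fos_sd <= 0) stop_perisim("fos_sd must be positive")
  if (fp < 0 || fn < 0 || fp + fn >= 1)
    stop_perisim("need fp >= 0, fn >= 0 and fp + fn < 1")
  structure(list(thresholds = as.numeric(thresholds), fos_sd = fos_sd,
                 fp = fp, fn = fn, rt_mean = rt_mean, rt_sd = rt_sd),
            class = "sim_observer")
}

#' Describe a stimulus
#'
#' Static luminance stimuli are fully supported by the simulation backend;
#' temporal and kinetic kinds are modeled as types but their presentation
#' logic is not simulated.
#'
#' @param x,y location in degrees of visual angle.
#' @param level dB attenuation level.
#' @param kind `"static"`, `"temporal"` or `"kinetic"`.
#' @param size stimulus diameter in degrees, or a Goldmann size `"I"`-`"V"`.
#' @param duration presentation duration in ms.
#' @param response_window response window in ms (>= duration).
#' @param eye `"left"`, `"right"` or `"both"`.
#' @param color stimulus color name.
#' @return an object of class `vf_stimulus`.
#' @export
stimulus <- function(x = 0, y = 0, level = 20, kind = "static",
                     size = "III", duration = 200, response_window = 1500,
                     eye = "both", color = "white") {
  kind <- match.arg(kind, c("static", "temporal", "kinetic"))
  if (is.character(size)) size <- goldmann_size(size)
  if (duration <= 0) stop_perisim("duration must be positive")
  if (response_window < duration)
    stop_perisim("response_window must be at least the stimulus duration")
  eye <- match.arg(eye, c("left", "right", "both"))
  structure(list(kind = kind, x = x, y = y, level = level, size = size,
                 duration = duration, response_window = response_window,
                 eye = eye, color = color),
            class = "vf_stimulus")
}

#' Goldmann stimulus sizes
#'
#' Diameters in degrees of visual angle for the standard Goldmann sizes
#' I-V (0.1, 0.25, 1, 4 and 16 mm^2 at 30 cm viewing distance).
#'
#' @param name one of `"I"` to `"V"`.
#' @return diameter in degrees.
#' @export
goldmann_size <- function(name) {
  sizes <- c(I = 0.1, II = 0.21, III = 0.43, IV = 0.86, V = 1.72)
  if (!name %in% names(sizes))
    stop_perisim("unknown Goldmann size '", name, "'")
  unname(sizes[name])
}

#' Open a connection to the (simulated) machine
#'
#' Creates a machine handle in the `initialized` state. The handle owns one
#' seeded RNG stream from which every observer response is drawn, so a full
#' session is bit-reproducible and independent of any procedure's internal
#' randomness. State transitions follow
#' `closed -> initialized -> background_set -> closed`; stimuli may only be
#' presented after the background has been set.
#'
#' @param config list with `floor_db`, `ceiling_db` (the dB dynamic range),
#'   `seed`, and optionally `observer` (a [sim_observer()]).
#' @return a machine handle (environment of class `opi_machine`).
#' @examples
#' m <- open_machine(list(floor_db = 0, ceiling_db = 40, seed = 1,
#'                        observer = sim_observer(30)))
#' query_machine(m)$dynamic_range
#' @export
open_machine <- function(config = list()) {
  floor_db <- config$floor_db %||% 0
  ceiling_db <- config$ceiling_db %||% 40
  if (floor_db >= ceiling_db)
    stop_perisim("floor_db (", floor_db, ") must be below ceiling_db (",
                 ceiling_db, ")", class = "machine_config_error")
  m <- new.env(parent = emptyenv())
  m$state <- "initialized"
  m$floor_db <- floor_db
  m$ceiling_db <- ceiling_db
  m$seed <- config$seed %||% 1L
  m$rng <- rng_stream(m$seed)
  m$observer <- config$observer
  m$background <- NULL
  m$n_presentations <- 0L
  m$elapsed_ms <- 0
  class(m) <- "opi_machine"
  m
}

#' Query machine capabilities and state
#'
#' @param machine an open machine handle.
#' @return list with `backend`, `state`, `dynamic_range`, `background`,
#'   `n_presentations`.
#' @export
query_machine <- function(machine) {
  check_machine(machine, c("initialized", "background_set"))
  list(backend = "simulation",
       state = machine$state,
       dynamic_range = c(machine$floor_db, machine$ceiling_db),
       background = machine$background,
       n_presentations = machine$n_presentations)
}

check_machine <- function(machine, allowed) {
  if (!inherits(machine, "opi_machine"))
    stop_perisim("not a machine handle", class = "machine_state_error")
  if (!machine$state %in% allowed)
    stop_perisim("machine is in state '", machine$state,
                 "'; operation requires ", paste(allowed, collapse = " or "),
                 class = "machine_state_error")
  invisible(machine)
}

#' Set the machine background
#'
#' Stores background luminance, color and fixation descriptor (optionally
#' per eye) and moves the machine into the `background_set` state, after
#' which stimuli may be presented.
#'
#' @param machine an initialized machine handle.
#' @param background list, e.g. `list(luminance = 10, color = "white",
#'   fixation = "cross", eye = "both")`.
#' @return the machine handle, invisibly.
#' @export
set_background <- function(machine, background = list(luminance = 10,
                                                      color = "white",
                                                      fixation = "cross",
                                                      eye = "both")) {
  check_machine(machine, c("initialized", "background_set"))
  eye <- background$eye %||% "both"
  if (!eye %in% c("left", "right", "both"))
    stop_perisim("background eye must be left, right or both")
  machine$background <- background
  machine$state <- "background_set"
  invisible(machine)
}

#' Present a stimulus and collect the observer's response
#'
#' The seen/not-seen answer is a Bernoulli draw with probability
#' [prob_seen()] evaluated at the observer's true threshold for the given
#' location; if seen, the response time is drawn from the observer's
#' Gaussian response-time model truncated to `(0, response_window]`. Levels
#' outside the machine's dynamic range are clamped to the range and the
#' response carries a `clamped` flag.
#'
#' @param machine a machine handle with background set and an attached
#'   observer.
#' @param stim a [stimulus()] of kind `"static"`.
#' @param location_index index into the observer's threshold map.
#' @return list with `seen` (logical), `time` (ms, `NA` if not seen),
#'   `level` (the level actually presented) and `clamped`.
#' @export
present_stimulus <- function(machine, stim, location_index = 1L) {
  check_machine(machine, "background_set")
  if (!inherits(stim, "vf_stimulus")) stop_perisim("stim must be a stimulus()")
  if (stim$kind != "static")
    stop_perisim("stimulus kind '", stim$kind,
                 "' is unsupported by the simulation backend",
                 class = "unsupported_stimulus_error")
  obs <- machine$observer
  if (is.null(obs)) stop_perisim("machine has no attached observer")
  if (location_index < 1 || location_index > length(obs$thresholds))
    stop_perisim("location_index out of range")
  thr <- obs$thresholds[location_index]
  if (is.na(thr)) stop_perisim("observer has no threshold at location ",
                               location_index)
  level <- stim$level
  clamped <- FALSE
  if (level < machine$floor_db || level > machine$ceiling_db) {
    level <- clamp(level, machine$floor_db, machine$ceiling_db)
    clamped <- TRUE
  }
  p <- prob_seen(level, thr, obs$fos_sd, obs$fp, obs$fn)
  res <- with_stream(machine$rng, {
    seen <- stats::runif(1) < p
    time <- NA_real_
    if (seen) {
      repeat {
        time <- stats::rnorm(1, obs$rt_mean, obs$rt_sd)
        if (time > 0 && time <= stim$response_window) break
      }
    }
    list(seen = seen, time = time)
  })
  machine$n_presentations <- machine$n_presentations + 1L
  machine$elapsed_ms <- machine$elapsed_ms +
    (if (res$seen) res$time else stim$response_window)
  list(seen = res$seen, time = res$time, level = level, clamped = clamped)
}

#' Close the machine and report the session summary
#'
#' @param machine an open machine handle.
#' @return list with `n_presentations` and `elapsed_seconds` of simulated
#'   test time.
#' @export
close_machine <- function(machine) {
  check_machine(machine, c("initialized", "background_set"))
  machine$state <- "closed"
  list(n_presentations = machine$n_presentations,
       elapsed_seconds = machine$elapsed_ms / 1000)
}
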