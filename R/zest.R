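# ZEST: Bayesian threshold estimation. A probability mass function over
# candidate thresholds on the dB grid is updated after every presentation by
# the psychometric likelihood of the response; the next level and the final
# estimate are the posterior mean (QUEST's posterior mode is available
# behind a flag).

#' Discrete probability mass function over the dB domain
#'
#' @param domain increasing, uniformly spaced dB grid.
#' @param masses non-negative weights; normalized to sum to 1.
#' @return an object of class `pmf`.
#' @export
pmf <- function(domain, masses) {
  domain <- as.numeric(domain); masses <- as.numeric(masses)
  if (length(domain) != length(masses))
    stop_perisim("domain and masses must have equal length")
  if (length(domain) > 1) {
    steps <- diff(domain)
    if (any(steps <= 0) || diff(range(steps)) > 1e-9)
      stop_perisim("domain must be an increasing uniform grid")
  }
  if (any(masses < 0)) stop_perisim("masses must be non-negative")
  s <- sum(masses)
  if (s <= 0) stop_perisim("masses must not all be zero")
  structure(list(domain = domain, masses = masses / s), class = "pmf")
}

pmf_mean <- function(p) sum(p$domain * p$masses)
pmf_sd <- function(p) {
  m <- pmf_mean(p)
  sqrt(sum((p$domain - m)^2 * p$masses))
}
pmf_mode <- function(p) p$domain[which.max(p$masses)]

#' Bimodal ZEST prior
#'
#' Mixture of two discretized Gaussian kernels: an "abnormal" component
#' centered at 0 dB modeling damaged locations, and a "normal" component
#' centered at `peak_normal`, which during a growth-pattern test is set from
#' sensitivity estimates at neighboring locations.
#'
#' @param domain dB grid (uniform, increasing).
#' @param peak_normal center of the normal component (dB), within the domain.
#' @param w_abn mixture weight of the abnormal component, in `(0, 1)`
#'   (0 or 1 collapse the mixture to a single component).
#' @param sd_abn,sd_norm spreads of the two components in dB.
#' @return a normalized [pmf()]; bimodal whenever the peaks are well
#'   separated relative to the spreads.
#' @examples
#' pr <- make_zest_prior(0:40, peak_normal = 30)
#' @export
make_zest_prior <- function(domain, peak_normal, w_abn = 0.3, sd_abn = 5,
                            sd_norm = 5) {
  if (w_abn < 0 || w_abn > 1)
    stop_perisim("w_abn must be in [0, 1]", class = "zest_config_error")
  if (peak_normal < min(domain) || peak_normal > max(domain))
    stop_perisim("peak_normal must lie within the domain")
  masses <- w_abn * stats::dnorm(domain, 0, sd_abn) +
    (1 - w_abn) * stats::dnorm(domain, peak_normal, sd_norm)
  pmf(domain, masses)
}

#' Create a ZEST procedure state
#'
#' @param prior a [pmf()] over the dB domain.
#' @param likelihood_sd spread of the internal psychometric likelihood (dB).
#' @param stop_sd stop when the pmf standard deviation falls below this
#'   (dB); set to 0 to run to `max_presentations` (fixed-count stopping).
#' @param min_presentations,max_presentations bounds on the number of trials.
#' @param fp_l,fn_l guess/lapse rates baked into the likelihood asymptotes.
#' @param rule `"mean"` (ZEST) or `"mode"` (QUEST) for the next level and
#'   final estimate.
#' @return an object of class `zest_state`.
#' @export
zest_create <- function(prior, likelihood_sd = 1.5, stop_sd = 1.5,
                        min_presentations = 4, max_presentations = 25,
                        fp_l = 0.03, fn_l = 0.03, rule = c("mean", "mode")) {
  stopifnot(inherits(prior, "pmf"))
  rule <- match.arg(rule)
  structure(list(pmf = prior, likelihood_sd = likelihood_sd,
                 stop_sd = stop_sd, min_presentations = min_presentations,
                 max_presentations = max_presentations,
                 fp_l = fp_l, fn_l = fn_l, rule = rule,
                 history = data.frame(level = numeric(0), seen = logical(0)),
                 finished = FALSE),
            class = "zest_state")
}

zest_point <- function(state) {
  if (state$rule == "mode") pmf_mode(state$pmf) else pmf_mean(state$pmf)
}

#' Next stimulus level proposed by ZEST
#'
#' The posterior mean (or mode) rounded to the nearest domain grid point.
#'
#' @param state a `zest_state`.
#' @return a dB level, or `NA` if the procedure has finished.
#' @export
zest_next_level <- function(state) {
  if (state$finished) return(NA_real_)
  dom <- state$pmf$domain
  dom[which.min(abs(dom - zest_point(state)))]
}

#' Update a ZEST state with a response
#'
#' Multiplies the pmf by the likelihood of the observed response for every
#' candidate threshold `t`: `prob_seen(level, t, likelihood_sd, fp_l, fn_l)`
#' if seen, its complement otherwise, then renormalizes. Termination: pmf
#' standard deviation below `stop_sd` after at least `min_presentations`
#' trials, or `max_presentations` reached.
#'
#' @param state a `zest_state`, not yet finished.
#' @param level the presented dB level.
#' @param seen logical response.
#' @return the updated `zest_state`.
#' @export
zest_update <- function(state, level, seen) {
  if (state$finished)
    stop_perisim("ZEST procedure already finished", class = "zest_state_error")
  lik <- prob_seen(level, state$pmf$domain, state$likelihood_sd,
                   state$fp_l, state$fn_l)
  if (!seen) lik <- 1 - lik
  masses <- state$pmf$masses * lik
  if (sum(masses) <= 0 || !all(is.finite(masses)))
    stop_perisim("ZEST posterior vanished numerically (level = ", level,
                 ", seen = ", seen, "); check likelihood configuration")
  state$pmf <- pmf(state$pmf$domain, masses)
  state$history <- rbind(state$history,
                         data.frame(level = level, seen = seen))
  n <- nrow(state$history)
  state$finished <- (n >= state$max_presentations) ||
    (n >= state$min_presentations && pmf_sd(state$pmf) < state$stop_sd)
  state
}

#' Current ZEST threshold estimate
#'
#' @param state a `zest_state`.
#' @return posterior mean (or mode, per the state's rule) in dB.
#' @export
zest_estimate <- function(state) zest_point(state)

#' @export
print.zest_state <- function(x, ...) {
  cat(sprintf("ZEST state: %d presentation(s), estimate %.2f dB (pmf sd %.2f)%s\n",
              nrow(x$history), zest_estimate(x), pmf_sd(x$pmf),
              if (x$finished) ", finished" else ""))
  invisible(x)
}
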