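# Method of constant stimuli: fixed levels presented repeatedly in a
# seeded shuffled order, then maximum-likelihood fitting of the
# frequency-of-seeing curve.

#' Run a method-of-constant-stimuli session
#'
#' Presents each level `reps` times in a seeded random permutation and
#' tallies seen counts per level.
#'
#' @param levels dB levels (>= 2 distinct values).
#' @param reps presentations per level (>= 1).
#' @param responder function `f(level)` returning logical seen.
#' @param seed integer seed for the presentation order.
#' @return an object of class `fos_record`: data frame with `level`,
#'   `n_presented`, `n_seen`; the presentation order is kept in the
#'   `"order"` attribute (data frame `level`, `seen`).
#' @export
mocs_run <- function(levels, reps, responder, seed = 1) {
  levels <- as.numeric(levels)
  if (length(unique(levels)) < 2)
    stop_perisim("MOCS needs at least 2 distinct levels")
  if (reps < 1) stop_perisim("reps must be >= 1")
  sched <- rep(levels, each = reps)
  sched <- with_seed(seed, sample(sched))
  seen <- vapply(sched, function(l) isTRUE(responder(l)), logical(1))
  tab <- data.frame(level = sort(unique(levels)))
  tab$n_presented <- vapply(tab$level, function(l) sum(sched == l), integer(1))
  tab$n_seen <- vapply(tab$level, function(l) sum(seen[sched == l]), integer(1))
  attr(tab, "order") <- data.frame(level = sched, seen = seen)
  class(tab) <- c("fos_record", "data.frame")
  tab
}

# 50% crossing by linear interpolation of seen fractions vs level.
fos_interpolate <- function(record) {
  f <- record$n_seen / record$n_presented
  lv <- record$level
  # seen fraction decreases with level (dB attenuation); find the first
  # bracketing pair around 0.5
  for (k in seq_len(length(lv) - 1)) {
    if ((f[k] - 0.5) * (f[k + 1] - 0.5) <= 0 && f[k] != f[k + 1]) {
      return(lv[k] + (0.5 - f[k]) * (lv[k + 1] - lv[k]) / (f[k + 1] - f[k]))
    }
  }
  # no crossing inside the range: fall back to the level nearest 0.5
  lv[which.min(abs(f - 0.5))]
}

#' Fit a frequency-of-seeing curve to a MOCS record
#'
#' Maximizes the Bernoulli likelihood of
#' `prob_seen(level, t, sigma, fp, fn)` over threshold `t` and spread
#' `sigma` (bounded to `[0.1, 20]` dB) with L-BFGS-B. If optimization fails
#' to converge the 50% crossing of the empirical curve is returned by
#' linear interpolation, flagged via `converged = FALSE`.
#'
#' @param record a [mocs_run()] result.
#' @param fp,fn asymptote rates assumed in the fit.
#' @return list with `threshold`, `fos_sd`, `converged`, `loglik`.
#' @export
fit_fos <- function(record, fp = 0, fn = 0) {
  stopifnot(inherits(record, "fos_record"))
  if (all(record$n_seen == record$n_presented) || all(record$n_seen == 0))
    stop_perisim("all responses identical; widen the MOCS level range",
                 class = "fos_fit_error")
  nll <- function(par) {
    p <- prob_seen(record$level, par[1], par[2], fp, fn)
    p <- clamp(p, 1e-12, 1 - 1e-12)
    -sum(record$n_seen * log(p) +
           (record$n_presented - record$n_seen) * log(1 - p))
  }
  t0 <- fos_interpolate(record)
  fit <- tryCatch(
    stats::optim(c(t0, 2), nll, method = "L-BFGS-B",
                 lower = c(min(record$level) - 10, 0.1),
                 upper = c(max(record$level) + 10, 20)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    return(list(threshold = t0, fos_sd = NA_real_, converged = FALSE,
                loglik = NA_real_))
  }
  list(threshold = fit$par[1], fos_sd = fit$par[2], converged = TRUE,
       loglik = -fit$value)
}
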