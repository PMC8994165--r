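# Shared fixtures and independent oracles for the test suite.

# Deterministic responder: sees every stimulus strictly brighter than the
# threshold (smaller dB), misses the rest.
hard_responder <- function(threshold) {
  function(level) level < threshold
}

# Independent 4-2 staircase tracer, written directly from the procedure
# definition (4 dB steps up to and including the move at the first
# reversal, 2 dB after, stop at the second reversal or when pinned at a
# range bound on two consecutive presentations). Takes a fixed response
# vector and returns the presented levels and the terminal estimate.
trace_staircase <- function(start, responses, floor_db = 0, ceiling_db = 40) {
  level <- start
  levels <- c()
  last <- NA
  reversals <- 0
  last_seen <- NA
  last_not <- NA
  estimate <- NA
  pinned <- FALSE
  for (seen in responses) {
    levels <- c(levels, level)
    if (seen) last_seen <- level else last_not <- level
    reversals_before <- reversals
    if (!is.na(last) && seen != last) reversals <- reversals + 1
    step <- if (reversals_before == 0) 4 else 2
    if (reversals >= 2) {
      estimate <- (last_seen + last_not) / 2
      break
    }
    nxt <- min(max(if (seen) level + step else level - step, floor_db),
               ceiling_db)
    if (nxt == level && (level == floor_db || level == ceiling_db)) {
      estimate <- level
      pinned <- TRUE
      break
    }
    last <- seen
    level <- nxt
  }
  list(levels = levels, estimate = estimate, reversals = reversals,
       pinned = pinned)
}

# Brute-force ZEST posterior: normalized product of the prior and the
# per-trial response likelihoods, computed directly from the psychometric
# model without any sequential updating.
brute_posterior <- function(prior_masses, domain, trials, likelihood_sd,
                            fp_l, fn_l) {
  m <- prior_masses
  for (k in seq_len(nrow(trials))) {
    p <- fp_l + (1 - fp_l - fn_l) *
      pnorm((domain - trials$level[k]) / likelihood_sd)
    m <- m * if (trials$seen[k]) p else 1 - p
  }
  m / sum(m)
}

# Small random field batch on a grid, rounded to the 2-decimal CSV
# resolution, with blind spots missing.
random_vf_batch <- function(grid, n = 3, seed = 1) {
  nloc <- nrow(grid$locations)
  withr_seed <- function(expr) { set.seed(seed); expr }
  sens <- withr_seed(matrix(round(runif(n * nloc, -5, 40), 2), n, nloc))
  sens[, grid$locations$is_blind_spot] <- NA_real_
  vf_table(id = sprintf("P%02d", seq_len(n)),
           eye = rep(c("OD", "OS"), length.out = n),
           date = as.Date("2021-03-05") + seq_len(n),
           age = round(seq(40, 70, length.out = n), 2),
           duration = round(seq(200, 300, length.out = n), 1),
           fpr = 0.02, fnr = 0.05, fl = 0.1,
           grid = grid, sensitivities = sens)
}
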