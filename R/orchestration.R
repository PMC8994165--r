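# Whole-field test execution. Seed locations (wave 1) are tested first;
# a location opens for testing once at least one adjacent location of a
# lower wave has finished, and its ZEST prior's normal peak is set from an
# inverse-distance-weighted mean of finished neighbors' estimates (the
# growth pattern). Presentations interleave uniformly at random among open
# locations from a scheduler RNG stream that is separate from the machine's
# response stream.

#' Voronoi neighbor graph of a grid
#'
#' Convenience wrapper: [voronoi_tessellate()] with the default clip
#' boundary followed by [adjacency_from_tessellation()]. A single-location
#' grid yields an empty graph.
#'
#' @param grid a `vf_grid`.
#' @return as [adjacency_from_tessellation()].
#' @export
grid_adjacency <- function(grid) {
  if (nrow(grid$locations) < 2)
    return(list(pairs = matrix(integer(0), ncol = 2),
                neighbors = list(integer(0))))
  adjacency_from_tessellation(voronoi_tessellate(grid))
}

#' Assign growth waves by breadth-first search
#'
#' Wave 1 = the seed locations; every other location's wave is one more
#' than the minimum wave among its neighbors (breadth-first distance from
#' the seed set over the adjacency graph). Deterministic given its inputs.
#'
#' @param grid a `vf_grid`.
#' @param seeds integer indices of seed locations, or a 2-column matrix of
#'   seed coordinates (matched exactly against the grid).
#' @param adjacency result of [adjacency_from_tessellation()]; computed from
#'   the grid's default tessellation when omitted.
#' @return list of class `growth_plan` with `wave` (integer per location),
#'   `seeds`, `adjacency`.
#' @export
assign_growth_waves <- function(grid, seeds, adjacency = NULL) {
  n <- nrow(grid$locations)
  if (is.null(adjacency))
    adjacency <- grid_adjacency(grid)
  if (is.matrix(seeds) || is.data.frame(seeds)) {
    seeds <- as.matrix(seeds)
    key <- paste(grid$locations$x, grid$locations$y)
    idx <- match(paste(seeds[, 1], seeds[, 2]), key)
    if (anyNA(idx))
      stop_perisim("seed coordinates not found in the grid")
    seeds <- idx
  }
  seeds <- sort(unique(as.integer(seeds)))
  if (length(seeds) < 1) stop_perisim("need at least one seed location")
  if (any(seeds < 1 | seeds > n)) stop_perisim("seed index out of range")
  wave <- rep(NA_integer_, n)
  wave[seeds] <- 1L
  frontier <- seeds
  w <- 1L
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      for (j in adjacency$neighbors[[i]]) {
        if (is.na(wave[j])) { wave[j] <- w + 1L; nxt <- c(nxt, j) }
      }
    }
    frontier <- unique(nxt)
    w <- w + 1L
  }
  if (anyNA(wave)) {
    bad <- which(is.na(wave))[1]
    stop_perisim("location ", bad, " (", grid$locations$x[bad], ", ",
                 grid$locations$y[bad], ") is unreachable from the seeds")
  }
  structure(list(wave = wave, seeds = seeds, adjacency = adjacency),
            class = "growth_plan")
}

#' Neighbor-conditioned threshold prediction
#'
#' Inverse-distance-weighted mean of the finished adjacent locations'
#' estimates; used as the normal-component peak of a newly opened
#' location's ZEST prior.
#'
#' @param plan a `growth_plan`.
#' @param grid the grid the plan was built on.
#' @param completed numeric vector of estimates (dB) with `NA` for
#'   unfinished locations.
#' @param target index of the location to predict.
#' @return predicted dB value, or `NA` if no adjacent location is finished.
#' @export
neighbor_prediction <- function(plan, grid, completed, target) {
  nb <- plan$adjacency$neighbors[[target]]
  nb <- nb[!is.na(completed[nb])]
  if (length(nb) == 0) return(NA_real_)
  dx <- grid$locations$x[nb] - grid$locations$x[target]
  dy <- grid$locations$y[nb] - grid$locations$y[target]
  w <- 1 / sqrt(dx^2 + dy^2)
  sum(w * completed[nb]) / sum(w)
}

#' Run a full simulated static visual-field test
#'
#' Executes a ZEST procedure at every non-blind-spot grid location under
#' the growth pattern, presenting stimuli through the machine's simulated
#' observer, and assembles the resulting visual field and trial log.
#'
#' @param grid a `vf_grid`.
#' @param machine an open machine with an attached observer whose threshold
#'   map matches the grid.
#' @param seeds seed locations (indices or coordinate matrix); defaults to
#'   the conventional four primary points `(+/-9, +/-9)` when present in
#'   the grid, else the location nearest fixation.
#' @param procedure list of ZEST settings passed to [zest_create()] /
#'   [make_zest_prior()]: `domain_step`, `likelihood_sd`, `stop_sd`,
#'   `min_presentations`, `max_presentations`, `fp_l`, `fn_l`, `w_abn`,
#'   `sd_abn`, `sd_norm`, `normal_guess` (prior peak used when no neighbor
#'   has finished; default the age-expected normal if supplied, else the
#'   domain midpoint).
#' @param scheduler_seed seed of the scheduler stream that picks which open
#'   location receives the next presentation (separate from the machine's
#'   response stream).
#' @param open_rule `"any"` (default) opens a location when one adjacent
#'   lower-wave location has finished; `"all"` waits for all of them.
#' @param subject list with `id`, `age`, `eye`, `date` for the output
#'   record.
#' @return list with `field` (one-row `vf` table; blind-spot locations
#'   `NA`) and `log` (data frame: presentation, location, level, seen,
#'   time).
#' @examples
#' g <- build_standard_grid("24-2")
#' thr <- rep(30, 54); thr[g$locations$is_blind_spot] <- 0
#' m <- open_machine(list(seed = 7, observer = sim_observer(thr)))
#' set_background(m)
#' res <- run_static_test(g, m, scheduler_seed = 11)
#' @export
run_static_test <- function(grid, machine, seeds = NULL, procedure = list(),
                            scheduler_seed = 1, open_rule = c("any", "all"),
                            subject = list()) {
  open_rule <- match.arg(open_rule)
  check_machine(machine, "background_set")
  loc <- grid$locations
  n <- nrow(loc)
  if (length(machine$observer$thresholds) != n)
    stop_perisim("observer threshold map does not match the grid size")
  if (is.null(seeds)) {
    key <- paste(loc$x, loc$y)
    conv <- match(paste(c(9, 9, -9, -9), c(9, -9, 9, -9)), key)
    seeds <- if (anyNA(conv)) which.min(loc$x^2 + loc$y^2) else conv
  }
  adj <- grid_adjacency(grid)
  plan <- assign_growth_waves(grid, seeds, adj)

  p <- procedure
  step <- p$domain_step %||% 1
  domain <- seq(machine$floor_db, machine$ceiling_db, by = step)
  normal_guess <- p$normal_guess %||% stats::median(domain)
  mk_state <- function(peak) {
    prior <- make_zest_prior(domain, clamp(peak, min(domain), max(domain)),
                            w_abn = p$w_abn %||% 0.3,
                            sd_abn = p$sd_abn %||% 5,
                            sd_norm = p$sd_norm %||% 5)
    zest_create(prior,
                likelihood_sd = p$likelihood_sd %||% 1.5,
                stop_sd = p$stop_sd %||% 1.5,
                min_presentations = p$min_presentations %||% 4,
                max_presentations = p$max_presentations %||% 25,
                fp_l = p$fp_l %||% 0.03, fn_l = p$fn_l %||% 0.03)
  }

  estimates <- rep(NA_real_, n)
  finished <- loc$is_blind_spot        # blind spots never tested
  states <- vector("list", n)
  sched_rng <- rng_stream(scheduler_seed)
  log <- list()
  k <- 0L

  openable <- function(i) {
    if (finished[i] || !is.null(states[[i]])) return(FALSE)
    if (plan$wave[i] == 1L) return(TRUE)
    nb <- adj$neighbors[[i]]
    lower <- nb[plan$wave[nb] < plan$wave[i]]
    if (length(lower) == 0) return(FALSE)
    if (open_rule == "any") any(finished[lower]) else all(finished[lower])
  }
  open_new <- function() {
    for (i in which(!finished & vapply(seq_len(n), function(j)
      is.null(states[[j]]), logical(1)))) {
      if (openable(i)) {
        peak <- neighbor_prediction(plan, grid, estimates, i)
        if (is.na(peak)) peak <- normal_guess
        states[[i]] <<- mk_state(peak)
      }
    }
  }
  open_new()
  repeat {
    active <- which(!finished & !vapply(states, is.null, logical(1)))
    if (length(active) == 0) {
      if (all(finished)) break
      stop_perisim("scheduling stalled: unfinished locations cannot open")
    }
    i <- if (length(active) == 1) active else
      with_stream(sched_rng, sample(active, 1))
    lev <- zest_next_level(states[[i]])
    resp <- present_stimulus(machine,
                             stimulus(x = loc$x[i], y = loc$y[i], level = lev),
                             location_index = i)
    states[[i]] <- zest_update(states[[i]], resp$level, resp$seen)
    k <- k + 1L
    log[[k]] <- data.frame(presentation = k, location = i, wave = plan$wave[i],
                           level = resp$level, seen = resp$seen,
                           time = resp$time)
    if (states[[i]]$finished) {
      finished[i] <- TRUE
      estimates[i] <- zest_estimate(states[[i]])
      open_new()
    }
  }
  log <- do.call(rbind, log) %||%
    data.frame(presentation = integer(0), location = integer(0),
               wave = integer(0), level = numeric(0), seen = logical(0),
               time = numeric(0))
  obs <- machine$observer
  field <- vf_table(id = subject$id %||% "SIM",
                    eye = subject$eye %||% "OD",
                    date = subject$date %||% Sys.Date(),
                    age = subject$age %||% 45,
                    duration = machine$elapsed_ms / 1000,
                    fpr = obs$fp, fnr = obs$fn, fl = 0,
                    grid = grid, sensitivities = matrix(estimates, nrow = 1))
  list(field = field, log = log, plan = plan)
}
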