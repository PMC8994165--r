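# Synthetic-data generators with known ground truth: healthy cohorts
# following an age-dependent hill of vision, longitudinal series with
# controlled progression, and observers built from fields so that
# analyze -> simulate -> re-test loops close. All generators are pure
# functions of (spec, seed).

#' Generate a synthetic healthy cohort
#'
#' Each subject's sensitivity surface is a hill of vision: height `H0` at
#' fixation minus `k` dB per degree of eccentricity, declining with age at
#' `gamma` dB/year around a reference age of 45, plus a between-subject
#' offset (sd `tau`) and independent within-subject test-retest noise
#' (sd `sigma_w`, optionally growing with eccentricity). Values are clamped
#' to the dB range after noise, mimicking a device's reporting floor.
#' Blind-spot locations are left missing.
#'
#' @param grid a `vf_grid`.
#' @param n_subjects number of subjects (one eye each).
#' @param age_range ages drawn uniformly from this range (years).
#' @param H0 hill-of-vision height at fixation (dB), default 33.
#' @param k eccentricity slope (dB/degree), default 0.25.
#' @param gamma age slope (dB/year), default 0.06 (sensitivity declines).
#' @param tau between-subject sd (dB).
#' @param sigma_w within-subject sd (dB).
#' @param sigma_w_ecc optional linear growth of `sigma_w` with
#'   eccentricity (dB per degree), default 0.
#' @param floor_db,ceiling_db clamping range (dB).
#' @param seed integer seed.
#' @return list with `fields` (a `vf` table, one row per subject) and
#'   `truth` (every generating parameter plus per-subject ages/offsets).
#' @examples
#' co <- synth_healthy_cohort(build_standard_grid("24-2"), n_subjects = 25,
#'                            seed = 1)
#' @export
synth_healthy_cohort <- function(grid, n_subjects = 200,
                                 age_range = c(20, 80), H0 = 33, k = 0.25,
                                 gamma = 0.06, tau = 1, sigma_w = 1.5,
                                 sigma_w_ecc = 0, floor_db = 0,
                                 ceiling_db = 40, seed = 1) {
  if (tau < 0 || sigma_w < 0) stop_perisim("sds must be non-negative")
  if (diff(range(age_range)) <= 0) stop_perisim("age range is degenerate")
  loc <- grid$locations
  ecc <- sqrt(loc$x^2 + loc$y^2)
  age_ref <- 45
  nloc <- nrow(loc)
  out <- with_seed(seed, {
    ages <- stats::runif(n_subjects, age_range[1], age_range[2])
    offsets <- stats::rnorm(n_subjects, 0, tau)
    sens <- matrix(NA_real_, n_subjects, nloc)
    sw <- sigma_w + sigma_w_ecc * ecc
    for (s in seq_len(n_subjects)) {
      mu <- H0 - k * ecc - gamma * (ages[s] - age_ref) + offsets[s]
      v <- mu + stats::rnorm(nloc, 0, sw)
      sens[s, ] <- clamp(v, floor_db, ceiling_db)
    }
    sens[, loc$is_blind_spot] <- NA_real_
    list(ages = ages, offsets = offsets, sens = sens)
  })
  fields <- vf_table(id = sprintf("S%04d", seq_len(n_subjects)), eye = "OD",
                     date = as.Date("2020-01-01"), age = round(out$ages, 2),
                     grid = grid, sensitivities = round(out$sens, 2))
  truth <- list(H0 = H0, k = k, gamma = gamma, tau = tau, sigma_w = sigma_w,
                sigma_w_ecc = sigma_w_ecc, age_ref = age_ref,
                ages = out$ages, offsets = out$offsets,
                expected = function(age) {
                  m <- outer(rep(1, length(age)), H0 - k * ecc) -
                    gamma * (age - age_ref)
                  m[, loc$is_blind_spot] <- NA_real_
                  m
                })
  list(fields = fields, truth = truth)
}

#' A single synthetic healthy baseline field
#'
#' Convenience wrapper: one noise-free (by default) hill-of-vision field at
#' a given age, useful as a baseline for series generation or as a
#' simulated observer's truth.
#'
#' @param grid a `vf_grid`.
#' @param age subject age in years.
#' @param sigma_w within-subject noise sd (dB), default 0.
#' @param seed seed (used only when `sigma_w > 0`).
#' @param ... passed to [synth_healthy_cohort()] (`H0`, `k`, `gamma`, ...).
#' @return a one-row `vf` table.
#' @export
synth_baseline_field <- function(grid, age = 55, sigma_w = 0, seed = 1, ...) {
  co <- synth_healthy_cohort(grid, n_subjects = 1, age_range = c(age, age + 1e-6),
                             tau = 0, sigma_w = sigma_w, seed = seed, ...)
  f <- co$fields
  f$age <- age
  f
}

#' Generate a synthetic longitudinal series
#'
#' Visit v's value at location i is
#' `baseline_i + slope_i * t_v + global_v + noise`, with a shared global
#' fluctuation per visit (sd `fluctuation_sd`) and independent measurement
#' noise (sd `measurement_sd`). Locations not listed in `prog_locations`
#' have slope 0 (stable).
#'
#' @param baseline a one-row `vf` table.
#' @param n_visits number of visits (>= 4).
#' @param spacing years between consecutive visits.
#' @param prog_locations integer indices of progressing locations.
#' @param prog_slopes slopes in dB/year, recycled over `prog_locations`.
#' @param fluctuation_sd global per-visit fluctuation sd (dB).
#' @param measurement_sd per-location measurement sd (dB).
#' @param floor_db,ceiling_db clamping range.
#' @param seed integer seed.
#' @return list with `fields` (a `vf` table, one row per visit) and
#'   `truth` (slopes per location, global effects, spec parameters).
#' @export
synth_series <- function(baseline, n_visits = 10, spacing = 0.5,
                         prog_locations = integer(0), prog_slopes = -1,
                         fluctuation_sd = 0, measurement_sd = 1,
                         floor_db = 0, ceiling_db = 40, seed = 1) {
  if (n_visits < 4) stop_perisim("a series needs at least 4 visits")
  if (spacing <= 0) stop_perisim("visit spacing must be positive")
  stopifnot(inherits(baseline, "vf"), nrow(baseline) == 1)
  base <- vf_sens_matrix(baseline)[1, ]
  nloc <- length(base)
  slopes <- rep(0, nloc)
  if (length(prog_locations) > 0)
    slopes[prog_locations] <- rep_len(prog_slopes, length(prog_locations))
  tv <- (seq_len(n_visits) - 1) * spacing
  out <- with_seed(seed, {
    glob <- stats::rnorm(n_visits, 0, fluctuation_sd)
    sens <- matrix(NA_real_, n_visits, nloc)
    for (v in seq_len(n_visits)) {
      val <- base + slopes * tv[v] + glob[v] +
        stats::rnorm(nloc, 0, measurement_sd)
      sens[v, ] <- clamp(val, floor_db, ceiling_db)
    }
    sens[, is.na(base)] <- NA_real_
    list(glob = glob, sens = sens)
  })
  dates <- as.Date(baseline$date[1]) + round(tv * 365.25)
  fields <- vf_table(id = baseline$id[1], eye = baseline$eye[1],
                     date = dates, age = baseline$age[1] + tv,
                     grid = baseline$grid[1],
                     sensitivities = round(out$sens, 2))
  truth <- list(slopes = slopes, global = out$glob, times = tv,
                baseline = base, fluctuation_sd = fluctuation_sd,
                measurement_sd = measurement_sd)
  list(fields = fields, truth = truth)
}

#' Build a simulated observer from a field
#'
#' Closes the loop between analysis and simulation: the observer's true
#' thresholds are the field's sensitivities; blind-spot locations get the
#' dynamic-range floor by convention.
#'
#' @param field a one-row `vf` table with no missing non-blind-spot values.
#' @param grid the field's `vf_grid`.
#' @param fos_sd,fp,fn,rt_mean,rt_sd observer parameters, see
#'   [sim_observer()].
#' @param floor_db threshold assigned to blind-spot locations.
#' @return a `sim_observer`.
#' @export
observer_from_field <- function(field, grid, fos_sd = 1, fp = 0.03,
                                fn = 0.03, rt_mean = 400, rt_sd = 60,
                                floor_db = 0) {
  stopifnot(inherits(field, "vf"), nrow(field) == 1)
  thr <- vf_sens_matrix(field)[1, ]
  bs <- grid$locations$is_blind_spot
  if (any(is.na(thr[!bs])))
    stop_perisim("field has missing values at non-blind-spot locations")
  thr[bs] <- floor_db
  sim_observer(thr, fos_sd = fos_sd, fp = fp, fn = fn,
               rt_mean = rt_mean, rt_sd = rt_sd)
}
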