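# Normative models from healthy cohorts, and per-field deviation analysis:
# total deviation (TD), pattern deviation (PD), probability categories,
# general height (GH) and mean deviation (MD).

norm_prob_levels <- c(0.005, 0.01, 0.02, 0.05)

#' Fit a normative model from a healthy cohort
#'
#' Per location, ordinary least squares of sensitivity on age gives the
#' age-expected normal value (intercept + slope x age) and a residual sd.
#' TD cutoffs are the empirical 0.5/1/2/5% quantiles of the cohort's TD
#' residuals; PD cutoffs are the analogous quantiles after general-height
#' correction of each cohort field. `method = "smooth"` additionally shrinks
#' each location's residual sd and cutoffs toward its Voronoi neighbors
#' (self weight 0.5, neighbors sharing 0.5 equally), the re-specified analog
#' of classical normative-value smoothing for irregular grids. MD weights
#' default to inverse residual variance, normalized over non-blind-spot
#' locations.
#'
#' @param cohort a `vf` table, one test per subject-eye, all on `grid`;
#'   OS rows are mirrored to right-eye format first. Needs >= 20 fields
#'   and an age span of >= 20 years.
#' @param grid the `vf_grid` the cohort was tested on.
#' @param method `"pointwise"` or `"smooth"`.
#' @param gh_percentile general-height percentile of TD (default 0.85).
#' @param md_weights `"invvar"` (default) or `"uniform"`.
#' @return an object of class `normative_model`.
#' @export
fit_normative_model <- function(cohort, grid, method = c("pointwise", "smooth"),
                                gh_percentile = 0.85,
                                md_weights = c("invvar", "uniform")) {
  method <- match.arg(method)
  md_weights <- match.arg(md_weights)
  stopifnot(inherits(cohort, "vf"), inherits(grid, "vf_grid"))
  if (length(unique(cohort$grid)) != 1 || cohort$grid[1] != grid$name)
    stop_perisim("cohort must be on the single grid '", grid$name, "'",
                 class = "norm_fit_error")
  if (anyDuplicated(paste(cohort$id, cohort$eye)))
    stop_perisim("duplicated subject-eye in cohort", class = "norm_fit_error")
  if (nrow(cohort) < 20)
    stop_perisim("need >= 20 cohort fields", class = "norm_fit_error")
  if (diff(range(cohort$age)) < 20)
    stop_perisim("cohort ages must span >= 20 years", class = "norm_fit_error")
  if (any(cohort$eye == "OS"))
    cohort[cohort$eye == "OS", ] <-
      mirror_to_right_eye(cohort[cohort$eye == "OS", ], "OS", grid)
  sens <- vf_sens_matrix(cohort)
  nloc <- nrow(grid$locations)
  if (ncol(sens) != nloc) stop_perisim("cohort columns do not match grid size")
  bs <- grid$locations$is_blind_spot
  age <- cohort$age

  intercept <- slope <- resid_sd <- rep(NA_real_, nloc)
  td_cohort <- matrix(NA_real_, nrow(cohort), nloc)
  for (i in which(!bs)) {
    y <- sens[, i]
    ok <- !is.na(y)
    fit <- stats::lm.fit(cbind(1, age[ok]), y[ok])
    intercept[i] <- fit$coefficients[1]
    slope[i] <- fit$coefficients[2]
    r <- fit$residuals
    resid_sd[i] <- if (length(r) > 2) sqrt(sum(r^2) / (length(r) - 2)) else 0
    td_cohort[ok, i] <- r
  }
  td_cut <- apply(td_cohort, 2, function(v)
    if (all(is.na(v))) rep(NA_real_, 4)
    else stats::quantile(v, norm_prob_levels, na.rm = TRUE, names = FALSE))
  # general-height correction of each cohort field, then PD quantiles
  gh <- apply(td_cohort, 1, function(v)
    stats::quantile(v[!bs], gh_percentile, na.rm = TRUE, names = FALSE))
  pd_cohort <- sweep(td_cohort, 1, gh, "-")
  pd_cut <- apply(pd_cohort, 2, function(v)
    if (all(is.na(v))) rep(NA_real_, 4)
    else stats::quantile(v, norm_prob_levels, na.rm = TRUE, names = FALSE))

  adjacency <- NULL
  if (method == "smooth") {
    adjacency <- adjacency_from_tessellation(voronoi_tessellate(grid))
    smooth_vec <- function(v) {
      out <- v
      for (i in which(!bs)) {
        nb <- setdiff(adjacency$neighbors[[i]], which(bs))
        nb <- nb[!is.na(v[nb])]
        if (length(nb) > 0)
          out[i] <- 0.5 * v[i] + sum(0.5 / length(nb) * v[nb])
      }
      out
    }
    resid_sd <- smooth_vec(resid_sd)
    td_cut <- apply(td_cut, 1, smooth_vec)   # rows of result = locations
    td_cut <- t(td_cut)
    pd_cut <- t(apply(pd_cut, 1, smooth_vec))
  }

  w <- rep(0, nloc)
  if (md_weights == "invvar" && all(resid_sd[!bs] > 1e-9)) {
    w[!bs] <- 1 / resid_sd[!bs]^2
  } else {
    w[!bs] <- 1
  }
  w <- w / sum(w)

  structure(list(grid_name = grid$name, intercept = intercept, slope = slope,
                 resid_sd = resid_sd, td_cutoffs = td_cut,
                 pd_cutoffs = pd_cut, md_weights = w,
                 gh_percentile = gh_percentile, prob_levels = norm_prob_levels,
                 method = method, is_blind_spot = bs, n_cohort = nrow(cohort)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model (%s) on grid '%s': %d locations, n = %d fields\n",
              x$method, x$grid_name, length(x$intercept), x$n_cohort))
  cat(sprintf("  mean age slope %.3f dB/year, mean residual sd %.2f dB\n",
              mean(x$slope, na.rm = TRUE), mean(x$resid_sd, na.rm = TRUE)))
  invisible(x)
}

check_model_field <- function(field, model) {
  if (field$grid[1] != model$grid_name)
    stop_perisim("field grid '", field$grid[1],
                 "' does not match model grid '", model$grid_name, "'")
}

#' Total deviation of a field
#'
#' Departure of each measured sensitivity from the age-expected normal
#' value: `td_i = sensitivity_i - (intercept_i + slope_i * age)`.
#' Blind-spot locations are left `NA`.
#'
#' @param field a one-row `vf` table (or multiple rows: a matrix with one
#'   TD row per test is returned).
#' @param model a `normative_model` on the same grid.
#' @return numeric matrix of TD values (dB), rows = tests.
#' @export
total_deviation <- function(field, model) {
  check_model_field(field, model)
  sens <- vf_sens_matrix(field)
  expected <- outer(field$age, model$slope) +
    matrix(model$intercept, nrow(sens), length(model$intercept), byrow = TRUE)
  td <- sens - expected
  td[, model$is_blind_spot] <- NA_real_
  td
}

#' Probability category of deviation values
#'
#' The category is the smallest level p in {0.5, 1, 2, 5}% whose cutoff the
#' value falls strictly below; values at or above the 5% cutoff are
#' `"normal"`.
#'
#' @param values numeric vector of deviation values (dB) per location.
#' @param cutoffs 4 x n matrix of cutoffs (rows = levels 0.5, 1, 2, 5%).
#' @return character vector in `{"<0.5%", "<1%", "<2%", "<5%", "normal"}`
#'   (`NA` where the value is missing).
#' @export
deviation_probability <- function(values, cutoffs) {
  labels <- c("<0.5%", "<1%", "<2%", "<5%")
  n <- length(values)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- values[i]
    if (is.na(v)) next
    cut <- cutoffs[, i]
    if (any(is.na(cut))) next
    hit <- which(v < cut)
    out[i] <- if (length(hit) > 0) labels[hit[1]] else "normal"
  }
  out
}

#' Pattern deviation and general height
#'
#' General height is a high percentile (default 85th) of the TD values over
#' non-blind-spot locations, estimating diffuse sensitivity change; pattern
#' deviation subtracts it, isolating localized loss.
#'
#' @param td numeric vector of TD values for one field.
#' @param model a `normative_model`.
#' @return list with `pd` (vector, dB) and `general_height` (dB).
#' @export
pattern_deviation <- function(td, model) {
  valid <- !model$is_blind_spot & !is.na(td)
  if (sum(valid) < 5)
    stop_perisim("need at least 5 valid locations for pattern deviation")
  gh <- stats::quantile(td[valid], model$gh_percentile, names = FALSE)
  pd <- td - gh
  pd[model$is_blind_spot] <- NA_real_
  list(pd = pd, general_height = gh)
}

#' Mean deviation of a field
#'
#' Weighted average of TD over non-blind-spot locations using the model's
#' MD weights (weights renormalized over non-missing locations).
#'
#' @param td numeric vector of TD values for one field.
#' @param model a `normative_model`.
#' @return MD in dB.
#' @export
mean_deviation <- function(td, model) {
  ok <- !model$is_blind_spot & !is.na(td)
  w <- model$md_weights[ok]
  sum(w * td[ok]) / sum(w)
}

#' Full deviation analysis of one field
#'
#' Convenience wrapper computing TD, PD, their probability categories, MD
#' and general height for a single test.
#'
#' @param field a one-row `vf` table; OS fields are mirrored to right-eye
#'   format first (mirror-symmetric grids).
#' @param model a `normative_model` on the same grid.
#' @param grid the grid (needed only to mirror OS fields).
#' @return list of class `deviation_map` with `td`, `pd`, `td_category`,
#'   `pd_category`, `md`, `general_height`.
#' @export
analyze_field <- function(field, model, grid = NULL) {
  stopifnot(nrow(field) == 1)
  if (field$eye[1] == "OS") {
    if (is.null(grid)) stop_perisim("mirroring an OS field requires the grid")
    field <- mirror_to_right_eye(field, "OS", grid)
    field$eye <- "OD"
  }
  td <- total_deviation(field, model)[1, ]
  pdres <- pattern_deviation(td, model)
  structure(list(td = td, pd = pdres$pd,
                 td_category = deviation_probability(td, model$td_cutoffs),
                 pd_category = deviation_probability(pdres$pd, model$pd_cutoffs),
                 md = mean_deviation(td, model),
                 general_height = pdres$general_height),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  worst <- sum(x$td_category %in% c("<0.5%", "<1%", "<2%", "<5%"), na.rm = TRUE)
  cat(sprintf("Deviation map: MD %.2f dB, GH %.2f dB, %d location(s) flagged on TD\n",
              x$md, x$general_height, worst))
  invisible(x)
}

#' Serialize a normative model to JSON
#'
#' @param model a `normative_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_normative_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a normative model from JSON
#'
#' @param path path written by [write_normative_json()].
#' @return a `normative_model`.
#' @export
read_normative_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_cut <- function(m) {
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    if (nrow(m) != 4 && ncol(m) == 4) m <- t(m)
    unname(m)
  }
  x$td_cutoffs <- fix_cut(x$td_cutoffs)
  x$pd_cutoffs <- fix_cut(x$pd_cutoffs)
  class(x) <- "normative_model"
  x
}
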