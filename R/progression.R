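# Longitudinal analysis of one eye's series of fields: pointwise linear
# regression (PLR) with one-sided slope tests and robust-variability flags,
# and the PoPLR combined permutation test.
#
# The permutation loop regresses a matrix response against the fixed time
# design, so the pseudo-inverse is computed once and each draw costs one
# row permutation and two small matrix products.

# OLS of every column of y on t. Returns slopes, intercepts, se of the
# slope, one-sided (lower-tail) p-values and raw residual MADs.
plr_matrix <- function(y, t) {
  m <- length(t)
  X <- cbind(1, t)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)            # 2 x m
  beta <- H %*% y                 # 2 x nloc
  resid <- y - X %*% beta
  df <- m - 2
  s2 <- colSums(resid^2) / df
  se <- sqrt(pmax(s2 * XtXinv[2, 2], 0))
  slope <- beta[2, ]
  tstat <- ifelse(se > 1e-12, slope / se,
                  ifelse(abs(slope) < 1e-12, 0, sign(slope) * Inf))
  p <- stats::pt(tstat, df)
  p <- pmax(p, 1e-300)            # keep p in (0, 1]
  mad_raw <- apply(resid, 2, function(r) stats::median(abs(r - stats::median(r))))
  list(slope = unname(slope), intercept = unname(beta[1, ]),
       se = unname(se), t_stat = unname(tstat), p = unname(p),
       residual_mad = unname(mad_raw), df = df)
}

series_values <- function(series, use, model) {
  use <- match.arg(use, c("td", "sensitivity"))
  if (use == "td") {
    if (is.null(model))
      stop_perisim("use = 'td' requires a normative model")
    total_deviation(series, model)
  } else {
    vf_sens_matrix(series)
  }
}

series_times <- function(series) {
  d <- as.Date(series$date)
  if (is.unsorted(d, strictly = TRUE))
    stop_perisim("series dates must be strictly increasing (no ties)")
  as.numeric(d - d[1]) / 365.25
}

#' Pointwise linear regression over a series of fields
#'
#' Per non-blind-spot location, ordinary least squares of the chosen value
#' (total deviation by default, raw sensitivity behind the `use` flag) on
#' time in years since the first visit. The p-value is the lower tail of
#' the t distribution with m - 2 degrees of freedom (alternative: slope is
#' negative, i.e. the location is deteriorating). Series whose residuals
#' have a raw median absolute deviation above `mad_threshold` (default
#' 2 dB) are flagged as highly variable.
#'
#' @param series a `vf` table with >= 4 visits of one eye, dates strictly
#'   increasing, all on one grid.
#' @param model a `normative_model` (required for `use = "td"`).
#' @param use `"td"` or `"sensitivity"`.
#' @param mad_threshold variability flag threshold in dB.
#' @return object of class `plr_fit`: data frame with one row per analyzed
#'   location (`location`, `slope`, `intercept`, `se`, `t_stat`, `p`,
#'   `residual_mad`, `flagged`, `n_visits`) plus attributes `times`,
#'   `values`, `analyzed` (location indices).
#' @export
pointwise_linear_regression <- function(series, model = NULL, use = "td",
                                        mad_threshold = 2) {
  if (nrow(series) < 4)
    stop_perisim("progression analysis needs at least 4 visits")
  if (length(unique(series$grid)) != 1)
    stop_perisim("series must be on a common grid")
  t <- series_times(series)
  vals <- series_values(series, use, model)
  analyzed <- which(colSums(!is.na(vals)) == nrow(vals))
  y <- vals[, analyzed, drop = FALSE]
  fit <- plr_matrix(y, t)
  out <- data.frame(location = analyzed, slope = fit$slope,
                    intercept = fit$intercept, se = fit$se,
                    t_stat = fit$t_stat, p = fit$p,
                    residual_mad = fit$residual_mad,
                    flagged = fit$residual_mad > mad_threshold,
                    n_visits = nrow(series))
  attr(out, "times") <- t
  attr(out, "values") <- y
  attr(out, "mad_threshold") <- mad_threshold
  class(out) <- c("plr_fit", "data.frame")
  out
}

#' @export
print.plr_fit <- function(x, ...) {
  cat(sprintf("Pointwise linear regression: %d locations, %d visits over %.1f years\n",
              nrow(x), x$n_visits[1], max(attr(x, "times"))))
  cat(sprintf("  %d location(s) with p < 0.05 (slope < 0), %d flagged as variable\n",
              sum(x$p < 0.05), sum(x$flagged)))
  invisible(x)
}

#' PoPLR: permutation of pointwise linear regression
#'
#' Combines the per-location one-sided slope p-values into the Fisher-type
#' statistic \eqn{S = \sum_i -\ln \max(p_i, \epsilon)} (\eqn{\epsilon =
#' 10^{-6}}) over the n analyzed locations, and calibrates it by
#' recomputing S after randomly permuting the visit order (one shared
#' permutation per draw across all locations, so the spatial correlation of
#' each field is preserved; dates stay fixed). The combined p-value is
#' `(1 + #\{S_perm >= S_obs\}) / (n_permutations + 1)`.
#'
#' @param series,model,use,mad_threshold as in
#'   [pointwise_linear_regression()].
#' @param n_permutations number of permutation draws (>= 100; capped with a
#'   warning at the number of distinct visit orderings).
#' @param seed integer seed for the permutation stream.
#' @return object of class `poplr` with `s_observed`, `n_locations`,
#'   `s_over_n`, `permutation_s`, `p_value`, `n_permutations`, `seed`,
#'   `trends` (the [pointwise_linear_regression()] fit) and `epsilon`.
#' @examples
#' \donttest{
#' g <- build_standard_grid("24-2")
#' series <- synth_series(synth_baseline_field(g, seed = 1),
#'                        n_visits = 8, seed = 2)
#' res <- poplr(series$fields, use = "sensitivity", n_permutations = 200,
#'              seed = 3)
#' }
#' @export
poplr <- function(series, model = NULL, use = "td", n_permutations = 5000,
                  seed = 1, mad_threshold = 2) {
  if (n_permutations < 100)
    stop_perisim("n_permutations must be at least 100")
  eps <- 1e-6
  trends <- pointwise_linear_regression(series, model, use, mad_threshold)
  t <- attr(trends, "times")
  y <- attr(trends, "values")
  m <- length(t)
  n_distinct <- factorial(m)
  if (n_permutations > n_distinct) {
    warning("n_permutations capped at the number of distinct visit orders (",
            n_distinct, ")")
    n_permutations <- n_distinct
  }
  s_stat <- function(p) sum(-log(pmax(p, eps)))
  s_obs <- s_stat(trends$p)
  X <- cbind(1, t)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)
  df <- m - 2
  c22 <- XtXinv[2, 2]
  perm_s <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      yp <- y[sample.int(m), , drop = FALSE]
      beta <- H %*% yp
      resid <- yp - X %*% beta
      s2 <- colSums(resid^2) / df
      se <- sqrt(pmax(s2 * c22, 0))
      slope <- beta[2, ]
      tstat <- ifelse(se > 1e-12, slope / se,
                      ifelse(abs(slope) < 1e-12, 0, sign(slope) * Inf))
      s_stat(pmax(stats::pt(tstat, df), 1e-300))
    }, numeric(1))
  })
  n <- nrow(trends)
  structure(list(s_observed = s_obs, n_locations = n, s_over_n = s_obs / n,
                 permutation_s = perm_s,
                 p_value = (1 + sum(perm_s >= s_obs)) / (n_permutations + 1),
                 n_permutations = n_permutations, seed = seed,
                 trends = trends, epsilon = eps),
            class = "poplr")
}

#' @export
print.poplr <- function(x, ...) {
  cat(sprintf("PoPLR: S = %.2f over n = %d locations (S/n = %.3f)\n",
              x$s_observed, x$n_locations, x$s_over_n))
  cat(sprintf("  permutation p-value = %.4f (%d permutations, seed %d)\n",
              x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
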