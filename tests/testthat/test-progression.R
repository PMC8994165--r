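grid242 <- build_standard_grid("24-2")

make_series <- function(sens_rows, dates = NULL) {
  m <- nrow(sens_rows)
  if (is.null(dates)) dates <- as.Date("2018-01-01") + round((0:(m - 1)) * 182.625)
  vf_table("P1", "OD", dates, age = 60 + (0:(m - 1)) * 0.5, grid = grid242,
           sensitivities = sens_rows)
}

test_that("constant series give zero slopes, zero MAD and p = 0.5", {
  base <- rep(28, 54); base[grid242$locations$is_blind_spot] <- NA
  series <- make_series(matrix(base, 6, 54, byrow = TRUE))
  fit <- pointwise_linear_regression(series, use = "sensitivity")
  expect_equal(nrow(fit), 52)
  expect_equal(fit$slope, rep(0, 52))
  expect_equal(fit$residual_mad, rep(0, 52))
  expect_equal(fit$p, rep(0.5, 52))
  expect_false(any(fit$flagged))
})

test_that("an exact linear decline is fit perfectly", {
  base <- rep(30, 54); base[grid242$locations$is_blind_spot] <- NA
  days <- round((0:5) * 0.5 * 365.25)
  t <- days / 365.25  # exact times implied by the visit dates
  sens <- t(vapply(t, function(tv) base - 1 * tv, numeric(54)))
  series <- make_series(sens, dates = as.Date("2018-01-01") + days)
  fit <- pointwise_linear_regression(series, use = "sensitivity")
  expect_equal(fit$slope, rep(-1, 52), tolerance = 1e-6)
  expect_equal(fit$residual_mad, rep(0, 52), tolerance = 1e-9)
  expect_true(all(fit$p < 1e-6))  # perfect negative trend
})

test_that("regression statistics match the lm()/pt() oracle to 1e-10", {
  set.seed(20)
  sens <- matrix(rnorm(8 * 54, 25, 3), 8, 54)
  sens[, grid242$locations$is_blind_spot] <- NA
  series <- make_series(round(sens, 2))
  fit <- pointwise_linear_regression(series, use = "sensitivity")
  t <- attr(fit, "times")
  y <- vf_sens_matrix(series)
  for (r in c(1, 13, 52)) {
    i <- fit$location[r]
    ref <- lm(y[, i] ~ t)
    sm <- summary(ref)$coefficients
    expect_equal(fit$slope[r], sm[2, 1], tolerance = 1e-10)
    expect_equal(fit$intercept[r], sm[1, 1], tolerance = 1e-10)
    expect_equal(fit$se[r], sm[2, 2], tolerance = 1e-10)
    expect_equal(fit$p[r], pt(sm[2, 3], df = 6), tolerance = 1e-10)
    res <- residuals(ref)
    expect_equal(fit$residual_mad[r], median(abs(res - median(res))),
                 tolerance = 1e-10)
  }
})

test_that("series preconditions are enforced", {
  base <- matrix(28, 3, 54)
  expect_error(pointwise_linear_regression(make_series(base),
                                           use = "sensitivity"),
               "4 visits")
  s <- make_series(matrix(28, 5, 54))
  s$date[2] <- s$date[1]
  expect_error(pointwise_linear_regression(s, use = "sensitivity"),
               "strictly increasing")
  expect_error(pointwise_linear_regression(make_series(matrix(28, 5, 54)),
                                           use = "td"),
               "requires a normative model")
})

test_that("variability flags follow the residual-MAD threshold", {
  set.seed(33)
  base <- rep(28, 54); base[grid242$locations$is_blind_spot] <- NA
  sens <- matrix(base, 8, 54, byrow = TRUE)
  sens[, 5] <- 28 + c(-6, 6, -6, 6, -6, 6, -6, 6)  # violently variable
  series <- make_series(sens)
  fit <- pointwise_linear_regression(series, use = "sensitivity",
                                     mad_threshold = 2)
  expect_true(fit$flagged[fit$location == 5])
  expect_equal(sum(fit$flagged), 1)
  expect_true(all(fit$residual_mad[fit$flagged] > 2))
})

test_that("PoPLR on a 24-2 series analyzes 52 locations", {
  syn <- synth_series(synth_baseline_field(grid242, age = 55),
                      n_visits = 8, measurement_sd = 1, seed = 2)
  res <- poplr(syn$fields, use = "sensitivity", n_permutations = 200,
               seed = 3)
  expect_equal(res$n_locations, 52)
  expect_equal(res$s_over_n, res$s_observed / 52)
  expect_length(res$permutation_s, 200)
  expect_equal(res$p_value,
               (1 + sum(res$permutation_s >= res$s_observed)) / 201)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("identical fields give a degenerate permutation null with p = 1", {
  base <- rep(27, 54); base[grid242$locations$is_blind_spot] <- NA
  series <- make_series(matrix(base, 6, 54, byrow = TRUE))
  res <- poplr(series, use = "sensitivity", n_permutations = 150, seed = 1)
  expect_equal(res$p_value, 1)
  expect_equal(length(unique(round(res$permutation_s, 9))), 1)
  expect_equal(res$s_observed, res$permutation_s[1], tolerance = 1e-9)
})

test_that("S is invariant to location order and decreasing in each p", {
  p <- c(0.01, 0.2, 0.6, 0.95)
  s_stat <- function(p) sum(-log(pmax(p, 1e-6)))
  expect_equal(s_stat(p), s_stat(rev(p)))
  for (i in seq_along(p)) {
    p2 <- p; p2[i] <- p2[i] / 2
    expect_gt(s_stat(p2), s_stat(p))
  }
  # observed S equals the Fisher-type sum over the reported trends
  syn <- synth_series(synth_baseline_field(grid242), n_visits = 6,
                      measurement_sd = 1, seed = 9)
  res <- poplr(syn$fields, use = "sensitivity", n_permutations = 120,
               seed = 5)
  expect_equal(res$s_observed, s_stat(res$trends$p), tolerance = 1e-12)
})

test_that("permutation draws are capped at the number of distinct orders", {
  base <- rep(30, 54); base[grid242$locations$is_blind_spot] <- NA
  set.seed(4)
  sens <- matrix(base, 4, 54, byrow = TRUE) + rnorm(4 * 54)
  series <- make_series(round(sens, 2))
  expect_warning(res <- poplr(series, use = "sensitivity",
                              n_permutations = 100, seed = 1),
                 "capped")
  expect_equal(res$n_permutations, 24)
})

test_that("progressing series are detected more often than stable ones", {
  base <- synth_baseline_field(grid242, age = 55)
  nrep <- 40
  reject <- function(prog) {
    mean(vapply(seq_len(nrep), function(k) {
      syn <- synth_series(base, n_visits = 10, spacing = 0.5,
                          prog_locations = if (prog) 1:5 else integer(0),
                          prog_slopes = -1.5, measurement_sd = 1,
                          seed = 1000 * prog + k)
      poplr(syn$fields, use = "sensitivity", n_permutations = 200,
            seed = k)$p_value <= 0.05
    }, logical(1)))
  }
  r_stable <- reject(FALSE)
  r_prog <- reject(TRUE)
  expect_lt(r_stable, 0.2)
  expect_gt(r_prog, r_stable)
})
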