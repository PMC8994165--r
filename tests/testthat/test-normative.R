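grid242 <- build_standard_grid("24-2")

noise_free_cohort <- function(n = 30, gamma = 0, tau = 0, sigma_w = 0,
                              seed = 1) {
  synth_healthy_cohort(grid242, n_subjects = n, gamma = gamma, tau = tau,
                       sigma_w = sigma_w, seed = seed)
}

test_that("age slopes are recovered within their OLS confidence intervals", {
  co <- synth_healthy_cohort(grid242, n_subjects = 200, gamma = 0.06,
                             seed = 11)
  nm <- fit_normative_model(co$fields, grid242)
  ok <- !grid242$locations$is_blind_spot
  # independent oracle: lm() at a handful of locations
  sens <- vf_sens_matrix(co$fields)
  for (i in c(1, 10, 30)) {
    ref <- lm(sens[, i] ~ co$fields$age)
    expect_equal(nm$slope[i], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(nm$intercept[i], unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(nm$resid_sd[i], summary(ref)$sigma, tolerance = 1e-10)
    ci <- confint(ref)[2, ]
    covered <- ci[1] <= -0.06 && -0.06 <= ci[2]
    se <- summary(ref)$coefficients[2, 2]
    expect_equal(covered,
                 abs(nm$slope[i] + 0.06) <= qt(0.975, 198) * se)
  }
  # coverage across the field
  sens_age <- sd(co$fields$age)
  covered <- vapply(which(ok), function(i) {
    se <- nm$resid_sd[i] / (sens_age * sqrt(199))
    abs(nm$slope[i] - (-0.06)) <= qt(0.975, 198) * se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("a noise-free, age-flat cohort gives zero residuals and cutoffs", {
  co <- noise_free_cohort()
  nm <- fit_normative_model(co$fields, grid242)
  ok <- !grid242$locations$is_blind_spot
  expect_equal(nm$resid_sd[ok], rep(0, sum(ok)), tolerance = 1e-8)
  expect_equal(max(abs(nm$td_cutoffs[, ok])), 0, tolerance = 1e-8)
  expect_equal(sum(nm$md_weights), 1, tolerance = 1e-9)
  # uniform fallback when variances degenerate
  expect_equal(nm$md_weights[ok], rep(1 / sum(ok), sum(ok)))
})

test_that("smoothing is the identity on spatially homogeneous dispersion", {
  # every location carries the same per-subject value, so the
  # adjacency-weighted mean has nothing to change
  set.seed(5)
  n <- 40
  vals <- 30 + rnorm(n, 0, 2)
  sens <- matrix(vals, n, 54)
  sens[, grid242$locations$is_blind_spot] <- NA_real_
  cohort <- vf_table(sprintf("H%02d", 1:n), "OD", "2020-01-01",
                     age = seq(20, 75, length.out = n), grid = grid242,
                     sensitivities = sens)
  nm_p <- fit_normative_model(cohort, grid242, method = "pointwise")
  nm_s <- fit_normative_model(cohort, grid242, method = "smooth")
  ok <- !grid242$locations$is_blind_spot
  expect_equal(nm_s$resid_sd[ok], nm_p$resid_sd[ok], tolerance = 1e-9)
  expect_equal(nm_s$td_cutoffs[, ok], nm_p$td_cutoffs[, ok], tolerance = 1e-9)
  expect_equal(nm_s$pd_cutoffs[, ok], nm_p$pd_cutoffs[, ok], tolerance = 1e-9)
})

test_that("cohort preconditions are enforced", {
  co <- synth_healthy_cohort(grid242, n_subjects = 25, seed = 2)
  f <- co$fields
  dup <- f; dup$id[2] <- dup$id[1]
  expect_error(fit_normative_model(dup, grid242), "duplicated",
               class = "norm_fit_error")
  young <- f; young$age <- 30 + young$age / 100
  expect_error(fit_normative_model(young, grid242), "20 years")
  expect_error(fit_normative_model(f[1:10, ], grid242), ">= 20 cohort")
})

test_that("total deviation is the departure from the age-expected normal", {
  co <- synth_healthy_cohort(grid242, n_subjects = 50, seed = 3)
  nm <- fit_normative_model(co$fields, grid242)
  age <- 52
  expected <- nm$intercept + nm$slope * age
  ok <- !grid242$locations$is_blind_spot
  f <- vf_table("X", "OD", "2022-05-01", age, grid = grid242,
                sensitivities = matrix(expected, nrow = 1))
  td <- total_deviation(f, nm)[1, ]
  expect_equal(td[ok], rep(0, sum(ok)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(is.na(td[!ok])))
  # subtraction and equivariance
  f2 <- f; f2[, vf_sens_cols(f2)] <- f[, vf_sens_cols(f)] - 8
  td2 <- total_deviation(f2, nm)[1, ]
  expect_equal(td2[ok], td[ok] - 8, tolerance = 1e-9)
  # grid mismatch
  expect_error(total_deviation(vf_table("X", "OD", "2022-05-01", 50,
                                        grid = "other",
                                        sensitivities = matrix(0, 1, 54)),
                               nm),
               "does not match")
})

test_that("probability categories use strict cutoffs and are monotone", {
  cutoffs <- matrix(c(-10, -8, -6, -4), ncol = 1)
  expect_equal(deviation_probability(-11, cutoffs), "<0.5%")
  expect_equal(deviation_probability(-9, cutoffs), "<1%")
  expect_equal(deviation_probability(-5, cutoffs), "<5%")
  expect_equal(deviation_probability(-4, cutoffs), "normal")  # strict
  expect_equal(deviation_probability(0, cutoffs), "normal")
  vals <- seq(-12, 0, by = 0.25)
  cats <- vapply(vals, function(v) deviation_probability(v, cutoffs),
                 character(1))
  ranks <- match(cats, c("<0.5%", "<1%", "<2%", "<5%", "normal"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("pattern deviation subtracts the general height", {
  co <- synth_healthy_cohort(grid242, n_subjects = 50, seed = 4)
  nm <- fit_normative_model(co$fields, grid242)
  ok <- !grid242$locations$is_blind_spot
  td <- rep(NA_real_, 54); td[ok] <- -3
  res <- pattern_deviation(td, nm)
  expect_equal(res$general_height, -3)
  expect_equal(res$pd[ok], rep(0, 52))
  # translation invariance
  td_shift <- td + 5
  expect_equal(pattern_deviation(td_shift, nm)$pd, res$pd)
  # a single deep defect barely moves the 85th percentile
  td2 <- rep(NA_real_, 54); td2[ok] <- 0; td2[which(ok)[7]] <- -15
  res2 <- pattern_deviation(td2, nm)
  expect_equal(res2$pd[which(ok)[7]], -15, tolerance = 0.1)
  expect_error(pattern_deviation(rep(NA_real_, 54), nm), "5 valid")
})

test_that("mean deviation is the weighted TD average and linear", {
  co <- synth_healthy_cohort(grid242, n_subjects = 50, seed = 6)
  nm <- fit_normative_model(co$fields, grid242)
  ok <- !grid242$locations$is_blind_spot
  td0 <- rep(NA_real_, 54); td0[ok] <- 0
  expect_equal(mean_deviation(td0, nm), 0)
  tda <- td0; tda[ok] <- rnorm(52)
  tdb <- td0; tdb[ok] <- rnorm(52)
  expect_equal(mean_deviation(tda + tdb - td0, nm),
               mean_deviation(tda, nm) + mean_deviation(tdb, nm),
               tolerance = 1e-9)
  # uniform-weight arithmetic on a tiny grid
  g <- vf_grid("duo3", x = c(-3, 3, 0), y = c(0, 0, 5))
  co2 <- synth_healthy_cohort(g, n_subjects = 25, tau = 0, sigma_w = 0,
                              seed = 1)
  nm2 <- fit_normative_model(co2$fields, g)
  expect_equal(mean_deviation(c(-2, -4, NA), nm2), -3)
})

test_that("normative models survive a JSON round trip", {
  co <- synth_healthy_cohort(grid242, n_subjects = 30, seed = 9)
  nm <- fit_normative_model(co$fields, grid242)
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_json(nm, path)
  back <- read_normative_json(path)
  expect_equal(back$slope, nm$slope, tolerance = 1e-12)
  expect_equal(back$td_cutoffs, unname(nm$td_cutoffs), tolerance = 1e-12)
  expect_equal(back$md_weights, nm$md_weights, tolerance = 1e-12)
  f <- synth_baseline_field(grid242, age = 60)
  expect_equal(analyze_field(f, back)$md, analyze_field(f, nm)$md,
               tolerance = 1e-9)
})

test_that("analyze_field mirrors OS input and assembles the deviation map", {
  g <- generate_custom_grid(list(mode = "cartesian", name = "sym6",
                                 x_range = c(-9, 9), y_range = c(-9, 9),
                                 spacing = 6))
  co <- synth_healthy_cohort(g, n_subjects = 40, seed = 12)
  nm <- fit_normative_model(co$fields, g)
  f_od <- synth_baseline_field(g, age = 50)
  f_os <- f_od; f_os$eye <- "OS"
  # a symmetric noise-free field analyzed as OS equals the OD analysis
  dm_od <- analyze_field(f_od, nm)
  dm_os <- analyze_field(f_os, nm, grid = g)
  # the underlying field is mirror-symmetric, so OS re-matching is exact
  sens <- vf_sens_matrix(f_od)[1, ]
  for (i in seq_along(sens)) {
    j <- which(g$locations$x == -g$locations$x[i] &
                 g$locations$y == g$locations$y[i])
    expect_equal(unname(sens[j]), unname(sens[i]))
  }
  expect_equal(dm_os$td, dm_od$td, tolerance = 1e-9)
  expect_equal(dm_os$md, dm_od$md, tolerance = 1e-9)
  expect_true(all(dm_od$td_category %in%
                    c("<0.5%", "<1%", "<2%", "<5%", "normal")))
})
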