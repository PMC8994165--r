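test_that("growth waves follow breadth-first order from the quadrant seeds", {
  g <- build_standard_grid("24-2")
  tess <- voronoi_tessellate(g)
  adj <- adjacency_from_tessellation(tess)
  seeds <- cbind(c(9, 9, -9, -9), c(9, -9, 9, -9))
  plan <- assign_growth_waves(g, seeds, adj)
  seed_idx <- match(paste(seeds[, 1], seeds[, 2]),
                    paste(g$locations$x, g$locations$y))
  expect_equal(plan$wave[seed_idx], rep(1L, 4))
  # every Voronoi neighbor of a seed that is not itself a seed is wave 2
  for (s in seed_idx) {
    nb <- setdiff(adj$neighbors[[s]], seed_idx)
    expect_true(all(plan$wave[nb] == 2L))
  }
  # BFS property: every non-seed wave is 1 + min neighbor wave
  for (i in seq_along(plan$wave)) {
    if (i %in% seed_idx) next
    expect_equal(plan$wave[i],
                 1L + min(plan$wave[adj$neighbors[[i]]]))
  }
})

test_that("degenerate growth inputs are handled", {
  g1 <- vf_grid("one", 0, 0)
  plan <- assign_growth_waves(g1, seeds = 1,
                              adjacency = list(neighbors = list(integer(0))))
  expect_equal(plan$wave, 1L)
  # two disconnected clusters, seed in one: unreachable error names a location
  g2 <- vf_grid("two", x = c(0, 50), y = c(0, 0))
  expect_error(assign_growth_waves(g2, seeds = 1,
                                   adjacency = list(neighbors =
                                     list(integer(0), integer(0)))),
               "unreachable")
  expect_error(assign_growth_waves(g2, seeds = cbind(1, 1)), "not found")
})

test_that("neighbor prediction is the inverse-distance-weighted mean", {
  g <- vf_grid("line", x = c(0, 1, 3), y = c(0, 0, 0))
  plan <- list(adjacency = list(neighbors = list(c(2L, 3L), integer(0),
                                                 integer(0))))
  expect_equal(neighbor_prediction(plan, g, c(NA, 28, NA), 1), 28)
  expect_equal(neighbor_prediction(plan, g, c(NA, 30, 10), 1),
               (30 / 1 + 10 / 3) / (1 + 1 / 3))  # = 25
  expect_true(is.na(neighbor_prediction(plan, g, c(NA, NA, NA), 1)))
  g2 <- vf_grid("sym", x = c(0, -2, 2), y = c(0, 0, 0))
  expect_equal(neighbor_prediction(plan, g2, c(NA, 20, 30), 1), 25)
})

test_that("a single-location grid reduces to one ZEST run", {
  g <- vf_grid("one", 0, 0)
  m <- open_machine(list(seed = 2, observer = sim_observer(25, fos_sd = 0.01,
                                                           fp = 0, fn = 0)))
  set_background(m)
  res <- run_static_test(g, m, scheduler_seed = 1)
  est <- vf_sens_matrix(res$field)[1, 1]
  expect_lt(abs(est - 25), 2)
  expect_true(all(res$log$location == 1))
})

test_that("fixed seeds make the whole session reproducible", {
  g <- build_standard_grid("24-2")
  run <- function() {
    thr <- 30 - 0.2 * sqrt(g$locations$x^2 + g$locations$y^2)
    thr[g$locations$is_blind_spot] <- 0
    m <- open_machine(list(seed = 42,
                           observer = sim_observer(thr, fp = 0.03, fn = 0.03)))
    set_background(m)
    run_static_test(g, m, scheduler_seed = 7)
  }
  a <- run(); b <- run()
  expect_identical(a$log, b$log)
  expect_identical(vf_sens_matrix(a$field), vf_sens_matrix(b$field))
})

test_that("no location is tested before a lower-wave neighbor finishes", {
  g <- build_standard_grid("24-2")
  thr <- rep(28, 54); thr[g$locations$is_blind_spot] <- 0
  m <- open_machine(list(seed = 8, observer = sim_observer(thr, fp = 0.03,
                                                           fn = 0.03)))
  set_background(m)
  res <- run_static_test(g, m, scheduler_seed = 3)
  log <- res$log
  plan <- res$plan
  adj <- plan$adjacency
  finish_idx <- rep(0, nrow(g$locations))  # blind spots finish at time 0
  for (i in unique(log$location))
    finish_idx[i] <- max(log$presentation[log$location == i])
  for (i in unique(log$location)) {
    w <- plan$wave[i]
    if (w == 1L) next
    first <- min(log$presentation[log$location == i])
    lower <- adj$neighbors[[i]][plan$wave[adj$neighbors[[i]]] < w]
    expect_true(any(finish_idx[lower] < first),
                info = paste("location", i))
  }
  # presentation counts respect the procedure bounds
  counts <- table(log$location)
  expect_true(all(counts >= 4 & counts <= 25))
  # blind spots are never presented
  expect_false(any(log$location %in% which(g$locations$is_blind_spot)))
  # field is complete away from the blind spot
  sens <- vf_sens_matrix(res$field)[1, ]
  expect_true(all(!is.na(sens[!g$locations$is_blind_spot])))
  expect_true(all(is.na(sens[g$locations$is_blind_spot])))
})
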