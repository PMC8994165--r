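test_that("the standard 24-2 grid has the conventional structure", {
  g <- build_standard_grid("24-2")
  loc <- g$locations
  expect_equal(nrow(loc), 54)
  expect_equal(sum(!loc$is_blind_spot), 52)
  # temporal blind spot in right-eye format
  bs <- loc[loc$is_blind_spot, ]
  expect_true(all(bs$x == 15))
  expect_setequal(bs$y, c(3, -3))
  # extents: 21 degrees vertically, nasal extension to -27
  expect_equal(max(abs(loc$y)), 21)
  expect_equal(range(loc$x), c(-27, 21))
  # 6-degree lattice offset by 3
  expect_true(all(abs(loc$x) %% 6 == 3))
  expect_true(all(abs(loc$y) %% 6 == 3))
  # row pattern 4-6-8-9 mirrored
  counts <- table(loc$y)[as.character(c(21, 15, 9, 3, -3, -9, -15, -21))]
  expect_equal(unname(as.integer(counts)), c(4, 6, 8, 9, 9, 8, 6, 4))
  expect_false(anyDuplicated(paste(loc$x, loc$y)) > 0)
})

test_that("unknown grid names raise a registry error listing known grids", {
  expect_error(build_standard_grid("99-9"), "registered grids.*24-2")
})

test_that("registered custom grids are retrievable and usable in CSV I/O", {
  g <- generate_custom_grid(list(mode = "polar", name = "ring-test",
                                 rings = c(10, 20),
                                 meridians = c(0, 90, 180, 270)))
  register_grid(g)
  expect_true("ring-test" %in% registered_grids())
  expect_equal(nrow(build_standard_grid("ring-test")$locations), 8)
})

test_that("custom grid generation covers all three modes", {
  cart <- generate_custom_grid(list(mode = "cartesian",
                                    x_range = c(-3, 3), y_range = c(-3, 3),
                                    spacing = 6))
  expect_equal(nrow(cart$locations), 4)
  pol <- generate_custom_grid(list(mode = "polar", rings = c(10, 20),
                                   meridians = c(0, 90, 180, 270)))
  expect_equal(nrow(pol$locations), 8)
  expect_equal(sort(sqrt(pol$locations$x^2 + pol$locations$y^2)),
               rep(c(10, 20), each = 4), tolerance = 1e-9)
  expl <- generate_custom_grid(list(mode = "explicit",
                                    points = list(c(0, 0), c(5, 5))))
  expect_equal(nrow(expl$locations), 2)
})

test_that("degenerate custom grid specs are rejected", {
  expect_error(generate_custom_grid(list(mode = "explicit",
                                         points = list(c(1, 2), c(1, 2)))),
               "duplicate")
  expect_error(generate_custom_grid(list(mode = "explicit",
                                         points = list(c(95, 0)))),
               "90")
  expect_error(generate_custom_grid(list(mode = "warp")), "unknown grid mode")
})

test_that("eye mirroring is an involution that preserves blind-spot flags", {
  g <- build_standard_grid("24-2")
  expect_identical(mirror_to_right_eye(g, "OD"), g)
  m <- mirror_to_right_eye(g, "OS")
  expect_equal(m$locations$x, -g$locations$x)
  expect_equal(m$locations$y, g$locations$y)
  expect_identical(m$locations$is_blind_spot, g$locations$is_blind_spot)
  expect_equal(mirror_to_right_eye(m, "OS"), g)
  # spot check the sign flip
  i <- which(g$locations$x == -15 & g$locations$y == 3)
  expect_equal(m$locations$x[i], 15)
})

test_that("mirroring a field table re-matches sensitivities on symmetric grids", {
  g <- generate_custom_grid(list(mode = "cartesian", x_range = c(-9, 9),
                                 y_range = c(-3, 3), spacing = 6))
  n <- nrow(g$locations)
  f <- vf_table("A", "OS", "2022-01-01", 50, grid = g,
                sensitivities = matrix(seq_len(n), nrow = 1))
  m <- mirror_to_right_eye(f, "OS", g)
  sens <- vf_sens_matrix(f)[1, ]
  msens <- vf_sens_matrix(m)[1, ]
  # value originally at (x, y) now sits in the column of location (-x, y)
  for (i in seq_len(n)) {
    j <- which(g$locations$x == -g$locations$x[i] &
                 g$locations$y == g$locations$y[i])
    expect_equal(unname(msens[j]), unname(sens[i]))
  }
  expect_equal(vf_sens_matrix(mirror_to_right_eye(m, "OS", g)),
               vf_sens_matrix(f))
})
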