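test_that("boundary bank covers 12 directions x 19 distances", {
  bank <- make_boundary_bank()
  expect_equal(nrow(bank), 228)
  expect_equal(length(unique(bank$theta)), 12)
  expect_equal(length(unique(bank$d)), 19)
  expect_equal(sum(bank$range_class == "short"), 8 * 12)
  expect_equal(sum(bank$range_class == "long"), 11 * 12)
  expect_true(any(abs(bank$d - 16.2) < 1e-9))
  expect_true(any(abs(bank$d - 33.8) < 1e-6))
  expect_true(all(bank$sigma_theta == pi / 12))
  # radial width grows with tuning distance
  dd <- unique(bank[, c("d", "sigma_rad")])
  expect_true(all(diff(dd$sigma_rad[order(dd$d)]) > 0))
})

test_that("sensory code peaks at the matching cell and is zero without hits", {
  bank <- make_boundary_bank()
  empty <- data.frame(angle = numeric(0), distance = numeric(0),
                      hit = numeric(0))
  attr(empty, "regime") <- "vision"
  expect_equal(sensory_boundary_code(empty, 0.3, bank), rep(0, 228))
  # single hit exactly at a cell's tuning distance/direction
  cell <- bank[bank$dist_index == 10 & bank$dir_index == 4, ]
  obs <- data.frame(angle = cell$theta - 0.7, distance = cell$d, hit = 1)
  attr(obs, "regime") <- "vision"
  act <- sensory_boundary_code(obs, heading_estimate = 0.7, bank)
  expect_equal(act[cell$cell], 1, tolerance = 1e-12)
  expect_true(all(act <= 1 + 1e-12) && all(act >= 0))
})

test_that("darkness masks long-range cells everywhere", {
  bank <- make_boundary_bank()
  obs <- data.frame(angle = c(0, 1), distance = c(30, 8), hit = c(1, 1))
  attr(obs, "regime") <- "dark"
  act <- sensory_boundary_code(obs, 0, bank)
  expect_true(all(act[bank$range_class == "long"] == 0))
  expect_gt(max(act[bank$range_class == "short"]), 0.5)
})

test_that("active cells under vision match the geometric support oracle", {
  bank <- make_boundary_bank()
  sq <- build_arena("square", 100)
  pose <- c(30, 40, 0.4)
  obs <- observe_boundaries(sq, pose, "vision",
                            noise_config(sigma_boundary = 0))
  act <- sensory_boundary_code(obs, pose[3], bank)
  hits <- obs[obs$hit > 0, ]
  alpha <- hits$angle + pose[3]
  for (c_i in seq_len(nrow(bank))) {
    supported <- any(abs(hits$distance - bank$d[c_i]) <
                       3 * bank$sigma_rad[c_i] &
                     abs(gridslam:::wrap_angle(alpha - bank$theta[c_i])) <
                       3 * bank$sigma_theta[c_i])
    if (act[c_i] > 0.012) expect_true(supported)
    if (!supported) expect_lt(act[c_i], 0.012)
  }
})

test_that("expected field distance follows the wrapped-Gaussian shrinkage", {
  expect_equal(expected_field_distance(16.2, pi / 12),
               16.2 * exp(-(pi / 12)^2 / 2))
  expect_equal(expected_field_distance(16.2, pi / 12), 15.65,
               tolerance = 0.005)
  expect_equal(expected_field_distance(7, 0), 7)
  d <- seq(2, 80, by = 3)
  expect_true(all(diff(expected_field_distance(d)) > 0))
  expect_error(expected_field_distance(-1))
})
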