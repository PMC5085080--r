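test_that("rate maps conserve total activity and handle edge cases", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 120, seed = 1)
  rates <- runif(nrow(tr))
  rm <- rate_map(rates, tr, bin = 2, smoothing = 0, occupancy_min = 0,
                 bbox = sq$bbox)
  # occupancy-weighted map mean equals the time-average rate
  ok <- is.finite(rm$raw)
  expect_equal(sum(rm$raw[ok] * rm$occupancy[ok]) / sum(rm$occupancy[ok]),
               mean(rates), tolerance = 1e-9)
  # constant rate gives a flat map
  rmf <- rate_map(rep(0.5, nrow(tr)), tr, smoothing = 0, bbox = sq$bbox)
  expect_equal(range(rmf$raw[is.finite(rmf$raw)]), c(0.5, 0.5),
               tolerance = 1e-12)
  # no spikes: all-zero map
  rms <- rate_map(trajectory = tr, spikes = numeric(0), bbox = sq$bbox)
  expect_true(all(rms$raw[is.finite(rms$raw)] == 0))
  expect_error(rate_map(1, tr[1, , drop = FALSE]), "empty")
})

test_that("spike-based and rate-based maps agree for high firing rates", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 300, seed = 2)
  rates <- 0.5 + 0.5 * sin(tr$x / 8)
  spikes <- poisson_spikes(rates, peak_rate = 40,
                           dt = attr(tr, "dt"), seed = 3)
  rm_r <- rate_map(rates, tr, bbox = sq$bbox)
  rm_s <- rate_map(trajectory = tr, spikes = spikes, bbox = sq$bbox)
  ok <- is.finite(rm_r$rate) & is.finite(rm_s$rate)
  expect_gt(stats::cor(rm_r$rate[ok], rm_s$rate[ok] / 40), 0.9)
})

test_that("autocorrelogram is 1 at zero lag and point symmetric", {
  rm <- analytic_grid_map(lambda = 30)
  ac <- autocorrelogram(rm, max_lag = 50)
  L <- ac$max_lag
  expect_equal(ac$ac[L + 1, L + 1], 1, tolerance = 1e-12)
  flipped <- ac$ac[rev(seq_len(2 * L + 1)), rev(seq_len(2 * L + 1))]
  expect_equal(ac$ac, flipped, tolerance = 1e-12)
  # six inner peaks at 60-degree spacing
  pk <- gridslam:::acorr_peaks(ac)
  expect_gte(nrow(pk), 6)
  angs <- sort(atan2(pk[1:6, 2], pk[1:6, 1]) %% (2 * pi))
  expect_equal(diff(angs), rep(pi / 3, 5), tolerance = 0.06)
  expect_error(autocorrelogram(matrix(NA_real_, 5, 5)), "masked")
})

test_that("gridness separates hexagonal from white-noise maps", {
  rm <- analytic_grid_map(lambda = 30)
  ac <- autocorrelogram(rm, max_lag = 50)
  for (v in 1:4) expect_gt(as.numeric(gridness(ac, v)), 1)
  set.seed(4)
  gs <- replicate(30, {
    m <- matrix(runif(2500), 50, 50)
    rnoise <- structure(list(rate = gridslam:::smooth_masked_cpp(m, 1),
                             raw = m, occupancy = matrix(1, 50, 50),
                             bin = 2, bbox = c(0, 100, 0, 100),
                             smoothing = 2), class = "rate_map")
    as.numeric(gridness(autocorrelogram(rnoise, max_lag = 70), 1))
  })
  expect_lt(abs(mean(gs, na.rm = TRUE)), 0.3)
  expect_lt(max(abs(gs), na.rm = TRUE), 0.7)
})

test_that("border score ranks wall-hugging above central fields", {
  size <- 100; bin <- 2; nb <- size / bin
  xs <- seq(bin / 2, size - bin / 2, by = bin)
  wall_field <- outer(exp(-(xs - 4)^2 / 100), rep(1, nb)) # west wall ridge
  rm_wall <- structure(list(rate = wall_field, raw = wall_field,
                            occupancy = matrix(1, nb, nb), bin = bin,
                            bbox = c(0, size, 0, size), smoothing = 0),
                       class = "rate_map")
  blob <- outer(exp(-(xs - 50)^2 / 200), exp(-(xs - 50)^2 / 200))
  rm_blob <- structure(list(rate = blob, raw = blob,
                            occupancy = matrix(1, nb, nb), bin = bin,
                            bbox = c(0, size, 0, size), smoothing = 0),
                       class = "rate_map")
  b_wall <- border_score(rm_wall)
  b_blob <- border_score(rm_blob)
  expect_gt(b_wall, 0.5)
  expect_lt(b_blob, 0)
  empty <- rm_blob; empty$rate[] <- 0
  expect_true(is.na(border_score(empty)))
})

test_that("directional information has the stated closed forms", {
  set.seed(5)
  h <- runif(4000, -pi, pi)
  expect_equal(directional_info(rep(0.5, 4000), h), 0, tolerance = 1e-6)
  # rate confined to one of 8 equally occupied bins carries 3 bits/spike
  hb <- rep(seq(-pi + pi / 8, pi - pi / 8, by = pi / 4), each = 500)
  r <- as.numeric(hb > -pi + pi / 4 * 0.5 & hb < -pi + pi / 4 * 1.4)
  r <- as.numeric(abs(hb - hb[1]) < 1e-9)
  expect_equal(directional_info(r, hb), 3, tolerance = 1e-9)
  expect_error(directional_info(rep(0, 10), runif(10)), "zero mean")
})

test_that("map correlation behaves under identity and rotation", {
  rm <- analytic_grid_map(lambda = 30, orientation = 0.2)
  expect_equal(map_correlation(rm, rm), 1, tolerance = 1e-12)
  rot <- rm
  rot$rate <- t(rot$rate)[ncol(rot$rate):1, ] # 90-degree rotation
  expect_lt(map_correlation(rm, rot), 1)
  expect_error(map_correlation(rm$rate[1:3, 1:3], rm$rate[1:3, 1:3] * NA),
               "overlap")
})
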