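test_that("module bank follows the geometric scale progression", {
  bank <- make_module_bank(8, 30, 1.42)
  expect_equal(nrow(bank), 8)
  expect_equal(bank$scale[1], 30)
  expect_equal(bank$scale[8], 30 * 1.42^7, tolerance = 1e-12)
  expect_equal(30 * 1.42^7, 349.28, tolerance = 0.01)
  expect_equal(nrow(make_module_bank(1, 50, 2)), 1)
  expect_error(make_module_bank(3, -1, 1.4))
  # nominal axes 60 degrees apart
  expect_equal(bank$phi2 - bank$phi1, rep(pi / 3, 8))
})

test_that("irregular axis perturbations are reproducible with the stated SD", {
  b1 <- make_module_bank(8, irregular = TRUE, seed = 5)
  b2 <- make_module_bank(8, irregular = TRUE, seed = 5)
  expect_identical(b1, b2)
  nominal <- make_module_bank(8)
  dev <- as.matrix(b1[, c("phi1", "phi2", "phi3")]) -
    as.matrix(nominal[, c("phi1", "phi2", "phi3")])
  big <- make_module_bank(400, irregular = TRUE, seed = 6)
  devb <- as.matrix(big[, c("phi1", "phi2", "phi3")]) -
    outer(rep(1, 400), (0:2) * pi / 3)
  expect_equal(stats::sd(devb), 0.2, tolerance = 0.02)
  expect_true(any(dev != 0))
})

test_that("phase advance integrates displacement along each axis", {
  bank <- make_module_bank(2, 30, 1.42)
  s0 <- grid_phase_state(bank, c(0, 0))
  # displacement of one wavelength along axis 1 leaves its phase unchanged
  set.seed(1)
  s1 <- advance_phase(s0, bank, lam = 30, heading_estimate = 0,
                      comp_noise_sd = 0)
  expect_equal(s1[1, 1], s0[1, 1], tolerance = 1e-9)
  # forward map consistency: phases from a position equal integrated steps
  set.seed(1)
  s <- grid_phase_state(bank, c(0, 0))
  for (i in 1:10)
    s <- advance_phase(s, bank, lam = 3.3, heading_estimate = pi / 5,
                       comp_noise_sd = 0)
  target <- grid_phase_state(bank, 33 * c(cos(pi / 5), sin(pi / 5)))
  expect_equal(s, target, tolerance = 1e-9)
})

test_that("compensatory jitter is one shared 2-D draw across modules", {
  bank <- make_module_bank(4, 30, 1.42)
  n <- 3000
  dp <- matrix(NA_real_, n, 12)
  set.seed(2)
  s0 <- grid_phase_state(bank, c(0, 0))
  for (i in seq_len(n)) {
    s1 <- advance_phase(s0, bank, lam = 0, heading_estimate = 0,
                        comp_noise_sd = 3, dt = 0.1)
    d <- gridslam:::wrap_angle(s1 - s0)
    # undo the per-module wavenumber so every column estimates the same
    # 2-D jitter projection
    dp[i, ] <- as.numeric(d * bank$scale / (2 * pi))
  }
  ev <- eigen(stats::cov(dp), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[2], 100 * max(ev[-(1:2)])) # rank 2 up to noise
})

test_that("grid activity is the rectified three-cosine product", {
  bank <- make_module_bank(1, 40, 1.42)
  s <- grid_phase_state(bank, c(0, 0))
  expect_equal(grid_activity(s, list(module = 1, offsets = c(0, 0, 0))), 1)
  expect_equal(grid_activity(s, list(module = 1, offsets = c(pi, 0, 0))),
               0)
  s2 <- grid_phase_state(bank, c(7, 3))
  f <- grid_activity(s2, list(module = 1, offsets = c(0, 0, 0)))
  expect_gte(f, 0)
  expect_lte(f, 1)
})

test_that("noise-free analytic map is hexagonal with the expected spacing", {
  rm <- analytic_grid_map(lambda = 30, size = 100)
  ac <- autocorrelogram(rm, max_lag = 60)
  g <- gridness(ac, 2)
  expect_gt(as.numeric(g), 1)
  pk <- attr(g, "peaks")
  expect_gte(nrow(pk), 6)
  d <- sqrt(pk[, 1]^2 + pk[, 2]^2)
  # measured inter-peak spacing is 2 lambda / sqrt(3)
  expect_equal(stats::median(d), 2 * 30 / sqrt(3), tolerance = 0.02 * 34.6)
})

test_that("phase decoding inverts the forward map", {
  bank <- make_module_bank(8, 30, 1.42)
  p <- c(37.3, 61.8)
  st <- grid_phase_state(bank, p)
  dec <- phase_to_nominal_position(st, bank, bbox = c(0, 100, 0, 100))
  expect_lt(sqrt(sum((dec$position - p)^2)), 1e-6)
  expect_false(dec$ambiguous)
})

test_that("small-module-only decoding is ambiguous with lattice aliases", {
  bank <- make_module_bank(8, 30, 1.42)
  p <- c(20, 35)
  st <- grid_phase_state(bank, p)
  dec <- phase_to_nominal_position(st, bank, modules = 1,
                                   bbox = c(0, 100, 0, 100))
  expect_true(dec$ambiguous)
  expect_gt(nrow(dec$aliases), 1)
  # every alias reproduces the module-1 phases
  for (i in seq_len(nrow(dec$aliases))) {
    st2 <- grid_phase_state(bank, dec$aliases[i, ])
    expect_equal(unname(gridslam:::wrap_angle(st2[1, ] - st[1, ])),
                 rep(0, 3), tolerance = 1e-3)
  }
  # dropping the large modules shrinks the unambiguous range: aliases of
  # modules 1:4 are denser than the full-bank decode (which has none)
  dec4 <- phase_to_nominal_position(st, bank, modules = 1:4,
                                    bbox = c(0, 100, 0, 100))
  full <- phase_to_nominal_position(st, bank, bbox = c(0, 100, 0, 100))
  expect_false(full$ambiguous)
  expect_lt(sqrt(sum((dec4$position - p)^2)), 1e-3)
})
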