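test_that("grid template fit recovers a noiseless lattice exactly", {
  rm <- analytic_grid_map(lambda = 40 * sqrt(3) / 2, orientation = 0,
                          size = 150, bin = 1)
  ac <- autocorrelogram(rm, max_lag = 70)
  gp <- fit_grid_template(ac)
  expect_equal(gp$lambda1, 40, tolerance = 0.1)
  expect_equal(gp$lambda2, 40, tolerance = 0.1)
  expect_equal(gp$psi, pi / 3, tolerance = 0.5 * pi / 180)
  expect_equal(gp$theta %% (pi / 3), 0.523, tolerance = 0.02)
})

test_that("template recovery is robust to peak jitter", {
  # jitter the six ideal peaks directly and refit via the LS basis solve
  set.seed(6)
  lam <- 40
  base <- rbind(c(lam, 0), c(lam / 2, lam * sqrt(3) / 2),
                c(-lam / 2, lam * sqrt(3) / 2))
  errs <- replicate(40, {
    pk <- rbind(base, -base) + matrix(rnorm(12, 0, 1), 6, 2)
    # integer coords of the 6 inner peaks in the (b1, b2) basis
    NN <- rbind(c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1))
    B <- solve(crossprod(NN), crossprod(NN, pk))
    sqrt(sum(B[1, ]^2)) / lam - 1
  })
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("phase fitting localizes the field offset of an analytic grid", {
  off <- c(11, 7)
  rm <- analytic_grid_map(lambda = 30, size = 100, offset = off)
  ac <- autocorrelogram(rm, max_lag = 55)
  gp <- fit_grid_template(ac)
  ph <- fit_grid_phase(rm, gp)
  expect_gt(ph$r, 0.95)
  # recovered offset matches modulo the lattice
  B <- gp$basis
  dd <- as.numeric(solve(t(B), ph$offset - off))
  expect_equal(dd - round(dd), c(0, 0), tolerance = 0.03)
})

test_that("rescaling magnitude recovers an analytic axis compression", {
  rm1 <- analytic_grid_map(lambda = 30, size = 100, orientation = 0.2)
  rm2 <- rm1
  # compress horizontally by 0.7: resample columns
  nb <- nrow(rm1$rate)
  idx <- pmin(nb, pmax(1, round((seq_len(nb) - nb / 2) / 0.7 + nb / 2)))
  rm2$rate <- rm1$rate[idx, ]
  ac1 <- autocorrelogram(rm1, max_lag = 40)
  ac2 <- autocorrelogram(rm2, max_lag = 40)
  expect_equal(rescaling_magnitude(ac1, ac1, "h"), 1, tolerance = 0.02)
  expect_equal(rescaling_magnitude(ac2, ac1, "h"), 0.7, tolerance = 0.06)
  expect_equal(rescaling_magnitude(ac2, ac1, "v"), 1, tolerance = 0.06)
})

test_that("phase drift separates common-mode translation from pair offsets", {
  set.seed(7)
  p1 <- matrix(runif(60), 30, 2)
  # identical trials: both distributions degenerate at zero
  pd0 <- phase_drift(p1, p1)
  expect_true(all(pd0$within == 0) && all(pd0$between == 0))
  # global translation: within-cell magnitudes equal the shift,
  # between-cell offsets unchanged
  shift <- c(0.2, 0.1)
  pd1 <- phase_drift(p1, sweep(p1, 2, -shift))
  expect_equal(pd1$within, rep(sqrt(sum(shift^2)), 30), tolerance = 1e-9)
  expect_true(all(pd1$between < 1e-12))
  # independent per-cell drift: within exceeds between on average
  pd2 <- phase_drift(p1, (p1 + matrix(runif(60, 0, 0.2), 30, 2)) %% 1)
  expect_gt(mean(pd2$within), 0)
})

test_that("boundary field distance reads a wall-parallel ridge", {
  size <- 100; bin <- 2; nb <- size / bin
  xs <- seq(bin / 2, size - bin / 2, by = bin)
  ridge <- outer(exp(-(xs - 20)^2 / 18), rep(1, nb))
  rm <- structure(list(rate = ridge, raw = ridge,
                       occupancy = matrix(1, nb, nb), bin = bin,
                       bbox = c(0, size, 0, size), smoothing = 0),
                  class = "rate_map")
  sq <- build_arena("square", size)
  # tuning direction pi (west wall): distance from the west wall ~ 20 cm
  expect_equal(boundary_field_distance(rm, pi, sq), 20, tolerance = bin)
  flat <- rm; flat$rate[] <- 1
  expect_error(boundary_field_distance(flat, pi, sq), "above the mean")
})

test_that("arm correlation matrices are 1 on the diagonal and respond to shuffling", {
  hp <- build_arena("hairpin", 150)
  tr <- generate_hairpin_path(hp, n_traversals = 2, seed = 8)
  # synthetic rate depending on y only: all same-direction arms correlate
  rates <- matrix(sin(tr$y / 15), nrow = 1)
  m <- arm_correlation_matrix(rates, tr, hp, "E")
  expect_equal(diag(m$r), rep(1, 10), tolerance = 1e-9)
  inner <- m$r[2:9, 2:9]
  expect_gt(min(inner, na.rm = TRUE), 0.8)
  # shuffling bins destroys the correlation
  set.seed(9)
  v1 <- m$vectors[, 3]; v2 <- sample(m$vectors[, 5])
  expect_lt(abs(stats::cor(v1, v2, use = "complete.obs")),
            abs(stats::cor(m$vectors[, 3], m$vectors[, 5],
                           use = "complete.obs")))
})

test_that("attractor diagnostics distinguish coherent from independent cells", {
  set.seed(10)
  Tn <- 3000; dt <- 0.1
  shared <- pmax(0, sin(seq_len(Tn) / 40))
  coherent <- rbind(shared, shared, shared)
  ad <- attractor_distance(coherent, dt)
  expect_lt(max(ad$d, na.rm = TRUE), 1e-12)
  expect_true(all(is.na(ad$mean_r) | ad$mean_r > 0.99))
  noise <- matrix(runif(3 * Tn), 3, Tn)
  adn <- attractor_distance(noise, dt)
  expect_gt(stats::median(adn$d, na.rm = TRUE), 0.1)
  expect_lt(abs(mean(adn$mean_r, na.rm = TRUE)), 0.1)
})

test_that("dynamic rate maps recover displacement structure", {
  sq <- build_arena("square", 100)
  tr <- generate_forage(sq, 600, seed = 11)
  # drift-free grid cell: spikes from the analytic rate along the path
  k <- 2 * pi / 30
  f <- rep(1, nrow(tr))
  for (j in 0:2) {
    a <- j * pi / 3
    f <- f * pmax(0, cos(k * (tr$x * cos(a) + tr$y * sin(a))))
  }
  spikes <- poisson_spikes(f, peak_rate = 25, dt = 0.1, seed = 12)
  dm <- dynamic_rate_map(spikes, tr, window = 20, extent = 40)
  acd <- autocorrelogram(dm, max_lag = 34)
  g <- gridness(acd, 2)
  expect_gt(as.numeric(g), 0.5)
  # tiny window leaves only the central peak
  dm0 <- dynamic_rate_map(spikes, tr, window = 0.2, extent = 40,
                          min_spikes = 10)
  ctr <- ceiling(nrow(dm0$rate) / 2)
  far <- dm0$rate[abs(row(dm0$rate) - ctr) > 5 | abs(col(dm0$rate) -
                                                       ctr) > 5]
  expect_true(all(!is.finite(far) | far == 0))
  expect_error(dynamic_rate_map(spikes[1:5], tr), "few spikes")
})

test_that("the parametric classifier identifies analytic grid and boundary maps", {
  rm_g <- analytic_grid_map(lambda = 35, orientation = 0.3, size = 100)
  sq <- build_arena("square", 100)
  pg <- parametric_ratemap_correlation(rm_g, sq, n_starts = 10, seed = 13)
  expect_equal(pg$class, "grid")
  expect_gt(pg$r_gc, 0.9)
  expect_gt(pg$r_gc, pg$r_bvc)
  # long-range boundary cell disjoint from its wall: border score fails but
  # the classifier still reads it as a boundary cell
  rm_b <- analytic_boundary_map(d = 30, theta = 0)
  pb <- parametric_ratemap_correlation(rm_b, sq, n_starts = 10, seed = 14)
  expect_equal(pb$class, "boundary")
  expect_gt(pb$r_bvc, 0.8)
  b <- border_score(rm_b, sq)
  expect_lt(b, 0.5)
})

test_that("classifier stays correct under moderate map noise", {
  sq <- build_arena("square", 100)
  set.seed(15)
  for (noise_sd in c(0.1, 0.15)) {
    rm_g <- analytic_grid_map(lambda = 35, size = 100)
    rm_g$rate <- pmax(rm_g$rate + matrix(rnorm(length(rm_g$rate), 0,
                                               noise_sd),
                                         nrow(rm_g$rate)), 0)
    pg <- parametric_ratemap_correlation(rm_g, sq, n_starts = 14,
                                         seed = 16)
    expect_equal(pg$class, "grid")
    rm_b <- analytic_boundary_map(d = 25, theta = pi / 2)
    rm_b$rate <- pmax(rm_b$rate + matrix(rnorm(length(rm_b$rate), 0,
                                               noise_sd),
                                         nrow(rm_b$rate)), 0)
    pb <- parametric_ratemap_correlation(rm_b, sq, n_starts = 14,
                                         seed = 17)
    expect_equal(pb$class, "boundary")
  }
})
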