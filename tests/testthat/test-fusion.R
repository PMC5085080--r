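test_that("predictive readout behaves at visited, unvisited and symmetric nodes", {
  sq <- tiny_square()
  map <- association_map(sq, spacing = 2, sigma_g = 4, d_max = 12)
  c1 <- runif(228); c2 <- runif(228)
  # single visited node: identity readout at that node
  map1 <- update_association(map, c(30, 30), c1)
  pred <- predict_boundary(map1, c(30, 30))
  expect_equal(pred, c1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_false(attr(pred, "unvisited"))
  # far from any visited node: zero vector + flag
  far <- predict_boundary(map1, c(2, 2))
  expect_true(attr(far, "unvisited"))
  expect_equal(as.numeric(far), rep(0, 228))
  # two equidistant visited nodes average their codes
  map2 <- update_association(map, c(28, 30), c1)
  map2 <- update_association(map2, c(36, 30), c2)
  mid <- predict_boundary(map2, c(32, 30))
  expect_equal(as.numeric(mid), (c1 + c2) / 2, tolerance = 1e-2)
})

test_that("running average converges to the mean of noisy codes", {
  sq <- tiny_square()
  map <- association_map(sq)
  true_code <- rep(0.4, 228)
  set.seed(11)
  n <- 150
  for (i in seq_len(n))
    map <- update_association(map, c(30, 30),
                              pmin(1, pmax(0, true_code +
                                             rnorm(228, 0, 0.1))))
  node <- gridslam:::map_stencil(map, c(30, 30))
  center <- node$node[which.max(node$k)]
  est <- map$W[center, ]
  expect_lt(max(abs(est - true_code)), 4 * 0.1 / sqrt(n) * 3 + 0.02)
  # delta rule with eta = 1 and unit kernel copies the sensed code
  m2 <- association_map(sq)
  m2 <- update_association(m2, c(30, 30), true_code, rule = "delta",
                           eta = 1)
  expect_equal(m2$W[center, ], true_code, tolerance = 1e-6)
})

test_that("prediction error has the stated closed forms and dark subset", {
  bank <- make_boundary_bank()
  a <- runif(228)
  expect_equal(prediction_error(a, a, "vision", bank), 0)
  b <- rep(0, 228); s <- rep(0, 228); s[5] <- 1
  expect_equal(prediction_error(b, s, "vision", bank), 1 / sqrt(228))
  # codes differing only on long-range cells are equivalent in darkness
  d1 <- rep(0, 228); d2 <- rep(0, 228)
  d2[bank$range_class == "long"] <- runif(sum(bank$range_class == "long"))
  expect_equal(prediction_error(d1, d2, "dark", bank), 0)
  expect_gt(prediction_error(d1, d2, "vision", bank), 0)
})

test_that("disoriented initialization is uniform over the arena", {
  sq <- build_arena("square", 100)
  cfg <- fusion_config(n_particles = 200)
  ps <- c()
  for (s in 1:10) {
    set.seed(s)
    st <- init_particles(cfg, sq, "disoriented")
    ps <- c(ps, stats::ks.test(st$z[, 1] / 100, "punif")$p.value,
            stats::ks.test(st$z[, 2] / 100, "punif")$p.value)
  }
  expect_gt(min(ps), 0.001)
  expect_gt(stats::median(ps), 0.05)
  set.seed(1)
  sto <- init_particles(cfg, sq, "oriented_at_pose", pose = c(50, 50, 0),
                        pos_jitter = 0, head_jitter = 0)
  expect_true(all(sto$z[, 1] == 50) && all(sto$psi == 0))
})

test_that("systematic resampling is deterministic and respects weights", {
  set.seed(21)
  w <- c(1, rep(0, 9))
  rs <- systematic_resample(w)
  expect_equal(rs$assign, rep(1, 10))
  set.seed(22)
  a1 <- systematic_resample(rep(0.1, 10))
  set.seed(22)
  a2 <- systematic_resample(rep(0.1, 10))
  expect_identical(a1, a2)
  # uniform weights: every parent gets exactly one offspring
  expect_equal(sort(a1$counts), rep(1L, 10))
  # offspring counts track weights over repeated draws
  w2 <- c(0.5, 0.3, 0.2, rep(0, 7))
  cnt <- matrix(0, 1000, 10)
  set.seed(23)
  for (i in 1:1000) cnt[i, ] <- systematic_resample(w2)$counts
  expect_equal(colMeans(cnt)[1:3], 10 * w2[1:3], tolerance = 0.05)
})

test_that("map checkpoints round-trip bit-for-bit", {
  dir <- withr::local_tempdir()
  sq <- tiny_square()
  map <- update_association(association_map(sq), c(30, 30), runif(228))
  f <- file.path(dir, "map.rds")
  save_checkpoint(map, f)
  back <- load_checkpoint(f)
  expect_identical(back$W, map$W)
  expect_identical(back$mass, map$mass)
})

test_that("weights stay normalized and particles identical without compensatory noise", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 31)
  cfg <- mini_config(comp_noise_sd = 0, head_jitter_sd = 0)
  fit <- sifm(tr, sq, config = cfg, seed = 32, init_pos_jitter = 0,
              init_head_jitter = 0)
  z <- fit$particles$z
  expect_true(all(z[, 1] == z[1, 1]) && all(z[, 2] == z[1, 2]))
  expect_true(all(fit$particles$psi == fit$particles$psi[1]))
  expect_equal(sum(fit$particles$w), 1, tolerance = 1e-12)
})

test_that("feedback-off ablation leaves weights uniform for all time", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 41)
  cfg <- mini_config(feedback_on = FALSE)
  fit <- sifm(tr, sq, config = cfg, seed = 42)
  expect_true(all(abs(fit$particles$w - 1 / 20) < 1e-15))
  expect_true(all(abs(fit$diagnostics$ess - 20) < 1e-9))
  expect_equal(fit$diagnostics$n_resample, 0)
})

test_that("the compiled engine matches the pure-R reference step for step", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 6, seed = 51)
  bank <- make_module_bank()
  bbank <- make_boundary_bank()
  cfg <- fusion_config(n_particles = 5, resample_min_interval = 0)
  nz <- noise_config()
  cells <- make_grid_cells(bank, 2, seed = 52)
  fit <- sifm(tr, sq, config = cfg, noise = nz, bank = bank,
              bbank = bbank, cells = cells, seed = 53)
  # replay with the R reference implementation under the same seeds
  cues <- make_cues(tr, sq, "vision", nz, seed = 53)
  lattice <- association_map(sq, cfg$spacing, cfg$sigma_g, cfg$d_max)
  set.seed(53 + 3000017L)
  st <- init_particles(cfg, sq, "oriented_at_pose",
                       pose = c(tr$x[1], tr$y[1], tr$heading[1]))
  z <- st$z; psi <- st$psi; w <- st$w
  maps <- replicate(5, lattice, simplify = FALSE)
  set.seed(53 + 4000037L)
  for (k in seq_along(cues$dphi)) {
    stp <- gridslam:::r_reference_step(z, psi, w, maps, cues, k, cfg,
                                       bank, bbank)
    z <- stp$z; psi <- stp$psi; w <- stp$w; maps <- stp$maps
  }
  expect_equal(fit$particles$z, z, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(fit$particles$psi, psi, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$particles$w, w, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("lesions prune the readout without touching the filter state", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 61)
  bank <- make_module_bank()
  cells <- gridslam:::rbind_cells(lapply(1:4, function(m)
    make_grid_cells(bank, 4, module = m, seed = 60 + m)))
  fit <- sifm(tr, sq, config = mini_config(), cells = cells, seed = 62)
  expect_identical(lesion(fit, 0, "drop_cells"), fit)
  lc <- lesion(fit, 0.5, "drop_cells", seed = 63)
  expect_lt(nrow(lc$cells), nrow(fit$cells))
  expect_identical(lc$particles, fit$particles)
  lm <- lesion(fit, 0.75, "drop_modules")
  # largest scales dropped first
  expect_true(all(lm$active_modules %in% 1:2))
  expect_true(all(lm$cells$module %in% lm$active_modules))
  expect_error(lesion(fit, 1, "drop_modules"))
})

test_that("ensemble rates stay in [0, 1] and collapse correctly for one particle", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 71)
  fit <- sifm(tr, sq, config = mini_config(), seed = 72)
  expect_true(all(fit$rates >= 0 & fit$rates <= 1))
  expect_true(all(fit$bc_rates >= 0 & fit$bc_rates <= 1 + 1e-6))
  cfg1 <- fusion_config(n_particles = 2, comp_noise_sd = 0,
                        head_jitter_sd = 0)
  fit1 <- sifm(tr, sq, config = cfg1, seed = 73, init_pos_jitter = 0,
               init_head_jitter = 0)
  # identical particles: the ensemble rate is any particle's rate
  bank <- fit1$bank
  z <- fit1$particles$z[1, ]
  st <- grid_phase_state(bank, z)
  f <- grid_activity(st, list(module = 1,
                              offsets = as.numeric(fit1$cells[1,
                                c("off1", "off2", "off3")])))
  expect_equal(fit1$rates[1, ncol(fit1$rates)], f, tolerance = 1e-6)
})
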