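test_that("a fitted session exposes the standard modelling methods", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 1)
  fit <- sifm(tr, sq, config = mini_config(), seed = 2)
  expect_s3_class(fit, "sifm")
  expect_output(print(fit), "sifm")
  s <- summary(fit)
  expect_s3_class(s, "summary.sifm")
  expect_true(is.finite(s$decode_rmse))
  expect_equal(dim(fitted(fit)), c(600, 2))
  expect_length(residuals(fit), 600)
  expect_true(all(residuals(fit) >= 0))
  expect_equal(dim(coef(fit)), c(fit$map$nx * fit$map$ny, 228))
  pr <- predict(fit, rbind(c(30, 30), c(10, 50)))
  expect_equal(dim(pr), c(2, 228))
  sim <- simulate(fit, nsim = 1, seed = 3)
  expect_length(sim[[1]], nrow(fit$cells))
  expect_true(all(vapply(sim[[1]], function(x) all(diff(x) > 0),
                         logical(1))))
})

test_that("fits are reproducible per seed", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 4)
  f1 <- sifm(tr, sq, config = mini_config(), seed = 5)
  f2 <- sifm(tr, sq, config = mini_config(), seed = 5)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$particles, f2$particles)
  f3 <- sifm(tr, sq, config = mini_config(), seed = 6)
  expect_false(identical(f1$rates, f3$rates))
})

test_that("fusion tracks while pure path integration diverges", {
  sq <- build_arena("square", 100)
  tr <- generate_forage(sq, 420, seed = 7)
  cfg <- fusion_config(n_particles = 60)
  fit <- sifm(tr, sq, config = cfg, seed = 8)
  err_fused <- summary(fit)$decode_rmse_last
  cfg_pi <- fusion_config(n_particles = 60, comp_noise_sd = 0,
                          head_jitter_sd = 0)
  fit_pi <- sifm(tr, sq, config = cfg_pi, seed = 8)
  err_pi <- summary(fit_pi)$decode_rmse_last
  expect_lt(err_fused, 15)
  expect_gt(err_pi, 2 * err_fused)
})

test_that("weight normalization holds at every step", {
  sq <- tiny_square()
  tr <- short_forage(sq, duration = 60, seed = 9)
  fit <- sifm(tr, sq, config = mini_config(resample = "always"), seed = 10)
  expect_equal(sum(fit$particles$w), 1, tolerance = 1e-12)
  expect_true(all(fit$diagnostics$ess >= 1 - 1e-9 &
                    fit$diagnostics$ess <= 20 + 1e-9))
})

test_that("learning in a symmetric arena yields symmetric weight fields", {
  sq <- build_arena("square", 100)
  tr <- generate_forage(sq, 420, seed = 11)
  fit <- sifm(tr, sq, config = fusion_config(n_particles = 60), seed = 12)
  # visit-mass field should be roughly 4-fold symmetric: compare mass in
  # the four quadrants (trajectory coverage is the symmetric driver)
  m <- matrix(fit$map$mass, fit$map$nx, fit$map$ny)
  nx <- nrow(m); half <- floor(nx / 2)
  q <- c(sum(m[1:half, 1:half]), sum(m[(nx - half + 1):nx, 1:half]),
         sum(m[1:half, (nx - half + 1):nx]),
         sum(m[(nx - half + 1):nx, (nx - half + 1):nx]))
  expect_lt(max(q) / min(q), 4)
})
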