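test_that("square, circle and kite arenas have the expected geometry", {
  sq <- build_arena("square", 100)
  expect_equal(nrow(sq$walls), 4)
  expect_equal(sq$n_perimeter, 4)
  expect_equal(sq$symmetry_order, 4L)
  expect_equal(unname(sq$bbox), c(0, 100, 0, 100))

  ci <- build_arena("circle", 100)
  expect_true(is.infinite(ci$symmetry_order))
  expect_equal(ci$circle$radius, 50)

  kite <- build_arena("kite", 100)
  expect_equal(kite$symmetry_order, 1L)
  expect_equal(nrow(kite$walls), 4)
})

test_that("hairpin maze has 9 interior walls and 15 cm corridors", {
  hp <- build_arena("hairpin", 150)
  expect_equal(nrow(hp$walls) - hp$n_perimeter, 9)
  expect_equal(unname(hp$dims["corridor_width"]), 15)
  ints <- hp$walls[-(1:4), , drop = FALSE]
  # walls sit at multiples of the corridor width, alternating attachment
  expect_equal(ints[, 1], 15 * (1:9))
  expect_equal(ints[, 1], ints[, 3])
  gap_north <- abs(pmax(ints[, 2], ints[, 4]) - 150) > 1
  expect_equal(gap_north, rep(c(FALSE, TRUE), length.out = 9) == FALSE)
  # semi-transparent variant flags interior walls only
  st <- build_arena("semi_transparent_hairpin", 150)
  expect_true(all(st$walls[-(1:4), 5] == 1))
  expect_true(all(st$walls[1:4, 5] == 0))
})

test_that("spiral maze is a connected corridor whose centerline avoids walls", {
  sp <- build_arena("spiral", 150)
  expect_gt(nrow(sp$walls), 8)
  cl <- sp$centerline
  expect_true(all(arena_contains(sp, cl$waypoints)))
  g <- gridslam:::arena_geom(sp)
  n <- nrow(cl$waypoints)
  blocked <- step_blocked_cpp(g, cl$waypoints[-n, , drop = FALSE],
                              cl$waypoints[-1, , drop = FALSE])
  expect_false(any(blocked))
})

test_that("resize_arena scales per axis about the south-west corner", {
  sq <- build_arena("square", 100)
  r1 <- resize_arena(sq, 0.7, 1)
  expect_equal(unname(r1$dims), c(70, 100))
  expect_equal(unname(r1$bbox[c("xmin", "ymin")]), c(0, 0))
  r2 <- resize_arena(build_arena("rectangle", width = 100, height = 70),
                     1.42, 1.42)
  expect_equal(unname(r2$dims), c(142, 99.4))
  # inverse resize restores the original within 1e-9
  back <- resize_arena(r1, 1 / 0.7, 1)
  expect_equal(back$walls, sq$walls, tolerance = 1e-9)
  expect_error(resize_arena(build_arena("circle", 100), 0.7),
               "rectangular")
})

test_that("raycast matches geometry in each regime", {
  sq <- build_arena("square", 100)
  rc <- boundary_raycast(sq, c(50, 50, 0), n_rays = 4, regime = "vision")
  east <- rc[abs(rc$angle) < 1e-9, ]
  expect_equal(east$distance, 50, tolerance = 1e-9)
  dark <- boundary_raycast(sq, c(50, 50, 0), n_rays = 4, regime = "dark",
                           contact_range = 13)
  expect_true(all(dark$hit == 0))
  near <- boundary_raycast(sq, c(5, 50, pi), n_rays = 4, regime = "dark",
                           contact_range = 13)
  west <- near[abs(near$angle) < 1e-9, ] # ray ahead, heading west
  expect_equal(west$distance, 5, tolerance = 1e-9)
  expect_error(boundary_raycast(sq, c(150, 50, 0), 4), "outside")
})

test_that("semi-transparent rays see through interior walls to the perimeter", {
  st <- build_arena("semi_transparent_hairpin", 150)
  # inside arm 3 (x ~ 37.5), ray due east crosses transparent walls
  rc <- boundary_raycast(st, c(37.5, 75, 0), n_rays = 4,
                         regime = "semi_transparent")
  east <- rc[abs(rc$angle) < 1e-9 & rc$hit > 0, ]
  # union: nearest (transparent) wall by contact and the opaque perimeter
  expect_true(any(abs(east$distance - (45 - 37.5)) < 1e-9))
  expect_true(any(abs(east$distance - (150 - 37.5)) < 1e-9))
  # oracle: perimeter distance from brute-force opaque-only cast
  expect_equal(max(east$distance),
               brute_raycast(st, 37.5, 75, 0, opaque_only = TRUE),
               tolerance = 1e-9)
})

test_that("raycast agrees with a brute-force oracle on random poses", {
  set.seed(42)
  for (spec in list(build_arena("square", 100), build_arena("kite", 100),
                    build_arena("hairpin", 150),
                    build_arena("circle", 100))) {
    pts <- gridslam:::random_inside(spec, 60, margin = 2)
    angs <- runif(60, -pi, pi)
    for (i in seq_len(60)) {
      got <- raycast_cpp(gridslam:::arena_geom(spec), pts[i, 1], pts[i, 2],
                         angs[i], 0L, Inf)[1, 1]
      ref <- brute_raycast(spec, pts[i, 1], pts[i, 2], angs[i],
                           opaque_only = TRUE)
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("arena YAML round-trips", {
  dir <- withr::local_tempdir()
  for (kind in c("square", "circle", "hairpin", "kite")) {
    spec <- build_arena(kind, if (kind == "hairpin") 150 else 100)
    f <- file.path(dir, paste0(kind, ".yaml"))
    write_arena(spec, f)
    back <- read_arena(f)
    expect_equal(back$walls, spec$walls, tolerance = 1e-9)
    expect_equal(back$symmetry_order, spec$symmetry_order)
  }
})
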