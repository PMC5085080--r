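# shared small fixtures, built in code

tiny_square <- function(size = 60) build_arena("square", size)

short_forage <- function(spec = tiny_square(), duration = 60, seed = 1) {
  tr <- generate_forage(spec, max(60, duration), seed = seed)
  if (duration < 60) {
    dt <- attr(tr, "dt")
    tr2 <- tr[seq_len(round(duration / dt) + 1), ]
    attr(tr2, "dt") <- dt
    attr(tr2, "arena") <- attr(tr, "arena")
    class(tr2) <- class(tr)
    return(tr2)
  }
  tr
}

mini_config <- function(...) fusion_config(n_particles = 20, ...)

quiet_noise <- function()
  noise_config(sigma_ang = 0, cv_lin = 0, sigma_boundary = 0,
               sigma_compass = 0)

# independent brute-force first-hit oracle: loops over walls with the
# standard two-segment parametric solution, written independently of the
# compiled raycaster
brute_raycast <- function(spec, x, y, ang, opaque_only = FALSE) {
  walls <- spec$walls
  best <- Inf
  dx <- cos(ang); dy <- sin(ang)
  for (k in seq_len(nrow(walls))) {
    if (opaque_only && walls[k, 5] > 0.5) next
    ex <- walls[k, 3] - walls[k, 1]; ey <- walls[k, 4] - walls[k, 2]
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-14) next
    qx <- walls[k, 1] - x; qy <- walls[k, 2] - y
    tt <- (qx * ey - qy * ex) / den
    ss <- (qx * dy - qy * dx) / den
    if (tt > 1e-12 && ss >= -1e-9 && ss <= 1 + 1e-9 && tt < best)
      best <- tt
  }
  best <- unname(best)
  if (!is.null(spec$circle)) {
    fx <- x - spec$circle$cx; fy <- y - spec$circle$cy
    b <- fx * dx + fy * dy
    cc <- fx^2 + fy^2 - spec$circle$radius^2
    disc <- b^2 - cc
    if (disc >= 0) {
      for (tt in c(-b - sqrt(disc), -b + sqrt(disc)))
        if (tt > 1e-12 && tt < best) best <- tt
    }
  }
  best
}

# analytic rate map of an ideal interference grid cell over a square arena
analytic_grid_map <- function(lambda = 30, orientation = 0, size = 100,
                              bin = 2, offset = c(0, 0)) {
  xs <- seq(bin / 2, size - bin / 2, by = bin)
  k <- 2 * pi / lambda
  f <- matrix(1, length(xs), length(xs))
  for (j in 0:2) {
    a <- orientation + j * pi / 3
    ph <- k * outer((xs - offset[1]) * cos(a), (xs - offset[2]) * sin(a),
                    "+")
    f <- f * pmax(0, cos(ph))
  }
  structure(list(rate = f, raw = f, occupancy = matrix(1, nrow(f), ncol(f)),
                 bin = bin, bbox = c(0, size, 0, size), smoothing = 0),
            class = "rate_map")
}

# analytic long-range boundary-cell map (response to the nearest wall in
# the tuning direction)
analytic_boundary_map <- function(d = 30, theta = 0, sigma_rad = 4,
                                  sigma_theta = pi / 12, size = 100,
                                  bin = 2, n_dirs = 72) {
  spec <- build_arena("square", size)
  xs <- seq(bin / 2, size - bin / 2, by = bin)
  pts <- as.matrix(expand.grid(x = xs, y = xs))
  dirs <- seq(0, 2 * pi, length.out = n_dirs + 1)[seq_len(n_dirs)]
  D <- gridslam:::raycast_batch_cpp(gridslam:::arena_geom(spec), pts, dirs)
  ang <- exp(-(gridslam:::wrap_angle(dirs - theta))^2 / (2 * sigma_theta^2))
  act <- apply(sweep(exp(-(D - d)^2 / (2 * sigma_rad^2)), 2, ang, "*"), 1,
               max, na.rm = TRUE)
  f <- matrix(act, length(xs), length(xs))
  structure(list(rate = f, raw = f, occupancy = matrix(1, nrow(f), ncol(f)),
                 bin = bin, bbox = c(0, size, 0, size), smoothing = 0),
            class = "rate_map")
}
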