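#' Motion parameters for simulated foraging
#'
#' @param dt time step (s).
#' @param mean_speed,sd_speed,max_speed running speed statistics (cm/s).
#' @param turn_sd turning-rate SD (rad/s).
#' @param avoid_dist wall-avoidance steering distance (cm).
#' @return list of class `motion_params`.
#' @export
motion_params <- function(dt = 0.1, mean_speed = 20, sd_speed = 8,
                          max_speed = 60, turn_sd = 1.5, avoid_dist = 3) {
  stopifnot(dt >= 0.02, dt <= 0.5, mean_speed > 0, sd_speed > 0,
            max_speed > 0, turn_sd > 0, avoid_dist > 0)
  structure(list(dt = dt, mean_speed = mean_speed, sd_speed = sd_speed,
                 max_speed = max_speed, turn_sd = turn_sd,
                 avoid_dist = avoid_dist), class = "motion_params")
}

new_trajectory <- function(t, x, y, heading, arm = NA_integer_,
                           global_dir = NA_character_, dt, arena_name) {
  out <- data.frame(t = t, x = x, y = y, heading = heading, arm = arm,
                    global_dir = global_dir)
  attr(out, "dt") <- dt
  attr(out, "arena") <- arena_name
  class(out) <- c("sifm_trajectory", "data.frame")
  out
}

#' Generate a random foraging trajectory
#'
#' Correlated random walk with AR(1) speed, reflective wall avoidance and
#' full arena coverage over standard 20-minute sessions. The recorded
#' heading at each sample is the direction of the step that reached it, so
#' noise-free dead-reckoning of the derived self-motion cues reproduces the
#' path exactly.
#'
#' @param spec an `arena_spec`.
#' @param duration session length (s), at least 60.
#' @param params a `motion_params` object.
#' @param seed integer seed.
#' @return a `sifm_trajectory` data frame (t, x, y, heading, arm,
#'   global_dir).
#' @export
generate_forage <- function(spec, duration = 1200, params = motion_params(),
                            seed = 1) {
  stopifnot(inherits(spec, "arena_spec"), duration >= 60)
  set.seed(seed)
  g <- arena_geom(spec)
  n <- round(duration / params$dt)
  start <- random_inside(spec, 1)
  m <- forage_cpp(g, n, params$dt, params$mean_speed, params$sd_speed,
                  params$max_speed, params$turn_sd, params$avoid_dist,
                  start[1], start[2], stats::runif(1, -pi, pi))
  new_trajectory(t = seq(0, by = params$dt, length.out = n + 1),
                 x = m[, 1], y = m[, 2], heading = m[, 3],
                 dt = params$dt, arena_name = spec$name)
}

random_inside <- function(spec, n, margin = 5) {
  out <- matrix(NA_real_, n, 2)
  got <- 0
  bb <- spec$bbox
  g <- arena_geom(spec)
  while (got < n) {
    cand <- cbind(stats::runif(64, bb["xmin"], bb["xmax"]),
                  stats::runif(64, bb["ymin"], bb["ymax"]))
    ok <- inside_cpp(g, cand) & wall_distance_cpp(g, cand) > margin
    take <- min(n - got, sum(ok))
    if (take > 0) out[got + seq_len(take), ] <- cand[ok, , drop = FALSE][
      seq_len(take), , drop = FALSE]
    got <- got + take
  }
  out
}

#' Generate corridor-running trajectories in a hairpin or spiral maze
#'
#' The agent runs along corridor midlines with Gaussian lateral jitter,
#' alternating local north/south direction per arm. Easterly and westerly
#' traversals alternate; each sample is tagged with its arm index and the
#' global running direction.
#'
#' @param spec a hairpin or spiral `arena_spec` (any arena with a corridor
#'   centerline).
#' @param n_traversals number of end-to-end traversals (alternating
#'   easterly / westerly, starting easterly).
#' @param params a `motion_params` object.
#' @param seed integer seed.
#' @param lateral_sd lateral jitter SD about the corridor midline (cm).
#' @return a `sifm_trajectory`.
#' @export
generate_hairpin_path <- function(spec, n_traversals = 8,
                                  params = motion_params(), seed = 1,
                                  lateral_sd = 2) {
  if (is.null(spec$centerline))
    stop("arena has no corridor centerline (not a corridor maze)")
  set.seed(seed)
  cl <- spec$centerline
  dt <- params$dt
  xs <- list(); ys <- list(); arms <- list(); gd <- list()
  for (tr in seq_len(n_traversals)) {
    east <- tr %% 2 == 1
    wp <- cl$waypoints
    seg_arm <- cl$arm
    if (!east) { wp <- wp[rev(seq_len(nrow(wp))), ]; seg_arm <- rev(seg_arm) }
    # arc-length sampling with AR(1) speed noise
    seglen <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                            wp[-nrow(wp), , drop = FALSE])^2))
    cum <- c(0, cumsum(seglen))
    total <- cum[length(cum)]
    v <- params$mean_speed
    s <- 0; pos_s <- c()
    while (s < total) {
      pos_s <- c(pos_s, s)
      v <- params$mean_speed + 0.8 * (v - params$mean_speed) +
        stats::rnorm(1, 0, params$sd_speed * sqrt(1 - 0.8^2) * 0.5)
      v <- min(max(v, 5), params$max_speed)
      s <- s + v * dt
    }
    seg_of <- findInterval(pos_s, cum, rightmost.closed = TRUE)
    seg_of[seg_of > length(seglen)] <- length(seglen)
    frac <- (pos_s - cum[seg_of]) / seglen[seg_of]
    px <- wp[seg_of, 1] + frac * (wp[seg_of + 1, 1] - wp[seg_of, 1])
    py <- wp[seg_of, 2] + frac * (wp[seg_of + 1, 2] - wp[seg_of, 2])
    # smooth lateral jitter, clipped inside the corridor
    lat <- stats::filter(stats::rnorm(length(px), 0, lateral_sd * 0.6),
                         rep(1, 8) / sqrt(8), circular = TRUE)
    lat <- pmin(pmax(as.numeric(lat), -(cl$corridor_width / 2 - 2)),
                cl$corridor_width / 2 - 2)
    dirx <- (wp[seg_of + 1, 1] - wp[seg_of, 1]) / seglen[seg_of]
    diry <- (wp[seg_of + 1, 2] - wp[seg_of, 2]) / seglen[seg_of]
    xs[[tr]] <- px - diry * lat
    ys[[tr]] <- py + dirx * lat
    arms[[tr]] <- seg_arm[seg_of]
    gd[[tr]] <- rep(if (east) "E" else "W", length(px))
  }
  x <- unlist(xs); y <- unlist(ys)
  n <- length(x)
  heading <- c(0, atan2(diff(y), diff(x)))
  heading[1] <- heading[2]
  # tag corner samples (arm NA on horizontal segments) with the arm whose
  # x-band contains them
  arm <- unlist(arms)
  na <- is.na(arm)
  arm[na] <- pmin(pmax(ceiling(x[na] / cl$corridor_width), 1), cl$n_arms)
  new_trajectory(t = seq(0, by = dt, length.out = n), x = x, y = y,
                 heading = heading, arm = arm, global_dir = unlist(gd),
                 dt = dt, arena_name = spec$name)
}

#' Generate a virtual-hairpin trajectory in an open arena
#'
#' Follows the ideal hairpin corridor path inside an open arena of the same
#' outer dimensions (no interior walls exist).
#'
#' @param open_spec an open `arena_spec` whose outer dimensions match the
#'   hairpin maze.
#' @param n_traversals,params,seed,lateral_sd as in
#'   [generate_hairpin_path()].
#' @param n_arms,corridor_width hairpin template geometry.
#' @return a `sifm_trajectory`.
#' @export
generate_virtual_hairpin <- function(open_spec, n_traversals = 8,
                                     params = motion_params(), seed = 1,
                                     lateral_sd = 2, n_arms = 10,
                                     corridor_width = NULL) {
  size <- unname(open_spec$bbox["xmax"] - open_spec$bbox["xmin"])
  template <- build_arena("hairpin", size = size, n_arms = n_arms,
                          corridor_width = corridor_width)
  if (!isTRUE(all.equal(unname(template$bbox), unname(open_spec$bbox))))
    stop("open arena dimensions do not match the hairpin template")
  tr <- generate_hairpin_path(template, n_traversals, params, seed,
                              lateral_sd)
  attr(tr, "arena") <- open_spec$name
  tr
}

#' Trajectory summary statistics
#' @param object a `sifm_trajectory`.
#' @param bin occupancy bin size (cm) for coverage.
#' @param spec optional `arena_spec`; restricts coverage to reachable bins.
#' @param ... unused.
#' @return list with speed stats, coverage and duration.
#' @export
summary.sifm_trajectory <- function(object, bin = 2, spec = NULL, ...) {
  dt <- attr(object, "dt")
  sp <- step_speeds(object)
  cov <- trajectory_coverage(object, bin = bin, spec = spec)
  out <- list(duration = max(object$t), dt = dt,
              mean_speed = mean(sp), max_speed = max(sp), coverage = cov)
  class(out) <- "summary.sifm_trajectory"
  out
}

#' @export
print.summary.sifm_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %.0f s at dt unknown; mean speed %.1f cm/s; coverage %.3f\n",
              x$duration, x$mean_speed, x$coverage))
  invisible(x)
}

step_speeds <- function(tr) {
  dt <- attr(tr, "dt")
  sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dt
}

#' Fraction of reachable occupancy bins visited
#' @param tr a `sifm_trajectory`.
#' @param bin bin size (cm).
#' @param spec optional `arena_spec` to define reachable bins.
#' @return fraction in [0, 1].
#' @export
trajectory_coverage <- function(tr, bin = 2, spec = NULL) {
  bx <- floor(tr$x / bin); by <- floor(tr$y / bin)
  visited <- unique(paste(bx, by))
  if (is.null(spec)) {
    nx <- diff(range(bx)) + 1; ny <- diff(range(by)) + 1
    return(length(visited) / (nx * ny))
  }
  bb <- spec$bbox
  cx <- seq(floor(bb["xmin"] / bin), ceiling(bb["xmax"] / bin) - 1)
  cy <- seq(floor(bb["ymin"] / bin), ceiling(bb["ymax"] / bin) - 1)
  centers <- expand.grid(x = (cx + 0.5) * bin, y = (cy + 0.5) * bin)
  keep <- inside_cpp(arena_geom(spec), as.matrix(centers)) &
    wall_distance_cpp(arena_geom(spec), as.matrix(centers)) > 1
  total <- sum(keep)
  cells <- paste(floor(centers$x[keep] / bin), floor(centers$y[keep] / bin))
  length(intersect(visited, cells)) / total
}

#' Write a trajectory to CSV
#' @param tr a `sifm_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#' @param path file path.
#' @param dt time step (s); inferred from the time column when omitted.
#' @export
read_trajectory <- function(path, dt = NULL) {
  d <- utils::read.csv(path)
  if (is.null(dt)) dt <- stats::median(diff(d$t))
  new_trajectory(d$t, d$x, d$y, d$heading, d$arm, d$global_dir, dt,
                 arena_name = "loaded")
}
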