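#' Sensory noise configuration
#'
#' Magnitudes of the noise applied to each cue channel, plus the self-motion
#' speed gain used to model environmental novelty (a reduced gain slows the
#' integrated phase velocity).
#'
#' @param sigma_ang angular self-motion noise (rad per sqrt-second);
#'   calibrated so uncorrected heading drift reaches the rat-like ~0.5 rad
#'   by two minutes in darkness.
#' @param cv_lin coefficient of variation of linear displacement.
#' @param sigma_boundary boundary distance jitter SD (cm).
#' @param sigma_compass compass observation SD (rad).
#' @param gain self-motion speed gain (1 = veridical; novelty < 1).
#' @param contact_range maximum boundary detection distance without vision
#'   (cm).
#' @param n_rays number of egocentric boundary ray directions.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(sigma_ang = 0.0125, cv_lin = 0.3,
                         sigma_boundary = 1, sigma_compass = 0.1,
                         gain = 1, contact_range = 13, n_rays = 36) {
  stopifnot(sigma_ang >= 0, cv_lin >= 0, sigma_boundary >= 0,
            sigma_compass >= 0, gain > 0, gain <= 2, contact_range > 0,
            n_rays >= 4)
  structure(list(sigma_ang = sigma_ang, cv_lin = cv_lin,
                 sigma_boundary = sigma_boundary,
                 sigma_compass = sigma_compass, gain = gain,
                 contact_range = contact_range, n_rays = n_rays),
            class = "noise_config")
}

#' Scale self-motion noise variances
#'
#' Returns a copy of a noise configuration with the linear and angular
#' self-motion noise variances multiplied by `factor` (e.g. 4 or 0.25 for
#' the noise-magnitude series).
#'
#' @param noise a `noise_config`.
#' @param factor variance multiplier.
#' @export
scale_selfmotion_noise <- function(noise, factor) {
  stopifnot(factor > 0)
  noise$sigma_ang <- noise$sigma_ang * sqrt(factor)
  noise$cv_lin <- noise$cv_lin * sqrt(factor)
  noise
}

#' Noisy self-motion cue
#'
#' Adds integration noise to a true angular and linear displacement step:
#' `dphi = dheading + N(0, sigma_ang^2 dt)` and
#' `lam = gain * displacement * (1 + N(0, cv_lin^2))`, clipped at zero.
#'
#' @param dheading true heading change per step (rad); vectorized.
#' @param displacement true linear displacement per step (cm).
#' @param noise a `noise_config`.
#' @param dt time step (s).
#' @return list with components `dphi` (rad) and `lam` (cm).
#' @export
observe_self_motion <- function(dheading, displacement, noise, dt) {
  n <- length(dheading)
  stopifnot(length(displacement) == n, all(is.finite(dheading)),
            all(is.finite(displacement)))
  dphi <- dheading + stats::rnorm(n, 0, noise$sigma_ang * sqrt(dt))
  lam <- pmax(0, noise$gain * displacement *
                (1 + stats::rnorm(n, 0, noise$cv_lin)))
  list(dphi = dphi, lam = lam)
}

#' Noisy egocentric boundary observation at a pose
#'
#' Raycasts under the sensing regime, then jitters each hit distance with
#' Gaussian noise (clipped positive). In darkness rays beyond the contact
#' range report no hit.
#'
#' @param spec an `arena_spec`.
#' @param pose numeric length 3 (x, y, heading).
#' @param regime `"vision"`, `"dark"` or `"semi_transparent"`.
#' @param noise a `noise_config`.
#' @return data.frame (angle, distance, hit) with regime attribute.
#' @export
observe_boundaries <- function(spec, pose,
                               regime = c("vision", "dark",
                                          "semi_transparent"),
                               noise = noise_config()) {
  regime <- match.arg(regime)
  rc <- boundary_raycast(spec, pose, n_rays = noise$n_rays, regime = regime,
                         contact_range = noise$contact_range)
  hit <- rc$hit > 0
  rc$distance[hit] <- pmax(0.1, rc$distance[hit] +
                             stats::rnorm(sum(hit), 0, noise$sigma_boundary))
  if (regime == "dark") {
    drop <- hit & rc$distance > noise$contact_range
    rc$hit[drop] <- 0
    rc$distance[drop] <- NA_real_
  }
  attr(rc, "regime") <- regime
  rc
}

#' Noisy compass cue
#'
#' Available only in the presence of vision; the observation is the true
#' heading plus wrapped Gaussian noise.
#'
#' @param true_heading heading (rad); vectorized.
#' @param regime sensing regime.
#' @param noise a `noise_config`.
#' @return list with `heading` (rad, NA when unavailable) and `available`.
#' @export
observe_compass <- function(true_heading, regime, noise = noise_config()) {
  available <- regime == "vision"
  obs <- wrap_angle(true_heading +
                      stats::rnorm(length(true_heading), 0,
                                   noise$sigma_compass))
  obs[!available] <- NA_real_
  list(heading = obs, available = rep(available, length.out =
                                        length(true_heading)))
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Build the full cue streams for a session
#'
#' Converts a true trajectory into the noisy per-step cues consumed by the
#' fusion filter: self-motion (dphi, lam), egocentric boundary observations
#' at each post-step pose, and the compass stream. Channels use independent
#' seed streams derived from `seed`.
#'
#' @param trajectory a `sifm_trajectory`.
#' @param spec the `arena_spec` sensed (may differ from the arena that
#'   generated the trajectory, e.g. virtual hairpin).
#' @param regime a single regime or per-step vector.
#' @param noise a `noise_config`.
#' @param seed integer seed.
#' @return list of class `sifm_cues`.
#' @export
make_cues <- function(trajectory, spec,
                      regime = "vision", noise = noise_config(), seed = 1) {
  n <- nrow(trajectory) - 1L
  regime <- rep(regime, length.out = n)
  reg_code <- match(regime, c("vision", "dark", "semi_transparent")) - 1L
  dheading <- wrap_angle(diff(trajectory$heading))
  disp <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  dt <- attr(trajectory, "dt")

  set.seed(seed)
  sm <- observe_self_motion(dheading, disp, noise, dt)

  set.seed(seed + 1000003L)
  cmp <- observe_compass(trajectory$heading[-1], regime, noise)

  set.seed(seed + 2000003L)
  ego <- ego_ray_angles(noise$n_rays)
  nr <- noise$n_rays
  has_st <- any(reg_code == 2L)
  rows <- if (has_st) 2L * nr else nr
  obs_dist <- matrix(0, rows, n)
  obs_hit <- matrix(0L, rows, n)
  g <- arena_geom(spec)
  for (k in seq_len(n)) {
    pose <- c(trajectory$x[k + 1], trajectory$y[k + 1],
              trajectory$heading[k + 1])
    m <- raycast_cpp(g, pose[1], pose[2], ego + pose[3], reg_code[k],
                     noise$contact_range)
    if (reg_code[k] == 2L) {
      d <- c(m[, 1], m[, 3]); h <- c(m[, 2], m[, 4]) > 0
    } else {
      d <- m[, 1]; h <- m[, 2] > 0
      if (has_st) { d <- c(d, rep(NA_real_, nr)); h <- c(h, rep(FALSE, nr)) }
    }
    d[h] <- pmax(0.1, d[h] + stats::rnorm(sum(h), 0, noise$sigma_boundary))
    if (reg_code[k] == 1L) {
      drop <- h & d > noise$contact_range
      h[drop] <- FALSE
    }
    obs_dist[, k] <- ifelse(h, d, 0)
    obs_hit[, k] <- as.integer(h)
  }
  structure(list(dphi = sm$dphi, lam = sm$lam, obs_dist = obs_dist,
                 obs_hit = obs_hit,
                 obs_ang = if (has_st) c(ego, ego) else ego,
                 compass = cmp$heading, regime = regime,
                 regime_code = reg_code, dt = dt, noise = noise,
                 seed = seed),
            class = "sifm_cues")
}

#' Dead-reckon a path from self-motion cues
#'
#' Integrates the (possibly noisy) self-motion stream from an initial pose;
#' with noise-free cues and unit gain this reproduces the true path exactly.
#'
#' @param dphi,lam per-step cues.
#' @param start numeric length 3 (x, y, heading).
#' @return matrix (n+1) x 3 of x, y, heading.
#' @export
dead_reckon <- function(dphi, lam, start) {
  n <- length(dphi)
  h <- start[3] + cumsum(dphi)
  x <- start[1] + cumsum(lam * cos(h))
  y <- start[2] + cumsum(lam * sin(h))
  cbind(x = c(start[1], x), y = c(start[2], y), heading = c(start[3], h))
}
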