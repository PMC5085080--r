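#' Fusion filter configuration
#'
#' Parameters of the Rao-Blackwellized particle filter: particle count,
#' compensatory phase noise, the error-to-weight likelihood scale, the
#' association-map lattice resolution, learning rule, and the ablation
#' switches used by the compensatory-noise and prediction-error-feedback
#' ablations.
#'
#' @param n_particles number of particles (grid codes).
#' @param comp_noise_sd compensatory positional phase noise (cm per
#'   sqrt-second); 0 disables it (pure path-integration ablation).
#' @param head_jitter_sd per-particle private heading jitter (rad per
#'   sqrt-second); zeroed together with `comp_noise_sd` since both are
#'   per-particle (compensatory) noise sources.
#' @param sigma_e error-to-weight likelihood scale: `w propto
#'   exp(-err^2 / (2 sigma_e^2))`.
#' @param ess_frac resampling trigger as a fraction of `n_particles`.
#' @param resample_min_interval minimum number of steps between adaptive
#'   resampling events (limits map-copy churn; 0 disables).
#' @param resample `"adaptive"` (trigger on effective sample size) or
#'   `"always"`.
#' @param learning_on associative learning switch (recall sessions freeze
#'   the map).
#' @param feedback_on prediction-error feedback switch; when off the error
#'   is treated as constant so importance weights never change
#'   (non-probabilistic ablation).
#' @param rule `"running_average"` or `"delta"` (prediction-error rule with
#'   learning rate `eta`).
#' @param eta delta-rule learning rate in (0, 1].
#' @param compass_kappa von Mises concentration of the per-step compass
#'   likelihood applied to each particle's private heading (the compass,
#'   like the boundary cue, corrects only through importance weighting).
#' @param spacing association-map lattice spacing (cm).
#' @param sigma_g map kernel width (cm).
#' @param d_max map kernel support radius (cm).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(n_particles = 200, comp_noise_sd = 1.5,
                          head_jitter_sd = 0.01, sigma_e = 0.08,
                          ess_frac = 0.5, resample_min_interval = 10,
                          resample = c("adaptive", "always"),
                          learning_on = TRUE, feedback_on = TRUE,
                          rule = c("running_average", "delta"), eta = 0.1,
                          compass_kappa = 5, spacing = 2, sigma_g = 4,
                          d_max = 12) {
  resample <- match.arg(resample)
  rule <- match.arg(rule)
  stopifnot(n_particles >= 2, comp_noise_sd >= 0, sigma_e > 0,
            eta > 0, eta <= 1, spacing > 0, sigma_g > 0, d_max > 0)
  structure(list(n_particles = n_particles, comp_noise_sd = comp_noise_sd,
                 head_jitter_sd = head_jitter_sd, sigma_e = sigma_e,
                 ess_frac = ess_frac,
                 resample_min_interval = resample_min_interval,
                 resample = resample,
                 learning_on = learning_on, feedback_on = feedback_on,
                 rule = rule, eta = eta, compass_kappa = compass_kappa,
                 spacing = spacing, sigma_g = sigma_g, d_max = d_max),
            class = "fusion_config")
}

#' Create an empty association map over an arena
#'
#' A regular lattice of map grid codes covering the arena bounding box plus
#' a kernel-support margin; weights to the 228 boundary cells start at zero
#' with zero visit mass (naive map).
#'
#' @param spec an `arena_spec`.
#' @param spacing lattice spacing (cm).
#' @param sigma_g kernel width (cm).
#' @param d_max kernel support radius (cm).
#' @param n_bc boundary-code length.
#' @return list of class `association_map`.
#' @export
association_map <- function(spec, spacing = 2, sigma_g = 4, d_max = 12,
                            n_bc = 228) {
  bb <- spec$bbox
  x0 <- unname(bb["xmin"] - d_max); y0 <- unname(bb["ymin"] - d_max)
  nx <- ceiling((bb["xmax"] + d_max - x0) / spacing) + 1
  ny <- ceiling((bb["ymax"] + d_max - y0) / spacing) + 1
  structure(list(x0 = x0, y0 = y0, nx = as.integer(nx), ny = as.integer(ny),
                 spacing = spacing, sigma_g = sigma_g, d_max = d_max,
                 W = matrix(0, nx * ny, n_bc), mass = numeric(nx * ny)),
            class = "association_map")
}

# embed a checkpoint map into a (possibly larger) lattice by matching node
# world coordinates; nodes outside the old lattice start naive
map_embed <- function(map, lattice) {
  if (identical(c(map$x0, map$y0, map$nx, map$ny, map$spacing),
                c(lattice$x0, lattice$y0, lattice$nx, lattice$ny,
                  lattice$spacing)))
    return(map)
  stopifnot(isTRUE(all.equal(map$spacing, lattice$spacing)))
  out <- lattice
  ix_new <- rep(0:(lattice$nx - 1), times = lattice$ny)
  iy_new <- rep(0:(lattice$ny - 1), each = lattice$nx)
  # old-lattice indices of each new node (coordinate-aligned lattices)
  ox <- round((lattice$x0 + ix_new * lattice$spacing - map$x0) /
                map$spacing)
  oy <- round((lattice$y0 + iy_new * lattice$spacing - map$y0) /
                map$spacing)
  inside <- ox >= 0 & ox < map$nx & oy >= 0 & oy < map$ny
  src <- oy[inside] * map$nx + ox[inside] + 1L
  dst <- which(inside)
  out$W[dst, ] <- map$W[src, , drop = FALSE]
  out$mass[dst] <- map$mass[src]
  out
}

# smallest lattice covering both a checkpoint map and an arena
union_lattice <- function(map, spec, config) {
  bb <- spec$bbox
  x0 <- min(map$x0, bb["xmin"] - config$d_max)
  y0 <- min(map$y0, bb["ymin"] - config$d_max)
  x1 <- max(map$x0 + (map$nx - 1) * map$spacing, bb["xmax"] + config$d_max)
  y1 <- max(map$y0 + (map$ny - 1) * map$spacing, bb["ymax"] + config$d_max)
  # snap the origin onto the checkpoint's node grid so nodes align
  x0 <- map$x0 - ceiling((map$x0 - x0) / map$spacing) * map$spacing
  y0 <- map$y0 - ceiling((map$y0 - y0) / map$spacing) * map$spacing
  structure(list(x0 = unname(x0), y0 = unname(y0),
                 nx = as.integer(ceiling((x1 - x0) / map$spacing) + 1),
                 ny = as.integer(ceiling((y1 - y0) / map$spacing) + 1),
                 spacing = map$spacing, sigma_g = config$sigma_g,
                 d_max = config$d_max,
                 W = NULL, mass = NULL), class = "association_map")
}

# lattice nodes within kernel support of a position, with kernel values
map_stencil <- function(map, pos) {
  hw <- ceiling(map$d_max / map$spacing)
  cix <- floor((pos[1] - map$x0) / map$spacing + 0.5)
  ciy <- floor((pos[2] - map$y0) / map$spacing + 0.5)
  ix <- max(0, cix - hw):min(map$nx - 1, cix + hw)
  iy <- max(0, ciy - hw):min(map$ny - 1, ciy + hw)
  g <- expand.grid(ix = ix, iy = iy)
  dx <- pos[1] - (map$x0 + g$ix * map$spacing)
  dy <- pos[2] - (map$y0 + g$iy * map$spacing)
  r2 <- dx^2 + dy^2
  keep <- r2 <= map$d_max^2
  data.frame(node = g$iy[keep] * map$nx + g$ix[keep] + 1L,
             k = exp(-r2[keep] / (2 * map$sigma_g^2)))
}

#' Predictive boundary code read out from an association map
#'
#' Kernel-weighted, visit-mass-weighted average of the weight rows of
#' lattice nodes within support of the query position; zero (with an
#' `unvisited` attribute) where no visit mass lies in support.
#'
#' @param map an `association_map`.
#' @param position query position (cm).
#' @return boundary-code vector with attribute `unvisited`.
#' @export
predict_boundary <- function(map, position) {
  st <- map_stencil(map, position)
  km <- st$k * map$mass[st$node]
  den <- sum(km)
  if (den <= 0) {
    out <- numeric(ncol(map$W))
    attr(out, "unvisited") <- TRUE
    return(out)
  }
  out <- as.numeric(crossprod(map$W[st$node, , drop = FALSE], km) / den)
  attr(out, "unvisited") <- FALSE
  out
}

#' Associative update of the map at a position
#'
#' Running average: each node in support accumulates kernel mass and moves
#' its weights toward the sensed code with rate `k / mass` (an exact linear
#' average over time). Delta rule: rate `eta * k` (prediction-error
#' formulation).
#'
#' @param map an `association_map`.
#' @param position position (cm).
#' @param sensed sensed boundary-code vector.
#' @param rule `"running_average"` or `"delta"`.
#' @param eta delta-rule learning rate.
#' @return the updated map.
#' @export
update_association <- function(map, position, sensed,
                               rule = c("running_average", "delta"),
                               eta = 0.1) {
  rule <- match.arg(rule)
  st <- map_stencil(map, position)
  for (i in seq_len(nrow(st))) {
    n <- st$node[i]; k <- st$k[i]
    map$mass[n] <- map$mass[n] + k
    lr <- if (rule == "running_average") k / map$mass[n] else min(1, eta * k)
    map$W[n, ] <- map$W[n, ] + lr * (sensed - map$W[n, ])
  }
  map
}

#' Boundary prediction error
#'
#' Root-mean-square difference between predictive and sensed boundary codes
#' over the regime-admissible cells (darkness: short-range cells only).
#'
#' @param pred,sensed boundary-code vectors.
#' @param regime sensing regime.
#' @param bank boundary bank.
#' @return non-negative scalar.
#' @export
prediction_error <- function(pred, sensed, regime = "vision",
                             bank = make_boundary_bank()) {
  adm <- if (identical(regime, "dark")) bank$range_class == "short"
         else rep(TRUE, nrow(bank))
  sqrt(mean((pred[adm] - sensed[adm])^2))
}

#' Initialize the particle set
#'
#' Oriented mode places all particles at a given pose with small jitter;
#' disoriented mode redistributes grid-code activity at random: particle
#' positions uniform over the arena and headings uniform on the circle.
#' Maps start naive or are loaded from a learned checkpoint (shared by all
#' particles).
#'
#' @param config a `fusion_config`.
#' @param spec an `arena_spec`.
#' @param mode `"oriented_at_pose"` or `"disoriented"`.
#' @param pose numeric length 3 for oriented mode.
#' @param map optional learned `association_map` checkpoint.
#' @param pos_jitter oriented-mode position jitter SD (cm).
#' @param head_jitter oriented-mode heading jitter SD (rad).
#' @return list of class `fusion_state` (z, psi, w, map).
#' @export
init_particles <- function(config, spec,
                           mode = c("oriented_at_pose", "disoriented"),
                           pose = NULL, map = NULL, pos_jitter = 1,
                           head_jitter = 0.05) {
  mode <- match.arg(mode)
  P <- config$n_particles
  if (mode == "oriented_at_pose") {
    stopifnot(length(pose) == 3)
    z <- cbind(pose[1] + stats::rnorm(P, 0, pos_jitter),
               pose[2] + stats::rnorm(P, 0, pos_jitter))
    psi <- pose[3] + stats::rnorm(P, 0, head_jitter)
  } else {
    z <- random_inside(spec, P, margin = 0.5)
    psi <- stats::runif(P, -pi, pi)
  }
  structure(list(z = z, psi = psi, w = rep(1 / P, P), map = map,
                 config = config, arena = spec),
            class = "fusion_state")
}

#' Systematic resampling of a particle set
#'
#' One uniform draw defines the systematic positions; surviving particles
#' stay in place and extra offspring overwrite the slots of eliminated
#' particles (offspring copy phases, heading and map). Weights reset to
#' uniform.
#'
#' @param w normalized weights.
#' @return list: `counts` (offspring per parent) and `assign` (parent index
#'   for each slot).
#' @export
systematic_resample <- function(w) {
  P <- length(w)
  u <- stats::runif(1) / P
  cum <- cumsum(w)
  counts <- integer(P)
  i <- 0L
  for (p in seq_len(P)) {
    while (i < P && u + i / P < cum[p]) {
      counts[p] <- counts[p] + 1L
      i <- i + 1L
    }
  }
  assign <- seq_len(P)
  dead <- which(counts == 0L)
  di <- 1L
  for (p in seq_len(P)) {
    if (counts[p] > 1L) for (cc in seq_len(counts[p] - 1L)) {
      assign[dead[di]] <- p
      di <- di + 1L
    }
  }
  list(counts = counts, assign = assign)
}

#' Lesion a fitted model's readout
#'
#' `drop_modules` removes grid-scale modules (largest scales first by
#' default) from the readout and decode; `drop_cells` removes a random
#' fraction of readout cells across modules. The filter state itself is
#' untouched.
#'
#' @param fit a `sifm` fit.
#' @param fraction fraction in [0, 1).
#' @param mode `"drop_modules"` or `"drop_cells"`.
#' @param seed seed for the random cell drop.
#' @return the modified fit.
#' @export
lesion <- function(fit, fraction, mode = c("drop_modules", "drop_cells"),
                   seed = 1) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(fit)
  if (mode == "drop_modules") {
    M <- nrow(fit$bank)
    drop <- utils::tail(order(fit$bank$scale), round(fraction * M))
    fit$active_modules <- setdiff(fit$bank$module, fit$bank$module[drop])
    keep <- fit$cells$module %in% fit$active_modules
  } else {
    set.seed(seed)
    keep <- stats::runif(nrow(fit$cells)) >= fraction
  }
  fit$cells <- fit$cells[keep, , drop = FALSE]
  fit$rates <- fit$rates[keep, , drop = FALSE]
  fit
}

# ---- pure-R reference implementation of one filter step -----------------
# Mirrors the C++ engine draw-for-draw (per particle: heading jitter, then
# the 2-D compensatory jitter) so small runs can be checked against it.

r_reference_step <- function(z, psi, w, maps, cues, k, config, bank, bbank) {
  P <- nrow(z)
  dt <- cues$dt
  regime <- cues$regime[k]
  sensed_all <- vector("list", P)
  errv <- numeric(P)
  obs <- data.frame(angle = cues$obs_ang,
                    distance = ifelse(cues$obs_hit[, k] > 0,
                                      cues$obs_dist[, k], NA_real_),
                    hit = cues$obs_hit[, k])
  attr(obs, "regime") <- regime
  for (p in seq_len(P)) {
    e <- stats::rnorm(3)
    psi[p] <- psi[p] + cues$dphi[k] + e[1] * config$head_jitter_sd * sqrt(dt)
    sn <- config$comp_noise_sd * sqrt(dt)
    z[p, 1] <- z[p, 1] + cues$lam[k] * cos(psi[p]) + e[2] * sn
    z[p, 2] <- z[p, 2] + cues$lam[k] * sin(psi[p]) + e[3] * sn
    sensed <- sensory_boundary_code(obs, psi[p], bbank)
    if (config$learning_on)
      maps[[p]] <- update_association(maps[[p]], z[p, ], sensed,
                                      rule = config$rule, eta = config$eta)
    pred <- predict_boundary(maps[[p]], z[p, ])
    errv[p] <- prediction_error(pred, sensed, regime, bbank)
    sensed_all[[p]] <- sensed
  }
  if (config$feedback_on) {
    lw <- -errv^2 / (2 * config$sigma_e^2)
    if (is.finite(cues$compass[k]))
      lw <- lw + config$compass_kappa * cos(psi - cues$compass[k])
    wn <- w * exp(lw - max(lw))
    w <- wn / sum(wn)
  }
  ess <- 1 / sum(w^2)
  resampled <- FALSE
  if (config$resample == "always" || ess < config$ess_frac * P) {
    rs <- systematic_resample(w)
    z <- z[rs$assign, , drop = FALSE]
    psi <- psi[rs$assign]
    maps <- maps[rs$assign]
    w <- rep(1 / P, P)
    resampled <- TRUE
  }
  list(z = z, psi = psi, w = w, maps = maps, err = errv, ess = ess,
       resampled = resampled)
}
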