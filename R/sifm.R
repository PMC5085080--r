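#' Fit the spatial information fusion filter to a session
#'
#' Runs the Rao-Blackwellized particle filter along a trajectory: each
#' particle carries a multi-module grid phase state (equivalently a nominal
#' position), a private heading estimate and an association map from map
#' grid codes to the 228-cell boundary code. Per step the filter integrates
#' the noisy self-motion cue with compensatory phase noise, transforms the
#' egocentric boundary observation through each particle's heading,
#' optionally updates the association map, reads out a predictive boundary
#' code, and converts the boundary prediction error into importance weights
#' with systematic resampling.
#'
#' @param trajectory a `sifm_trajectory` (true path driving the cues).
#' @param arena the sensed `arena_spec`.
#' @param regime sensing regime: `"vision"`, `"dark"`,
#'   `"semi_transparent"`, or a per-step vector.
#' @param config a `fusion_config`.
#' @param noise a `noise_config`.
#' @param bank grid module bank (default 8 modules, base 30 cm, ratio
#'   1.42).
#' @param bbank boundary bank.
#' @param cells readout grid cells (data.frame from [make_grid_cells()]);
#'   default 16 cells of module 1.
#' @param init `"oriented_at_pose"` (at the trajectory start) or
#'   `"disoriented"` (uniform redistribution of grid-code activity).
#' @param map optional learned `association_map` checkpoint (recall).
#' @param track_particles particle indices whose phase-matched module cell
#'   activities are recorded individually (attractor diagnostics);
#'   `NULL` for none.
#' @param track_module module of the tracked per-particle cells.
#' @param init_pos_jitter,init_head_jitter oriented-mode initialization
#'   jitter (cm, rad).
#' @param seed integer seed controlling cues, initialization and filter
#'   noise.
#' @return an object of class `sifm`.
#' @export
sifm <- function(trajectory, arena, regime = "vision",
                 config = fusion_config(), noise = noise_config(),
                 bank = make_module_bank(), bbank = make_boundary_bank(),
                 cells = NULL, init = "oriented_at_pose", map = NULL,
                 track_particles = NULL, track_module = 1,
                 init_pos_jitter = 1, init_head_jitter = 0.05, seed = 1) {
  stopifnot(inherits(trajectory, "sifm_trajectory"),
            inherits(arena, "arena_spec"))
  if (is.null(cells)) cells <- make_grid_cells(bank, 16, module = 1,
                                               seed = seed)
  cues <- make_cues(trajectory, arena, regime = regime, noise = noise,
                    seed = seed)
  lattice <- association_map(arena, spacing = config$spacing,
                             sigma_g = config$sigma_g,
                             d_max = config$d_max)
  if (!is.null(map)) {
    # a checkpoint learned in a differently sized arena is embedded into a
    # lattice covering both geometries, node coordinates aligned
    ul <- union_lattice(map, arena, config)
    ul$W <- matrix(0, ul$nx * ul$ny, ncol(map$W))
    ul$mass <- numeric(ul$nx * ul$ny)
    map <- map_embed(map, ul)
    lattice <- map
  }
  set.seed(seed + 3000017L)
  state <- init_particles(config, arena, mode = init,
                          pose = c(trajectory$x[1], trajectory$y[1],
                                   trajectory$heading[1]),
                          map = map, pos_jitter = init_pos_jitter,
                          head_jitter = init_head_jitter)
  set.seed(seed + 4000037L)
  res <- sifm_filter_cpp(
    cues$dphi, cues$lam, cues$obs_dist, cues$obs_hit, cues$obs_ang,
    cues$compass, cues$regime_code, cues$dt,
    bank$scale, axis_matrix(bank),
    bbank$d[bbank$dir_index == 1], bbank$sigma_rad[bbank$dir_index == 1],
    as.integer(bbank$range_class[bbank$dir_index == 1] == "short"),
    bbank$theta[bbank$dist_index == 1], bbank$sigma_theta[1],
    lattice$x0, lattice$y0, lattice$nx, lattice$ny, lattice$spacing,
    lattice$sigma_g, lattice$d_max,
    config$n_particles, config$comp_noise_sd, config$head_jitter_sd,
    config$sigma_e, config$ess_frac, config$resample == "always",
    config$resample_min_interval,
    config$learning_on, config$feedback_on, config$compass_kappa,
    match(config$rule, c("running_average", "delta")) - 1L, config$eta,
    state$z, state$psi, state$w,
    if (is.null(map)) NULL else map$W,
    if (is.null(map)) NULL else map$mass,
    as.integer(cells$module), as.matrix(cells[, c("off1", "off2", "off3")]),
    if (is.null(track_particles)) integer(0) else
      as.integer(track_particles),
    as.integer(track_module), c(0, 0, 0))
  learned <- lattice
  learned$W <- res$map_W
  learned$mass <- as.numeric(res$map_mass)
  out <- list(trajectory = trajectory, arena = arena, regime = regime,
              config = config, noise = noise, bank = bank, bbank = bbank,
              cells = cells, rates = res$grid_rates,
              bc_rates = res$bc_rates,
              track_rates = if (is.null(track_particles)) NULL
                            else res$track_rates,
              diagnostics = list(err = res$err_mean, ess = res$ess,
                                 decoded = res$decoded,
                                 psi_mean = res$psi_mean,
                                 n_resample = res$n_resample,
                                 n_degenerate = res$n_degenerate),
              map = learned, particles = list(z = res$z, psi = res$psi,
                                              w = res$w,
                                              best = res$best_particle),
              active_modules = bank$module, seed = seed,
              call = match.call())
  class(out) <- "sifm"
  out
}

#' @export
print.sifm <- function(x, ...) {
  S <- length(x$diagnostics$err)
  cat("<sifm> probabilistic grid/boundary SLAM fit\n")
  cat(sprintf("  arena: %s | regime: %s | %d particles | %d steps (%.1f min)\n",
              x$arena$kind, paste(unique(x$regime), collapse = "/"),
              x$config$n_particles, S,
              S * attr(x$trajectory, "dt") / 60))
  cat(sprintf("  learning %s, feedback %s | resampled %d times\n",
              if (x$config$learning_on) "on" else "off",
              if (x$config$feedback_on) "on" else "off",
              x$diagnostics$n_resample))
  cat(sprintf("  final mean prediction error %.4f\n",
              mean(utils::tail(x$diagnostics$err, 50))))
  invisible(x)
}

#' @export
summary.sifm <- function(object, ...) {
  d <- object$diagnostics
  tr <- object$trajectory
  derr <- sqrt((d$decoded[, 1] - tr$x[-1])^2 + (d$decoded[, 2] -
                                                  tr$y[-1])^2)
  out <- list(
    steps = length(d$err), dt = attr(tr, "dt"),
    decode_rmse = sqrt(mean(derr^2)),
    decode_rmse_last = sqrt(mean(utils::tail(derr, 300)^2)),
    mean_error = mean(d$err), ess = stats::quantile(d$ess, c(.1, .5, .9)),
    n_resample = d$n_resample, n_degenerate = d$n_degenerate,
    map_visited = mean(object$map$mass > 0))
  class(out) <- "summary.sifm"
  out
}

#' @export
print.summary.sifm <- function(x, ...) {
  cat(sprintf("steps %d (dt %.2f s): decode RMSE %.2f cm (last: %.2f)\n",
              x$steps, x$dt, x$decode_rmse, x$decode_rmse_last))
  cat(sprintf("mean boundary prediction error %.4f; ESS q10/50/90 = %s\n",
              x$mean_error, paste(round(x$ess, 1), collapse = "/")))
  cat(sprintf("resampled %d times; %d degeneracy events; %.0f%% map nodes visited\n",
              x$n_resample, x$n_degenerate, 100 * x$map_visited))
  invisible(x)
}

#' Predict boundary-code activity at new positions
#'
#' Reads the learned association map at the supplied positions (the
#' checkpointed highest-weight particle's map).
#'
#' @param object a `sifm` fit.
#' @param newdata n x 2 matrix of positions (cm); default the trajectory.
#' @param ... unused.
#' @return n x 228 matrix of predictive boundary-code activity.
#' @export
predict.sifm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- cbind(object$trajectory$x, object$trajectory$y)
  newdata <- rbind(newdata)
  t(apply(newdata, 1, function(p) predict_boundary(object$map, p)))
}

#' Per-step weighted boundary prediction error
#' @param object a `sifm` fit.
#' @param ... unused.
#' @export
residuals.sifm <- function(object, ...) object$diagnostics$err

#' Posterior-mean decoded positions
#' @param object a `sifm` fit.
#' @param ... unused.
#' @export
fitted.sifm <- function(object, ...) object$diagnostics$decoded

#' Learned association weights
#' @param object a `sifm` fit.
#' @param ... unused.
#' @return the lattice-by-boundary-cell weight matrix of the checkpoint
#'   map.
#' @export
coef.sifm <- function(object, ...) object$map$W

#' Simulate spike trains from the fitted rate series
#'
#' @param object a `sifm` fit.
#' @param nsim number of repetitions.
#' @param seed integer seed.
#' @param peak_rate peak firing rate (Hz) scaling the unit rates.
#' @param ... unused.
#' @return a list (length `nsim`) of lists of spike-time vectors, one per
#'   readout cell.
#' @export
simulate.sifm <- function(object, nsim = 1, seed = 1, peak_rate = 15, ...) {
  dt <- attr(object$trajectory, "dt")
  lapply(seq_len(nsim), function(i) {
    lapply(seq_len(nrow(object$rates)), function(g)
      poisson_spikes(object$rates[g, ], peak_rate = peak_rate, dt = dt,
                     seed = seed + 7919L * i + g))
  })
}

#' Plot a fitted session
#'
#' @param x a `sifm` fit.
#' @param type `"decoded"` (true vs decoded path), `"ratemap"` (rate map of
#'   one readout cell), `"error"` (prediction error and ESS traces) or
#'   `"map"` (visit mass of the learned map).
#' @param cell readout cell index for `type = "ratemap"`.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.sifm <- function(x, type = c("decoded", "ratemap", "error", "map"),
                      cell = 1, ...) {
  type <- match.arg(type)
  tr <- x$trajectory
  if (type == "decoded") {
    plot(tr$x, tr$y, type = "l", col = "grey70", asp = 1, xlab = "x (cm)",
         ylab = "y (cm)", ...)
    graphics::lines(x$diagnostics$decoded[, 1], x$diagnostics$decoded[, 2],
                    col = "firebrick")
    graphics::legend("topleft", c("true", "decoded"), lty = 1,
                     col = c("grey70", "firebrick"), bty = "n")
  } else if (type == "ratemap") {
    rm <- rate_map(x$rates[cell, ], tr, bbox = x$arena$bbox)
    plot(rm, ...)
  } else if (type == "error") {
    graphics::par(mfrow = c(2, 1))
    plot(x$diagnostics$err, type = "l", xlab = "step",
         ylab = "prediction error", ...)
    plot(x$diagnostics$ess, type = "l", xlab = "step", ylab = "ESS", ...)
    graphics::par(mfrow = c(1, 1))
  } else {
    m <- matrix(x$map$mass, x$map$nx, x$map$ny)
    graphics::image(x$map$x0 + (seq_len(x$map$nx) - 1) * x$map$spacing,
                    x$map$y0 + (seq_len(x$map$ny) - 1) * x$map$spacing,
                    m, asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                    main = "map visit mass", ...)
  }
  invisible(x)
}

#' Weight-averaged ensemble rates for arbitrary readout cells
#'
#' Computes the posterior (weight-averaged) activity of grid readout cells
#' from a final particle set, or returns the per-step ensemble rate series
#' recorded during fitting.
#'
#' @param fit a `sifm` fit.
#' @return matrix cells x steps of ensemble rates in [0, 1].
#' @export
ensemble_rates <- function(fit) fit$rates

#' Save / load a learned map checkpoint
#'
#' Checkpoints are written with `saveRDS` at run time (map weights, visit
#' mass and lattice geometry).
#'
#' @param fit a `sifm` fit (or an `association_map`).
#' @param path file path.
#' @export
save_checkpoint <- function(fit, path) {
  map <- if (inherits(fit, "sifm")) fit$map else fit
  saveRDS(map, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
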