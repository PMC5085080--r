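#' Build a bank of grid-scale modules
#'
#' Modules follow a geometric progression of spacings; each module has three
#' plane-wave axes nominally 60 degrees apart. `scale` is the wavelength
#' along each axis normal; the measured inter-peak spacing of the resulting
#' hexagonal pattern is `2 * scale / sqrt(3)`.
#'
#' @param n_modules number of modules.
#' @param base_scale smallest axis wavelength (cm).
#' @param ratio scale ratio between successive modules.
#' @param orientation shared grid orientation (rad).
#' @param irregular perturb axis directions with Gaussian jitter
#'   (SD `irregular_sd`), giving anisotropic but stable grids.
#' @param irregular_sd axis jitter SD (rad).
#' @param seed seed for the irregular perturbations.
#' @return data.frame with one row per module: scale, orientation, phi1-3.
#' @export
make_module_bank <- function(n_modules = 8, base_scale = 30, ratio = 1.42,
                             orientation = 0, irregular = FALSE,
                             irregular_sd = 0.2, seed = 1) {
  stopifnot(n_modules >= 1, base_scale > 0, ratio > 0)
  scales <- base_scale * ratio^(seq_len(n_modules) - 1)
  ax <- matrix(rep(orientation + (0:2) * pi / 3, each = n_modules),
               n_modules, 3)
  if (irregular) {
    set.seed(seed)
    ax <- ax + matrix(stats::rnorm(3 * n_modules, 0, irregular_sd),
                      n_modules, 3)
  }
  data.frame(module = seq_len(n_modules), scale = scales,
             orientation = orientation, phi1 = ax[, 1], phi2 = ax[, 2],
             phi3 = ax[, 3])
}

axis_matrix <- function(bank) {
  as.matrix(bank[, c("phi1", "phi2", "phi3")])
}

#' Grid phase state at a position
#'
#' Phases are the projections of position onto each module axis scaled by
#' the module wavenumber, wrapped to [0, 2pi).
#'
#' @param bank a module bank.
#' @param position numeric length 2 (cm).
#' @return matrix n_modules x 3 of wrapped phases (rad).
#' @export
grid_phase_state <- function(bank, position = c(0, 0)) {
  ax <- axis_matrix(bank)
  k <- 2 * pi / bank$scale
  p <- k * (cos(ax) * position[1] + sin(ax) * position[2])
  p %% (2 * pi)
}

#' Advance grid phases from a self-motion cue
#'
#' Integrates the noisy displacement along each module axis through the
#' estimated heading, and adds compensatory phase noise: one 2-D positional
#' jitter per call (per particle per step), projected onto every axis of
#' every module, so the jitter is fully correlated across modules within a
#' grid code.
#'
#' @param state phase matrix from [grid_phase_state()].
#' @param bank the module bank.
#' @param lam noisy linear displacement (cm).
#' @param heading_estimate heading estimate (rad).
#' @param comp_noise_sd compensatory positional noise (cm per sqrt-second).
#' @param dt time step (s).
#' @return updated phase matrix.
#' @export
advance_phase <- function(state, bank, lam, heading_estimate,
                          comp_noise_sd = 0, dt = 0.1) {
  ax <- axis_matrix(bank)
  k <- 2 * pi / bank$scale
  eps <- stats::rnorm(2, 0, comp_noise_sd * sqrt(dt))
  dx <- lam * cos(heading_estimate) + eps[1]
  dy <- lam * sin(heading_estimate) + eps[2]
  (state + k * (cos(ax) * dx + sin(ax) * dy)) %% (2 * pi)
}

#' Grid cell activity from a phase state
#'
#' The rectified three-oscillator interference envelope:
#' `f = prod_j max(0, cos(p_j + psi_j))`, in [0, 1].
#'
#' @param state phase matrix.
#' @param cell list with `module` (index) and `offsets` (length-3 phase
#'   offsets, rad).
#' @return scalar rate in [0, 1].
#' @export
grid_activity <- function(state, cell) {
  p <- state[cell$module, ] + cell$offsets
  prod(pmax(0, cos(p)))
}

#' Sample grid readout cells of one module
#'
#' Each cell's three phase offsets derive from a single 2-D spatial offset
#' (uniform over the module's unit cell), so every cell is a translated copy
#' of the module pattern.
#'
#' @param bank module bank.
#' @param n_cells number of cells.
#' @param module module index.
#' @param seed seed.
#' @return data.frame: cell, module, off1-3, x0, y0.
#' @export
make_grid_cells <- function(bank, n_cells, module = 1, seed = 1) {
  set.seed(seed)
  lam <- bank$scale[module]
  ax <- axis_matrix(bank)[module, ]
  x0 <- stats::runif(n_cells, 0, 2 * lam)
  y0 <- stats::runif(n_cells, 0, 2 * lam)
  k <- 2 * pi / lam
  off <- -k * (outer(x0, cos(ax)) + outer(y0, sin(ax)))
  data.frame(cell = seq_len(n_cells), module = module,
             off1 = off[, 1] %% (2 * pi), off2 = off[, 2] %% (2 * pi),
             off3 = off[, 3] %% (2 * pi), x0 = x0, y0 = y0)
}

#' Decode a nominal position from grid phases
#'
#' Least-squares inversion of the wrapped axis phases: a coarse grid search
#' over the arena (phase-likelihood surface) followed by Gauss-Newton
#' refinement on wrapped residuals. With modules spanning at least the
#' arena, the decode is unique within the arena; with a reduced module
#' subset the solution is ambiguous modulo the remaining lattice and the
#' canonical (search-region) representative is returned with a flag.
#'
#' @param state phase matrix.
#' @param bank module bank.
#' @param modules module subset to use (default all).
#' @param bbox search region c(xmin, xmax, ymin, ymax).
#' @param coarse coarse search step (cm).
#' @return list: `position`, `ambiguous`, `aliases` (matrix of near-optimal
#'   candidates), `residual` (rad RMS).
#' @export
phase_to_nominal_position <- function(state, bank, modules = NULL,
                                      bbox = c(0, 100, 0, 100),
                                      coarse = 2) {
  if (is.null(modules)) modules <- bank$module
  stopifnot(length(modules) >= 1)
  ax <- axis_matrix(bank)[modules, , drop = FALSE]
  k <- 2 * pi / bank$scale[modules]
  ph <- state[modules, , drop = FALSE]
  ux <- cos(ax); uy <- sin(ax)
  xs <- seq(bbox[1], bbox[2], by = coarse)
  ys <- seq(bbox[3], bbox[4], by = coarse)
  # phase-likelihood: sum of cos(phase residual) over axes
  score <- matrix(0, length(xs), length(ys))
  for (m in seq_along(modules))
    for (j in 1:3) {
      proj <- outer(xs * ux[m, j], rep(1, length(ys))) +
        outer(rep(1, length(xs)), ys * uy[m, j])
      score <- score + cos(k[m] * proj - ph[m, j])
    }
  refine <- function(x0) {
    x <- x0
    for (it in 1:30) {
      r <- c(); Jx <- c(); Jy <- c()
      for (m in seq_along(modules))
        for (j in 1:3) {
          res <- wrap_angle(k[m] * (x[1] * ux[m, j] + x[2] * uy[m, j]) -
                              ph[m, j])
          r <- c(r, res); Jx <- c(Jx, k[m] * ux[m, j])
          Jy <- c(Jy, k[m] * uy[m, j])
        }
      J <- cbind(Jx, Jy)
      step <- tryCatch(solve(crossprod(J), crossprod(J, -r)),
                       error = function(e) matrix(0, 2, 1))
      x <- x + as.numeric(step)
      if (sqrt(sum(step^2)) < 1e-10) break
    }
    res <- c()
    for (m in seq_along(modules))
      for (j in 1:3)
        res <- c(res, wrap_angle(k[m] * (x[1] * ux[m, j] +
                                           x[2] * uy[m, j]) - ph[m, j]))
    list(x = x, rms = sqrt(mean(res^2)))
  }
  best_idx <- which(score == max(score), arr.ind = TRUE)[1, ]
  best <- refine(c(xs[best_idx[1]], ys[best_idx[2]]))
  # aliases: all local optima within tolerance of the best residual
  thr <- max(score) - 0.05 * 3 * length(modules)
  cand <- which(score >= thr, arr.ind = TRUE)
  aliases <- NULL
  if (nrow(cand) > 1) {
    pts <- cbind(xs[cand[, 1]], ys[cand[, 2]])
    keep <- rep(TRUE, nrow(pts))
    sols <- list()
    for (i in seq_len(nrow(pts))) {
      if (!keep[i]) next
      s <- refine(pts[i, ])
      if (s$rms < best$rms + 1e-3) {
        dup <- vapply(sols, function(q) sqrt(sum((q - s$x)^2)) < coarse,
                      logical(1))
        if (!any(dup)) sols[[length(sols) + 1]] <- s$x
      }
      d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
      keep[d2 < (2 * coarse)^2] <- FALSE
    }
    if (length(sols) > 1) aliases <- do.call(rbind, sols)
  }
  flagged <- best$rms > 0.5
  list(position = best$x, ambiguous = !is.null(aliases) || flagged,
       aliases = aliases, residual = best$rms)
}
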