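#' Fit a regular grid template to an autocorrelogram
#'
#' Least-squares fit of a two-basis-vector lattice to the inner
#' autocorrelogram peaks. Returns the axis wavelengths (measured inter-peak
#' spacings) `lambda1`, `lambda2`, the grid orientation `theta` (angle of
#' the first basis vector) and the relative axis angle `psi`.
#'
#' @param ac an `autocorrelogram`.
#' @param min_peaks minimum number of inner peaks required.
#' @return list of class `grid_params`: lambda1, lambda2, theta, psi,
#'   basis (2 x 2), peaks.
#' @export
fit_grid_template <- function(ac, min_peaks = 4) {
  peaks <- acorr_peaks(ac, n_keep = 6)
  if (is.null(peaks) || nrow(peaks) < min_peaks)
    stop("insufficient autocorrelogram peaks for template fit")
  P <- peaks[, 1:2, drop = FALSE]
  # collapse point symmetry: representative directions in [0, pi)
  ang <- atan2(P[, 2], P[, 1]) %% pi
  ord <- order(ang)
  ang_s <- ang[ord]
  # cluster into (up to) 3 axis directions
  brk <- which(diff(ang_s) > pi / 6)
  grp <- cumsum(c(1, seq_along(ang_s)[-1] %in% (brk + 1)))
  # merge wrap-around cluster (near 0 and near pi are the same axis)
  if (max(grp) > 1 && (ang_s[length(ang_s)] - ang_s[1]) > pi - pi / 6)
    grp[grp == max(grp)] <- 1
  dirs <- vapply(unique(grp), function(g) {
    a <- ang_s[grp == g]
    stats::median(a)
  }, numeric(1))
  dirs <- sort(dirs %% pi)
  if (length(dirs) < 2)
    stop("insufficient distinct peak directions for template fit")
  axis_of <- function(a) dirs[which.min(pmin(abs(a - dirs),
                                             pi - abs(a - dirs)))]
  b_init <- function(d) {
    sel <- vapply(ang, function(a) isTRUE(all.equal(axis_of(a), d)),
                  logical(1))
    v <- P[sel, , drop = FALSE]
    # orient along +direction
    sgn <- ifelse(v[, 1] * cos(d) + v[, 2] * sin(d) < 0, -1, 1)
    colMeans(v * sgn)
  }
  b1 <- b_init(dirs[1]); b2 <- b_init(dirs[2])
  # integer lattice coordinates of each peak, then linear LS for the basis
  B <- rbind(b1, b2)
  NN <- t(apply(P, 1, function(p)
    round(solve(t(B), p))))
  keep <- rowSums(abs(NN)) > 0
  NN <- NN[keep, , drop = FALSE]; Pk <- P[keep, , drop = FALSE]
  Bfit <- tryCatch(solve(crossprod(NN), crossprod(NN, Pk)),
                   error = function(e) B)
  b1 <- Bfit[1, ]; b2 <- Bfit[2, ]
  if (atan2(b1[2], b1[1]) %% pi > atan2(b2[2], b2[1]) %% pi) {
    tmp <- b1; b1 <- b2; b2 <- tmp
  }
  psi <- acos(sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2)))
  structure(list(lambda1 = sqrt(sum(b1^2)), lambda2 = sqrt(sum(b2^2)),
                 theta = atan2(b1[2], b1[1]),
                 psi = psi, basis = rbind(b1, b2), peaks = peaks),
            class = "grid_params")
}

#' @export
print.grid_params <- function(x, ...) {
  cat(sprintf("<grid_params> lambda1 %.1f cm, lambda2 %.1f cm, theta %.1f deg, psi %.1f deg\n",
              x$lambda1, x$lambda2, 180 / pi * x$theta, 180 / pi * x$psi))
  invisible(x)
}

# three-axis plane-wave template from a lattice basis: reciprocal vectors
template_axes <- function(params) {
  B <- params$basis
  K <- 2 * pi * t(solve(B))          # reciprocal basis (rows k1, k2)
  rbind(K[1, ], K[2, ], -(K[1, ] + K[2, ]))
}

grid_template_map <- function(params, phase, xs, ys) {
  K <- template_axes(params)
  f <- matrix(1, length(xs), length(ys))
  for (j in 1:3) {
    ph <- outer(xs * K[j, 1], ys * K[j, 2], "+") - phase[j]
    f <- f * pmax(0, cos(ph))
  }
  f
}

#' Fit the 2-D phase offset of a rate map given grid parameters
#'
#' Grid search over the lattice unit cell followed by local refinement,
#' maximizing the Pearson correlation between the rate map and an ideal
#' interference template.
#'
#' @param rm a `rate_map`.
#' @param params a `grid_params` fit.
#' @return list: `offset` (cm, position of a field peak modulo the
#'   lattice), `phase` (normalized phases along the two basis vectors, in
#'   [0, 1)), `r` (achieved correlation).
#' @export
fit_grid_phase <- function(rm, params) {
  m <- rm$rate
  ok <- is.finite(m)
  xs <- rm$bbox[1] + (seq_len(nrow(m)) - 0.5) * rm$bin
  ys <- rm$bbox[3] + (seq_len(ncol(m)) - 0.5) * rm$bin
  K <- template_axes(params)
  obj <- function(off) {
    f <- matrix(1, length(xs), length(ys))
    for (j in 1:3) {
      ph <- outer((xs - off[1]) * K[j, 1], (ys - off[2]) * K[j, 2], "+")
      f <- f * pmax(0, cos(ph))
    }
    suppressWarnings(stats::cor(f[ok], m[ok]))
  }
  B <- params$basis
  fr <- seq(0, 0.95, by = 0.05)
  grid <- expand.grid(a = fr, b = fr)
  cand <- as.matrix(grid) %*% B
  vals <- apply(cand, 1, obj)
  best <- cand[which.max(vals), ]
  op <- stats::optim(best, function(o) -obj(o), method = "Nelder-Mead",
                     control = list(maxit = 200))
  off <- op$par
  ph <- as.numeric(solve(t(B), off))   # lattice coordinates of the offset
  list(offset = off, phase = ph %% 1, r = -op$value)
}

#' Grid rescaling magnitude along an axis
#'
#' Matches the inner autocorrelogram peaks of a test session to those of a
#' reference session by direction and returns the least-squares ratio of
#' their coordinates projected on the named axis (1.0 = no rescaling; the
#' arena ratio = full rescaling).
#'
#' @param ac_test,ac_ref `autocorrelogram` objects.
#' @param axis `"h"` (horizontal) or `"v"` (vertical).
#' @return scale ratio (test / reference).
#' @export
rescaling_magnitude <- function(ac_test, ac_ref, axis = c("h", "v")) {
  axis <- match.arg(axis)
  pt <- acorr_peaks(ac_test); pr <- acorr_peaks(ac_ref)
  if (is.null(pt) || is.null(pr) || nrow(pt) < 4 || nrow(pr) < 4)
    stop("template fit failure: insufficient peaks")
  # match test peaks to reference peaks by angle
  at <- atan2(pt[, 2], pt[, 1]); ar <- atan2(pr[, 2], pr[, 1])
  comp <- if (axis == "h") 1 else 2
  num <- 0; den <- 0
  for (i in seq_len(nrow(pr))) {
    dd <- abs(wrap_angle(at - ar[i]))
    j <- which.min(dd)
    if (dd[j] > pi / 6) next
    num <- num + pt[j, comp] * pr[i, comp]
    den <- den + pr[i, comp]^2
  }
  if (den < 1e-6) stop("reference peaks carry no component on this axis")
  num / den
}

#' Grid phase drift between recall trials
#'
#' Compares normalized grid phases (lattice coordinates in [0, 1)) of
#' phase-matched cells across two independent recall trials. Within-cell
#' drift is each cell's wrapped phase change; between-cell drift is the
#' change of pairwise phase offsets.
#'
#' @param phases1,phases2 cells x 2 matrices of normalized phases.
#' @param max_pairs maximum number of cell pairs sampled.
#' @param seed seed for pair sampling.
#' @return list with `within` and `between` drift-magnitude vectors
#'   (normalized units, in [0, sqrt(2)/2]).
#' @export
phase_drift <- function(phases1, phases2, max_pairs = 2000, seed = 1) {
  stopifnot(all(dim(phases1) == dim(phases2)))
  wrap01 <- function(x) {
    y <- x %% 1
    ifelse(y > 0.5, y - 1, y)
  }
  dwithin <- wrap01(phases2 - phases1)
  within <- sqrt(rowSums(dwithin^2))
  n <- nrow(phases1)
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[, sample(ncol(pairs), max_pairs)]
  }
  off1 <- wrap01(phases1[pairs[1, ], , drop = FALSE] -
                   phases1[pairs[2, ], , drop = FALSE])
  off2 <- wrap01(phases2[pairs[1, ], , drop = FALSE] -
                   phases2[pairs[2, ], , drop = FALSE])
  doff <- wrap01(off2 - off1)
  between <- sqrt(rowSums(doff^2))
  list(within = within, between = between)
}

#' Distance of a boundary field from its wall
#'
#' Center of mass of bins firing above the map mean, measured along the
#' tuning direction to the perimeter.
#'
#' @param rm a `rate_map`.
#' @param direction allocentric tuning direction (rad).
#' @param arena the `arena_spec`.
#' @return distance (cm) from the wall the tuning direction points at.
#' @export
boundary_field_distance <- function(rm, direction, arena) {
  m <- rm$rate
  mu <- mean(m, na.rm = TRUE)
  sel <- which(is.finite(m) & m > mu, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("no bins above the mean rate")
  w <- m[sel]
  cx <- rm$bbox[1] + (sel[, 1] - 0.5) * rm$bin
  cy <- rm$bbox[3] + (sel[, 2] - 0.5) * rm$bin
  com <- c(sum(cx * w), sum(cy * w)) / sum(w)
  g <- arena_geom(arena)
  d <- raycast_cpp(g, com[1], com[2], direction, 0L, Inf)[1, 1]
  as.numeric(d)
}

#' Arm-by-arm rate vector correlation matrix
#'
#' For each corridor arm, the occupancy-weighted mean rate in bins along
#' the arm axis (default 10 cm), restricted to one global running
#' direction; the matrix holds pairwise Pearson correlations between arm
#' vectors. Supply a matrix of rates (cells x steps) to obtain the
#' population version (concatenated cell vectors).
#'
#' @param rates numeric vector (one cell) or matrix cells x steps, aligned
#'   to `trajectory` samples (length n or n - 1).
#' @param trajectory a corridor `sifm_trajectory` with arm tags.
#' @param spec the corridor `arena_spec`.
#' @param direction `"E"`, `"W"` or `"all"`.
#' @param bin bin length along the arm axis (cm).
#' @return list: `r` (arm x arm correlation matrix), `vectors` (bins*cells
#'   x arms), `arms`.
#' @export
arm_correlation_matrix <- function(rates, trajectory, spec,
                                   direction = c("all", "E", "W"),
                                   bin = 10) {
  direction <- match.arg(direction)
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  n <- nrow(trajectory)
  use <- if (ncol(rates) == n) seq_len(n) else seq(n - ncol(rates) + 1, n)
  tr <- trajectory[use, ]
  sel <- !is.na(tr$arm)
  if (direction != "all") sel <- sel & tr$global_dir == direction
  cl <- spec$centerline
  n_arms <- cl$n_arms
  # bin along each arm's own axis (vertical arms by y, horizontal by x)
  arm_vert <- vapply(seq_len(n_arms), function(a) {
    segs <- which(cl$arm == a)
    if (length(segs) == 0) TRUE else cl$vertical[segs[1]]
  }, logical(1))
  lim <- range(cl$waypoints)
  nb <- max(1, ceiling(diff(lim) / bin))
  yb <- pmin(nb, pmax(1, floor((tr$y - lim[1]) / bin) + 1))
  xb <- pmin(nb, pmax(1, floor((tr$x - lim[1]) / bin) + 1))
  vecs <- matrix(NA_real_, nb * nrow(rates), n_arms)
  for (a in seq_len(n_arms)) {
    ab <- if (arm_vert[a]) yb else xb
    for (g in seq_len(nrow(rates))) {
      for (b in seq_len(nb)) {
        idx <- which(sel & tr$arm == a & ab == b)
        vecs[(g - 1) * nb + b, a] <-
          if (length(idx) > 0) mean(rates[g, idx]) else NA_real_
      }
    }
  }
  r <- suppressWarnings(stats::cor(vecs, use = "pairwise.complete.obs"))
  list(r = r, vectors = vecs, arms = seq_len(n_arms))
}

#' Attractor diagnostics of ensemble activity
#'
#' Distance from the attractor: the norm of the component of the joint
#' activity vector orthogonal to the all-ones direction (zero when all
#' phase-matched cells agree), boxcar-smoothed. Pairwise Pearson
#' correlations are computed in sliding windows.
#'
#' @param act matrix cells x time of activity.
#' @param dt sampling interval (s).
#' @param smooth_s boxcar width for d(t) (s).
#' @param window_s sliding correlation window (s).
#' @param step_s window step (s).
#' @return list: `t`, `d`, `win_t`, `mean_r` (mean pairwise correlation per
#'   window; NA where activity is constant).
#' @export
attractor_distance <- function(act, dt, smooth_s = 10, window_s = 60,
                               step_s = 10) {
  stopifnot(nrow(act) >= 2)
  Tn <- ncol(act)
  dev <- sweep(act, 2, colMeans(act))
  d <- sqrt(colSums(dev^2))
  k <- max(1, round(smooth_s / dt))
  ds <- stats::filter(d, rep(1 / k, k), sides = 2)
  win <- max(2, round(window_s / dt))
  stp <- max(1, round(step_s / dt))
  starts <- seq(1, Tn - win + 1, by = stp)
  mean_r <- vapply(starts, function(s) {
    a <- act[, s:(s + win - 1), drop = FALSE]
    sds <- apply(a, 1, stats::sd)
    keep <- sds > 1e-10
    if (sum(keep) < 2) return(NA_real_)
    cm <- suppressWarnings(stats::cor(t(a[keep, , drop = FALSE])))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }, numeric(1))
  list(t = (seq_len(Tn) - 1) * dt, d = as.numeric(ds),
       win_t = (starts - 1) * dt + window_s / 2, mean_r = mean_r)
}

#' Spike-triggered dynamic rate map
#'
#' Accumulates occupancy and spikes in displacement coordinates relative to
#' each spike (path-integrated within a time window), revealing spatial
#' regularity that drifts in world coordinates.
#'
#' @param spikes spike times (s).
#' @param trajectory a `sifm_trajectory`.
#' @param window half-window (s).
#' @param bin displacement bin (cm).
#' @param extent half-extent of the displacement map (cm).
#' @param min_spikes minimum number of spikes.
#' @return a `rate_map` in displacement coordinates (Hz).
#' @export
dynamic_rate_map <- function(spikes, trajectory, window = 10, bin = 2,
                             extent = 50, min_spikes = 100) {
  if (length(spikes) < min_spikes) stop("too few spikes")
  dt <- attr(trajectory, "dt")
  n <- nrow(trajectory)
  nb <- 2 * ceiling(extent / bin) + 1
  occ <- matrix(0, nb, nb); cnt <- matrix(0, nb, nb)
  c0 <- ceiling(extent / bin) + 1
  si <- pmin(n, pmax(1, floor(spikes / dt) + 1))
  wsteps <- round(window / dt)
  spike_step <- si
  for (k in seq_along(si)) {
    i <- si[k]
    rng <- max(1, i - wsteps):min(n, i + wsteps)
    dx <- trajectory$x[rng] - trajectory$x[i]
    dy <- trajectory$y[rng] - trajectory$y[i]
    bx <- round(dx / bin) + c0; by <- round(dy / bin) + c0
    ok <- bx >= 1 & bx <= nb & by >= 1 & by <= nb
    for (q in which(ok)) occ[bx[q], by[q]] <- occ[bx[q], by[q]] + dt
    # other spikes within the window, at their displacement
    near <- which(abs(spike_step - i) <= wsteps)
    dxs <- trajectory$x[si[near]] - trajectory$x[i]
    dys <- trajectory$y[si[near]] - trajectory$y[i]
    bxs <- round(dxs / bin) + c0; bys <- round(dys / bin) + c0
    oks <- bxs >= 1 & bxs <= nb & bys >= 1 & bys <= nb
    for (q in which(oks)) cnt[bxs[q], bys[q]] <- cnt[bxs[q], bys[q]] + 1
  }
  raw <- ifelse(occ > 0.1, cnt / pmax(occ, 1e-12), NA_real_)
  sm <- smooth_masked_cpp(raw, 1)
  structure(list(rate = sm, raw = raw, occupancy = occ, bin = bin,
                 bbox = c(-extent, extent, -extent, extent),
                 smoothing = bin), class = "rate_map")
}
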