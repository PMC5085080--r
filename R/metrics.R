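#' Occupancy-normalized firing rate map
#'
#' Bins a rate series (or spike train) over position, divides by occupancy
#' time, masks bins below the occupancy threshold and smooths with a
#' masked Gaussian kernel.
#'
#' @param rates per-sample rate series; length `nrow(trajectory)` or
#'   `nrow(trajectory) - 1` (aligned to post-step samples). Ignored when
#'   `spikes` is given.
#' @param trajectory a `sifm_trajectory`.
#' @param bin bin size (cm).
#' @param smoothing Gaussian smoothing SD (cm); 0 disables.
#' @param occupancy_min minimum occupancy (s) for a valid bin.
#' @param bbox arena bounding box c(xmin, xmax, ymin, ymax); default from
#'   the trajectory extent.
#' @param spikes optional spike-time vector (s); the map is then in Hz.
#' @return object of class `rate_map`: smoothed `rate`, `raw`,
#'   `occupancy`, bin geometry.
#' @export
rate_map <- function(rates = NULL, trajectory, bin = 2, smoothing = 2,
                     occupancy_min = 0.1, bbox = NULL, spikes = NULL) {
  dt <- attr(trajectory, "dt")
  n <- nrow(trajectory)
  if (n < 2) stop("empty trajectory")
  if (is.null(bbox))
    bbox <- c(floor(min(trajectory$x)), ceiling(max(trajectory$x)),
              floor(min(trajectory$y)), ceiling(max(trajectory$y)))
  nx <- max(1, ceiling((bbox[2] - bbox[1]) / bin))
  ny <- max(1, ceiling((bbox[4] - bbox[3]) / bin))
  if (!is.null(spikes)) {
    idx <- pmin(n, pmax(1, floor(spikes / dt) + 1))
    sx <- trajectory$x[idx]; sy <- trajectory$y[idx]
    bxs <- pmin(nx, pmax(1, floor((sx - bbox[1]) / bin) + 1))
    bys <- pmin(ny, pmax(1, floor((sy - bbox[3]) / bin) + 1))
    cnt <- matrix(0, nx, ny)
    for (i in seq_along(bxs)) cnt[bxs[i], bys[i]] <- cnt[bxs[i], bys[i]] + 1
    bx <- pmin(nx, pmax(1, floor((trajectory$x - bbox[1]) / bin) + 1))
    by <- pmin(ny, pmax(1, floor((trajectory$y - bbox[3]) / bin) + 1))
    occ <- bin_rates_cpp(bx, by, rep(1, n), dt, nx, ny)$occ
    raw <- ifelse(occ >= occupancy_min, cnt / pmax(occ, 1e-12), NA_real_)
  } else {
    use <- if (length(rates) == n) seq_len(n) else seq(n - length(rates) + 1,
                                                       n)
    stopifnot(length(rates) == length(use))
    bx <- pmin(nx, pmax(1, floor((trajectory$x[use] - bbox[1]) / bin) + 1))
    by <- pmin(ny, pmax(1, floor((trajectory$y[use] - bbox[3]) / bin) + 1))
    acc <- bin_rates_cpp(bx, by, rates, dt, nx, ny)
    occ <- acc$occ
    raw <- ifelse(occ >= occupancy_min, acc$num / pmax(occ, 1e-12),
                  NA_real_)
  }
  sm <- if (smoothing > 0) smooth_masked_cpp(raw, smoothing / bin) else raw
  structure(list(rate = sm, raw = raw, occupancy = occ, bin = bin,
                 bbox = bbox, smoothing = smoothing), class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins of %.1f cm; peak %.3f; %.0f%% valid\n",
              nrow(x$rate), ncol(x$rate), x$bin,
              suppressWarnings(max(x$rate, na.rm = TRUE)),
              100 * mean(is.finite(x$rate))))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, main = "rate map", ...) {
  xs <- x$bbox[1] + (seq_len(nrow(x$rate)) - 0.5) * x$bin
  ys <- x$bbox[3] + (seq_len(ncol(x$rate)) - 0.5) * x$bin
  graphics::image(xs, ys, x$rate, asp = 1, xlab = "x (cm)",
                  ylab = "y (cm)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of overlapping valid bins at every 2-D lag.
#'
#' @param rm a `rate_map` (or a plain matrix with NA for invalid bins).
#' @param max_lag maximum lag (cm); default 80% of the map extent.
#' @param min_overlap minimum number of overlapping valid bins per lag.
#' @return object of class `autocorrelogram` (matrix plus bin size).
#' @export
autocorrelogram <- function(rm, max_lag = NULL, min_overlap = 20) {
  m <- if (inherits(rm, "rate_map")) rm$rate else rm
  bin <- if (inherits(rm, "rate_map")) rm$bin else 1
  if (all(!is.finite(m))) stop("all bins masked")
  if (is.null(max_lag)) max_lag <- 0.8 * max(dim(m)) * bin
  L <- min(max(dim(m)) - 1, ceiling(max_lag / bin))
  ac <- autocorr_cpp(m, L, min_overlap)
  structure(list(ac = ac, bin = bin, max_lag = L), class = "autocorrelogram")
}

#' @export
plot.autocorrelogram <- function(x, main = "autocorrelogram", ...) {
  L <- x$max_lag
  lag <- (-L:L) * x$bin
  graphics::image(lag, lag, x$ac, asp = 1, xlab = "lag (cm)",
                  ylab = "lag (cm)", main = main,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  zlim = c(-1, 1), ...)
  invisible(x)
}

# ring-averaged radial profile and estimated central-field radius (bins)
acorr_central_radius <- function(ac) {
  L <- ac$max_lag
  idx <- as.matrix(expand.grid(i = -L:L, j = -L:L))
  r <- sqrt(idx[, 1]^2 + idx[, 2]^2)
  v <- as.numeric(ac$ac)
  prof <- vapply(1:L, function(k)
    mean(v[r >= k - 0.5 & r < k + 0.5], na.rm = TRUE), numeric(1))
  r0 <- which(prof < 0.25)[1]
  if (is.na(r0)) {
    dpr <- diff(prof)
    r0 <- which(dpr > 0)[1] # first local minimum
    if (is.na(r0)) r0 <- max(2, floor(L / 4))
  }
  max(2, r0)
}

# local maxima of the autocorrelogram outside the central field, with
# quadratic sub-bin refinement; returns peak coordinates in cm
acorr_peaks <- function(ac, min_value = 0.1, n_keep = 6) {
  m <- ac$ac
  L <- ac$max_lag
  r0 <- acorr_central_radius(ac)
  nr <- nrow(m)
  pk <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nr - 1)) {
    v <- m[i, j]
    if (!is.finite(v) || v < min_value) next
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (any(!is.finite(nb))) next
    if (v < max(nb)) next
    if (sum(nb == v) > 2) next # plateau
    di <- i - (L + 1); dj <- j - (L + 1)
    if (di^2 + dj^2 <= r0^2) next
    # 1-D quadratic refinement in each direction
    ox <- 0.5 * (m[i - 1, j] - m[i + 1, j]) /
      (m[i - 1, j] - 2 * v + m[i + 1, j])
    oy <- 0.5 * (m[i, j - 1] - m[i, j + 1]) /
      (m[i, j - 1] - 2 * v + m[i, j + 1])
    if (!is.finite(ox) || abs(ox) > 1) ox <- 0
    if (!is.finite(oy) || abs(oy) > 1) oy <- 0
    pk <- rbind(pk, c(di + ox, dj + oy, v))
  }
  if (is.null(pk)) return(NULL)
  d <- sqrt(pk[, 1]^2 + pk[, 2]^2)
  pk <- pk[order(d), , drop = FALSE]
  utils::head(pk, n_keep) * c(ac$bin, ac$bin, 1)[col(utils::head(pk,
                                                                 n_keep))]
}

# bilinear interpolation from a matrix (NA outside / at invalid bins)
bilinear <- function(m, xi, yi) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 1 & x0 <= nr - 1 & y0 >= 1 & y0 <= nc - 1
  out <- rep(NA_real_, length(xi))
  i <- which(ok)
  v00 <- m[cbind(x0[i], y0[i])]; v10 <- m[cbind(x0[i] + 1, y0[i])]
  v01 <- m[cbind(x0[i], y0[i] + 1)]; v11 <- m[cbind(x0[i] + 1, y0[i] + 1)]
  out[i] <- (1 - fx[i]) * (1 - fy[i]) * v00 + fx[i] * (1 - fy[i]) * v10 +
    (1 - fx[i]) * fy[i] * v01 + fx[i] * fy[i] * v11
  out
}

#' Gridness index of an autocorrelogram
#'
#' Rotational-symmetry score over an annulus excluding the central peak:
#' `g = min(r60, r120) - max(r30, r90, r150)` where `r_a` is the Pearson
#' correlation between the annulus and its rotation by `a` degrees. Four
#' variants: (1) fixed annulus, (2) maximum over expanding annuli, (3) and
#' (4) the same after an elliptical correction fitted to the six inner
#' peaks.
#'
#' @param ac an `autocorrelogram`.
#' @param variant 1 to 4.
#' @return gridness (NA when the annulus cannot be formed), with the inner
#'   peaks as attribute `peaks`.
#' @export
gridness <- function(ac, variant = 2) {
  stopifnot(variant %in% 1:4)
  m <- ac$ac
  L <- ac$max_lag
  r0 <- acorr_central_radius(ac)
  peaks <- acorr_peaks(ac)
  transform <- diag(2)
  if (variant >= 3 && !is.null(peaks) && nrow(peaks) >= 5) {
    # least-squares ellipse through the inner peaks -> circularizing map
    P <- peaks[, 1:2] / ac$bin
    A <- cbind(P[, 1]^2, P[, 1] * P[, 2], P[, 2]^2)
    cf <- tryCatch(as.numeric(solve(crossprod(A), crossprod(A, rep(1,
      nrow(P))))), error = function(e) NULL)
    if (!is.null(cf)) {
      Q <- matrix(c(cf[1], cf[2] / 2, cf[2] / 2, cf[3]), 2)
      ei <- eigen(Q, symmetric = TRUE)
      if (all(ei$values > 0)) {
        S <- ei$vectors %*% diag(sqrt(ei$values / mean(ei$values))) %*%
          t(ei$vectors)
        transform <- S # maps ellipse toward circle
      }
    }
  }
  rot_corr <- function(r_in, r_out) {
    idx <- as.matrix(expand.grid(i = -L:L, j = -L:L))
    rr <- sqrt(rowSums((idx %*% t(transform))^2))
    sel <- rr > r_in & rr <= r_out
    pts <- idx[sel, , drop = FALSE]
    base <- m[cbind(pts[, 1] + L + 1, pts[, 2] + L + 1)]
    sapply(c(30, 60, 90, 120, 150), function(a) {
      th <- a * pi / 180
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      rp <- pts %*% Rm
      v <- bilinear(m, rp[, 1] + L + 1, rp[, 2] + L + 1)
      ok <- is.finite(base) & is.finite(v)
      if (sum(ok) < 20) return(NA_real_)
      stats::cor(base[ok], v[ok])
    })
  }
  gr <- function(rc) {
    if (any(!is.finite(rc))) return(NA_real_)
    min(rc[2], rc[4]) - max(rc[1], rc[3], rc[5])
  }
  peak_d <- if (!is.null(peaks)) stats::median(sqrt(peaks[, 1]^2 +
                                                      peaks[, 2]^2)) / ac$bin
            else NA_real_
  if (variant %in% c(1, 3)) {
    r_out <- if (is.finite(peak_d)) min(L - 1, 1.25 * peak_d)
             else min(L - 1, 3 * r0)
    g <- gr(rot_corr(r0, r_out))
  } else {
    outs <- seq(r0 + 3, L - 1, by = 2)
    if (length(outs) == 0) return(structure(NA_real_, peaks = peaks))
    gs <- vapply(outs, function(ro) gr(rot_corr(r0, ro)), numeric(1))
    g <- if (all(is.na(gs))) NA_real_ else max(gs, na.rm = TRUE)
  }
  structure(g, peaks = peaks)
}

#' Border score of a rate map
#'
#' `b = (cM - dm) / (cM + dm)` where `cM` is the maximal fraction of a
#' single wall covered by one firing field and `dm` the rate-weighted mean
#' distance of field bins to the nearest wall, normalized by half the
#' shorter arena side (the radius for circular arenas).
#'
#' @param rm a `rate_map`.
#' @param arena optional `arena_spec` (circular arenas treat the perimeter
#'   as a single wall).
#' @param field_threshold field threshold as a fraction of the peak rate.
#' @param min_area minimum field area (cm^2).
#' @return border score in [-1, 1], or NA when no field exists.
#' @export
border_score <- function(rm, arena = NULL, field_threshold = 0.3,
                         min_area = 200) {
  m <- rm$rate
  nx <- nrow(m); ny <- ncol(m)
  peak <- suppressWarnings(max(m, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  above <- is.finite(m) & m >= field_threshold * peak
  lab <- label_components(above)
  min_bins <- max(1, round(min_area / rm$bin^2))
  sizes <- table(lab[lab > 0])
  fields <- as.integer(names(sizes)[sizes >= min_bins])
  if (length(fields) == 0) return(NA_real_)
  circle <- !is.null(arena) && !is.null(arena$circle)
  valid <- is.finite(m)
  if (circle) {
    # four quadrant arcs stand for the walls (a full-perimeter "wall"
    # would cap the coverage of any directionally tuned field near 1/4)
    cx <- (arena$circle$cx - rm$bbox[1]) / rm$bin + 0.5
    cy <- (arena$circle$cy - rm$bbox[3]) / rm$bin + 0.5
    R <- arena$circle$radius / rm$bin
    ii <- row(m); jj <- col(m)
    rr <- sqrt((ii - cx)^2 + (jj - cy)^2)
    aa <- atan2(jj - cy, ii - cx)
    ring <- valid & rr > R - 1.5
    wall_bins <- lapply(c(-pi, -pi / 2, 0, pi / 2), function(a0)
      which(ring & aa >= a0 & aa < a0 + pi / 2))
    dist_wall <- (R - rr) * rm$bin
    norm <- arena$circle$radius
  } else {
    # outermost valid rows / columns stand for the four walls
    ii <- row(m); jj <- col(m)
    wall_bins <- list(which(valid & ii <= 2), which(valid & ii >= nx - 1),
                      which(valid & jj <= 2), which(valid & jj >= ny - 1))
    dx <- pmin(ii - 1, nx - ii) * rm$bin
    dy <- pmin(jj - 1, ny - jj) * rm$bin
    dist_wall <- pmin(dx, dy)
    norm <- min(nx, ny) * rm$bin / 2
  }
  cM <- 0
  for (f in fields) for (wb in wall_bins) {
    if (length(wb) == 0) next
    cov <- sum(lab[wb] == f) / length(wb)
    if (cov > cM) cM <- cov
  }
  fb <- which(lab %in% fields)
  wgt <- m[fb]
  dm <- sum(dist_wall[fb] * wgt) / sum(wgt) / norm
  (cM - dm) / (cM + dm)
}

# connected components (8-neighborhood) of a logical matrix
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- q[1] + di; b <- q[2] + dj
        if (a < 1 || a > nx || b < 1 || b > ny) next
        if (mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

#' Directional information content (bits per spike)
#'
#' Skaggs information of firing rate over heading bins:
#' `sum_i p_i (f_i / F) log2(f_i / F)`.
#'
#' @param rates per-sample rates.
#' @param headings per-sample headings (rad), same length.
#' @param n_bins number of heading bins.
#' @return bits per spike.
#' @export
directional_info <- function(rates, headings, n_bins = 8) {
  stopifnot(length(rates) == length(headings))
  b <- floor((wrap_angle(headings) + pi) / (2 * pi) * n_bins) + 1
  b[b > n_bins] <- n_bins
  p <- tabulate(b, n_bins) / length(b)
  f <- vapply(seq_len(n_bins), function(i)
    if (p[i] > 0) mean(rates[b == i]) else 0, numeric(1))
  FF <- sum(p * f)
  if (FF <= 0) stop("zero mean rate")
  ratio <- f / FF
  sum(p[ratio > 0] * ratio[ratio > 0] * log2(ratio[ratio > 0]))
}

#' Bin-wise Pearson correlation between two rate maps
#'
#' @param a,b `rate_map` objects (or matrices) with identical binning.
#' @param min_overlap minimum number of jointly valid bins.
#' @return Pearson r.
#' @export
map_correlation <- function(a, b, min_overlap = 20) {
  ma <- if (inherits(a, "rate_map")) a$rate else a
  mb <- if (inherits(b, "rate_map")) b$rate else b
  stopifnot(all(dim(ma) == dim(mb)))
  ok <- is.finite(ma) & is.finite(mb)
  if (sum(ok) < min_overlap) stop("insufficient overlap between maps")
  stats::cor(ma[ok], mb[ok])
}
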