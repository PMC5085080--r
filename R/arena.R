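#' Construct an arena specification
#'
#' Builds the wall geometry of a test environment: perimeter (polygon or
#' circle), interior barriers, per-wall transparency flags, the rotational
#' symmetry order, and -- for corridor mazes -- the corridor centerline used
#' by the corridor-running trajectory generator.
#'
#' @param kind one of `"square"`, `"rectangle"`, `"circle"`, `"kite"`,
#'   `"square_with_barrier"`, `"hairpin"`, `"spiral"`,
#'   `"semi_transparent_hairpin"`.
#' @param size side length (cm) for square-based arenas, diameter for the
#'   circle, bounding size for the kite.
#' @param width,height explicit rectangle dimensions (cm); override `size`.
#' @param n_arms number of hairpin corridors (default 10).
#' @param corridor_width corridor width (cm); defaults to `size / n_arms` for
#'   the hairpin and 15 cm for the spiral.
#' @param barrier_length length (cm) of the single inserted barrier for
#'   `"square_with_barrier"`.
#' @param kite_vertices 4 x 2 matrix of kite vertex coordinates (cm);
#'   default `(0,0), (100,0), (100,60), (40,100)` scaled by `size / 100`.
#' @return an object of class `arena_spec`.
#' @export
build_arena <- function(kind = c("square", "rectangle", "circle", "kite",
                                 "square_with_barrier", "hairpin", "spiral",
                                 "semi_transparent_hairpin"),
                        size = 100, width = NULL, height = NULL,
                        n_arms = 10, corridor_width = NULL,
                        barrier_length = 50, kite_vertices = NULL) {
  kind <- match.arg(kind)
  stopifnot(size > 0)
  wall <- function(x1, y1, x2, y2, transparent = 0)
    c(x1, y1, x2, y2, transparent)
  perimeter_rect <- function(w, h)
    rbind(wall(0, 0, w, 0), wall(w, 0, w, h), wall(w, h, 0, h),
          wall(0, h, 0, 0))
  barriers <- NULL
  circle <- NULL
  centerline <- NULL
  sym <- 4L
  if (kind == "square") {
    per <- perimeter_rect(size, size)
    dims <- c(width = size, height = size)
  } else if (kind == "rectangle") {
    w <- if (is.null(width)) size else width
    h <- if (is.null(height)) size else height
    stopifnot(w > 0, h > 0)
    per <- perimeter_rect(w, h)
    sym <- if (isTRUE(all.equal(w, h))) 4L else 2L
    dims <- c(width = w, height = h)
  } else if (kind == "circle") {
    per <- matrix(numeric(0), 0, 5)
    circle <- list(cx = size / 2, cy = size / 2, radius = size / 2)
    sym <- Inf
    dims <- c(diameter = size)
  } else if (kind == "kite") {
    v <- if (is.null(kite_vertices))
      rbind(c(0, 0), c(100, 0), c(100, 60), c(40, 100)) * (size / 100)
    else kite_vertices
    stopifnot(nrow(v) == 4)
    per <- do.call(rbind, lapply(1:4, function(i) {
      j <- if (i == 4) 1 else i + 1
      wall(v[i, 1], v[i, 2], v[j, 1], v[j, 2])
    }))
    sym <- 1L
    dims <- c(size = size)
  } else if (kind == "square_with_barrier") {
    per <- perimeter_rect(size, size)
    barriers <- rbind(wall(size / 2, size - barrier_length, size / 2, size))
    sym <- 1L
    dims <- c(width = size, height = size)
  } else if (kind %in% c("hairpin", "semi_transparent_hairpin")) {
    cw <- if (is.null(corridor_width)) size / n_arms else corridor_width
    if (cw * n_arms > size + 1e-9)
      stop("hairpin corridors do not fit inside the arena")
    if (cw < 6) stop("corridor narrower than agent clearance")
    per <- perimeter_rect(size, size)
    transp <- if (kind == "semi_transparent_hairpin") 1 else 0
    # interior wall k at x = k*cw; odd walls attached to the south perimeter
    # (turn gap at north), even walls to the north (gap at south)
    barriers <- do.call(rbind, lapply(seq_len(n_arms - 1), function(k) {
      x <- k * cw
      if (k %% 2 == 1) wall(x, 0, x, size - cw, transp)
      else wall(x, cw, x, size, transp)
    }))
    sym <- 1L
    dims <- c(width = size, height = size, n_arms = n_arms,
              corridor_width = cw)
    centerline <- hairpin_centerline(size, n_arms, cw)
  } else if (kind == "spiral") {
    cw <- if (is.null(corridor_width)) 15 else corridor_width
    per <- perimeter_rect(size, size)
    sp <- spiral_geometry(size, cw)
    barriers <- sp$walls
    centerline <- sp$centerline
    sym <- 1L
    dims <- c(width = size, height = size, corridor_width = cw)
  }
  walls <- rbind(per, barriers)
  colnames(walls) <- c("x1", "y1", "x2", "y2", "transparent")
  bbox <- if (!is.null(circle))
    c(xmin = 0, xmax = size, ymin = 0, ymax = size)
  else c(xmin = min(walls[, c(1, 3)]), xmax = max(walls[, c(1, 3)]),
         ymin = min(walls[, c(2, 4)]), ymax = max(walls[, c(2, 4)]))
  structure(list(kind = kind, name = kind, dims = dims, walls = walls,
                 n_perimeter = nrow(per), circle = circle,
                 symmetry_order = sym, centerline = centerline, bbox = bbox),
            class = "arena_spec")
}

# corridor centerline for the hairpin maze: alternating north/south runs,
# easterly order; segments carry arm id and local running sign
hairpin_centerline <- function(size, n_arms, cw) {
  m <- cw / 2
  pts <- matrix(NA_real_, 2 * n_arms, 2)
  for (k in seq_len(n_arms)) {
    x <- (k - 0.5) * cw
    if (k %% 2 == 1) {                      # odd arms run south -> north
      pts[2 * k - 1, ] <- c(x, m)
      pts[2 * k, ] <- c(x, size - m)
    } else {
      pts[2 * k - 1, ] <- c(x, size - m)
      pts[2 * k, ] <- c(x, m)
    }
  }
  nseg <- nrow(pts) - 1
  arm <- integer(nseg); vert <- logical(nseg); locdir <- integer(nseg)
  for (s in seq_len(nseg)) {
    vert[s] <- abs(pts[s + 1, 1] - pts[s, 1]) < 1e-9
    arm[s] <- if (vert[s]) ceiling(pts[s, 1] / cw) else NA_integer_
    locdir[s] <- sign(pts[s + 1, 2] - pts[s, 2])
  }
  list(waypoints = pts, arm = arm, vertical = vert, local_dir = locdir,
       corridor_width = cw, n_arms = n_arms)
}

# inward rectangular spiral: one wall polyline plus a parallel centerline;
# legs shrink by one corridor width per half-turn
spiral_walk <- function(start, first_len, cw, min_len) {
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0)) # up, right, down, left
  pts <- list(start)
  k <- 0
  repeat {
    len <- first_len - cw * ceiling(k / 2)
    if (len < min_len) break
    d <- dirs[(k %% 4) + 1, ]
    pts <- c(pts, list(pts[[length(pts)]] + len * d))
    k <- k + 1
  }
  do.call(rbind, pts)
}

spiral_geometry <- function(size, cw) {
  # wall legs: 135,120,120,105,... ; centerline legs: 135,135,135,120,120,
  # 105,... (the first three legs hug the full perimeter)
  p <- spiral_walk(c(cw, 0), size - cw, cw, 3 * cw)
  walls <- do.call(rbind, lapply(seq_len(nrow(p) - 1), function(i)
    c(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2], 0)))
  m <- cw / 2
  dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))
  wp <- list(c(m, m))
  k <- 0
  repeat {
    len <- (size - cw) - cw * floor(max(0, k - 1) / 2)
    if (len < 2 * cw) break
    d <- dirs[(k %% 4) + 1, ]
    wp <- c(wp, list(wp[[length(wp)]] + len * d))
    k <- k + 1
  }
  wp <- do.call(rbind, wp)
  nseg <- nrow(wp) - 1
  vert <- abs(wp[-1, 1] - wp[-nrow(wp), 1]) < 1e-9
  locdir <- ifelse(vert, sign(wp[-1, 2] - wp[-nrow(wp), 2]),
                   sign(wp[-1, 1] - wp[-nrow(wp), 1]))
  # arms numbered left to right (vertical segments by x), then bottom to top
  # (horizontal segments by y)
  xs <- wp[-nrow(wp), 1]; ys <- wp[-nrow(wp), 2]
  key <- ifelse(vert, xs, 1e6 + ys)
  arm <- match(key, sort(unique(key)))
  list(walls = walls,
       centerline = list(waypoints = wp, arm = arm, vertical = vert,
                         local_dir = locdir, corridor_width = cw,
                         n_arms = length(unique(arm))))
}

#' Rescale a rectangular arena
#'
#' Scales the perimeter per axis about the south-west corner (the anchor is
#' a convention; only relative geometry matters downstream).
#'
#' @param spec an `arena_spec` with a rectangular perimeter.
#' @param sx,sy positive per-axis scale ratios.
#' @return the rescaled `arena_spec`.
#' @export
resize_arena <- function(spec, sx, sy = sx) {
  stopifnot(inherits(spec, "arena_spec"), sx > 0, sy > 0)
  if (!spec$kind %in% c("square", "rectangle"))
    stop("resize_arena requires a rectangular arena")
  w <- spec$walls
  x0 <- spec$bbox["xmin"]; y0 <- spec$bbox["ymin"]
  w[, c(1, 3)] <- x0 + (w[, c(1, 3)] - x0) * sx
  w[, c(2, 4)] <- y0 + (w[, c(2, 4)] - y0) * sy
  spec$walls <- w
  spec$bbox <- c(xmin = min(w[, c(1, 3)]), xmax = max(w[, c(1, 3)]),
                 ymin = min(w[, c(2, 4)]), ymax = max(w[, c(2, 4)]))
  wd <- unname(spec$bbox["xmax"] - spec$bbox["xmin"])
  ht <- unname(spec$bbox["ymax"] - spec$bbox["ymin"])
  spec$dims <- c(width = wd, height = ht)
  spec$kind <- if (isTRUE(all.equal(wd, ht))) "square" else "rectangle"
  spec$symmetry_order <- if (isTRUE(all.equal(wd, ht))) 4L else 2L
  spec
}

# geometry list handed to the C++ routines
arena_geom <- function(spec) {
  list(walls = spec$walls, n_perimeter = spec$n_perimeter,
       is_circle = !is.null(spec$circle),
       cx = if (is.null(spec$circle)) 0 else spec$circle$cx,
       cy = if (is.null(spec$circle)) 0 else spec$circle$cy,
       radius = if (is.null(spec$circle)) 0 else spec$circle$radius)
}

#' Is a point inside the navigable space?
#' @param spec an `arena_spec`.
#' @param pts n x 2 matrix of positions (cm).
#' @return logical vector.
#' @export
arena_contains <- function(spec, pts) {
  pts <- rbind(pts)
  inside_cpp(arena_geom(spec), pts)
}

#' Cast boundary-detection rays from a pose
#'
#' Computes per-ray first-hit distances under a sensing regime. Under
#' `vision`, rays stop at the first opaque wall with unbounded range; under
#' `dark` a hit is reported only within the somatosensory contact range
#' (any wall); under `semi_transparent` each ray reports the union of the
#' nearest-wall hit and the first opaque (perimeter) hit, transparent walls
#' being invisible but touchable.
#'
#' @param spec an `arena_spec`.
#' @param pose numeric length 3: x, y (cm) and heading (rad).
#' @param n_rays number of egocentric ray directions (uniform spacing).
#' @param regime `"vision"`, `"dark"` or `"semi_transparent"`.
#' @param contact_range maximum boundary detection distance without vision
#'   (cm).
#' @return data.frame with columns `angle` (egocentric, rad), `distance`
#'   (cm, NA when no hit) and `hit` (0/1).
#' @export
boundary_raycast <- function(spec, pose, n_rays = 36,
                             regime = c("vision", "dark", "semi_transparent"),
                             contact_range = 13) {
  regime <- match.arg(regime)
  if (!arena_contains(spec, pose[1:2]))
    stop("pose outside the arena")
  ego <- ego_ray_angles(n_rays)
  ang <- ego + pose[3]
  mode <- match(regime, c("vision", "dark", "semi_transparent")) - 1L
  m <- raycast_cpp(arena_geom(spec), pose[1], pose[2], ang, mode,
                   contact_range)
  if (regime == "semi_transparent") {
    out <- data.frame(angle = c(ego, ego),
                      distance = c(m[, 1], m[, 3]),
                      hit = c(m[, 2], m[, 4]))
    # drop duplicate rows where the nearest wall is the opaque wall
    dup <- duplicated(round(cbind(out$angle, out$distance), 9))
    out[!dup | !out$hit, , drop = FALSE]
  } else {
    data.frame(angle = ego, distance = m[, 1], hit = m[, 2])
  }
}

ego_ray_angles <- function(n_rays) {
  seq(0, 2 * pi, length.out = n_rays + 1)[seq_len(n_rays)] - pi
}

#' Write or read an arena specification as a YAML config
#' @param spec an `arena_spec`.
#' @param path file path.
#' @return `read_arena` returns an `arena_spec`.
#' @export
write_arena <- function(spec, path) {
  obj <- list(kind = spec$kind, dims = as.list(spec$dims),
              symmetry_order = if (is.infinite(spec$symmetry_order)) "inf"
                               else spec$symmetry_order,
              walls = apply(spec$walls, 1, as.list),
              n_perimeter = spec$n_perimeter,
              circle = spec$circle)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  obj <- yaml::read_yaml(path)
  walls <- do.call(rbind, lapply(obj$walls, function(w)
    as.numeric(unlist(w))))
  if (is.null(walls)) walls <- matrix(numeric(0), 0, 5)
  colnames(walls) <- c("x1", "y1", "x2", "y2", "transparent")
  sym <- if (identical(obj$symmetry_order, "inf")) Inf
         else as.numeric(obj$symmetry_order)
  # rebuild through the constructor when possible to recover centerlines
  dims <- unlist(obj$dims)
  spec <- switch(obj$kind,
    hairpin = build_arena("hairpin", size = dims[["width"]],
                          n_arms = dims[["n_arms"]],
                          corridor_width = dims[["corridor_width"]]),
    semi_transparent_hairpin =
      build_arena("semi_transparent_hairpin", size = dims[["width"]],
                  n_arms = dims[["n_arms"]],
                  corridor_width = dims[["corridor_width"]]),
    spiral = build_arena("spiral", size = dims[["width"]],
                         corridor_width = dims[["corridor_width"]]),
    NULL)
  if (!is.null(spec)) return(spec)
  bbox <- if (!is.null(obj$circle))
    c(xmin = 0, xmax = 2 * obj$circle$radius, ymin = 0,
      ymax = 2 * obj$circle$radius)
  else c(xmin = min(walls[, c(1, 3)]), xmax = max(walls[, c(1, 3)]),
         ymin = min(walls[, c(2, 4)]), ymax = max(walls[, c(2, 4)]))
  structure(list(kind = obj$kind, name = obj$kind, dims = dims,
                 walls = walls, n_perimeter = obj$n_perimeter,
                 circle = obj$circle, symmetry_order = sym,
                 centerline = NULL, bbox = bbox),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat("<arena_spec>", x$kind, "\n")
  cat("  dims:", paste(names(x$dims), signif(x$dims, 4), sep = "=",
                       collapse = ", "), "cm\n")
  cat("  walls:", nrow(x$walls), "(", x$n_perimeter, "perimeter )",
      if (any(x$walls[, 5] > 0)) "with transparent walls" else "", "\n")
  cat("  rotational symmetry:", x$symmetry_order, "\n")
  invisible(x)
}
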