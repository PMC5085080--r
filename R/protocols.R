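#' Run a named experimental protocol
#'
#' Seeded end-to-end reproductions of the simulated experiments: naive
#' learning in open arenas, the compensatory-noise and feedback ablations,
#' the darkness series, arena-resizing series, novelty (reduced-gain)
#' series, hairpin / virtual-hairpin / semi-transparent / spiral corridor
#' series, lesions, association-map resolution and self-motion-noise
#' series, and irregular-grid learning.
#'
#' @param name protocol name (see Details).
#' @param config named list of overrides: `duration` (s), `n_trials`,
#'   `n_cells`, `n_particles`, `n_traversals`, `noise` (a `noise_config`),
#'   `fusion` (a `fusion_config`), `recall_duration`.
#' @param seed integer master seed; all session seeds derive from it.
#' @param reduced reduced problem sizes (default) or paper-scale replicate
#'   counts.
#' @param out_dir optional directory: metric tables are written as CSV and
#'   the record as RDS.
#' @return a `sifm_run` record: name, seed, params, per-session summaries,
#'   metric tables.
#' @details Protocol names: `learn_square`, `learn_circle`, `barrier`,
#'   `darkness_series`, `kite_dark_naive`, `resize_series_A`,
#'   `resize_series_B`, `novelty_gain_series`, `hairpin_series`,
#'   `virtual_hairpin`, `semi_transparent`, `spiral`, `lesion_series`,
#'   `ablate_comp_noise`, `ablate_feedback`, `map_resolution_series`,
#'   `selfmotion_noise_series`, `irregular_grid`.
#' @export
run_protocol <- function(name, config = list(), seed = 1, reduced = TRUE,
                         out_dir = NULL) {
  protocols <- c("learn_square", "learn_circle", "barrier",
                 "darkness_series", "kite_dark_naive", "resize_series_A",
                 "resize_series_B", "novelty_gain_series", "hairpin_series",
                 "virtual_hairpin", "semi_transparent", "spiral",
                 "lesion_series", "ablate_comp_noise", "ablate_feedback",
                 "map_resolution_series", "selfmotion_noise_series",
                 "irregular_grid")
  if (!name %in% protocols) stop("unknown protocol: ", name)
  p <- protocol_params(config, reduced)
  fn <- get(paste0("proto_", name), mode = "function")
  rec <- fn(p, seed)
  rec$name <- name
  rec$seed <- seed
  rec$reduced <- reduced
  rec$params <- p[setdiff(names(p), c("noise", "fusion"))]
  class(rec) <- "sifm_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(rec$metrics))
      if (is.data.frame(rec$metrics[[nm]]))
        utils::write.csv(rec$metrics[[nm]],
                         file.path(out_dir, paste0(name, "_", nm, ".csv")),
                         row.names = FALSE)
    saveRDS(rec, file.path(out_dir, paste0(name, "_record.rds")))
  }
  rec
}

#' @export
print.sifm_run <- function(x, ...) {
  cat("<sifm_run>", x$name, "| seed", x$seed,
      if (isTRUE(x$reduced)) "(reduced scale)" else "(full scale)", "\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    if (is.data.frame(m))
      cat(sprintf("  %s: %d x %d table\n", nm, nrow(m), ncol(m)))
    else if (is.numeric(m) && length(m) <= 4)
      cat(sprintf("  %s: %s\n", nm, paste(signif(m, 4), collapse = ", ")))
  }
  invisible(x)
}

protocol_params <- function(config, reduced) {
  p <- list(
    duration = 1200, recall_duration = 600,
    n_trials = if (reduced) 2 else 10,
    n_cells = if (reduced) 25 else 200,
    n_particles = if (reduced) 100 else 200,
    n_traversals = if (reduced) 14 else 20,
    n_recall = if (reduced) 6 else 10,
    classify = FALSE, n_classify_grid = 12, n_classify_bc = 15,
    noise = noise_config(), fusion = NULL)
  p[names(config)] <- config
  if (is.null(p$fusion))
    p$fusion <- fusion_config(n_particles = p$n_particles)
  else p$fusion$n_particles <- p$n_particles
  p
}

#' Grid-cell metric table for a fitted session
#'
#' Gridness (expanding-annuli variant), directional information and,
#' optionally, parametric classification for each readout grid cell of a
#' fit.
#'
#' @param fit a `sifm` fit.
#' @param classify_idx cell indices to classify (costly); empty for none.
#' @param n_starts classifier restarts.
#' @return data.frame with one row per readout cell.
#' @export
grid_cell_metrics <- function(fit, classify_idx = integer(0),
                              n_starts = 12) {
  tr <- fit$trajectory
  bb <- fit$arena$bbox
  n <- nrow(fit$rates)
  out <- data.frame(cell = seq_len(n), gridness = NA_real_,
                    dir_info = NA_real_, r_gc = NA_real_, r_bvc = NA_real_,
                    class = NA_character_)
  for (i in seq_len(n)) {
    rm <- rate_map(fit$rates[i, ], tr, bbox = bb)
    ac <- try(autocorrelogram(rm, max_lag = 0.7 * min(bb[2] - bb[1],
                                                      bb[4] - bb[3])),
              silent = TRUE)
    if (!inherits(ac, "try-error"))
      out$gridness[i] <- as.numeric(gridness(ac, 2))
    out$dir_info[i] <- tryCatch(
      directional_info(fit$rates[i, ], tr$heading[-1]),
      error = function(e) NA_real_)
    if (i %in% classify_idx) {
      pc <- tryCatch(parametric_ratemap_correlation(rm, fit$arena,
                                                    n_starts = n_starts,
                                                    seed = 100 + i),
                     error = function(e) NULL)
      if (!is.null(pc)) {
        out$r_gc[i] <- pc$r_gc; out$r_bvc[i] <- pc$r_bvc
        out$class[i] <- pc$class
      }
    }
  }
  out
}

#' Predictive boundary-cell metric table for a fitted session
#'
#' Border score, boundary-field distance and optional parametric
#' classification for each predictive boundary cell (ensemble readout)
#' with tuning distance inside `d_range`.
#'
#' @param fit a `sifm` fit.
#' @param d_range tuning-distance window (cm).
#' @param classify_idx row indices to classify; empty for none.
#' @param n_starts classifier restarts.
#' @return data.frame with one row per boundary cell.
#' @export
boundary_cell_metrics <- function(fit, d_range = c(3, 100),
                                  classify_idx = integer(0),
                                  n_starts = 12) {
  bbank <- fit$bbank
  keep <- which(bbank$d >= d_range[1] & bbank$d <= d_range[2])
  tr <- fit$trajectory
  bb <- fit$arena$bbox
  out <- data.frame(cell = keep, d = bbank$d[keep],
                    theta = bbank$theta[keep],
                    range_class = bbank$range_class[keep],
                    border = NA_real_, field_dist = NA_real_,
                    r_gc = NA_real_, r_bvc = NA_real_,
                    class = NA_character_)
  for (i in seq_along(keep)) {
    rm <- rate_map(fit$bc_rates[keep[i], ], tr, bbox = bb)
    out$border[i] <- tryCatch(border_score(rm, fit$arena),
                              error = function(e) NA_real_)
    out$field_dist[i] <- tryCatch(
      boundary_field_distance(rm, bbank$theta[keep[i]], fit$arena),
      error = function(e) NA_real_)
    if (i %in% classify_idx) {
      pc <- tryCatch(parametric_ratemap_correlation(rm, fit$arena,
                                                    n_starts = n_starts,
                                                    seed = 500 + i),
                     error = function(e) NULL)
      if (!is.null(pc)) {
        out$r_gc[i] <- pc$r_gc; out$r_bvc[i] <- pc$r_bvc
        out$class[i] <- pc$class
      }
    }
  }
  out
}

session_summary <- function(fit) {
  s <- summary(fit)
  data.frame(steps = s$steps, decode_rmse = s$decode_rmse,
             mean_error = s$mean_error, ess_median = unname(s$ess[2]),
             n_resample = s$n_resample)
}

# -------- open-arena learning protocols -----------------------------------

proto_open_learning <- function(arena, p, seed, cfg = NULL) {
  cfg <- if (is.null(cfg)) p$fusion else cfg
  bank <- make_module_bank()
  grid_tabs <- list(); bc_tabs <- list(); sess <- list(); maps <- list()
  for (tr_i in seq_len(p$n_trials)) {
    s0 <- seed + 101 * tr_i
    cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = s0)
    traj <- generate_forage(arena, p$duration, seed = s0 + 1)
    fit <- sifm(traj, arena, config = cfg, noise = p$noise, bank = bank,
                cells = cells, seed = s0 + 2)
    gi <- if (p$classify) seq_len(min(p$n_classify_grid, p$n_cells))
          else integer(0)
    g <- grid_cell_metrics(fit, classify_idx = gi)
    g$trial <- tr_i
    grid_tabs[[tr_i]] <- g
    bi <- if (p$classify) {
      set.seed(s0 + 9)
      sample(seq_len(168), min(p$n_classify_bc, 168))
    } else integer(0)
    b <- boundary_cell_metrics(fit, classify_idx = bi)
    b$trial <- tr_i
    bc_tabs[[tr_i]] <- b
    sess[[tr_i]] <- session_summary(fit)
    maps[[tr_i]] <- fit$map
  }
  list(metrics = list(grid_cells = do.call(rbind, grid_tabs),
                      boundary_cells = do.call(rbind, bc_tabs),
                      sessions = do.call(rbind, sess),
                      mean_gridness =
                        mean(do.call(rbind, grid_tabs)$gridness,
                             na.rm = TRUE)),
       checkpoints = maps)
}

proto_learn_square <- function(p, seed)
  proto_open_learning(build_arena("square", 100), p, seed)

proto_learn_circle <- function(p, seed)
  proto_open_learning(build_arena("circle", 100), p, seed)

proto_barrier <- function(p, seed)
  proto_open_learning(build_arena("square_with_barrier", 100), p, seed)

proto_irregular_grid <- function(p, seed) {
  arena <- build_arena("square", 100)
  bank <- make_module_bank(irregular = TRUE, seed = seed)
  cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = seed + 3)
  traj <- generate_forage(arena, p$duration, seed = seed + 4)
  fit <- sifm(traj, arena, config = p$fusion, noise = p$noise, bank = bank,
              cells = cells, seed = seed + 5)
  # stability: first-half vs second-half rate maps
  S <- ncol(fit$rates)
  h1 <- seq_len(S %/% 2); h2 <- (S %/% 2 + 1):S
  stab <- vapply(seq_len(nrow(fit$rates)), function(i) {
    m1 <- rate_map(fit$rates[i, h1], traj[c(1, h1 + 1), ],
                   bbox = arena$bbox)
    m2 <- rate_map(fit$rates[i, h2], traj[c(1, h2 + 1), ],
                   bbox = arena$bbox)
    tryCatch(map_correlation(m1, m2), error = function(e) NA_real_)
  }, numeric(1))
  g <- grid_cell_metrics(fit)
  list(metrics = list(grid_cells = g, stability = stab,
                      mean_stability = mean(stab, na.rm = TRUE),
                      sessions = session_summary(fit)),
       checkpoints = list(fit$map))
}

proto_ablate_comp_noise <- function(p, seed) {
  cfg <- p$fusion
  cfg$comp_noise_sd <- 0
  cfg$head_jitter_sd <- 0
  sq <- proto_open_learning(build_arena("square", 100), p, seed, cfg = cfg)
  ci <- proto_open_learning(build_arena("circle", 100), p, seed + 7000,
                            cfg = cfg)
  gs <- sq$metrics$grid_cells$gridness
  gc <- ci$metrics$grid_cells$gridness
  list(metrics = list(
    grid_cells_square = sq$metrics$grid_cells,
    grid_cells_circle = ci$metrics$grid_cells,
    mean_gridness_square = mean(gs, na.rm = TRUE),
    mean_gridness_circle = mean(gc, na.rm = TRUE),
    frac_nonpositive = mean(c(gs, gc) <= 0, na.rm = TRUE)))
}

# -------- darkness ---------------------------------------------------------

proto_darkness_series <- function(p, seed) {
  arena <- build_arena("circle", 100)
  bank <- make_module_bank()
  tabs <- list()
  for (tr_i in seq_len(p$n_trials)) {
    s0 <- seed + 211 * tr_i
    cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = s0)
    tl <- generate_forage(arena, p$duration, seed = s0 + 1)
    fitL <- sifm(tl, arena, config = p$fusion, noise = p$noise,
                 bank = bank, cells = cells, seed = s0 + 2)
    td <- generate_forage(arena, p$duration, seed = s0 + 3)
    fitD <- sifm(td, arena, regime = "dark", config = p$fusion,
                 noise = p$noise, bank = bank, cells = cells,
                 map = fitL$map, seed = s0 + 4)
    t2 <- generate_forage(arena, p$duration, seed = s0 + 5)
    fitL2 <- sifm(t2, arena, config = p$fusion, noise = p$noise,
                  bank = bank, cells = cells, map = fitD$map, seed = s0 + 6)
    bb <- arena$bbox
    tabs[[tr_i]] <- do.call(rbind, lapply(seq_len(p$n_cells), function(i) {
      mL <- rate_map(fitL$rates[i, ], tl, bbox = bb)
      mD <- rate_map(fitD$rates[i, ], td, bbox = bb)
      mL2 <- rate_map(fitL2$rates[i, ], t2, bbox = bb)
      data.frame(trial = tr_i, cell = i,
                 light_dark = tryCatch(map_correlation(mL, mD),
                                       error = function(e) NA_real_),
                 dark_light = tryCatch(map_correlation(mD, mL2),
                                       error = function(e) NA_real_))
    }))
  }
  tab <- do.call(rbind, tabs)
  list(metrics = list(map_correlations = tab,
                      mean_light_dark = mean(tab$light_dark, na.rm = TRUE),
                      mean_dark_light = mean(tab$dark_light, na.rm = TRUE)))
}

# -------- kite / attractor -------------------------------------------------

proto_kite_dark_naive <- function(p, seed, feedback_recall = TRUE) {
  arena <- build_arena("kite", 100)
  bank <- make_module_bank()
  cells <- make_grid_cells(bank, min(p$n_cells, 20), module = 1,
                           seed = seed + 11)
  traj <- generate_forage(arena, p$duration, seed = seed + 12)
  fitL <- sifm(traj, arena, regime = "dark", config = p$fusion,
               noise = p$noise, bank = bank, cells = cells, seed = seed + 13)
  n_track <- min(20, p$fusion$n_particles)
  # attractor readout: phase-matched cells of the module whose scale is
  # closest to the arena extent (coherence on the scale of the
  # localization problem)
  extent <- max(arena$bbox[2] - arena$bbox[1], arena$bbox[4] - arena$bbox[3])
  track_mod <- c(which(bank$scale >= extent), nrow(bank))[1]
  rcfg <- p$fusion
  rcfg$learning_on <- FALSE
  rcfg$feedback_on <- feedback_recall
  wins <- list(); dists <- list(); recall_fits <- list()
  for (rt in seq_len(p$n_recall)) {
    s0 <- seed + 307 * rt
    tr2 <- generate_forage(arena, p$recall_duration, seed = s0)
    fitR <- sifm(tr2, arena, regime = "dark", config = rcfg,
                 noise = p$noise, bank = bank, cells = cells,
                 init = "disoriented", map = fitL$map,
                 track_particles = seq_len(n_track),
                 track_module = track_mod, seed = s0 + 1)
    ad <- attractor_distance(fitR$track_rates, dt = attr(tr2, "dt"))
    wins[[rt]] <- data.frame(trial = rt, t = ad$win_t, mean_r = ad$mean_r)
    dists[[rt]] <- data.frame(trial = rt, t = ad$t, d = ad$d)
    if (rt <= 2) recall_fits[[rt]] <- fitR
  }
  # within-cell vs between-cell grid phase drift across the two recall
  # trials, from template + phase fits of the readout cell maps
  drift <- NULL
  if (length(recall_fits) >= 2) drift <- tryCatch({
    phases <- lapply(recall_fits[1:2], function(f) {
      t(vapply(seq_len(nrow(cells)), function(i) {
        rm <- rate_map(f$rates[i, ], f$trajectory, bbox = arena$bbox)
        gp <- fit_grid_template(autocorrelogram(rm, max_lag = 50))
        fit_grid_phase(rm, gp)$phase
      }, numeric(2)))
    })
    phase_drift(phases[[1]], phases[[2]])
  }, error = function(e) NULL)
  win <- do.call(rbind, wins)
  list(metrics = list(
    windows = win, attractor_d = do.call(rbind, dists),
    mean_r_after_min1 = mean(win$mean_r[win$t >= 60], na.rm = TRUE),
    phase_drift = drift,
    learning_session = session_summary(fitL)),
    checkpoints = list(fitL$map))
}

proto_ablate_feedback <- function(p, seed)
  proto_kite_dark_naive(p, seed, feedback_recall = FALSE)

# -------- resizing / novelty ----------------------------------------------

resize_trial_metrics <- function(fits, trajs, arenas, cells_n, ref = 1) {
  bbr <- arenas[[ref]]$bbox
  acr <- lapply(seq_len(cells_n), function(i)
    tryCatch(autocorrelogram(rate_map(fits[[ref]]$rates[i, ], trajs[[ref]],
                                      bbox = bbr), max_lag = 60),
             silent = TRUE, error = function(e) NULL))
  out <- list()
  for (k in seq_along(fits)) {
    if (k == ref) next
    bb <- arenas[[k]]$bbox
    for (i in seq_len(cells_n)) {
      ac <- tryCatch(autocorrelogram(rate_map(fits[[k]]$rates[i, ],
                                              trajs[[k]], bbox = bb),
                                     max_lag = 60),
                     error = function(e) NULL)
      if (is.null(ac) || is.null(acr[[i]])) next
      rh <- tryCatch(rescaling_magnitude(ac, acr[[i]], "h"),
                     error = function(e) NA_real_)
      rv <- tryCatch(rescaling_magnitude(ac, acr[[i]], "v"),
                     error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(session = k, cell = i,
                                           ratio_h = rh, ratio_v = rv)
    }
  }
  do.call(rbind, out)
}

proto_resize_generic <- function(p, seed, train_dims, test_list) {
  bank <- make_module_bank()
  cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = seed + 21)
  arenas <- c(list(build_arena("rectangle", width = train_dims[1],
                               height = train_dims[2])),
              lapply(test_list, function(d)
                build_arena("rectangle", width = d[1], height = d[2])))
  fits <- list(); trajs <- list(); bc_tabs <- list()
  rcfg <- p$fusion
  rcfg$learning_on <- FALSE # test sessions probe the trained map
  map <- NULL
  for (k in seq_along(arenas)) {
    s0 <- seed + 401 * k
    trk <- generate_forage(arenas[[k]], p$duration, seed = s0)
    fit <- sifm(trk, arenas[[k]],
                config = if (k == 1) p$fusion else rcfg,
                noise = p$noise, bank = bank, cells = cells, map = map,
                seed = s0 + 1)
    if (k == 1) map <- fit$map
    fits[[k]] <- fit; trajs[[k]] <- trk
    b <- boundary_cell_metrics(fit, d_range = c(15, 40))
    b$session <- k
    bc_tabs[[k]] <- b
  }
  rs <- resize_trial_metrics(fits, trajs, arenas, p$n_cells)
  list(metrics = list(rescaling = rs,
                      boundary_fields = do.call(rbind, bc_tabs),
                      sessions = do.call(rbind, lapply(fits,
                                                       session_summary))))
}

proto_resize_series_A <- function(p, seed)
  proto_resize_generic(p, seed, c(100, 100),
                       list(c(100, 70), c(70, 100), c(70, 70),
                            c(100, 100)))

proto_resize_series_B <- function(p, seed)
  proto_resize_generic(p, seed, c(100, 70),
                       list(c(70, 70), c(100, 100), c(100, 70)))

proto_novelty_gain_series <- function(p, seed) {
  arena <- build_arena("square", 100)
  bank <- make_module_bank()
  cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = seed + 31)
  tl <- generate_forage(arena, p$duration, seed = seed + 32)
  fitF <- sifm(tl, arena, config = p$fusion, noise = p$noise, bank = bank,
               cells = cells, seed = seed + 33)
  rcfg <- p$fusion; rcfg$learning_on <- FALSE
  gains <- c(6 / 9, 7 / 9, 8 / 9, 1)
  bb <- arena$bbox
  acr <- lapply(seq_len(p$n_cells), function(i)
    tryCatch(autocorrelogram(rate_map(fitF$rates[i, ], tl, bbox = bb),
                             max_lag = 60), error = function(e) NULL))
  out <- list()
  for (k in seq_along(gains)) {
    nz <- p$noise; nz$gain <- gains[k]
    s0 <- seed + 501 * k
    trk <- generate_forage(arena, p$duration, seed = s0)
    fit <- sifm(trk, arena, config = rcfg, noise = nz, bank = bank,
                cells = cells, map = fitF$map, seed = s0 + 1)
    for (i in seq_len(p$n_cells)) {
      ac <- tryCatch(autocorrelogram(rate_map(fit$rates[i, ], trk,
                                              bbox = bb), max_lag = 60),
                     error = function(e) NULL)
      if (is.null(ac) || is.null(acr[[i]])) next
      rh <- tryCatch(rescaling_magnitude(ac, acr[[i]], "h"),
                     error = function(e) NA_real_)
      rv <- tryCatch(rescaling_magnitude(ac, acr[[i]], "v"),
                     error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(gain = gains[k], cell = i,
                                           ratio_h = rh, ratio_v = rv)
    }
  }
  list(metrics = list(rescaling = do.call(rbind, out)))
}

# -------- corridor mazes ---------------------------------------------------

hairpin_arm_stats <- function(rates, traj, spec, exclude = c(1, 10),
                              n_shuffle = 20, seed = 1) {
  me <- arm_correlation_matrix(rates, traj, spec, "E")
  mw <- arm_correlation_matrix(rates, traj, spec, "W")
  n_arms <- spec$centerline$n_arms
  arms <- setdiff(seq_len(n_arms), exclude)
  odd <- arms[arms %% 2 == 1]; even <- arms[arms %% 2 == 0]
  pick <- function(m, a, b) {
    v <- c()
    for (i in a) for (j in b) if (i < j) v <- c(v, m[i, j])
    v
  }
  same_local <- c(pick(me$r, odd, odd), pick(me$r, even, even),
                  pick(mw$r, odd, odd), pick(mw$r, even, even))
  diff_local <- c(pick(me$r, odd, even), pick(mw$r, odd, even))
  # same local direction but opposite global direction: easterly arm i runs
  # the same way as westerly arm j when i and j have opposite parity
  cross <- c()
  for (i in arms) for (j in arms)
    if ((i + j) %% 2 == 1)
      cross <- c(cross, suppressWarnings(stats::cor(me$vectors[, i],
                                                    mw$vectors[, j],
                                                    use = "complete.obs")))
  # shuffled-bin control: same-local-direction pairs with permuted bins
  set.seed(seed)
  shuf <- c()
  for (s in seq_len(n_shuffle)) {
    i <- sample(odd, 1); j <- sample(setdiff(odd, i), 1)
    v1 <- me$vectors[, i]; v2 <- me$vectors[, j]
    ok <- is.finite(v1) & is.finite(v2)
    if (sum(ok) > 3)
      shuf <- c(shuf, stats::cor(v1[ok], sample(v2[ok])))
  }
  list(mat_east = me$r, mat_west = mw$r, same_local = same_local,
       diff_local = diff_local, cross_global = cross, shuffled = shuf)
}

proto_hairpin_series <- function(p, seed, st_walls = FALSE) {
  size <- 150
  open_arena <- build_arena("square", size)
  hp <- build_arena(if (st_walls) "semi_transparent_hairpin" else "hairpin",
                    size)
  bank <- make_module_bank()
  recs <- list()
  for (tr_i in seq_len(p$n_trials)) {
    s0 <- seed + 601 * tr_i
    cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = s0)
    # OF1: open-field learning
    t_of <- generate_forage(open_arena, p$duration, seed = s0 + 1)
    fit_of <- sifm(t_of, open_arena, config = p$fusion, noise = p$noise,
                   bank = bank, cells = cells, seed = s0 + 2)
    # HP: hairpin learning along corridor paths
    t_hp <- generate_hairpin_path(hp, p$n_traversals, seed = s0 + 3)
    fit_hp <- sifm(t_hp, hp,
                   regime = if (st_walls) "semi_transparent" else "vision",
                   config = p$fusion, noise = p$noise, bank = bank,
                   cells = cells, seed = s0 + 4)
    # VH: recall along a virtual hairpin path in the familiar open arena
    rcfg <- p$fusion; rcfg$learning_on <- FALSE
    t_vh <- generate_virtual_hairpin(open_arena, p$n_traversals,
                                     seed = s0 + 5)
    fit_vh <- sifm(t_vh, open_arena, config = rcfg, noise = p$noise,
                   bank = bank, cells = cells, map = fit_of$map,
                   seed = s0 + 6)
    # OF2: recall in the open arena along a random path
    t_of2 <- generate_forage(open_arena, p$recall_duration, seed = s0 + 7)
    fit_of2 <- sifm(t_of2, open_arena, config = rcfg, noise = p$noise,
                    bank = bank, cells = cells, map = fit_of$map,
                    seed = s0 + 8)
    arm <- hairpin_arm_stats(fit_hp$rates, t_hp, hp, seed = s0)
    bb <- open_arena$bbox
    corr_of <- vapply(seq_len(p$n_cells), function(i) {
      m1 <- rate_map(fit_of$rates[i, ], t_of, bbox = bb)
      hpmap <- rate_map(fit_hp$rates[i, ], t_hp, bbox = bb)
      vh <- rate_map(fit_vh$rates[i, ], t_vh, bbox = bb)
      of2 <- rate_map(fit_of2$rates[i, ], t_of2, bbox = bb)
      c(tryCatch(map_correlation(m1, hpmap), error = function(e) NA_real_),
        tryCatch(map_correlation(m1, vh), error = function(e) NA_real_),
        tryCatch(map_correlation(m1, of2), error = function(e) NA_real_))
    }, numeric(3))
    g_vh <- vapply(seq_len(p$n_cells), function(i)
      as.numeric(gridness(autocorrelogram(
        rate_map(fit_vh$rates[i, ], t_vh, bbox = bb), max_lag = 70), 2)),
      numeric(1))
    g_hp <- vapply(seq_len(p$n_cells), function(i)
      as.numeric(gridness(autocorrelogram(
        rate_map(fit_hp$rates[i, ], t_hp, bbox = bb), max_lag = 70), 2)),
      numeric(1))
    recs[[tr_i]] <- list(arm = arm, corr_of = corr_of, g_vh = g_vh,
                         g_hp = g_hp)
  }
  same <- unlist(lapply(recs, function(r) r$arm$same_local))
  diff <- unlist(lapply(recs, function(r) r$arm$diff_local))
  cross <- unlist(lapply(recs, function(r) r$arm$cross_global))
  shuf <- unlist(lapply(recs, function(r) r$arm$shuffled))
  list(metrics = list(
    same_local = same, diff_local = diff, cross_global = cross,
    shuffled = shuf,
    median_same = stats::median(same, na.rm = TRUE),
    median_diff = stats::median(diff, na.rm = TRUE),
    mean_cross_global = mean(cross, na.rm = TRUE),
    of_correlations = rowMeans(do.call(cbind, lapply(recs, function(r)
      rowMeans(r$corr_of, na.rm = TRUE))), na.rm = TRUE),
    gridness_vh = unlist(lapply(recs, function(r) r$g_vh)),
    gridness_hp = unlist(lapply(recs, function(r) r$g_hp)),
    arm_matrices = recs[[1]]$arm[c("mat_east", "mat_west")]))
}

proto_semi_transparent <- function(p, seed)
  proto_hairpin_series(p, seed, st_walls = TRUE)

proto_virtual_hairpin <- function(p, seed) proto_hairpin_series(p, seed)

proto_spiral <- function(p, seed) {
  arena <- build_arena("spiral", 150)
  bank <- make_module_bank()
  cells <- make_grid_cells(bank, p$n_cells, module = 1, seed = seed + 41)
  traj <- generate_hairpin_path(arena, p$n_traversals, seed = seed + 42)
  fit <- sifm(traj, arena, config = p$fusion, noise = p$noise, bank = bank,
              cells = cells, seed = seed + 43)
  # inward = easterly tag (odd traversals), outward = westerly
  m_in <- arm_correlation_matrix(fit$rates, traj, arena, "E")
  m_out <- arm_correlation_matrix(fit$rates, traj, arena, "W")
  list(metrics = list(mat_inward = m_in$r, mat_outward = m_out$r,
                      sessions = session_summary(fit)))
}

proto_map_resolution_series <- function(p, seed) {
  out <- list()
  for (f in c(0.5, 2)) {
    cfg <- p$fusion
    cfg$spacing <- cfg$spacing * f
    cfg$sigma_g <- cfg$sigma_g * f
    cfg$d_max <- cfg$d_max * f
    pp <- p; pp$fusion <- cfg; pp$n_trials <- 1
    r <- proto_hairpin_series(pp, seed + round(1000 * f))
    out[[paste0("res_x", 1 / f)]] <-
      r$metrics[c("median_same", "median_diff", "gridness_hp")]
  }
  list(metrics = out)
}

proto_selfmotion_noise_series <- function(p, seed) {
  out <- list()
  for (f in c(0.25, 4)) {
    pp <- p
    pp$noise <- scale_selfmotion_noise(p$noise, f)
    pp$n_trials <- 1
    r <- proto_hairpin_series(pp, seed + round(100 * f))
    out[[paste0("var_x", f)]] <-
      list(median_same = r$metrics$median_same,
           median_diff = r$metrics$median_diff,
           gridness_hp = r$metrics$gridness_hp,
           mean_gridness_hp = mean(r$metrics$gridness_hp, na.rm = TRUE))
  }
  list(metrics = out)
}

proto_lesion_series <- function(p, seed) {
  arena <- build_arena("square", 100)
  bank <- make_module_bank()
  cells <- rbind_cells(lapply(1:4, function(m)
    make_grid_cells(bank, max(4, p$n_cells %/% 4), module = m,
                    seed = seed + m)))
  traj <- generate_forage(arena, p$duration, seed = seed + 51)
  fit <- sifm(traj, arena, config = p$fusion, noise = p$noise, bank = bank,
              cells = cells, seed = seed + 52)
  g_pre <- grid_cell_metrics(fit)$gridness
  fit_cells <- lesion(fit, 0.5, "drop_cells", seed = seed)
  g_cells <- grid_cell_metrics(fit_cells)$gridness
  fit_mod <- lesion(fit, 0.5, "drop_modules")
  g_mod <- grid_cell_metrics(fit_mod)$gridness
  list(metrics = list(gridness_pre = g_pre, gridness_drop_cells = g_cells,
                      gridness_drop_modules = g_mod,
                      mean_pre = mean(g_pre, na.rm = TRUE),
                      mean_drop_cells = mean(g_cells, na.rm = TRUE),
                      mean_drop_modules = mean(g_mod, na.rm = TRUE)))
}

rbind_cells <- function(lst) {
  out <- do.call(rbind, lst)
  out$cell <- seq_len(nrow(out))
  out
}

#' Classification sensitivity over labelled cells from learning runs
#'
#' Pools the classified grid and predictive-boundary cells of one or more
#' open-arena learning runs (run with `classify = TRUE`) and returns the
#' per-class sensitivity of the parametric rate-map correlation method
#' (unclassified cells count as misses).
#'
#' @param runs list of `sifm_run` records from `learn_square` /
#'   `learn_circle`.
#' @return list: `sens_grid`, `sens_boundary`, `n_grid`, `n_boundary`.
#' @export
classifier_sensitivity <- function(runs) {
  g <- unlist(lapply(runs, function(r) r$metrics$grid_cells$class))
  b <- unlist(lapply(runs, function(r) r$metrics$boundary_cells$class))
  g <- g[!is.na(g)]
  b <- b[!is.na(b)]
  list(sens_grid = mean(g == "grid"),
       sens_boundary = mean(b == "boundary"),
       n_grid = length(g), n_boundary = length(b))
}

#' Summarize metrics across protocol runs
#'
#' Aggregates a numeric metric over runs with mean, SD and a bootstrap
#' confidence interval of the mean.
#'
#' @param records list of `sifm_run` records (or numeric vectors).
#' @param metric name of the metric to pool (scalar or vector per record).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed seed for resampling.
#' @return data.frame with n, mean, sd, ci_lo, ci_hi.
#' @export
summarize_runs <- function(records, metric = NULL, n_boot = 10000,
                           conf = 0.95, seed = 1) {
  vals <- unlist(lapply(records, function(r) {
    if (is.numeric(r)) r
    else r$metrics[[metric]]
  }))
  vals <- vals[is.finite(vals)]
  ci <- boot_ci(vals, n_boot = n_boot, conf = conf, seed = seed)
  data.frame(n = length(vals), mean = mean(vals), sd = stats::sd(vals),
             ci_lo = ci[1], ci_hi = ci[2])
}

#' Bootstrap confidence interval of a statistic
#'
#' @param x numeric vector.
#' @param stat statistic function (default mean).
#' @param n_boot resamples.
#' @param conf confidence level.
#' @param seed seed.
#' @return length-2 vector (lower, upper); zero-width for constant input.
#' @export
boot_ci <- function(x, stat = mean, n_boot = 10000, conf = 0.95, seed = 1) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  if (length(unique(x)) == 1) return(c(x[1], x[1]))
  set.seed(seed)
  bs <- vapply(seq_len(n_boot), function(i) stat(sample(x, replace = TRUE)),
               numeric(1))
  unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}
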