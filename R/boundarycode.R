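#' Build the 228-cell boundary code bank
#'
#' Twelve allocentric tuning directions (30 degree spacing) crossed with
#' nineteen tuning distances: eight short-range distances within the
#' somatosensory contact range (enabling boundary detection in darkness)
#' and eleven long-range distances on a geometric ladder through the
#' place-cell-derived optima at 16.2 and 33.8 cm. Radial tuning width grows
#' linearly with tuning distance, `sigma_rad = a (d / beta + 1)`; angular
#' width is a wrapped Gaussian with `sigma_theta = pi / 12`.
#'
#' @param contact_range contact sensing range (cm); the short-range
#'   distances span up to this value.
#' @param a,beta radial width parameters (cm).
#' @param sigma_theta angular tuning width (rad).
#' @return data.frame with 228 rows: cell, dist_index, dir_index, d, theta,
#'   sigma_rad, sigma_theta, range_class.
#' @export
make_boundary_bank <- function(contact_range = 13, a = 2.4, beta = 30,
                               sigma_theta = pi / 12) {
  d_short <- c(1, 2, 3, 4.5, 6.5, 9, 11, 13) * (contact_range / 13)
  # geometric ladder through the place-field-derived optima at 16.2 and
  # 33.8 cm (three rungs apart), spanning ~8-90 cm as in hippocampal
  # boundary-vector fits where most tuning distances sit near the wall
  g <- (33.8 / 16.2)^(1 / 3)
  d_long <- 16.2 * g^(-3:7)
  d <- c(d_short, d_long)
  theta <- (0:11) * pi / 6
  grid <- expand.grid(dist_index = seq_along(d),
                      dir_index = seq_along(theta))
  out <- data.frame(cell = seq_len(nrow(grid)),
                    dist_index = grid$dist_index,
                    dir_index = grid$dir_index,
                    d = d[grid$dist_index], theta = theta[grid$dir_index],
                    sigma_rad = a * (d[grid$dist_index] / beta + 1),
                    sigma_theta = sigma_theta,
                    range_class = ifelse(grid$dist_index <=
                                           length(d_short), "short", "long"))
  out
}

#' Sensory boundary-code activity from an egocentric observation
#'
#' Each egocentric hit is rotated into allocentric coordinates via the
#' heading estimate; cell (i, j) responds with the product of a radial
#' Gaussian around its tuning distance and a wrapped-Gaussian angular
#' kernel around its tuning direction, aggregated over hits by maximum. In
#' darkness long-range cells are masked to zero.
#'
#' @param obs observation data.frame from [observe_boundaries()] (columns
#'   angle, distance, hit; attribute `regime`).
#' @param heading_estimate heading estimate used for the egocentric to
#'   allocentric transform (rad).
#' @param bank boundary bank from [make_boundary_bank()].
#' @return numeric vector of length `nrow(bank)` in [0, 1], with the regime
#'   mask applied.
#' @export
sensory_boundary_code <- function(obs, heading_estimate, bank) {
  act <- numeric(nrow(bank))
  regime <- attr(obs, "regime")
  hits <- obs[obs$hit > 0 & is.finite(obs$distance), , drop = FALSE]
  if (nrow(hits) > 0) {
    alpha <- hits$angle + heading_estimate
    for (h in seq_len(nrow(hits))) {
      radial <- exp(-(hits$distance[h] - bank$d)^2 / (2 * bank$sigma_rad^2))
      delta <- wrap_angle(alpha[h] - bank$theta)
      angular <- exp(-delta^2 / (2 * bank$sigma_theta^2))
      angular[abs(delta) > 3.5 * bank$sigma_theta] <- 0
      act <- pmax(act, radial * angular)
    }
  }
  if (identical(regime, "dark")) act[bank$range_class == "long"] <- 0
  act
}

#' Expected perpendicular firing-field distance of a boundary cell
#'
#' The wrapped-Gaussian angular tuning shortens the mean perpendicular
#' response distance relative to the tuning distance:
#' `y = d * exp(-sigma_theta^2 / 2)`.
#'
#' @param d tuning distance (cm).
#' @param sigma_theta angular tuning width (rad).
#' @return expected field distance (cm).
#' @export
expected_field_distance <- function(d, sigma_theta = pi / 12) {
  stopifnot(all(d > 0))
  d * exp(-sigma_theta^2 / 2)
}
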