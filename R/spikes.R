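#' Simulate spikes from a rate series by Poisson thinning
#'
#' Inhomogeneous Poisson process with instantaneous rate
#' `peak_rate * rate(t)`: candidate events are drawn from a homogeneous
#' process at `peak_rate` and accepted with probability equal to the
#' normalized rate at their time.
#'
#' @param rates rate series in [0, 1] sampled at `dt`.
#' @param peak_rate peak firing rate (Hz).
#' @param dt sampling interval (s).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return strictly increasing spike times (s) within [0, duration].
#' @export
poisson_spikes <- function(rates, peak_rate = 15, dt = 0.1, seed = NULL) {
  if (any(rates < 0)) stop("negative rates")
  stopifnot(all(rates <= 1 + 1e-9), peak_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  duration <- length(rates) * dt
  n_cand <- stats::rpois(1, peak_rate * duration)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(stats::runif(n_cand, 0, duration))
  idx <- pmin(length(rates), floor(tt / dt) + 1)
  keep <- stats::runif(n_cand) < rates[idx]
  tt[keep]
}
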