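#' The four-parameter Boltzmann sigmoid
#'
#' Evaluates `y(t) = A2 + (A1 - A2) / (1 + exp((t - t0)/dt))`, the standard
#' "Boltzmann" form used by curve-fitting software for sigmoidal growth or
#' accumulation series. `A1` is the left (initial) asymptote, `A2` the right
#' (final) asymptote, `t0` the inflection time and `dt` the slope factor:
#' smaller `dt` means a steeper transition. At `t = t0` the curve passes
#' exactly through the midpoint `(A1 + A2)/2`.
#'
#' @param t numeric vector of times (h).
#' @param A1 initial asymptote (concentration units, e.g. µmol L⁻¹).
#' @param A2 final asymptote.
#' @param t0 inflection time (h).
#' @param dt slope factor (h); must be non-zero.
#' @return numeric vector of curve values, same length as `t`.
#' @seealso [boltzmann_deriv()] for the analytic first derivative,
#'   [fit_boltzmann()] to estimate the parameters from data.
#' @examples
#' boltzmann(30, A1 = 0, A2 = 100, t0 = 30, dt = 5)  # exactly 50
#' @export
boltzmann <- function(t, A1, A2, t0, dt) {
  stopifnot(is.numeric(t), length(dt) == 1L, dt != 0)
  A2 + (A1 - A2) / (1 + exp((t - t0) / dt))
}

#' Analytic first derivative of the Boltzmann sigmoid
#'
#' Returns `dy/dt = (A2 - A1) * exp(u) / (dt * (1 + exp(u))^2)` with
#' `u = (t - t0)/dt`. For a rising curve (`A2 > A1`, `dt > 0`) this is a
#' symmetric bell around `t0` with maximum `(A2 - A1)/(4*dt)` attained exactly
#' at `t = t0` — the maximum instantaneous transformation rate.
#'
#' The expression is evaluated through `1/(e^u + 2 + e^-u)` so that it
#' underflows gracefully to 0 in the far tails instead of producing `Inf/Inf`.
#'
#' @inheritParams boltzmann
#' @return numeric vector of rates (concentration per hour).
#' @export
boltzmann_deriv <- function(t, A1, A2, t0, dt) {
  stopifnot(is.numeric(t), length(dt) == 1L, dt != 0)
  u <- (t - t0) / dt
  # (A2-A1)/dt * e^u/(1+e^u)^2, tail-safe
  (A2 - A1) / dt / (exp(u) + 2 + exp(-u))
}

#' Sample a Boltzmann curve with optional Gaussian noise
#'
#' Fixture generator for fit-recovery experiments: evaluates the sigmoid on a
#' sampling grid and adds iid Gaussian measurement noise. With a fixed `seed`
#' the output is bit-reproducible.
#'
#' @inheritParams boltzmann
#' @param times strictly increasing, non-empty sampling grid (h).
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (concentration units); 0 gives the noiseless curve.
#' @param seed optional integer seed for the noise draw.
#' @return numeric vector `y(times)` (+ noise).
#' @examples
#' y <- generate_boltzmann_series(0, 100, 30, 5, times = seq(0, 80, 2),
#'                                noise_sd = 2, seed = 1)
#' @export
generate_boltzmann_series <- function(A1, A2, t0, dt, times,
                                      noise_sd = 0, seed = NULL) {
  if (length(times) == 0L) stop("'times' must be non-empty")
  if (any(!is.finite(times))) stop("'times' must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (dt == 0) stop("'dt' must be non-zero")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  y <- boltzmann(times, A1, A2, t0, dt)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  y
}
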