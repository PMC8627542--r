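#' Replicate-average an analyte series from an incubation table
#'
#' Collapses a long-format incubation table to one mean (and SD) value per
#' sampling time for the requested analyte. `"NOx"` (nitrite + nitrate) tracks
#' cumulative ammonia oxidation; `"NO3"` tracks cumulative nitrite oxidation;
#' the derived sums are always recomputed from the stored columns. At least 5
#' distinct time points are required — the sigmoid has 4 parameters and a fit
#' needs at least one residual degree of freedom.
#'
#' @param series an incubation data frame as returned by
#'   [simulate_incubation()] or [read_incubation_csv()]: columns `time_h`,
#'   `replicate`, `nh4_umol_L`, `no2_umol_L`, `no3_umol_L`.
#' @param analyte one of `"NOx"`, `"NO3"`, `"NO2"`, `"NH4"`.
#' @return a data frame with columns `time_h`, `mean`, `sd` (SD is `NA` where
#'   only one replicate is present) and `n`, ordered by time.
#' @export
prepare_analyte_series <- function(series, analyte = c("NOx", "NO3", "NO2", "NH4")) {
  analyte <- match.arg(analyte)
  series <- validate_incubation(series)
  v <- switch(analyte,
    NOx = series$no2_umol_L + series$no3_umol_L,
    NO3 = series$no3_umol_L,
    NO2 = series$no2_umol_L,
    NH4 = series$nh4_umol_L)
  tt <- series$time_h
  ut <- sort(unique(tt))
  if (length(ut) < 5L)
    stop("need >= 5 distinct time points to fit a 4-parameter sigmoid, got ",
         length(ut))
  m <- vapply(ut, function(x) mean(v[tt == x]), numeric(1))
  s <- vapply(ut, function(x) {
    vi <- v[tt == x]
    if (length(vi) > 1L) stats::sd(vi) else NA_real_
  }, numeric(1))
  n <- vapply(ut, function(x) sum(tt == x), integer(1))
  data.frame(time_h = ut, mean = m, sd = s, n = n)
}

#' Fit the Boltzmann sigmoid to a concentration time series
#'
#' Bounded nonlinear least squares (Levenberg–Marquardt) fit of
#' `y = A2 + (A1 - A2)/(1 + exp((t - t0)/dt))` to a cumulative analyte series,
#' typically the replicate-mean NOx⁻ (for ammonia oxidation) or NO3⁻ (for
#' nitrite oxidation) trace of a potential-rate incubation.
#'
#' Starting values are taken from the data: `A1` from the first observation,
#' `A2` from the last, `t0` from the first linear-interpolated crossing of the
#' midpoint `(A1 + A2)/2`, and `dt` as one tenth of the observed time span.
#' `A1` and `A2` are bounded within one data range of the observed minimum and
#' maximum; `dt` is bounded in `(1e-6, time span]`, which keeps fitted rising
#' series rising. If the first attempt does not converge, up to three restarts
#' from multiplicatively jittered (±20%, seed-controlled) starting values are
#' tried before failing with the optimizer diagnostics — a silently
#' non-converged fit is never returned.
#'
#' @param times numeric vector of sampling times (h).
#' @param values concentrations at `times` (µmol L⁻¹). May also be given as a
#'   prepared data frame from [prepare_analyte_series()] in place of `times`.
#' @param weights optional fit weights (e.g. `1/sd^2`); default unweighted.
#' @param analyte optional label (`"NOx"`, `"NO3"`, ...) carried into reports.
#' @param restart_seed integer seed for the jittered restarts.
#' @return an object of class `boltzmann_fit`: a list with components
#'   `coefficients` (named `A1`, `A2`, `t0`, `dt`), `vcov`, `rss`, `r2`,
#'   `sigma`, `n`, `analyte`, `data` and `convergence`. Methods:
#'   [coef()], [vcov()], [predict.boltzmann_fit()], [fitted()], [residuals()],
#'   [simulate.boltzmann_fit()], [print()], [summary()], [plot()].
#' @examples
#' t <- seq(0, 80, 2)
#' fit <- fit_boltzmann(t, boltzmann(t, 0, 100, 30, 5))
#' coef(fit)
#' @export
fit_boltzmann <- function(times, values = NULL, weights = NULL,
                          analyte = NA_character_, restart_seed = 1L) {
  if (is.data.frame(times) && is.null(values)) {
    values <- times$mean
    times <- times$time_h
  }
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  ok <- is.finite(times) & is.finite(values)
  if (!all(ok)) stop("non-finite values in input series")
  if (length(unique(times)) < 5L)
    stop("need >= 5 distinct time points to fit a 4-parameter sigmoid")
  o <- order(times)
  times <- times[o]; values <- values[o]
  if (diff(range(values)) == 0)
    stop("degenerate flat series: all values equal (", values[1],
         "); no sigmoid can be fitted")

  span <- diff(range(times))
  rng <- diff(range(values))
  start <- c(A1 = values[1L], A2 = values[length(values)],
             t0 = .midpoint_crossing(times, values), dt = span / 10)
  lower <- c(A1 = min(values) - rng, A2 = min(values) - rng,
             t0 = min(times) - span, dt = 1e-6)
  upper <- c(A1 = max(values) + rng, A2 = max(values) + rng,
             t0 = max(times) + span, dt = span)
  start <- pmin(pmax(start, lower), upper)

  if (!is.null(weights)) {
    if (length(weights) != length(values) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop("'weights' must be positive, finite and match the series length")
    weights <- weights[o]
  }
  sw <- if (is.null(weights)) rep(1, length(values)) else sqrt(weights)

  # weighted residuals and their analytic Jacobian for Levenberg-Marquardt
  resid_fn <- function(p) {
    sw * (values - boltzmann(times, p[1L], p[2L], p[3L], p[4L]))
  }
  jac_fn <- function(p) {
    u <- (times - p[3L]) / p[4L]
    s <- stats::plogis(-u)                 # 1/(1+e^u)
    g <- 1 / (exp(u) + 2 + exp(-u))        # e^u/(1+e^u)^2, tail-safe
    -sw * cbind(A1 = s, A2 = 1 - s,
                t0 = (p[1L] - p[2L]) * g / p[4L],
                dt = (p[1L] - p[2L]) * g * u / p[4L])
  }
  ctrl <- minpack.lm::nls.lm.control(maxfev = 2000, ptol = 1e-10, ftol = 1e-12)
  do_fit <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, jac = jac_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) e)
  }
  converged <- function(f) !inherits(f, "error") && f$info %in% 1:3

  fit <- do_fit(start)
  attempts <- 1L
  diag_msgs <- character()
  jit_rng <- local({ set.seed(restart_seed); function(n) stats::runif(n, 0.8, 1.2) })
  while (!converged(fit) && attempts <= 3L) {
    diag_msgs <- c(diag_msgs, if (inherits(fit, "error")) conditionMessage(fit)
                   else fit$message)
    st <- start * jit_rng(4L)
    st <- pmin(pmax(st, lower), upper)
    fit <- do_fit(st)
    attempts <- attempts + 1L
  }
  if (!converged(fit))
    stop("Boltzmann fit failed to converge after ", attempts,
         " attempts (jittered restarts included); diagnostics: ",
         paste(unique(diag_msgs), collapse = "; "))

  cf <- fit$par
  res <- values - boltzmann(times, cf["A1"], cf["A2"], cf["t0"], cf["dt"])
  rss <- sum(sw^2 * res^2)
  tss <- sum(sw^2 * (values - stats::weighted.mean(values, sw^2))^2)
  s2 <- rss / max(1L, length(values) - 4L)
  vc <- tryCatch(s2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf)))
  })
  dimnames(vc) <- list(names(cf), names(cf))
  structure(list(
    coefficients = cf,
    vcov = vc,
    rss = rss,
    r2 = 1 - rss / tss,
    sigma = sqrt(rss / max(1L, length(values) - 4L)),
    n = length(values),
    analyte = analyte,
    data = data.frame(time_h = times, value = values),
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter, deviance = fit$deviance),
    attempts = attempts,
    call = match.call()
  ), class = "boltzmann_fit")
}

# first linear-interpolated crossing of the midpoint between first and last
# value; falls back to mid-window when the series never crosses it
.midpoint_crossing <- function(times, values) {
  mid <- (values[1L] + values[length(values)]) / 2
  s <- values - mid
  i <- which(s[-length(s)] * s[-1L] <= 0 & s[-length(s)] != s[-1L])
  if (length(i) == 0L) return(mean(range(times)))
  i <- i[1L]
  times[i] + (times[i + 1L] - times[i]) * (mid - values[i]) / (values[i + 1L] - values[i])
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
vcov.boltzmann_fit <- function(object, ...) object$vcov

#' Predict concentrations or instantaneous rates from a Boltzmann fit
#'
#' @param object a [fit_boltzmann()] result.
#' @param times times (h) at which to evaluate; defaults to the fitted data
#'   grid.
#' @param type `"conc"` for the fitted sigmoid (µmol L⁻¹) or `"rate"` for its
#'   analytic first derivative (µmol L⁻¹ h⁻¹), the instantaneous
#'   transformation rate.
#' @param ... unused.
#' @export
predict.boltzmann_fit <- function(object, times = NULL,
                                  type = c("conc", "rate"), ...) {
  type <- match.arg(type)
  if (is.null(times)) times <- object$data$time_h
  if (any(!is.finite(times))) stop("'times' must be finite")
  cf <- object$coefficients
  f <- if (type == "conc") boltzmann else boltzmann_deriv
  f(times, cf[["A1"]], cf[["A2"]], cf[["t0"]], cf[["dt"]])
}

#' @export
fitted.boltzmann_fit <- function(object, ...) predict(object)

#' @export
residuals.boltzmann_fit <- function(object, ...)
  object$data$value - fitted(object)

#' @export
deviance.boltzmann_fit <- function(object, ...) object$rss

#' Simulate new noisy series from a fitted Boltzmann curve
#'
#' Draws `nsim` replicate series on the fitted time grid, adding Gaussian
#' noise with the residual standard deviation of the fit.
#'
#' @param object a [fit_boltzmann()] result.
#' @param nsim number of simulated series.
#' @param seed integer seed.
#' @param ... unused.
#' @return a data frame with one column per simulated series.
#' @export
simulate.boltzmann_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  row.names(out) <- NULL
  out
}

#' @export
print.boltzmann_fit <- function(x, digits = 4, ...) {
  cat("Boltzmann sigmoid fit",
      if (!is.na(x$analyte)) paste0(" (analyte: ", x$analyte, ")"), "\n", sep = "")
  cat("  y(t) = A2 + (A1 - A2)/(1 + exp((t - t0)/dt))\n")
  print(round(x$coefficients, digits))
  cat("  n =", x$n, " RSS =", signif(x$rss, digits),
      " R^2 =", round(x$r2, max(digits, 4)), "\n")
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  cf <- object$coefficients
  tab <- cbind(Estimate = cf, `Std. Error` = se)
  structure(list(coefficients = tab, rss = object$rss, r2 = object$r2,
                 sigma = object$sigma, n = object$n, analyte = object$analyte,
                 peak_rate = unname((cf["A2"] - cf["A1"]) / (4 * cf["dt"])),
                 t_peak = unname(cf["t0"])),
            class = "summary.boltzmann_fit")
}

#' @export
print.summary.boltzmann_fit <- function(x, digits = 4, ...) {
  cat("Boltzmann sigmoid fit",
      if (!is.na(x$analyte)) paste0(" (analyte: ", x$analyte, ")"), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nResidual SD:", signif(x$sigma, digits), "on", x$n - 4, "d.o.f.",
      "  R^2:", round(x$r2, 4), "\n")
  cat("Peak instantaneous rate (A2-A1)/(4 dt):", signif(x$peak_rate, digits),
      "at t0 =", signif(x$t_peak, digits), "h\n")
  invisible(x)
}

#' Plot a Boltzmann fit with its instantaneous-rate curve
#'
#' Data points, the fitted sigmoid, and (optionally, on a second panel) the
#' analytic first-derivative rate curve.
#'
#' @param x a [fit_boltzmann()] result.
#' @param deriv also draw the derivative (rate) panel.
#' @param n_grid curve resolution.
#' @param ... passed to [plot.default()] for the data panel.
#' @export
plot.boltzmann_fit <- function(x, deriv = TRUE, n_grid = 201, ...) {
  tg <- seq(min(x$data$time_h), max(x$data$time_h), length.out = n_grid)
  if (deriv) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  plot(x$data$time_h, x$data$value, xlab = "time (h)",
       ylab = expression(paste("concentration (", mu, "mol ", L^-1, ")")),
       main = if (!is.na(x$analyte)) paste("Boltzmann fit:", x$analyte)
              else "Boltzmann fit", ...)
  graphics::lines(tg, predict(x, tg), col = "firebrick", lwd = 2)
  if (deriv) {
    plot(tg, predict(x, tg, type = "rate"), type = "l", col = "steelblue",
         lwd = 2, xlab = "time (h)",
         ylab = expression(paste("rate (", mu, "mol ", L^-1, " ", h^-1, ")")))
    graphics::abline(v = x$coefficients[["t0"]], lty = 3)
  }
  invisible(x)
}
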