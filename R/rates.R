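#' Average transformation rate over a window from a fitted curve
#'
#' The average ammonia-oxidation rate \eqn{\bar V_a} (from a NOx⁻ fit) or
#' nitrite-oxidation rate \eqn{\bar V_n} (from a NO3⁻ fit) over a window
#' `[T_i, T_f]` is the fitted concentration change divided by the elapsed
#' time:
#' \deqn{\bar V = (y_{fit}(T_f) - y_{fit}(T_i)) / (T_f - T_i).}
#' Endpoint values are taken from the fitted curve, not the raw data, which
#' smooths over measurement noise at the two endpoints; see
#' [average_rate_raw()] for the raw-endpoint alternative.
#'
#' @param fit a [fit_boltzmann()] result.
#' @param window numeric length-2, `c(T_i, T_f)` with `T_f > T_i` (h);
#'   defaults to the fitted data span.
#' @return average rate (µmol L⁻¹ h⁻¹).
#' @export
average_rate <- function(fit, window = range(fit$data$time_h)) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  window <- .check_window(window)
  diff(predict(fit, window)) / diff(window)
}

#' Average rate from raw endpoint observations
#'
#' Companion to [average_rate()]: uses the replicate-mean observed values at
#' the sampled times nearest to the window endpoints instead of the fitted
#' curve. More sensitive to endpoint noise; provided for comparison.
#'
#' @param series an incubation data frame (see [prepare_analyte_series()]).
#' @param analyte `"NOx"` or `"NO3"` (or `"NO2"`, `"NH4"`).
#' @param window numeric length-2 window (h); defaults to the sampled span.
#' @return average rate (µmol L⁻¹ h⁻¹).
#' @export
average_rate_raw <- function(series, analyte = "NOx", window = NULL) {
  prep <- prepare_analyte_series(series, analyte)
  if (is.null(window)) window <- range(prep$time_h)
  window <- .check_window(window)
  i <- which.min(abs(prep$time_h - window[1L]))
  f <- which.min(abs(prep$time_h - window[2L]))
  if (i == f) stop("window endpoints map to the same sampled time")
  (prep$mean[f] - prep$mean[i]) / (prep$time_h[f] - prep$time_h[i])
}

.check_window <- function(window) {
  if (length(window) != 2L || any(!is.finite(window)))
    stop("'window' must be two finite times c(T_i, T_f)")
  if (window[2L] <= window[1L])
    stop("'window' must satisfy T_f > T_i (got [", window[1L], ", ",
         window[2L], "])")
  as.numeric(window)
}

#' Lag / exponential / plateau phase boundaries of a sigmoid fit
#'
#' The instantaneous rate of a rising Boltzmann curve peaks at
#' `(A2 - A1)/(4 dt)` at `t = t0`. The lag phase is taken to end — and the
#' plateau phase to begin — where the rate crosses a fraction
#' `threshold_frac` of that maximum. Writing `r = exp((t - t0)/dt)`, the
#' crossing condition is the quadratic `r^2 - (4/f - 2) r + 1 = 0`
#' (`f = threshold_frac`), solved in closed form; its two roots are
#' reciprocal, so the boundaries are symmetric about `t0`.
#'
#' @param fit a [fit_boltzmann()] result (rising: `A2 > A1`).
#' @param window optional length-2 window (h) to clip the boundaries to.
#' @param threshold_frac fraction of the maximum derivative defining the
#'   phase boundaries, in (0, 1); default 0.10.
#' @return named numeric `c(lag_end, plateau_start)` (h).
#' @examples
#' fit <- fit_boltzmann(seq(0, 80, 2), boltzmann(seq(0, 80, 2), 0, 100, 30, 5))
#' segment_phases(fit)  # ~ 30 -+ 18.18 h
#' @export
segment_phases <- function(fit, window = NULL, threshold_frac = 0.10) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  if (!is.finite(threshold_frac) || threshold_frac <= 0 || threshold_frac >= 1)
    stop("'threshold_frac' must lie strictly within (0, 1)")
  cf <- fit$coefficients
  b <- 4 / threshold_frac - 2            # sum of the reciprocal root pair
  r_hi <- (b + sqrt(b^2 - 4)) / 2        # > 1 root; the other is 1/r_hi
  delta <- cf[["dt"]] * log(r_hi)        # half-width of the exponential phase
  out <- c(lag_end = cf[["t0"]] - delta, plateau_start = cf[["t0"]] + delta)
  if (!is.null(window)) {
    window <- .check_window(window)
    out <- pmin(pmax(out, window[1L]), window[2L])
  }
  out
}

#' Instantaneous-rate profile of a fitted analyte curve
#'
#' Assembles the full rate description of one fitted series over a window:
#' the average rate ([average_rate()]), the maximum instantaneous rate and
#' its time, the lag/plateau phase boundaries ([segment_phases()]), and a
#' dense grid of the fitted curve and its derivative for plotting or export.
#'
#' The derivative of a rising Boltzmann curve increases monotonically up to
#' `t0` and decreases beyond it, so the window maximum is `(A2 - A1)/(4 dt)`
#' at `t0` when `t0` lies inside the window and the derivative at the nearer
#' window endpoint otherwise — the closed form is used, not a grid search.
#'
#' @param fit a [fit_boltzmann()] result.
#' @param window numeric length-2 window (h); defaults to the fitted span.
#' @param threshold_frac passed to [segment_phases()].
#' @param n_grid resolution of the exported rate grid.
#' @return an object of class `rate_profile`: list with `analyte`, `v_avg`,
#'   `v_max`, `t_at_vmax`, `phases`, `window`, `grid` (data frame `time_h`,
#'   `fitted`, `rate`) and the underlying `fit`.
#' @export
instantaneous_profile <- function(fit, window = range(fit$data$time_h),
                                  threshold_frac = 0.10, n_grid = 201L) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  window <- .check_window(window)
  cf <- fit$coefficients
  t0 <- cf[["t0"]]
  if (t0 >= window[1L] && t0 <= window[2L]) {
    t_star <- t0
    v_max <- (cf[["A2"]] - cf[["A1"]]) / (4 * cf[["dt"]])
  } else {
    t_star <- window[which.min(abs(window - t0))]
    v_max <- predict(fit, t_star, type = "rate")
  }
  tg <- seq(window[1L], window[2L], length.out = n_grid)
  structure(list(
    analyte = fit$analyte,
    v_avg = average_rate(fit, window),
    v_max = unname(v_max),
    t_at_vmax = unname(t_star),
    phases = segment_phases(fit, window, threshold_frac),
    window = window,
    grid = data.frame(time_h = tg, fitted = predict(fit, tg),
                      rate = predict(fit, tg, type = "rate")),
    fit = fit
  ), class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, digits = 4, ...) {
  cat("Rate profile", if (!is.na(x$analyte)) paste0(" (", x$analyte, ")"),
      " over [", x$window[1L], ", ", x$window[2L], "] h\n", sep = "")
  cat(sprintf("  average rate      %.4g umol/L/h\n", x$v_avg))
  cat(sprintf("  max instantaneous %.4g umol/L/h at %.4g h\n", x$v_max, x$t_at_vmax))
  cat(sprintf("  lag end %.4g h, plateau start %.4g h\n",
              x$phases[["lag_end"]], x$phases[["plateau_start"]]))
  invisible(x)
}

#' Index of nitrogen balance (INB) time series
#'
#' The INB at time t is the ratio of total dissolved inorganic nitrogen to
#' its initial value,
#' \deqn{INB(t) = DIN(t)/DIN(0),\quad DIN = [NH_4^+] + [NO_2^-] + [NO_3^-],}
#' computed on replicate means. In a closed incubation nitrification only
#' shuffles nitrogen between the three pools, so INB stays at 1; values below
#' `1 - tolerance` indicate net nitrogen loss (denitrification, anammox,
#' assimilation), values above `1 + tolerance` net release by organic-matter
#' mineralization.
#'
#' @param series an incubation data frame (see [prepare_analyte_series()]).
#' @param tolerance half-width of the "balanced" band around 1; default 0.05.
#' @return an object of class `inb_series`: data frame with `time_h`, `din`,
#'   `inb` and `label` (`loss`/`balanced`/`mineralization`), with the
#'   tolerance as an attribute. The last row's `inb` is the classical
#'   final/initial index.
#' @export
compute_inb <- function(series, tolerance = 0.05) {
  if (!is.finite(tolerance) || tolerance < 0)
    stop("'tolerance' must be finite and >= 0")
  series <- validate_incubation(series)
  din <- series$nh4_umol_L + series$no2_umol_L + series$no3_umol_L
  ut <- sort(unique(series$time_h))
  dmean <- vapply(ut, function(x) mean(din[series$time_h == x]), numeric(1))
  if (dmean[1L] <= 0)
    stop("DIN at the first sampled time is ", dmean[1L],
         "; INB = DIN(t)/DIN(0) is undefined")
  inb <- dmean / dmean[1L]
  label <- ifelse(inb < 1 - tolerance, "loss",
                  ifelse(inb > 1 + tolerance, "mineralization", "balanced"))
  structure(data.frame(time_h = ut, din = dmean, inb = inb, label = label),
            tolerance = tolerance, class = c("inb_series", "data.frame"))
}

#' @export
print.inb_series <- function(x, ...) {
  tol <- attr(x, "tolerance")
  cat("Index of nitrogen balance, DIN(t)/DIN(0); balanced band 1 +/- ",
      tol, "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  final <- x$inb[nrow(x)]
  cat(sprintf("Final INB = %.3f (%s)\n", final, x$label[nrow(x)]))
  invisible(x)
}

#' Full per-sample nitrification analysis
#'
#' Runs the complete per-sample workflow on one incubation series: fits the
#' Boltzmann sigmoid to the cumulative NOx⁻ (nitrite + nitrate) series for
#' ammonia oxidation and to the NO3⁻ series for nitrite oxidation, derives
#' the average and instantaneous rate profiles for each, and computes the INB
#' time series. Deterministic given the inputs; a failure in any stage is
#' re-raised with the stage name.
#'
#' @param series an incubation data frame.
#' @param window analysis window (h); default the sampled span.
#' @param tolerance INB balanced-band half width (default 0.05).
#' @param threshold_frac phase-boundary threshold (default 0.10).
#' @param weighted use `1/sd^2` replicate weights in the fits (default
#'   unweighted; requires >= 2 replicates).
#' @return an object of class `nitrification_report`: list with `fits`
#'   (`NOx`, `NO3` [fit_boltzmann()] objects), `profiles` (`va`, `vn`
#'   [instantaneous_profile()] objects), `inb`, `nh4_summary`, `window` and
#'   the option values used.
#' @examples
#' sim <- simulate_incubation(sim_preset("sample_B_like"))
#' rep <- analyze_sample(sim$series)
#' rep
#' @export
analyze_sample <- function(series, window = NULL, tolerance = 0.05,
                           threshold_frac = 0.10, weighted = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  series <- stage("validate", validate_incubation(series))
  prep_nox <- stage("prepare_NOx", prepare_analyte_series(series, "NOx"))
  prep_no3 <- stage("prepare_NO3", prepare_analyte_series(series, "NO3"))
  wts <- function(prep) {
    if (!weighted) return(NULL)
    if (anyNA(prep$sd) || any(prep$sd == 0))
      stop("weighted fit needs a positive SD at every time point")
    1 / prep$sd^2
  }
  fit_nox <- stage("fit_NOx",
                   fit_boltzmann(prep_nox$time_h, prep_nox$mean,
                                 weights = wts(prep_nox), analyte = "NOx"))
  fit_no3 <- stage("fit_NO3",
                   fit_boltzmann(prep_no3$time_h, prep_no3$mean,
                                 weights = wts(prep_no3), analyte = "NO3"))
  if (is.null(window)) window <- range(prep_nox$time_h)
  va <- stage("profile_Va",
              instantaneous_profile(fit_nox, window, threshold_frac))
  vn <- stage("profile_Vn",
              instantaneous_profile(fit_no3, window, threshold_frac))
  inb <- stage("inb", compute_inb(series, tolerance))
  nh4 <- stage("nh4_summary", {
    p <- prepare_analyte_series(series, "NH4")
    c(initial = p$mean[1L], minimum = min(p$mean),
      t_at_min = p$time_h[which.min(p$mean)], final = p$mean[nrow(p)])
  })
  structure(list(fits = list(NOx = fit_nox, NO3 = fit_no3),
                 profiles = list(va = va, vn = vn),
                 inb = inb, nh4_summary = nh4, window = window,
                 options = list(tolerance = tolerance,
                                threshold_frac = threshold_frac,
                                weighted = weighted)),
            class = "nitrification_report")
}

#' @export
print.nitrification_report <- function(x, ...) {
  cat("Nitrification analysis over [", x$window[1L], ", ", x$window[2L],
      "] h\n\n", sep = "")
  tab <- report_table(x)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("\nNH4+: %.4g -> min %.4g at %g h -> final %.4g umol/L\n",
              x$nh4_summary[["initial"]], x$nh4_summary[["minimum"]],
              x$nh4_summary[["t_at_min"]], x$nh4_summary[["final"]]))
  final <- x$inb$inb[nrow(x$inb)]
  cat(sprintf("Final INB = %.3f (%s)\n", final, x$inb$label[nrow(x$inb)]))
  invisible(x)
}

#' One-row-per-analyte summary table of a nitrification report
#'
#' @param report an [analyze_sample()] result.
#' @return data frame with one row per (rate, analyte): fitted parameters,
#'   average and maximum rates, time of the maximum, phase boundaries and R².
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "nitrification_report"))
  row <- function(rate, prof) {
    cf <- prof$fit$coefficients
    data.frame(rate = rate, analyte = prof$analyte,
               A1 = cf[["A1"]], A2 = cf[["A2"]], t0 = cf[["t0"]],
               dt = cf[["dt"]],
               v_avg = prof$v_avg, v_max = prof$v_max,
               t_at_vmax = prof$t_at_vmax,
               lag_end = prof$phases[["lag_end"]],
               plateau_start = prof$phases[["plateau_start"]],
               r2 = prof$fit$r2, n = prof$fit$n)
  }
  out <- rbind(row("Va", report$profiles$va), row("Vn", report$profiles$vn))
  row.names(out) <- NULL
  out
}

#' Plot a nitrification report
#'
#' Three panels: observed concentrations with the two fitted sigmoids, the
#' instantaneous rate curves, and the INB trajectory with its balanced band.
#'
#' @param x an [analyze_sample()] result.
#' @param ... unused.
#' @export
plot.nitrification_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  va <- x$profiles$va; vn <- x$profiles$vn
  d <- va$fit$data
  plot(d$time_h, d$value, pch = 16, xlab = "time (h)",
       ylab = "conc (umol/L)", main = "cumulative oxidized nitrogen")
  graphics::points(vn$fit$data$time_h, vn$fit$data$value, pch = 1)
  graphics::lines(va$grid$time_h, va$grid$fitted, col = "firebrick")
  graphics::lines(vn$grid$time_h, vn$grid$fitted, col = "steelblue")
  graphics::legend("topleft", c("NOx (Va)", "NO3 (Vn)"), bty = "n",
                   col = c("firebrick", "steelblue"), lty = 1)
  plot(va$grid$time_h, va$grid$rate, type = "l", col = "firebrick",
       ylim = range(0, va$grid$rate, vn$grid$rate),
       xlab = "time (h)", ylab = "rate (umol/L/h)",
       main = "instantaneous rates")
  graphics::lines(vn$grid$time_h, vn$grid$rate, col = "steelblue")
  tol <- attr(x$inb, "tolerance")
  plot(x$inb$time_h, x$inb$inb, type = "b", xlab = "time (h)", ylab = "INB",
       main = "index of nitrogen balance",
       ylim = range(x$inb$inb, 1 - tol, 1 + tol))
  graphics::abline(h = c(1 - tol, 1, 1 + tol), lty = c(3, 2, 3))
  invisible(x)
}
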