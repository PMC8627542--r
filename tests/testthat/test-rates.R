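# rate statistics, phase segmentation, INB, per-sample analysis

test_that("average rate over a window uses fitted endpoint values", {
  f <- ref_fit()
  # closed-form endpoint evaluation over [0, 68]
  expect_equal(round(average_rate(f, c(0, 68)), 3), 1.466)
  expect_equal(average_rate(f, c(0, 68)),
               (predict(f, 68) - predict(f, 0)) / 68)
  # any window containing t0: mean below max of the non-negative rate curve
  for (w in list(c(20, 40), c(0, 68), c(29, 31))) {
    expect_lt(average_rate(f, w), 100 / 20)
    expect_gte(average_rate(f, w), 0)
  }
  expect_error(average_rate(f, c(10, 10)), "T_f > T_i")
  expect_error(average_rate(f, c(40, 10)), "T_f > T_i")
})

test_that("a flat fitted curve has zero average rate", {
  # construct a boltzmann_fit by hand with A1 = A2 (a fit would refuse flat data)
  f <- ref_fit()
  f$coefficients[c("A1", "A2")] <- c(50, 50)
  expect_equal(average_rate(f, c(0, 68)), 0)
})

test_that("average rate equals the trapezoidal mean of the instantaneous curve", {
  f <- ref_fit()
  for (w in list(c(0, 68), c(10, 50), c(35, 60))) {
    tg <- seq(w[1], w[2], length.out = 4001)
    expect_equal(average_rate(f, w),
                 trapz(tg, predict(f, tg, type = "rate")) / diff(w),
                 tolerance = 1e-6)
  }
})

test_that("raw-endpoint average rate matches hand computation on replicate means", {
  s <- toy_series()
  p <- prepare_analyte_series(s, "NO3")
  expect_equal(average_rate_raw(s, "NO3"),
               (p$mean[nrow(p)] - p$mean[1]) / (p$time_h[nrow(p)] - p$time_h[1]))
})

test_that("phase boundaries solve the derivative-threshold equation and are symmetric", {
  f <- ref_fit()
  ph <- segment_phases(f, threshold_frac = 0.10)
  # independent oracle: root-find dy/dt = f * (A2-A1)/(4 dt) on each side of t0
  cf <- coef(f)
  target <- 0.10 * (cf[["A2"]] - cf[["A1"]]) / (4 * cf[["dt"]])
  g <- function(t) boltzmann_deriv(t, cf[["A1"]], cf[["A2"]], cf[["t0"]], cf[["dt"]]) - target
  left <- uniroot(g, c(cf[["t0"]] - 40, cf[["t0"]]), tol = 1e-12)$root
  right <- uniroot(g, c(cf[["t0"]], cf[["t0"]] + 40), tol = 1e-12)$root
  expect_equal(unname(ph), c(left, right), tolerance = 1e-9)
  expect_equal(round(unname(ph), 2), c(11.82, 48.18))
  # symmetry about t0
  expect_equal(cf[["t0"]] - ph[["lag_end"]], ph[["plateau_start"]] - cf[["t0"]],
               tolerance = 1e-9)
  # threshold at the maximum collapses both boundaries onto t0
  ph1 <- segment_phases(f, threshold_frac = 1 - 1e-12)
  expect_equal(unname(ph1), c(30, 30), tolerance = 1e-4)
  expect_error(segment_phases(f, threshold_frac = 0), "threshold_frac")
  expect_error(segment_phases(f, threshold_frac = 1.2), "threshold_frac")
})

test_that("instantaneous profile locates the window maximum in closed form", {
  f <- ref_fit()
  # t0 interior: maximum (A2-A1)/(4 dt) at t0
  p1 <- instantaneous_profile(f, c(0, 80))
  expect_equal(p1$v_max, 5, tolerance = 1e-6)
  expect_equal(p1$t_at_vmax, 30, tolerance = 1e-6)
  # window right of t0: maximum at the left endpoint (derivative declines)
  p2 <- instantaneous_profile(f, c(40, 80))
  expect_equal(p2$t_at_vmax, 40)
  expect_equal(round(p2$v_max, 3), 2.100)
  # window left of t0: maximum at the right endpoint
  p3 <- instantaneous_profile(f, c(0, 20))
  expect_equal(p3$t_at_vmax, 20)
  # grid agrees with the closed forms and never exceeds v_max
  expect_true(all(p1$grid$rate <= p1$v_max + 1e-12))
  expect_gte(p1$v_max, p1$v_avg)
  expect_error(instantaneous_profile(f, c(10, 10)), "T_f > T_i")
})

test_that("INB is DIN(t)/DIN(0) with the loss/balanced/mineralization rule", {
  # conservation: pools shuffle, DIN unchanged
  s <- data.frame(time_h = rep(c(0, 12), each = 1), replicate = "R1",
                  nh4_umol_L = c(100, 50), no2_umol_L = c(0, 20),
                  no3_umol_L = c(0, 30))
  inb <- compute_inb(s)
  expect_equal(inb$inb, c(1, 1))
  expect_equal(inb$label, c("balanced", "balanced"))
  # the interpretive rule at the values the labels turn on
  s2 <- data.frame(time_h = c(0, 6, 12), replicate = "R1",
                   nh4_umol_L = c(100, 80, 137), no2_umol_L = 0, no3_umol_L = 0)
  inb2 <- compute_inb(s2, tolerance = 0.05)
  expect_equal(inb2$inb, c(1, 0.8, 1.37))
  expect_equal(inb2$label, c("balanced", "loss", "mineralization"))
  # inb(0) is exactly 1; band edges are balanced at the default tolerance
  s3 <- data.frame(time_h = c(0, 6, 12), replicate = "R1",
                   nh4_umol_L = c(100, 95, 105), no2_umol_L = 0, no3_umol_L = 0)
  expect_equal(compute_inb(s3)$label, rep("balanced", 3))
  expect_error(compute_inb(data.frame(time_h = c(0, 6), replicate = "R1",
                                      nh4_umol_L = 0, no2_umol_L = 0,
                                      no3_umol_L = 0)), "undefined")
})

test_that("closed-system simulator output keeps INB at 1 to 1e-6 at all times", {
  sim <- simulate_incubation(sim_preset("closed_system"))
  inb <- compute_inb(sim$series)
  expect_true(all(abs(inb$inb - 1) < 1e-6))
})

test_that("per-sample analysis recovers the true mean AO rate on the delayed-NO preset", {
  sim <- simulate_incubation(sim_preset("sample_A_like"))
  rep <- analyze_sample(sim$series)
  va <- rep$profiles$va$v_avg
  # truth averaged over the sampled window (sampling stops at 66 h)
  w <- rep$window
  tr <- sim$truth
  sel <- tr$time_h >= w[1] & tr$time_h <= w[2]
  true_va <- trapz(tr$time_h[sel], tr$v_ao[sel]) / diff(w)
  expect_lt(abs(va - true_va) / true_va, 0.10)
  # nitrite has an interior peak in this regime
  no2 <- prepare_analyte_series(sim$series, "NO2")$mean
  expect_gt(which.max(no2), 1)
  expect_lt(which.max(no2), length(no2))
})

test_that("fast-NO preset accumulates no material nitrite and keeps INB near 1", {
  sim <- simulate_incubation(sim_preset("sample_B_like"))
  rep <- analyze_sample(sim$series)
  nh4 <- prepare_analyte_series(sim$series, "NH4")$mean
  no2 <- prepare_analyte_series(sim$series, "NO2")$mean
  expect_lt(max(no2) - no2[1], 0.1 * (nh4[1] - min(nh4)))
  expect_true(all(abs(rep$inb$inb - 1) < 0.05))
})

test_that("doubling concentrations doubles rates and leaves INB unchanged", {
  sim <- simulate_incubation(sim_preset("sample_A_like"))
  s1 <- sim$series
  s2 <- s1
  s2[, c("nh4_umol_L", "no2_umol_L", "no3_umol_L")] <-
    2 * s1[, c("nh4_umol_L", "no2_umol_L", "no3_umol_L")]
  r1 <- analyze_sample(s1); r2 <- analyze_sample(s2)
  expect_equal(r2$profiles$va$v_avg, 2 * r1$profiles$va$v_avg, tolerance = 1e-6)
  expect_equal(r2$profiles$va$v_max, 2 * r1$profiles$va$v_max, tolerance = 1e-6)
  expect_equal(r2$inb$inb, r1$inb$inb, tolerance = 1e-9)
})

test_that("stage failures identify the failing stage; empty input fails at validation", {
  expect_error(analyze_sample(data.frame()), "non-empty")
  few <- data.frame(time_h = c(0, 6, 12), replicate = "R1",
                    nh4_umol_L = 3:1, no2_umol_L = 0, no3_umol_L = 1:3)
  expect_error(analyze_sample(few), "prepare_NOx")
  flatno3 <- data.frame(time_h = seq(0, 30, 6), replicate = "R1",
                        nh4_umol_L = 6:1, no2_umol_L = 1:6, no3_umol_L = 5)
  expect_error(analyze_sample(flatno3), "fit_NO3")
})

test_that("report table carries one row per rate with coherent values", {
  sim <- simulate_incubation(sim_preset("sample_A_like"))
  rep <- analyze_sample(sim$series)
  tab <- report_table(rep)
  expect_equal(tab$rate, c("Va", "Vn"))
  expect_equal(tab$analyte, c("NOx", "NO3"))
  expect_true(all(tab$v_max >= tab$v_avg))
  expect_true(all(tab$r2 > 0.99))
  expect_true(all(tab$lag_end <= tab$plateau_start))
})
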