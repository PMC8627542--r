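# two-step nitrification ODE simulator

test_that("closed system conserves total dissolved inorganic nitrogen", {
  sim <- simulate_incubation(sim_config(nh4_0 = 200, no2_0 = 5, no3_0 = 10,
                                        v_ao_max = 8, v_no_max = 10,
                                        t_end = 48, noise_sd = 0))
  din <- with(sim$series, nh4_umol_L + no2_umol_L + no3_umol_L)
  expect_true(all(abs(din - 215) / 215 < 1e-6))
  # dense truth conserves too
  din_t <- with(sim$truth, nh4_umol_L + no2_umol_L + no3_umol_L)
  expect_true(all(abs(din_t - 215) / 215 < 1e-6))
})

test_that("without nitrite oxidation, nitrate is frozen and nitrite rises monotonically", {
  sim <- simulate_incubation(sim_config(nh4_0 = 150, no2_0 = 2, no3_0 = 30,
                                        v_ao_max = 8, v_no_max = 0,
                                        t_end = 48, noise_sd = 0))
  expect_equal(sim$series$no3_umol_L, rep(30, nrow(sim$series)),
               tolerance = 1e-8)
  expect_true(all(diff(sim$series$no2_umol_L) > 0))
})

test_that("loss makes DIN strictly decreasing; mineralization strictly increasing", {
  loss <- simulate_incubation(sim_config(loss_rate = 0.01, no2_0 = 10,
                                         no3_0 = 10, noise_sd = 0))
  din <- with(loss$series, nh4_umol_L + no2_umol_L + no3_umol_L)
  expect_true(all(diff(din) < 0))
  mino <- simulate_incubation(sim_config(mineralization_rate = 0.5, noise_sd = 0))
  din2 <- with(mino$series, nh4_umol_L + no2_umol_L + no3_umol_L)
  expect_true(all(diff(din2) > 0))
})

test_that("equal configurations give bit-identical output, different seeds differ", {
  cfg <- sim_config(noise_sd = 2, n_replicates = 3, seed = 7)
  expect_identical(simulate_incubation(cfg), simulate_incubation(cfg))
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_incubation(cfg)$series,
                         simulate_incubation(cfg2)$series))
})

test_that("first-order limit agrees with the closed-form linear chain solution", {
  # k >> concentrations: Monod v*N/(k+N) ~ (v/k) N, a linear cascade
  nh4_0 <- 1; a <- 0.08; b <- 0.05
  k <- 1e6
  cfg <- sim_config(nh4_0 = nh4_0, no2_0 = 0, no3_0 = 0,
                    v_ao_max = a * k, k_ao = k, v_no_max = b * k, k_no = k,
                    t_end = 48, sample_interval = 4, noise_sd = 0)
  sim <- simulate_incubation(cfg)
  ref <- linear_chain(sim$series$time_h, nh4_0, a, b)
  expect_equal(sim$series$nh4_umol_L, ref[, "nh4"], tolerance = 1e-4)
  expect_equal(sim$series$no2_umol_L, ref[, "no2"], tolerance = 1e-4)
  expect_equal(sim$series$no3_umol_L, ref[, "no3"], tolerance = 1e-4)
})

test_that("truth trajectories satisfy the stated ODE: dNO3/dt = v_no - loss term", {
  sim <- simulate_incubation(sim_config(nh4_0 = 300, v_ao_max = 10,
                                        v_no_max = 12, loss_rate = 0.005,
                                        no2_0 = 5, no3_0 = 20,
                                        t_end = 48, noise_sd = 0))
  tr <- sim$truth
  dno3 <- diff(tr$no3_umol_L) / diff(tr$time_h)
  mid_rhs <- (tr$v_no[-1] + tr$v_no[-nrow(tr)]) / 2 -
    0.005 * (tr$no3_umol_L[-1] + tr$no3_umol_L[-nrow(tr)]) / 2
  expect_equal(dno3, mid_rhs, tolerance = 1e-4)
  expect_true(all(tr$v_ao >= 0 & tr$v_no >= 0))
})

test_that("delayed nitrite oxidation yields an interior nitrite peak; fast NO prevents accumulation", {
  # delayed-NO regime: induction at ~20 h with comparable capacities
  a <- simulate_incubation(sim_config(nh4_0 = 300, no2_0 = 1, no3_0 = 10,
                                      v_ao_max = 10, v_no_max = 10,
                                      induction_lag_no = 20, ramp_no = 3,
                                      t_end = 68, sample_interval = 6,
                                      noise_sd = 0))
  no2 <- a$series$no2_umol_L
  imax <- which.max(no2)
  expect_gt(imax, 1)
  expect_lt(imax, length(no2))
  expect_gt(max(no2), no2[1])
  expect_gt(max(no2), no2[length(no2)])
  # immediate, stronger NO: nitrite excess under 10% of ammonium consumed
  b <- simulate_incubation(sim_config(nh4_0 = 300, no2_0 = 1, no3_0 = 10,
                                      v_ao_max = 10, v_no_max = 15,
                                      induction_lag_no = 0,
                                      t_end = 68, sample_interval = 6,
                                      noise_sd = 0))
  consumed <- b$series$nh4_umol_L[1] - min(b$series$nh4_umol_L)
  expect_lt(max(b$series$no2_umol_L) - b$series$no2_umol_L[1], 0.1 * consumed)
})

test_that("noise is clipped at zero and invalid configurations are rejected", {
  sim <- simulate_incubation(sim_config(nh4_0 = 0.1, no2_0 = 0, no3_0 = 0,
                                        v_ao_max = 1, noise_sd = 5,
                                        n_replicates = 5, t_end = 24, seed = 3))
  expect_true(all(sim$series[, 3:5] >= 0))
  expect_error(sim_config(nh4_0 = -1), "nh4_0")
  expect_error(sim_config(t_end = 0), "t_end")
  expect_error(sim_config(sample_interval = -2), "sample_interval")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
})

test_that("true average rates integrate the instantaneous truth curves", {
  sim <- simulate_incubation(sim_preset("closed_system"))
  tr <- sim$truth
  expect_equal(sim$truth_avg[["v_ao_avg"]],
               trapz(tr$time_h, tr$v_ao) / diff(range(tr$time_h)),
               tolerance = 1e-12)
  # in a closed system, integrated AO equals the NOx increment
  nox <- tr$no2_umol_L + tr$no3_umol_L
  expect_equal(sim$truth_avg[["v_ao_avg"]] * diff(range(tr$time_h)),
               nox[nrow(tr)] - nox[1], tolerance = 1e-4)
})
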