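# shared fixtures, built in code

# canonical rising sigmoid used throughout: A1=0, A2=100, t0=30, dt=5
ref_pars <- c(A1 = 0, A2 = 100, t0 = 30, dt = 5)

ref_fit <- function(times = seq(0, 80, 2)) {
  fit_boltzmann(times, boltzmann(times, 0, 100, 30, 5))
}

# tiny hand-made 2-replicate incubation table
toy_series <- function() {
  tt <- seq(0, 48, 6)
  nh4 <- 100 * exp(-0.05 * tt)
  no3 <- 100 - nh4
  rbind(
    data.frame(time_h = tt, replicate = "R1", nh4_umol_L = nh4,
               no2_umol_L = 0, no3_umol_L = no3),
    data.frame(time_h = tt, replicate = "R2", nh4_umol_L = nh4 + 1,
               no2_umol_L = 0, no3_umol_L = no3 + 1))
}

# closed-form solution of the linear two-step chain
# NH4' = -a NH4; NO2' = a NH4 - b NO2; NO3' = b NO2  (a != b)
linear_chain <- function(t, nh4_0, a, b) {
  nh4 <- nh4_0 * exp(-a * t)
  no2 <- nh4_0 * a / (b - a) * (exp(-a * t) - exp(-b * t))
  no3 <- nh4_0 * (1 + (a * exp(-b * t) - b * exp(-a * t)) / (b - a))
  cbind(nh4 = nh4, no2 = no2, no3 = no3)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
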