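test_that("cycle detection recovers the generator schedule on clean input", {
  p <- swimmer_params(pulse_freq = 2.5)
  tr <- simulate_swimmer(p, duration = 10.5 / 2.5, dt = 1 / (200 * 2.5))
  ks <- kinematics(tr)
  cyc <- detect_cycles(ks$u, ks$midtimes)
  ## ten full cycles in span -> 9 complete (first and last are edge-truncated)
  expect_equal(nrow(cyc), 9L)
  dt <- 1 / (200 * 2.5)
  periods <- ks$midtimes[cyc$i_end] - ks$midtimes[cyc$i_start]
  expect_true(all(abs(periods - 1 / 2.5) <= 2 * dt))
})

test_that("a constant-velocity glider yields no cycles and NaN metrics", {
  t <- seq(0, 5, 0.01)
  tr <- trajectory(t, 1.5 * t, 0 * t)
  ks <- kinematics(tr)
  cyc <- detect_cycles(ks$u, ks$midtimes)
  expect_identical(nrow(cyc), 0L)
  mt <- swim_metrics(cyc, ks)
  expect_identical(mt$n_pulses, 0L)
  expect_true(is.nan(mt$P_freq))
  expect_true(is.nan(mt$PER))
  expect_equal(mt$u_mean, 1.5, tolerance = 1e-9)
})

test_that("phase boundaries follow the biomechanical definitions", {
  dt <- 1 / (250 * 2.5)
  p <- swimmer_params(pulse_freq = 2.5, frac_contraction = 0.3,
                      frac_relaxation = 0.3, frac_interpulse = 0.4)
  tr <- simulate_swimmer(p, duration = 4, dt = dt)
  a <- analyze_sequence(tr)
  expect_lt(abs(a$metrics$C_time - 0.3 * 0.4), 2 * dt)
  expect_lt(abs(a$metrics$R_time - 0.3 * 0.4), 2 * dt)
  expect_lt(abs(a$metrics$I_time - 0.4 * 0.4), 2 * dt)
  ## velocity peak coincides with minimum diameter in the generator
  expect_true(all(abs(a$cycles$peak_offset_s) <= 2 * dt))

  ## no interpulse: I_time collapses to at most two samples
  p0 <- swimmer_params(pulse_freq = 2.5, frac_contraction = 0.4,
                       frac_relaxation = 0.6, frac_interpulse = 0,
                       interpulse_gain = 0)
  a0 <- analyze_sequence(simulate_swimmer(p0, duration = 4, dt = dt))
  expect_lte(a0$metrics$I_time, 2 * dt)
  expect_lte(a0$metrics$I_dist, 2 * dt * p0$peak_velocity)
  expect_lt(a0$metrics$PER, 0.03)
})

test_that("times and distances partition every cycle exactly", {
  p <- swimmer_params()
  tr <- simulate_swimmer(p, duration = 5, dt = 0.005)
  a <- analyze_sequence(tr)
  with(a$cycles, {
    expect_equal(C_time + R_time + I_time, cycle_time, tolerance = 1e-9)
    expect_equal(C_dist + R_dist + I_dist, cycle_dist, tolerance = 1e-9)
  })
})

test_that("segmentation without bell data falls back to the velocity minimum", {
  p <- swimmer_params()
  tr <- simulate_swimmer(p, duration = 5, dt = 0.005)
  bare <- trajectory(tr$t, tr$x, tr$y)
  ks <- kinematics(bare)
  cyc <- detect_cycles(ks$u, ks$midtimes)
  ph <- segment_phases(cyc, ks)
  expect_true(all(ph$fallback))
  mt <- swim_metrics(ph, ks)
  expect_true(mt$fallback_segmentation)
  expect_true(is.nan(mt$reference_diameter))
  ## the fallback relaxation end is the post-peak velocity minimum, which in
  ## this generator marks the start of the interpulse bump
  expect_equal(mt$C_time + mt$R_time,
               (p$frac_contraction + p$frac_relaxation) / p$pulse_freq,
               tolerance = 0.02)
})

test_that("swim metrics implement the stated ratios and averages", {
  ## two cycles of 0.5 s spanning 1 s -> P_freq = 2 Hz; PER = ratio of means
  tau <- seq(0, 1.1, 0.05)
  ks <- structure(list(midtimes = tau, u = rep(1, length(tau)),
                       m = rep(0.05, length(tau)),
                       Re = rep(NA_real_, length(tau)),
                       f = rep(NA_real_, length(tau) + 1), D = NULL,
                       D_interval = rep(NA_real_, length(tau)),
                       f_interval = rep(NA_real_, length(tau)),
                       t = c(tau - 0.025, max(tau) + 0.025)),
                  class = "kinematic_series")
  phases <- data.frame(i_start = c(1, 11), i_peak_u = c(4, 14),
                       i_max_D = c(8, 18), i_end = c(11, 21),
                       C_time = c(0.15, 0.15), R_time = c(0.2, 0.2),
                       I_time = c(0.15, 0.15),
                       C_dist = c(0.4, 0.3), R_dist = c(0.4, 0.3),
                       I_dist = c(0.2, 0.4),
                       cycle_time = c(0.5, 0.5), cycle_dist = c(1, 1),
                       u_max = c(1, 1), Re_max = NA_real_, D_max = NA_real_,
                       peak_offset_s = 0, fallback = FALSE)
  mt <- swim_metrics(phases, ks)
  expect_equal(mt$P_freq, 2, tolerance = 1e-12)
  expect_equal(mt$PER, 0.3, tolerance = 1e-12)
  expect_equal(mt$PER_cyclewise, 0.3, tolerance = 1e-12)
  expect_equal(mt$P_time, 0.5, tolerance = 1e-12)
  expect_equal(mt$P_dist, 1, tolerance = 1e-12)
})

test_that("single-cycle sequences report metrics but no frequency", {
  p <- swimmer_params(pulse_freq = 1)
  tr <- simulate_swimmer(p, duration = 2.4, dt = 0.005)
  a <- analyze_sequence(tr)
  expect_identical(a$metrics$n_pulses, 1L)
  expect_true(is.nan(a$metrics$P_freq))
  expect_true(is.finite(a$metrics$P_time))
  expect_true(is.finite(a$metrics$PER))
})

test_that("segmentation is invariant to time shifts and rigid transforms", {
  p <- swimmer_params(heading = 0.4)
  tr <- simulate_swimmer(p, duration = 5, dt = 0.005)
  base <- analyze_sequence(tr)$metrics
  th <- -2.2
  tr2 <- trajectory(tr$t + 100,
                    cos(th) * tr$x - sin(th) * tr$y + 7,
                    sin(th) * tr$x + cos(th) * tr$y - 4,
                    h = tr$h, D = tr$D, temperature = tr$temperature)
  shifted <- analyze_sequence(tr2)$metrics
  for (v in c("n_pulses", "P_freq", "P_time", "P_dist", "C_time", "R_time",
              "I_time", "C_dist", "R_dist", "I_dist", "PER", "u_max"))
    expect_equal(shifted[[v]], base[[v]], tolerance = 1e-9)
})

test_that("noiseless recovery holds across a parameter grid; noisy within 10%", {
  for (freq in c(1, 4)) {
    for (fc in c(0.2, 0.35)) {
      p <- swimmer_params(pulse_freq = freq, frac_contraction = fc,
                          frac_relaxation = 0.65 - fc, frac_interpulse = 0.35)
      dt <- 1 / (200 * freq)
      a <- analyze_sequence(simulate_swimmer(p, duration = 6 / freq, dt = dt))
      truth <- swimmer_truth(p)
      expect_lte(abs(1 / a$metrics$P_freq - truth$period), 2 * dt)
      expect_lte(abs(a$metrics$C_time - truth$C_time), 2 * dt)
      expect_lte(abs(a$metrics$R_time - truth$R_time), 2 * dt)
      expect_lte(abs(a$metrics$I_time - truth$I_time), 2 * dt)
      expect_lte(abs(a$metrics$PER - truth$PER), 0.03)
    }
  }
  ## positional jitter at 2% of the per-cycle displacement
  p <- swimmer_params()
  truth <- swimmer_truth(p)
  pn <- swimmer_params(noise_sd = 0.02 * truth$P_dist)
  an <- analyze_noisy(simulate_swimmer(pn, duration = 16, dt = 0.005, seed = 31),
                      truth$period)
  for (v in c("C_time", "R_time", "I_time"))
    expect_lt(abs(an$metrics[[v]] - truth[[v]]) / truth[[v]], 0.1)
  expect_lt(abs(1 / an$metrics$P_freq - truth$period) / truth$period, 0.1)
  expect_lt(abs(an$metrics$PER - truth$PER) / truth$PER, 0.1)
})
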