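#' Parameters of the synthetic pulsed swimmer
#'
#' Generative description of one pulsating medusa.  Each pulsation cycle of
#' period `1/pulse_freq` is split into three phases whose durations are fixed
#' fractions of the cycle: contraction (speed ramps from `trough_velocity` up
#' to `peak_velocity` while the bell compresses), relaxation (speed decays
#' back to the trough while the bell re-expands), and interpulse (the bell
#' stays fully relaxed and the speed shows a secondary bump of amplitude
#' `interpulse_gain * peak_velocity` -- the passive-energy-recapture
#' signature of the stopping vortex after elastic recoil).
#'
#' Within-phase profiles are raised-cosine ramps: smooth, differentiable,
#' and with unambiguous extrema, so that segmentation tests are not
#' confounded by spurious peaks.
#'
#' Bell shape is driven by a prescribed fineness trajectory `f(t)` moving
#' between `fineness_relaxed` and `fineness_contracted` in antiphase with
#' speed; bell height is held constant at
#' `fineness_relaxed * bell_diameter_relaxed` and the diameter series is
#' `D(t) = h / f(t)`, so fineness recomputation from the written series is
#' exact.
#'
#' The defaults describe a mid-sized medusa pulsing at 1 Hz with a faster
#' contraction than relaxation and a long interpulse coast, giving a
#' passive-energy-recapture fraction of about 0.25 -- the order of the
#' largest contributions reported for *Aurelia*-like swimmers.
#'
#' @param pulse_freq pulsation frequency (Hz), > 0.
#' @param frac_contraction,frac_relaxation,frac_interpulse fractions of one
#'   cycle spent in each phase; must sum to 1.
#' @param peak_velocity,trough_velocity speed extrema (cm s^-1);
#'   `peak_velocity > trough_velocity >= 0`.
#' @param interpulse_gain relative amplitude (>= 0) of the secondary speed
#'   bump during the interpulse, as a fraction of `peak_velocity`.
#' @param bell_diameter_relaxed relaxed bell diameter (cm), > 0.
#' @param fineness_relaxed,fineness_contracted bell fineness (height /
#'   diameter) in the relaxed and contracted state;
#'   `fineness_contracted > fineness_relaxed > 0`.
#' @param heading swimming direction (radians); paths are straight so that
#'   displacement decomposition is exact.
#' @param noise_sd sd of Gaussian positional jitter (cm) added per frame,
#'   emulating digitization error.
#' @param temperature water temperature (degrees C).
#' @param species,individual labels.
#'
#' @return An object of class `"swimmer_params"`.
#' @seealso [simulate_swimmer()], [swimmer_truth()]
#' @export
swimmer_params <- function(pulse_freq = 1,
                           frac_contraction = 0.25,
                           frac_relaxation = 0.35,
                           frac_interpulse = 0.40,
                           peak_velocity = 4,
                           trough_velocity = 0.5,
                           interpulse_gain = 0.3,
                           bell_diameter_relaxed = 3,
                           fineness_relaxed = 0.5,
                           fineness_contracted = 0.9,
                           heading = 0,
                           noise_sd = 0,
                           temperature = 20,
                           species = "synthetic",
                           individual = "1") {
  assert_scalar_num(pulse_freq, "pulse_freq", positive = TRUE)
  for (nm in c("frac_contraction", "frac_relaxation", "frac_interpulse"))
    assert_scalar_num(get(nm), nm, nonneg = TRUE)
  if (abs(frac_contraction + frac_relaxation + frac_interpulse - 1) > 1e-12)
    stop_invalid("phase fractions must sum to 1")
  if (frac_contraction <= 0 || frac_relaxation <= 0)
    stop_invalid("contraction and relaxation fractions must be > 0")
  assert_scalar_num(peak_velocity, "peak_velocity", positive = TRUE)
  assert_scalar_num(trough_velocity, "trough_velocity", nonneg = TRUE)
  if (peak_velocity <= trough_velocity)
    stop_invalid("peak_velocity must exceed trough_velocity")
  assert_scalar_num(interpulse_gain, "interpulse_gain", nonneg = TRUE)
  assert_scalar_num(bell_diameter_relaxed, "bell_diameter_relaxed", positive = TRUE)
  assert_scalar_num(fineness_relaxed, "fineness_relaxed", positive = TRUE)
  assert_scalar_num(fineness_contracted, "fineness_contracted", positive = TRUE)
  if (fineness_contracted <= fineness_relaxed)
    stop_invalid("fineness_contracted must exceed fineness_relaxed")
  assert_scalar_num(heading, "heading")
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(temperature, "temperature")
  structure(list(pulse_freq = pulse_freq,
                 frac_contraction = frac_contraction,
                 frac_relaxation = frac_relaxation,
                 frac_interpulse = frac_interpulse,
                 peak_velocity = peak_velocity,
                 trough_velocity = trough_velocity,
                 interpulse_gain = interpulse_gain,
                 bell_diameter_relaxed = bell_diameter_relaxed,
                 fineness_relaxed = fineness_relaxed,
                 fineness_contracted = fineness_contracted,
                 heading = heading,
                 noise_sd = noise_sd,
                 temperature = temperature,
                 species = as.character(species),
                 individual = as.character(individual)),
            class = "swimmer_params")
}

#' @export
print.swimmer_params <- function(x, ...) {
  cat(sprintf(paste0("<swimmer_params> %s: %.3g Hz, phases C/R/I = %.2f/%.2f/%.2f,",
                     " u %.3g-%.3g cm/s, PER gain %.2f, D_relaxed %.3g cm\n"),
              x$species, x$pulse_freq, x$frac_contraction, x$frac_relaxation,
              x$frac_interpulse, x$trough_velocity, x$peak_velocity,
              x$interpulse_gain, x$bell_diameter_relaxed))
  invisible(x)
}

#' Analytic speed and fineness profiles of the synthetic swimmer
#'
#' Noiseless instantaneous speed (cm s^-1) and bell fineness at arbitrary
#' times, from the generator's phase schedule.
#'
#' @param params a [swimmer_params()] object.
#' @param t numeric vector of times (s).
#' @return numeric vector, same length as `t`.
#' @export
swimmer_speed <- function(params, t) {
  p <- params
  s <- (t * p$pulse_freq) %% 1
  fc <- p$frac_contraction; fr <- p$frac_relaxation; fi <- p$frac_interpulse
  u0 <- p$trough_velocity; up <- p$peak_velocity
  out <- numeric(length(s))
  ic <- s < fc
  out[ic] <- u0 + (up - u0) * (1 - cos(pi * s[ic] / fc)) / 2
  ir <- !ic & s < fc + fr
  q <- (s[ir] - fc) / fr
  out[ir] <- u0 + (up - u0) * (1 + cos(pi * q)) / 2
  if (fi > 0) {
    ii <- s >= fc + fr
    q <- (s[ii] - fc - fr) / fi
    out[ii] <- u0 + p$interpulse_gain * up * (1 - cos(2 * pi * q)) / 2
  }
  out
}

#' @rdname swimmer_speed
#' @export
swimmer_fineness <- function(params, t) {
  p <- params
  s <- (t * p$pulse_freq) %% 1
  fc <- p$frac_contraction; fr <- p$frac_relaxation
  f0 <- p$fineness_relaxed; f1 <- p$fineness_contracted
  out <- rep(f0, length(s))
  ic <- s < fc
  out[ic] <- f0 + (f1 - f0) * (1 - cos(pi * s[ic] / fc)) / 2
  ir <- !ic & s < fc + fr
  q <- (s[ir] - fc) / fr
  out[ir] <- f1 - (f1 - f0) * (1 - cos(pi * q)) / 2
  out
}

#' Simulate a pulsed-swimmer trajectory
#'
#' Integrates the analytic speed profile of [swimmer_params()] along a
#' straight heading (cumulative trapezoid), derives the bell height/diameter
#' series from the prescribed fineness trajectory, and adds Gaussian
#' positional jitter of sd `noise_sd` to each coordinate.
#'
#' @param params a [swimmer_params()] object.
#' @param duration sequence length (s); must cover at least two cycles.
#' @param dt sampling interval (s); must be at most `1/(50 * pulse_freq)` so
#'   each phase spans several samples.
#' @param seed integer seed for the positional jitter; required when
#'   `noise_sd > 0`.  With `noise_sd = 0` the output is deterministic.
#' @return A [trajectory()] with the generating parameters attached as
#'   attribute `"params"`.
#' @export
simulate_swimmer <- function(params, duration, dt, seed = NULL) {
  if (!inherits(params, "swimmer_params")) stop_invalid("'params' must be swimmer_params")
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  if (duration < 2 / params$pulse_freq)
    stop_invalid("duration must cover at least two pulsation cycles")
  if (dt > 1 / (50 * params$pulse_freq))
    stop_invalid("dt too coarse: need dt <= 1/(50*pulse_freq)")
  if (params$noise_sd > 0 && is.null(seed))
    stop_invalid("a seed is required when noise_sd > 0")
  n <- floor(duration / dt + 1e-9)
  t <- (0:n) * dt
  u <- swimmer_speed(params, t)
  path <- c(0, cumsum((u[-1] + u[-(n + 1)]) / 2) * dt)
  x <- cos(params$heading) * path
  y <- sin(params$heading) * path
  if (params$noise_sd > 0) {
    jitter <- with_seed(seed, matrix(stats::rnorm(2 * (n + 1), 0, params$noise_sd), ncol = 2))
    x <- x + jitter[, 1]
    y <- y + jitter[, 2]
  }
  f <- swimmer_fineness(params, t)
  h0 <- params$fineness_relaxed * params$bell_diameter_relaxed
  traj <- trajectory(t = t, x = x, y = y, h = rep(h0, n + 1), D = h0 / f,
                     temperature = params$temperature,
                     species = params$species, individual = params$individual)
  attr(traj, "params") <- params
  traj
}

#' Closed-form per-cycle kinematics of the synthetic swimmer
#'
#' Analytic phase times, phase distances, cycle displacement, mean speed and
#' passive-energy-recapture fraction implied by a [swimmer_params()] object
#' (exact integrals of the raised-cosine profiles).  This is the ground
#' truth that segmentation and metric recovery are tested against.
#'
#' @param params a [swimmer_params()] object.
#' @return A list with elements `period`, `C_time`, `R_time`, `I_time`,
#'   `C_dist`, `R_dist`, `I_dist`, `P_dist`, `PER`, `u_mean`, `u_max`,
#'   `f_mean`.
#' @export
swimmer_truth <- function(params) {
  p <- params
  T <- 1 / p$pulse_freq
  u0 <- p$trough_velocity; up <- p$peak_velocity
  C_time <- p$frac_contraction * T
  R_time <- p$frac_relaxation * T
  I_time <- p$frac_interpulse * T
  ## raised-cosine ramps average to the midpoint of their endpoints;
  ## the interpulse bump averages to half its amplitude above the trough
  C_dist <- C_time * (u0 + up) / 2
  R_dist <- R_time * (u0 + up) / 2
  I_dist <- I_time * (u0 + p$interpulse_gain * up / 2)
  P_dist <- C_dist + R_dist + I_dist
  f_mean <- (p$frac_contraction + p$frac_relaxation) *
    (p$fineness_relaxed + p$fineness_contracted) / 2 +
    p$frac_interpulse * p$fineness_relaxed
  list(period = T, C_time = C_time, R_time = R_time, I_time = I_time,
       C_dist = C_dist, R_dist = R_dist, I_dist = I_dist,
       P_dist = P_dist, PER = I_dist / P_dist,
       u_mean = P_dist / T, u_max = up, f_mean = f_mean)
}
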