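#' Instantaneous bell fineness
#'
#' Elementwise fineness ratio `f = h / D` (bell height over bell diameter):
#' `f < 1` oblate, `f > 1` prolate.  `NA` in either input propagates.
#'
#' @param h bell height series (cm).
#' @param D bell diameter series (cm), positive where not `NA`.
#' @return numeric vector, same length.
#' @export
fineness_series <- function(h, D) {
  if (length(h) != length(D)) stop_invalid("h and D must have equal length")
  if (any(D[!is.na(D)] <= 0)) stop_invalid("D must be positive")
  if (any(h[!is.na(h)] <= 0)) stop_invalid("h must be positive")
  h / D
}

#' Inter-frame displacement
#'
#' Euclidean distance between successive apex positions
#' (`m_i = sqrt((X_f - X_i)^2 + (Y_f - Y_i)^2)`).
#'
#' @param x,y apex coordinate series (cm), length >= 2.
#' @return numeric vector of length `length(x) - 1`.
#' @export
displacement_series <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 2L) stop_invalid("need at least 2 frames")
  sqrt(diff(x)^2 + diff(y)^2)
}

#' Instantaneous velocity
#'
#' Per-interval speed `u_i = m_i / (t_{i+1} - t_i)`.
#'
#' @param m displacement series (cm), length `length(t) - 1`.
#' @param t timestamps (s), strictly increasing.
#' @return numeric vector (cm s^-1), length `length(m)`.
#' @export
velocity_series <- function(m, t) {
  if (length(t) != length(m) + 1L) stop_invalid("need length(t) == length(m) + 1")
  dt <- diff(t)
  if (any(!is.finite(dt)) || any(dt <= 0)) stop_invalid("t must be strictly increasing")
  m / dt
}

#' Instantaneous Reynolds number
#'
#' `Re_i = D_i * u_i / v` with `D` and `u` converted from cm to SI metres
#' before division by the kinematic viscosity `v` (m^2 s^-1).  `D` must
#' already be aligned to the velocity intervals (see [kinematics()], which
#' averages the two endpoint frames of each interval).
#'
#' @param D interval-aligned bell diameter series (cm).
#' @param u velocity series (cm s^-1), same length as `D`.
#' @param viscosity kinematic viscosity (m^2 s^-1); see [seawater_viscosity()].
#' @return dimensionless numeric vector.
#' @export
reynolds_series <- function(D, u, viscosity = 1.05e-6) {
  if (length(D) != length(u)) stop_invalid("D and u must have equal length")
  assert_scalar_num(viscosity, "viscosity", positive = TRUE)
  (D / 100) * (u / 100) / viscosity
}

#' Kinematic viscosity of seawater
#'
#' Linear interpolation of a reference table
#' (15 degC: 1.17e-6, 20 degC: 1.05e-6, 25 degC: 0.95e-6 m^2 s^-1),
#' clamped outside 15-25 degC.
#'
#' @param temperature water temperature (degrees C).
#' @return kinematic viscosity (m^2 s^-1).
#' @export
seawater_viscosity <- function(temperature = 20) {
  stats::approx(x = c(15, 20, 25), y = c(1.17e-6, 1.05e-6, 0.95e-6),
                xout = temperature, rule = 2)$y
}

#' Per-frame and per-interval kinematic series of a trajectory
#'
#' Computes the four instantaneous quantities from a digitized swim:
#' fineness (per frame), displacement, velocity and Reynolds number (per
#' inter-frame interval).  Optional uniform resampling (linear
#' interpolation of all series to a fixed `resample_dt`) and centered
#' moving-average smoothing of the coordinates are applied *before*
#' differentiation; both are recorded in the output metadata.  Sequences
#' without bell measurements get `NA` fineness and Reynolds series but
#' full displacement/velocity series.
#'
#' @param traj a [trajectory()].
#' @param viscosity kinematic viscosity (m^2 s^-1); default derived from the
#'   trajectory temperature via [seawater_viscosity()].
#' @param smooth_window odd integer moving-average window (samples) applied
#'   to the coordinates `x`, `y`; `NULL` (default) for none.
#' @param resample_dt target uniform sampling interval (s); `NULL` to keep
#'   the original frames.
#' @return An object of class `"kinematic_series"`: list with per-frame
#'   `t`, `f`, `h`, `D`; per-interval `midtimes`, `m`, `u`, `Re`,
#'   `D_interval`, `f_interval`; plus `temperature`, `species`,
#'   `individual` and a `meta` record.
#' @export
kinematics <- function(traj, viscosity = NULL, smooth_window = NULL,
                       resample_dt = NULL) {
  if (!inherits(traj, "trajectory")) stop_invalid("'traj' must be a trajectory")
  t <- traj$t; x <- traj$x; y <- traj$y; h <- traj$h; D <- traj$D
  ## smoothing targets the coordinates (the series that get differentiated)
  ## and runs before any resampling, so that jitter is averaged over the
  ## original frames; it assumes near-uniform input sampling.  The bell
  ## series are direct slowly-varying measurements and smoothing them would
  ## delay the diameter plateau that ends the relaxation phase.
  if (!is.null(smooth_window) && smooth_window > 1L) {
    x <- moving_average(x, smooth_window)
    y <- moving_average(y, smooth_window)
  }
  if (!is.null(resample_dt)) {
    assert_scalar_num(resample_dt, "resample_dt", positive = TRUE)
    tt <- seq(t[1], t[length(t)], by = resample_dt)
    lin <- function(v) if (is.null(v)) NULL else stats::approx(t, v, xout = tt)$y
    x <- lin(x); y <- lin(y); h <- lin(h); D <- lin(D)
    t <- tt
  }
  n <- length(t)
  f <- if (!is.null(h) && !is.null(D)) fineness_series(h, D) else rep(NA_real_, n)
  m <- displacement_series(x, y)
  u <- velocity_series(m, t)
  ux <- diff(x) / diff(t)
  uy <- diff(y) / diff(t)
  midtimes <- (t[-1] + t[-n]) / 2
  ## interval quantities use the mean of the two endpoint frames for D and f
  D_interval <- if (!is.null(D)) (D[-1] + D[-n]) / 2 else rep(NA_real_, n - 1L)
  f_interval <- (f[-1] + f[-n]) / 2
  visc <- viscosity %||% seawater_viscosity(traj$temperature)
  Re <- reynolds_series(D_interval, u, visc)
  structure(list(t = t, f = f, h = h, D = D,
                 midtimes = midtimes, m = m, u = u, ux = ux, uy = uy, Re = Re,
                 D_interval = D_interval, f_interval = f_interval,
                 temperature = traj$temperature,
                 species = traj$species, individual = traj$individual,
                 meta = list(viscosity = visc,
                             smooth_window = smooth_window %||% NA_integer_,
                             resample_dt = resample_dt %||% NA_real_,
                             dt_in = stats::median(diff(traj$t)),
                             dt_out = stats::median(diff(t)))),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %s / %s: %d intervals, u %.3g-%.3g cm/s%s\n",
              x$species, x$individual, length(x$u), min(x$u), max(x$u),
              if (all(is.na(x$Re))) ", no bell series" else
                sprintf(", Re up to %.3g", max(x$Re, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.kinematic_series <- function(x, ...) {
  data.frame(midtime_s = x$midtimes, m_cm = x$m, u_cm_per_s = x$u,
             re = x$Re, d_interval_cm = x$D_interval,
             f_interval = x$f_interval)
}

#' Sequence-level means of the kinematic series
#'
#' Arithmetic means of fineness, velocity and Reynolds number over a
#' sequence, ignoring `NA` (an all-`NA` fineness series yields `NaN`,
#' not an error, matching literature-extracted records without bell data).
#'
#' @param ks a [kinematics()] result.
#' @return named list `f_mean`, `u_mean`, `Re_mean`.
#' @export
sequence_means <- function(ks) {
  if (!inherits(ks, "kinematic_series")) stop_invalid("'ks' must be a kinematic_series")
  mean_na <- function(v) if (all(is.na(v))) NaN else mean(v, na.rm = TRUE)
  list(f_mean = mean_na(ks$f), u_mean = mean_na(ks$u), Re_mean = mean_na(ks$Re))
}
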