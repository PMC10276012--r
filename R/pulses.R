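## --- peak detection -------------------------------------------------------

## Local maxima of a series with topographic prominence.  Plateau maxima
## report their first index (ties: earliest wins).  Returns a data.frame
## (index, height, prominence).
local_maxima <- function(u) {
  n <- length(u)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  idx <- integer()
  i <- 2L
  while (i < n) {
    if (u[i] > u[i - 1L]) {
      j <- i
      while (j < n && u[j + 1L] == u[j]) j <- j + 1L  # walk plateau
      if (j < n && u[j + 1L] < u[j]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(idx, function(p) {
    side_min <- function(rng) {
      lo <- u[p]
      for (k in rng) {
        if (u[k] > u[p]) return(lo)
        if (u[k] < lo) lo <- u[k]
      }
      lo
    }
    left <- if (p > 1L) side_min((p - 1L):1L) else u[p]
    right <- if (p < n) side_min((p + 1L):n) else u[p]
    u[p] - max(left, right)
  }, numeric(1))
  data.frame(index = idx, height = u[idx], prominence = prom)
}

#' Detect pulsation cycles in a velocity profile
#'
#' Finds the prominent velocity maxima (one per bell contraction) and
#' anchors each cycle at the onset of contraction: the last local velocity
#' minimum immediately preceding the peak.  A cycle runs from its onset to
#' the next cycle's onset, so the final (edge-truncated) pulse is
#' discarded; `k` prominent peaks yield `k - 1` complete cycles.
#'
#' Detection parameters (exposed because published profiles state no
#' criteria): peaks must have topographic prominence of at least
#' `prominence` times the 5th-95th percentile span of `u`; peaks shorter
#' than `height_frac` of that span above the valley floor are then dropped
#' when at least two tall peaks exist (this removes the secondary
#' passive-energy-recapture bump of the interpulse, which is a genuine
#' local maximum but not a new pulse); finally peaks closer than
#' `sep_frac` times the dominant period (median tall-peak spacing) to a
#' taller accepted peak are discarded.
#'
#' @param u velocity series (cm s^-1), per interval.
#' @param t interval midtimes (s); defaults to the sample index.
#' @param prominence minimum peak prominence, as a fraction of the
#'   5th-95th percentile span of `u` (default 0.25).
#' @param min_separation minimum peak spacing in seconds; default
#'   `sep_frac` times the estimated period.
#' @param height_frac,sep_frac tuning constants for the bump filter, period
#'   estimate and separation rule (defaults 0.6 and 0.6).
#' @param onset_floor_frac onset candidates must lie within this fraction of
#'   the valley-to-peak range above the valley floor (default 0.15), which
#'   keeps noise dips on the contraction ramp from truncating the phase.
#' @param smooth_window odd moving-average window (samples) applied to a
#'   *copy* of `u` for detection only; boundary indices are then located on
#'   the smoothed series.
#' @return data.frame with one row per complete cycle: integer sample
#'   indices `i_start`, `i_peak`, `i_end` (a cycle spans `i_start..i_end`,
#'   and `i_end` is the next cycle's `i_start`).  Zero rows when no
#'   pulsation is found (a constant-velocity glide is a signal, not an
#'   error).
#' @export
detect_cycles <- function(u, t = NULL, prominence = 0.25, min_separation = NULL,
                          height_frac = 0.6, sep_frac = 0.6,
                          onset_floor_frac = 0.15, smooth_window = NULL) {
  if (inherits(u, "kinematic_series")) {
    if (is.null(t)) t <- u$midtimes
    u <- u$u
  }
  t <- t %||% seq_along(u)
  if (length(t) != length(u)) stop_invalid("t and u must have equal length")
  empty <- data.frame(i_start = integer(), i_peak = integer(), i_end = integer())
  us <- moving_average(u, smooth_window %||% 1L)
  span <- diff(stats::quantile(us, c(0.05, 0.95), names = FALSE))
  ## a flat profile (constant glide) has no pulsation; the guard is relative
  ## so that numerical wiggle on an exactly constant series is not "signal"
  if (!is.finite(span) || span <= 1e-8 * max(abs(us), .Machine$double.xmin))
    return(empty)
  pk <- local_maxima(us)
  pk <- pk[pk$prominence >= prominence * span, , drop = FALSE]
  if (nrow(pk) < 2L) return(empty)
  ## the recapture bump of the interpulse is a genuine local maximum but not
  ## a new pulse: contraction peaks stand tall over the whole profile, so
  ## drop short peaks (unless that leaves < 2 -- low-contrast pulsing)
  floor_u <- stats::quantile(us, 0.05, names = FALSE)
  tall <- pk[pk$height >= floor_u + height_frac * span, , drop = FALSE]
  if (nrow(tall) >= 2L) pk <- tall
  ## dominant period, then greedy separation by descending height
  period <- stats::median(diff(t[pk$index]))
  min_sep <- min_separation %||% (sep_frac * period)
  ord <- order(-pk$height, pk$index)
  accepted <- integer()
  for (i in ord) {
    if (!length(accepted) || all(abs(t[pk$index[i]] - t[accepted]) >= min_sep))
      accepted <- c(accepted, pk$index[i])
  }
  peaks <- sort(accepted)
  if (length(peaks) < 2L) return(empty)
  ## cycle onset: last local minimum of the (smoothed) series before each peak
  starts <- vapply(seq_along(peaks), function(j) {
    lo <- if (j > 1L) peaks[j - 1L] else 1L
    last_local_min(us, lo, peaks[j], floor_frac = onset_floor_frac)
  }, integer(1))
  keep <- !is.na(starts)
  peaks <- peaks[keep]; starts <- starts[keep]
  if (length(peaks) < 2L) return(empty)
  k <- length(peaks)
  data.frame(i_start = starts[-k], i_peak = peaks[-k], i_end = starts[-1L])
}

## Last interior local minimum of u in (lo, hi) that lies near the valley
## floor; NA_integer_ if none.  Restricting candidates to the floor (within
## `floor_frac` of the valley-to-peak range) keeps noise-induced dips on the
## contraction ramp from truncating the contraction phase, while on clean
## profiles -- where both the relaxation-end and the interpulse-end trough
## sit at the floor -- the *last* floor minimum is the contraction onset.
last_local_min <- function(u, lo, hi, floor_frac = 0.15) {
  if (hi - lo < 2L) return(NA_integer_)
  rng <- (lo + 1L):(hi - 1L)
  floor_u <- min(u[rng])
  cutoff <- floor_u + floor_frac * (u[hi] - floor_u)
  for (i in rev(rng)) {
    ## on an exactly flat trough (interpulse coast) the scan from the right
    ## stops at the plateau's last sample: the onset is where the rise
    ## begins, not where the coast began
    if (u[i] <= cutoff && u[i] <= u[i + 1L] && u[i] <= u[i - 1L]) return(i)
  }
  NA_integer_
}

## --- phase segmentation ---------------------------------------------------

#' Split detected cycles into contraction, relaxation and interpulse
#'
#' Phase boundaries follow the biomechanical definitions: contraction runs
#' from the pulsation onset to the highest velocity (which coincides with
#' the minimum bell diameter / maximum fineness); relaxation from the end
#' of contraction until bell expansion reaches the maximum diameter
#' (minimum fineness); and the interpulse -- the coast during which the
#' passive velocity gain appears -- from full expansion to the next
#' contraction onset.  The relaxation end is the *first* maximum-diameter
#' sample after the velocity peak (ties: earliest).  When the sequence has
#' no bell series the relaxation end falls back to the post-peak velocity
#' minimum and the row is flagged (`fallback = TRUE`).  Phase times are
#' midtime differences and phase distances are sums of inter-frame
#' displacements, so times and distances each partition the cycle exactly.
#'
#' @param cycles boundary data.frame from [detect_cycles()].
#' @param ks the [kinematics()] result the boundaries index into.
#' @return data.frame with one row per cycle: indices (`i_start`,
#'   `i_peak_u`, `i_max_D`, `i_end`), phase times `C_time`, `R_time`,
#'   `I_time` (s), distances `C_dist`, `R_dist`, `I_dist` (cm), cycle
#'   totals `cycle_time`/`cycle_dist`, per-cycle `u_max`, `Re_max`,
#'   `D_max` and the diagnostic `peak_offset_s` (lag from the velocity
#'   peak to the minimum-diameter sample, 0 when they coincide).
#' @export
segment_phases <- function(cycles, ks) {
  if (!inherits(ks, "kinematic_series")) stop_invalid("'ks' must be a kinematic_series")
  tau <- ks$midtimes; u <- ks$u; m <- ks$m
  have_bell <- !all(is.na(ks$D_interval)) || !all(is.na(ks$f_interval))
  seg <- function(a, b) if (b >= a + 1L) sum(m[(a + 1L):b]) else 0
  out <- lapply(seq_len(nrow(cycles)), function(r) {
    s <- cycles$i_start[r]; p <- cycles$i_peak[r]; e <- cycles$i_end[r]
    if (!(s < p && p < e)) stop_invalid("invalid cycle boundaries")
    if (have_bell) {
      bell <- if (!all(is.na(ks$D_interval))) ks$D_interval else -ks$f_interval
      win <- bell[p:e]
      d <- p + which.max(win) - 1L  # first maximum-diameter sample after peak
      fallback <- FALSE
    } else {
      d <- p + which.min(u[p:e]) - 1L  # post-peak velocity minimum
      fallback <- TRUE
    }
    ## diagnostic: lag between velocity peak and minimum-diameter sample
    off <- if (have_bell && !all(is.na(ks$D_interval))) {
      dmin <- s + which.min(ks$D_interval[s:e]) - 1L
      tau[dmin] - tau[p]
    } else NA_real_
    data.frame(i_start = s, i_peak_u = p, i_max_D = d, i_end = e,
               C_time = tau[p] - tau[s], R_time = tau[d] - tau[p],
               I_time = tau[e] - tau[d],
               C_dist = seg(s, p), R_dist = seg(p, d), I_dist = seg(d, e),
               cycle_time = tau[e] - tau[s], cycle_dist = seg(s, e),
               u_max = max(u[s:e]),
               Re_max = if (all(is.na(ks$Re[s:e]))) NA_real_ else
                 max(ks$Re[s:e], na.rm = TRUE),
               D_max = if (is.null(ks$D)) NA_real_ else
                 max(ks$D[s:(e + 1L)], na.rm = TRUE),
               peak_offset_s = off, fallback = fallback)
  })
  do.call(rbind, out)
}

## --- ensemble (phase-folded) cycle profile --------------------------------

## Least-squares fit of the piecewise raised-cosine pulse template
## (contraction rise, relaxation fall, interpulse recapture bump) to a
## peak-aligned folded cycle.  The floor/peak levels and bump amplitude
## enter linearly, so the search is 2-D over the contraction and
## relaxation durations: coarse grid, then simplex refinement.  Returns
## NULL when the profile cannot be fit.
fit_cycle_template <- function(lag, uf, period, C0 = NA_real_, R0 = NA_real_,
                               smear = NULL) {
  ok <- is.finite(uf)
  if (sum(ok) < 32L) return(NULL)
  l <- lag[ok]; y <- uf[ok]
  dl <- stats::median(diff(l))
  ## the data were low-pass filtered before differentiation, so the basis
  ## functions receive the same (known) kernels; the lag grid is uniform
  ## and the wrapped template is continuous across its ends
  kern <- 2L * floor((smear %||% numeric(0)) / dl / 2) + 1L  # odd windows >= 1
  smear_col <- function(v) {
    for (w in kern) if (w > 1L) v <- moving_average(v, w)
    v
  }
  shape <- function(C, R, delta) {
    ## cycle phase in [-C, period - C): lags outside wrap into the
    ## neighboring cycles of the same periodic profile
    s <- ((l - delta + C) %% period) - C
    I <- period - C - R
    rise <- fall <- bump <- numeric(length(s))
    ic <- s >= -C & s <= 0
    rise[ic] <- (1 - cos(pi * (s[ic] + C) / C)) / 2
    ir <- s > 0 & s <= R
    fall[ir] <- (1 + cos(pi * s[ir] / R)) / 2
    if (I > 1e-9 * period) {
      ii <- s > R
      bump[ii] <- (1 - cos(2 * pi * (s[ii] - R) / I)) / 2
    }
    cbind(1, smear_col(rise + fall), smear_col(bump))
  }
  sse <- function(par) {
    C <- par[1]; R <- par[2]; delta <- par[3]
    if (C < 0.02 * period || R < 0.02 * period || C + R > period ||
        abs(delta) > 0.08 * period)
      return(Inf)
    fit <- tryCatch(stats::lm.fit(shape(C, R, delta), y),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    sum(fit$residuals^2)
  }
  Cs <- seq(0.05, 0.60, by = 0.025) * period
  Rs <- seq(0.05, 0.70, by = 0.025) * period
  if (is.finite(C0)) Cs <- sort(c(Cs, C0))
  if (is.finite(R0)) Rs <- sort(c(Rs, R0))
  grid <- as.matrix(expand.grid(C = Cs, R = Rs, delta = 0))
  vals <- apply(grid, 1L, sse)
  if (!any(is.finite(vals))) return(NULL)
  best <- grid[which.min(vals), ]
  ## parscale keeps the simplex steps meaningful for the alignment shift,
  ## which starts at zero
  opt <- stats::optim(best, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 800,
                                     parscale = period * c(0.2, 0.2, 0.05)))
  if (!is.finite(opt$value)) return(NULL)
  list(C_time = unname(opt$par[1]), R_time = unname(opt$par[2]),
       delta = unname(opt$par[3]), sse = opt$value)
}

#' Ensemble-averaged pulsation cycle
#'
#' Folds the velocity and bell-diameter series of all detected cycles into
#' one peak-aligned average cycle profile and re-derives the mean phase
#' boundaries and phase distances from it.  Averaging across cycles
#' *before* locating the contraction onset and the full-expansion point
#' suppresses positional-jitter noise that would otherwise scatter the
#' per-cycle boundaries, so the ensemble estimates are the recommended
#' summary for noisy digitizations; on clean data they coincide with the
#' across-cycle means of the per-cycle segmentation to within a sample.
#'
#' @param ks a [kinematics()] result.
#' @param bounds cycle boundaries from [detect_cycles()] (or a
#'   [segment_phases()] table).
#' @param onset_floor_frac floor tolerance for the onset search, as in
#'   [detect_cycles()].
#' @return list with the folded grid (`lag`, `u`, `D`), the mean cycle
#'   `period`, phase times `C_time`, `R_time`, `I_time`, distances
#'   `C_dist`, `R_dist`, `I_dist`, `P_dist`, and `PER`.
#' @export
ensemble_cycle <- function(ks, bounds, onset_floor_frac = 0.15) {
  if (!inherits(ks, "kinematic_series")) stop_invalid("'ks' must be a kinematic_series")
  if (is.null(bounds) || nrow(bounds) == 0L) stop_invalid("no cycles to fold")
  ipk <- if ("i_peak" %in% names(bounds)) bounds$i_peak else bounds$i_peak_u
  tau <- ks$midtimes
  n <- nrow(bounds)
  period <- if (n > 1L) (tau[bounds$i_start[n]] - tau[bounds$i_start[1L]]) / (n - 1L)
            else tau[bounds$i_end[1L]] - tau[bounds$i_start[1L]]
  ## fine lag grid: cycles sample the cycle phase at offsets that are
  ## incommensurate with the period, so the peak-aligned average resolves
  ## structure below the sampling interval of a single cycle
  dl <- period / 256
  lag <- seq(-0.65 * period, period, by = dl)
  centers <- tau[ipk]
  fold <- function(v) {
    if (all(is.na(v))) return(rep(NA_real_, length(lag)))
    m <- vapply(centers, function(ct) stats::approx(tau - ct, v, xout = lag)$y,
                numeric(length(lag)))
    rowMeans(m, na.rm = TRUE)
  }
  ## fold the velocity *components* and take the norm of the mean: for the
  ## near-straight swimming within a cycle this equals the folded speed but
  ## without the upward noise bias of averaging |v + noise|
  fold_u <- function() {
    if (!is.null(ks$ux)) sqrt(fold(ks$ux)^2 + fold(ks$uy)^2) else fold(ks$u)
  }
  uf <- fold_u()
  ## registration pass: the sample-argmax alignment jitters asymmetrically
  ## when the contraction rise is steeper than the relaxation fall, which
  ## would skew the folded profile; re-align each cycle on the whole folded
  ## shape by least squares and fold again
  if (length(centers) > 2L) {
    dt_grid <- stats::median(diff(tau))
    shifts <- seq(-1.5 * dt_grid, 1.5 * dt_grid, by = dl)
    for (k in seq_along(centers)) {
      ssek <- vapply(shifts, function(s) {
        v <- stats::approx(tau - (centers[k] + s), ks$u, xout = lag)$y
        keep <- is.finite(v) & is.finite(uf)
        if (sum(keep) < 32L) return(Inf)
        mean((v[keep] - uf[keep])^2)
      }, numeric(1))
      centers[k] <- centers[k] + shifts[which.min(ssek)]
    }
    uf <- fold_u()
  }
  i0 <- which.min(abs(lag))  # the aligned contraction peak sits at lag 0
  ## contraction onset, first pass: last near-floor local minimum before
  ## the peak (exact on clean profiles)
  j <- last_local_min(uf, 1L, i0, floor_frac = onset_floor_frac)
  C_time <- if (is.na(j)) NA_real_ else -lag[j]
  ## relaxation end (full bell expansion): across-cycle mean of the
  ## per-cycle peak-to-maximum-diameter lag -- the bell series is not
  ## differentiated, so the per-cycle boundary is already tight, and the
  ## mean is unbiased where a folded first-attainment rule would be
  ## delayed by peak-alignment jitter
  imaxd <- if ("i_max_D" %in% names(bounds)) bounds$i_max_D else NULL
  R_time <- if (!is.null(imaxd)) mean(tau[imaxd] - tau[ipk]) else {
    hi <- min(length(lag), i0 + as.integer(ceiling(0.9 * period / dl)))
    lag[i0 + which.min(uf[(i0 + 1L):hi])]  # velocity-only fallback
  }
  ## refine the contraction boundaries by least-squares fit of the
  ## piecewise raised-cosine pulse template to the folded profile: under
  ## digitization jitter the template fit uses the whole rise, not a
  ## single noisy trough sample, so the onset is localized far below the
  ## sampling noise; on clean profiles it reproduces the first pass
  ## kernels the folded profile inherits: the coordinate moving average,
  ## the finite difference over one output step, and the fold
  ## interpolation (a triangle kernel, approximated by a boxcar of equal
  ## variance); cycle alignment is handled by the registration pass above
  smear <- c(if (is.finite(ks$meta$smooth_window) && ks$meta$smooth_window > 1L)
               ks$meta$smooth_window * ks$meta$dt_in,
             ks$meta$dt_out, 0.7 * ks$meta$dt_out)
  tpl <- fit_cycle_template(lag, uf, period,
                            C0 = C_time, R0 = R_time, smear = smear)
  shift <- 0
  if (!is.null(tpl)) {
    C_time <- tpl$C_time
    shift <- tpl$delta
    R_time <- tpl$R_time
  }
  I_time <- period - C_time - R_time
  integrate_u <- function(a, b) {  # trapezoid over the folded grid
    ia <- which.min(abs(lag - a)); ib <- which.min(abs(lag - b))
    if (ib <= ia) return(0)
    sum((uf[ia:(ib - 1L)] + uf[(ia + 1L):ib]) / 2 * diff(lag[ia:ib]))
  }
  C_dist <- integrate_u(shift - C_time, shift)
  R_dist <- integrate_u(shift, shift + R_time)
  I_dist <- integrate_u(shift + R_time, shift + period - C_time)
  P_dist <- C_dist + R_dist + I_dist
  bellf <- if (all(is.na(ks$D_interval))) NULL else fold(ks$D_interval)
  list(lag = lag, u = uf, D = bellf,
       period = period, C_time = C_time, R_time = R_time, I_time = I_time,
       C_dist = C_dist, R_dist = R_dist, I_dist = I_dist,
       P_dist = P_dist, PER = I_dist / P_dist)
}

## --- per-sequence metrics -------------------------------------------------

#' Per-sequence swimming metrics
#'
#' Across-cycle summary of a segmented sequence.  Pulsation time and
#' distance (`P_time`, `P_dist`) and the phase times/distances are
#' across-cycle means; pulsation frequency is the number of pulses divided
#' by the elapsed time from the first cycle onset to the last cycle end,
#' and is only defined for sequences with two or more pulses (`NaN`
#' otherwise); the reciprocal-mean-period alternative is reported as
#' `P_freq_alt`.  Passive energy recapture is the ratio of the mean
#' interpulse distance to the mean cycle displacement
#' (`PER = mean(I_dist) / mean(P_dist)`); the mean of per-cycle ratios is
#' reported as `PER_cyclewise`.  `u_max` and `Re_max` average each cycle's
#' maximum.  `reference_diameter` is the mean over cycles of the per-cycle
#' maximum (fully relaxed) bell diameter, the size used in ontogenetic
#' regressions.
#'
#' @param phases output of [segment_phases()] (or a [detect_cycles()]
#'   boundary frame, in which case `ks` is used to segment first).
#' @param ks the corresponding [kinematics()] result.
#' @return An object of class `"swim_metrics"` (a one-row data.frame).
#'   With an empty cycle list all metrics are `NaN` and `n_pulses = 0`.
#' @export
swim_metrics <- function(phases, ks) {
  if (!is.null(phases) && nrow(phases) && !("C_time" %in% names(phases)))
    phases <- segment_phases(phases, ks)
  sm <- sequence_means(ks)
  if (is.null(phases) || nrow(phases) == 0L) {
    out <- data.frame(n_pulses = 0L, P_freq = NaN, P_freq_alt = NaN,
                      P_time = NaN, P_dist = NaN,
                      C_time = NaN, R_time = NaN, I_time = NaN,
                      C_dist = NaN, R_dist = NaN, I_dist = NaN,
                      PER = NaN, PER_cyclewise = NaN,
                      u_max = NaN, Re_max = NaN,
                      f_mean = sm$f_mean, u_mean = sm$u_mean, Re_mean = sm$Re_mean,
                      reference_diameter = NaN, fallback_segmentation = FALSE)
    class(out) <- c("swim_metrics", class(out))
    return(out)
  }
  n <- nrow(phases)
  tau <- ks$midtimes
  span <- tau[phases$i_end[n]] - tau[phases$i_start[1L]]
  out <- data.frame(
    n_pulses = n,
    P_freq = if (n >= 2L) n / span else NaN,
    P_freq_alt = 1 / mean(phases$cycle_time),
    P_time = mean(phases$cycle_time),
    P_dist = mean(phases$cycle_dist),
    C_time = mean(phases$C_time), R_time = mean(phases$R_time),
    I_time = mean(phases$I_time),
    C_dist = mean(phases$C_dist), R_dist = mean(phases$R_dist),
    I_dist = mean(phases$I_dist),
    PER = mean(phases$I_dist) / mean(phases$cycle_dist),
    PER_cyclewise = mean(phases$I_dist / phases$cycle_dist),
    u_max = mean(phases$u_max),
    Re_max = if (all(is.na(phases$Re_max))) NaN else mean(phases$Re_max, na.rm = TRUE),
    f_mean = sm$f_mean, u_mean = sm$u_mean, Re_mean = sm$Re_mean,
    reference_diameter = if (all(is.na(phases$D_max))) NaN else
      mean(phases$D_max, na.rm = TRUE),
    fallback_segmentation = any(phases$fallback))
  class(out) <- c("swim_metrics", class(out))
  out
}

#' One-call sequence analysis
#'
#' Convenience wrapper: [kinematics()] then [detect_cycles()],
#' [segment_phases()] and [swim_metrics()].
#'
#' @param traj a [trajectory()].
#' @param viscosity,smooth_window,resample_dt passed to [kinematics()].
#' @param detect_smooth_window,prominence,min_separation,onset_floor_frac
#'   passed to [detect_cycles()].
#' @param ensemble refine the phase times, phase distances and PER from the
#'   ensemble-averaged cycle profile ([ensemble_cycle()]); recommended (and
#'   the default) because it is far more robust to digitization jitter
#'   than averaging per-cycle boundaries.  Set to `FALSE` to report plain
#'   across-cycle means of the per-cycle segmentation.
#' @return list with `kinematics`, `cycles` (segmented phases), `metrics`
#'   and `ensemble` (the folded profile, or `NULL`).
#' @export
analyze_sequence <- function(traj, viscosity = NULL, smooth_window = NULL,
                             resample_dt = NULL, detect_smooth_window = NULL,
                             prominence = 0.25, min_separation = NULL,
                             onset_floor_frac = 0.15, ensemble = TRUE) {
  ks <- kinematics(traj, viscosity = viscosity, smooth_window = smooth_window,
                   resample_dt = resample_dt)
  bounds <- detect_cycles(ks$u, ks$midtimes, prominence = prominence,
                          min_separation = min_separation,
                          onset_floor_frac = onset_floor_frac,
                          smooth_window = detect_smooth_window)
  phases <- if (nrow(bounds)) segment_phases(bounds, ks) else bounds
  metrics <- swim_metrics(phases, ks)
  ens <- NULL
  if (ensemble && nrow(bounds)) {
    ens <- tryCatch(ensemble_cycle(ks, phases, onset_floor_frac),
                    error = function(e) NULL)
    if (!is.null(ens) && is.finite(ens$C_time) && is.finite(ens$R_time) &&
        ens$C_time > 0 && ens$R_time > 0) {
      metrics$P_time <- ens$period
      metrics$P_freq_alt <- 1 / ens$period
      for (v in c("C_time", "R_time", "I_time", "C_dist", "R_dist", "I_dist",
                  "P_dist", "PER"))
        metrics[[v]] <- ens[[v]]
    } else ens <- NULL
  }
  list(kinematics = ks, cycles = phases, metrics = metrics, ensemble = ens)
}
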