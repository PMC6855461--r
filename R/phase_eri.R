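#' Extract place-field traversals
#'
#' Maximal contiguous trajectory segments inside a field's bin set (dilated
#' by one bin), i.e. single passes through the place field. Segments shorter
#' than `min_duration` or containing fewer than `min_spikes` place-cell
#' spikes are dropped, as are segments longer than `max_duration`, which
#' are in-field meanders rather than single traversals. Position along the
#' pass is cumulative path length from field entry.
#'
#' @param traj a [trajectory].
#' @param field one entry of a [detect_fields()] `field_set` (a list with a
#'   `bins` index matrix).
#' @param bin bin size of the field's rate map, m.
#' @param spikes optional place-cell `spike_train` used for the
#'   `min_spikes` filter.
#' @param min_duration minimum pass duration, s.
#' @param min_spikes minimum spikes within the pass.
#' @param max_duration maximum pass duration, s (single-traversal bound).
#' @return list of passes, each a list with `t_entry`, `t_exit`, `t`, `x`,
#'   `y`, `path_cm` (cumulative), `spike_times`.
#' @export
extract_passes <- function(traj, field, bin = 0.03, spikes = NULL,
                           min_duration = 0.5, min_spikes = 3,
                           max_duration = 5) {
  nb_max <- max(field$bins)
  # membership mask on the bin lattice, dilated by one bin (8-neighborhood)
  side <- max(ceiling(attr(traj, "arena_side") / bin - 1e-9), nb_max)
  mask <- matrix(FALSE, side, side)
  mask[field$bins] <- TRUE
  dil <- mask
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 + di):min(side, side + di)
    ti <- max(1, 1 - di):min(side, side - di)
    sj <- max(1, 1 + dj):min(side, side + dj)
    tj <- max(1, 1 - dj):min(side, side - dj)
    dil[ti, tj] <- dil[ti, tj] | mask[si, sj]
  }
  bx <- pmin(pmax(floor(traj$x / bin), 0), side - 1) + 1
  by <- pmin(pmax(floor(traj$y / bin), 0), side - 1) + 1
  inside <- dil[cbind(bx, by)]
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  passes <- list()
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    t0 <- traj$t[i0]; t1 <- traj$t[i1]
    if (t1 - t0 < min_duration || t1 - t0 > max_duration) next
    sp <- if (!is.null(spikes))
      spikes$times[spikes$times >= t0 & spikes$times <= t1] else numeric(0)
    if (!is.null(spikes) && length(sp) < min_spikes) next
    seg_x <- traj$x[i0:i1]; seg_y <- traj$y[i0:i1]
    path <- c(0, cumsum(sqrt(diff(seg_x)^2 + diff(seg_y)^2))) * 100
    if (max(path) <= 0) next
    passes[[length(passes) + 1]] <-
      list(t_entry = t0, t_exit = t1, t = traj$t[i0:i1],
           x = seg_x, y = seg_y, path_cm = path, spike_times = sp)
  }
  passes
}

#' Extract the excitatory ramp input of a pass
#'
#' Restricts the somatic voltage to the pass interval and removes action
#' potentials by capping at `cap_mV` and median-filtering with a `win_ms`
#' window, leaving the despiked subthreshold depolarization envelope (the
#' ERI).
#'
#' @param trace a `membrane_trace` covering the pass.
#' @param pass one pass from [extract_passes()].
#' @param cap_mV spike-capping level, mV.
#' @param win_ms median filter window, ms.
#' @return object of class `eri_segment`: list with `t`, `v` (despiked mV),
#'   `baseline`.
#' @export
extract_eri <- function(trace, pass, cap_mV = -50, win_ms = 40) {
  if (pass$t_entry < min(trace$t) - 1e-9 || pass$t_exit > max(trace$t) + 1e-9)
    stop("data error: pass outside trace span")
  sel <- trace$t >= pass$t_entry & trace$t <= pass$t_exit
  t <- trace$t[sel]
  v <- pmin(trace$v_m[sel], cap_mV)
  dt <- if (length(t) > 1) median(diff(t)) else 1e-3
  k <- max(3, round(win_ms / 1000 / dt))
  if (k %% 2 == 0) k <- k + 1
  if (length(v) > k) v <- stats::runmed(v, k, endrule = "median")
  structure(list(t = t, v = as.numeric(v), baseline = min(v)),
            class = "eri_segment")
}

#' Classify an ERI by its smoothed peak position
#'
#' Fits a smoothing spline with the conventional smoothing factor `p`
#' (penalized cubic spline minimizing
#' `p * sum (y - f)^2 + (1 - p) * integral f''^2`), takes the relative
#' position `R_peak` of the smoothed maximum within the segment, and
#' classifies: `R_peak < 0.35` left-skewed (L), `> 0.65` right-skewed (R),
#' otherwise symmetric (S). Boundary values map to S.
#'
#' @param seg an `eri_segment` (or list with `t`, `v`), at least 10 samples.
#' @param smoothing smoothing factor `p` in (0, 1); default 0.9.
#' @param time_unit timescale (s) on which the roughness penalty is
#'   evaluated; default one theta period (0.1 s), so the fitted curve
#'   resolves the ramp while discarding the theta-frequency oscillation.
#' @return list with `r_peak`, `class` (factor L/S/R), `smoothed` (fitted
#'   values at `t`).
#' @export
classify_eri <- function(seg, smoothing = 0.9, time_unit = 0.1) {
  t <- seg$t; v <- seg$v
  if (length(t) < 10) {
    return(list(r_peak = NA_real_, class = NA_character_, smoothed = NULL))
  }
  # downsample long envelopes to ~100 Hz for a stable spline fit
  if (length(t) > 400) {
    idx <- unique(round(seq(1, length(t), length.out = 400)))
    t_fit <- t[idx]; v_fit <- v[idx]
  } else {
    t_fit <- t; v_fit <- v
  }
  # penalized-spline equivalent of the p-weighted smoothing criterion,
  # with time measured in units of `time_unit` and mapped to
  # smooth.spline's unit-interval lambda via the cubed range
  r <- (max(t_fit) - min(t_fit)) / time_unit
  lambda <- (1 - smoothing) / smoothing / r^3
  fit <- tryCatch(
    smooth.spline(t_fit, v_fit, lambda = lambda, cv = FALSE),
    error = function(e) NULL)
  smoothed <- if (is.null(fit)) v else predict(fit, t)$y
  r_peak <- (t[which.max(smoothed)] - t[1]) / (t[length(t)] - t[1])
  cls <- if (r_peak < 0.35) "L" else if (r_peak > 0.65) "R" else "S"
  list(r_peak = r_peak, class = cls, smoothed = smoothed)
}

#' Spike phases relative to the theta conductance
#'
#' Phase of each spike between the bracketing peaks of the injected theta
#' oscillation: `phi = 360 * (t - t1) / (t2 - t1)` with `t1` the last peak
#' at or before the spike and `t2` the first after. Spikes outside the peak
#' coverage are dropped.
#'
#' @param spike_times spike times, s.
#' @param peaks theta peak times, s (strictly periodic; see
#'   [theta_peak_times()]).
#' @return data frame with `t` (spike time) and `phase` (degrees in
#'   `[0, 360)`).
#' @export
spike_phase <- function(spike_times, peaks) {
  if (length(peaks) < 2) return(data.frame(t = numeric(0), phase = numeric(0)))
  keep <- spike_times >= peaks[1] & spike_times < peaks[length(peaks)]
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("dropped ", n_drop, " spikes outside theta peak coverage")
  st <- spike_times[keep]
  i1 <- findInterval(st, peaks)
  t1 <- peaks[i1]; t2 <- peaks[i1 + 1]
  phase <- 360 * (st - t1) / (t2 - t1)
  phase[phase >= 360] <- 0
  data.frame(t = st, phase = phase)
}

#' Circular-linear regression of phase on position
#'
#' Estimates the phase-precession slope `rho` (degrees/cm) by maximizing
#' the mean resultant length
#' `R(rho) = | mean_j exp(i * (phase_j - rho * x_j)) |`
#' over a dense slope grid with local refinement; ties broken toward the
#' smaller `|rho|`.
#'
#' @param phase spike phases, degrees.
#' @param x positions along the pass, cm.
#' @param slope_bounds search bounds, degrees/cm.
#' @param grid_step grid resolution, degrees/cm.
#' @return object of class `circlin_fit` with `rho` (deg/cm), `R`
#'   (resultant length at the optimum), `phi0` (phase intercept, deg), `n`.
#' @export
circular_linear_fit <- function(phase, x, slope_bounds = c(-30, 30),
                                grid_step = 0.05) {
  n <- length(phase)
  if (n < 3) stop("fit undefined: need at least 3 points")
  if (length(x) != n) stop("phase and x must have equal length")
  ph <- phase * pi / 180
  resultant <- function(rho) {
    a <- ph - rho * pi / 180 * x
    sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  }
  grid <- seq(slope_bounds[1], slope_bounds[2], by = grid_step)
  Rg <- vapply(grid, resultant, numeric(1))
  best <- max(Rg)
  # ties (within numerical tolerance) resolved toward smaller |rho|
  cand <- grid[Rg >= best - 1e-12]
  rho0 <- cand[which.min(abs(cand))]
  opt <- optimize(function(r) -resultant(r),
                  lower = max(slope_bounds[1], rho0 - grid_step),
                  upper = min(slope_bounds[2], rho0 + grid_step))
  rho <- opt$minimum
  if (resultant(rho) <= resultant(rho0) + 1e-12 &&
      abs(rho0) < abs(rho)) rho <- rho0
  a <- ph - rho * pi / 180 * x
  phi0 <- (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
  structure(list(rho = rho, R = resultant(rho), phi0 = phi0, n = n),
            class = "circlin_fit")
}

#' @export
print.circlin_fit <- function(x, ...) {
  cat(sprintf("Circular-linear fit: rho = %.2f deg/cm (R = %.3f, n = %d)\n",
              x$rho, x$R, x$n))
  invisible(x)
}

#' @export
coef.circlin_fit <- function(object, ...) {
  c(rho = object$rho, phi0 = object$phi0)
}

#' Replay an ERI through the place cell under theta inhibition
#'
#' Re-simulates the place cell with the despiked excitatory ramp input
#' injected as somatic current (depolarization envelope times a conversion
#' conductance), superimposed with the theta-frequency inhibitory
#' conductance, the calibrated step current, and Gaussian white noise. This
#' is the stage at which spike phase precession is assessed: the smooth
#' ramp interacting with the rhythmic inhibition shifts the spike time
#' within each theta cycle as the ramp grows.
#'
#' A `lead_in` period at the ramp baseline precedes the ERI so the cell
#' settles before the pass begins; replay spike times are reported relative
#' to the start of the ERI (negative times fall in the lead-in).
#'
#' @param cell a [build_cell()] result.
#' @param seg an `eri_segment` from [extract_eri()].
#' @param drive a [theta_drive()] (theta conductance, step current, noise).
#' @param dt_neuro integration step, s.
#' @param seed noise seed.
#' @param g_conv conversion conductance (uS per mV of ramp depolarization);
#'   calibrated so that replayed in-field passes reproduce the in-field
#'   firing rates of the network simulation (the Na-blocked measurement
#'   trace understates the effective drive of the intact cell).
#' @param lead_in settling time before the ramp, s.
#' @param i_ramp_max ceiling on the injected ramp current, nA, emulating
#'   the driving-force saturation of the conductance input it stands for.
#' @return list with `spikes` (s, relative to ERI start), `t`, `v_m`, and
#'   `theta_peaks` (same time base).
#' @export
eri_replay <- function(cell, seg, drive, dt_neuro = 1e-4, seed = 1L,
                       g_conv = 0.15, lead_in = 1, i_ramp_max = 1.2) {
  dt_ms <- dt_neuro * 1000
  dur_seg <- max(seg$t) - min(seg$t)
  duration <- lead_in + dur_seg
  n_steps <- ceiling(duration / dt_neuro)
  tt <- (seq_len(n_steps) - 1) * dt_neuro
  env <- approx(seg$t - min(seg$t) + lead_in, seg$v - seg$baseline, tt,
                yleft = 0, yright = 0)$y
  set.seed(as.integer(seed))
  i_soma <- drive$i_step + pmin(env * g_conv, i_ramp_max) +
    rnorm(n_steps, sd = drive$noise_sd / sqrt(dt_ms))
  res <- hh_simulate_cpp(cell$cap_nF, cell$g_ax_uS, cell$gbar_uS, cell$erev,
                         dt_ms, as.integer(n_steps),
                         integer(0), integer(0), 0, 30, 0,
                         drive$f, drive$g_inh_amp, drive$E_rev,
                         i_soma, max(1L, as.integer(round(0.001 / dt_neuro))),
                         -1L, -68)
  peaks <- theta_peak_times(drive, duration)
  list(spikes = res$spikes - lead_in, t = res$t - lead_in, v_m = res$v_soma,
       theta_peaks = peaks - lead_in)
}

#' Analyze all passes of a viable place field
#'
#' For each qualifying pass: despike the ERI from the network-simulation
#' trace and classify its shape; then replay the ERI through the place cell
#' under theta inhibition ([eri_replay()]), compute replay spike phases
#' against the injected oscillation's peaks, and fit the circular-linear
#' precession slope using distance from field entry.
#'
#' @param traj a [trajectory].
#' @param field a field entry from [detect_fields()].
#' @param bin rate-map bin size, m.
#' @param trace place-cell `membrane_trace` from the network run.
#' @param spikes place-cell `spike_train` from the network run.
#' @param drive the [theta_drive()] for the replay stage.
#' @param cell the [build_cell()] model used for the replay.
#' @param min_duration,min_spikes pass inclusion thresholds (applied to the
#'   network-run spikes).
#' @param dt_neuro replay integration step, s.
#' @param seed base seed for replay noise.
#' @param cap_mV spike-capping level for the ERI extraction; use a high
#'   value (e.g. 0) when the measurement trace is already subthreshold.
#' @return data frame, one row per pass: `pass`, `r_peak`, `class`, `rho`,
#'   `n_spikes`, `duration`.
#' @export
analyze_field_passes <- function(traj, field, bin, trace, spikes, drive,
                                 cell, min_duration = 0.5, min_spikes = 3,
                                 dt_neuro = 1e-4, seed = 1L, cap_mV = -50) {
  passes <- extract_passes(traj, field, bin = bin, spikes = spikes,
                           min_duration = min_duration,
                           min_spikes = min_spikes)
  rows <- list()
  for (i in seq_along(passes)) {
    p <- passes[[i]]
    seg <- extract_eri(trace, p, cap_mV = cap_mV)
    cls <- classify_eri(seg)
    if (is.na(cls$r_peak)) next
    # the characterized (spline-smoothed) ramp is what is replayed under
    # theta inhibition; residual theta-band wiggle in the raw envelope
    # would otherwise decouple spike phase from position
    seg_smooth <- list(t = seg$t, v = cls$smoothed,
                       baseline = min(cls$smoothed))
    rep <- eri_replay(cell, seg_smooth, drive, dt_neuro = dt_neuro,
                      seed = seed + i)
    # discard the settling transient: spikes in the first theta cycle
    # after ramp onset carry arbitrary phase
    sp <- rep$spikes[rep$spikes >= 1 / drive$f]
    ph <- spike_phase(sp, rep$theta_peaks)
    if (nrow(ph) < 3) next
    xs <- approx(p$t - p$t_entry, p$path_cm, ph$t, rule = 2)$y
    # bound the search so total phase change across the pass is at most
    # one theta cycle; steeper solutions are aliased wrap fits
    bmax <- min(30, 360 / max(p$path_cm))
    fit <- circular_linear_fit(ph$phase, xs, slope_bounds = c(-bmax, bmax))
    rows[[length(rows) + 1]] <-
      data.frame(pass = i, r_peak = cls$r_peak, class = cls$class,
                 rho = fit$rho, n_spikes = nrow(ph),
                 duration = p$t_exit - p$t_entry)
  }
  if (length(rows) == 0)
    return(data.frame(pass = integer(0), r_peak = numeric(0),
                      class = character(0), rho = numeric(0),
                      n_spikes = integer(0), duration = numeric(0)))
  do.call(rbind, rows)
}
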