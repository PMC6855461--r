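#' Channel configuration for the place cell
#'
#' Conductance densities and reversal potentials of the six membrane
#' currents of the Hodgkin-Huxley CA1 pyramidal model: leak, transient Na
#' (gates m^3 h s, with s a slow inactivation), delayed-rectifier K (n),
#' M-type K (z), A-type K (a b), and the hyperpolarization-activated
#' h-current (q). Densities are the model's stated values; kinetics are a
#' standard CA1-style sigmoidal parameterization compiled into the
#' integrator.
#'
#' @param g_L,g_Na,g_KDR,g_KM,g_KA,g_h maximal conductance densities in
#'   mS/cm^2 (defaults: 0.0125, 9.4, 1.05, 0.045, 1.04, 0.005).
#' @param E_L,E_Na,E_K,E_h reversal potentials, mV.
#' @return object of class `channel_config`.
#' @export
channel_config <- function(g_L = 0.0125, g_Na = 9.4, g_KDR = 1.05,
                           g_KM = 0.045, g_KA = 1.04, g_h = 0.005,
                           E_L = -65, E_Na = 50, E_K = -90, E_h = -30) {
  dens <- c(L = g_L, Na = g_Na, KDR = g_KDR, KM = g_KM, KA = g_KA, H = g_h)
  if (any(dens < 0)) stop("conductance densities must be >= 0")
  structure(list(densities = dens,
                 erev = c(E_L, E_Na, E_K, E_K, E_K, E_h)),
            class = "channel_config")
}

#' Build the reduced place-cell morphology
#'
#' Discretizes a soma plus uniform apical equivalent cylinder into
#' compartments with per-compartment membrane area, capacitance, path
#' distance from the soma, and axial coupling conductances. The cable must
#' be at least 400 um long so the distal synaptic zone (300-400 um) exists.
#' The default cylinder diameter is chosen so the reduced cell's total
#' membrane area (and hence input conductance) approximates a full
#' reconstructed CA1 pyramidal cell rather than a bare 2-um neurite; see the
#' methods vignette.
#'
#' @param n_comp total compartment count including the soma (default 155).
#' @param soma_l,soma_d soma cylinder length and diameter, um.
#' @param cable_l apical cable length, um (must be >= 400).
#' @param cable_d apical cable diameter, um.
#' @param ra axial resistivity, Ohm cm.
#' @param cm specific capacitance, uF/cm^2.
#' @param channels a [channel_config()].
#' @return object of class `cell_model` with vectors `area_cm2`, `cap_nF`,
#'   `path_um`, `g_ax_uS` and the absolute conductance matrix `gbar_uS`.
#' @export
build_cell <- function(n_comp = 155, soma_l = 20, soma_d = 20,
                       cable_l = 600, cable_d = 50, ra = 150, cm = 1,
                       channels = channel_config()) {
  if (cable_l < 400)
    stop("configuration error: apical cable must reach 400 um")
  if (n_comp < 2) stop("configuration error: need soma plus >= 1 cable compartment")
  n_seg <- n_comp - 1
  seg_l <- cable_l / n_seg
  um2cm <- 1e-4
  # membrane areas (cylinder side walls), cm^2
  a_soma <- pi * soma_d * soma_l * um2cm^2
  a_seg <- pi * cable_d * seg_l * um2cm^2
  area <- c(a_soma, rep(a_seg, n_seg))
  cap <- cm * area * 1e3        # uF/cm^2 * cm^2 -> uF; *1e3 -> nF
  path <- c(0, (seq_len(n_seg) - 0.5) * seg_l)
  # axial resistances between compartment centers (Ohm), then uS
  cross_soma <- pi * (soma_d / 2)^2 * um2cm^2
  cross_seg <- pi * (cable_d / 2)^2 * um2cm^2
  r_half_soma <- ra * (soma_l / 2 * um2cm) / cross_soma
  r_half_seg <- ra * (seg_l / 2 * um2cm) / cross_seg
  r01 <- r_half_soma + r_half_seg
  rseg <- 2 * r_half_seg
  g_ax <- 1e6 / c(r01, rep(rseg, n_seg - 1))
  gbar <- outer(area, channels$densities) * 1e3  # mS/cm^2 * cm^2 -> mS; -> uS
  structure(list(n_comp = n_comp, area_cm2 = area, cap_nF = cap,
                 path_um = path, g_ax_uS = g_ax, gbar_uS = gbar,
                 erev = channels$erev, channels = channels,
                 soma_l = soma_l, soma_d = soma_d,
                 cable_l = cable_l, cable_d = cable_d, ra = ra, cm = cm),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Cell model: ", x$n_comp, " compartments, cable ", x$cable_l,
      " um x ", x$cable_d, " um, total area ",
      sprintf("%.0f", sum(x$area_cm2) / 1e-8), " um2\n", sep = "")
  invisible(x)
}

#' Excitatory postsynaptic conductance kernel
#'
#' Single-exponential EPSG: `w * exp(-t / tau_decay)`. Contributions of
#' successive presynaptic spikes sum linearly.
#'
#' @param t_since_spike time since the presynaptic spike, seconds
#'   (vectorized).
#' @param w peak synaptic conductance, pS (default 200).
#' @param tau_decay decay time constant, ms (default 30).
#' @return conductance in pS.
#' @export
epsg <- function(t_since_spike, w = 200, tau_decay = 30) {
  stopifnot(all(t_since_spike >= 0))
  w * exp(-t_since_spike * 1000 / tau_decay)
}

#' Attach grid-cell spike trains to the place cell
#'
#' `single` placement converges all trains on the compartment nearest to
#' 315.95 um path distance; `distributed` assigns each train to a
#' compartment drawn uniformly over path distances in 300-400 um.
#'
#' @param cell a [build_cell()] result.
#' @param trains list of `spike_train` objects.
#' @param placement `"single"` or `"distributed"`.
#' @param seed seed for distributed placement draws.
#' @param single_site_um path distance of the single synaptic site, um.
#' @param w synaptic conductance, pS.
#' @param tau_decay decay constant, ms.
#' @param E_syn synaptic reversal potential, mV.
#' @return object of class `synapse_set`: data frame of (train, comp,
#'   path_um) plus the spike trains and synapse constants.
#' @export
attach_synapses <- function(cell, trains, placement = c("single", "distributed"),
                            seed = 1L, single_site_um = 315.95,
                            w = 200, tau_decay = 30, E_syn = 0) {
  placement <- match.arg(placement)
  if (length(trains) == 0) stop("no presynaptic trains supplied")
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (placement == "single") {
    comp <- which.min(abs(cell$path_um - single_site_um))
    comps <- rep(comp, length(trains))
  } else {
    in_zone <- which(cell$path_um >= 300 & cell$path_um <= 400)
    if (length(in_zone) == 0)
      stop("configuration error: no compartment with path distance in [300, 400] um")
    set.seed(as.integer(seed))
    comps <- sample(in_zone, length(trains), replace = TRUE)
  }
  structure(list(comp = comps, path_um = cell$path_um[comps],
                 trains = trains, w_pS = w, tau_decay_ms = tau_decay,
                 E_syn = E_syn, placement = placement),
            class = "synapse_set")
}

#' @export
print.synapse_set <- function(x, ...) {
  ns <- sum(vapply(x$trains, function(tr) length(tr$times), numeric(1)))
  cat("Synapse set: ", length(x$trains), " synapses (", x$placement,
      "), path ", sprintf("%.1f-%.1f", min(x$path_um), max(x$path_um)),
      " um, ", ns, " presynaptic spikes\n", sep = "")
  invisible(x)
}

#' Somatic drive: theta inhibition, step current, noise
#'
#' The theta-frequency inhibitory oscillation is a rectified sinusoidally
#' gated conductance `g_inh_amp * max(sin(2 pi f t), 0)` at the soma with
#' reversal -70 mV; its peaks (phase reference 0/360 degrees) fall at
#' `(k + 1/4) / f`. A constant step current and Gaussian white noise are
#' injected at the soma as well.
#'
#' @param f theta frequency, Hz.
#' @param g_inh_amp inhibitory conductance amplitude, uS.
#' @param E_rev reversal potential of the inhibitory conductance, mV.
#' @param i_step step current, nA.
#' @param noise_sd Gaussian white-noise current intensity, nA sqrt(ms)
#'   (the per-step SD is `noise_sd / sqrt(dt_ms)`, so the voltage noise is
#'   independent of the integration step). The default produces ~1-2 mV of
#'   subthreshold membrane noise, matching in vivo-like conditions.
#' @return object of class `theta_drive`.
#' @export
theta_drive <- function(f = 10, g_inh_amp = 1e-2, E_rev = -70,
                        i_step = 0, noise_sd = 0.2) {
  if (f <= 0) stop("theta frequency must be positive")
  structure(list(f = f, g_inh_amp = g_inh_amp, E_rev = E_rev,
                 i_step = i_step, noise_sd = noise_sd),
            class = "theta_drive")
}

#' Peak times of the injected theta conductance
#'
#' @param drive a [theta_drive()].
#' @param duration session length, s.
#' @return vector of peak times (s), exactly periodic at `1/f`.
#' @export
theta_peak_times <- function(drive, duration) {
  p0 <- 0.25 / drive$f
  seq(p0, duration, by = 1 / drive$f)
}

#' Simulate the place cell
#'
#' Integrates the compartmental cable model with the six membrane currents,
#' distal synaptic input from the attached grid-cell trains, and the somatic
#' theta/step/noise drive. Somatic voltage is recorded at >= 1 kHz; spikes
#' are upward 0-mV crossings with a 2-ms dead time.
#'
#' @param cell a [build_cell()] result.
#' @param synapses a [attach_synapses()] result, or `NULL` for no synaptic
#'   input.
#' @param drive a [theta_drive()].
#' @param duration simulated time, seconds.
#' @param dt_neuro integration step, seconds (<= 1e-4).
#' @param seed seed for the injected current noise.
#' @param record_comp optional compartment index (1-based) to record in
#'   addition to the soma.
#' @param v_init initial voltage, mV.
#' @return object of class `membrane_trace`: list with `t` (s), `v_m` (mV,
#'   soma), `spikes` (s), and the drive used.
#' @export
simulate_place_cell <- function(cell, synapses = NULL, drive = theta_drive(),
                                duration, dt_neuro = 2.5e-5, seed = 1L,
                                record_comp = NULL, v_init = -68) {
  if (dt_neuro > 1e-4 + 1e-12)
    stop("parameter error: dt_neuro must be <= 0.1 ms")
  if (duration <= 0) stop("duration must be positive")
  dt_ms <- dt_neuro * 1000
  n_steps <- ceiling(duration / dt_neuro)
  # presynaptic events -> (step, compartment), sorted by step
  if (!is.null(synapses)) {
    ev_t <- unlist(lapply(seq_along(synapses$trains),
                          function(i) synapses$trains[[i]]$times))
    ev_c <- unlist(lapply(seq_along(synapses$trains),
                          function(i) rep(synapses$comp[i] - 1L,
                                          length(synapses$trains[[i]]$times))))
    keep <- ev_t >= 0 & ev_t < duration
    ev_t <- ev_t[keep]; ev_c <- ev_c[keep]
    ord <- order(ev_t)
    syn_step <- as.integer(floor(ev_t[ord] / dt_neuro))
    syn_comp <- as.integer(ev_c[ord])
    w_uS <- synapses$w_pS * 1e-6
    tau_ms <- synapses$tau_decay_ms
    e_syn <- synapses$E_syn
  } else {
    syn_step <- integer(0); syn_comp <- integer(0)
    w_uS <- 0; tau_ms <- 30; e_syn <- 0
  }
  set.seed(as.integer(seed))
  i_soma <- if (drive$noise_sd > 0) {
    drive$i_step + rnorm(n_steps, sd = drive$noise_sd / sqrt(dt_ms))
  } else {
    drive$i_step
  }
  record_every <- max(1L, as.integer(round(0.001 / dt_neuro)))
  res <- hh_simulate_cpp(cell$cap_nF, cell$g_ax_uS, cell$gbar_uS, cell$erev,
                         dt_ms, as.integer(n_steps),
                         syn_step, syn_comp, w_uS, tau_ms, e_syn,
                         drive$f, drive$g_inh_amp, drive$E_rev,
                         i_soma, record_every,
                         if (is.null(record_comp)) -1L
                         else as.integer(record_comp - 1L),
                         v_init)
  out <- list(t = res$t, v_m = res$v_soma, spikes = res$spikes,
              drive = drive, dt = dt_neuro, duration = duration)
  if (!is.null(record_comp)) out$v_comp <- res$v_comp
  class(out) <- "membrane_trace"
  out
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat("Membrane trace: ", sprintf("%.1f", x$duration), " s, ",
      length(x$spikes), " spikes (",
      sprintf("%.2f", length(x$spikes) / x$duration), " Hz), Vm range [",
      sprintf("%.1f, %.1f", min(x$v_m), max(x$v_m)), "] mV\n", sep = "")
  invisible(x)
}

#' @export
plot.membrane_trace <- function(x, ...) {
  plot(x$t, x$v_m, type = "l", xlab = "time (s)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' Calibrate the somatic step current
#'
#' Bisection over the step amplitude until the mean firing rate over a
#' calibration simulation is within +0.25 Hz above the target ("minimum
#' mean rate" semantics: the returned amplitude attains at least the
#' target). By default the cell is calibrated in isolation; passing the
#' experiment's `synapses` calibrates the session-mean rate of the driven
#' cell instead, which sets the operating point so that out-of-field
#' firing stays sparse.
#'
#' @param cell a [build_cell()] result.
#' @param drive a [theta_drive()]; its `i_step` is ignored.
#' @param target_rate target mean rate, Hz.
#' @param duration calibration simulation length, s.
#' @param dt_neuro integration step, s.
#' @param upper initial upper search bound, nA.
#' @param seed noise seed used for every evaluation.
#' @param synapses optional [attach_synapses()] result present during
#'   calibration.
#' @return step current amplitude in nA.
#' @export
calibrate_step_current <- function(cell, drive = theta_drive(),
                                   target_rate = 2.5, duration = 10,
                                   dt_neuro = 1e-4, upper = 2, seed = 1L,
                                   synapses = NULL) {
  rate_at <- function(i) {
    d <- drive; d$i_step <- i
    tr <- simulate_place_cell(cell, synapses, d, duration, dt_neuro,
                              seed = seed)
    length(tr$spikes) / duration
  }
  r0 <- rate_at(0)
  if (r0 >= target_rate) return(0)
  lo <- 0; hi <- upper
  r_hi <- rate_at(hi)
  tries <- 0
  while (r_hi < target_rate && tries < 6) {
    lo <- hi; hi <- hi * 2; r_hi <- rate_at(hi); tries <- tries + 1
  }
  if (r_hi < target_rate)
    stop("calibration error: search range does not bracket the target rate")
  for (it in 1:25) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (r < target_rate) lo <- mid else {
      hi <- mid
      if (r <= target_rate + 0.25) break
    }
  }
  hi
}
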