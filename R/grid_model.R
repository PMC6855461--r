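#' Grid cell parameters
#'
#' Parameter record for one oscillatory-interference (OI) grid cell. Six
#' velocity-controlled oscillators (VCOs) with preferred directions
#' `phi_pref + {0, 60, ..., 300}` degrees interfere with a background theta
#' oscillator; `beta` scales the speed-to-frequency gain and thereby grid
#' spacing and field size. The *in vivo*-like variant thins OI spikes by a
#' Gaussian acceptance profile around the firing-field centers.
#'
#' @param beta VCO gain in Hz/(m/s); the pool spans `[1, 3.5]`.
#' @param phi_pref base preferred direction of VCO 1, degrees in `[0, 60)`.
#' @param f_theta theta frequency, Hz (default 10).
#' @param n_vco number of VCOs (default 6).
#' @param g_thres spike threshold on the interference signal; per the model's
#'   rule, 1 x `n_vco`.
#' @param sigma Gaussian thinning SD in meters, or `NULL` to derive it as
#'   one-third of the measured firing-field radius of the un-thinned map.
#' @param accept_peak thinning acceptance probability at a field center,
#'   in (0, 1].
#' @param refractory absolute refractory period of the OI spike rule, s.
#'   The default (1 ms, equal to the default oscillator step) emits one
#'   spike per supra-threshold sample, which reproduces the conventional
#'   model's characteristic ~300 Hz peak map rate.
#' @param phase_offset 2-vector (meters): spatial offset of the grid
#'   lattice (the grid phase). Implemented as initial VCO phases
#'   `2 pi beta (u_i . offset)`, which translates the firing lattice
#'   without affecting spacing or orientation. Default `c(0, 0)` puts a
#'   grid vertex at the trajectory origin.
#' @param theta_phase initial phase of the cell's baseline theta
#'   oscillator, radians. Shifts the cell's burst timing within the theta
#'   cycle without moving its firing lattice; distinct cells in vivo fire
#'   at diverse theta phases.
#' @return object of class `grid_cell_params`.
#' @export
grid_cell_params <- function(beta = 2, phi_pref = 30, f_theta = 10,
                             n_vco = 6, g_thres = n_vco, sigma = NULL,
                             accept_peak = 0.15, refractory = 0.001,
                             phase_offset = c(0, 0), theta_phase = 0) {
  if (beta < 1 || beta > 3.5) stop("beta must lie in [1, 3.5]")
  if (phi_pref < 0 || phi_pref >= 60) stop("phi_pref must lie in [0, 60)")
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be positive")
  if (accept_peak <= 0 || accept_peak > 1) stop("accept_peak must be in (0, 1]")
  structure(list(beta = beta, phi_pref = phi_pref, f_theta = f_theta,
                 n_vco = n_vco, g_thres = g_thres, sigma = sigma,
                 accept_peak = accept_peak, refractory = refractory,
                 phase_offset = phase_offset, theta_phase = theta_phase),
            class = "grid_cell_params")
}

#' VCO frequency
#'
#' Frequency of one velocity-controlled oscillator:
#' `f_theta + beta * s * cos(phi_pref_i - phi)`.
#'
#' @param s running speed, m/s.
#' @param phi heading, radians.
#' @param phi_pref_i preferred direction of the VCO, radians.
#' @param beta gain, Hz/(m/s).
#' @param f_theta baseline theta frequency, Hz.
#' @return frequency in Hz (vectorized).
#' @export
vco_frequency <- function(s, phi, phi_pref_i, beta, f_theta = 10) {
  f_theta + beta * s * cos(phi_pref_i - phi)
}

#' Conventional OI grid cell spikes
#'
#' Runs the OI interference model on a trajectory. Kinematic signals are
#' linearly resampled to the simulation step `dt_sim`; VCO phases are
#' path-integrated and a spike is emitted at every step where the
#' interference signal reaches threshold, subject to an absolute refractory
#' period. The model is deterministic given the trajectory.
#'
#' @param traj a [trajectory].
#' @param kin optional precomputed [kinematics] of `traj`.
#' @param params a [grid_cell_params] record.
#' @param dt_sim oscillator integration step in seconds (default 1 ms); must
#'   not exceed the position sampling interval.
#' @return object of class `spike_train`: list with `times` (s), `x`, `y`
#'   (spike positions, m) and `cell_id`.
#' @export
oi_spikes <- function(traj, kin = NULL, params = grid_cell_params(),
                      dt_sim = 0.001) {
  dt_pos <- attr(traj, "dt_pos")
  if (!is.na(dt_pos) && dt_sim > dt_pos + 1e-12)
    stop("parameter error: dt_sim must not exceed the position sampling interval")
  if (is.null(kin)) kin <- kinematics(traj)
  tt <- seq(0, max(traj$t), by = dt_sim)
  s <- approx(kin$t, kin$s, tt, rule = 2)$y
  # interpolate heading via its unit vector to avoid wrap artifacts
  cph <- approx(kin$t, cos(kin$phi), tt, rule = 2)$y
  sph <- approx(kin$t, sin(kin$phi), tt, rule = 2)$y
  phi <- atan2(sph, cph)
  phi_pref <- (params$phi_pref + seq(0, 300, by = 60)[seq_len(params$n_vco)]) *
    pi / 180
  off <- params$phase_offset
  if (is.null(off)) off <- c(0, 0)
  theta0 <- 2 * pi * params$beta * (cos(phi_pref) * off[1] +
                                      sin(phi_pref) * off[2])
  tb0 <- params$theta_phase
  if (is.null(tb0)) tb0 <- 0
  times <- oi_spikes_cpp(s, phi, dt_sim, params$beta, phi_pref,
                         params$f_theta, params$g_thres, params$refractory,
                         theta0, tb0)
  new_spike_train(times, traj)
}

new_spike_train <- function(times, traj = NULL, cell_id = NA_character_) {
  st <- list(times = as.numeric(times), cell_id = cell_id,
             x = NULL, y = NULL)
  if (!is.null(traj) && length(times) > 0 && nrow(traj) > 1) {
    st$x <- approx(traj$t, traj$x, times, rule = 2)$y
    st$y <- approx(traj$t, traj$y, times, rule = 2)$y
  } else if (length(times) == 0) {
    st$x <- numeric(0); st$y <- numeric(0)
  }
  class(st) <- "spike_train"
  st
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train: ", length(x$times), " spikes",
      if (length(x$times) > 0)
        sprintf(" over %.1f s (mean %.2f Hz)", max(x$times),
                length(x$times) / max(max(x$times), 1e-9)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Firing-field centers of a rate map
#'
#' Local maxima of a (smoothed) rate map exceeding 20% of the global peak,
#' deduplicated within one bin; returned as bin-center coordinates in meters.
#'
#' @param rmap a [rate_map] object.
#' @param peak_fraction threshold as a fraction of the global peak.
#' @return matrix with columns `x`, `y` (meters); zero rows for an all-zero
#'   map.
#' @export
field_centers <- function(rmap, peak_fraction = 0.2) {
  r <- rmap$rates
  mx <- max(r, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  thr <- peak_fraction * mx
  nr <- nrow(r); nc <- ncol(r)
  cand <- which(r >= thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    nb <- r[max(1, a - 1):min(nr, a + 1), max(1, b - 1):min(nc, b + 1)]
    keep[i] <- r[a, b] >= max(nb, na.rm = TRUE)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  # deduplicate plateau maxima within one bin of each other
  ord <- order(-r[cand])
  cand <- cand[ord, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!sel[i]) next
    if (i < nrow(cand)) {
      d <- pmax(abs(cand[(i + 1):nrow(cand), 1] - cand[i, 1]),
                abs(cand[(i + 1):nrow(cand), 2] - cand[i, 2]))
      sel[(i + 1):nrow(cand)][d <= 1] <- FALSE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  bin <- rmap$bin
  cbind(x = (cand[, 1] - 0.5) * bin, y = (cand[, 2] - 0.5) * bin)
}

#' Gaussian thinning of a spike train
#'
#' Retains each spike independently with probability
#' `accept_peak * exp(-d^2 / (2 sigma^2))`, where `d` is the distance from
#' the spike's position to the nearest firing-field center. This converts
#' the near-continuous OI spike output into *in vivo*-like Gaussian firing
#' fields with realistic peak rates.
#'
#' @param spikes a `spike_train` carrying spike positions.
#' @param centers matrix of field-center coordinates (columns x, y, meters).
#' @param sigma Gaussian SD, meters.
#' @param accept_peak acceptance probability at a field center.
#' @param seed integer seed for the thinning draws.
#' @return a thinned `spike_train` (subset of the input).
#' @export
gaussian_thinning <- function(spikes, centers, sigma, accept_peak = 0.15,
                              seed = 1L) {
  if (is.null(dim(centers)) || nrow(centers) == 0)
    stop("thinning undefined: empty field-center set")
  if (is.null(spikes$x)) stop("spike train carries no positions")
  n <- length(spikes$times)
  if (n == 0) return(spikes)
  d2 <- rep(Inf, n)
  for (j in seq_len(nrow(centers))) {
    d2 <- pmin(d2, (spikes$x - centers[j, 1])^2 + (spikes$y - centers[j, 2])^2)
  }
  p <- accept_peak * exp(-d2 / (2 * sigma^2))
  set.seed(as.integer(seed))
  u <- runif(n)
  keep <- u < p
  out <- spikes
  out$times <- spikes$times[keep]
  out$x <- spikes$x[keep]
  out$y <- spikes$y[keep]
  out
}

#' Simulate a grid cell (conventional or in vivo-like)
#'
#' `conventional` mode runs the raw OI threshold model. `invivo_like` mode
#' additionally builds the un-thinned rate map, finds its field centers, and
#' Gaussian-thins the spikes; the thinning SD defaults to one-third of the
#' measured field radius of the un-thinned map unless `params$sigma` is set.
#'
#' @inheritParams oi_spikes
#' @param mode `"conventional"` or `"invivo_like"`.
#' @param seed seed for the thinning draws (ignored in conventional mode).
#' @return a `spike_train`.
#' @export
simulate_grid_cell <- function(traj, params = grid_cell_params(),
                               mode = c("invivo_like", "conventional"),
                               dt_sim = 0.001, seed = 1L, kin = NULL) {
  mode <- match.arg(mode)
  raw <- oi_spikes(traj, kin = kin, params = params, dt_sim = dt_sim)
  if (mode == "conventional") return(raw)
  rmap <- rate_map(raw, traj, smooth = TRUE)
  centers <- field_centers(rmap)
  if (nrow(centers) == 0) {
    out <- raw; out$times <- numeric(0); out$x <- numeric(0); out$y <- numeric(0)
    return(out)
  }
  sigma <- params$sigma
  if (is.null(sigma)) {
    fs <- detect_fields(rmap, min_bins = 1)
    if (length(fs$fields) > 0) {
      area_m2 <- mean(vapply(fs$fields, function(f) f$area, numeric(1))) / 1e4
      sigma <- sqrt(area_m2 / pi) / 3
    } else {
      sigma <- 0.069
    }
  }
  gaussian_thinning(raw, centers, sigma, params$accept_peak, seed = seed)
}

#' Build the grid-cell parameter pool
#'
#' Lattice of `n_beta x n_phi` parameter pairs covering the closed `beta`
#' range and half-open `phi_pref` range uniformly (default 100 x 100 =
#' 10,000 cells over `beta` in `[1, 3.5]` and `phi_pref` in `[0, 60)`).
#'
#' @param n_beta,n_phi lattice dimensions.
#' @param beta_range closed interval for `beta`.
#' @param phi_range half-open interval for `phi_pref` (degrees).
#' @param ... thinning defaults passed to [grid_cell_params()].
#' @return object of class `grid_cell_pool`: data frame of `beta`,
#'   `phi_pref` plus the shared defaults as attributes.
#' @export
build_pool <- function(n_beta = 100, n_phi = 100, beta_range = c(1, 3.5),
                       phi_range = c(0, 60), ...) {
  if (n_beta < 1 || n_phi < 1) stop("parameter error: lattice dims must be >= 1")
  if (beta_range[1] > beta_range[2] || phi_range[1] > phi_range[2])
    stop("parameter error: inverted range")
  betas <- if (n_beta == 1) beta_range[1] else
    seq(beta_range[1], beta_range[2], length.out = n_beta)
  phis <- phi_range[1] +
    (seq_len(n_phi) - 1) / n_phi * (phi_range[2] - phi_range[1])
  pool <- expand.grid(beta = betas, phi_pref = phis, KEEP.OUT.ATTRS = FALSE)
  attr(pool, "defaults") <- list(...)
  class(pool) <- c("grid_cell_pool", "data.frame")
  pool
}

#' @export
print.grid_cell_pool <- function(x, ...) {
  cat("Grid cell pool: ", nrow(x), " cells, beta in [",
      min(x$beta), ", ", max(x$beta), "], phi_pref in [",
      min(x$phi_pref), ", ", max(x$phi_pref), "] deg\n", sep = "")
  invisible(x)
}

#' Randomly select cells from the pool
#'
#' Uniform sampling without replacement, plus a randomness measure: the
#' Shannon entropy (base 2) of the empirical distribution over the selected
#' parameter pairs relative to its maximum `log2(n)` (all pairs distinct),
#' expressed in percent. Sampling without replacement from a lattice pool
#' always yields distinct pairs, hence 100%.
#'
#' @param pool a [build_pool()] result.
#' @param n number of cells to select.
#' @param seed integer seed.
#' @param replace sample with replacement (for studying duplicate-induced
#'   loss of randomness).
#' @return list with `selection` (row indices), `params` (data frame) and
#'   `randomness` (percent).
#' @export
sample_cells <- function(pool, n, seed = 1L, replace = FALSE) {
  if (n < 1 || (!replace && n > nrow(pool)))
    stop("parameter error: n must be in [1, pool size]")
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(pool), n, replace = replace)
  counts <- table(idx)
  p <- as.numeric(counts) / n
  H <- -sum(p * log2(p))
  Hmax <- log2(n)
  randomness <- if (Hmax == 0) 100 else 100 * H / Hmax
  list(selection = idx, params = pool[idx, , drop = FALSE],
       randomness = randomness)
}

#' Serialize a pool to JSON
#' @param pool a [build_pool()] result.
#' @param path output path.
#' @export
write_pool <- function(pool, path) {
  jsonlite::write_json(as.data.frame(pool), path, digits = NA)
  invisible(path)
}

#' Write spike times as CSV (cell_id, time_s)
#' @param spikes a `spike_train`.
#' @param path output path.
#' @export
write_spike_train <- function(spikes, path) {
  write.csv(data.frame(cell_id = spikes$cell_id, time_s = spikes$times),
            path, row.names = FALSE)
  invisible(path)
}
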