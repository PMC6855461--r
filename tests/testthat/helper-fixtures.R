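# shared fixtures, all built in code

# trajectory with externally prescribed coordinates
make_traj <- function(t, x, y, arena_side = 1) {
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "arena_side") <- arena_side
  attr(out, "dt_pos") <- if (length(t) > 1) t[2] - t[1] else NA_real_
  class(out) <- c("trajectory", "data.frame")
  out
}

# straight run along +x at constant speed, wrapping across the arena
straight_traj <- function(duration = 40, speed = 0.25, dt = 0.02, y = 0.5) {
  n <- round(duration / dt)
  tt <- (0:(n - 1)) * dt
  make_traj(tt, (tt * speed) %% 1, rep(y, n))
}

make_kin <- function(traj, s, phi) {
  data.frame(t = traj$t, s = rep_len(s, nrow(traj)),
             phi = rep_len(phi, nrow(traj)))
}

# rate map object wrapping a given matrix (visited everywhere)
make_map <- function(m, bin = 0.03, arena_side = nrow(m) * bin) {
  structure(list(rates = m, dwell = matrix(1, nrow(m), ncol(m)),
                 counts = m, bin = bin, arena_side = arena_side,
                 smoothed = TRUE),
            class = "rate_map")
}

# square map with Gaussian bumps at the given centers (meters)
bump_map <- function(centers, sigma = 0.04, n = 34, bin = 0.03, peak = 10) {
  xs <- (seq_len(n) - 0.5) * bin
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((xs - centers[k, 1])^2, (xs - centers[k, 2])^2, "+")
    m <- m + peak * exp(-d2 / (2 * sigma^2))
  }
  make_map(m, bin)
}

# hexagonal lattice of bump centers around the arena center
hex_centers <- function(spacing = 0.30, center = c(0.5, 0.5)) {
  ang <- seq(0, 300, by = 60) * pi / 180
  rbind(center,
        cbind(center[1] + spacing * cos(ang),
              center[2] + spacing * sin(ang)))
}

# membrane-trace stand-in from explicit samples
make_trace <- function(t, v, duration = max(t), spikes = numeric(0)) {
  structure(list(t = t, v_m = v, spikes = spikes,
                 drive = theta_drive(), dt = t[2] - t[1],
                 duration = duration),
            class = "membrane_trace")
}

# brute-force interference signal per the printed sum-of-cosines scheme,
# evaluated by direct phase accumulation in R (independent of the C++ core)
oi_g_oracle <- function(s, phi, dt, beta, phi_pref, f_theta = 10) {
  nv <- length(phi_pref)
  theta <- numeric(nv)
  theta_base <- 0
  g <- numeric(length(s))
  for (k in seq_along(s)) {
    g[k] <- nv * cos(theta_base) + sum(cos(theta_base + theta))
    fv <- f_theta + beta * s[k] * cos(phi_pref - phi[k])
    theta <- theta + 2 * pi * fv * dt
    theta_base <- theta_base + 2 * pi * f_theta * dt
  }
  g
}

scaled_cell <- function() build_cell(n_comp = 31)
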