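#' Synthetic rodent foraging trajectory
#'
#' Generates a smooth correlated random walk confined to a square arena,
#' emulating open-field foraging of a rat: speed follows an
#' Ornstein-Uhlenbeck process around `speed_mean` (clipped at zero), heading
#' accumulates wrapped-normal increments, and wall collisions are resolved by
#' specular reflection of the heading so speed statistics are unaffected by
#' the boundary.
#'
#' @param duration session length in seconds.
#' @param dt_pos position sampling interval in seconds (default 0.02 s, i.e.
#'   50 Hz tracking).
#' @param arena_side side of the square arena in meters (default 1 m).
#' @param speed_mean,speed_sd mean and stationary standard deviation of the
#'   running speed (m/s).
#' @param turn_sd standard deviation of the per-step heading increment
#'   (radians).
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @return an object of class `trajectory`: a data frame with columns
#'   `t`, `x`, `y` and attributes `arena_side`, `dt_pos`.
#' @examples
#' traj <- generate_trajectory(60, seed = 1)
#' range(traj$x)
#' @export
generate_trajectory <- function(duration, dt_pos = 0.02, arena_side = 1,
                                speed_mean = 0.2, speed_sd = 0.1,
                                turn_sd = 0.3, seed = 1L) {
  if (dt_pos <= 0) stop("dt_pos must be positive")
  if (arena_side <= 0) stop("arena_side must be positive")
  if (duration < 0) stop("duration must be non-negative")
  n <- floor(duration / dt_pos)
  if (n == 0) {
    return(new_trajectory(numeric(0), numeric(0), numeric(0),
                          arena_side, dt_pos))
  }
  set.seed(as.integer(seed))
  # OU speed: relaxation time 1 s; sd given is the stationary sd
  tau <- 1
  a <- exp(-dt_pos / tau)
  sig_step <- speed_sd * sqrt(1 - a^2)
  s <- numeric(n); phi <- numeric(n)
  s[1] <- max(0, speed_mean + speed_sd * rnorm(1))
  phi[1] <- runif(1, 0, 2 * pi)
  eps_s <- rnorm(n) * sig_step
  eps_phi <- rnorm(n) * turn_sd
  for (k in seq_len(n - 1)) {
    s[k + 1] <- max(0, speed_mean + a * (s[k] - speed_mean) + eps_s[k])
    phi[k + 1] <- (phi[k] + eps_phi[k]) %% (2 * pi)
  }
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 0.1, 0.9) * arena_side
  y[1] <- runif(1, 0.1, 0.9) * arena_side
  for (k in seq_len(n - 1)) {
    dx <- s[k] * cos(phi[k]) * dt_pos
    dy <- s[k] * sin(phi[k]) * dt_pos
    nx <- x[k] + dx; ny <- y[k] + dy
    # specular reflection off the walls, possibly repeatedly for large steps
    for (i in 1:4) {
      ref <- FALSE
      if (nx < 0) { nx <- -nx; ref <- TRUE; phi[k + 1] <- (pi - phi[k + 1]) %% (2 * pi) }
      if (nx > arena_side) { nx <- 2 * arena_side - nx; ref <- TRUE; phi[k + 1] <- (pi - phi[k + 1]) %% (2 * pi) }
      if (ny < 0) { ny <- -ny; ref <- TRUE; phi[k + 1] <- (-phi[k + 1]) %% (2 * pi) }
      if (ny > arena_side) { ny <- 2 * arena_side - ny; ref <- TRUE; phi[k + 1] <- (-phi[k + 1]) %% (2 * pi) }
      if (!ref) break
    }
    x[k + 1] <- min(max(nx, 0), arena_side)
    y[k + 1] <- min(max(ny, 0), arena_side)
  }
  new_trajectory((seq_len(n) - 1) * dt_pos, x, y, arena_side, dt_pos)
}

new_trajectory <- function(t, x, y, arena_side, dt_pos) {
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "arena_side") <- arena_side
  attr(out, "dt_pos") <- dt_pos
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Read a position file
#'
#' Reads a plain-text position file with columns time, x, y (comma, tab or
#' whitespace separated; header optional). Coordinates larger than 2 are
#' assumed to be centimeters and are rescaled to meters with a message.
#' NaN/missing samples are linearly interpolated.
#'
#' @param path path to the file.
#' @param arena_side arena side in meters; defaults to the max coordinate
#'   rounded up to the next 0.5 m.
#' @return a [trajectory] object.
#' @export
read_position_file <- function(path, arena_side = NULL) {
  first_line <- readLines(path, n = 1)
  if (length(first_line) == 0)
    stop("format error: empty position file '", path, "'")
  sep <- if (grepl(",", first_line, fixed = TRUE)) "," else
    if (grepl("\t", first_line, fixed = TRUE)) "\t" else ""
  raw <- tryCatch(
    read.table(path, header = FALSE, sep = sep, fill = TRUE,
               stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("format error: cannot parse '", path, "': ",
                             conditionMessage(e)))
  if (nrow(raw) == 0) stop("format error: empty position file '", path, "'")
  if (ncol(raw) < 3) stop("format error: need columns time, x, y")
  # drop a header row if the first row is non-numeric
  first <- suppressWarnings(as.numeric(raw[1, 1:3]))
  if (any(is.na(first)) && !any(is.na(raw[1, 1:3]))) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("format error: empty position file '", path, "'")
  num <- suppressWarnings(vapply(1:3, function(j) as.numeric(raw[[j]]),
                                 numeric(nrow(raw))))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num[, 1]) & !is.na(raw[[1]]) &
                 !grepl("^\\s*(nan|na)?\\s*$", raw[[1]], ignore.case = TRUE))
  if (length(bad) > 0) {
    stop("format error: unparseable row at line ", bad[1])
  }
  t <- num[, 1]; x <- num[, 2]; y <- num[, 3]
  if (any(is.na(t))) stop("data error: missing time stamps")
  if (any(diff(t) <= 0)) stop("data error: non-monotonic time")
  n_gap <- sum(is.na(x) | is.na(y))
  if (n_gap > 0) {
    x <- approx(t[!is.na(x)], x[!is.na(x)], t, rule = 2)$y
    y <- approx(t[!is.na(y)], y[!is.na(y)], t, rule = 2)$y
    message("interpolated ", n_gap, " missing position samples")
  }
  if (max(c(x, y), na.rm = TRUE) > 2) {
    message("coordinates exceed 2: assuming centimeters, rescaling to meters")
    x <- x / 100; y <- y / 100
  }
  # shift coordinates so the arena corner is at the origin
  x <- x - min(x); y <- y - min(y)
  if (is.null(arena_side)) arena_side <- ceiling(max(x, y, 1e-9) / 0.5) * 0.5
  dt <- if (length(t) > 1) median(diff(t)) else NA_real_
  new_trajectory(t - t[1], x, y, arena_side, dt)
}

#' Speed and heading of a trajectory
#'
#' Derives the kinematic signals that drive the velocity-controlled
#' oscillators: central-difference velocity, speed `s = |v|`, and heading
#' `phi = atan2(vy, vx)` mapped to `[0, 2*pi)`. When speed falls below
#' 1 mm/s the heading is undefined and held at its previous value.
#'
#' @param traj a [trajectory] object with at least 2 samples.
#' @return a data frame of class `kinematics` with columns `t`, `s`, `phi`.
#' @export
kinematics <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("data error: trajectory must have at least 2 samples")
  t <- traj$t; x <- traj$x; y <- traj$y
  vx <- numeric(n); vy <- numeric(n)
  idx <- 2:(n - 1)
  vx[idx] <- (x[idx + 1] - x[idx - 1]) / (t[idx + 1] - t[idx - 1])
  vy[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1]); vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  s <- sqrt(vx^2 + vy^2)
  phi <- atan2(vy, vx) %% (2 * pi)
  # hold heading through near-stationary samples
  slow <- s < 1e-3
  if (any(slow)) {
    if (slow[1]) phi[1] <- 0
    for (k in which(slow)) if (k > 1) phi[k] <- phi[k - 1]
  }
  out <- data.frame(t = t, s = s, phi = phi)
  class(out) <- c("kinematics", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", nrow(x), " samples, ",
      if (nrow(x) > 0) sprintf("%.1f s, ", max(x$t)) else "",
      "arena ", attr(x, "arena_side"), " m\n", sep = "")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  L <- attr(x, "arena_side")
  plot(x$x, x$y, type = "l", xlim = c(0, L), ylim = c(0, L), asp = 1,
       xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Write / read a trajectory as CSV
#' @param traj a [trajectory].
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("t", "x", "y")], path, row.names = FALSE)
  invisible(path)
}
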