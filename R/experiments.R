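#' Experiment configuration
#'
#' Bundles every setting of an end-to-end grid-to-place run. Full-scale
#' settings mirror the study conditions (600-s session, 250 cells, 100
#' repeats, 155 compartments, 0.025-ms step); `scaled = TRUE` selects the
#' desk-scale profile (150-s session, 15 repeats, 31-compartment cable,
#' 0.1-ms step).
#'
#' @param duration session length, s.
#' @param n_cells grid cells per input set.
#' @param n_repeats number of independently sampled input sets.
#' @param placement `"single"` or `"distributed"` synapse placement.
#' @param n_comp place-cell compartment count.
#' @param dt_neuro place-cell integration step, s.
#' @param dt_sim OI oscillator step, s.
#' @param seed master seed; each repeat derives its own sub-seeds.
#' @param pool grid-cell pool (default the full 100 x 100 lattice).
#' @param traj optional pre-generated [trajectory] (otherwise generated from
#'   `seed`).
#' @param scaled use the scaled-down profile defaults.
#' @param i_step precalibrated step current, nA, or `NULL` to calibrate.
#' @param target_rate step-current calibration target, Hz.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(duration = if (scaled) 150 else 600,
                              n_cells = 250,
                              n_repeats = if (scaled) 15 else 100,
                              placement = "single",
                              n_comp = if (scaled) 31 else 155,
                              dt_neuro = if (scaled) 1e-4 else 2.5e-5,
                              dt_sim = 0.001, seed = 1L,
                              pool = NULL, traj = NULL, scaled = FALSE,
                              i_step = NULL, target_rate = 2.5) {
  structure(list(duration = duration, n_cells = n_cells,
                 n_repeats = n_repeats, placement = placement,
                 n_comp = n_comp, dt_neuro = dt_neuro, dt_sim = dt_sim,
                 seed = as.integer(seed), pool = pool, traj = traj,
                 scaled = scaled, i_step = i_step,
                 target_rate = target_rate),
            class = "experiment_config")
}

#' Run the grid-to-place transformation experiment
#'
#' For each repeat: sample `n_cells` grid cells from the pool, simulate
#' each *in vivo*-like OI cell on the shared session, feed the pooled spikes
#' through distal synapses into the Hodgkin-Huxley place cell (calibrated
#' step current plus noise), compute the smoothed rate map, detect fields,
#' and record viability and field metrics. For each viable field, the
#' per-pass ERIs are measured on a Na-blocked twin run, classified, and
#' replayed under the theta inhibitory conductance to obtain precession
#' slopes ([analyze_field_passes()]). Component failures abort the repeat
#' and are reported distinctly from non-viable outcomes.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-repeat progress.
#' @return object of class `experiment_result`: list with `repeats` (one
#'   record each), `viable` (logical), `proportion_viable`, pooled
#'   `pass_table`, and the config.
#' @export
run_transformation <- function(config, verbose = FALSE) {
  pool <- config$pool
  if (is.null(pool)) pool <- build_pool()
  traj <- config$traj
  if (is.null(traj))
    traj <- generate_trajectory(config$duration, seed = config$seed)
  kin <- kinematics(traj)
  cell <- build_cell(n_comp = config$n_comp)
  # the network transformation runs use step current + noise only; the
  # theta inhibitory conductance enters at the ERI-replay (phase) stage
  drive <- theta_drive(g_inh_amp = 0)
  i_step <- config$i_step
  trains1 <- NULL
  if (is.null(i_step)) {
    # calibrate the session-mean rate of the driven cell on the first
    # repeat's input set, then reuse the amplitude for every repeat
    seed_1 <- config$seed * 1000L + 1L
    trains1 <- build_grid_trains(pool, traj, kin, config, seed_1)
    syn1 <- if (length(trains1) > 0)
      attach_synapses(cell, trains1, placement = config$placement,
                      seed = seed_1) else NULL
    i_step <- calibrate_step_current(cell, drive,
                                     target_rate = config$target_rate,
                                     duration = min(config$duration, 50),
                                     dt_neuro = config$dt_neuro,
                                     seed = config$seed,
                                     synapses = syn1)
  }
  drive$i_step <- i_step
  repeats <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$seed * 1000L + r
    rec <- tryCatch(
      run_one_repeat(pool, traj, kin, cell, drive, config, seed_r,
                     trains = if (r == 1L) trains1 else NULL),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e)))
    rec$repeat_id <- r
    repeats[[r]] <- rec
    if (verbose)
      message(sprintf("repeat %d/%d: %s", r, config$n_repeats,
                      if (rec$status == "ok")
                        paste0(if (rec$viable) "viable" else "non-viable",
                               sprintf(" (peak %.1f Hz)", rec$peak_rate))
                      else rec$status))
  }
  ok <- vapply(repeats, function(x) identical(x$status, "ok"), logical(1))
  viable <- vapply(repeats, function(x) isTRUE(x$viable), logical(1))
  pass_tables <- lapply(repeats[viable], function(x) x$pass_table)
  pass_table <- if (length(pass_tables) > 0) {
    tb <- do.call(rbind, Map(function(tbl, id) {
      if (nrow(tbl) > 0) tbl$repeat_id <- id
      tbl
    }, pass_tables,
    vapply(repeats[viable], function(x) x$repeat_id, numeric(1))))
    tb[!is.na(tb$class), , drop = FALSE]
  } else {
    data.frame()
  }
  structure(list(repeats = repeats, ok = ok, viable = viable,
                 proportion_viable = mean(viable[ok]),
                 n_failed = sum(!ok), pass_table = pass_table,
                 i_step = i_step, config = config),
            class = "experiment_result")
}

build_grid_trains <- function(pool, traj, kin, config, seed_r) {
  if (config$n_cells == 0) return(list())
  sel <- sample_cells(pool, config$n_cells, seed = seed_r)
  # per-cell grid phase: uniform spatial lattice offsets, so selected cells
  # differ in spacing, orientation and lattice phase; the baseline theta
  # clock is shared across cells, as in the interference model's equations
  set.seed(seed_r + 500000L)
  offs <- matrix(runif(2 * config$n_cells), ncol = 2)
  trains <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    params <- grid_cell_params(beta = sel$params$beta[i],
                               phi_pref = sel$params$phi_pref[i],
                               phase_offset = offs[i, ])
    trains[[i]] <- simulate_grid_cell(traj, params, mode = "invivo_like",
                                      dt_sim = config$dt_sim,
                                      seed = seed_r + i, kin = kin)
  }
  attr(trains, "selection") <- sel$selection
  attr(trains, "randomness") <- sel$randomness
  trains
}

run_one_repeat <- function(pool, traj, kin, cell, drive, config, seed_r,
                           trains = NULL) {
  if (is.null(trains))
    trains <- build_grid_trains(pool, traj, kin, config, seed_r)
  if (length(trains) > 0) {
    syn <- attach_synapses(cell, trains, placement = config$placement,
                           seed = seed_r)
  } else {
    syn <- NULL
  }
  trace <- simulate_place_cell(cell, syn, drive, config$duration,
                               dt_neuro = config$dt_neuro, seed = seed_r)
  pc_spikes <- new_spike_train(trace$spikes, traj)
  rmap <- rate_map(pc_spikes, traj, smooth = TRUE)
  fs <- detect_fields(rmap)
  viable_fields <- Filter(function(f) f$viable, fs$fields)
  viable <- length(viable_fields) > 0
  rec <- list(status = "ok",
              selection = if (config$n_cells > 0)
                attr(trains, "selection") else integer(0),
              randomness = if (config$n_cells > 0)
                attr(trains, "randomness") else NA_real_,
              viable = viable,
              n_fields = length(fs$fields),
              peak_rate = max(rmap$rates),
              field_area = if (viable) viable_fields[[1]]$area else NA_real_,
              field_centroid = if (viable) viable_fields[[1]]$centroid else
                c(NA_real_, NA_real_),
              pass_table = data.frame())
  if (viable) {
    # analyze the dominant (highest-peak) viable field
    peaks <- vapply(viable_fields, function(f) f$peak_rate, numeric(1))
    fld <- viable_fields[[which.max(peaks)]]
    rec$field_area <- fld$area
    rec$field_centroid <- fld$centroid
    # Na-blocked twin run (same inputs and noise): isolates the
    # subthreshold synaptic ramp that spiking and after-potentials mask
    # in the spiking trace
    cell_sub <- cell
    cell_sub$gbar_uS[, 2] <- 0
    trace_sub <- simulate_place_cell(cell_sub, syn, drive, config$duration,
                                     dt_neuro = config$dt_neuro,
                                     seed = seed_r)
    # replay drive: the network drive (step current + noise) plus theta
    # inhibition strong enough to gate spike timing within the cycle
    replay_drive <- theta_drive(i_step = drive$i_step, g_inh_amp = 0.02)
    rec$pass_table <- analyze_field_passes(traj, fld, rmap$bin, trace_sub,
                                           pc_spikes, replay_drive, cell,
                                           dt_neuro = config$dt_neuro,
                                           seed = seed_r, cap_mV = 0)
  }
  rec
}

#' @export
print.experiment_result <- function(x, ...) {
  n_ok <- sum(x$ok)
  cat("Experiment: ", length(x$repeats), " repeats (", x$n_failed,
      " failed), ", sum(x$viable), "/", n_ok, " viable (",
      sprintf("%.0f%%", 100 * x$proportion_viable), ")\n", sep = "")
  if (nrow(x$pass_table) > 0) {
    cat("  ", nrow(x$pass_table), " classified ERIs: ",
        paste(sprintf("%s %.1f%%", names(table(x$pass_table$class)),
                      100 * as.numeric(table(x$pass_table$class)) /
                        nrow(x$pass_table)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Sweep the grid-cell count
#'
#' Runs [run_transformation()] for each cell count and tabulates the viable
#' proportion, mean peak rate, and mean field area against the count. The
#' step current is calibrated once at the base configuration's cell count
#' (the reference network) and held fixed across the sweep: with a fixed
#' operating point, too few grid cells evoke too few spikes for a field
#' and too many produce excess excitation, so viability peaks at
#' intermediate counts.
#'
#' @param config base [experiment_config()]; its `n_cells` is the
#'   calibration reference.
#' @param counts vector of cell counts (the study sweeps 50 to 500 by 50).
#' @param verbose print progress.
#' @return data frame with one row per count: `n_cells`,
#'   `proportion_viable`, `peak_rate`, `field_area`.
#' @export
sweep_cell_count <- function(config, counts = seq(50, 500, by = 50),
                             verbose = FALSE) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (is.null(config$i_step)) {
    pool <- config$pool
    if (is.null(pool)) pool <- build_pool()
    traj <- config$traj
    if (is.null(traj))
      traj <- generate_trajectory(config$duration, seed = config$seed)
    kin <- kinematics(traj)
    cell <- build_cell(n_comp = config$n_comp)
    seed_1 <- config$seed * 1000L + 1L
    trains1 <- build_grid_trains(pool, traj, kin, config, seed_1)
    syn1 <- if (length(trains1) > 0)
      attach_synapses(cell, trains1, placement = config$placement,
                      seed = seed_1) else NULL
    config$i_step <- calibrate_step_current(
      cell, theta_drive(g_inh_amp = 0),
      target_rate = config$target_rate,
      duration = min(config$duration, 50),
      dt_neuro = config$dt_neuro, seed = config$seed, synapses = syn1)
    config$pool <- pool
    config$traj <- traj
  }
  rows <- lapply(counts, function(nc) {
    cfg <- config
    cfg$n_cells <- nc
    res <- run_transformation(cfg, verbose = verbose)
    areas <- vapply(res$repeats,
                    function(x) if (identical(x$status, "ok"))
                      x$field_area else NA_real_, numeric(1))
    pk <- vapply(res$repeats,
                 function(x) if (identical(x$status, "ok"))
                   x$peak_rate else NA_real_, numeric(1))
    data.frame(n_cells = nc,
               proportion_viable = res$proportion_viable,
               peak_rate = mean(pk, na.rm = TRUE),
               field_area = mean(areas, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' ERI census over an experiment
#'
#' Pools classified ERIs over viable repeats and reports count and
#' percentage per class, with the across-repeat SEM of the per-repeat
#' percentages.
#'
#' @param result an `experiment_result`.
#' @return data frame with `class`, `n`, `percent`, `sem`.
#' @export
eri_census <- function(result) {
  tb <- result$pass_table
  if (is.null(tb) || nrow(tb) == 0) {
    warning("no classified ERIs")
    return(data.frame(class = character(0), n = integer(0),
                      percent = numeric(0), sem = numeric(0)))
  }
  classes <- c("L", "S", "R")
  n_per <- vapply(classes, function(cl) sum(tb$class == cl), numeric(1))
  pct <- 100 * n_per / nrow(tb)
  per_rep <- split(tb$class, tb$repeat_id)
  rep_pct <- vapply(classes, function(cl) {
    p <- vapply(per_rep, function(v) 100 * mean(v == cl), numeric(1))
    if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else NA_real_
  }, numeric(1))
  data.frame(class = classes, n = as.integer(n_per), percent = pct,
             sem = rep_pct, row.names = NULL)
}

#' Per-class precession slope summary
#'
#' Mean and across-pass SEM of the circular-linear slope per ERI class.
#'
#' @param result an `experiment_result`.
#' @return data frame with `class`, `n`, `mean_rho`, `sem`.
#' @export
precession_stats <- function(result) {
  tb <- result$pass_table
  if (is.null(tb) || nrow(tb) == 0)
    return(data.frame(class = character(0), n = integer(0),
                      mean_rho = numeric(0), sem = numeric(0)))
  classes <- intersect(c("L", "S", "R"), unique(tb$class))
  rows <- lapply(classes, function(cl) {
    rho <- tb$rho[tb$class == cl]
    data.frame(class = cl, n = length(rho), mean_rho = mean(rho),
               sem = if (length(rho) > 1)
                 stats::sd(rho) / sqrt(length(rho)) else NA_real_)
  })
  do.call(rbind, rows)
}
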