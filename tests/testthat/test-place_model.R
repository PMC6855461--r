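test_that("morphology discretization honors geometry and placement rules", {
  cell <- build_cell()
  expect_equal(cell$n_comp, 155)
  expect_gte(max(cell$path_um), 400)
  expect_true(all(cell$gbar_uS >= 0))

  # 2-compartment cell: the distal site maps to the single cable compartment
  c2 <- build_cell(n_comp = 2, cable_l = 600)
  st <- structure(list(times = 0.1, cell_id = NA, x = NULL, y = NULL),
                  class = "spike_train")
  syn <- attach_synapses(c2, list(st), "single")
  expect_equal(syn$comp, 2)

  expect_error(build_cell(cable_l = 300), "configuration error")

  # synapse placement: single mode converges on one compartment near
  # 315.95 um; distributed mode stays within 300-400 um and is seeded
  cell31 <- scaled_cell()
  trains <- replicate(50, st, simplify = FALSE)
  s1 <- attach_synapses(cell31, trains, "single")
  expect_equal(length(unique(s1$comp)), 1)
  expect_lt(abs(s1$path_um[1] - 315.95), 600 / 30)
  sd1 <- attach_synapses(cell31, trains, "distributed", seed = 5)
  expect_true(all(sd1$path_um >= 300 & sd1$path_um <= 400))
  sd2 <- attach_synapses(cell31, trains, "distributed", seed = 5)
  expect_identical(sd1$comp, sd2$comp)
})

test_that("the EPSG kernel has the stated amplitude, decay, and integral", {
  expect_equal(epsg(0), 200)
  expect_equal(epsg(0.030), 200 / exp(1))
  # integral of w exp(-t / tau) is w tau = 200 pS * 0.030 s = 6 pS s
  tt <- seq(0, 1, by = 1e-5)
  expect_equal(sum(epsg(tt)) * 1e-5, 6, tolerance = 1e-3)
  expect_error(epsg(-1), "t_since_spike")
})

test_that("the quiescent cell rests stably and theta drive imposes a 10-Hz rhythm", {
  cell <- scaled_cell()
  d0 <- theta_drive(g_inh_amp = 0, i_step = 0, noise_sd = 0)
  tr <- simulate_place_cell(cell, NULL, d0, duration = 3, dt_neuro = 1e-4)
  expect_length(tr$spikes, 0)
  late <- tr$v_m[tr$t > 2]
  expect_lt(diff(range(late)), 2)

  # theta conductance alone: dominant subthreshold spectral peak at 10 Hz
  # (depolarized operating point so the oscillation has driving force)
  d1 <- theta_drive(g_inh_amp = 5e-3, i_step = 0.3, noise_sd = 0)
  tr1 <- simulate_place_cell(cell, NULL, d1, duration = 4, dt_neuro = 1e-4)
  v <- tr1$v_m[tr1$t > 1]
  sp <- Mod(fft(v - mean(v)))[2:80]
  freqs <- (1:79) / 3
  expect_equal(freqs[which.max(sp)], 10, tolerance = 0.4)

  # theta reference peaks are exactly periodic at 1/f
  pk <- theta_peak_times(theta_drive(f = 10), 5)
  expect_equal(unique(round(diff(pk), 12)), 0.1)
})

test_that("a distal EPSP attenuates toward the soma and sums sublinearly", {
  # thin-cable cell so the distal synapse is electrotonically remote
  cell <- build_cell(n_comp = 31, cable_d = 2)
  comp <- which.min(abs(cell$path_um - 315.95))
  st1 <- structure(list(times = 0.5, cell_id = NA, x = NULL, y = NULL),
                   class = "spike_train")
  d <- theta_drive(g_inh_amp = 0, i_step = 0, noise_sd = 0)
  syn <- attach_synapses(cell, list(st1), "single", w = 200)
  tr <- simulate_place_cell(cell, syn, d, duration = 1, dt_neuro = 1e-4,
                            record_comp = comp)
  rest_s <- tail(tr$v_m[tr$t > 0.45 & tr$t < 0.5], 1)
  rest_d <- tail(tr$v_comp[tr$t > 0.45 & tr$t < 0.5], 1)
  peak_soma <- max(tr$v_m[tr$t >= 0.5]) - rest_s
  peak_dend <- max(tr$v_comp[tr$t >= 0.5]) - rest_d
  expect_gt(peak_dend, peak_soma)
  expect_gt(peak_soma, 0)

  # two synchronous spikes produce at most twice the single-spike EPSP
  st2 <- structure(list(times = c(0.5, 0.5), cell_id = NA, x = NULL, y = NULL),
                   class = "spike_train")
  syn2 <- attach_synapses(cell, list(st2), "single", w = 200)
  tr2 <- simulate_place_cell(cell, syn2, d, duration = 1, dt_neuro = 1e-4)
  peak2 <- max(tr2$v_m[tr2$t >= 0.5]) - rest_s
  expect_lte(peak2, 2 * peak_soma + 1e-6)
})

test_that("gating variables stay in [0, 1] through a strongly driven run", {
  cell <- scaled_cell()
  set.seed(1)
  n <- 20000
  i_soma <- 1.5 + rnorm(n, sd = 0.5)
  res <- gridplace:::hh_simulate_cpp(cell$cap_nF, cell$g_ax_uS, cell$gbar_uS,
                                     cell$erev, 0.1, n, integer(0), integer(0),
                                     0, 30, 0, 10, 0.02, -70, i_soma,
                                     10L, -1L, -68, record_gates = TRUE)
  expect_gt(length(res$spikes), 0)
  g <- res$gates_final
  expect_true(all(unlist(g) >= 0 & unlist(g) <= 1))
})

test_that("halving the production integration step changes the spike count by at most one", {
  cell <- scaled_cell()
  st <- structure(list(times = seq(0.5, 2.5, by = 0.1), cell_id = NA,
                       x = NULL, y = NULL), class = "spike_train")
  syn <- attach_synapses(cell, list(st), "single", w = 5e4)
  d <- theta_drive(g_inh_amp = 0.005, i_step = 0.4, noise_sd = 0)
  n1 <- length(simulate_place_cell(cell, syn, d, 3, dt_neuro = 2.5e-5)$spikes)
  n2 <- length(simulate_place_cell(cell, syn, d, 3, dt_neuro = 1.25e-5)$spikes)
  expect_lte(abs(n1 - n2), 1)
})

test_that("step-current calibration attains the minimum-rate target monotonically", {
  cell <- scaled_cell()
  drive <- theta_drive()
  i25 <- calibrate_step_current(cell, drive, target_rate = 2.5, duration = 8,
                                dt_neuro = 1e-4, seed = 2)
  d <- drive; d$i_step <- i25
  tr <- simulate_place_cell(cell, NULL, d, duration = 10, dt_neuro = 1e-4,
                            seed = 2)
  expect_gte(length(tr$spikes) / 10, 2.2)

  # a larger target requires a larger amplitude
  i50 <- calibrate_step_current(cell, drive, target_rate = 5, duration = 8,
                                dt_neuro = 1e-4, seed = 2)
  expect_gt(i50, i25)

  # target 0 accepted at amplitude 0 for a quiescent cell
  d0 <- theta_drive(g_inh_amp = 0, noise_sd = 0)
  expect_equal(calibrate_step_current(cell, d0, target_rate = 0, duration = 2,
                                      dt_neuro = 1e-4), 0)
})
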