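test_that("pass extraction finds single traversals through a field", {
  # field: circular region of diameter ~20 cm at the arena center
  n <- 34; bin <- 0.03
  xs <- (seq_len(n) - 0.5) * bin
  mask <- sqrt(outer((xs - 0.5)^2, (xs - 0.5)^2, "+")) <= 0.10
  field <- list(bins = which(mask, arr.ind = TRUE))

  # straight crossing at 0.2 m/s: one pass of ~1 s and ~20+ cm path
  tt <- seq(0, 5, by = 0.02)
  tr <- make_traj(tt, 0.2 * tt, rep(0.5, length(tt)))
  p1 <- extract_passes(tr, field, bin)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$t_exit - p1[[1]]$t_entry, 1.2, tolerance = 0.4)
  expect_equal(max(p1[[1]]$path_cm), 24, tolerance = 8)

  # a trajectory that never enters the field yields no passes
  tr_out <- make_traj(tt, 0.2 * tt, rep(0.1, length(tt)))
  expect_length(extract_passes(tr_out, field, bin), 0)

  # two separated crossings yield two passes
  tt2 <- seq(0, 10, by = 0.02)
  x2 <- c(0.2 * tt2[tt2 <= 5], 2 - 0.2 * tt2[tt2 > 5])
  tr2 <- make_traj(tt2, pmin(pmax(x2, 0), 1), rep(0.5, length(tt2)))
  expect_length(extract_passes(tr2, field, bin), 2)

  # in-field meanders longer than the traversal bound are excluded
  tr3 <- make_traj(tt2, 0.5 + 0.03 * sin(tt2), 0.5 + 0.03 * cos(tt2))
  expect_length(extract_passes(tr3, field, bin, max_duration = 5), 0)
})

test_that("ERI extraction despikes while preserving the underlying ramp", {
  tt <- seq(0, 2, by = 1e-3)
  ramp <- -65 + 8 * tt / 2
  pass <- list(t_entry = 0.2, t_exit = 1.8, t = seq(0.2, 1.8, by = 0.02),
               x = seq(0, 0.32, length.out = 81), y = rep(0.5, 81),
               path_cm = seq(0, 32, length.out = 81), spike_times = numeric(0))

  # subthreshold-only trace: output equals the input restricted to the pass
  tr_sub <- make_trace(tt, ramp)
  seg <- extract_eri(tr_sub, pass, cap_mV = 0)
  expect_equal(range(seg$t), c(0.2, 1.8), tolerance = 1e-6)
  expect_equal(seg$v, ramp[tt >= 0.2 & tt <= 1.8], tolerance = 0.2)

  # spikes riding on the ramp: capped and filtered to within 1 mV
  v_sp <- ramp
  for (t0 in seq(0.4, 1.6, by = 0.1)) {
    idx <- which(abs(tt - t0) < 2e-3)
    v_sp[idx] <- 30
  }
  seg2 <- extract_eri(make_trace(tt, v_sp), pass)
  expect_lte(max(seg2$v), -50)
  in_sub <- seg2$v[seg2$t > 0.3 & seg2$t < 1.5]
  truth <- ramp[tt >= 0.3 & tt <= 1.5][seq_along(in_sub)]
  expect_lt(max(abs(in_sub - truth)), 1)

  expect_error(extract_eri(make_trace(tt, ramp),
                           modifyList(pass, list(t_exit = 5))), "data error")
})

test_that("ERI classification follows the R_peak cutoffs and is affine-invariant", {
  tt <- seq(0, 2, by = 0.01)
  peaked <- function(pos) {
    v <- -65 + 10 * exp(-(tt - pos * 2)^2 / (2 * 0.35^2))
    list(t = tt, v = v, baseline = -65)
  }
  # the three printed exemplar positions map to R, S, L
  cR <- classify_eri(peaked(0.75))
  cS <- classify_eri(peaked(0.43))
  cL <- classify_eri(peaked(0.30))
  expect_equal(cR$class, "R")
  expect_equal(cS$class, "S")
  expect_equal(cL$class, "L")
  expect_equal(cR$r_peak, 0.75, tolerance = 0.06)
  expect_equal(cS$r_peak, 0.43, tolerance = 0.06)
  expect_equal(cL$r_peak, 0.30, tolerance = 0.06)

  # the classification rule partitions [0, 1] with a closed middle interval
  cls_of <- function(rp) if (rp < 0.35) "L" else if (rp > 0.65) "R" else "S"
  expect_equal(cls_of(0.35), "S")
  expect_equal(cls_of(0.65), "S")
  expect_setequal(unique(vapply(seq(0, 1, by = 0.05), cls_of, character(1))),
                  c("L", "S", "R"))

  # affine rescaling of the voltage axis does not change the class
  seg <- peaked(0.72)
  seg_aff <- list(t = tt, v = 3 * seg$v + 40, baseline = min(3 * seg$v + 40))
  expect_equal(classify_eri(seg)$class, classify_eri(seg_aff)$class)
  expect_equal(classify_eri(seg)$r_peak, classify_eri(seg_aff)$r_peak,
               tolerance = 1e-6)

  # segments that are too short are flagged unclassifiable
  expect_true(is.na(classify_eri(list(t = tt[1:5], v = seg$v[1:5]))$r_peak))
})

test_that("spike phases interpolate linearly between theta peaks", {
  pk <- theta_peak_times(theta_drive(f = 10), 2)   # 0.025, 0.125, ...
  # a spike exactly at a peak has phase 0
  expect_equal(spike_phase(pk[3], pk)$phase, 0)
  # midpoint between peaks: 180 degrees
  expect_equal(spike_phase(mean(pk[2:3]), pk)$phase, 180)
  # 25 ms after a peak at 10 Hz: 90 degrees
  expect_equal(spike_phase(pk[2] + 0.025, pk)$phase, 90)
  # spikes outside coverage are dropped with a message
  expect_message(ph <- spike_phase(c(0.01, pk[2] + 0.025), pk), "dropped")
  expect_equal(nrow(ph), 1)
  expect_true(all(ph$phase >= 0 & ph$phase < 360))
})

test_that("circular-linear regression recovers known slopes", {
  x <- seq(0, 30, length.out = 40)
  # exact linear phase advance of -10 deg/cm
  ph <- (360 - 10 * x) %% 360
  fit <- circular_linear_fit(ph, x)
  expect_equal(fit$rho, -10, tolerance = 0.05)

  # constant phase: tie broken toward zero slope
  fit0 <- circular_linear_fit(rep(120, 20), seq_len(20))
  expect_equal(fit0$rho, 0, tolerance = 1e-6)

  expect_error(circular_linear_fit(c(10, 20), c(1, 2)), "fit undefined")

  # wrapped von Mises noise (kappa = 4): recovery within 1.5 deg/cm on
  # average, and the negative sign recovered almost always at kappa >= 2
  set.seed(99)
  errs <- numeric(60)
  signs <- logical(60)
  for (i in 1:60) {
    kappa <- if (i <= 30) 4 else 2
    xi <- runif(30, 0, 25)
    noise <- suppressWarnings(
      atan2(sin(rnorm(30, 0, 1 / sqrt(kappa))),
            cos(rnorm(30, 0, 1 / sqrt(kappa))))) * 180 / pi
    phi <- (300 - 8 * xi + noise) %% 360
    f <- circular_linear_fit(phi, xi, slope_bounds = c(-20, 20))
    errs[i] <- f$rho + 8
    signs[i] <- f$rho < 0
  }
  expect_lt(mean(abs(errs[1:30])), 1.5)
  expect_gte(mean(signs), 0.95)
})

test_that("replaying a ramp under theta inhibition produces phase precession", {
  cell <- scaled_cell()
  tt <- seq(0, 2.5, by = 1e-3)
  seg_up <- list(t = tt, v = -62 + 7 * tt / 2.5, baseline = -62)
  drive <- theta_drive(i_step = 0.42, g_inh_amp = 0.02, noise_sd = 0.05)
  rep_up <- eri_replay(cell, seg_up, drive, seed = 5)
  sp <- rep_up$spikes[rep_up$spikes >= 0.1]
  expect_gt(length(sp), 4)
  ph <- spike_phase(sp, rep_up$theta_peaks)
  fit <- circular_linear_fit(ph$phase, ph$t * 20, slope_bounds = c(-10, 10))
  expect_lt(fit$rho, 0)

  # the mirrored (decaying) ramp moves phases the opposite way
  seg_dn <- list(t = tt, v = rev(seg_up$v), baseline = -62)
  rep_dn <- eri_replay(cell, seg_dn, drive, seed = 5)
  sp2 <- rep_dn$spikes[rep_dn$spikes >= 0.1]
  ph2 <- spike_phase(sp2, rep_dn$theta_peaks)
  fit2 <- circular_linear_fit(ph2$phase, ph2$t * 20, slope_bounds = c(-10, 10))
  expect_gt(fit2$rho, fit$rho)
})
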