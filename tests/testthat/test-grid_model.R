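test_that("VCO frequency follows the speed-gain cosine rule", {
  expect_equal(vco_frequency(0, 1.2, 0.4, beta = 2), 10)
  expect_equal(vco_frequency(0.25, 0, 0, beta = 2), 10.5)
  expect_equal(vco_frequency(0.25, pi / 2, 0, beta = 2), 10, tolerance = 1e-12)
  expect_equal(vco_frequency(0.3, 0, pi, beta = 3), 10 - 0.9)
})

test_that("interference threshold rule emits spikes as the brute-force signal predicts", {
  # all oscillator phases zero at t = 0: g(0) = 2 * n_vco >= 6 -> spike at 0
  tr <- straight_traj(2)
  kin <- make_kin(tr, 0.25, 0)
  st <- oi_spikes(tr, kin, grid_cell_params())
  expect_equal(st$times[1], 0)

  # unreachable threshold (|g| <= 12) gives an empty train
  p13 <- grid_cell_params()
  p13$g_thres <- 13
  expect_length(oi_spikes(tr, kin, p13)$times, 0)

  # stationary rat: spike count equals supra-threshold samples thinned by
  # the refractory period, per an independent R phase-accumulation oracle
  trs <- make_traj(seq(0, 1, by = 0.02), rep(0.4, 51), rep(0.6, 51))
  kins <- make_kin(trs, 0, 0)
  prm <- grid_cell_params(refractory = 0.003)
  st2 <- oi_spikes(trs, kins, prm)
  tt <- seq(0, 1, by = 0.001)
  g <- oi_g_oracle(rep(0, length(tt)), rep(0, length(tt)), 0.001, 2,
                   (30 + seq(0, 300, by = 60)) * pi / 180)
  expected <- 0
  last <- -Inf
  for (k in seq_along(tt)) {
    if (g[k] >= 6 && tt[k] - last >= 0.003) {
      expected <- expected + 1
      last <- tt[k]
    }
  }
  expect_equal(length(st2$times), expected)

  # |g| is bounded by 2 * n_vco everywhere (sum of 12 unit cosines)
  traj <- generate_trajectory(20, seed = 3)
  kin2 <- kinematics(traj)
  ttg <- seq(0, max(traj$t), by = 0.001)
  gg <- gridplace:::oi_g_cpp(approx(kin2$t, kin2$s, ttg, rule = 2)$y,
                 approx(kin2$t, kin2$phi, ttg, rule = 2)$y,
                 0.001, 2.5, (10 + seq(0, 300, by = 60)) * pi / 180, 10,
                 numeric(6))
  expect_true(all(abs(gg) <= 12 + 1e-9))

  # determinism
  expect_identical(oi_spikes(tr, kin, grid_cell_params())$times,
                   oi_spikes(tr, kin, grid_cell_params())$times)
})

test_that("field centers are the local maxima of the smoothed map", {
  # one Gaussian bump: a single center within one bin of the truth
  m1 <- bump_map(matrix(c(0.5, 0.5), 1))
  c1 <- field_centers(m1)
  expect_equal(nrow(c1), 1)
  expect_lt(max(abs(c1[1, ] - 0.5)), 0.03 + 1e-9)

  # hexagonal lattice of 7 bumps: 7 centers matching the construction
  ctr <- hex_centers(0.3)
  c7 <- field_centers(bump_map(ctr))
  expect_equal(nrow(c7), 7)
  d <- vapply(seq_len(7), function(k)
    min(sqrt((c7[, 1] - ctr[k, 1])^2 + (c7[, 2] - ctr[k, 2])^2)), numeric(1))
  expect_true(all(d < 0.045))

  # all-zero map: no centers
  expect_equal(nrow(field_centers(make_map(matrix(0, 10, 10)))), 0)
})

test_that("Gaussian thinning retains spikes with the closed-form acceptance profile", {
  # spikes pinned at controlled distances from a single center
  n <- 40000
  st <- structure(list(times = seq_len(n) * 1e-3, cell_id = NA,
                       x = rep(c(0.5, 0.5 + 0.05, 0.5 + 0.15), length.out = n),
                       y = rep(0.5, n)), class = "spike_train")
  centers <- matrix(c(0.5, 0.5), 1)
  sigma <- 0.05
  thin <- gaussian_thinning(st, centers, sigma, accept_peak = 1, seed = 42)
  keep_d <- function(d) {
    sel <- abs(st$x - 0.5 - d) < 1e-12
    kept <- sum(abs(thin$x - 0.5 - d) < 1e-12)
    kept / sum(sel)
  }
  # p(0) = accept_peak; p(sigma)/p(0) = exp(-1/2); p(3 sigma)/p(0) = exp(-4.5)
  expect_equal(keep_d(0), 1)
  expect_equal(keep_d(0.05), exp(-0.5), tolerance = 0.03)
  expect_equal(keep_d(0.15), exp(-4.5), tolerance = 0.35)

  # thinning returns a subset and is monotone in accept_peak at fixed seed
  t_lo <- gaussian_thinning(st, centers, sigma, accept_peak = 0.3, seed = 7)
  t_hi <- gaussian_thinning(st, centers, sigma, accept_peak = 0.6, seed = 7)
  expect_true(all(t_lo$times %in% st$times))
  expect_true(all(t_lo$times %in% t_hi$times))

  expect_error(gaussian_thinning(st, matrix(numeric(0), ncol = 2), sigma),
               "empty")
})

test_that("in vivo-like simulation thins the conventional train into grid fields", {
  traj <- generate_trajectory(120, seed = 5)
  kin <- kinematics(traj)
  prm <- grid_cell_params(beta = 2, phi_pref = 30)
  conv <- simulate_grid_cell(traj, prm, mode = "conventional", kin = kin)
  thin <- simulate_grid_cell(traj, prm, mode = "invivo_like", seed = 8, kin = kin)
  expect_lt(length(thin$times), length(conv$times))
  expect_true(all(thin$times %in% conv$times))
  # same inputs and seed reproduce the identical train
  thin2 <- simulate_grid_cell(traj, prm, mode = "invivo_like", seed = 8, kin = kin)
  expect_identical(thin$times, thin2$times)
})

test_that("the parameter pool covers the stated ranges on a uniform lattice", {
  pool <- build_pool()
  expect_equal(nrow(pool), 10000)
  expect_equal(range(pool$beta), c(1, 3.5))
  expect_true(all(pool$phi_pref >= 0 & pool$phi_pref < 60))

  p1 <- build_pool(1, 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$beta, 1)
  expect_equal(p1$phi_pref, 0)

  p6 <- build_pool(2, 3)
  expect_equal(nrow(p6), 6)
  expect_setequal(unique(p6$beta), c(1, 3.5))

  expect_error(build_pool(0, 5), "parameter error")
  expect_error(build_pool(2, 2, beta_range = c(3, 1)), "parameter error")
})

test_that("selection randomness is the relative entropy of the sampled pairs", {
  pool <- build_pool()
  sel <- sample_cells(pool, 250, seed = 3)
  expect_equal(sel$randomness, 100)
  expect_length(sel$selection, 250)
  expect_false(anyDuplicated(sel$selection) > 0)

  # with replacement, any duplicate lowers the entropy below maximal
  reps <- vapply(1:20, function(sd) {
    s <- sample_cells(pool, 250, seed = sd, replace = TRUE)
    c(dup = anyDuplicated(s$selection) > 0, rand = s$randomness)
  }, numeric(2))
  has_dup <- reps[1, ] > 0
  expect_true(any(has_dup))
  expect_true(all(reps[2, has_dup] < 100))
  expect_true(all(reps[2, !has_dup] == 100))

  # a forced single-cell multiset has zero entropy
  one <- table(rep(1L, 50))
  p <- as.numeric(one) / 50
  expect_equal(-sum(p * log2(p)), 0)

  expect_error(sample_cells(pool, 10001), "parameter error")
})

test_that("grid spacing shrinks as beta rises and rotates with phi_vco", {
  traj <- generate_trajectory(300, seed = 6)
  kin <- kinematics(traj)
  spacing_of <- function(beta, phi) {
    st <- simulate_grid_cell(traj, grid_cell_params(beta = beta, phi_pref = phi),
                             seed = 11, kin = kin)
    rm <- rate_map(st, traj)
    grid_spacing_and_area(autocorrelogram(rm), rm)$spacing_cm
  }
  s_low <- spacing_of(1.2, 30)
  s_high <- spacing_of(3.2, 30)
  expect_gt(s_low, s_high)
  # beta = 1.2 -> 2/(sqrt(3) beta) = 96 cm; beta = 3.2 -> 36 cm
  expect_equal(s_low, 200 / (sqrt(3) * 1.2), tolerance = 0.25)
  expect_equal(s_high, 200 / (sqrt(3) * 3.2), tolerance = 0.25)
})
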