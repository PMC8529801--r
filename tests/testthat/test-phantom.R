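test_that("phantom_config enforces its invariants", {
  expect_error(phantom_config(c(8, 8, 8), voxel_size = 0), "voxel_size")
  expect_error(phantom_config(c(8, 8, 8), n_phases = 1), "n_phases")
  expect_error(phantom_config(c(8, 8, 8), rr_ms = -1), "rr_ms")
  expect_error(phantom_config(c(8, 8, 8), noise_sd = -0.1), "noise_sd")
})

test_that("tube phantom carries the closed-form flow for both profiles", {
  cfg <- phantom_config(c(24, 24, 8), rr_ms = 1000, n_phases = 2)
  # plug: Q = v * pi R^2 (mL/s with v in m/s, R in mm)
  tb <- make_tube_phantom(cfg, 6, "plug", rep(1, 2), 0.5)
  expect_equal(tb$truth$true_flow_curve, rep(0.5 * pi * 36, 2))
  # discrete axial-velocity integral matches the analytic flow closely
  q_vox <- sum(tb$field$vz[, , 1, 1]) * cfg$voxel_size^2
  expect_lt(abs(q_vox / (0.5 * pi * 36) - 1), 0.005)
  # parabolic: Q = v_max * pi R^2 / 2
  tb2 <- make_tube_phantom(cfg, 6, "parabolic", rep(1, 2), 1)
  expect_equal(tb2$truth$true_flow_curve, rep(pi * 36 / 2, 2))
  # centerline voxel holds the partial-volume average of the profile,
  # slightly below the analytic peak
  expect_gt(max(tb2$field$vz), 0.95)
  expect_lte(max(tb2$field$vz), 1)
  # zero velocity well outside the lumen
  expect_equal(max(abs(tb2$field$vz[1, 1, , ])), 0)
})

test_that("pulsatile tube SV equals the quadrature of the analytic flow", {
  cfg <- phantom_config(c(24, 24, 8), rr_ms = 1000, n_phases = 15)
  phi <- (0:14) / 15
  wave <- 1 + sin(2 * pi * phi)
  tb <- make_tube_phantom(cfg, 10, "plug", wave, 0.5)
  # symbolic integral: Q0 * RR since sin integrates to 0 over a period,
  # and the uniform-phase periodic trapezoid is exact for this waveform
  q0 <- 0.5 * pi * 100
  expect_equal(tb$truth$true_sv, q0 * 1000 / 1000, tolerance = 1e-10)
  # invariant: true_sv equals the periodic trapezoid of the curve
  tt <- tb$field$phase_times
  trap <- mean(tb$truth$true_flow_curve) * 1000 / 1000
  expect_equal(tb$truth$true_sv, trap)
})

test_that("vortex ground truth matches brute-force voxel quadrature", {
  cfg <- phantom_config(c(20, 20, 12), rr_ms = 900, n_phases = 2)
  for (omega in c(1, 5)) {
    vx <- make_vortex_phantom(cfg, "solid_body", omega, core_radius = 7)
    expect_equal(vx$truth$true_mean_vorticity, rep(2 * omega, 2))
    ke_oracle <- oracle_solid_body_ke(cfg$grid_shape, cfg$voxel_size,
                                      omega, 7)
    expect_rel_equal(vx$truth$true_ke_curve[1], ke_oracle, 1e-9)
  }
  # Lamb-Oseen mean vorticity vs independent quadrature
  lo <- make_vortex_phantom(cfg, "lamb_oseen", 0.02, core_radius = 4,
                            mask_radius = 8)
  mv <- oracle_lamb_oseen_mean_vort(cfg$grid_shape, cfg$voxel_size,
                                    0.02, 4, 8)
  expect_rel_equal(lo$truth$true_mean_vorticity[1], mv, 1e-9)
})

test_that("vortex waveform scales KE quadratically and vorticity linearly", {
  cfg <- phantom_config(c(16, 16, 10), rr_ms = 800, n_phases = 4)
  w <- c(1, 0.5, 2, 0.25)
  vx <- make_vortex_phantom(cfg, "solid_body", 3, 6, waveform = w)
  expect_equal(vx$truth$true_ke_curve, vx$truth$true_ke_curve[1] * w^2)
  expect_equal(vx$truth$true_mean_vorticity, rep(6, 4) * w)
})

test_that("uniform translation has zero curl everywhere", {
  cfg <- phantom_config(c(12, 12, 12), rr_ms = 1000, n_phases = 2)
  d <- cfg$grid_shape
  u <- array(0.3, dim = c(d, 2))
  f <- velocity_field(u, u * 0.5, u * -1, array(1, dim = c(d, 2)),
                      cfg$voxel_size, cfg$rr_ms)
  w <- vorticity_field(f, 1)
  expect_equal(max(abs(w)), 0)
})

test_that("background offset injection is exact and reversible", {
  cfg <- phantom_config(c(12, 14, 10), rr_ms = 700, n_phases = 3)
  tb <- make_tube_phantom(cfg, 4, "plug", rep(1, 3), 0.4)
  f0 <- tb$field
  # all-zero coefficients: identity
  f_id <- add_background_offset(f0, matrix(0, 20, 3))
  expect_identical(f_id$vx, f0$vx)
  # constant-only offset on one component
  cf <- matrix(0, 20, 3); cf[1, 2] <- 0.123
  f_c <- add_background_offset(f0, cf)
  expect_equal(f_c$vy, f0$vy + 0.123)
  expect_identical(f_c$vx, f0$vx)
  # random cubic: mean offset over a region equals the polynomial mean
  # evaluated directly (direct evaluation oracle), and add-then-
  # subtract restores the field to float accuracy
  set.seed(31)
  cf2 <- matrix(rnorm(60, sd = 0.05), 20, 3)
  f_r <- add_background_offset(f0, cf2)
  region <- tb$truth$static_mask
  # direct oracle: evaluate monomials at normalized coords by hand
  nx <- dim(f0$vx)[1]; ny <- dim(f0$vx)[2]; nz <- dim(f0$vx)[3]
  norm1 <- function(i, n) 2 * (i - 1) / (n - 1) - 1
  ex <- expand.grid(c = 0:3, b = 0:3, a = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3, c("a", "b", "c")]
  ex <- ex[order(ex$a + ex$b + ex$c, ex$a, ex$b, ex$c), ]
  vals <- 0
  idx <- which(region, arr.ind = TRUE)
  for (m in seq_len(20)) {
    vals <- vals + cf2[m, 1] * norm1(idx[, 1], nx)^ex$a[m] *
      norm1(idx[, 2], ny)^ex$b[m] * norm1(idx[, 3], nz)^ex$c[m]
  }
  got <- mean(f_r$vx[, , , 1][region] - f0$vx[, , , 1][region])
  expect_equal(got, mean(vals), tolerance = 1e-12)
  f_b <- add_background_offset(f_r, -cf2)
  expect_lt(max(abs(f_b$vx - f0$vx)), 1e-12)
  # degree > 3 rejected
  expect_error(add_background_offset(f0, matrix(0, 35, 3)), "degree")
})

test_that("trigger simulation is reproducible and respects drop_prob", {
  a <- simulate_triggers(60, 100, drop_prob = 0.1, seed = 5)
  b <- simulate_triggers(60, 100, drop_prob = 0.1, seed = 5)
  expect_identical(a$log$trigger_times, b$log$trigger_times)
  # drop_prob = 0, jitter = 0: recorded == true beats; all cardiac
  # times below RR
  c0 <- simulate_triggers(75, 30, drop_prob = 0, seed = 1)
  expect_equal(c0$log$trigger_times, c0$true_beat_times)
  expect_equal(c0$true_rr_ms, 800)
  # RNG replay oracle: replay the same uniform stream by hand
  set.seed(9)
  n_beats <- length(seq(0, 100 * 1000, by = 1000))
  keep <- runif(n_beats) >= 0.1
  d <- simulate_triggers(60, 100, drop_prob = 0.1, seed = 9)
  expect_equal(length(d$log$trigger_times), sum(keep))
  # a single dropped beat leaves one double-length RR
  log1 <- trigger_log(c(0, 1000, 3000, 4000), seq(0, 4000, by = 6.2))
  expect_equal(sum(abs(diff(log1$trigger_times) - 2000) < 1), 1)
  expect_error(simulate_triggers(60, 0.5), "duration")
})

test_that("respiration waveform has the documented plateau and symmetry", {
  r <- simulate_respiration(4, 60, sample_ms = 10, plateau_frac = 0.3)
  expect_equal(max(r$values), 1)
  # plateau occupies ~30% of the cycle at the maximum
  expect_equal(mean(r$values > 1 - 1e-9), 0.3, tolerance = 0.02)
  # constant convention
  rc <- simulate_respiration(Inf, 10)
  expect_true(all(rc$values == 1))
  # sinusoid thresholded at its median accepts half the samples
  t <- seq(0, 9999)
  v <- sin(2 * pi * t / 500)
  expect_equal(mean(v <= median(v)), 0.5, tolerance = 1e-3)
})
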