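test_that("kinetic energy reproduces direct arithmetic and phantom truth", {
  # 1000-voxel mask at uniform speed 0.1 m/s with V = 1.95 mm^3
  dims <- c(10, 10, 10)
  v <- array(0.1 / sqrt(3), dim = c(dims, 2))
  f <- velocity_field(v, v, v, array(1, dim = c(dims, 2)), 1.25, 1000)
  m <- chamber_mask(array(TRUE, dims))
  ke <- kinetic_energy(f, m, rho = 1060, voxel_volume_mm3 = 1.95)
  expect_equal(ke$ke_j, rep(0.5 * 1060 * 1.95e-9 * 1000 * 0.01, 2),
               tolerance = 1e-12)
  # zero velocity: zero KE in every phase
  z <- velocity_field(v * 0, v * 0, v * 0, array(1, dim = c(dims, 2)),
                      1.25, 1000)
  expect_equal(kinetic_energy(z, m)$ke_j, c(0, 0))
  # vortex phantom: matches the closed-form ground truth
  cfg <- phantom_config(c(20, 20, 12), rr_ms = 900, n_phases = 3)
  vx <- make_vortex_phantom(cfg, "solid_body", 5, 7, waveform = c(1, 2, 0.5))
  ke2 <- kinetic_energy(vx$field, vx$mask)
  expect_rel_equal(ke2$ke_j, vx$truth$true_ke_curve, 1e-9)
  # quadratic scaling under velocity scaling
  f3 <- vx$field
  f3$vx <- 3 * f3$vx; f3$vy <- 3 * f3$vy; f3$vz <- 3 * f3$vz
  expect_equal(kinetic_energy(f3, vx$mask)$ke_j, 9 * ke2$ke_j)
  expect_error(kinetic_energy(f, chamber_mask(array(FALSE, dims))), "empty")
})

test_that("energy efficiency is SV/KE in mL/mJ", {
  expect_equal(energy_efficiency(54, 5.4e-3), 54 / 5.4)
  expect_equal(energy_efficiency(108, 5.4e-3), 2 * energy_efficiency(54, 5.4e-3))
  expect_error(energy_efficiency(54, 0), "undefined-efficiency")
  # phantom-derived ratio to machine accuracy
  cfg <- phantom_config(c(16, 16, 10), rr_ms = 800, n_phases = 2)
  vx <- make_vortex_phantom(cfg, "solid_body", 4, 6)
  ke <- kinetic_energy(vx$field, vx$mask)$ke_j[1]
  expect_equal(energy_efficiency(63, ke), 63 / (ke * 1000), tolerance = 1e-12)
})

test_that("discrete curl is exact on linear fields and matches brute force", {
  set.seed(44)
  for (rep in 1:5) {
    A <- matrix(runif(9, -50, 50), 3, 3)
    b <- runif(3, -0.2, 0.2)
    f <- linear_velocity_field(c(9, 8, 7), 1.25, A, b)
    w <- vorticity_field(f, 1)
    truth <- c(A[3, 2] - A[2, 3], A[1, 3] - A[3, 1], A[2, 1] - A[1, 2])
    for (c3 in 1:3)
      expect_lt(max(abs(w[, , , c3] - truth[c3])), 1e-10)
    # brute-force central differences agree in the interior
    oc <- oracle_interior_curl(f$vx[, , , 1], f$vy[, , , 1], f$vz[, , , 1],
                               1.25)
    expect_equal(w[2:8, 2:7, 2:6, ], oc[2:8, 2:7, 2:6, ], tolerance = 1e-10)
  }
})

test_that("curl components permute when the rotation axis moves", {
  # rigid rotation about each axis in turn; curl = (0,0,2w) permuted
  dims <- c(10, 10, 10); vox <- 1.25
  ax <- (seq_len(10) - 1) * vox / 1000
  ctr <- mean(ax)
  X <- array(rep(ax - ctr, 100), dim = dims)
  Y <- array(rep(rep(ax - ctr, each = 10), 10), dim = dims)
  Z <- array(rep(ax - ctr, each = 100), dim = dims)
  zero <- array(0, dim = c(dims, 1))
  as4 <- function(a) array(a, dim = c(dims, 1))
  mk <- function(vx, vy, vz) velocity_field(as4(vx), as4(vy), as4(vz),
                                            as4(X * 0 + 1), vox, 1000)
  om <- 5
  w_z <- vorticity_field(mk(-om * Y, om * X, X * 0), 1)
  w_x <- vorticity_field(mk(X * 0, -om * Z, om * Y), 1)
  w_y <- vorticity_field(mk(om * Z, Y * 0, -om * X), 1)
  expect_equal(mean(w_z[, , , 3]), 2 * om, tolerance = 1e-10)
  expect_equal(mean(w_x[, , , 1]), 2 * om, tolerance = 1e-10)
  expect_equal(mean(w_y[, , , 2]), 2 * om, tolerance = 1e-10)
  expect_lt(max(abs(w_z[, , , 1:2])), 1e-10)
})

test_that("mask-mean vorticity follows the magnitude-sum convention", {
  cfg <- phantom_config(c(20, 20, 12), rr_ms = 900, n_phases = 2)
  vx <- make_vortex_phantom(cfg, "solid_body", 5, 7)
  w <- vorticity_field(vx$field, 1)
  expect_rel_equal(total_vorticity(w, vx$mask), 10, 1e-9)
  # half the mask rotating at 2*Omega, half irrotational -> mean 2*Omega
  d <- cfg$grid_shape
  half1 <- array(FALSE, d); half1[, 1:10, ] <- vx$mask$voxels[, 1:10, ]
  half2 <- array(FALSE, d); half2[, 11:20, ] <- vx$mask$voxels[, 11:20, ]
  wv <- w
  wv[, , , 3][half1] <- 20   # 2*Omega doubled region: |w| = 20
  wv[, , , 3][half2] <- 0
  wv[, , , 1:2] <- 0
  full <- chamber_mask(half1 | half2)
  n1 <- sum(half1); n2 <- sum(half2)
  expect_equal(total_vorticity(wv, full), 20 * n1 / (n1 + n2))
  # vector convention cancels symmetric structure; magnitude does not
  wv2 <- w
  wv2[, , , 3][half1] <- 10
  wv2[, , , 3][half2] <- -10
  wv2[, , , 1:2] <- 0
  expect_equal(total_vorticity(wv2, full, "magnitude"), 10)
  expect_lt(total_vorticity(wv2, full, "vector"), 1)
  # Lamb-Oseen curl vs analytic profile where the core is resolved
  cfg2 <- phantom_config(c(48, 48, 8), voxel_size = 1, rr_ms = 900,
                         n_phases = 2)
  lo <- make_vortex_phantom(cfg2, "lamb_oseen", 0.05, 8, mask_radius = 16)
  w2 <- vorticity_field(lo$field, 1)
  co <- oracle_centered_coords(cfg2$grid_shape, 1)
  errs <- c()
  for (i in seq(8, 40)) for (j in seq(8, 40)) {
    r <- sqrt(co$x[i]^2 + co$y[j]^2)
    truth <- oracle_lamb_oseen_vort(r, 0.05, 8)
    errs <- c(errs, abs(w2[i, j, 4, 3] - truth) / oracle_lamb_oseen_vort(0, 0.05, 8))
  }
  expect_lt(max(errs), 0.02)
})

test_that("cycle splitting matches constructions and shifts cyclically", {
  mk_fc <- function(q) structure(list(phase_times = seq_along(q) - 1,
                                      flow_ml_s = q, rr_ms = length(q)),
                                 class = "flow_curve")
  # half-sinusoid pulse over phases 0..6, near-zero after
  q <- c(sin(pi * (0:6 + 0.5) / 7), rep(0.001, 8))
  w <- split_cycle(mk_fc(q))
  expect_equal(w$systole_window, 0:6)
  expect_equal(w$diastole_window, 7:14)
  # peak at phase 0 with immediate drop: minimal nonempty systole
  q2 <- c(1, rep(0.001, 14))
  w2 <- split_cycle(mk_fc(q2))
  expect_equal(w2$systole_window, 0L)
  expect_length(w2$diastole_window, 14)
  # cyclic equivariance: shifting the pulse shifts both windows
  rot <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  for (k in c(3, 9)) {
    wk <- split_cycle(mk_fc(rot(q, k)))
    expect_setequal(wk$systole_window, (w$systole_window + k) %% 15)
    expect_setequal(wk$diastole_window, (w$diastole_window + k) %% 15)
  }
  expect_error(split_cycle(mk_fc(rep(1, 15))), "flat")
})

test_that("peak extraction reports window maxima with their phase", {
  windows <- list(systole_window = 0:6, diastole_window = 7:14)
  # monotone curve: diastolic peak at the last phase
  inc <- seq(1, 15)
  p <- peak_values(inc, windows)
  expect_equal(p$diastolic$value, 15)
  expect_equal(p$diastolic$phase, 14L)
  expect_equal(p$systolic$phase, 6L)
  # single interior bump per window
  curve <- dnorm(0:14, mean = 3, sd = 1) + dnorm(0:14, mean = 10, sd = 1)
  p2 <- peak_values(curve, windows)
  expect_equal(p2$systolic$phase, 3L)
  expect_equal(p2$diastolic$phase, 10L)
})

test_that("ventricular metrics are invariant to rigid translation", {
  cfg <- phantom_config(c(26, 26, 14), rr_ms = 900, n_phases = 15)
  wavef <- 0.4 + 0.6 * exp(-((0:14 - 10) / 2)^2)
  vx <- make_vortex_phantom(cfg, "solid_body", 40, 7, waveform = wavef)
  qf <- c(sin(pi * (0:6 + 0.5) / 7), rep(0.01, 8))
  fc <- structure(list(phase_times = (0:14) * 60, flow_ml_s = 100 * qf,
                       rr_ms = 900), class = "flow_curve")
  vm <- ventricular_metrics(vx$field, vx$mask, fc)
  # peaks fall in their windows; diastolic vorticity peak at phase 10
  expect_true(vm$peaks$vorticity$diastolic$phase %in% vm$diastole_window)
  expect_equal(vm$peaks$vorticity$diastolic$phase, 10L)
  expect_rel_equal(vm$peaks$vorticity$diastolic$value, 80, 1e-9)
  # translate field and mask together by two voxels: identical metrics
  f2 <- vx$field
  f2$vx <- f2$vx[c(3:26, 1:2), , , , drop = FALSE]
  f2$vy <- f2$vy[c(3:26, 1:2), , , , drop = FALSE]
  f2$vz <- f2$vz[c(3:26, 1:2), , , , drop = FALSE]
  m2 <- chamber_mask(vx$mask$voxels[c(3:26, 1:2), , ])
  vm2 <- ventricular_metrics(f2, m2, fc)
  expect_equal(vm2$ke_j, vm$ke_j, tolerance = 1e-12)
  expect_equal(vm2$peaks$ke$systolic$value, vm$peaks$ke$systolic$value,
               tolerance = 1e-12)
})
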