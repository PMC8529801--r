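tube_plane <- function(dims = c(32, 32, 16), voxel = 1.25,
                       half_extent = 12, spacing = 0.625,
                       normal = c(0, 0, 1)) {
  ctr <- (dims - 1) / 2 * voxel
  measurement_plane(ctr, normal, half_extent, spacing)
}

test_that("plane extraction projects velocity onto the normal", {
  dims <- c(16, 16, 16)
  u <- array(0.8, dim = c(dims, 2))
  z <- array(0, dim = c(dims, 2))
  f <- velocity_field(z, z, u, array(1, dim = c(dims, 2)), 1.25, 1000)
  pl <- tube_plane(dims, half_extent = 5, spacing = 1)
  g <- extract_plane(f, pl)
  expect_equal(max(abs(g$vthrough - 0.8)), 0, tolerance = 1e-12)
  # tilted plane: through-plane speed scales with cos(60 deg) = 0.5
  n60 <- c(sin(pi / 3), 0, cos(pi / 3))
  pl60 <- measurement_plane((dims - 1) / 2 * 1.25, n60, 4, 1)
  g60 <- extract_plane(f, pl60)
  expect_equal(max(abs(g60$vthrough - 0.4)), 0, tolerance = 1e-12)
  # out-of-grid plane reports the offending extent
  bad <- measurement_plane(c(1, 1, 1), c(0, 0, 1), 10, 1)
  expect_error(extract_plane(f, bad), "boundary error")
})

test_that("extracted parabolic profile matches the analytic profile", {
  # radius chosen so the trilinear interpolation error bound
  # (h^2/8)(|fxx|+|fyy|) stays below 1% of the centerline velocity
  cfg <- phantom_config(c(40, 40, 12), rr_ms = 1000, n_phases = 2)
  tb <- make_tube_phantom(cfg, 12, "parabolic", rep(1, 2), 1)
  pl <- tube_plane(c(40, 40, 12), half_extent = 14)
  g <- extract_plane(tb$field, pl)
  r <- sqrt(outer(g$s^2, g$s^2, "+"))
  interior <- r <= 12 - 2 * 1.25   # clear of the partial-volume edge
  analytic <- 1 - r^2 / 144
  expect_lt(max(abs(g$vthrough[, , 1][interior] - analytic[interior])), 0.01)
})

test_that("lumen segmentation matches brute-force component labelling", {
  cfg <- phantom_config(c(32, 32, 16), rr_ms = 1000, n_phases = 2,
                        noise_sd = 0.02, seed = 6)
  tb <- make_tube_phantom(cfg, 8, "plug", rep(1, 2), 1)
  g <- extract_plane(tb$field, tube_plane())
  lum <- segment_lumen(g, threshold_frac = 0.1)
  tmax <- apply(abs(g$vthrough), 1:2, max)
  m <- tmax >= 0.1 * max(tmax)
  ctr <- (nrow(m) + 1) / 2
  expect_equal(lum[, , 1], oracle_component(m, ctr, ctr))
  # area within an annulus of the analytic cross-section; the
  # partial-volume edge widens the apparent lumen by up to one voxel
  # on top of the sample spacing
  area <- sum(lum[, , 1]) * g$spacing^2
  expect_lt(abs(area - pi * 64), 2 * pi * 8 * (g$spacing + 1.25))
  # provided masks pass through; zero planes error
  pm <- matrix(TRUE, nrow(m), ncol(m))
  expect_equal(segment_lumen(g, "provided", mask = pm)[, , 2], pm)
  g0 <- g; g0$vthrough[] <- 0
  expect_error(segment_lumen(g0), "segmentation error")
})

test_that("flow and SV recover closed forms across radii and profiles", {
  cfg <- phantom_config(c(32, 32, 16), rr_ms = 1000, n_phases = 2)
  for (R in c(6, 8, 10)) for (prof in c("plug", "parabolic")) {
    tb <- make_tube_phantom(cfg, R, prof, rep(1, 2), 1)
    pl <- tube_plane(half_extent = R + 4)
    fc <- flow_curve(extract_plane(tb$field, pl),
                     segment_lumen(extract_plane(tb$field, pl)))
    q_true <- if (prof == "plug") pi * R^2 else pi * R^2 / 2
    expect_lt(abs(fc$flow_ml_s[1] / q_true - 1), 0.03)
    expect_lt(abs(stroke_volume(fc) / tb$truth$true_sv - 1), 0.03)
  }
})

test_that("pulsatile flow tracks the phantom ground truth per phase", {
  cfg <- phantom_config(c(32, 32, 16), rr_ms = 900, n_phases = 15)
  wave <- 0.1 + sin(pi * (0:14 + 0.5) / 15)
  tb <- make_tube_phantom(cfg, 8, "parabolic", wave, 1.2)
  g <- extract_plane(tb$field, tube_plane())
  fc <- flow_curve(g, segment_lumen(g))
  expect_true(all(abs(fc$flow_ml_s / tb$truth$true_flow_curve - 1) < 0.03))
})

test_that("flow is linear in velocity and antisymmetric in the normal", {
  cfg <- phantom_config(c(32, 32, 16), rr_ms = 1000, n_phases = 2,
                        noise_sd = 0.01, seed = 3)
  tb <- make_tube_phantom(cfg, 8, "plug", rep(1, 2), 0.9)
  f2 <- tb$field
  f2$vx <- 2.5 * f2$vx; f2$vy <- 2.5 * f2$vy; f2$vz <- 2.5 * f2$vz
  pl <- tube_plane()
  g <- extract_plane(tb$field, pl)
  lum <- segment_lumen(g)
  q1 <- flow_curve(g, lum)$flow_ml_s
  q2 <- flow_curve(extract_plane(f2, pl), lum)$flow_ml_s
  expect_equal(q2, 2.5 * q1)
  # reversed normal negates the curve exactly
  rev_pl <- measurement_plane(pl$origin, -pl$normal, pl$half_extent,
                              pl$sample_spacing)
  grev <- extract_plane(tb$field, rev_pl)
  lumrev <- lum[dim(lum)[1]:1, , , drop = FALSE]  # mirrored in-plane axis
  qrev <- flow_curve(grev, lumrev)$flow_ml_s
  expect_equal(qrev, -q1)
})

test_that("stroke volume integrates periodically and cyclic-invariantly", {
  # constant flow: SV = Q * RR
  fc <- structure(list(phase_times = (0:9) * 100, flow_ml_s = rep(100, 10),
                       rr_ms = 1000), class = "flow_curve")
  expect_equal(stroke_volume(fc), 100)
  # sinusoid on top of a mean integrates away over the period
  q0 <- 40
  fc2 <- fc; fc2$flow_ml_s <- q0 * (1 + sin(2 * pi * (0:9) / 10))
  expect_equal(stroke_volume(fc2), q0, tolerance = 1e-12)
  # 15-phase sampled sinusoid against the symbolic integral: periodic
  # trapezoid is spectrally accurate for a pure tone, so equality is
  # tight
  t15 <- (0:14) * 1000 / 15
  fc3 <- structure(list(phase_times = t15,
                        flow_ml_s = 60 + 25 * sin(2 * pi * t15 / 1000),
                        rr_ms = 1000), class = "flow_curve")
  expect_equal(stroke_volume(fc3), 60, tolerance = 1e-10)
  # cyclic rotation of phase labels leaves SV unchanged
  rot <- function(x, k) x[((seq_along(x) - 1 + k) %% length(x)) + 1]
  fc4 <- fc3; fc4$flow_ml_s <- rot(fc3$flow_ml_s, 4)
  expect_equal(stroke_volume(fc4), stroke_volume(fc3), tolerance = 1e-10)
  expect_error(stroke_volume(fc3, rr_ms = -5), "rr_ms")
})

test_that("hemodynamic summary arithmetic is exact", {
  h <- summarize_hemodynamics(70, 70, 1.75)
  expect_equal(h$co_l_min, 4.9)
  expect_equal(h$ci_l_min_m2, 2.8)
  expect_equal(h$sv_index_ml_m2, 40)
  # homogeneity: doubling BSA halves indexed values exactly
  h2 <- summarize_hemodynamics(70, 70, 3.5)
  expect_equal(h2$sv_index_ml_m2, h$sv_index_ml_m2 / 2)
  expect_equal(h2$ci_l_min_m2, h$ci_l_min_m2 / 2)
  # tiny SV stays exact
  expect_equal(summarize_hemodynamics(0.001, 70, 1)$co_l_min, 7e-5)
  expect_error(summarize_hemodynamics(-1, 70, 1.75), "domain error")
  expect_equal(bsa_du_bois(70, 175), 0.007184 * 70^0.425 * 175^0.725)
})
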