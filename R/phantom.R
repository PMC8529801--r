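#' Phantom configuration
#'
#' Grid and acquisition parameters shared by all synthetic phantoms.
#' Defaults mirror a typical radial 4D flow protocol: 1.25 mm isotropic
#' voxels and fifteen reconstructed cardiac phases.
#'
#' @param grid_shape Integer triple: voxels along x, y, z.
#' @param voxel_size Isotropic voxel size in mm.
#' @param n_phases Number of cardiac phases (>= 2).
#' @param rr_ms Cardiac cycle length in ms.
#' @param noise_sd Standard deviation of i.i.d. Gaussian velocity noise
#'   added per component, voxel and phase (m/s).
#' @param seed Integer RNG seed for the noise; NULL leaves the global
#'   RNG stream untouched.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape, voxel_size = 1.25, n_phases = 15,
                           rr_ms = 1000, noise_sd = 0, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    stop("grid_shape must be three integers >= 2")
  if (voxel_size <= 0) stop("invariant violated: voxel_size must be > 0")
  if (n_phases < 2) stop("invariant violated: n_phases must be >= 2")
  if (rr_ms <= 0) stop("invariant violated: rr_ms must be > 0")
  if (noise_sd < 0) stop("invariant violated: noise_sd must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_phases = as.integer(n_phases), rr_ms = rr_ms,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_config")
}

# mm coordinates of voxel centers relative to the in-plane (x, y) grid
# center, as full 3-D arrays. Used by the generators.
phantom_coords <- function(cfg) {
  d <- cfg$grid_shape
  x <- axis_coords(d[1], cfg$voxel_size)
  y <- axis_coords(d[2], cfg$voxel_size)
  z <- axis_coords(d[3], cfg$voxel_size)
  cx <- mean(range(x)); cy <- mean(range(y)); cz <- mean(range(z))
  list(
    x = array(rep(x - cx, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(y - cy, each = d[1]), times = d[3]), dim = d),
    z = array(rep(z - cz, each = d[1] * d[2]), dim = d),
    center = c(cx, cy, cz)
  )
}

add_phantom_noise <- function(vx, vy, vz, cfg) {
  if (cfg$noise_sd > 0) {
    n <- length(vx)
    noise <- with_seed(cfg$seed, stats::rnorm(3 * n, sd = cfg$noise_sd))
    vx <- vx + array(noise[seq_len(n)], dim = dim(vx))
    vy <- vy + array(noise[n + seq_len(n)], dim = dim(vy))
    vz <- vz + array(noise[2 * n + seq_len(n)], dim = dim(vz))
  }
  list(vx = vx, vy = vy, vz = vz)
}

#' Pulsatile tube phantom
#'
#' A straight tube along the z axis, centered in-plane, carrying plug or
#' parabolic (Poiseuille) axial flow modulated by a per-phase waveform.
#' Stands in for a great vessel such as the main pulmonary artery. The
#' returned ground truth carries the closed-form flow curve
#' (Q = v*pi*R^2 for plug, half that for parabolic, in mL/s with v in
#' m/s and R in mm) and the stroke volume obtained by periodic
#' trapezoidal integration of that curve over one RR interval.
#'
#' A static-tissue shell (bright magnitude, zero velocity) surrounds the
#' tube so that stationary-tissue detection and background-phase fitting
#' can be exercised; air outside the shell has low magnitude.
#'
#' @param config A \code{\link{phantom_config}}.
#' @param radius Tube radius in mm; must fit inside the in-plane grid.
#' @param profile "plug" or "parabolic".
#' @param waveform Per-phase non-negative scale factors (length
#'   \code{n_phases}); defaults to steady flow.
#' @param peak_velocity Axial velocity scale in m/s (centerline velocity
#'   for the parabolic profile) at waveform value 1.
#' @return A list with components \code{field} (a
#'   \code{\link{velocity_field}}) and \code{truth} (ground-truth list:
#'   \code{true_flow_curve} mL/s per phase, \code{true_sv} mL,
#'   \code{lumen_mask}, \code{static_mask}, \code{air_mask}).
#' @export
make_tube_phantom <- function(config, radius, profile = c("parabolic", "plug"),
                              waveform = NULL, peak_velocity = 1) {
  profile <- match.arg(profile)
  d <- config$grid_shape
  if (is.null(waveform)) waveform <- rep(1, config$n_phases)
  if (length(waveform) != config$n_phases || any(waveform < 0))
    stop("waveform must have n_phases non-negative entries")
  half_extent <- (min(d[1], d[2]) - 1) / 2 * config$voxel_size
  if (radius >= half_extent)
    stop("configuration error: tube radius exceeds the in-plane grid extent")
  if (peak_velocity < 0)
    stop("configuration error: peak_velocity must be non-negative")

  co <- phantom_coords(config)
  r2 <- co$x^2 + co$y^2
  lumen <- r2 <= radius^2

  # Partial-volume (supersampled) in-plane profile: each voxel carries
  # the mean of the analytic profile over an 8x8 subvoxel lattice, as
  # an imaging voxel would, so the discrete integral of the axial
  # velocity matches the closed-form flow to high accuracy.
  ss <- 8
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * config$voxel_size
  x2d <- co$x[, , 1]; y2d <- co$y[, , 1]
  prof2d <- matrix(0, d[1], d[2])
  for (ox in off) for (oy in off) {
    rr2 <- (x2d + ox)^2 + (y2d + oy)^2
    prof2d <- prof2d + if (profile == "plug") (rr2 <= radius^2)
                       else pmax(0, 1 - rr2 / radius^2)
  }
  prof2d <- prof2d / ss^2
  prof <- array(rep(prof2d, d[3]), dim = d)

  np <- config$n_phases
  vz <- array(0, dim = c(d, np))
  for (p in seq_len(np)) vz[, , , p] <- peak_velocity * waveform[p] * prof
  vx <- array(0, dim = c(d, np)); vy <- vx

  # magnitude: bright lumen, bright static shell, dim air
  shell_outer <- min(half_extent, radius + max(4 * config$voxel_size,
                                               0.3 * half_extent))
  static <- r2 > (radius + config$voxel_size)^2 & r2 <= shell_outer^2
  air <- !lumen & !static
  mag3 <- 0.1 + 0.9 * static + 1.9 * lumen
  magnitude <- array(rep(mag3, np), dim = c(d, np))

  nz <- add_phantom_noise(vx, vy, vz, config)
  field <- velocity_field(nz$vx, nz$vy, nz$vz, magnitude,
                          config$voxel_size, config$rr_ms)

  area_factor <- if (profile == "plug") pi * radius^2 else pi * radius^2 / 2
  q <- peak_velocity * waveform * area_factor  # mL/s (v m/s x mm^2)
  sv <- periodic_trapz(field$phase_times, q, config$rr_ms) / 1000
  truth <- list(true_flow_curve = q, true_sv = sv,
                true_ke_curve = NULL, true_mean_vorticity = NULL,
                background_coeffs = NULL,
                lumen_mask = lumen, static_mask = static, air_mask = air,
                radius = radius, profile = profile,
                peak_velocity = peak_velocity, waveform = waveform)
  list(field = field, truth = truth)
}

#' Vortex phantom with closed-form kinetic energy and vorticity
#'
#' Analytic rotating velocity fields standing in for intraventricular
#' (diastolic filling) vortices:
#' \describe{
#'   \item{solid_body}{rigid rotation about the z axis through the grid
#'     center at angular speed \code{strength} rad/s, defined over the
#'     whole grid; vorticity magnitude is exactly 2*strength everywhere.}
#'   \item{lamb_oseen}{a Lamb-Oseen vortex about the z axis with
#'     circulation \code{strength} m^2/s and core radius
#'     \code{core_radius} mm, defined over the whole grid.}
#'   \item{hill}{Hill's spherical vortex of radius \code{core_radius} mm
#'     and translation speed \code{strength} m/s; the interior solution
#'     only, zero velocity outside the sphere (the boundary slip is a
#'     documented simplification).}
#' }
#' The evaluation mask is a cylinder (sphere for \code{hill}) of radius
#' \code{mask_radius} (default \code{core_radius}). Ground-truth mean
#' vorticity magnitude and KE are the analytic values evaluated at voxel
#' centers inside the mask, optionally modulated in time by
#' \code{waveform} (velocity scales linearly, KE quadratically).
#'
#' @param config A \code{\link{phantom_config}}.
#' @param mode "solid_body", "lamb_oseen" or "hill".
#' @param strength Angular speed (rad/s) for solid_body, circulation
#'   (m^2/s) for lamb_oseen, translation speed (m/s) for hill.
#' @param core_radius Core (or sphere) radius in mm.
#' @param mask_radius Radius of the evaluation mask in mm; defaults to
#'   \code{core_radius}; must fit inside the grid.
#' @param field_radius Cylindrical radius (mm) beyond which the
#'   velocity is zeroed, leaving a stationary "tissue" region around
#'   the vortex (default Inf: the analytic field fills the grid). Keep
#'   at least one voxel of margin between \code{mask_radius} and
#'   \code{field_radius} so the curl stencil at mask voxels never
#'   touches the truncation. Ignored for \code{hill}, whose support is
#'   the sphere itself.
#' @param waveform Optional per-phase scale factors (default steady).
#' @param rho Blood density kg/m^3 used for the ground-truth KE.
#' @return A list with \code{field}, \code{mask} (a
#'   \code{\link{chamber_mask}}) and \code{truth} (per-phase
#'   \code{true_ke_curve} J, \code{true_mean_vorticity} 1/s).
#' @export
make_vortex_phantom <- function(config, mode = c("solid_body", "lamb_oseen", "hill"),
                                strength, core_radius, mask_radius = NULL,
                                field_radius = Inf, waveform = NULL,
                                rho = 1060) {
  mode <- match.arg(mode)
  d <- config$grid_shape
  if (is.null(waveform)) waveform <- rep(1, config$n_phases)
  if (length(waveform) != config$n_phases)
    stop("waveform must have n_phases entries")
  if (is.null(mask_radius)) mask_radius <- core_radius
  ext_d <- if (mode == "hill") d else d[1:2]  # cylindrical masks: in-plane only
  half_extent <- (min(ext_d) - 1) / 2 * config$voxel_size
  if (mask_radius > half_extent)
    stop("configuration error: vortex mask does not fit inside the grid")

  co <- phantom_coords(config)
  x_m <- co$x / 1000; y_m <- co$y / 1000; z_m <- co$z / 1000
  s_m <- sqrt(x_m^2 + y_m^2)           # cylindrical radius, m
  rc_m <- core_radius / 1000

  if (mode == "solid_body") {
    ux <- -strength * y_m; uy <- strength * x_m; uz <- array(0, dim = d)
    vort <- array(2 * abs(strength), dim = d)
    mask <- (co$x^2 + co$y^2) <= mask_radius^2
  } else if (mode == "lamb_oseen") {
    vt <- ifelse(s_m > 0,
                 strength / (2 * pi * s_m) * (1 - exp(-s_m^2 / rc_m^2)), 0)
    ux <- ifelse(s_m > 0, -vt * y_m / s_m, 0)
    uy <- ifelse(s_m > 0, vt * x_m / s_m, 0)
    ux <- array(ux, dim = d); uy <- array(uy, dim = d)
    uz <- array(0, dim = d)
    vort <- array(abs(strength) / (pi * rc_m^2) * exp(-s_m^2 / rc_m^2), dim = d)
    mask <- (co$x^2 + co$y^2) <= mask_radius^2
  } else { # hill
    r_m <- sqrt(s_m^2 + z_m^2)
    inside <- r_m <= rc_m
    us <- -1.5 * strength * s_m * z_m / rc_m^2
    uz <- 1.5 * strength * (1 - (2 * s_m^2 + z_m^2) / rc_m^2)
    ux <- ifelse(s_m > 0, us * x_m / s_m, 0) * inside
    uy <- ifelse(s_m > 0, us * y_m / s_m, 0) * inside
    uz <- uz * inside
    ux <- array(ux, dim = d); uy <- array(uy, dim = d); uz <- array(uz, dim = d)
    vort <- array(7.5 * abs(strength) * s_m / rc_m^2, dim = d) * inside
    mask <- (co$x^2 + co$y^2 + co$z^2) <= mask_radius^2
  }

  if (is.finite(field_radius) && mode != "hill") {
    if (field_radius < mask_radius + config$voxel_size)
      stop("configuration error: field_radius must exceed mask_radius by a voxel")
    support <- (co$x^2 + co$y^2) <= field_radius^2
    ux <- ux * support; uy <- uy * support; uz <- uz * support
    vort <- vort * support
  }

  np <- config$n_phases
  vx <- array(0, dim = c(d, np)); vy <- vx; vz <- vx
  for (p in seq_len(np)) {
    vx[, , , p] <- ux * waveform[p]
    vy[, , , p] <- uy * waveform[p]
    vz[, , , p] <- uz * waveform[p]
  }
  magnitude <- array(1, dim = c(d, np))

  vvol_m3 <- (config$voxel_size / 1000)^3
  speed2 <- ux^2 + uy^2 + uz^2
  ke0 <- 0.5 * rho * vvol_m3 * sum(speed2[mask])
  mv0 <- mean(vort[mask])
  nz <- add_phantom_noise(vx, vy, vz, config)
  field <- velocity_field(nz$vx, nz$vy, nz$vz, magnitude,
                          config$voxel_size, config$rr_ms)
  truth <- list(true_flow_curve = NULL, true_sv = NULL,
                true_ke_curve = ke0 * waveform^2,
                true_mean_vorticity = mv0 * abs(waveform),
                background_coeffs = NULL,
                vorticity_voxelwise = vort, mode = mode,
                strength = strength, core_radius = core_radius)
  list(field = field, mask = chamber_mask(mask, paste0(mode, "_vortex")),
       truth = truth)
}

#' Inject a static polynomial background phase offset
#'
#' Adds, to every cardiac phase of each velocity component, a 3rd-order
#' (or lower) polynomial in coordinates normalized to [-1, 1] per axis —
#' the eddy-current-like offset that background phase correction must
#' later remove. The monomial ordering is the one reported by
#' \code{\link{fit_background}}.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param coeffs Numeric matrix (n_monomials x 3, columns vx, vy, vz) or
#'   a list of three equal-length coefficient vectors. The number of
#'   rows must correspond to a polynomial order <= 3.
#' @return The field with the offset added (magnitude untouched).
#' @export
add_background_offset <- function(field, coeffs) {
  if (is.list(coeffs) && !is.matrix(coeffs)) coeffs <- do.call(cbind, coeffs)
  coeffs <- as.matrix(coeffs)
  if (ncol(coeffs) != 3) stop("coeffs must have one column per velocity component")
  n_mono <- vapply(0:3, function(o) nrow(poly_exponents(o)), 1)
  if (!nrow(coeffs) %in% n_mono)
    stop("configuration error: coefficient count implies monomial degree > 3")
  order <- (0:3)[match(nrow(coeffs), n_mono)]
  d <- field_dims(field)
  basis <- poly_basis(grid_coords_norm(d), order)
  np <- n_phases(field)
  for (ci in 1:3) {
    comp <- c("vx", "vy", "vz")[ci]
    off <- array(basis %*% coeffs[, ci], dim = d)
    for (p in seq_len(np)) {
      field[[comp]][, , , p] <- field[[comp]][, , , p] + off
    }
  }
  field
}

#' Simulate an ECG trigger stream with missed triggers
#'
#' True beats occur every RR = 60000/hr ms; each beat is independently
#' missed with probability \code{drop_prob} and recorded triggers are
#' jittered with Gaussian noise. Projections are acquired every
#' \code{tr_ms}. The true beat times are retained as ground truth.
#'
#' @param hr_bpm True heart rate, beats/min.
#' @param duration_s Acquisition duration, s; must cover at least one RR.
#' @param drop_prob Per-beat miss probability in [0, 1).
#' @param jitter_sd_ms Gaussian jitter SD on recorded triggers, ms.
#' @param tr_ms Projection repetition time, ms (default 6.2).
#' @param seed Integer RNG seed; NULL uses the global stream.
#' @return A list: \code{log} (a \code{\link{trigger_log}}),
#'   \code{true_rr_ms}, \code{true_beat_times}.
#' @export
simulate_triggers <- function(hr_bpm, duration_s, drop_prob = 0,
                              jitter_sd_ms = 0, tr_ms = 6.2, seed = NULL) {
  if (hr_bpm <= 0) stop("hr_bpm must be > 0")
  if (tr_ms <= 0) stop("tr_ms must be > 0")
  if (drop_prob < 0 || drop_prob >= 1) stop("drop_prob must be in [0, 1)")
  rr <- 60000 / hr_bpm
  dur <- duration_s * 1000
  if (dur < rr) stop("configuration error: duration shorter than one RR interval")
  beats <- seq(0, dur, by = rr)
  with_seed(seed, {
    keep <- stats::runif(length(beats)) >= drop_prob
    rec <- beats[keep]
    if (jitter_sd_ms > 0 && length(rec))
      rec <- sort(rec + stats::rnorm(length(rec), sd = jitter_sd_ms))
    proj <- seq(0, dur, by = tr_ms)
    list(log = trigger_log(rec, proj), true_rr_ms = rr, true_beat_times = beats)
  })
}

#' Simulate a periodic respiratory waveform
#'
#' An asymmetric bellows trace: an end-expiration plateau at the maximum
#' value occupying \code{plateau_frac} of each cycle, and a raised-cosine
#' inspiration dip over the remainder. \code{period_s = Inf} yields a
#' constant trace (breath-hold convention).
#'
#' @param period_s Respiratory period, s.
#' @param duration_s Duration, s.
#' @param sample_ms Sampling interval, ms.
#' @param plateau_frac Fraction of the cycle spent on the expiration
#'   plateau (default 0.3).
#' @return A \code{\link{resp_waveform}}.
#' @export
simulate_respiration <- function(period_s, duration_s, sample_ms = 10,
                                 plateau_frac = 0.3) {
  if (period_s <= 0) stop("period_s must be > 0")
  if (plateau_frac < 0 || plateau_frac >= 1)
    stop("plateau_frac must be in [0, 1)")
  t <- seq(0, duration_s * 1000, by = sample_ms)
  if (!is.finite(period_s)) return(resp_waveform(t, rep(1, length(t))))
  u <- (t / (period_s * 1000)) %% 1
  v <- ifelse(u < plateau_frac, 1,
              1 - 0.5 * (1 - cos(2 * pi * (u - plateau_frac) / (1 - plateau_frac))))
  resp_waveform(t, v)
}
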