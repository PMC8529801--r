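# Independent closed-form and brute-force oracles. Nothing here calls
# the package's generator or metric internals, so a shared bug between
# oracle and implementation is impossible.

# Analytic Lamb-Oseen tangential velocity (m/s) and axial vorticity
# (1/s) at cylindrical radius r_mm, circulation gamma m^2/s, core rc_mm.
oracle_lamb_oseen_vt <- function(r_mm, gamma, rc_mm) {
  r <- r_mm / 1000; rc <- rc_mm / 1000
  ifelse(r > 0, gamma / (2 * pi * r) * (1 - exp(-r^2 / rc^2)), 0)
}
oracle_lamb_oseen_vort <- function(r_mm, gamma, rc_mm) {
  r <- r_mm / 1000; rc <- rc_mm / 1000
  gamma / (pi * rc^2) * exp(-r^2 / rc^2)
}

# Voxel-center coordinates (mm) relative to the grid center, as used by
# the corner-origin convention: coordinate = 0-based index * voxel.
oracle_centered_coords <- function(dims, voxel) {
  ax <- function(n) (seq_len(n) - 1) * voxel - (n - 1) / 2 * voxel
  list(x = ax(dims[1]), y = ax(dims[2]), z = ax(dims[3]))
}

# Brute-force KE of a solid-body rotation (angular speed omega rad/s
# about z through the grid center) over a cylindrical mask: plain voxel
# loop, 0.5 * rho * V * sum(omega^2 r^2).
oracle_solid_body_ke <- function(dims, voxel, omega, mask_radius_mm,
                                 rho = 1060) {
  co <- oracle_centered_coords(dims, voxel)
  v_m3 <- (voxel / 1000)^3
  total <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    r2_mm <- co$x[i]^2 + co$y[j]^2
    if (r2_mm <= mask_radius_mm^2)
      total <- total + dims[3] * omega^2 * (r2_mm * 1e-6)
  }
  0.5 * rho * v_m3 * total
}

# Brute-force mean in-mask Lamb-Oseen vorticity by per-voxel quadrature
# of the analytic profile.
oracle_lamb_oseen_mean_vort <- function(dims, voxel, gamma, rc_mm,
                                        mask_radius_mm) {
  co <- oracle_centered_coords(dims, voxel)
  tot <- 0; n <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    r_mm <- sqrt(co$x[i]^2 + co$y[j]^2)
    if (r_mm <= mask_radius_mm) {
      tot <- tot + dims[3] * oracle_lamb_oseen_vort(r_mm, gamma, rc_mm)
      n <- n + dims[3]
    }
  }
  tot / n
}

# Brute-force curl of one phase of a velocity field by explicit
# per-voxel central differences (interior only).
oracle_interior_curl <- function(vx, vy, vz, voxel_mm) {
  h <- voxel_mm / 1000
  d <- dim(vx)
  out <- array(NA_real_, dim = c(d, 3))
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    dvz_dy <- (vz[i, j + 1, k] - vz[i, j - 1, k]) / (2 * h)
    dvy_dz <- (vy[i, j, k + 1] - vy[i, j, k - 1]) / (2 * h)
    dvx_dz <- (vx[i, j, k + 1] - vx[i, j, k - 1]) / (2 * h)
    dvz_dx <- (vz[i + 1, j, k] - vz[i - 1, j, k]) / (2 * h)
    dvy_dx <- (vy[i + 1, j, k] - vy[i - 1, j, k]) / (2 * h)
    dvx_dy <- (vx[i, j + 1, k] - vx[i, j - 1, k]) / (2 * h)
    out[i, j, k, ] <- c(dvz_dy - dvy_dz, dvx_dz - dvz_dx, dvy_dx - dvx_dy)
  }
  out
}

# A globally linear velocity field v = A %*% x_m + b (x in meters from
# the grid corner); its curl is constant:
# (A32 - A23, A13 - A31, A21 - A12).
linear_velocity_field <- function(dims, voxel, A, b, n_ph = 2,
                                  rr_ms = 1000) {
  ax <- function(n) (seq_len(n) - 1) * voxel / 1000
  X <- array(rep(ax(dims[1]), times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ax(dims[2]), each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(ax(dims[3]), each = dims[1] * dims[2]), dim = dims)
  comp <- function(r) A[r, 1] * X + A[r, 2] * Y + A[r, 3] * Z + b[r]
  rep4 <- function(a) array(rep(a, n_ph), dim = c(dims, n_ph))
  velocity_field(rep4(comp(1)), rep4(comp(2)), rep4(comp(3)),
                 rep4(array(1, dim = dims)), voxel, rr_ms)
}

# Brute-force per-projection late fraction: explicit loop, no
# vectorized shortcuts.
oracle_late_fraction <- function(trig, proj) {
  rr <- diff(trig)
  s <- sort(rr)
  med <- s[floor((length(s) + 1) / 2)]
  n_late <- 0; n_tot <- 0
  for (p in proj) {
    prev <- NA
    for (t in trig) if (t <= p) prev <- t else break
    if (!is.na(prev)) {
      n_tot <- n_tot + 1
      if (p - prev > med) n_late <- n_late + 1
    }
  }
  list(late_fraction = n_late / n_tot, median_rr = med)
}

# Full-sort respiratory acceptance oracle: accept the ceil(eff*N)
# values closest to the extreme, ties at the threshold included.
oracle_resp_accept <- function(values, efficiency, polarity = "max") {
  key <- if (polarity == "max") -values else values
  thr <- sort(key)[ceiling(efficiency * length(key))]
  which(key <= thr)
}

# Brute-force 4-connected component labelling containing a start cell.
oracle_component <- function(m, i0, j0) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (si in seq_len(nrow(m))) for (sj in seq_len(ncol(m))) {
    if (m[si, sj] && lab[si, sj] == 0L) {
      cur <- cur + 1L
      queue <- list(c(si, sj)); lab[si, sj] <- cur
      while (length(queue)) {
        c0 <- queue[[1]]; queue <- queue[-1]
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          i <- c0[1] + dd[1]; j <- c0[2] + dd[2]
          if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
              m[i, j] && lab[i, j] == 0L) {
            lab[i, j] <- cur
            queue <- c(queue, list(c(i, j)))
          }
        }
      }
    }
  }
  if (!m[i0, j0]) matrix(FALSE, nrow(m), ncol(m)) else lab == lab[i0, j0]
}

# Analytic Lamb-Oseen velocity function (mm position -> m/s vector)
# about a vertical axis through ctr_mm.
analytic_lamb_oseen <- function(ctr_mm, gamma, rc_mm) {
  function(x) {
    dx <- x[1] - ctr_mm[1]; dy <- x[2] - ctr_mm[2]
    r <- sqrt(dx^2 + dy^2)
    if (r == 0) return(c(0, 0, 0))
    vt <- oracle_lamb_oseen_vt(r, gamma, rc_mm)
    c(-vt * dy / r, vt * dx / r, 0)
  }
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
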