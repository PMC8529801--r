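#' Streamline/pathline tracing configuration
#'
#' @param step_mm Integration step in mm of arclength (streamlines) or
#'   the target spatial step used to derive the time step (pathlines).
#' @param max_steps Maximum number of integration steps.
#' @param min_speed_m_s Termination speed: integration stops when the
#'   local speed falls below this (default 1e-4 m/s).
#' @param direction "forward", "backward" or "both".
#' @return An object of class \code{trace_config}.
#' @export
trace_config <- function(step_mm = 0.5, max_steps = 2000,
                         min_speed_m_s = 1e-4,
                         direction = c("forward", "backward", "both")) {
  direction <- match.arg(direction)
  if (step_mm <= 0) stop("invariant violated: step_mm must be > 0")
  if (max_steps < 1) stop("invariant violated: max_steps must be >= 1")
  if (min_speed_m_s < 0) stop("invariant violated: min_speed must be >= 0")
  structure(list(step_mm = step_mm, max_steps = as.integer(max_steps),
                 min_speed_m_s = min_speed_m_s, direction = direction),
            class = "trace_config")
}

#' Seed points on a measurement plane
#'
#' A uniform k x k lattice (k = floor(sqrt(n_seeds))) spanning
#' +/- half_extent in the plane; \code{n_seeds = 1} returns the plane
#' origin. All seeds satisfy (p - origin) . normal = 0.
#'
#' @param plane A \code{\link{measurement_plane}}.
#' @param n_seeds Requested number of seeds.
#' @return Matrix (n x 3) of mm positions.
#' @export
seed_points <- function(plane, n_seeds) {
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  if (n_seeds == 1) return(matrix(plane$origin, 1, 3))
  k <- floor(sqrt(n_seeds))
  u <- seq(-plane$half_extent, plane$half_extent, length.out = k)
  b <- plane_basis(plane)
  g <- expand.grid(u = u, v = u)
  cbind(plane$origin[1] + g$u * b$e1[1] + g$v * b$e2[1],
        plane$origin[2] + g$u * b$e1[2] + g$v * b$e2[2],
        plane$origin[3] + g$u * b$e1[3] + g$v * b$e2[3])
}

# Velocity (m/s) at a mm position for a fixed phase; NA outside grid.
velocity_at <- function(field, pos, phase) {
  p <- matrix(pos, 1, 3)
  c(interp_trilinear(field$vx[, , , phase], p, field$voxel_size),
    interp_trilinear(field$vy[, , , phase], p, field$voxel_size),
    interp_trilinear(field$vz[, , , phase], p, field$voxel_size))
}

# Velocity at (pos, t_ms): linear interpolation between the two
# surrounding cardiac phases with periodic wrap over rr_ms.
velocity_at_time <- function(field, pos, t_ms) {
  pt <- field$phase_times
  np <- length(pt)
  tau <- t_ms %% field$rr_ms
  k <- findInterval(tau, pt)
  if (k == 0) k <- np  # before first phase time: wrap to last
  k2 <- if (k == np) 1 else k + 1
  t1 <- pt[k]
  gap <- if (k == np) field$rr_ms - pt[np] + pt[1] else pt[k + 1] - pt[k]
  w <- ((tau - t1) %% field$rr_ms) / gap
  v1 <- velocity_at(field, pos, k)
  v2 <- velocity_at(field, pos, k2)
  (1 - w) * v1 + w * v2
}

rk4_step <- function(f, x, h) {
  k1 <- f(x)
  if (anyNA(k1)) return(NULL)
  k2 <- f(x + h / 2 * k1)
  if (anyNA(k2)) return(NULL)
  k3 <- f(x + h / 2 * k2)
  if (anyNA(k3)) return(NULL)
  k4 <- f(x + h * k3)
  if (anyNA(k4)) return(NULL)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Trace a streamline at a fixed cardiac phase
#'
#' 4th-order Runge-Kutta integration of dx/ds = v(x)/|v(x)| (arclength
#' parameterization, so stagnant regions do not stall the step) with
#' step \code{step_mm}. Terminates on grid exit, speed below
#' \code{min_speed_m_s}, or \code{max_steps}. Direction "both"
#' concatenates the reversed backward trace with the forward trace.
#'
#' @param field A \code{\link{velocity_field}}, or a function taking a
#'   mm position 3-vector and returning the velocity 3-vector in m/s
#'   (an analytic field, e.g. for integrator verification).
#' @param seed mm position (3-vector) inside the grid.
#' @param phase Cardiac phase index (1-based); ignored for analytic
#'   fields.
#' @param cfg A \code{\link{trace_config}}.
#' @return Matrix (n_points x 3) of mm positions along the streamline.
#' @export
trace_streamline <- function(field, seed, phase = 1, cfg = trace_config()) {
  vel <- if (is.function(field)) function(x) field(x)
         else function(x) velocity_at(field, x, phase)
  trace_dir <- function(sign) {
    f <- function(x) {
      v <- vel(x)
      if (anyNA(v)) return(c(NA, NA, NA))
      sp <- sqrt(sum(v^2))
      if (sp < cfg$min_speed_m_s) return(c(0, 0, 0))
      sign * v / sp
    }
    x <- as.numeric(seed)
    v0 <- vel(x)
    if (anyNA(v0)) stop("domain error: seed outside the grid")
    pts <- matrix(0, cfg$max_steps + 1, 3)
    pts[1, ] <- x
    n_pts <- 1L
    if (sqrt(sum(v0^2)) >= cfg$min_speed_m_s) {
      for (i in seq_len(cfg$max_steps)) {
        nxt <- rk4_step(f, x, cfg$step_mm)
        if (is.null(nxt)) break                     # grid exit mid-step
        if (anyNA(vel(nxt))) break
        x <- nxt
        n_pts <- n_pts + 1L
        pts[n_pts, ] <- x
        v <- vel(x)
        if (sqrt(sum(v^2)) < cfg$min_speed_m_s) break
      }
    }
    pts[seq_len(n_pts), , drop = FALSE]
  }
  out <- switch(cfg$direction,
    forward = trace_dir(1),
    backward = trace_dir(-1),
    both = {
      bk <- trace_dir(-1)
      fw <- trace_dir(1)
      rbind(bk[rev(seq_len(nrow(bk)))[-nrow(bk)], , drop = FALSE], fw)
    })
  dimnames(out) <- list(NULL, c("x_mm", "y_mm", "z_mm"))
  out
}

#' Trace a pathline through the time-varying field
#'
#' RK4 integration of dx/dt = v(x, t) with linear interpolation of the
#' velocity between cardiac phases and periodic wrap over the RR
#' interval. The time step is step_mm divided by the local speed
#' (1 m/s = 1 mm/ms numerically), capped so each step spans at most
#' half a phase interval.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param seed mm position inside the grid.
#' @param start_phase 1-based phase index at which the particle is
#'   released.
#' @param cfg A \code{\link{trace_config}}.
#' @param duration_ms Total integration time (default one RR interval).
#' @return Matrix (n_points x 4): columns x_mm, y_mm, z_mm, t_ms.
#' @export
trace_pathline <- function(field, seed, start_phase = 1,
                           cfg = trace_config(), duration_ms = field$rr_ms) {
  x <- as.numeric(seed)
  t <- field$phase_times[start_phase]
  if (anyNA(velocity_at(field, x, start_phase)))
    stop("domain error: seed outside the grid")
  cap_ms <- field$rr_ms / (2 * n_phases(field))
  pts <- matrix(0, cfg$max_steps + 1, 4)
  pts[1, ] <- c(x, t)
  n_pts <- 1L
  t_end <- t + duration_ms
  for (i in seq_len(cfg$max_steps)) {
    v <- velocity_at_time(field, x, t)
    if (anyNA(v)) break
    sp <- sqrt(sum(v^2))
    if (sp < cfg$min_speed_m_s) break
    dt <- min(cfg$step_mm / sp, cap_ms, t_end - t)
    if (dt <= 0) break
    # RK4 in (x, t): each stage evaluated at its own time
    k1 <- velocity_at_time(field, x, t)
    k2 <- velocity_at_time(field, x + dt / 2 * k1, t + dt / 2)
    if (anyNA(k2)) break
    k3 <- velocity_at_time(field, x + dt / 2 * k2, t + dt / 2)
    if (anyNA(k3)) break
    k4 <- velocity_at_time(field, x + dt * k3, t + dt)
    if (anyNA(k4)) break
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (anyNA(velocity_at_time(field, x, t))) break
    n_pts <- n_pts + 1L
    pts[n_pts, ] <- c(x, t)
    if (t >= t_end) break
  }
  pts <- pts[seq_len(n_pts), , drop = FALSE]
  dimnames(pts) <- list(NULL, c("x_mm", "y_mm", "z_mm", "t_ms"))
  pts
}

#' Write polylines as legacy ASCII VTK polydata
#'
#' For inspection in external viewers (ParaView and kin).
#'
#' @param lines A list of polyline matrices (n_i x 3, mm).
#' @param path Output file path (.vtk).
#' @return Invisibly, \code{path}.
#' @export
write_vtk_polylines <- function(lines, path) {
  if (is.matrix(lines)) lines <- list(lines)
  npts <- vapply(lines, nrow, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "flow4d polylines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", sum(npts))), con)
  for (l in lines)
    writeLines(apply(l[, 1:3, drop = FALSE], 1, paste, collapse = " "), con)
  writeLines(sprintf("LINES %d %d", length(lines), length(lines) + sum(npts)), con)
  off <- 0L
  for (i in seq_along(lines)) {
    writeLines(paste(c(npts[i], off + seq_len(npts[i]) - 1L), collapse = " "), con)
    off <- off + npts[i]
  }
  invisible(path)
}
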