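#' Time-resolved 3-component velocity field
#'
#' The central container all metrics consume: three velocity component
#' arrays and a magnitude array of shape (nx, ny, nz, n_phases), the
#' isotropic voxel size, the cardiac cycle length and the phase times.
#' Velocities are in m/s, lengths in mm, times in ms. The grid is
#' axis-aligned with a corner origin: world coordinate = 0-based index
#' times \code{voxel_size}.
#'
#' @param vx,vy,vz Velocity component arrays (m/s), dim (nx, ny, nz, n_phases).
#' @param magnitude Signal magnitude array, same dim (arbitrary units).
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param rr_ms Cardiac cycle (RR interval) length in ms.
#' @param phase_times Time of each cardiac phase in ms; strictly
#'   increasing, all below \code{rr_ms}. Defaults to a uniform grid
#'   starting at 0.
#' @return An object of class \code{velocity_field}.
#' @export
velocity_field <- function(vx, vy, vz, magnitude, voxel_size, rr_ms,
                           phase_times = NULL) {
  d <- dim(vx)
  if (length(d) != 4) stop("velocity arrays must be 4-D (x, y, z, phase)")
  for (nm in c("vy", "vz", "magnitude")) {
    a <- get(nm)
    if (!identical(dim(a), d))
      stop(sprintf("invariant violated: '%s' shape differs from 'vx'", nm))
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("invariant violated: voxel_size must be a positive scalar (mm)")
  if (!is.numeric(rr_ms) || rr_ms <= 0)
    stop("invariant violated: rr_ms must be positive")
  if (is.null(phase_times)) phase_times <- (seq_len(d[4]) - 1) * rr_ms / d[4]
  if (length(phase_times) != d[4])
    stop("invariant violated: phase_times length must equal n_phases")
  if (any(diff(phase_times) <= 0) || any(phase_times >= rr_ms) ||
      any(phase_times < 0))
    stop("invariant violated: phase_times must be strictly increasing in [0, rr_ms)")
  structure(list(vx = vx, vy = vy, vz = vz, magnitude = magnitude,
                 voxel_size = voxel_size, rr_ms = rr_ms,
                 phase_times = as.numeric(phase_times)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d phases\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3g mm, RR %.4g ms, peak speed %.3g m/s\n",
              x$voxel_size, x$rr_ms, sqrt(max(x$vx^2 + x$vy^2 + x$vz^2))))
  invisible(x)
}

field_dims <- function(field) dim(field$vx)[1:3]
n_phases <- function(field) dim(field$vx)[4]

# Per-voxel speed array for one phase.
speed_at_phase <- function(field, phase) {
  sqrt(field$vx[, , , phase]^2 + field$vy[, , , phase]^2 +
         field$vz[, , , phase]^2)
}

#' Binary chamber (or tissue) mask
#'
#' @param voxels Logical (or 0/1 numeric) 3-D array.
#' @param label Free-text label, e.g. "RV".
#' @return An object of class \code{chamber_mask}.
#' @export
chamber_mask <- function(voxels, label = "mask") {
  if (length(dim(voxels)) != 3) stop("mask must be a 3-D array")
  v <- array(voxels != 0, dim = dim(voxels))
  structure(list(voxels = v, label = as.character(label)[1]),
            class = "chamber_mask")
}

#' @export
print.chamber_mask <- function(x, ...) {
  cat(sprintf("<chamber_mask> '%s': %d of %d voxels set\n",
              x$label, sum(x$voxels), length(x$voxels)))
  invisible(x)
}

check_mask_field <- function(mask, field) {
  if (!identical(dim(mask$voxels), field_dims(field)))
    stop("mask shape does not match the field's spatial shape")
  if (!any(mask$voxels)) stop("mask is empty")
  invisible(TRUE)
}

#' ECG trigger log
#'
#' Recorded trigger times plus per-projection acquisition timestamps,
#' both in ms and ascending.
#'
#' @param trigger_times Numeric vector of R-wave trigger times (ms).
#' @param projection_times Numeric vector of projection acquisition
#'   times (ms); may be empty.
#' @return An object of class \code{trigger_log}.
#' @export
trigger_log <- function(trigger_times, projection_times = numeric(0)) {
  trigger_times <- as.numeric(trigger_times)
  projection_times <- as.numeric(projection_times)
  if (is.unsorted(trigger_times))
    stop("invariant violated: trigger_times must be ascending")
  if (length(projection_times) && is.unsorted(projection_times))
    stop("invariant violated: projection_times must be ascending")
  structure(list(trigger_times = trigger_times,
                 projection_times = projection_times),
            class = "trigger_log")
}

#' @export
print.trigger_log <- function(x, ...) {
  cat(sprintf("<trigger_log> %d triggers, %d projections over %.3g s\n",
              length(x$trigger_times), length(x$projection_times),
              diff(range(c(x$trigger_times, x$projection_times))) / 1000))
  invisible(x)
}

#' Respiratory belt waveform
#'
#' @param sample_times Sample times in ms, ascending.
#' @param values Belt readings (arbitrary units), same length.
#' @return An object of class \code{resp_waveform}.
#' @export
resp_waveform <- function(sample_times, values) {
  if (length(sample_times) != length(values))
    stop("invariant violated: sample_times and values must have equal length")
  if (is.unsorted(sample_times))
    stop("invariant violated: sample_times must be ascending")
  structure(list(sample_times = as.numeric(sample_times),
                 values = as.numeric(values)),
            class = "resp_waveform")
}

#' Oriented measurement plane
#'
#' A square planar sampling patch used for through-plane flow
#' quantification: origin (mm), unit normal, half-extent (mm) and
#' in-plane sample spacing (mm). The normal is renormalized on
#' construction; a zero normal is rejected.
#'
#' @param origin Numeric 3-vector, mm.
#' @param normal Numeric 3-vector; need not be unit length.
#' @param half_extent Half edge length of the patch, mm.
#' @param sample_spacing In-plane sample spacing, mm.
#' @return An object of class \code{measurement_plane}.
#' @export
measurement_plane <- function(origin, normal, half_extent, sample_spacing) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  if (length(origin) != 3 || length(normal) != 3)
    stop("origin and normal must be 3-vectors")
  if (sqrt(sum(normal^2)) == 0)
    stop("invariant violated: plane normal has zero length")
  if (half_extent <= 0) stop("invariant violated: half_extent must be > 0")
  if (sample_spacing <= 0) stop("invariant violated: sample_spacing must be > 0")
  structure(list(origin = origin, normal = normalize3(normal),
                 half_extent = as.numeric(half_extent),
                 sample_spacing = as.numeric(sample_spacing)),
            class = "measurement_plane")
}

# Orthonormal in-plane basis (e1, e2) completing the plane normal.
plane_basis <- function(plane) {
  n <- plane$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(cross3(n, a))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}
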