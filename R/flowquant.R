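#' Sample a measurement plane through the field
#'
#' Trilinearly interpolates the three velocity components and the
#' magnitude on a square lattice of points spanning +/- half_extent in
#' the plane, for every cardiac phase, and projects velocity onto the
#' plane normal. The lattice always has an odd number of samples per
#' side so the plane origin is the central sample.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param plane A \code{\link{measurement_plane}} lying inside the grid.
#' @return A \code{plane_grids} list: \code{vthrough} (m/s, dim ns x ns
#'   x n_phases), \code{magnitude}, \code{spacing} (mm), \code{s}
#'   (in-plane offsets, mm), \code{plane}, \code{phase_times}.
#' @export
extract_plane <- function(field, plane) {
  b <- plane_basis(plane)
  k <- floor(plane$half_extent / plane$sample_spacing)
  s <- plane$sample_spacing * (-k:k)
  ns <- length(s)
  g <- expand.grid(u = s, v = s)
  pts <- cbind(plane$origin[1] + g$u * b$e1[1] + g$v * b$e2[1],
               plane$origin[2] + g$u * b$e1[2] + g$v * b$e2[2],
               plane$origin[3] + g$u * b$e1[3] + g$v * b$e2[3])
  d <- field_dims(field)
  lim <- (d - 1) * field$voxel_size
  out_of <- pts[, 1] < 0 | pts[, 1] > lim[1] | pts[, 2] < 0 |
    pts[, 2] > lim[2] | pts[, 3] < 0 | pts[, 3] > lim[3]
  if (any(out_of)) {
    rng <- apply(pts[out_of, , drop = FALSE], 2, range)
    stop(sprintf(paste("boundary error: %d plane samples outside grid",
                       "[0, %.4g] x [0, %.4g] x [0, %.4g] mm (offending extent",
                       "x [%.4g, %.4g], y [%.4g, %.4g], z [%.4g, %.4g])"),
                 sum(out_of), lim[1], lim[2], lim[3],
                 rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  np <- n_phases(field)
  vthrough <- array(0, dim = c(ns, ns, np))
  mag <- array(0, dim = c(ns, ns, np))
  n <- plane$normal
  for (p in seq_len(np)) {
    ix <- interp_trilinear(field$vx[, , , p], pts, field$voxel_size)
    iy <- interp_trilinear(field$vy[, , , p], pts, field$voxel_size)
    iz <- interp_trilinear(field$vz[, , , p], pts, field$voxel_size)
    vthrough[, , p] <- matrix(ix * n[1] + iy * n[2] + iz * n[3], ns, ns)
    mag[, , p] <- matrix(interp_trilinear(field$magnitude[, , , p], pts,
                                          field$voxel_size), ns, ns)
  }
  structure(list(vthrough = vthrough, magnitude = mag,
                 spacing = plane$sample_spacing, s = s, plane = plane,
                 phase_times = field$phase_times, rr_ms = field$rr_ms),
            class = "plane_grids")
}

# Connected component of TRUE cells containing (i0, j0), 4-connectivity.
flood_component <- function(m, i0, j0) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (!m[i0, j0]) return(out)
  stack <- matrix(c(i0, j0), ncol = 2)
  out[i0, j0] <- TRUE
  while (nrow(stack)) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i <- cur[1] + d[1]; j <- cur[2] + d[2]
      if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
          m[i, j] && !out[i, j]) {
        out[i, j] <- TRUE
        stack <- rbind(stack, c(i, j))
      }
    }
  }
  out
}

#' Segment the vessel lumen on a measurement plane
#'
#' Threshold method: the lumen is the 4-connected component containing
#' the plane center in which the time-maximum absolute through-plane
#' velocity is at least \code{threshold_frac} of its plane-wide maximum.
#' By default the lumen is contoured once on the time-maximum map and
#' reused for every phase (static lumen); per-phase contouring is
#' available. The provided method passes an explicit mask through.
#'
#' @param grids A \code{plane_grids} from \code{\link{extract_plane}}.
#' @param method "threshold" or "provided".
#' @param threshold_frac Velocity threshold as a fraction of the plane
#'   maximum (default 0.1).
#' @param mask Logical ns x ns matrix for method "provided".
#' @param per_phase If TRUE, contour each phase separately on that
#'   phase's |velocity| map (default FALSE).
#' @return Logical array ns x ns x n_phases of lumen membership.
#' @export
segment_lumen <- function(grids, method = c("threshold", "provided"),
                          threshold_frac = 0.1, mask = NULL,
                          per_phase = FALSE) {
  method <- match.arg(method)
  d <- dim(grids$vthrough)
  if (method == "provided") {
    if (is.null(mask) || !identical(dim(mask), d[1:2]))
      stop("provided mask must be an ns x ns logical matrix")
    return(array(mask, dim = d))
  }
  ctr <- (d[1] + 1) / 2
  seg_one <- function(map) {
    mx <- max(abs(map))
    if (mx == 0) stop("segmentation error: no through-plane velocity on the plane")
    comp <- flood_component(abs(map) >= threshold_frac * mx, ctr, ctr)
    if (!any(comp))
      stop("segmentation error: plane center below the velocity threshold")
    comp
  }
  if (per_phase) {
    out <- array(FALSE, dim = d)
    for (p in seq_len(d[3])) out[, , p] <- seg_one(grids$vthrough[, , p])
    out
  } else {
    tmax <- apply(abs(grids$vthrough), 1:2, max)
    array(seg_one(tmax), dim = d)
  }
}

#' Through-plane flow curve
#'
#' Q(phase) = sum over lumen samples of through-plane velocity times the
#' sample area. With velocity in m/s and spacing in mm the sum is
#' directly in mL/s.
#'
#' @param grids A \code{plane_grids}.
#' @param lumen Logical ns x ns x n_phases array from
#'   \code{\link{segment_lumen}}.
#' @return A \code{flow_curve}: \code{phase_times} (ms),
#'   \code{flow_ml_s}, \code{lumen_area_mm2}, \code{rr_ms}.
#' @export
flow_curve <- function(grids, lumen) {
  d <- dim(grids$vthrough)
  if (!identical(dim(lumen), d)) stop("lumen shape does not match plane grids")
  q <- numeric(d[3]); area <- numeric(d[3])
  for (p in seq_len(d[3])) {
    sel <- lumen[, , p]
    if (!any(sel)) stop(sprintf("empty lumen at phase %d", p))
    q[p] <- sum(grids$vthrough[, , p][sel]) * grids$spacing^2
    area[p] <- sum(sel) * grids$spacing^2
  }
  structure(list(phase_times = grids$phase_times, flow_ml_s = q,
                 lumen_area_mm2 = area, rr_ms = grids$rr_ms),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %d phases, peak %.3g mL/s, mean lumen %.3g mm^2\n",
              length(x$flow_ml_s), max(x$flow_ml_s), mean(x$lumen_area_mm2)))
  invisible(x)
}

#' @export
plot.flow_curve <- function(x, ...) {
  graphics::plot(x$phase_times, x$flow_ml_s, type = "b", pch = 16,
                 xlab = "cardiac time [ms]", ylab = "flow [mL/s]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# Periodic trapezoidal integral of y(t) over one period: the wrap
# segment from the last sample back to the first (t_1 + period) is
# included. Uniform sampling reduces to mean(y) * period.
periodic_trapz <- function(t, y, period) {
  n <- length(t)
  if (length(y) != n || n < 2) stop("need matching t and y of length >= 2")
  tt <- c(t, t[1] + period)
  yy <- c(y, y[1])
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Stroke volume from a flow curve
#'
#' Periodic trapezoidal integral of the flow curve over one RR interval
#' (the wrap-around segment from the last phase back to the first is
#' included), converted from mL/s x ms to mL.
#'
#' @param curve A \code{flow_curve}.
#' @param rr_ms RR interval in ms; defaults to the curve's own.
#' @return Stroke volume in mL.
#' @export
stroke_volume <- function(curve, rr_ms = curve$rr_ms) {
  if (is.null(rr_ms) || rr_ms <= 0)
    stop("configuration error: rr_ms must be positive")
  periodic_trapz(curve$phase_times, curve$flow_ml_s, rr_ms) / 1000
}

#' Hemodynamic summary: CO, CI and BSA-indexed stroke volume
#'
#' Cardiac output is stroke volume times heart rate; SV and CO are
#' indexed by body surface area.
#'
#' @param sv_ml Stroke volume, mL.
#' @param hr_bpm Heart rate, beats/min.
#' @param bsa_m2 Body surface area, m^2.
#' @return A \code{hemo_summary}: \code{sv_ml}, \code{hr_bpm},
#'   \code{co_l_min}, \code{bsa_m2}, \code{sv_index_ml_m2},
#'   \code{ci_l_min_m2}.
#' @export
summarize_hemodynamics <- function(sv_ml, hr_bpm, bsa_m2) {
  if (sv_ml <= 0 || hr_bpm <= 0 || bsa_m2 <= 0)
    stop("domain error: sv, hr and bsa must all be positive")
  co <- sv_ml * hr_bpm / 1000
  structure(list(sv_ml = sv_ml, hr_bpm = hr_bpm, co_l_min = co,
                 bsa_m2 = bsa_m2, sv_index_ml_m2 = sv_ml / bsa_m2,
                 ci_l_min_m2 = co / bsa_m2),
            class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf("<hemo_summary> SV %.1f mL, HR %.1f bpm, CO %.2f L/min\n",
              x$sv_ml, x$hr_bpm, x$co_l_min))
  cat(sprintf("  indexed by BSA %.2f m^2: SVi %.1f mL/m^2, CI %.2f L/min/m^2\n",
              x$bsa_m2, x$sv_index_ml_m2, x$ci_l_min_m2))
  invisible(x)
}

#' Du Bois body surface area
#'
#' BSA = 0.007184 * weight^0.425 * height^0.725, weight in kg, height
#' in cm. Offered as a helper when BSA is not recorded directly.
#'
#' @param weight_kg Body mass, kg.
#' @param height_cm Height, cm.
#' @return BSA in m^2.
#' @export
bsa_du_bois <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}
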