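#' Detect stationary tissue
#'
#' A voxel is classed as stationary tissue when its time-averaged signal
#' magnitude is at or above a magnitude quantile (bright enough to carry
#' reliable phase) and the temporal standard deviation of its speed is
#' at or below a velocity threshold (no pulsatile motion). This is the
#' automatic counterpart of semi-automatic magnitude/velocity
#' thresholding; both thresholds are exposed.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param magnitude_quantile Quantile of the time-averaged magnitude
#'   used as the brightness cut (default 0.25).
#' @param velocity_sd_max Maximum temporal SD of speed, m/s. Default
#'   NULL sets it adaptively to the 10th percentile of the temporal SD
#'   distribution over the volume.
#' @return A \code{\link{chamber_mask}} labelled "stationary".
#' @export
stationary_mask <- function(field, magnitude_quantile = 0.25,
                            velocity_sd_max = NULL) {
  d <- field_dims(field)
  np <- n_phases(field)
  nv <- prod(d)
  mag_avg <- rowMeans(matrix(field$magnitude, nv, np))
  speed <- matrix(sqrt(field$vx^2 + field$vy^2 + field$vz^2), nv, np)
  sp_mean <- rowMeans(speed)
  sp_sq <- rowMeans(speed^2)
  sp_sd <- sqrt(pmax(0, (sp_sq - sp_mean^2) * np / (np - 1)))
  if (is.null(velocity_sd_max))
    velocity_sd_max <- stats::quantile(sp_sd, 0.10, names = FALSE)
  mag_thr <- stats::quantile(mag_avg, magnitude_quantile, names = FALSE)
  m <- mag_avg >= mag_thr & sp_sd <= velocity_sd_max
  if (!any(m))
    stop(paste("threshold error: stationary mask is empty;",
               "lower magnitude_quantile or raise velocity_sd_max"))
  chamber_mask(array(m, dim = d), "stationary")
}

#' Fit a polynomial background phase model
#'
#' Least-squares fit, per velocity component, of the time-averaged
#' velocity over stationary-tissue voxels against 3rd-order (by
#' default) monomials in coordinates normalized to [-1, 1] per axis.
#' Solved by QR decomposition; a rank-deficient design (e.g. a mask
#' confined to a plane) is rejected.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param mask Stationary-tissue \code{\link{chamber_mask}} with at
#'   least as many voxels as monomials.
#' @param order Polynomial order (default 3, giving 20 monomials).
#' @return A \code{background_model}: \code{coeffs} (n_monomials x 3
#'   matrix, columns vx/vy/vz), \code{fit_rmse} (m/s per component),
#'   \code{n_fit_voxels}, \code{order}, \code{dims}.
#' @export
fit_background <- function(field, mask, order = 3) {
  check_mask_field(mask, field)
  d <- field_dims(field)
  sel <- which(mask$voxels)
  basis_all <- poly_basis(grid_coords_norm(d), order)
  X <- basis_all[sel, , drop = FALSE]
  if (length(sel) < ncol(X))
    stop(sprintf("mask has %d voxels but the order-%d fit needs at least %d",
                 length(sel), order, ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("conditioning error: rank-deficient design (mask geometry too degenerate)")
  coeffs <- matrix(0, ncol(X), 3,
                   dimnames = list(colnames(X), c("vx", "vy", "vz")))
  rmse <- numeric(3)
  for (ci in 1:3) {
    comp <- c("vx", "vy", "vz")[ci]
    y <- rowMeans(matrix(field[[comp]], prod(d), n_phases(field))[sel, , drop = FALSE])
    beta <- qr.coef(qrX, y)
    coeffs[, ci] <- beta
    rmse[ci] <- sqrt(mean((y - X %*% beta)^2))
  }
  structure(list(coeffs = coeffs, fit_rmse = rmse,
                 n_fit_voxels = length(sel), order = order, dims = d),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> order %d, %d voxels fitted\n",
              x$order, x$n_fit_voxels))
  cat(sprintf("  RMSE (m/s): vx %.3g, vy %.3g, vz %.3g\n",
              x$fit_rmse[1], x$fit_rmse[2], x$fit_rmse[3]))
  invisible(x)
}

#' Subtract a fitted background phase model
#'
#' Evaluates the fitted polynomial at every voxel and subtracts it from
#' every cardiac phase of each velocity component; the magnitude is
#' untouched. Linear: subtracting model A then model B equals
#' subtracting the coefficient-sum model.
#'
#' @param field A \code{\link{velocity_field}}.
#' @param model A \code{background_model} fitted on the same grid.
#' @return The corrected \code{\link{velocity_field}}.
#' @export
subtract_background <- function(field, model) {
  d <- field_dims(field)
  if (!identical(as.integer(model$dims), as.integer(d)))
    stop("shape error: background model was fitted on a different grid")
  add_background_offset(field, -model$coeffs)
}
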