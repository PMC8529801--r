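#' Write a velocity field to a directory
#'
#' Four 4-D NIfTI volumes (vx, vy, vz, magnitude; layout x, y, z,
#' phase with phase slowest on disk) with the voxel size in the header,
#' plus a \code{meta.json} sidecar recording voxel size, RR interval,
#' phase times and the velocity unit (m/s; nothing is rescaled on
#' read or write).
#'
#' @param field A \code{\link{velocity_field}}.
#' @param dir Output directory (created if needed).
#' @param compress Write .nii.gz (default) rather than .nii.
#' @return Invisibly, \code{dir}.
#' @export
write_field <- function(field, dir, compress = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (compress) ".nii.gz" else ".nii"
  dt_ms <- field$rr_ms / n_phases(field)
  for (nm in c("vx", "vy", "vz", "magnitude")) {
    img <- RNifti::asNifti(field[[nm]])
    RNifti::pixdim(img) <- c(rep(field$voxel_size, 3), dt_ms)
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ext)))
  }
  meta <- list(voxel_size_mm = field$voxel_size, rr_ms = field$rr_ms,
               phase_times_ms = field$phase_times, velocity_unit = "m/s")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

find_volume <- function(dir, stem) {
  for (ext in c(".nii.gz", ".nii")) {
    p <- file.path(dir, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  stop(sprintf("format error: volume '%s' not found in %s", stem, dir))
}

#' Read a velocity field from a directory
#'
#' Reads the four volumes written by \code{\link{write_field}},
#' validating that all headers agree on shape and voxel size and that
#' the metadata sidecar carries the RR interval.
#'
#' @param dir Directory containing vx/vy/vz/magnitude volumes and
#'   \code{meta.json}.
#' @return A \code{\link{velocity_field}}.
#' @export
read_field <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("format error: meta.json not found (rr_ms metadata is required)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$rr_ms))
    stop("format error: meta.json lacks rr_ms")
  vols <- lapply(c("vx", "vy", "vz", "magnitude"), function(nm) {
    img <- RNifti::readNifti(find_volume(dir, nm))
    list(data = array(as.numeric(img), dim = dim(img)),
         pix = RNifti::pixdim(img)[1])
  })
  shapes <- lapply(vols, function(v) dim(v$data))
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stop("format error: component volumes disagree on grid shape")
  pix <- vapply(vols, `[[`, 1, "pix")
  if (max(abs(pix - pix[1])) > 1e-6)
    stop("format error: component volumes disagree on voxel size")
  if (!is.null(meta$voxel_size_mm) &&
      abs(meta$voxel_size_mm - pix[1]) > 1e-4)
    stop("format error: header voxel size disagrees with meta.json")
  velocity_field(vols[[1]]$data, vols[[2]]$data, vols[[3]]$data,
                 vols[[4]]$data, voxel_size = pix[1], rr_ms = meta$rr_ms,
                 phase_times = meta$phase_times_ms)
}

#' Write / read a chamber mask as 8-bit NIfTI
#'
#' Masks are stored with 0/1 values; on read any nonzero voxel is
#' treated as true (tolerant of 255-valued exports).
#'
#' @param mask A \code{\link{chamber_mask}}.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Voxel size recorded in the header, mm.
#' @return \code{write_mask}: invisibly, \code{path};
#'   \code{read_mask}: a \code{\link{chamber_mask}}.
#' @export
write_mask <- function(mask, path, voxel_size = 1.25) {
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @param label Label for the mask read back.
#' @export
read_mask <- function(path, label = "mask") {
  img <- RNifti::readNifti(path)
  chamber_mask(array(as.numeric(img) != 0, dim = dim(img)), label)
}

#' Write a trigger log as tab-separated text
#'
#' Two columns: \code{event_type} (trigger or projection) and
#' \code{time_ms}, sorted within each type.
#'
#' @param log A \code{\link{trigger_log}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_trigger_log <- function(log, path) {
  df <- rbind(
    data.frame(event_type = rep("trigger", length(log$trigger_times)),
               time_ms = log$trigger_times),
    data.frame(event_type = rep("projection", length(log$projection_times)),
               time_ms = log$projection_times))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trigger log from tab-separated text
#'
#' Expects the two-column format of \code{\link{write_trigger_log}}.
#' A malformed row raises an error naming its line number.
#'
#' @param path Input path.
#' @return A \code{\link{trigger_log}}.
#' @export
read_trigger_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("format error: empty trigger log")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("event_type", "time_ms")))
    stop("format error: expected header 'event_type\\ttime_ms'")
  trig <- numeric(0); proj <- numeric(0)
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    t <- suppressWarnings(as.numeric(f[2]))
    if (length(f) != 2 || !f[1] %in% c("trigger", "projection") || is.na(t))
      stop(sprintf("format error in trigger log at line %d: '%s'", i, lines[i]))
    if (f[1] == "trigger") trig <- c(trig, t) else proj <- c(proj, t)
  }
  trigger_log(sort(trig), sort(proj))
}

#' Write / read a measurement plane as JSON
#'
#' Fields: origin (mm), normal (renormalized on read; zero rejected),
#' half_extent (mm), sample_spacing (mm). Missing fields raise a format
#' error naming the field.
#'
#' @param plane A \code{\link{measurement_plane}}.
#' @param path JSON file path.
#' @return \code{write_plane}: invisibly, \code{path};
#'   \code{read_plane}: a \code{\link{measurement_plane}}.
#' @export
write_plane <- function(plane, path) {
  jsonlite::write_json(list(origin = plane$origin, normal = plane$normal,
                            half_extent = plane$half_extent,
                            sample_spacing = plane$sample_spacing),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("origin", "normal", "half_extent", "sample_spacing"))
    if (is.null(x[[f]]))
      stop(sprintf("format error: plane JSON lacks field '%s'", f))
  measurement_plane(x$origin, x$normal, x$half_extent, x$sample_spacing)
}

#' Write a respiratory waveform as tab-separated text
#'
#' @param resp A \code{\link{resp_waveform}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_resp_waveform <- function(resp, path) {
  utils::write.table(data.frame(time_ms = resp$sample_times,
                                value = resp$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resp_waveform
#' @export
read_resp_waveform <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("time_ms", "value") %in% names(df)))
    stop("format error: respiratory waveform needs columns time_ms, value")
  resp_waveform(df$time_ms, df$value)
}
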