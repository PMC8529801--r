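#' @name gating
#' @title Retrospective ECG and respiratory gating
#' @description
#' Tools to assess trigger-log quality (the 5\% late-projection rule),
#' repair logs compromised by missed ECG triggers, apply respiratory
#' gating at a target efficiency, and bin projections into cardiac
#' phases. Cardiac time of a projection is the time elapsed since the
#' most recent preceding trigger; a log is flagged as compromised when
#' more than 5\% of projections have cardiac time exceeding the median
#' RR interval (lower median for even counts).
NULL

# Cardiac time of each projection (ms since most recent preceding
# trigger) and the index of that trigger; NA before the first trigger.
cardiac_times <- function(log) {
  tt <- log$trigger_times
  pt <- log$projection_times
  idx <- findInterval(pt, tt)
  ct <- rep(NA_real_, length(pt))
  has <- idx >= 1
  ct[has] <- pt[has] - tt[idx[has]]
  list(cardiac_time = ct, beat_index = ifelse(has, idx, NA_integer_))
}

#' Assess a trigger log for compromised gating
#'
#' @param log A \code{\link{trigger_log}} with at least two triggers and
#'   one projection.
#' @param late_threshold Fraction of late projections above which the
#'   log is flagged for correction (default 0.05).
#' @return A \code{gating_report}: \code{median_rr_ms},
#'   \code{late_fraction}, \code{corrected} (flag recommending
#'   correction), \code{n_inserted_triggers}, \code{mean_hr_bpm}.
#' @export
assess_gating <- function(log, late_threshold = 0.05) {
  if (length(log$trigger_times) < 2)
    stop("insufficient data: at least two triggers required")
  if (length(log$projection_times) < 1)
    stop("insufficient data: at least one projection required")
  rr <- diff(log$trigger_times)
  med <- lower_median(rr)
  ct <- cardiac_times(log)$cardiac_time
  ok <- !is.na(ct)
  late <- sum(ct[ok] > med) / sum(ok)
  structure(list(median_rr_ms = med, late_fraction = late,
                 corrected = late > late_threshold,
                 n_inserted_triggers = 0L,
                 mean_hr_bpm = 60000 / mean(rr)),
            class = "gating_report")
}

#' @export
print.gating_report <- function(x, ...) {
  cat(sprintf(paste0("<gating_report> median RR %.1f ms, late fraction %.3f,",
                     " mean HR %.1f bpm\n  correction %s (%d triggers inserted)\n"),
              x$median_rr_ms, x$late_fraction, x$mean_hr_bpm,
              if (x$corrected) "indicated/applied" else "not indicated",
              x$n_inserted_triggers))
  invisible(x)
}

#' Repair a compromised trigger log
#'
#' Every recorded RR interval longer than \code{split_threshold} times
#' the median RR is interpreted as k merged beats, k = round(interval /
#' median RR), and split by inserting k - 1 synthetic triggers spaced
#' uniformly. Original triggers and projection timestamps are never
#' altered. Clean logs (late fraction at or below the detection
#' threshold) are returned unchanged. The repair is idempotent.
#'
#' @param log A \code{\link{trigger_log}}.
#' @param split_threshold Interval/median ratio above which an interval
#'   is split (default 1.5).
#' @param late_threshold Detection threshold on the late fraction
#'   (default 0.05).
#' @param reassess If TRUE, run one further assess-and-repair pass on
#'   the corrected log (default FALSE).
#' @param force If TRUE, split over-long intervals even when the
#'   late-projection fraction is below the detection threshold. A log
#'   without merged beats is unchanged (no interval exceeds the split
#'   threshold), so forcing is harmless on clean logs; it removes the
#'   residual heart-rate bias of logs with a few missed beats that sit
#'   just below the detection gate. Recommended for heart-rate
#'   estimation; the default FALSE follows the detection rule.
#' @return A list: \code{log} (corrected \code{\link{trigger_log}}) and
#'   \code{report} (a \code{gating_report} for the corrected log, with
#'   \code{n_inserted_triggers} accumulated).
#' @export
correct_triggers <- function(log, split_threshold = 1.5,
                             late_threshold = 0.05, reassess = FALSE,
                             force = FALSE) {
  rep0 <- assess_gating(log, late_threshold)
  if (!rep0$corrected && !force) return(list(log = log, report = rep0))
  tt <- log$trigger_times
  rr <- diff(tt)
  med <- rep0$median_rr_ms
  new_tt <- tt[1]
  inserted <- 0L
  for (i in seq_along(rr)) {
    if (rr[i] > split_threshold * med) {
      k <- max(1L, as.integer(round(rr[i] / med)))
      if (k > 1) {
        ins <- tt[i] + rr[i] * seq_len(k - 1) / k
        new_tt <- c(new_tt, ins)
        inserted <- inserted + (k - 1L)
      }
    }
    new_tt <- c(new_tt, tt[i + 1])
  }
  out <- trigger_log(new_tt, log$projection_times)
  if (reassess) {
    res <- correct_triggers(out, split_threshold, late_threshold, FALSE)
    out <- res$log
    inserted <- inserted + res$report$n_inserted_triggers
  }
  rep1 <- assess_gating(out, late_threshold)
  rep1$corrected <- rep0$corrected || inserted > 0
  rep1$n_inserted_triggers <- inserted
  list(log = out, report = rep1)
}

#' Respiratory gating by adaptive thresholding
#'
#' Accepts the projections acquired closest to end-expiration so that
#' the requested gating efficiency is met: the adaptive threshold is the
#' order statistic of the interpolated belt value at rank
#' ceiling(efficiency * N). Ties at the threshold are all accepted, so
#' the accepted count can exceed the target by the tie count.
#'
#' @param log A \code{\link{trigger_log}} whose projections all fall
#'   inside the waveform's time span.
#' @param resp A \code{\link{resp_waveform}}.
#' @param efficiency Target acceptance fraction in (0, 1], default 0.5.
#' @param polarity "max" if end-expiration is the waveform maximum
#'   (default), "min" otherwise.
#' @return Integer indices of accepted projections.
#' @export
respiratory_gate <- function(log, resp, efficiency = 0.5,
                             polarity = c("max", "min")) {
  polarity <- match.arg(polarity)
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]")
  pt <- log$projection_times
  if (!length(pt)) return(integer(0))
  if (min(pt) < min(resp$sample_times) || max(pt) > max(resp$sample_times))
    stop("coverage error: projection times outside the respiratory waveform span")
  v <- stats::approx(resp$sample_times, resp$values, xout = pt)$y
  key <- if (polarity == "max") -v else v
  n_target <- ceiling(efficiency * length(pt))
  thr <- sort(key)[n_target]
  which(key <= thr)
}

#' Bin projections into cardiac phases
#'
#' Each projection is assigned phase floor(n_phases * cardiac_time / RR)
#' where RR is the interval of the beat it falls in (the median RR for
#' projections after the last trigger), clamped to n_phases - 1.
#' Projections before the first trigger, or whose cardiac time exceeds
#' their beat's RR, are rejected (phase NA).
#'
#' @param log A clean or corrected \code{\link{trigger_log}}.
#' @param n_phases Number of cardiac phases (default 15).
#' @return A data.frame (class \code{phase_assignment}) with one row per
#'   projection: \code{projection_time_ms}, \code{cardiac_time_ms},
#'   \code{rr_ms}, \code{phase_index} (0-based, NA if rejected).
#' @export
bin_projections <- function(log, n_phases = 15) {
  if (n_phases < 2) stop("configuration error: n_phases must be >= 2")
  if (length(log$trigger_times) < 2)
    stop("insufficient data: at least two triggers required")
  ct <- cardiac_times(log)
  rr_all <- diff(log$trigger_times)
  med <- lower_median(rr_all)
  rr_of <- rep(NA_real_, length(ct$cardiac_time))
  has <- !is.na(ct$beat_index)
  last <- length(log$trigger_times)
  interior <- has & ct$beat_index < last
  rr_of[interior] <- rr_all[ct$beat_index[interior]]
  rr_of[has & ct$beat_index == last] <- med
  phase <- floor(n_phases * ct$cardiac_time / rr_of)
  phase <- pmin(phase, n_phases - 1)
  phase[!has | ct$cardiac_time > rr_of] <- NA
  structure(data.frame(projection_time_ms = log$projection_times,
                       cardiac_time_ms = ct$cardiac_time,
                       rr_ms = rr_of, phase_index = as.integer(phase)),
            class = c("phase_assignment", "data.frame"))
}

#' Mean heart rate from a trigger log
#'
#' 60000 divided by the mean RR interval in ms. Apply
#' \code{\link{correct_triggers}} first when the log is compromised.
#'
#' @param log A \code{\link{trigger_log}} with at least two triggers.
#' @return Heart rate in beats/min.
#' @export
mean_heart_rate <- function(log) {
  if (length(log$trigger_times) < 2)
    stop("insufficient data: at least two triggers required")
  60000 / mean(diff(log$trigger_times))
}
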