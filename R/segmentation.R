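#' Five-minute segmentation and quality control
#'
#' Day-batched recordings are regularized onto the nominal-rate sample grid
#' anchored at local midnight and cut into fixed 5-minute segments
#' (00:00:00-23:59:59, 288 per day). Samples snap to the nearest grid slot;
#' duplicate hits are averaged. Gaps shorter than 30 s are linearly
#' interpolated within a segment; coverage is assessed before interpolation so
#' repair can never create validity.
#'
#' @name segmentation
NULL

SEGMENT_SECONDS <- 300L
SEGMENTS_PER_DAY <- 288L

#' Quality-control thresholds
#'
#' @param min_coverage_hr_temp minimum pre-repair coverage for HR and
#'   temperature segments (inclusive).
#' @param min_coverage_eda_ppg minimum coverage for EDA and BVP segments.
#' @param max_gap_s gaps strictly shorter than this are interpolated.
#' @param ibi_tolerance allowed relative mismatch between IBI beat count and
#'   the count implied by mean HR over the same segment.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_coverage_hr_temp = 0.50,
                          min_coverage_eda_ppg = 0.70,
                          max_gap_s = 30, ibi_tolerance = 0.10) {
  stopifnot(min_coverage_hr_temp > 0, min_coverage_hr_temp <= 1,
            min_coverage_eda_ppg > 0, min_coverage_eda_ppg <= 1,
            ibi_tolerance > 0, ibi_tolerance <= 1, max_gap_s > 0)
  structure(list(min_coverage_hr_temp = min_coverage_hr_temp,
                 min_coverage_eda_ppg = min_coverage_eda_ppg,
                 max_gap_s = max_gap_s, ibi_tolerance = ibi_tolerance),
            class = "qc_thresholds")
}

new_segment <- function(subject_id, day, slot, channel, fs, values, coverage) {
  structure(list(subject_id = subject_id, day = day, slot = slot,
                 channel = channel, fs = fs, values = values,
                 coverage = coverage),
            class = "wc_segment")
}

#' @export
print.wc_segment <- function(x, ...) {
  cat(sprintf("<segment> %s day %d slot %d (%02d:%02d) %s: coverage %.2f\n",
              x$subject_id, x$day, x$slot, (x$slot * 5) %/% 60,
              (x$slot * 5) %% 60, x$channel, x$coverage))
  invisible(x)
}

#' Segment one recording onto the daily 5-minute grid
#'
#' @param rec a [channel_recording()] (scalar channels only).
#' @param day local day index, i.e. `floor(local_time / 86400)`.
#' @param utc_offset fixed study UTC offset in seconds used to derive local
#'   clock time (the night window is wall-clock).
#' @param subject_id carried through to the segments.
#' @return list of `wc_segment` objects (segments with at least one observed
#'   sample); empty list if the recording does not overlap the day.
#' @export
segment_day <- function(rec, day, utc_offset = 0, subject_id = "s") {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$channel == "ACC") stop("segmentation operates on scalar channels")
  n <- n_samples(rec)
  if (n == 0L) return(list())
  fs <- rec$sampling_rate
  local0 <- rec$start_time + utc_offset - day * 86400
  t_loc <- local0 + (seq_len(n) - 1) / fs
  k <- as.integer(round(t_loc * fs))
  keep <- k >= 0L & k < as.integer(86400 * fs)
  if (!any(keep)) return(list())
  k <- k[keep]
  v <- rec$values[keep]
  if (!is.unsorted(k, strictly = TRUE)) {
    # already strictly on-grid: no duplicates to average
    slots_obs <- k
    vals_obs <- v
  } else {
    # average duplicate grid hits
    agg <- rowsum(v, k)
    cnt <- rowsum(rep(1, length(k)), k)
    slots_obs <- as.integer(rownames(agg))
    vals_obs <- agg[, 1L] / cnt[, 1L]
  }
  seg_len <- as.integer(SEGMENT_SECONDS * fs)
  seg_idx <- slots_obs %/% seg_len
  segs <- list()
  for (s in sort(unique(seg_idx))) {
    sel <- seg_idx == s
    offs <- slots_obs[sel] - s * seg_len + 1L
    vv <- rep(NA_real_, seg_len)
    vv[offs] <- vals_obs[sel]
    cov <- sum(sel) / seg_len
    segs[[length(segs) + 1L]] <-
      new_segment(subject_id, day, as.integer(s), rec$channel, fs, vv, cov)
  }
  segs
}

#' Linearly interpolate short interior gaps
#'
#' Missing runs strictly shorter than `max_gap_s` that have observed samples
#' on both sides are filled by linear interpolation; longer gaps and gaps at
#' segment edges are left missing. Observed samples are never altered and
#' coverage keeps its pre-repair value.
#'
#' @param seg a `wc_segment`.
#' @param max_gap_s gap-length threshold in seconds.
#' @return the repaired segment.
#' @export
fill_small_gaps <- function(seg, max_gap_s = 30) {
  v <- seg$values
  isna <- is.na(v)
  if (!any(isna) || all(isna)) return(seg)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max_len <- max_gap_s * seg$fs
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    if (r$lengths[i] >= max_len) next
    a <- starts[i] - 1L
    b <- ends[i] + 1L
    if (a < 1L || b > length(v)) next  # edge gap: no flank
    fill_idx <- starts[i]:ends[i]
    v[fill_idx] <- v[a] + (v[b] - v[a]) * (fill_idx - a) / (b - a)
  }
  seg$values <- v
  seg
}

#' Channel-specific coverage validity
#'
#' @param seg a `wc_segment`.
#' @param th a [qc_thresholds()].
#' @return `TRUE` iff pre-repair coverage meets the channel's threshold
#'   (inclusive).
#' @export
coverage_valid <- function(seg, th = qc_thresholds()) {
  thr <- switch(seg$channel,
    HR = , TEMP = th$min_coverage_hr_temp,
    EDA = , BVP = th$min_coverage_eda_ppg,
    stop("unknown channel for coverage validity: ", seg$channel))
  seg$coverage >= thr
}

#' IBI-vs-HR consistency check for a 5-minute segment
#'
#' The number of beats recorded in the IBI stream must be within
#' `tol` (relative) of the count implied by the mean HR over the same
#' segment (`mean HR [bpm] * 5 min`).
#'
#' @param n_ibi number of IBI events falling inside the segment.
#' @param hr_segment the HR `wc_segment` for the same window, or `NULL`.
#' @param tol relative tolerance (default 0.10).
#' @return logical flag; `FALSE` with a `reason` attribute when the HR
#'   segment is missing or empty or the count disagrees.
#' @export
ibi_beats_valid <- function(n_ibi, hr_segment, tol = 0.10) {
  if (is.null(hr_segment)) {
    return(structure(FALSE, reason = "missing HR segment"))
  }
  hr <- hr_segment$values
  if (all(is.na(hr))) return(structure(FALSE, reason = "empty HR segment"))
  expected <- mean(hr, na.rm = TRUE) * (SEGMENT_SECONDS / 60)
  if (n_ibi == 0L) return(structure(FALSE, reason = "no IBI events"))
  abs(n_ibi - expected) <= tol * expected
}

# Clip IBI events to one 5-minute window in local seconds-of-day.
ibi_in_window <- function(ev, day, slot, utc_offset = 0) {
  t_loc <- ev$start_time + utc_offset + ev$offsets - day * 86400
  lo <- slot * SEGMENT_SECONDS
  sel <- t_loc >= lo & t_loc < lo + SEGMENT_SECONDS
  list(times = t_loc[sel] - lo, durations = ev$durations[sel], n = sum(sel))
}
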