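#' Aggregation: from 5-minute feature rows to analysis intervals
#'
#' Segment-level feature rows are filtered to those with valid IBI (the most
#' sensitive indicator of proper device wear), restricted to the calmest 5-h
#' night window, reduced to daily medians (at least four valid samples per
#' day) and then to 10-day interval means, and finally pruned of redundant
#' features (squared Pearson correlation >= 0.95).
#'
#' @name aggregation
NULL

#' Keep only rows with valid IBI measures
#'
#' @param rows data.frame of segment feature rows with a logical
#'   `ibi_valid` column.
#' @return the filtered data.frame (idempotent).
#' @export
require_ibi <- function(rows) {
  out <- rows[isTRUE_vec(rows$ibi_valid), , drop = FALSE]
  if (nrow(out) == 0L) warning("no rows with valid IBI measures remain")
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' The calmest night window by rolling population mean HR
#'
#' Pools mean HR per 5-minute clock slot over all subjects and days, then
#' slides a contiguous `duration_h`-hour window over the candidate span and
#' returns the window minimizing the mean over slots with data. Candidate
#' windows with no data are excluded; ties go to the earliest start within
#' the span.
#'
#' @param hr_rows data.frame with columns `slot` (0-287) and `hr` (segment
#'   mean HR in bpm).
#' @param span_start_h,span_end_h candidate span in clock hours (may wrap
#'   midnight; default 21:00 to 09:00).
#' @param duration_h window length in hours.
#' @return list of class `night_window` with `start_slot`, `n_slots`,
#'   `start_hms` and the per-slot pooled means used.
#' @export
select_night_window <- function(hr_rows, span_start_h = 21, span_end_h = 9,
                                duration_h = 5) {
  slot_mean <- rep(NA_real_, SEGMENTS_PER_DAY)
  agg <- tapply(hr_rows$hr, factor(hr_rows$slot, levels = 0:287), mean,
                na.rm = TRUE)
  slot_mean[] <- as.numeric(agg)
  n_win <- as.integer(duration_h * 12)
  start0 <- as.integer(span_start_h * 12)
  end0 <- as.integer(span_end_h * 12)
  span_len <- (end0 - start0) %% SEGMENTS_PER_DAY
  if (span_len == 0L) span_len <- SEGMENTS_PER_DAY
  if (span_len < n_win) stop("candidate span shorter than window duration")
  starts <- (start0 + seq_len(span_len - n_win + 1L) - 1L) %% SEGMENTS_PER_DAY
  means <- vapply(starts, function(s) {
    sl <- (s + seq_len(n_win) - 1L) %% SEGMENTS_PER_DAY
    v <- slot_mean[sl + 1L]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(means))) stop("no candidate window has HR data")
  best <- which.min(means)   # first minimum = earliest start in span order
  structure(list(start_slot = starts[best], n_slots = n_win,
                 start_hms = sprintf("%02d:%02d", (starts[best] * 5) %/% 60,
                                     (starts[best] * 5) %% 60),
                 slot_means = means, starts = starts),
            class = "night_window")
}

#' @export
print.night_window <- function(x, ...) {
  cat(sprintf("<night_window> start %s, %d slots (%.1f h)\n",
              x$start_hms, x$n_slots, x$n_slots / 12))
  invisible(x)
}

#' Fixed night window (no data-driven selection)
#'
#' @param start_h window start in clock hours.
#' @param duration_h window length in hours.
#' @return a `night_window`.
#' @export
fixed_night_window <- function(start_h = 1, duration_h = 5) {
  structure(list(start_slot = as.integer(start_h * 12),
                 n_slots = as.integer(duration_h * 12),
                 start_hms = sprintf("%02d:%02d", as.integer(start_h), 0L),
                 slot_means = NULL, starts = NULL),
            class = "night_window")
}

# Is a clock slot inside the window? Handles midnight wrap.
slot_in_window <- function(slot, win) {
  rel <- (slot - win$start_slot) %% SEGMENTS_PER_DAY
  rel < win$n_slots
}

# Night date rule: a night belongs to the calendar date on which the window
# starts; slots that wrapped past midnight are assigned to the previous date.
night_of <- function(day, slot, win) {
  wraps <- win$start_slot + win$n_slots > SEGMENTS_PER_DAY
  if (!wraps) return(day)
  ifelse(slot >= win$start_slot, day, day - 1L)
}

#' Daily medians within the night window
#'
#' @param rows segment feature rows (one row per valid 5-min window) with
#'   columns `subject_id`, `day`, `slot` and feature columns.
#' @param win a `night_window`.
#' @param min_samples minimum number of valid 5-min samples for a day to be
#'   kept.
#' @param feature_cols character vector of feature column names.
#' @return data.frame keyed (`subject_id`, `night`) with per-feature medians
#'   and a `n_samples` provenance column.
#' @export
daily_aggregate <- function(rows, win, min_samples = 4L,
                            feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_registry()$name, names(rows))
  }
  rows <- rows[slot_in_window(rows$slot, win), , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(data.frame(subject_id = character(), night = integer(),
                      n_samples = integer()))
  }
  rows$night <- night_of(rows$day, rows$slot, win)
  key <- interaction(rows$subject_id, rows$night, drop = TRUE)
  pieces <- lapply(split(rows, key), function(d) {
    if (nrow(d) < min_samples) return(NULL)
    med <- vapply(feature_cols,
                  function(cl) median(d[[cl]], na.rm = TRUE), numeric(1))
    cbind(data.frame(subject_id = d$subject_id[1], night = d$night[1],
                     n_samples = nrow(d)),
          as.data.frame(as.list(med)))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(data.frame(subject_id = character(), night = integer(),
                      n_samples = integer()))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject_id, out$night), , drop = FALSE]
}

#' Ten-day interval means of daily medians
#'
#' Interval `i` covers days `[10(i-1)+1, 10i]` relative to each subject's
#' first observed night; feature values are means of the available daily
#' medians, and a row exists only if the interval has at least one valid day.
#'
#' @param daily output of [daily_aggregate()].
#' @param interval_days days per interval.
#' @param observation_days total observation span (days beyond it are
#'   dropped).
#' @param feature_cols feature column names.
#' @return data.frame keyed (`subject_id`, `interval`) with feature means and
#'   a `n_days` provenance column.
#' @export
interval_aggregate <- function(daily, interval_days = 10L,
                               observation_days = 70L, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_registry()$name, names(daily))
  }
  if (nrow(daily) == 0L) {
    return(data.frame(subject_id = character(), interval = integer(),
                      n_days = integer()))
  }
  first <- stats::ave(daily$night, daily$subject_id, FUN = min)
  rel <- daily$night - first + 1L
  keep <- rel <= observation_days
  daily <- daily[keep, , drop = FALSE]
  rel <- rel[keep]
  daily$interval <- as.integer(ceiling(rel / interval_days))
  key <- interaction(daily$subject_id, daily$interval, drop = TRUE)
  pieces <- lapply(split(daily, key), function(d) {
    mu <- vapply(feature_cols,
                 function(cl) mean(d[[cl]], na.rm = TRUE), numeric(1))
    mu[is.nan(mu)] <- NA_real_
    cbind(data.frame(subject_id = d$subject_id[1], interval = d$interval[1],
                     n_days = nrow(d)),
          as.data.frame(as.list(mu)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$subject_id, out$interval), , drop = FALSE]
}

#' Greedy redundancy pruning of the feature matrix
#'
#' Walks features in frozen registry order; a feature is dropped if its
#' squared Pearson correlation with any already-kept feature meets the
#' threshold. Zero-variance (or all-missing) features are dropped first.
#'
#' @param X numeric matrix or data.frame of interval-level feature values
#'   (columns named by registry features).
#' @param r2_threshold squared-correlation threshold (inclusive).
#' @return list with `kept` (character), `dropped` (data.frame `name`,
#'   `reason`).
#' @export
drop_redundant_features <- function(X, r2_threshold = 0.95) {
  X <- as.data.frame(X)
  ord <- intersect(feature_registry()$name, names(X))
  if (length(ord) == 0L) ord <- names(X)
  kept <- character()
  dropped <- data.frame(name = character(), reason = character())
  keep_mat <- NULL
  for (nm in ord) {
    v <- X[[nm]]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0 ||
        is.na(stats::sd(v, na.rm = TRUE))) {
      dropped <- rbind(dropped, data.frame(name = nm, reason = "zero variance"))
      next
    }
    if (length(kept)) {
      r2 <- vapply(kept, function(k) {
        r <- suppressWarnings(stats::cor(v, X[[k]],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else r^2
      }, numeric(1))
      if (any(r2 >= r2_threshold)) {
        dropped <- rbind(dropped,
                         data.frame(name = nm, reason = "redundant"))
        next
      }
    }
    kept <- c(kept, nm)
  }
  list(kept = kept, dropped = dropped)
}
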