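#' E4-dialect channel and event I/O
#'
#' One directory per subject-session holds `BVP.csv`, `EDA.csv`, `TEMP.csv`,
#' `HR.csv`, `IBI.csv` and optionally `ACC.csv`. Channel files carry a
#' two-line header (start UTC timestamp in seconds, then sampling rate in Hz)
#' followed by one sample per line (comma-separated x,y,z triplets for ACC).
#' IBI files carry the start timestamp followed by `offset,duration` pairs in
#' seconds; they have no rate line because beats are irregular events.
#'
#' @name io_e4
NULL

CHANNELS <- c("BVP", "EDA", "TEMP", "HR", "ACC")
NOMINAL_RATE <- c(BVP = 64, EDA = 4, TEMP = 4, HR = 1, ACC = 32)

#' Construct a uniformly sampled channel recording
#'
#' @param channel one of `"BVP"`, `"EDA"`, `"TEMP"`, `"HR"`, `"ACC"`.
#' @param start_time UTC start time in seconds.
#' @param sampling_rate sampling rate in Hz, strictly positive.
#' @param values numeric sample vector (n x 3 matrix for ACC). The timestamp
#'   of sample `i` is `start_time + (i-1)/sampling_rate`.
#' @return an object of class `channel_recording`.
#' @export
channel_recording <- function(channel, start_time, sampling_rate, values) {
  channel <- match.arg(channel, CHANNELS)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (channel == "ACC") {
    values <- as.matrix(values)
    if (ncol(values) != 3L) stop("ACC values must be an n x 3 matrix")
  } else {
    values <- as.numeric(values)
  }
  structure(
    list(channel = channel, start_time = as.numeric(start_time),
         sampling_rate = as.numeric(sampling_rate), values = values),
    class = "channel_recording"
  )
}

#' @export
print.channel_recording <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat(sprintf("<channel_recording> %s: %d samples @ %g Hz from t=%.3f (%.1f s)\n",
              x$channel, n, x$sampling_rate, x$start_time,
              n / x$sampling_rate))
  invisible(x)
}

n_samples <- function(rec) {
  if (is.matrix(rec$values)) nrow(rec$values) else length(rec$values)
}

# Timestamps of samples, affine in index with slope 1/rate.
rec_times <- function(rec) {
  rec$start_time + (seq_len(n_samples(rec)) - 1) / rec$sampling_rate
}

#' Construct an inter-beat-interval event list
#'
#' @param start_time UTC start time in seconds.
#' @param offsets seconds since `start_time` of each beat, strictly increasing.
#' @param durations inter-beat interval in seconds, each in (0, `max_ibi`).
#' @param max_ibi physiological upper bound on a beat interval, seconds.
#' @return an object of class `ibi_events`.
#' @export
ibi_events <- function(start_time, offsets = numeric(), durations = numeric(),
                       max_ibi = 3.0) {
  if (length(offsets) != length(durations)) {
    stop("offsets and durations must have equal length")
  }
  if (length(offsets) > 1L && any(diff(offsets) <= 0)) {
    stop("IBI offsets must be strictly increasing")
  }
  if (any(durations <= 0)) stop("IBI durations must be positive")
  if (any(durations >= max_ibi)) {
    stop(sprintf("IBI durations must be below %g s", max_ibi))
  }
  structure(
    list(start_time = as.numeric(start_time), offsets = as.numeric(offsets),
         durations = as.numeric(durations)),
    class = "ibi_events"
  )
}

#' @export
print.ibi_events <- function(x, ...) {
  cat(sprintf("<ibi_events> %d beats from t=%.3f\n",
              length(x$offsets), x$start_time))
  invisible(x)
}

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read a channel file in the E4 dialect
#'
#' @param path file path.
#' @param channel channel name; decides ACC triplet handling and validation.
#' @return a [channel_recording()].
#' @export
read_channel <- function(path, channel) {
  channel <- match.arg(channel, CHANNELS)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed header in ", path, ": expected start time on row 1 and sampling rate on row 2")
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_time)) stop("malformed header in ", path, ": row 1 is not a numeric start timestamp")
  rate <- suppressWarnings(as.numeric(lines[2L]))
  if (is.na(rate)) stop("malformed header in ", path, ": row 2 is not a numeric sampling rate")
  if (rate <= 0) stop("non-positive sampling rate in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (channel == "ACC") {
    if (length(body) == 0L) {
      vals <- matrix(numeric(), ncol = 3L)
    } else {
      parts <- strsplit(body, ",", fixed = TRUE)
      if (any(lengths(parts) != 3L)) {
        stop("malformed ACC row in ", path, ": expected x,y,z triplets")
      }
      vals <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
    }
  } else {
    vals <- as.numeric(body)
    if (anyNA(vals)) stop("malformed sample row in ", path)
  }
  channel_recording(channel, start_time, rate, vals)
}

#' Write a channel recording in the E4 dialect
#'
#' @param rec a [channel_recording()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(rec, path) {
  stopifnot(inherits(rec, "channel_recording"))
  if (rec$channel == "ACC") {
    body <- apply(rec$values, 1L, function(r) paste(fmt_full(r), collapse = ","))
    body <- as.character(body)
  } else {
    body <- fmt_full(rec$values)
    if (n_samples(rec) == 0L) body <- character()
  }
  writeLines(c(fmt_full(rec$start_time), fmt_full(rec$sampling_rate), body), path)
  invisible(path)
}

#' Read an IBI event file
#'
#' @param path file path; row 1 is the start timestamp, rows 2+ are
#'   `offset,duration` pairs in seconds.
#' @return an [ibi_events()].
#' @export
read_ibi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("malformed header in ", path, ": expected start timestamp on row 1")
  start_time <- suppressWarnings(as.numeric(lines[1L]))
  if (is.na(start_time)) stop("malformed header in ", path, ": row 1 is not numeric")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(ibi_events(start_time))
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed IBI row in ", path)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  ibi_events(start_time, m[, 1L], m[, 2L])
}

#' Write an IBI event file
#'
#' @param ev an [ibi_events()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_ibi <- function(ev, path) {
  stopifnot(inherits(ev, "ibi_events"))
  body <- if (length(ev$offsets)) {
    paste(fmt_full(ev$offsets), fmt_full(ev$durations), sep = ",")
  } else character()
  writeLines(c(fmt_full(ev$start_time), body), path)
  invisible(path)
}

#' Read / write the subject table
#'
#' `subjects.csv` columns: `subject_id`, `age` (years), `sex`
#' (`"female"`/`"male"`).
#'
#' @param path file path.
#' @param age_range permitted age range for validation (the study enrolled
#'   50-70 year olds; widen for synthetic cohorts if needed).
#' @return data.frame with one row per subject.
#' @export
read_subjects <- function(path, age_range = c(18, 110)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "age", "sex")
  if (!all(req %in% names(df))) stop("subjects table must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in subjects table")
  if (!all(df$sex %in% c("female", "male"))) stop("sex must be 'female' or 'male'")
  if (any(df$age < age_range[1] | df$age > age_range[2])) {
    stop("age outside configured study range")
  }
  df
}

#' @rdname read_subjects
#' @param subjects data.frame as returned by [read_subjects()].
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Read / write the assessments table
#'
#' Long form: `subject_id`, `composite`, `timepoint` (`"baseline"`/`"post"`),
#' `z`, `day` (integer study-day index of the assessment). Each subject must
#' have both timepoints for all five composites, with `post` after `baseline`.
#'
#' @param path file path.
#' @return data.frame in long form.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "composite", "timepoint", "z", "day")
  if (!all(req %in% names(df))) stop("assessments table must have columns ", paste(req, collapse = ", "))
  if (!all(df$timepoint %in% c("baseline", "post"))) stop("timepoint must be 'baseline' or 'post'")
  for (sid in unique(df$subject_id)) {
    d <- df[df$subject_id == sid, ]
    for (comp in COMPOSITES) {
      b <- d$day[d$composite == comp & d$timepoint == "baseline"]
      p <- d$day[d$composite == comp & d$timepoint == "post"]
      if (length(b) != 1L || length(p) != 1L) {
        stop("subject ", sid, " lacks a complete baseline/post pair for ", comp)
      }
      if (p <= b) stop("post day must be after baseline day for subject ", sid)
    }
  }
  df
}

#' @rdname read_assessments
#' @param assessments data.frame as returned by [read_assessments()].
#' @export
write_assessments <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE)
  invisible(path)
}
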