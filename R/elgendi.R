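#' Systolic peak detection in BVP by two moving averages
#'
#' The Elgendi detector: band-pass the raw pulse signal (Butterworth order 2,
#' 0.5-8 Hz, zero phase), clip negative excursions and square; compare a short
#' moving average (peak scale, ~111 ms) against a long one (beat scale,
#' ~667 ms) plus an offset `beta * mean(squared signal)`; contiguous blocks
#' where the short average exceeds that threshold and that are at least one
#' peak-window wide each contribute one beat at the block's squared-signal
#' maximum.
#'
#' @param x numeric BVP samples (a valid 5-min segment; interior NAs are
#'   interpolated, edge NAs zeroed).
#' @param fs sampling rate in Hz (64 for the E4).
#' @param w_peak,w_beat moving-average window lengths in seconds.
#' @param beta threshold offset as a fraction of the mean squared signal.
#' @return an [nn_series()] with `source = "PPG"`; empty with a `reason`
#'   attribute when fewer than 2 peaks are found.
#' @export
elgendi_peaks <- function(x, fs = 64, w_peak = 0.111, w_beat = 0.667,
                          beta = 0.02) {
  empty <- function(reason) {
    structure(list(times = numeric(), intervals = numeric(), source = "PPG"),
              class = "nn_series", reason = reason)
  }
  if (fs < 16) stop("sampling rate too low to resolve the pulse template")
  x <- interp_na(x)
  x[is.na(x)] <- 0
  n <- length(x)
  if (n < fs) return(empty("segment too short"))
  bp <- smooth_filter(x, fs, c(0.5, 8), order = 2, type = "pass")
  y <- pmax(bp, 0)^2
  if (all(y == 0)) return(empty("flat signal"))
  w1 <- max(1L, as.integer(round(w_peak * fs)))
  w2 <- max(w1 + 1L, as.integer(round(w_beat * fs)))
  ma <- function(v, w) {
    cs <- cumsum(c(0, v))
    lo <- pmax(0L, seq_len(n) - (w %/% 2L) - 1L)
    hi <- pmin(n, seq_len(n) + ((w - 1L) %/% 2L))
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  ma_peak <- ma(y, w1)
  ma_beat <- ma(y, w2)
  thr <- ma_beat + beta * mean(y)
  blocks <- ma_peak > thr
  r <- rle(blocks)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer()
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] < w1) next
    blk <- starts[i]:ends[i]
    peaks[length(peaks) + 1L] <- blk[which.max(y[blk])]
  }
  if (length(peaks) < 2L) return(empty("fewer than 2 peaks"))
  times <- (peaks - 1L) / fs
  structure(list(times = times[-1L], intervals = diff(times) * 1000,
                 source = "PPG"),
            class = "nn_series", peak_times = times)
}
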