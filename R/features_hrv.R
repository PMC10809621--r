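#' Heart-rate-variability features
#'
#' Time-domain, frequency-domain and nonlinear (Poincare, asymmetry,
#' fragmentation) HRV measures computed from a cleaned normal-to-normal
#' interval series. The same catalogue is computed twice per segment: from the
#' device IBI stream and from beats detected in the raw BVP signal.
#'
#' @name hrv
NULL

#' Construct a normal-to-normal interval series
#'
#' @param intervals beat-to-beat intervals in milliseconds.
#' @param times beat times in seconds (defaults to the cumulative sum of
#'   intervals anchored at 0).
#' @param source `"IBI"` or `"PPG"`.
#' @return object of class `nn_series`.
#' @export
nn_series <- function(intervals, times = NULL, source = "IBI") {
  source <- match.arg(source, c("IBI", "PPG"))
  intervals <- as.numeric(intervals)
  if (any(intervals <= 0)) stop("NN intervals must be positive")
  if (is.null(times)) times <- cumsum(intervals) / 1000
  if (length(times) != length(intervals)) {
    stop("times and intervals must have equal length")
  }
  structure(list(times = as.numeric(times), intervals = intervals,
                 source = source),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d beats (%s), mean NN %.1f ms\n",
              length(x$intervals), x$source,
              if (length(x$intervals)) mean(x$intervals) else NA_real_))
  invisible(x)
}

#' Drop physiologically implausible intervals
#'
#' Keeps intervals strictly inside (`lo`, `hi`) ms and re-derives beat times
#' from the retained intervals.
#'
#' @param nn an [nn_series()].
#' @param lo,hi open interval of plausible NN durations in ms.
#' @return a cleaned [nn_series()].
#' @export
clean_nn <- function(nn, lo = 200, hi = 3000) {
  keep <- nn$intervals > lo & nn$intervals < hi
  ints <- nn$intervals[keep]
  if (length(ints) == 0L) {
    return(structure(list(times = numeric(), intervals = numeric(),
                          source = nn$source), class = "nn_series"))
  }
  nn_series(ints, source = nn$source)
}

hrv_time_names <- c("MeanNN", "SDNN", "RMSSD", "SDSD", "CVNN", "CVSD",
                    "MedianNN", "MADNN", "MCVNN", "IQRNN", "pNN50", "pNN20",
                    "MinNN", "MaxNN", "RangeNN", "HTI")
hrv_freq_names <- c("LF", "HF", "VHF", "TotalPower", "LFHF", "LFn", "HFn",
                    "LnHF")
hrv_nonlinear_names <- c("SD1", "SD2", "SD1SD2", "EllipseArea", "CSI", "CVI",
                         "CSIModified", "GuzikIndex", "PortaIndex",
                         "PIP", "IALS", "PSS", "PAS",
                         "SD1d", "SD1a", "C1d", "C1a", "SD2d", "SD2a",
                         "C2d", "C2a", "SDNNd", "SDNNa", "Cd", "Ca")

#' Time-domain HRV features
#'
#' SDNN and SDSD use the sample standard deviation (ddof 1); pNN thresholds
#' are strict (`|delta| > 50` resp. `20` ms); MADNN uses the 1.4826
#' normal-consistency factor; HTI is the total beat count divided by the
#' modal histogram bin count at the conventional 1/128 s bin width.
#'
#' @param nn an [nn_series()] with at least 2 intervals.
#' @return named numeric vector over the time-domain catalogue (`NA`s with a
#'   `reason` attribute when the series is too short).
#' @export
hrv_time <- function(nn) {
  out <- setNames(rep(NA_real_, length(hrv_time_names)), hrv_time_names)
  x <- nn$intervals
  n <- length(x)
  if (n < 2L) return(structure(out, reason = "fewer than 2 intervals"))
  d <- diff(x)
  out["MeanNN"] <- mean(x)
  out["SDNN"] <- sd(x)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["SDSD"] <- if (length(d) >= 2L) sd(d) else NA_real_
  out["CVNN"] <- out["SDNN"] / out["MeanNN"]
  out["CVSD"] <- out["RMSSD"] / out["MeanNN"]
  out["MedianNN"] <- median(x)
  out["MADNN"] <- 1.4826 * median(abs(x - median(x)))
  out["MCVNN"] <- out["MADNN"] / out["MedianNN"]
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  out["IQRNN"] <- q[2] - q[1]
  out["pNN50"] <- 100 * mean(abs(d) > 50)
  out["pNN20"] <- 100 * mean(abs(d) > 20)
  out["MinNN"] <- min(x)
  out["MaxNN"] <- max(x)
  out["RangeNN"] <- out["MaxNN"] - out["MinNN"]
  binw <- 1000 / 128  # 7.8125 ms
  counts <- table(floor(x / binw))
  out["HTI"] <- n / max(counts)
  out
}

#' Frequency-domain HRV features from the beat tachogram
#'
#' The irregular tachogram is cubic-spline interpolated to a uniform 4 Hz
#' series, linearly detrended, and a Welch PSD (120 s Hann segments, 50%
#' overlap) is integrated over LF 0.04-0.15, HF 0.15-0.40 and VHF
#' 0.40-0.50 Hz by the trapezoid rule. Normalized powers divide by LF+HF.
#'
#' @param nn an [nn_series()] spanning at least `min_span` seconds.
#' @param resample_fs uniform resampling rate in Hz.
#' @param min_span minimum tachogram span in seconds.
#' @return named numeric vector over the frequency catalogue.
#' @export
hrv_freq <- function(nn, resample_fs = 4, min_span = 30) {
  out <- setNames(rep(NA_real_, length(hrv_freq_names)), hrv_freq_names)
  if (length(nn$intervals) < 4L) {
    return(structure(out, reason = "too few beats"))
  }
  span <- nn$times[length(nn$times)] - nn$times[1]
  if (span < min_span) return(structure(out, reason = "span too short"))
  grid <- seq(nn$times[1], nn$times[length(nn$times)], by = 1 / resample_fs)
  z <- spline(nn$times, nn$intervals, xout = grid)$y
  psd <- welch_psd(z, fs = resample_fs,
                   nperseg = min(length(z), 120L * resample_fs))
  spectral_bands(psd, out)
}

#' Frequency-domain features from a uniformly sampled periodic signal
#'
#' Same PSD machinery as [hrv_freq()] applied directly to a continuous
#' signal (e.g. the device heart-rate channel).
#'
#' @param x numeric signal (NAs interpolated over).
#' @param fs sampling rate in Hz.
#' @return named numeric vector over the frequency catalogue.
#' @export
signal_freq <- function(x, fs) {
  out <- setNames(rep(NA_real_, length(hrv_freq_names)), hrv_freq_names)
  x <- interp_na(x)
  if (length(x) < 32L) return(structure(out, reason = "signal too short"))
  psd <- welch_psd(x, fs = fs, nperseg = min(length(x), as.integer(120 * fs)))
  spectral_bands(psd, out)
}

spectral_bands <- function(psd, out) {
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  vhf <- band_power(psd, 0.40, 0.50)
  out["LF"] <- lf
  out["HF"] <- hf
  out["VHF"] <- vhf
  out["TotalPower"] <- band_power(psd, 0, 0.50)
  out["LFHF"] <- if (hf > 0) lf / hf else NA_real_
  tot <- lf + hf
  out["LFn"] <- if (tot > 0) lf / tot else NA_real_
  out["HFn"] <- if (tot > 0) hf / tot else NA_real_
  out["LnHF"] <- if (hf > 0) log(hf) else NA_real_
  out
}

# Linear interpolation over interior NAs; edge NAs carried from nearest value.
interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x[!is.na(x)])
  approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Nonlinear HRV features: Poincare geometry, asymmetry, fragmentation
#'
#' SD1/SD2 use population variances so that `SD1^2 + SD2^2 = 2 Var(NN)`
#' holds as an exact identity (SD2^2 floored at 0). The Poincare ellipse
#' axes `T = 4 SD1`, `L = 4 SD2` give CSI = L/T, CVI = log10(L*T) and
#' modified CSI = L^2/T. Asymmetry follows the Guzik/Porta decomposition of
#' points about the identity line, including the directional contributions
#' SD1d/SD1a, SD2d/SD2a, SDNNd/SDNNa and their normalized shares. The
#' fragmentation indices PIP, IALS, PSS and PAS summarize the sign structure
#' of successive interval differences.
#'
#' @param nn an [nn_series()] with at least 4 intervals.
#' @return named numeric vector over the nonlinear catalogue. Ratio features
#'   are `NA` with a reason when SD1 or SD2 is zero.
#' @export
hrv_nonlinear <- function(nn) {
  out <- setNames(rep(NA_real_, length(hrv_nonlinear_names)),
                  hrv_nonlinear_names)
  v <- nn$intervals
  n <- length(v)
  if (n < 4L) return(structure(out, reason = "fewer than 4 intervals"))
  d <- diff(v)
  var_pop <- function(z) mean((z - mean(z))^2)
  sd1sq <- var_pop(d) / 2
  sd2sq <- max(0, 2 * var_pop(v) - sd1sq)
  sd1 <- sqrt(sd1sq); sd2 <- sqrt(sd2sq)
  out["SD1"] <- sd1
  out["SD2"] <- sd2
  reason <- NULL
  if (sd1 > 0 && sd2 > 0) {
    TT <- 4 * sd1; LL <- 4 * sd2
    out["SD1SD2"] <- sd1 / sd2
    out["EllipseArea"] <- pi * sd1 * sd2
    out["CSI"] <- LL / TT
    out["CVI"] <- log10(LL * TT)
    out["CSIModified"] <- LL^2 / TT
  } else {
    reason <- "degenerate Poincare axis (SD1 or SD2 = 0)"
  }
  # asymmetry: Poincare points (x_i, y_i) = (NN_i, NN_{i+1})
  x <- v[-n]; y <- v[-1]
  dist <- (x - y) / sqrt(2)        # signed distance to identity line
  above <- y > x                   # decelerations
  below <- y < x                   # accelerations
  off <- above | below
  ss <- sum(dist[off]^2)
  if (ss > 0) {
    out["GuzikIndex"] <- 100 * sum(dist[above]^2) / ss
  }
  if (sum(off) > 0) {
    out["PortaIndex"] <- 100 * sum(below) / sum(off)
  }
  m <- length(dist)
  sd1d <- sqrt(sum(dist[above]^2) / m)
  sd1a <- sqrt(sum(dist[below]^2) / m)
  out["SD1d"] <- sd1d; out["SD1a"] <- sd1a
  if (sd1d^2 + sd1a^2 > 0) {
    out["C1d"] <- sd1d^2 / (sd1d^2 + sd1a^2)
    out["C1a"] <- sd1a^2 / (sd1d^2 + sd1a^2)
  }
  long <- (x + y) / sqrt(2)
  longc <- long - mean(long)
  sd2d <- sqrt((sum(longc[above]^2) + 0.5 * sum(longc[!off]^2)) / m)
  sd2a <- sqrt((sum(longc[below]^2) + 0.5 * sum(longc[!off]^2)) / m)
  out["SD2d"] <- sd2d; out["SD2a"] <- sd2a
  if (sd2d^2 + sd2a^2 > 0) {
    out["C2d"] <- sd2d^2 / (sd2d^2 + sd2a^2)
    out["C2a"] <- sd2a^2 / (sd2d^2 + sd2a^2)
  }
  sdnnd <- sqrt(0.5 * (sd1d^2 + sd2d^2))
  sdnna <- sqrt(0.5 * (sd1a^2 + sd2a^2))
  out["SDNNd"] <- sdnnd; out["SDNNa"] <- sdnna
  if (sdnnd^2 + sdnna^2 > 0) {
    out["Cd"] <- sdnnd^2 / (sdnnd^2 + sdnna^2)
    out["Ca"] <- sdnna^2 / (sdnnd^2 + sdnna^2)
  }
  # fragmentation over the sign sequence of successive differences
  s <- sign(d)
  nd <- length(s)
  changes <- s[-1] != s[-nd]
  out["PIP"] <- 100 * sum(changes) / nd
  runs <- rle(s)
  nz <- runs$lengths[runs$values != 0]
  out["IALS"] <- if (length(nz)) 1 / mean(nz) else NA_real_
  out["PSS"] <- if (length(nz)) 100 * sum(nz[nz < 3]) / sum(runs$lengths) else NA_real_
  # alternation segments: maximal stretches of strictly alternating signs
  alt <- s[-1] == -s[-nd] & s[-1] != 0
  ar <- rle(alt)
  alt_len <- ar$lengths[ar$values] + 1L   # in differences
  out["PAS"] <- 100 * sum(alt_len[alt_len >= 4L]) / nd
  if (!is.null(reason)) attr(out, "reason") <- reason
  out
}
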