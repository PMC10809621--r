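#' Electrodermal activity decomposition and features
#'
#' The raw skin-conductance signal is denoised with a zero-phase Butterworth
#' low-pass (order 4, 1 Hz); the tonic component is a second low-pass at
#' 0.05 Hz (order 2) and the phasic component is their difference. Skin
#' conductance responses (SCRs) are local maxima of the phasic component
#' rising at least `min_amp` microSiemens above the preceding trough.
#'
#' @param x numeric EDA samples in microSiemens (interior NAs interpolated).
#' @param fs sampling rate in Hz (4 for the E4).
#' @param min_amp minimum SCR amplitude in microSiemens.
#' @param max_rise_s maximum trough-to-peak rise time in seconds; genuine
#'   responses rise within a few seconds, which rejects slow residual bumps
#'   left by the tonic filter around large responses.
#' @return list with `tonic`, `phasic` (numeric vectors) and `scr`
#'   (data.frame: `index`, `time_s`, `amplitude`).
#' @export
eda_process <- function(x, fs = 4, min_amp = 0.01, max_rise_s = 5) {
  x <- interp_na(x)
  x[is.na(x)] <- 0
  n <- length(x)
  den <- smooth_filter(x, fs, fc = 1, order = 4, type = "low")
  tonic <- smooth_filter(den, fs, fc = 0.05, order = 2, type = "low")
  phasic <- den - tonic
  # local maxima of the phasic component
  dp <- diff(phasic)
  pk <- which(dp[-length(dp)] > 0 & dp[-1] <= 0) + 1L
  idx <- integer(); amp <- numeric()
  prev_end <- 1L
  for (p in pk) {
    ti <- prev_end - 1L + which.min(phasic[prev_end:p])
    a <- phasic[p] - phasic[ti]
    rise_ok <- (p - ti) / fs <= max_rise_s
    if (a >= min_amp && rise_ok) {
      idx[length(idx) + 1L] <- p
      amp[length(amp) + 1L] <- a
      prev_end <- p
    }
  }
  list(tonic = tonic, phasic = phasic,
       scr = data.frame(index = idx, time_s = (idx - 1) / fs,
                        amplitude = amp))
}

eda_feature_names <- c("TonicMean", "TonicMedian", "TonicSD", "TonicSlope",
                       "PhasicMean", "PhasicSD", "PhasicMax",
                       "SCRCount", "SCRRate", "SCRMeanAmplitude",
                       "SympatheticPower", "SympatheticPowerNormalized")

#' Summary features of the EDA decomposition
#'
#' Sympathetic activation is indexed by the Welch-PSD power of the phasic
#' component over the 0.045-0.25 Hz band; the normalized variant divides by
#' total 0-0.5 Hz power.
#'
#' @param decomp output of [eda_process()].
#' @param fs sampling rate in Hz.
#' @return named numeric vector over the EDA catalogue.
#' @export
eda_features <- function(decomp, fs = 4) {
  out <- setNames(rep(NA_real_, length(eda_feature_names)), eda_feature_names)
  tonic <- decomp$tonic; phasic <- decomp$phasic
  dur_min <- length(tonic) / fs / 60
  out["TonicMean"] <- mean(tonic)
  out["TonicMedian"] <- median(tonic)
  out["TonicSD"] <- sd(tonic)
  out["TonicSlope"] <- slope_per_hour(tonic, fs)
  out["PhasicMean"] <- mean(phasic)
  out["PhasicSD"] <- sd(phasic)
  out["PhasicMax"] <- max(phasic)
  nscr <- nrow(decomp$scr)
  out["SCRCount"] <- nscr
  out["SCRRate"] <- nscr / dur_min
  out["SCRMeanAmplitude"] <- if (nscr > 0) mean(decomp$scr$amplitude) else 0
  if (length(phasic) >= 32L) {
    psd <- welch_psd(phasic, fs = fs,
                     nperseg = min(length(phasic), as.integer(120 * fs)))
    sp <- band_power(psd, 0.045, 0.25)
    tot <- band_power(psd, 0, 0.5)
    out["SympatheticPower"] <- sp
    out["SympatheticPowerNormalized"] <- if (tot > 0) sp / tot else 0
  }
  out
}

stat_feature_names <- c("Mean", "Median", "SD", "Min", "Max", "Slope")

#' Time-domain statistics of a scalar channel segment
#'
#' Mean, median, standard deviation, min, max and least-squares slope per
#' hour, computed over observed samples.
#'
#' @param x numeric samples (NAs ignored).
#' @param fs sampling rate in Hz.
#' @return named numeric vector `Mean`, `Median`, `SD`, `Min`, `Max`, `Slope`.
#' @export
channel_stats <- function(x, fs) {
  out <- setNames(rep(NA_real_, length(stat_feature_names)),
                  stat_feature_names)
  if (all(is.na(x))) return(out)
  out["Mean"] <- mean(x, na.rm = TRUE)
  out["Median"] <- median(x, na.rm = TRUE)
  out["SD"] <- sd(x[!is.na(x)])
  out["Min"] <- min(x, na.rm = TRUE)
  out["Max"] <- max(x, na.rm = TRUE)
  out["Slope"] <- slope_per_hour(x, fs)
  out
}
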