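#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor fft lm mad median pnorm pt quantile
#'   rbinom rnorm rpois runif sd setNames spline t.test var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so substreams do not perturb each other.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from a master seed and integer tags
# (subject index, day index, ...). Kept strictly below 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.double(t) * 96731 + 11) %% 2147483647
  }
  as.integer(h)
}

# Zero-phase Butterworth low-pass with mean removal and odd-reflection
# padding; signal::filtfilt alone starts from zero initial conditions and
# leaves large edge transients on slow filters.
smooth_filter <- function(x, fs, fc, order = 2, type = "low") {
  n <- length(x)
  if (n < 8L) return(x)
  mu <- mean(x)
  xc <- x - mu
  if (type == "low") {
    flt <- signal::butter(order, fc / (fs / 2), type = "low")
    pad <- ceiling(3 * fs / fc)
  } else {
    flt <- signal::butter(order, fc / (fs / 2), type = "pass")
    pad <- ceiling(3 * fs / fc[1])
  }
  pad <- min(n - 1L, pad)
  head_ref <- 2 * xc[1] - xc[seq(pad + 1L, 2L)]
  tail_ref <- 2 * xc[n] - xc[seq(n - 1L, n - pad)]
  xe <- c(head_ref, xc, tail_ref)
  ye <- signal::filtfilt(flt, xe)
  ye[seq(pad + 1L, pad + n)] + mu
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hann-windowed, linearly detrended,
#' 50%-overlapping segments; one-sided density scaling so that integrating
#' the PSD over frequency recovers signal variance (up to window effects).
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (clipped to `length(x)`).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 480L, overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 8L, fs > 0)
  nperseg <- as.integer(min(nperseg, n))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  k <- seq_len(nperseg) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * k / (nperseg - 1L))
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  tt <- seq_len(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    # linear detrend
    seg <- stats::.lm.fit(cbind(1, tt), seg)$residuals
    X <- stats::fft(seg * w)
    pxx <- (Mod(X[seq_len(nf)])^2) / scale
    # double interior bins for one-sided density
    if (nperseg %% 2L == 0L) {
      pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
    } else {
      pxx[2:nf] <- 2 * pxx[2:nf]
    }
    acc <- acc + pxx
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

# Trapezoidal band power over [lo, hi] Hz from a welch_psd() result.
band_power <- function(psd, lo, hi) {
  idx <- which(psd$freq >= lo & psd$freq <= hi)
  if (length(idx) < 2L) return(0)
  pracma::trapz(psd$freq[idx], psd$psd[idx])
}

# Least-squares slope of y against time in hours.
slope_per_hour <- function(y, fs) {
  ok <- !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  t_h <- (which(ok) - 1) / fs / 3600
  yy <- y[ok]
  stats::cov(t_h, yy) / stats::var(t_h)
}

# Fast two-sided correlation test p-value via the t transform (the same
# large-sample machinery cor.test uses for Spearman in the presence of ties).
cor_pval <- function(r, n) {
  if (is.na(r) || n < 3L) return(NA_real_)
  r <- max(-1 + 1e-15, min(1 - 1e-15, r))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}
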