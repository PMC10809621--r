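#' Synthetic cohorts with known signal-cognition coupling
#'
#' Generates complete cohorts -- raw signals in the E4 dialect plus subject
#' and assessment tables -- in which selected physiological parameters are
#' linearly coupled to a latent per-subject cognitive trajectory, so every
#' downstream stage of the pipeline has a recoverable ground truth.
#'
#' @name synthetic_data
NULL

#' Simulate an RR (beat-to-beat) interval series
#'
#' Direct interval modulation: the instantaneous interval at elapsed time `t`
#' is `mean_rr + lf_amp sin(2 pi 0.10 t) + hf_amp sin(2 pi 0.25 t) + N(0,
#' jitter_sd)`, i.e. sinusoidal modulation placed at the centres of the LF
#' and HF bands plus white jitter. Beats accumulate until the requested
#' duration is reached (the last beat is truncated).
#'
#' @param mean_rr mean interval in ms.
#' @param lf_amp,hf_amp modulation amplitudes in ms at 0.10 / 0.25 Hz.
#' @param jitter_sd white jitter SD in ms.
#' @param duration total duration in seconds.
#' @param seed RNG seed.
#' @return an [nn_series()] with `source = "IBI"`.
#' @export
simulate_rr_series <- function(mean_rr = 850, lf_amp = 0, hf_amp = 0,
                               jitter_sd = 0, duration = 300, seed = 1L) {
  stopifnot(duration > 0, jitter_sd >= 0, lf_amp >= 0, hf_amp >= 0)
  if (mean_rr - lf_amp - hf_amp <= 0) {
    stop("modulation amplitudes produce non-positive intervals")
  }
  n_max <- as.integer(ceiling(duration * 1000 / mean_rr * 1.5)) + 10L
  jit <- if (jitter_sd > 0) {
    local_seed(seed, rnorm(n_max, 0, jitter_sd))
  } else rep(0, n_max)
  ints <- numeric(n_max)
  t <- 0; i <- 0L
  while (TRUE) {
    rr <- mean_rr + lf_amp * sin(2 * pi * 0.10 * t) +
      hf_amp * sin(2 * pi * 0.25 * t) + jit[i + 1L]
    if (rr <= 0) stop("parameters produced a non-positive interval")
    if (t + rr / 1000 > duration) break
    i <- i + 1L
    ints[i] <- rr
    t <- t + rr / 1000
    if (i >= n_max) break
  }
  nn_series(ints[seq_len(i)], source = "IBI")
}

#' Render an RR series as a BVP channel recording
#'
#' Places one asymmetric pulse template (a gamma-shaped bump with its peak
#' aligned to the beat time) per beat, plus additive white noise.
#'
#' @param nn an [nn_series()] (non-empty).
#' @param fs output sampling rate in Hz.
#' @param pulse_amp template peak amplitude (0 gives a flat signal).
#' @param pulse_rise time-to-peak of the template in seconds.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @param start_time UTC start time of the recording.
#' @return a [channel_recording()] for channel BVP.
#' @export
rr_to_bvp <- function(nn, fs = 64, pulse_amp = 1, pulse_rise = 0.12,
                      noise_sd = 0.02, seed = 1L, start_time = 0) {
  if (length(nn$intervals) == 0L) stop("empty NN series")
  if (fs < 16) stop("sampling rate too low to resolve the pulse template")
  duration <- sum(nn$intervals) / 1000
  n <- as.integer(ceiling(duration * fs))
  beats <- nn$times
  # gamma-shaped template, peak value pulse_amp at t = pulse_rise
  tk <- seq(0, pulse_rise + 0.35, by = 1 / fs)
  kern <- pulse_amp * (tk / pulse_rise)^2 * exp(2 * (1 - tk / pulse_rise))
  peak_off <- which.max(kern) - 1L
  y <- numeric(n)
  starts <- as.integer(round(beats * fs)) - peak_off + 1L
  for (s in starts) {
    seg <- max(1L, s):min(n, s + length(kern) - 1L)
    if (length(seg) == 0L || seg[1] > n) next
    y[seg] <- y[seg] + kern[seg - s + 1L]
  }
  if (noise_sd > 0) y <- y + local_seed(seed, rnorm(n, 0, noise_sd))
  channel_recording("BVP", start_time, fs, y)
}

#' Simulate an EDA channel recording
#'
#' Tonic ramp plus Poisson-timed skin conductance responses with a Bateman
#' kernel `A (exp(-t/tau1) - exp(-t/tau2))`, `tau1 > tau2 > 0`, normalized so
#' each response peaks at `scr_amp`; the signal is clipped at zero.
#'
#' @param tonic_level baseline conductance in microSiemens (> 0).
#' @param drift tonic drift in microSiemens per hour.
#' @param scr_rate SCR rate per minute.
#' @param scr_amp SCR peak amplitude in microSiemens.
#' @param duration seconds.
#' @param fs sampling rate (4 Hz for the E4).
#' @param tau1,tau2 Bateman decay/rise time constants in seconds.
#' @param noise_sd measurement noise SD in microSiemens.
#' @param seed RNG seed.
#' @param start_time UTC start time.
#' @return a [channel_recording()] for channel EDA.
#' @export
simulate_eda <- function(tonic_level = 1.5, drift = 0, scr_rate = 1,
                         scr_amp = 0.3, duration = 300, fs = 4,
                         tau1 = 4, tau2 = 0.75, noise_sd = 0.002,
                         seed = 1L, start_time = 0) {
  stopifnot(tonic_level > 0, scr_rate >= 0, duration > 0)
  if (tau1 <= tau2) stop("Bateman kernel requires tau1 > tau2 > 0")
  if (tau2 <= 0) stop("Bateman kernel requires tau1 > tau2 > 0")
  n <- as.integer(ceiling(duration * fs))
  t <- (seq_len(n) - 1) / fs
  tonic <- tonic_level + drift * t / 3600
  x <- local_seed(seed, {
    phasic <- numeric(n)
    n_scr <- rpois(1, scr_rate * duration / 60)
    if (n_scr > 0) {
      times <- sort(runif(n_scr, 0, duration))
      tk <- seq(0, 8 * tau1, by = 1 / fs)
      kern <- exp(-tk / tau1) - exp(-tk / tau2)
      kern <- scr_amp * kern / max(kern)
      imp <- numeric(n + length(kern))
      ei <- as.integer(round(times * fs)) + 1L
      ei <- ei[ei >= 1L & ei <= n]
      for (e in ei) {
        seg <- e:min(n, e + length(kern) - 1L)
        phasic[seg] <- phasic[seg] + kern[seq_along(seg)]
      }
      attr(phasic, "scr_times") <- times
    }
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    out <- pmax(tonic + phasic + noise, 0)
    attr(out, "scr_times") <- attr(phasic, "scr_times")
    out
  })
  rec <- channel_recording("EDA", start_time, fs, as.numeric(x))
  attr(rec, "scr_times") <- attr(x, "scr_times")
  rec
}

#' Simulate a skin-temperature channel recording
#'
#' Mean plus a slow 24-h sinusoid plus white noise.
#'
#' @param mean_temp mean temperature in degrees C.
#' @param circadian_amp sinusoid amplitude in degrees C.
#' @param noise_sd noise SD in degrees C.
#' @param duration seconds.
#' @param fs sampling rate in Hz.
#' @param phase phase offset in seconds of the 24-h cycle.
#' @param seed RNG seed.
#' @param start_time UTC start time.
#' @return a [channel_recording()] for channel TEMP.
#' @export
simulate_temperature <- function(mean_temp = 33.5, circadian_amp = 0,
                                 noise_sd = 0, duration = 300, fs = 4,
                                 phase = 0, seed = 1L, start_time = 0) {
  stopifnot(noise_sd >= 0, duration > 0)
  n <- as.integer(ceiling(duration * fs))
  t <- (seq_len(n) - 1) / fs
  x <- mean_temp + circadian_amp * sin(2 * pi * (t + phase) / 86400)
  if (noise_sd > 0) x <- x + local_seed(seed, rnorm(n, 0, noise_sd))
  channel_recording("TEMP", start_time, fs, x)
}

#' Simulate a latent cognitive trajectory between two assessments
#'
#' Interior interval values follow the normalized Gompertz interpolation of
#' the two assessment scores plus independent noise; endpoints are exact.
#'
#' @param baseline,post observed composite scores.
#' @param n_intervals number of 10-day intervals.
#' @param shape a [gompertz_shape()].
#' @param noise_sd SD of interior deviations.
#' @param seed RNG seed.
#' @return numeric latent series of length `n_intervals`.
#' @export
simulate_cognition <- function(baseline, post, n_intervals = 7L,
                               shape = gompertz_shape(), noise_sd = 0,
                               seed = 1L) {
  stopifnot(n_intervals >= 2L)
  y <- gompertz_series(baseline, post, n_intervals, shape)
  if (noise_sd > 0 && n_intervals > 2L) {
    y[2:(n_intervals - 1L)] <- y[2:(n_intervals - 1L)] +
      local_seed(seed, rnorm(n_intervals - 2L, 0, noise_sd))
  }
  y
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: 17 analyzable subjects observed for
#' 70 days (seven 10-day intervals), night-dominant wear inside the
#' 01:00-06:00 calm window with occasional whole-night non-wear, an RR series
#' with LF/HF modulation and white jitter, EDA with tonic drift and
#' Bateman-shaped responses, slowly varying temperature, and a latent
#' cognitive trajectory per composite whose chosen physiological parameters
#' follow it linearly.
#'
#' @param n_subjects number of subjects.
#' @param observation_days observation span in days (>= 10).
#' @param nightly_wear_hours nightly wear duration in hours (snapped to whole
#'   5-min segments).
#' @param non_wear_prob probability a whole night is missing.
#' @param wear_start_h clock hour at which wear can begin.
#' @param wear_jitter_slots uniform integer jitter (in 5-min slots) of the
#'   wear start.
#' @param mean_rr,lf_amp,hf_amp,jitter_sd RR-series base parameters (ms).
#' @param scr_rate,tonic_level,scr_amp,eda_drift EDA base parameters.
#' @param temp_mean,temp_amp,temp_noise temperature parameters (degrees C).
#' @param coupling named list of linear slopes onto the latent score of
#'   `coupling_outcome`; names from `mean_rr`, `lf_amp`, `hf_amp`,
#'   `jitter_sd`, `scr_rate`, `tonic_level`, `temp_mean`.
#' @param coupling_outcome the composite whose latent trajectory drives the
#'   coupling.
#' @param trajectory_noise_sd SD of interior latent deviations.
#' @param baseline_mean,baseline_sd distribution of baseline composite
#'   z-scores.
#' @param change_mean,change_sd distribution of baseline-to-post change.
#' @param shape Gompertz shape of the latent trajectory.
#' @param seed master seed; fixes the cohort exactly.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 17L, observation_days = 70L,
                              nightly_wear_hours = 5, non_wear_prob = 0.15,
                              wear_start_h = 1, wear_jitter_slots = 0L,
                              mean_rr = 850, lf_amp = 25, hf_amp = 20,
                              jitter_sd = 20, scr_rate = 1,
                              tonic_level = 1.5, scr_amp = 0.3,
                              eda_drift = -0.05, temp_mean = 33.5,
                              temp_amp = 0.4, temp_noise = 0.05,
                              coupling = list(hf_amp = 8),
                              coupling_outcome = "executive_function",
                              trajectory_noise_sd = 0.05,
                              baseline_mean = 0, baseline_sd = 1,
                              change_mean = 0.2, change_sd = 0.4,
                              shape = gompertz_shape(), seed = 1L) {
  stopifnot(observation_days >= 10L, n_subjects >= 1L,
            nightly_wear_hours > 0, non_wear_prob >= 0, non_wear_prob < 1,
            jitter_sd >= 0, scr_rate >= 0, trajectory_noise_sd >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

sim_params_for_night <- function(cfg, latent) {
  base <- list(mean_rr = cfg$mean_rr, lf_amp = cfg$lf_amp,
               hf_amp = cfg$hf_amp, jitter_sd = cfg$jitter_sd,
               scr_rate = cfg$scr_rate, tonic_level = cfg$tonic_level,
               temp_mean = cfg$temp_mean)
  for (nm in names(cfg$coupling)) {
    base[[nm]] <- base[[nm]] + cfg$coupling[[nm]] * latent
  }
  # physiological floors: amplitudes/rates cannot go negative
  base$hf_amp <- max(0.5, base$hf_amp)
  base$lf_amp <- max(0.5, base$lf_amp)
  base$jitter_sd <- max(0.5, base$jitter_sd)
  base$scr_rate <- max(0, base$scr_rate)
  base$tonic_level <- max(0.05, base$tonic_level)
  base$mean_rr <- max(400, base$mean_rr)
  base
}

#' Generate a complete synthetic cohort
#'
#' @param cfg a [simulation_config()].
#' @param dir if non-`NULL`, the cohort is also written to disk in the E4
#'   dialect: `subjects.csv`, `assessments.csv`, `truth.csv` and one
#'   directory per subject-night holding `BVP.csv`, `EDA.csv`, `TEMP.csv`,
#'   `HR.csv`, `IBI.csv`.
#' @param channels which channels to synthesize (HR and IBI always).
#' @return list of class `wc_cohort`: `subjects`, `assessments`, `truth`
#'   (per-subject latent interval values and per-night true parameters),
#'   and `sessions` (per subject-night recordings and IBI events).
#' @export
generate_cohort <- function(cfg, dir = NULL,
                            channels = c("BVP", "EDA", "TEMP")) {
  stopifnot(inherits(cfg, "sim_config"))
  n_int <- as.integer(cfg$observation_days / 10L)
  seg_per_night <- max(1L, as.integer(round(cfg$nightly_wear_hours * 12)))
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(cfg$n_subjects)),
    age = local_seed(derive_seed(cfg$seed, 1),
                     sample(50:70, cfg$n_subjects, replace = TRUE)),
    sex = local_seed(derive_seed(cfg$seed, 2),
                     sample(c("female", "male"), cfg$n_subjects,
                            replace = TRUE)))
  assess <- list(); truth_lat <- list(); truth_par <- list()
  sessions <- list()
  for (si in seq_len(cfg$n_subjects)) {
    sid <- subjects$subject_id[si]
    sc <- local_seed(derive_seed(cfg$seed, 3, si), {
      b <- rnorm(length(COMPOSITES), cfg$baseline_mean, cfg$baseline_sd)
      p <- b + rnorm(length(COMPOSITES), cfg$change_mean, cfg$change_sd)
      list(b = setNames(b, COMPOSITES), p = setNames(p, COMPOSITES))
    })
    assess[[si]] <- data.frame(
      subject_id = sid,
      composite = rep(COMPOSITES, 2L),
      timepoint = rep(c("baseline", "post"), each = length(COMPOSITES)),
      z = c(sc$b, sc$p),
      day = rep(c(-7L, cfg$observation_days + 5L),
                each = length(COMPOSITES)))
    lat <- sapply(COMPOSITES, function(comp) {
      if (n_int == 1L) return(sc$b[comp])
      simulate_cognition(sc$b[comp], sc$p[comp], n_int, cfg$shape,
                         cfg$trajectory_noise_sd,
                         derive_seed(cfg$seed, 4, si, match(comp, COMPOSITES)))
    })
    if (n_int == 1L) lat <- matrix(lat, nrow = 1,
                                   dimnames = list(NULL, COMPOSITES))
    truth_lat[[si]] <- data.frame(subject_id = sid,
                                  interval = seq_len(n_int), lat)
    nights <- list()
    for (d in seq_len(cfg$observation_days)) {
      skip <- local_seed(derive_seed(cfg$seed, 5, si, d),
                         runif(1) < cfg$non_wear_prob)
      if (skip) next
      iv <- min(n_int, as.integer(ceiling(d / 10)))
      latent <- lat[iv, cfg$coupling_outcome]
      par <- sim_params_for_night(cfg, latent)
      jit <- if (cfg$wear_jitter_slots > 0L) {
        local_seed(derive_seed(cfg$seed, 6, si, d),
                   sample(0:cfg$wear_jitter_slots, 1L))
      } else 0L
      start_slot <- as.integer(cfg$wear_start_h * 12) + jit
      dur <- seg_per_night * SEGMENT_SECONDS
      t0 <- (d - 1) * 86400 + start_slot * SEGMENT_SECONDS
      nn <- simulate_rr_series(par$mean_rr, par$lf_amp, par$hf_amp,
                               par$jitter_sd, dur,
                               derive_seed(cfg$seed, 7, si, d))
      beats <- nn$times
      ibi <- ibi_events(t0, beats, nn$intervals / 1000)
      # HR channel at 1 Hz from the instantaneous rate
      hr_grid <- seq(0, dur - 1)
      hr_vals <- approx(beats, 60000 / nn$intervals, xout = hr_grid,
                        rule = 2)$y
      recs <- list(HR = channel_recording("HR", t0, 1, hr_vals))
      if ("BVP" %in% channels) {
        recs$BVP <- rr_to_bvp(nn, fs = 64,
                              seed = derive_seed(cfg$seed, 8, si, d),
                              start_time = t0)
      }
      if ("EDA" %in% channels) {
        recs$EDA <- simulate_eda(par$tonic_level, cfg$eda_drift,
                                 par$scr_rate, cfg$scr_amp, dur, fs = 4,
                                 seed = derive_seed(cfg$seed, 9, si, d),
                                 start_time = t0)
      }
      if ("TEMP" %in% channels) {
        recs$TEMP <- simulate_temperature(par$temp_mean, cfg$temp_amp,
                                          cfg$temp_noise, dur, fs = 4,
                                          phase = t0 %% 86400,
                                          seed = derive_seed(cfg$seed, 10, si, d),
                                          start_time = t0)
      }
      nights[[as.character(d)]] <- list(day = d, recordings = recs,
                                        ibi = ibi)
      truth_par[[length(truth_par) + 1L]] <-
        cbind(data.frame(subject_id = sid, day = d, interval = iv,
                         latent = latent),
              as.data.frame(par))
    }
    sessions[[sid]] <- nights
  }
  cohort <- structure(
    list(subjects = subjects,
         assessments = do.call(rbind, assess),
         truth = list(latent = do.call(rbind, truth_lat),
                      params = do.call(rbind, truth_par)),
         sessions = sessions, config = cfg),
    class = "wc_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.wc_cohort <- function(x, ...) {
  n_nights <- sum(vapply(x$sessions, length, integer(1)))
  cat(sprintf("<wc_cohort> %d subjects, %d nights with data\n",
              nrow(x$subjects), n_nights))
  invisible(x)
}

#' Write a cohort to disk in the E4 dialect
#'
#' @param cohort a `wc_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  write_assessments(cohort$assessments, file.path(dir, "assessments.csv"))
  utils::write.csv(cohort$truth$latent, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth$params, file.path(dir, "truth_params.csv"),
                   row.names = FALSE)
  for (sid in names(cohort$sessions)) {
    for (night in cohort$sessions[[sid]]) {
      sdir <- file.path(dir, sprintf("%s_day%03d", sid, night$day))
      dir.create(sdir, showWarnings = FALSE)
      for (ch in names(night$recordings)) {
        write_channel(night$recordings[[ch]],
                      file.path(sdir, paste0(ch, ".csv")))
      }
      write_ibi(night$ibi, file.path(sdir, "IBI.csv"))
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `wc_cohort` (without truth unless present on disk).
#' @export
read_cohort <- function(dir) {
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  assessments <- read_assessments(file.path(dir, "assessments.csv"))
  sess_dirs <- list.dirs(dir, recursive = FALSE)
  sessions <- list()
  for (sd in sess_dirs) {
    base <- basename(sd)
    m <- regmatches(base, regexec("^(.+)_day([0-9]+)$", base))[[1]]
    if (length(m) != 3L) next
    sid <- m[2]; day <- as.integer(m[3])
    recs <- list()
    for (ch in c("BVP", "EDA", "TEMP", "HR")) {
      f <- file.path(sd, paste0(ch, ".csv"))
      if (file.exists(f)) recs[[ch]] <- read_channel(f, ch)
    }
    ibi <- NULL
    f <- file.path(sd, "IBI.csv")
    if (file.exists(f)) ibi <- read_ibi(f)
    sessions[[sid]][[as.character(day)]] <-
      list(day = day, recordings = recs, ibi = ibi)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- list(latent = utils::read.csv(file.path(dir, "truth.csv")))
    if (file.exists(file.path(dir, "truth_params.csv"))) {
      truth$params <- utils::read.csv(file.path(dir, "truth_params.csv"))
    }
  }
  structure(list(subjects = subjects, assessments = assessments,
                 truth = truth, sessions = sessions, config = NULL),
            class = "wc_cohort")
}
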