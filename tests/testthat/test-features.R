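test_that("time-domain features match hand-computed values", {
  ht <- hrv_time(nn_series(rep(800, 10)))
  expect_equal(unname(ht["MeanNN"]), 800)
  expect_equal(unname(ht["SDNN"]), 0)
  expect_equal(unname(ht["RMSSD"]), 0)
  expect_equal(unname(ht["pNN50"]), 0)

  ht2 <- hrv_time(nn_series(c(800, 810, 790, 805)))
  expect_equal(unname(ht2["RMSSD"]), sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-12)

  ht3 <- hrv_time(nn_series(rep(c(800, 860), 10)))
  expect_equal(unname(ht3["pNN50"]), 100)
  expect_equal(unname(ht3["pNN20"]), 100)
  # strict pNN thresholds: |delta| exactly at the threshold does not count
  ht4 <- hrv_time(nn_series(rep(c(800, 850), 10)))
  expect_equal(unname(ht4["pNN50"]), 0)
  expect_equal(unname(ht4["pNN20"]), 100)
})

test_that("clean_nn drops implausible intervals and re-derives times", {
  nn <- nn_series(c(800, 5000, 820, 150, 810))
  cl <- clean_nn(nn)
  expect_identical(cl$intervals, c(800, 820, 810))
  expect_equal(cl$times, cumsum(c(800, 820, 810)) / 1000)
  ok <- nn_series(c(800, 810))
  expect_identical(clean_nn(ok)$intervals, ok$intervals)
  expect_length(clean_nn(nn_series(numeric()))$intervals, 0)
})

test_that("spectral band placement localizes LF and HF modulation", {
  hf_only <- hrv_freq(simulate_rr_series(850, 0, 30, 0, 300, 1))
  expect_gt(unname(hf_only["HFn"]), 0.9)
  lf_only <- hrv_freq(simulate_rr_series(850, 30, 0, 0, 300, 1))
  expect_gt(unname(lf_only["LFHF"]), 5)
  const <- hrv_freq(nn_series(rep(800, 400)))
  expect_lt(unname(const["TotalPower"]), 1e-6)
})

test_that("Welch total power approximates tachogram variance on stationary series", {
  nn <- simulate_rr_series(850, 20, 15, 10, 300, 3)
  tp <- unname(hrv_freq(nn)["TotalPower"])
  expect_lt(abs(tp - var(nn$intervals)) / var(nn$intervals), 0.15)
})

test_that("time and frequency features agree with the independent reference values", {
  # reference values computed with numpy/scipy (CubicSpline + welch) on the
  # same deterministic series
  nn <- oracle_nn()
  ht <- hrv_time(nn)
  ref_t <- c(MeanNN = 850.1219723910424, SDNN = 29.776055881445664,
             RMSSD = 23.26944244205456, SDSD = 23.298607098477717,
             pNN50 = 0, pNN20 = 48.62155388471178,
             MedianNN = 850.8121344552835, MADNN = 35.15679444420707,
             IQRNN = 46.96725274665391, MinNN = 784.3481406271725,
             MaxNN = 914.8468912955026)
  for (nm in names(ref_t)) {
    expect_equal(unname(ht[nm]), unname(ref_t[nm]), tolerance = 1e-6,
                 label = nm)
  }
  hf <- hrv_freq(nn)
  ref_f <- c(LF = 682.3719305056104, HF = 191.69039211396387,
             VHF = 0.08300250765305585, TotalPower = 876.2225206605841)
  for (nm in names(ref_f)) {
    expect_lt(abs(hf[nm] - ref_f[nm]) / max(ref_f[nm], 1e-12), 0.10)
  }
})

test_that("Poincare geometry: closed forms, identity, and degenerate axes", {
  # alternating 800/850: Var(d)=2500 -> SD1=sqrt(1250); SD2 ~ 0
  nl <- hrv_nonlinear(nn_series(rep(c(800, 850), 300)))
  expect_equal(unname(nl["SD1"]), sqrt(1250), tolerance = 1e-2)
  expect_lt(unname(nl["SD2"]), 1)
  expect_true(is.na(nl["SD1SD2"]) || unname(nl["SD2"]) > 0)

  # SD1^2 + SD2^2 = 2 Var_pop(NN) on random series
  for (sd_i in 1:5) {
    set.seed(sd_i)
    v <- 800 + rnorm(150, 0, 25)
    nl2 <- hrv_nonlinear(nn_series(v))
    vp <- mean((v - mean(v))^2)
    expect_lt(abs(nl2["SD1"]^2 + nl2["SD2"]^2 - 2 * vp) / (2 * vp), 1e-9)
  }

  # strictly increasing series: no accelerations, no inflections
  inc <- hrv_nonlinear(nn_series(seq(700, 1000, by = 2)))
  expect_equal(unname(inc["PortaIndex"]), 0)
  expect_lt(unname(inc["PIP"]), 1)
  expect_equal(unname(inc["GuzikIndex"]), 100)
})

test_that("asymmetry decomposition shares sum to one and CSI/CVI are consistent", {
  set.seed(42)
  nl <- hrv_nonlinear(nn_series(800 + rnorm(200, 0, 30)))
  expect_equal(unname(nl["C1d"] + nl["C1a"]), 1, tolerance = 1e-12)
  expect_equal(unname(nl["C2d"] + nl["C2a"]), 1, tolerance = 1e-12)
  expect_equal(unname(nl["Cd"] + nl["Ca"]), 1, tolerance = 1e-12)
  expect_equal(unname(nl["CSI"]), unname(nl["SD2"] / nl["SD1"]),
               tolerance = 1e-12)
  expect_equal(unname(nl["CVI"]),
               log10(16 * unname(nl["SD1"] * nl["SD2"])), tolerance = 1e-12)
  expect_equal(unname(nl["CSIModified"]),
               unname(4 * nl["SD2"]^2 / nl["SD1"]), tolerance = 1e-12)
})

test_that("the beat detector recovers planted beats and handles degenerate input", {
  nn <- simulate_rr_series(850, 25, 20, 20, 300, 4)
  bvp <- rr_to_bvp(nn, seed = 5)
  det <- elgendi_peaks(bvp$values, 64)
  pt <- attr(det, "peak_times")
  hits <- vapply(nn$times, function(t) any(abs(pt - t) <= 0.05), logical(1))
  expect_gte(mean(hits), 0.99)

  expect_length(elgendi_peaks(rep(0, 19200), 64)$intervals, 0)
  flat <- rr_to_bvp(nn, pulse_amp = 0, noise_sd = 0)
  expect_length(elgendi_peaks(flat$values, 64)$intervals, 0)

  # strictly periodic 1 Hz pulses for 300 s -> ~299 intervals of ~1000 ms
  per <- rr_to_bvp(nn_series(rep(1000, 300)), noise_sd = 0.01, seed = 1)
  detp <- elgendi_peaks(per$values, 64)
  expect_true(abs(length(detp$intervals) - 299) <= 1)
  expect_lt(max(abs(detp$intervals - 1000)), 35)
})

test_that("EDA decomposition recovers tonic structure and planted responses", {
  dec <- eda_process(rep(2, 1200), 4)
  expect_lt(max(abs(dec$tonic - 2)), 0.01)
  expect_lt(max(abs(dec$phasic)), 0.01)
  expect_identical(nrow(dec$scr), 0L)

  # pure slow ramp: no SCRs, tonic slope tracks the ramp
  ramp <- seq(1, 2, length.out = 1200)
  decr <- eda_process(ramp, 4)
  expect_identical(nrow(decr$scr), 0L)
  fr <- eda_features(decr, 4)
  expect_equal(unname(fr["TonicSlope"]), 12, tolerance = 0.05)

  # five well-separated planted responses are found exactly
  kern_t <- seq(0, 32, by = 0.25)
  kern <- exp(-kern_t / 4) - exp(-kern_t / 0.75)
  kern <- 0.5 * kern / max(kern)
  x <- rep(2, 1200)
  onsets <- c(100, 300, 500, 700, 900)
  for (o in onsets) {
    seg <- o:min(1200, o + length(kern) - 1)
    x[seg] <- x[seg] + kern[seq_along(seg)]
  }
  dec5 <- eda_process(x, 4)
  expect_identical(nrow(dec5$scr), 5L)
  f5 <- eda_features(dec5, 4)
  expect_equal(unname(f5["SCRCount"]), 5)
  expect_equal(unname(f5["SCRRate"]), 1.0)
})

test_that("sympathetic band power prefers in-band oscillations", {
  t <- (0:1199) / 4
  in_band <- sin(2 * pi * 0.1 * t)
  out_band <- sin(2 * pi * 0.45 * t)
  p_in <- eda_features(list(tonic = rep(2, 1200), phasic = in_band,
                            scr = data.frame()), 4)["SympatheticPower"]
  p_out <- eda_features(list(tonic = rep(2, 1200), phasic = out_band,
                             scr = data.frame()), 4)["SympatheticPower"]
  expect_gt(unname(p_in), unname(p_out))
  zero <- eda_features(list(tonic = rep(2, 1200), phasic = rep(0, 1200),
                            scr = data.frame()), 4)
  expect_equal(unname(zero["SympatheticPowerNormalized"]), 0)
})

test_that("channel statistics include the least-squares slope per hour", {
  cs <- channel_stats(rep(33, 1200), 4)
  expect_equal(unname(cs["Mean"]), 33)
  expect_equal(unname(cs["SD"]), 0)
  expect_equal(unname(cs["Slope"]), 0)
  ramp <- seq(33, 33.5, length.out = 1200)  # +0.5 C over 5 min
  expect_equal(unname(channel_stats(ramp, 4)["Slope"]), 6, tolerance = 0.01)
  set.seed(1); v <- rnorm(300, 70)
  expect_equal(unname(channel_stats(v, 1)["Mean"]), mean(v))
})

test_that("features are invariant to time translation of the segment", {
  nn <- simulate_rr_series(850, 20, 15, 10, 300, 9)
  shifted <- nn_series(nn$intervals, times = nn$times + 1234,
                       source = nn$source)
  expect_equal(hrv_freq(nn), hrv_freq(shifted), tolerance = 1e-12)
  expect_equal(hrv_time(nn), hrv_time(shifted))
})

test_that("the registry is frozen, grouped, and at least as large as the study catalogue", {
  reg <- feature_registry()
  expect_identical(anyDuplicated(reg$name), 0L)
  counts <- table(reg$group)
  expect_gte(counts[["PPG"]], 45)
  expect_gte(counts[["IBI"]], 37)
  expect_gte(counts[["EDA"]], 12)
  expect_gte(counts[["HR"]], 7)
  expect_gte(counts[["TEMP"]], 5)
  expect_identical(feature_registry(), reg)  # deterministic order
})

test_that("extract_all honors validity flags and source equivalence", {
  nn <- simulate_rr_series(850, 25, 20, 20, 300, 11)
  bvp_vals <- c(rr_to_bvp(nn, seed = 2)$values, rep(0, 19200))[1:19200]
  bvp <- make_segment("BVP", bvp_vals, 64)
  eda <- make_segment("EDA",
                      simulate_eda(duration = 300, seed = 3)$values, 4)
  temp <- make_segment("TEMP",
                       simulate_temperature(duration = 300, noise_sd = 0.05,
                                            seed = 4)$values, 4)
  hr_vals <- approx(nn$times, 60000 / nn$intervals, xout = 0:299,
                    rule = 2)$y
  hr <- make_segment("HR", hr_vals, 1)
  ibi <- list(times = nn$times, durations = nn$intervals / 1000,
              n = length(nn$times))
  fv <- extract_all(bvp = bvp, eda = eda, temp = temp, hr = hr, ibi = ibi)
  valid <- attr(fv, "valid")
  expect_true(all(valid))
  expect_false(anyNA(fv[c("IBI_MeanNN", "PPG_MeanNN", "EDA_TonicMean",
                          "HR_Mean", "TEMP_Mean", "HR_HF")]))

  # dropping IBI leaves other groups intact
  fv2 <- extract_all(bvp = bvp, eda = eda, temp = temp, hr = hr, ibi = NULL)
  expect_false(attr(fv2, "valid")[["IBI"]])
  expect_true(attr(fv2, "valid")[["EDA"]])
  expect_true(is.na(fv2["IBI_MeanNN"]))
  expect_false(is.na(fv2["EDA_TonicMean"]))

  # identical beat streams fed as IBI give the same HRV values as direct
  # computation (source equivalence of the shared catalogue)
  direct <- c(hrv_time(nn), hrv_freq(nn), hrv_nonlinear(nn))
  ibi_vals <- fv[paste0("IBI_", names(direct))]
  expect_equal(unname(ibi_vals), unname(direct), tolerance = 1e-9)
})
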