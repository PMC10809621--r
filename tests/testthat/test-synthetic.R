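test_that("RR simulation honors its closed-form oracles", {
  # zero modulation and jitter -> constant series, zero variability downstream
  const <- simulate_rr_series(800, 0, 0, 0, 60, 1)
  expect_true(all(const$intervals == 800))
  ht <- hrv_time(const)
  expect_equal(unname(ht["SDNN"]), 0)
  expect_equal(unname(ht["RMSSD"]), 0)

  # iid jitter: RMSSD -> sigma * sqrt(2) (Var of differences = 2 sigma^2)
  nj <- simulate_rr_series(900, 0, 0, 25, 18000, 2)
  expect_gt(length(nj$intervals), 19000)
  expect_lt(abs(hrv_time(nj)["RMSSD"] - 25 * sqrt(2)) / (25 * sqrt(2)), 0.05)

  # HF-only modulation lands in the HF band
  hf <- hrv_freq(simulate_rr_series(850, 0, 25, 0, 300, 3))
  expect_gt(unname(hf["HFn"]), 0.9)

  # duration is respected (last beat truncated)
  expect_lte(sum(nj$intervals) / 1000, 18000)
  expect_gt(sum(nj$intervals) / 1000, 18000 - 2)

  expect_error(simulate_rr_series(500, 300, 300, 0, 10, 1), "non-positive")
})

test_that("BVP rendering places one template per beat", {
  nn <- nn_series(rep(c(800, 820), 20))
  bvp <- rr_to_bvp(nn, noise_sd = 0, seed = 1)
  expect_identical(bvp$sampling_rate, 64)
  # local maxima of the noiseless signal = beats (count matches)
  v <- bvp$values
  pk <- which(diff(sign(diff(v))) == -2) + 1
  pk <- pk[v[pk] > 0.5]
  # the final template can be truncated by the recording boundary
  expect_lte(abs(length(pk) - length(nn$times)), 1)
  expect_error(rr_to_bvp(nn, fs = 4), "too low")
  expect_error(rr_to_bvp(nn_series(numeric())), "empty")
})

test_that("EDA simulation is Poisson in count and Bateman in shape", {
  expect_error(simulate_eda(tau1 = 0.5, tau2 = 0.75), "tau1 > tau2")
  none <- simulate_eda(2, 0, 0, 0.5, 300, seed = 1, noise_sd = 0)
  expect_identical(nrow(eda_process(none$values, 4)$scr), 0L)

  # Poisson 99% interval for rate 4/min over 60 min: qpois bounds
  rec <- simulate_eda(2, 0, 4, 0.3, 3600, seed = 5)
  n <- length(attr(rec, "scr_times"))
  expect_gte(n, qpois(0.005, 4 * 60))
  expect_lte(n, qpois(0.995, 4 * 60))
  expect_true(all(rec$values >= 0))
})

test_that("temperature simulation matches its construction", {
  const <- simulate_temperature(33, 0, 0, 300, seed = 1)
  expect_true(all(const$values == 33))
  noisy <- simulate_temperature(33, 0, 0.1, 3600, seed = 2)
  n <- length(noisy$values)
  expect_lt(abs(mean(noisy$values) - 33), 3 * 0.1 / sqrt(n))
  wavy <- simulate_temperature(33, 0.5, 0.05, 86400, fs = 0.1, seed = 3)
  expect_gte(max(wavy$values) - min(wavy$values), 2 * 0.5 - 4 * 0.05)
})

test_that("latent trajectories interpolate the assessments", {
  noiseless <- simulate_cognition(0.2, 0.8, 7, noise_sd = 0, seed = 1)
  expect_identical(noiseless, gompertz_series(0.2, 0.8, 7))
  expect_identical(simulate_cognition(0.5, 0.5, 7, noise_sd = 0, seed = 1),
                   rep(0.5, 7))
  noisy <- simulate_cognition(0.2, 0.8, 7, noise_sd = 0.1, seed = 2)
  expect_identical(noisy[c(1, 7)], c(0.2, 0.8))
  # interior deviations have the requested variance (MC over seeds)
  devs <- unlist(lapply(1:300, function(s) {
    simulate_cognition(0, 1, 7, noise_sd = 0.1, seed = s)[2:6] -
      gompertz_series(0, 1, 7)[2:6]
  }))
  expect_lt(abs(sd(devs) - 0.1) / 0.1, 0.1)
})

test_that("cohort generation is deterministic and honors channel contracts", {
  sim <- simulation_config(n_subjects = 2L, observation_days = 10L,
                           nightly_wear_hours = 1 / 3, non_wear_prob = 0.2,
                           seed = 99L)
  a <- generate_cohort(sim)
  b <- generate_cohort(sim)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions, b$sessions)

  night <- a$sessions[[1]][[1]]
  expect_identical(night$recordings$BVP$sampling_rate, 64)
  expect_identical(night$recordings$EDA$sampling_rate, 4)
  expect_identical(night$recordings$TEMP$sampling_rate, 4)
  expect_identical(night$recordings$HR$sampling_rate, 1)
  # trajectory endpoints equal the subject's assessments
  tr <- a$truth$latent
  for (sid in a$subjects$subject_id) {
    d <- a$assessments[a$assessments$subject_id == sid, ]
    lat <- tr[tr$subject_id == sid, "executive_function"]
    expect_equal(lat[1],
                 d$z[d$composite == "executive_function" &
                       d$timepoint == "baseline"])
  }
})

test_that("cohorts round-trip through the on-disk E4 tree", {
  tmp <- withr::local_tempdir()
  sim <- simulation_config(n_subjects = 2L, observation_days = 10L,
                           nightly_wear_hours = 1 / 6, non_wear_prob = 0,
                           seed = 5L)
  coh <- generate_cohort(sim, dir = tmp)
  expect_true(file.exists(file.path(tmp, "subjects.csv")))
  expect_true(file.exists(file.path(tmp, "truth.csv")))
  back <- read_cohort(tmp)
  expect_identical(back$subjects$subject_id, coh$subjects$subject_id)
  expect_identical(length(back$sessions), length(coh$sessions))
  n1 <- coh$sessions[[1]][[1]]; n2 <- back$sessions[[1]][[1]]
  expect_identical(n2$recordings$EDA$values, n1$recordings$EDA$values)
  expect_identical(n2$ibi$durations, n1$ibi$durations)
  # identical features from the disk and memory paths
  f1 <- cohort_segment_features(coh)
  f2 <- cohort_segment_features(back)
  expect_equal(f1[order(f1$subject_id, f1$day, f1$slot), ],
               f2[order(f2$subject_id, f2$day, f2$slot), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("planted coupling is recovered by the extracted features", {
  # strong HF coupling: the HF feature correlates with the latent score
  sim <- simulation_config(n_subjects = 8L, observation_days = 30L,
                           nightly_wear_hours = 1 / 3, non_wear_prob = 0,
                           coupling = list(hf_amp = 10), seed = 11L)
  coh <- generate_cohort(sim, channels = c("EDA", "TEMP"))
  sf <- cohort_segment_features(coh)
  win <- fixed_night_window(1, 5)
  daily <- daily_aggregate(require_ibi(sf), win)
  iv <- interval_aggregate(daily, observation_days = 30L)
  truth <- coh$truth$latent[, c("subject_id", "interval",
                                "executive_function")]
  m <- merge(iv, truth, by = c("subject_id", "interval"))
  r_hf <- cor(m$IBI_HF, m$executive_function)
  expect_gt(r_hf, 0.5)
  # the coupled parameter's feature dominates every feature of the
  # uncoupled channels (HF modulation propagates to all beat-derived
  # measures, so ranking within that family is a tie by construction)
  reg <- feature_registry()
  uncoupled <- reg$name[reg$group %in% c("EDA", "TEMP")]
  rs <- vapply(intersect(uncoupled, names(m)), function(f) {
    if (all(is.na(m[[f]]))) return(NA_real_)
    suppressWarnings(abs(cor(m[[f]], m$executive_function,
                             use = "pairwise.complete.obs")))
  }, numeric(1))
  rs <- rs[!is.na(rs)]
  expect_gte(abs(r_hf), quantile(rs, 0.9))
})

test_that("zero coupling leaves features uncorrelated with the latent score", {
  rs <- vapply(1:3, function(s) {
    sim <- simulation_config(n_subjects = 8L, observation_days = 30L,
                             nightly_wear_hours = 1 / 3, non_wear_prob = 0,
                             coupling = list(hf_amp = 0), seed = 1000L + s)
    coh <- generate_cohort(sim, channels = character())
    sf <- cohort_segment_features(coh)
    daily <- daily_aggregate(require_ibi(sf), fixed_night_window(1, 5))
    iv <- interval_aggregate(daily, observation_days = 30L)
    truth <- coh$truth$latent[, c("subject_id", "interval",
                                  "executive_function")]
    m <- merge(iv, truth, by = c("subject_id", "interval"))
    abs(cor(m$IBI_HF, m$executive_function))
  }, numeric(1))
  expect_lt(median(rs), 0.2)
})
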