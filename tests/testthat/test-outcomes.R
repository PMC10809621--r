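test_that("composites average their constituent tests and global averages all tests", {
  tests <- c("digit_span", "similarities", "trail_making_b",
             "category_fluency", "letter_fluency",
             "category_switching_fluency", "trail_making_a", "symbol_digit",
             "logical_memory_i", "ravlt_i_v", "visual_reproduction_i",
             "logical_memory_ii", "ravlt_vii", "visual_reproduction_ii")
  z1 <- setNames(rep(1, length(tests)), tests)
  expect_true(all(compute_composites(z1) == 1))

  z2 <- z1 * 0
  z2[c("digit_span", "similarities", "trail_making_b")] <- c(0.5, -0.5, 1.0)
  cc <- compute_composites(z2)
  expect_equal(unname(cc["executive_function"]), 1 / 6, tolerance = 1e-12)
  # global is the mean over tests, not over composites (unequal group sizes)
  expect_equal(unname(cc["global_cognition"]), mean(z2), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(cc["global_cognition"]),
                                mean(cc[1:4]))))

  z3 <- z1[-1]
  cc3 <- compute_composites(z3)
  expect_true(is.na(cc3["executive_function"]))
  expect_false(is.na(cc3["processing_speed"]))
  expect_match(attr(cc3, "reason")[["executive_function"]], "missing")
})

test_that("Gompertz interpolation is endpoint-exact, monotone, and matches the closed form", {
  for (b in c(0.5, 1, 3, 6)) for (cc in c(0.5, 2, 4, 8)) {
    g <- gompertz_series(-1.2, 0.4, 7, gompertz_shape(b, cc))
    expect_identical(g[1], -1.2)
    expect_identical(g[7], 0.4)
    expect_true(all(diff(g) >= -1e-12))
  }
  expect_identical(gompertz_series(0.3, 0.3, 7), rep(0.3, 7))
  # b=3, c=4 at u=0.5 -> g ~ 0.6875 (interval 4 of 7)
  g <- gompertz_series(0, 1, 7)
  expect_equal(g[4], 0.6875, tolerance = 1e-3)
  expect_error(gompertz_shape(-1, 2), "positive")
})

test_that("linear and random series keep their endpoint and support contracts", {
  lin <- linear_series(0, 0.6, 7)
  expect_equal(lin[4], 0.3, tolerance = 1e-12)
  r1 <- random_series(0.1, 0.9, 7, seed = 4)
  r2 <- random_series(0.1, 0.9, 7, seed = 4)
  expect_identical(r1, r2)
  expect_identical(r1[c(1, 7)], c(0.1, 0.9))
  for (s in 1:20) {
    rr <- random_series(-0.5, 0.7, 7, seed = s)
    expect_true(all(rr >= -0.5 & rr <= 0.7))
  }
})

test_that("imputation concordance distinguishes identical, shifted, and unrelated vectors", {
  set.seed(3)
  a <- runif(30, -0.8, 0.8)
  ident <- imputation_concordance(a, a)
  expect_equal(ident$r, 1)
  expect_equal(ident$mean_diff, 0)
  shifted <- imputation_concordance(a + 0.2, a)
  expect_equal(shifted$r, 1)
  expect_lt(shifted$p, 1e-6)
  null_r <- vapply(1:50, function(s) {
    set.seed(s); imputation_concordance(runif(100, -1, 1),
                                        runif(100, -1, 1))$r
  }, numeric(1))
  expect_lt(median(abs(null_r)), 0.3)
  expect_error(imputation_concordance(1:3, 1:4), "equal length")
})

test_that("individual centering removes subject medians and half-ranges", {
  df <- data.frame(subject_id = rep(c("a", "b"), each = 7),
                   interval = rep(1:7, 2),
                   f1 = as.numeric(c(1:7, 101:107)), f2 = rnorm(14))
  cen <- center_features(df, cols = c("f1", "f2"))
  meds <- tapply(cen$f1, cen$subject_id, median)
  expect_true(all(meds == 0))
  # shift invariance: adding a constant to one subject changes nothing
  df2 <- df; df2$f1[df2$subject_id == "a"] <- df2$f1[df2$subject_id == "a"] + 50
  cen2 <- center_features(df2, cols = c("f1", "f2"))
  expect_identical(cen2$f1, cen$f1)
  # single-interval subject centers to zero
  one <- center_features(data.frame(subject_id = "z", interval = 1, f1 = 9),
                         cols = "f1")
  expect_identical(one$f1, 0)

  ser <- gompertz_series(0.2, 0.8, 7)
  cent <- center_outcomes(ser, 0.2, 0.8)
  expect_equal(cent[1], -0.3, tolerance = 1e-12)
  expect_equal(cent[7], 0.3, tolerance = 1e-12)
  expect_equal(cent[1] + cent[7], 0)
  expect_identical(center_outcomes(rep(0.5, 7), 0.5, 0.5), rep(0, 7))
  # un-centering recovers the series exactly
  expect_identical(cent + (0.2 + 0.8) / 2, ser)
})

test_that("random imputation attenuates planted correlations relative to Gompertz", {
  deltas <- vapply(1:12, function(s) {
    set.seed(s)
    n_subj <- 12; n_int <- 7
    y0 <- rnorm(n_subj); y1 <- y0 + rnorm(n_subj, 0.3, 0.3)
    g <- unlist(lapply(1:n_subj, function(i) gompertz_series(y0[i], y1[i], n_int)))
    rnd <- unlist(lapply(1:n_subj, function(i) {
      random_series(y0[i], y1[i], n_int, seed = s * 100 + i)
    }))
    x <- g + rnorm(length(g), 0, 0.4)  # feature coupled to the latent course
    abs(cor(x, g)) - abs(cor(x, rnd))
  }, numeric(1))
  expect_gt(median(deltas), 0)
})

test_that("impute_outcomes builds a per-interval table for every composite", {
  assess <- do.call(rbind, lapply(c("a", "b"), function(sid) {
    data.frame(subject_id = sid,
               composite = rep(c("executive_function", "processing_speed",
                                 "immediate_memory", "delayed_memory",
                                 "global_cognition"), 2),
               timepoint = rep(c("baseline", "post"), each = 5),
               z = rnorm(10), day = rep(c(-7L, 75L), each = 5))
  }))
  out <- impute_outcomes(assess, 7)
  expect_identical(nrow(out), 14L)
  a_ef <- out$executive_function[out$subject_id == "a"]
  expect_equal(a_ef[1], assess$z[assess$subject_id == "a" &
                                   assess$composite == "executive_function" &
                                   assess$timepoint == "baseline"])
  cen <- impute_outcomes(assess, 7, centered = TRUE)
  expect_equal(cen$executive_function[cen$subject_id == "a"][1] +
                 cen$executive_function[cen$subject_id == "a"][7], 0,
               tolerance = 1e-12)
})
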