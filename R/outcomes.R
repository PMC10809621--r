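#' Neuropsychological composite scores and interval outcome series
#'
#' Composite z-scores are arithmetic means of their constituent test z-scores;
#' the global score averages all tests. Scores observed only at baseline and
#' post-intervention are expanded to one value per 10-day interval by
#' interpolation (Gompertz sigmoid by default, linear and random as
#' comparators), and two centering transforms isolate intra-individual change.
#'
#' @name outcomes
NULL

COMPOSITES <- c("executive_function", "processing_speed", "immediate_memory",
                "delayed_memory", "global_cognition")

COMPOSITE_TESTS <- list(
  executive_function = c("digit_span", "similarities", "trail_making_b",
                         "category_fluency", "letter_fluency",
                         "category_switching_fluency"),
  processing_speed = c("trail_making_a", "symbol_digit"),
  immediate_memory = c("logical_memory_i", "ravlt_i_v", "visual_reproduction_i"),
  delayed_memory = c("logical_memory_ii", "ravlt_vii", "visual_reproduction_ii")
)

#' Compute composite scores from individual test z-scores
#'
#' Executive function averages digit span, similarities, trail-making B and the
#' three verbal fluency tests; processing speed averages trail-making A and
#' symbol-digit; immediate and delayed memory average their three memory tests;
#' global cognition is the mean of all fourteen tests (not of the composites).
#'
#' @param z named numeric vector of test z-scores; names from the canonical
#'   test list (see `COMPOSITE_TESTS`).
#' @return named numeric vector over the five composites; a composite whose
#'   constituents are incomplete is `NA` with a `reason` attribute.
#' @export
compute_composites <- function(z) {
  out <- setNames(rep(NA_real_, length(COMPOSITES)), COMPOSITES)
  reasons <- character()
  for (comp in names(COMPOSITE_TESTS)) {
    tests <- COMPOSITE_TESTS[[comp]]
    if (all(tests %in% names(z)) && !anyNA(z[tests])) {
      out[comp] <- mean(z[tests])
    } else {
      reasons[comp] <- "missing constituent test"
    }
  }
  all_tests <- unlist(COMPOSITE_TESTS, use.names = FALSE)
  if (all(all_tests %in% names(z)) && !anyNA(z[all_tests])) {
    out["global_cognition"] <- mean(z[all_tests])
  } else {
    reasons["global_cognition"] <- "missing constituent test"
  }
  if (length(reasons)) attr(out, "reason") <- reasons
  out
}

#' Gompertz shape parameters
#'
#' @param b displacement parameter, strictly positive.
#' @param c growth-rate parameter, strictly positive.
#' @return list of class `gompertz_shape`.
#' @export
gompertz_shape <- function(b = 3, c = 4) {
  if (!is.finite(b) || b <= 0 || !is.finite(c) || c <= 0) {
    stop("Gompertz shape parameters b and c must be strictly positive")
  }
  structure(list(b = b, c = c), class = "gompertz_shape")
}

# Normalized Gompertz ramp on [0,1] with g(0)=0, g(1)=1 exactly.
gompertz_ramp <- function(u, shape) {
  b <- shape$b; cc <- shape$c
  raw <- function(v) exp(-b * exp(-cc * v))
  (raw(u) - raw(0)) / (raw(1) - raw(0))
}

#' Interval outcome series by Gompertz interpolation
#'
#' Values at intervals `i = 1..n` follow
#' `y0 + (y1 - y0) * g((i-1)/(n-1))` where `g` is the Gompertz sigmoid
#' normalized to pass exactly through both assessments. Short-term cognitive
#' change is assumed monotone and plateauing, which the asymmetric sigmoid
#' encodes.
#'
#' @param y0,y1 baseline and post-intervention scores.
#' @param n number of intervals (default 7, i.e. 70 days in 10-day steps).
#' @param shape a [gompertz_shape()].
#' @return numeric vector of length `n`; endpoints equal `y0`, `y1` exactly.
#' @export
gompertz_series <- function(y0, y1, n = 7L, shape = gompertz_shape()) {
  stopifnot(n >= 2L)
  if (!inherits(shape, "gompertz_shape")) stop("shape must be a gompertz_shape")
  u <- (seq_len(n) - 1) / (n - 1)
  g <- gompertz_ramp(u, shape)
  out <- y0 + (y1 - y0) * g
  out[1] <- y0
  out[n] <- y1
  out
}

#' Linear interval outcome series
#' @inheritParams gompertz_series
#' @return numeric vector of length `n`, equally spaced from `y0` to `y1`.
#' @export
linear_series <- function(y0, y1, n = 7L) {
  stopifnot(n >= 2L)
  seq(y0, y1, length.out = n)
}

#' Random-imputation outcome series
#'
#' Endpoints are the observed scores; interior values are i.i.d. uniform on
#' the closed envelope between them -- a null imputation preserving range but
#' destroying temporal structure.
#'
#' @inheritParams gompertz_series
#' @param seed RNG seed for the interior draws.
#' @return numeric vector of length `n`.
#' @export
random_series <- function(y0, y1, n = 7L, seed = 1L) {
  stopifnot(n >= 2L)
  out <- numeric(n)
  out[1] <- y0; out[n] <- y1
  if (n > 2L) {
    out[2:(n - 1)] <- local_seed(seed, runif(n - 2L, min(y0, y1), max(y0, y1)))
  }
  out
}

#' Concordance between two sets of paired correlation coefficients
#'
#' Used to check that imputation does not distort the association structure:
#' feature-outcome correlations from the imputed dataset are compared with the
#' same pairs computed without imputation.
#'
#' @param corrs_a,corrs_b equal-length vectors of correlation coefficients for
#'   the same (outcome, feature) pairs.
#' @return list with `r` (Pearson correlation between the vectors),
#'   `p` (two-sided paired t-test p on the differences) and `mean_diff`.
#' @export
imputation_concordance <- function(corrs_a, corrs_b) {
  if (length(corrs_a) != length(corrs_b)) stop("paired vectors must have equal length")
  ok <- stats::complete.cases(corrs_a, corrs_b)
  a <- corrs_a[ok]; b <- corrs_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  d <- a - b
  # (near-)zero-variance differences: identical vectors carry no evidence of
  # a shift, a deterministic constant shift is unambiguous
  p <- if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) 1 else 0
  } else {
    stats::t.test(a, b, paired = TRUE)$p.value
  }
  list(r = stats::cor(a, b), p = p, mean_diff = mean(d), n = length(a))
}

#' Center features around individual medians
#'
#' Subtracts, per subject and feature, the median over that subject's
#' intervals, turning values into deviations from a conditional personal
#' baseline.
#'
#' @param df data.frame with a `subject_id` column and numeric feature columns.
#' @param cols character vector of columns to center (default: all numeric
#'   columns except `interval`, `age`).
#' @return data.frame of the same shape with centered columns.
#' @export
center_features <- function(df, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(df, is.numeric, logical(1))
    cols <- setdiff(names(df)[num], c("interval", "age", "day"))
  }
  for (cl in cols) {
    med <- stats::ave(df[[cl]], df$subject_id,
                      FUN = function(v) median(v, na.rm = TRUE))
    df[[cl]] <- df[[cl]] - med
  }
  df
}

#' Center an outcome series around its individual half-range
#'
#' Subtracts `(y0 + y1) / 2`, the midpoint between the subject's baseline and
#' post-intervention scores, so centered endpoints sum to zero.
#'
#' @param series numeric outcome series built from `(y0, y1)`.
#' @param y0,y1 the observed baseline and post scores.
#' @return centered numeric vector.
#' @export
center_outcomes <- function(series, y0, y1) {
  series - (y0 + y1) / 2
}

#' Build the per-subject interval outcome table
#'
#' @param assessments long-form assessments table (see [read_assessments()]).
#' @param n_intervals number of 10-day intervals.
#' @param method `"gompertz"`, `"linear"` or `"random"`.
#' @param shape [gompertz_shape()] used when `method = "gompertz"`.
#' @param seed seed for `method = "random"`.
#' @param centered if `TRUE`, apply the half-range centering.
#' @return data.frame: `subject_id`, `interval`, one column per composite.
#' @export
impute_outcomes <- function(assessments, n_intervals = 7L, method = "gompertz",
                            shape = gompertz_shape(), seed = 1L,
                            centered = FALSE) {
  method <- match.arg(method, c("gompertz", "linear", "random"))
  subjects <- unique(assessments$subject_id)
  rows <- lapply(seq_along(subjects), function(si) {
    sid <- subjects[si]
    d <- assessments[assessments$subject_id == sid, ]
    out <- data.frame(subject_id = sid, interval = seq_len(n_intervals))
    for (comp in COMPOSITES) {
      y0 <- d$z[d$composite == comp & d$timepoint == "baseline"]
      y1 <- d$z[d$composite == comp & d$timepoint == "post"]
      ser <- switch(method,
        gompertz = gompertz_series(y0, y1, n_intervals, shape),
        linear = linear_series(y0, y1, n_intervals),
        random = random_series(y0, y1, n_intervals, derive_seed(seed, si)))
      if (centered) ser <- center_outcomes(ser, y0, y1)
      out[[comp]] <- ser
    }
    out
  })
  do.call(rbind, rows)
}
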