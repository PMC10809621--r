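#' End-to-end pipeline orchestration
#'
#' From raw recordings to cross-validated predictions: segmentation and QC,
#' per-segment feature extraction, IBI-availability filtering, night-window
#' restriction, daily/interval aggregation, redundancy pruning, outcome
#' imputation, association screening and the prediction grid -- for the
#' uncentered and centered dataset variants.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param th [qc_thresholds()].
#' @param utc_offset study UTC offset in seconds (wall-clock night window).
#' @param night_window `"auto"` for data-driven selection via
#'   [select_night_window()], or a `night_window` object to pin it.
#' @param span_start_h,span_end_h candidate span for auto selection.
#' @param min_day_samples minimum valid 5-min samples per day.
#' @param interval_days,observation_days aggregation spans.
#' @param imputation_method,shape,imputation_seed outcome imputation.
#' @param variants dataset variants to build.
#' @param outcomes composites to screen/predict.
#' @param schemes CV schemes to run.
#' @param thresholds feature-selection thresholds for the grid.
#' @param run_lmer whether to run the mixed-model screen.
#' @param run_grid whether to run the prediction grid.
#' @param seed seed for stochastic learners.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(th = qc_thresholds(), utc_offset = 0,
                            night_window = "auto", span_start_h = 21,
                            span_end_h = 9, min_day_samples = 4L,
                            interval_days = 10L, observation_days = 70L,
                            imputation_method = "gompertz",
                            shape = gompertz_shape(), imputation_seed = 1L,
                            variants = c("uncentered", "centered"),
                            outcomes = COMPOSITES,
                            schemes = c("LOSO", "LOIO"),
                            thresholds = DEFAULT_THRESHOLDS,
                            run_lmer = FALSE, run_grid = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Segment a cohort and extract per-window features
#'
#' @param cohort a `wc_cohort`.
#' @param th [qc_thresholds()].
#' @param utc_offset UTC offset in seconds.
#' @return data.frame: `subject_id`, `day`, `slot`, group validity flags and
#'   one column per registry feature.
#' @export
cohort_segment_features <- function(cohort, th = qc_thresholds(),
                                    utc_offset = 0) {
  rows <- list()
  sids <- character()
  for (sid in names(cohort$sessions)) {
    for (night in cohort$sessions[[sid]]) {
      recs <- night$recordings
      segs <- list()
      for (ch in names(recs)) {
        rec <- recs[[ch]]
        t0 <- rec$start_time + utc_offset
        t1 <- t0 + n_samples(rec) / rec$sampling_rate
        for (dy in seq.int(floor(t0 / 86400), floor(max(t0, t1 - 1e-9) / 86400))) {
          for (sg in segment_day(rec, dy, utc_offset, sid)) {
            key <- sprintf("%d_%d", dy, sg$slot)
            segs[[key]][[ch]] <- sg
          }
        }
      }
      for (key in names(segs)) {
        parts <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
        dy <- parts[1]; slot <- parts[2]
        ibi <- if (!is.null(night$ibi)) {
          ibi_in_window(night$ibi, dy, slot, utc_offset)
        } else NULL
        fv <- extract_all(bvp = segs[[key]]$BVP, eda = segs[[key]]$EDA,
                          temp = segs[[key]]$TEMP, hr = segs[[key]]$HR,
                          ibi = ibi, th = th)
        valid <- attr(fv, "valid")
        rows[[length(rows) + 1L]] <- c(
          day = dy, slot = slot,
          ppg_valid = valid[["PPG"]], ibi_valid = valid[["IBI"]],
          eda_valid = valid[["EDA"]], hr_valid = valid[["HR"]],
          temp_valid = valid[["TEMP"]], fv)
        sids[length(sids) + 1L] <- sid
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject_id = character(), day = integer(),
                      slot = integer()))
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(subject_id = sids, mat, check.names = FALSE)
  for (fl in c("ppg_valid", "ibi_valid", "eda_valid", "hr_valid",
               "temp_valid")) {
    out[[fl]] <- as.logical(out[[fl]])
  }
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' @param cohort a `wc_cohort` (in memory or from [read_cohort()]).
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_run`: interval datasets per variant,
#'   association tables, prediction grids, the chosen night window, kept
#'   features, and a manifest of row counts per stage.
#' @export
run_full <- function(cohort, cfg = pipeline_config()) {
  manifest <- list(seed = cfg$seed)
  seg_rows <- cohort_segment_features(cohort, cfg$th, cfg$utc_offset)
  manifest$n_segment_rows <- nrow(seg_rows)

  ibi_rows <- require_ibi(seg_rows)
  manifest$n_ibi_rows <- nrow(ibi_rows)

  win <- if (inherits(cfg$night_window, "night_window")) {
    cfg$night_window
  } else {
    hr_rows <- seg_rows[seg_rows$hr_valid, c("slot", "HR_Mean")]
    names(hr_rows) <- c("slot", "hr")
    select_night_window(hr_rows, cfg$span_start_h, cfg$span_end_h)
  }
  manifest$night_window <- win$start_hms

  daily <- daily_aggregate(ibi_rows, win, cfg$min_day_samples)
  manifest$n_days <- nrow(daily)

  interval <- interval_aggregate(daily, cfg$interval_days,
                                 cfg$observation_days)
  manifest$n_intervals <- nrow(interval)

  feat_cols0 <- intersect(feature_registry()$name, names(interval))
  pruning <- drop_redundant_features(interval[, feat_cols0, drop = FALSE])
  feat_cols <- pruning$kept
  manifest$n_features_kept <- length(feat_cols)

  demo <- cohort$subjects
  demo$sex_code <- ifelse(demo$sex == "female", 1, 0)

  out <- list(night_window = win, pruning = pruning, manifest = manifest,
              variants = list())
  for (variant in cfg$variants) {
    centered <- variant == "centered"
    outc <- impute_outcomes(cohort$assessments,
                            n_intervals = as.integer(cfg$observation_days /
                                                       cfg$interval_days),
                            method = cfg$imputation_method,
                            shape = cfg$shape, seed = cfg$imputation_seed,
                            centered = centered)
    feats <- interval
    if (centered) {
      feats <- center_features(feats, cols = feat_cols)
    }
    ds <- merge(feats, outc, by = c("subject_id", "interval"))
    ds <- merge(ds, demo[, c("subject_id", "age", "sex_code")],
                by = "subject_id")
    names(ds)[names(ds) == "sex_code"] <- "sex"
    ds <- ds[order(ds$subject_id, ds$interval), ]
    rownames(ds) <- NULL

    assoc <- correlation_screen(ds[, feat_cols, drop = FALSE],
                                ds[, cfg$outcomes, drop = FALSE])
    lmer_tab <- NULL
    if (cfg$run_lmer) {
      lmer_tab <- lmer_screen_all(ds[, feat_cols, drop = FALSE],
                                  ds[, cfg$outcomes, drop = FALSE],
                                  ds$subject_id)
    }
    grids <- NULL
    if (cfg$run_grid) {
      grids <- list()
      for (oc in cfg$outcomes) {
        for (sch in cfg$schemes) {
          grids[[paste(oc, sch, sep = "|")]] <-
            model_grid(ds, oc, feat_cols, scheme = sch,
                       thresholds = cfg$thresholds, seed = cfg$seed)
        }
      }
    }
    out$variants[[variant]] <- list(dataset = ds, associations = assoc,
                                    lmer = lmer_tab, grids = grids,
                                    feature_cols = feat_cols)
  }
  structure(out, class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<pipeline_run> %d segment rows -> %d with IBI -> ",
                     "%d days -> %d intervals; %d features kept; window %s\n"),
              m$n_segment_rows, m$n_ibi_rows, m$n_days, m$n_intervals,
              m$n_features_kept, m$night_window))
  invisible(x)
}

#' One-command synthetic demonstration
#'
#' Generates a cohort with strong high-frequency-HRV coupling to executive
#' function (or a zero-coupling null when `coupling_slope = 0`), runs the
#' full pipeline at a desk-scale problem size, and returns the run together
#' with the cohort truth. Problem size defaults: 17 subjects x 70 days,
#' ~25 min of nightly wear inside a pinned 01:00-06:00 window.
#'
#' @param seed master seed.
#' @param coupling_slope linear slope of the HF modulation amplitude (ms per
#'   z-score of latent executive function).
#' @param n_subjects,observation_days cohort size.
#' @param nightly_wear_hours nightly wear duration (hours).
#' @param channels channels to synthesize.
#' @param outcomes outcomes to screen/predict.
#' @param schemes CV schemes.
#' @param run_grid whether to run the prediction grid.
#' @param run_lmer whether to run the mixed-model screen.
#' @return list: `cohort`, `run` (a `pipeline_run`), `config`.
#' @export
run_demo <- function(seed = 1L, coupling_slope = 8, n_subjects = 17L,
                     observation_days = 70L, nightly_wear_hours = 5 / 12,
                     channels = c("BVP", "EDA", "TEMP"),
                     outcomes = "executive_function",
                     schemes = c("LOSO", "LOIO"), run_grid = TRUE,
                     run_lmer = FALSE) {
  sim <- simulation_config(
    n_subjects = n_subjects, observation_days = observation_days,
    nightly_wear_hours = nightly_wear_hours, wear_jitter_slots = 2L,
    coupling = list(hf_amp = coupling_slope), seed = derive_seed(seed, 101))
  cohort <- generate_cohort(sim, channels = channels)
  cfg <- pipeline_config(night_window = fixed_night_window(1, 5),
                         observation_days = observation_days,
                         outcomes = outcomes, schemes = schemes,
                         run_grid = run_grid, run_lmer = run_lmer,
                         seed = derive_seed(seed, 202))
  run <- run_full(cohort, cfg)
  list(cohort = cohort, run = run, config = cfg)
}

#' Bookkeeping arithmetic of a study layout
#'
#' Converts sample counts and spans into the derived quantities the analysis
#' reports: minutes of valid data from the number of 5-min samples, mean
#' observed days per subject, intervals per subject, and the number of
#' models trained per outcome in the grid.
#'
#' @param n_samples number of valid 5-min samples.
#' @param n_days total days with data.
#' @param n_subjects number of subjects.
#' @param observation_days,interval_days aggregation spans.
#' @param thresholds feature-selection thresholds in the grid.
#' @return list: `minutes`, `mean_days_per_subject`,
#'   `intervals_per_subject`, `models_per_outcome`.
#' @export
study_bookkeeping <- function(n_samples, n_days, n_subjects,
                              observation_days = 70L, interval_days = 10L,
                              thresholds = DEFAULT_THRESHOLDS) {
  list(minutes = n_samples * SEGMENT_SECONDS / 60,
       mean_days_per_subject = n_days / n_subjects,
       intervals_per_subject = observation_days %/% interval_days,
       models_per_outcome = length(thresholds) * length(ALGORITHMS))
}
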