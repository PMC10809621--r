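#' Cross-validated prediction of composite scores
#'
#' Three model families (elastic-net linear regression, random forest,
#' gradient-boosted trees) by three feature sets (demographics only, combined,
#' physiology only) by four feature-selection thresholds, evaluated under
#' leave-one-subject-out (LOSO) and leave-one-interval-out (LOIO)
#' cross-validation with statistical feature selection re-run inside every
#' training fold.
#'
#' @name prediction
NULL

DEFAULT_THRESHOLDS <- c(0.05, 0.001, 1e-4, 1e-5)
ALGORITHMS <- c("elasticnet", "random_forest", "xgboost")

#' Per-fold statistical feature selection
#'
#' Keeps features whose Pearson AND Spearman correlation p-values with the
#' training outcome are below the threshold, orders them by descending
#' absolute Pearson r, then greedily prunes any feature correlated at
#' `|r| > prune_r` with an already-kept one.
#'
#' @param X training feature data.frame.
#' @param y training outcome vector.
#' @param p_threshold selection threshold applied to both p-values (strict).
#' @param prune_r multicollinearity pruning threshold on `|r|` (strict).
#' @return character vector of selected feature names (possibly empty).
#' @export
select_features <- function(X, y, p_threshold = 0.05, prune_r = 0.9) {
  X <- as.data.frame(X)
  stats_tab <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(name = nm, r = NA_real_, p_p = 1, p_s = 1))
    }
    r <- stats::cor(x[ok], y[ok])
    rho <- stats::cor(rank(x[ok]), rank(y[ok]))
    data.frame(name = nm, r = r, p_p = cor_pval(r, sum(ok)),
               p_s = cor_pval(rho, sum(ok)))
  })
  tab <- do.call(rbind, stats_tab)
  tab <- tab[!is.na(tab$r) & tab$p_p < p_threshold & tab$p_s < p_threshold, ]
  if (nrow(tab) == 0L) return(character())
  tab <- tab[order(-abs(tab$r)), ]
  kept <- character()
  for (nm in tab$name) {
    if (length(kept)) {
      rr <- vapply(kept, function(k) {
        r <- suppressWarnings(stats::cor(X[[nm]], X[[k]],
                                         use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1))
      if (any(rr > prune_r)) next
    }
    kept <- c(kept, nm)
  }
  kept
}

fit_predict <- function(algorithm, Xtr, ytr, Xte, seed) {
  # guard: no usable predictors -> training-mean prediction
  if (ncol(Xtr) == 0L) return(rep(mean(ytr), nrow(Xte)))
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  # impute residual NAs with training-column means
  mu <- colMeans(Xtr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(Xtr))) {
    Xtr[is.na(Xtr[, j]), j] <- mu[j]
    Xte[is.na(Xte[, j]), j] <- mu[j]
  }
  if (algorithm == "elasticnet") {
    if (ncol(Xtr) < 2L) {
      d <- data.frame(y = ytr, x = Xtr[, 1L])
      fit <- stats::lm(y ~ x, data = d)
      return(as.numeric(stats::predict(fit, data.frame(x = Xte[, 1L]))))
    }
    fit <- glmnet::glmnet(Xtr, ytr, alpha = 0.5, standardize = TRUE)
    return(as.numeric(stats::predict(fit, newx = Xte, s = 0.05)))
  }
  if (algorithm == "random_forest") {
    fit <- local_seed(seed,
      randomForest::randomForest(Xtr, ytr, ntree = 500L))
    return(as.numeric(stats::predict(fit, Xte)))
  }
  if (algorithm == "xgboost") {
    fit <- local_seed(seed,
      xgboost::xgb.train(
        params = list(max_depth = 3L, eta = 0.1,
                      objective = "reg:squarederror", nthread = 1L),
        data = xgboost::xgb.DMatrix(Xtr, label = ytr), nrounds = 300L))
    return(as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(Xte))))
  }
  stop("unknown algorithm: ", algorithm)
}

#' Pooled out-of-fold performance metrics
#'
#' @param pred pooled out-of-fold predictions.
#' @param actual actual values (same length, >= 3).
#' @return list `r`, `rho`, `mae`; correlations are `NA` with a reason when
#'   either vector is constant, MAE is always computed.
#' @export
evaluate_predictions <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("prediction/actual length mismatch")
  stopifnot(length(pred) >= 3L)
  mae <- mean(abs(actual - pred))
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    return(list(r = NA_real_, rho = NA_real_, mae = mae,
                reason = "constant predictions or outcomes"))
  }
  list(r = stats::cor(pred, actual),
       rho = stats::cor(rank(pred), rank(actual)),
       mae = mae)
}

#' Run one cross-validated model configuration
#'
#' LOSO holds out all rows of one subject per fold; LOIO holds out all rows
#' of one interval index. Feature selection, missing-value imputation and
#' model fitting see training rows only; the audit trail records the exact
#' row indices used so leakage is checkable after the fact.
#'
#' @param data interval dataset: columns `subject_id`, `interval`, `age`,
#'   `sex` (female = 1, male = 0), feature columns, and the outcome.
#' @param outcome outcome column name.
#' @param feature_cols physiological feature column names.
#' @param feature_set `"demographics"`, `"combined"` or `"physio"`.
#' @param algorithm one of `"elasticnet"`, `"random_forest"`, `"xgboost"`.
#' @param scheme `"LOSO"` or `"LOIO"`.
#' @param selection_p feature-selection p threshold (ignored for
#'   demographics).
#' @param seed RNG seed for stochastic learners.
#' @return list of class `cv_result`: pooled predictions aligned to rows,
#'   metrics, per-fold selected features, and the audit log.
#' @export
run_cv <- function(data, outcome, feature_cols,
                   feature_set = c("combined", "demographics", "physio"),
                   algorithm = "elasticnet", scheme = c("LOSO", "LOIO"),
                   selection_p = 0.05, seed = 1L) {
  feature_set <- match.arg(feature_set)
  scheme <- match.arg(scheme)
  fold_var <- if (scheme == "LOSO") data$subject_id else data$interval
  folds <- unique(fold_var)
  if (length(folds) < 3L) stop("need at least 3 folds")
  pred <- rep(NA_real_, nrow(data))
  audit <- list()
  selected <- list()
  demo_cols <- c("age", "sex")
  for (f in folds) {
    te <- which(fold_var == f)
    tr <- which(fold_var != f)
    if (length(tr) == 0L) stop("fold with empty training set")
    ytr <- data[[outcome]][tr]
    feats <- character()
    if (feature_set != "demographics") {
      feats <- select_features(data[tr, feature_cols, drop = FALSE], ytr,
                               p_threshold = selection_p)
    }
    cols <- switch(feature_set,
      demographics = demo_cols,
      physio = feats,
      combined = c(demo_cols, feats))
    if (feature_set == "combined" && length(feats) == 0L) cols <- demo_cols
    if (length(cols) == 0L) {
      pred[te] <- mean(ytr)
    } else {
      pred[te] <- fit_predict(algorithm,
                              data[tr, cols, drop = FALSE], ytr,
                              data[te, cols, drop = FALSE],
                              derive_seed(seed, match(f, folds)))
    }
    audit[[as.character(f)]] <- list(train_rows = tr, test_rows = te)
    selected[[as.character(f)]] <- feats
  }
  metrics <- evaluate_predictions(pred, data[[outcome]])
  n_feats <- vapply(selected, length, integer(1))
  structure(list(outcome = outcome, feature_set = feature_set,
                 algorithm = algorithm, scheme = scheme,
                 selection_p = selection_p, predictions = pred,
                 actual = data[[outcome]],
                 r = metrics$r, rho = metrics$rho, mae = metrics$mae,
                 n_features_median = stats::median(n_feats),
                 n_features_union = length(unique(unlist(selected))),
                 selected = selected, audit = audit, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %s | %s | p<%g: r=%.3f rho=%.3f mae=%.3f\n",
              x$outcome, x$scheme, x$algorithm, x$selection_p,
              x$r, x$rho, x$mae))
  invisible(x)
}

#' Check a CV audit trail for train/test leakage
#'
#' @param audit the `audit` element of a `cv_result` (or a like-shaped list).
#' @return `TRUE` if every fold's training rows are disjoint from its test
#'   rows and every row is predicted exactly once; otherwise `FALSE` with a
#'   `reason` attribute.
#' @export
detect_leakage <- function(audit) {
  tested <- integer()
  for (f in audit) {
    if (length(intersect(f$train_rows, f$test_rows))) {
      return(structure(FALSE, reason = "train/test overlap within a fold"))
    }
    tested <- c(tested, f$test_rows)
  }
  if (anyDuplicated(tested)) {
    return(structure(FALSE, reason = "row predicted in more than one fold"))
  }
  TRUE
}

#' The full model grid for one outcome and scheme
#'
#' Runs 4 selection thresholds x 3 algorithms for the combined and
#' physiology-only feature sets, plus a demographics-only baseline per
#' algorithm; gains are computed against the matched demographics baseline.
#' Best model: highest Pearson r among combined models, ties broken by fewer
#' features then by algorithm order (elastic net first).
#'
#' @inheritParams run_cv
#' @param thresholds selection thresholds (default
#'   `c(0.05, 0.001, 1e-4, 1e-5)`).
#' @return list with `results` (data.frame over all configurations), `best`
#'   (the best combined `cv_result`) and `baseline` r by algorithm.
#' @export
model_grid <- function(data, outcome, feature_cols, scheme = "LOSO",
                       thresholds = DEFAULT_THRESHOLDS, seed = 1L) {
  baseline <- list()
  for (alg in ALGORITHMS) {
    baseline[[alg]] <- run_cv(data, outcome, feature_cols, "demographics",
                              alg, scheme, selection_p = NA_real_,
                              seed = seed)
  }
  rows <- list(); fits <- list()
  for (fs in c("combined", "physio")) {
    for (alg in ALGORITHMS) {
      for (p in thresholds) {
        cv <- run_cv(data, outcome, feature_cols, fs, alg, scheme,
                     selection_p = p, seed = seed)
        base <- baseline[[alg]]
        r_gain <- if (is.na(cv$r)) NA_real_ else {
          cv$r - if (is.na(base$r)) 0 else base$r
        }
        rho_gain <- if (is.na(cv$rho)) NA_real_ else {
          cv$rho - if (is.na(base$rho)) 0 else base$rho
        }
        key <- sprintf("%s|%s|%g", fs, alg, p)
        fits[[key]] <- cv
        rows[[key]] <- data.frame(
          outcome = outcome, scheme = scheme, feature_set = fs,
          algorithm = alg, selection_p = p, r = cv$r, rho = cv$rho,
          mae = cv$mae, r_gain = r_gain, rho_gain = rho_gain,
          n_features_median = cv$n_features_median,
          n_features_union = cv$n_features_union)
      }
    }
  }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  comb <- results[results$feature_set == "combined", ]
  ord <- order(-ifelse(is.na(comb$r), -Inf, comb$r),
               comb$n_features_median,
               match(comb$algorithm, ALGORITHMS))
  best_row <- comb[ord[1L], ]
  best_key <- sprintf("combined|%s|%g", best_row$algorithm,
                      best_row$selection_p)
  list(results = results, best = fits[[best_key]], best_row = best_row,
       baseline = vapply(baseline, function(b) b$r, numeric(1)),
       baseline_rho = vapply(baseline, function(b) b$rho, numeric(1)))
}

#' Summary tables of a completed grid
#'
#' @param grids named list of [model_grid()] outputs, keyed
#'   `outcome|scheme`.
#' @return list with `best` (one row per outcome x scheme: algorithm,
#'   number of features, selection p, r, r gain, rho, rho gain, MAE) and
#'   `by_algorithm` (mean Pearson r across thresholds for combined models).
#' @export
grid_report <- function(grids) {
  best <- do.call(rbind, lapply(grids, function(g) {
    b <- g$best_row
    data.frame(scheme = b$scheme, outcome = b$outcome,
               algorithm = b$algorithm,
               n_features = b$n_features_median,
               selection_p = b$selection_p,
               r = b$r, r_gain = b$r_gain, rho = b$rho,
               rho_gain = b$rho_gain, mae = b$mae)
  }))
  rownames(best) <- NULL
  by_alg <- do.call(rbind, lapply(grids, function(g) {
    comb <- g$results[g$results$feature_set == "combined", ]
    agg <- tapply(comb$r, comb$algorithm, mean, na.rm = TRUE)
    data.frame(scheme = comb$scheme[1], outcome = comb$outcome[1],
               algorithm = names(agg), mean_r = as.numeric(agg))
  }))
  rownames(by_alg) <- NULL
  list(best = best, by_algorithm = by_alg)
}
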