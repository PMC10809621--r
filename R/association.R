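#' Association screening between features and outcomes
#'
#' Pearson and Spearman correlations for every (outcome, feature) pair, with
#' Benjamini-Hochberg FDR adjustment across all pairs (separately per
#' statistic family), a both-statistics significance rule, and
#' random-intercept mixed-model screening of fixed effects.
#'
#' @name association
NULL

#' Pearson/Spearman correlation screen over all outcome-feature pairs
#'
#' Two-sided p-values use the t transform on the coefficient (the standard
#' large-sample approximation, also used for Spearman under ties); pairs are
#' computed on pairwise-complete rows and require at least `min_n` of them.
#'
#' @param X data.frame/matrix of features (columns = features).
#' @param Y data.frame of outcome columns.
#' @param min_n minimum complete pairs per cell.
#' @return data.frame keyed (`outcome`, `feature`) with `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n`, `flag`, plus BH-adjusted
#'   columns `pearson_p_adj`, `spearman_p_adj` (each family adjusted across
#'   all pairs).
#' @export
correlation_screen <- function(X, Y, min_n = 3L) {
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  grid <- expand.grid(feature = names(X), outcome = names(Y),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- X[[grid$feature[i]]]; y <- Y[[grid$outcome[i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    row <- data.frame(outcome = grid$outcome[i], feature = grid$feature[i],
                      pearson_r = NA_real_, pearson_p = NA_real_,
                      spearman_rho = NA_real_, spearman_p = NA_real_,
                      n = n, flag = "")
    if (n < min_n) { row$flag <- "too few pairs"; return(row) }
    xv <- x[ok]; yv <- y[ok]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      row$flag <- "zero variance"; return(row)
    }
    r <- stats::cor(xv, yv)
    rho <- stats::cor(rank(xv), rank(yv))
    row$pearson_r <- r
    row$pearson_p <- cor_pval(r, n)
    row$spearman_rho <- rho
    row$spearman_p <- cor_pval(rho, n)
    row
  })
  out <- do.call(rbind, res)
  out$pearson_p_adj <- NA_real_
  out$spearman_p_adj <- NA_real_
  ok <- !is.na(out$pearson_p)
  out$pearson_p_adj[ok] <- fdr_adjust(out$pearson_p[ok])
  ok <- !is.na(out$spearman_p)
  out$spearman_p_adj[ok] <- fdr_adjust(out$spearman_p[ok])
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairs significant under the both-statistics rule
#'
#' @param table output of [correlation_screen()].
#' @param alpha significance level; both adjusted p-values must be strictly
#'   below it.
#' @return the subset of rows passing the rule.
#' @export
significant_pairs <- function(table, alpha = 0.05) {
  sel <- !is.na(table$pearson_p_adj) & !is.na(table$spearman_p_adj) &
    table$pearson_p_adj < alpha & table$spearman_p_adj < alpha
  table[sel, , drop = FALSE]
}

#' Random-intercept mixed-model screen of one feature-outcome pair
#'
#' Fits `outcome ~ feature + (1 | subject)` by REML; the slope p-value uses
#' the normal approximation to the t statistic, and the fixed-effect R^2 is
#' `Var(slope * feature) / (Var(slope * feature) + Var(intercept) +
#' Var(residual))`.
#'
#' @param x feature values.
#' @param y outcome values.
#' @param subject subject identifiers (grouping factor).
#' @return one-row data.frame: `slope`, `slope_p`, `r2_fixed`, `converged`.
#' @export
lmer_screen <- function(x, y, subject) {
  fail <- data.frame(slope = NA_real_, slope_p = NA_real_,
                     r2_fixed = NA_real_, converged = FALSE)
  ok <- stats::complete.cases(x, y, subject)
  x <- x[ok]; y <- y[ok]; subject <- subject[ok]
  if (length(unique(subject)) < 2L || stats::sd(x) == 0) return(fail)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | subject),
                 data = data.frame(x = x, y = y, subject = subject),
                 REML = TRUE)
    )),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  sm <- summary(fit)$coefficients
  if (!"x" %in% rownames(sm)) return(fail)
  beta <- sm["x", "Estimate"]
  tval <- sm["x", "t value"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_int <- vc$vcov[vc$grp == "subject"][1]
  v_res <- vc$vcov[vc$grp == "Residual"][1]
  v_fix <- stats::var(beta * x)
  data.frame(slope = beta,
             slope_p = 2 * stats::pnorm(-abs(tval)),
             r2_fixed = v_fix / (v_fix + v_int + v_res),
             converged = TRUE)
}

#' Mixed-model screen over all outcome-feature pairs
#'
#' @param X features data.frame.
#' @param Y outcomes data.frame.
#' @param subject subject identifiers aligned with rows.
#' @return data.frame keyed (`outcome`, `feature`) with slope, p, fixed-effect
#'   R^2 and BH-adjusted p across all converged pairs.
#' @export
lmer_screen_all <- function(X, Y, subject) {
  X <- as.data.frame(X); Y <- as.data.frame(Y)
  grid <- expand.grid(feature = names(X), outcome = names(Y),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cbind(data.frame(outcome = grid$outcome[i], feature = grid$feature[i]),
          lmer_screen(X[[grid$feature[i]]], Y[[grid$outcome[i]]], subject))
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- out$converged & !is.na(out$slope_p)
  out$p_adj[ok] <- fdr_adjust(out$slope_p[ok])
  out
}
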