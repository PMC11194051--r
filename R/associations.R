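#' Standardized-beta regression of one outcome on one exposure
#'
#' Ordinary least squares of the outcome on the exposure plus covariates,
#' on the complete-case subsample, with all continuous variables z-scored
#' on that subsample (binary sex enters as a 0/1 indicator, not z-scored).
#' The exposure coefficient is reported with a normal-theory 95% CI and a
#' two-tailed p-value. When `transform = "auto"`, the outcome is log10
#' transformed first if the base-model residuals are markedly non-normal
#' (see [transform_rule()]); this mirrors the convention of applying log10
#' transformations as needed.
#'
#' @param outcome,exposure column names in `data`.
#' @param covariates character vector of covariate column names; `"sex"` is
#'   treated as binary.
#' @param data data.frame.
#' @param transform `"auto"`, `"never"` or `"always"` (log10 of outcome).
#' @param conf_level confidence level.
#' @param min_n minimum complete cases.
#' @param z_covariates also z-score continuous covariates (default TRUE).
#' @return data.frame of class `association_result`: `outcome`, `exposure`,
#'   `std_beta`, `ci_low`, `ci_high`, `p`, `n`, `transformed`, `covariates`.
#' @export
standardized_beta <- function(outcome, exposure, covariates = character(0),
                              data, transform = c("auto", "never", "always"),
                              conf_level = 0.95, min_n = 10,
                              z_covariates = TRUE) {
  transform <- match.arg(transform)
  cols <- unique(c(outcome, exposure, covariates))
  d <- data[, cols, drop = FALSE]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    mf_stop("metflexr_insufficient_n",
            sprintf("only %d complete cases (< %d)", n, min_n))
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      mf_stop("metflexr_collinearity", "constant variable in design")
    (x - mean(x)) / s
  }
  prep <- function(nm, z = TRUE) {
    x <- d[[nm]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- as.numeric(as.factor(x)) - 1
      if (length(unique(x)) > 2) mf_config_error("only binary factors supported")
      return(x)
    }
    if (z) zscore(x) else x
  }
  y_raw <- d[[outcome]]
  transformed <- FALSE
  needs_log <- function() {
    preds <- c(exposure, covariates)
    Xb <- as.data.frame(lapply(setNames(preds, preds), prep, z = FALSE))
    transform_rule(residuals(lm(y_raw ~ ., data = Xb)))
  }
  if (transform == "always" || (transform == "auto" && needs_log())) {
    if (any(y_raw <= 0))
      transformed <- FALSE  # log10 impossible; keep raw scale
    else {
      y_raw <- log10(y_raw)
      transformed <- TRUE
    }
  }
  y <- zscore(y_raw)
  X <- data.frame(x = prep(exposure))
  for (cv in covariates) X[[cv]] <- prep(cv, z = z_covariates)
  fit <- lm(y ~ ., data = X)
  if (anyNA(coef(fit)))
    mf_stop("metflexr_collinearity", "singular design matrix")
  sm <- summary(fit)
  est <- sm$coefficients["x", "Estimate"]
  se <- sm$coefficients["x", "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  out <- data.frame(
    outcome = outcome, exposure = exposure,
    std_beta = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    p = sm$coefficients["x", "Pr(>|t|)"],
    n = n, transformed = transformed,
    covariates = paste(covariates, collapse = "+")
  )
  class(out) <- c("association_result", class(out))
  out
}

#' Sensitivity refit with total physical activity as extra covariate
#'
#' Refits a sedentary-time / standing / steps association with total PA
#' appended to the covariate set and reports both models side by side,
#' flagging a change in significance at `alpha`, plus the augmented-model
#' VIFs.
#'
#' @param outcome,exposure,covariates,data as in [standardized_beta()].
#' @param total_pa name of the total-PA column.
#' @param alpha significance level for the change flag.
#' @param ... passed to [standardized_beta()].
#' @return List with `base`, `adjusted`, `significance_changed`, `vif`.
#' @export
sensitivity_adjust_total_pa <- function(outcome, exposure, covariates,
                                        data, total_pa = "total_pa_h",
                                        alpha = 0.05, ...) {
  base <- standardized_beta(outcome, exposure, covariates, data, ...)
  adj <- standardized_beta(outcome, exposure, c(covariates, total_pa), data, ...)
  cols <- unique(c(exposure, covariates, total_pa))
  dd <- data[complete.cases(data[, unique(c(outcome, cols))]), cols, drop = FALSE]
  dd <- as.data.frame(lapply(dd, function(x)
    if (is.character(x) || is.factor(x)) as.numeric(as.factor(x)) - 1 else x))
  list(
    base = base, adjusted = adj,
    significance_changed = (base$p < alpha) != (adj$p < alpha),
    vif = vif_check(dd)
  )
}

#' Partial Pearson correlation
#'
#' Residualizes `x` and `y` on the covariates by least squares and returns
#' the Pearson correlation of the residuals, with a t-distribution p-value
#' on n − 2 − k degrees of freedom.
#'
#' @param x,y column names in `data`.
#' @param covariates covariate column names (default sex and age).
#' @param data data.frame.
#' @param min_n minimum complete cases.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_pearson <- function(x, y, covariates = c("sex", "age"), data,
                            min_n = 10) {
  cols <- unique(c(x, y, covariates))
  d <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < min_n)
    mf_stop("metflexr_insufficient_n", sprintf("only %d complete cases", n))
  num <- function(v) if (is.character(v) || is.factor(v)) as.numeric(as.factor(v)) - 1 else v
  d[] <- lapply(d, num)
  resid_on <- function(v) {
    if (!length(covariates)) return(v - mean(v))
    residuals(lm(v ~ ., data = d[, covariates, drop = FALSE]))
  }
  rx <- resid_on(d[[x]]); ry <- resid_on(d[[y]])
  if (sd(rx) == 0 || sd(ry) == 0)
    mf_stop("metflexr_undefined_correlation", "constant residuals")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - length(covariates)
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Paired change test
#'
#' Two-tailed paired t test for within-subject change (fasting to insulin
#' stimulation, or low-intensity to maximal exercise).
#'
#' @param before,after paired numeric vectors.
#' @return List with `mean_delta`, `p`, `n`.
#' @export
paired_change_test <- function(before, after) {
  ok <- complete.cases(before, after)
  b <- before[ok]; a <- after[ok]
  if (length(b) < 2L) mf_insufficient_data("paired test needs n >= 2")
  d <- a - b
  if (sd(d) == 0)
    return(list(mean_delta = mean(d), p = if (mean(d) == 0) 1 else 0,
                n = length(d)))
  tt <- t.test(a, b, paired = TRUE)
  list(mean_delta = mean(d), p = tt$p.value, n = length(d))
}

#' Median-split group contrast
#'
#' Splits the cohort at a threshold of the exposure (e.g., sedentary time
#' at 10.0 h/day) and compares the outcome between groups by unpaired
#' two-tailed t test, reporting group means with 95% CIs.
#'
#' @param exposure,outcome column names.
#' @param data data.frame.
#' @param threshold split point; `NULL` uses the exposure median.
#' @return List with `threshold`, `groups` (data.frame of n/mean/ci) and `p`.
#' @export
median_split_compare <- function(exposure, outcome, data, threshold = NULL) {
  x <- data[[exposure]]; y <- data[[outcome]]
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (is.null(threshold)) threshold <- median(x)
  lo <- y[x <= threshold]; hi <- y[x > threshold]
  if (!length(lo) || !length(hi))
    mf_stop("metflexr_split_error", "threshold leaves an empty group")
  ci <- function(v) {
    m <- mean(v)
    if (length(v) < 2L) return(c(m, NA, NA))
    half <- qt(0.975, length(v) - 1L) * sd(v) / sqrt(length(v))
    c(m, m - half, m + half)
  }
  g <- rbind(ci(lo), ci(hi))
  p <- if (length(lo) < 2L || length(hi) < 2L) NA_real_
  else if (sd(c(lo, hi)) == 0) 1 else t.test(lo, hi)$p.value
  list(
    threshold = threshold,
    groups = data.frame(
      group = c(sprintf("<=%.2f", threshold), sprintf(">%.2f", threshold)),
      n = c(length(lo), length(hi)),
      mean = g[, 1L], ci_low = g[, 2L], ci_high = g[, 3L]
    ),
    p = p
  )
}

#' Decide whether a log10 transform is needed
#'
#' Fires when the residual skewness exceeds a threshold or a Shapiro-Wilk
#' normality test rejects strongly; stands in for the visual residual
#' checks of conventional practice, made explicit and reproducible.
#'
#' @param residuals numeric residual vector from the base model.
#' @param skew_threshold absolute skewness above which the rule fires.
#' @param normality_p Shapiro-Wilk p-value below which the rule fires.
#' @return logical.
#' @export
transform_rule <- function(residuals, skew_threshold = 1, normality_p = 0.01) {
  r <- residuals[is.finite(residuals)]
  if (length(r) < 8L || sd(r) == 0) return(FALSE)
  skew <- mean((r - mean(r))^3) / sd(r)^3
  if (abs(skew) > skew_threshold) return(TRUE)
  if (length(r) <= 5000) {
    p <- tryCatch(stats::shapiro.test(r)$p.value, error = function(e) 1)
    if (p < normality_p) return(TRUE)
  }
  FALSE
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 − R²_j), where R²_j is from regressing predictor j on the
#' remaining predictors; values of 5 or more flag multicollinearity.
#'
#' @param design data.frame or matrix of numeric predictors (no outcome).
#' @param flag_at flagging threshold.
#' @return data.frame with `term`, `vif`, `flagged`.
#' @export
vif_check <- function(design, flag_at = 5) {
  design <- as.data.frame(design)
  if (ncol(design) < 2L) mf_config_error("VIF needs at least two predictors")
  vifs <- vapply(seq_along(design), function(j) {
    fit <- lm(design[[j]] ~ ., data = design[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = names(design), vif = vifs, flagged = vifs >= flag_at)
}

#' @importFrom stats residuals
NULL
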