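#' Model accuracy and comparison statistics
#'
#' Per-stage regression diagnostics (Pearson R, fitted slope, MSE) computed
#' on observations flattened across targets; outlier counting against
#' 95% prediction bounds of the predicted-vs-observed regression; one-way
#' ANOVA with Tukey HSD and a compact letter display.
#'
#' @name evaluation
NULL

#' Regression diagnostics for one stage
#'
#' Flattens predictions and targets across targets ("observations" =
#' samples x targets), then computes the Pearson correlation `r`, the
#' least-squares slope `b` of `pred = a + b * target`, and the mean squared
#' error.
#'
#' @param pred prediction matrix or vector.
#' @param target matching target matrix or vector.
#' @param stage label: `"training"`, `"validation"`, `"testing"`, `"overall"`.
#' @return one-row [tibble::tibble()] with `stage`, `n_samples`,
#'   `n_observations`, `r`, `slope`, `mse`.
#' @export
regression_diagnostics <- function(pred, target, stage = "overall") {
  pred_m <- as.matrix(pred); target_m <- as.matrix(target)
  stopifnot(all(dim(pred_m) == dim(target_m)))
  p <- as.vector(pred_m); t <- as.vector(target_m)
  if (stats::var(t) < 1e-24) stop("zero variance in target: r undefined")
  slope <- stats::cov(p, t) / stats::var(t)
  # constant predictions (e.g. a fully shrunk network): r is undefined
  r <- if (stats::var(p) < 1e-24) NA_real_ else stats::cor(p, t)
  tibble::tibble(
    stage = stage,
    n_samples = nrow(pred_m),
    n_observations = length(p),
    r = r,
    slope = slope,
    mse = mean((p - t)^2)
  )
}

#' Outlier report bookkeeping
#'
#' @param n_outliers,n_total counts.
#' @param level confidence level of the bounds.
#' @return list of class `outlier_report` with `percent` rounded to 2 dp.
#' @export
outlier_report <- function(n_outliers, n_total, level = 0.95) {
  stopifnot(n_total > 0, n_outliers >= 0, n_outliers <= n_total)
  structure(
    list(n_total = n_total, n_outliers = n_outliers,
         percent = round(100 * n_outliers / n_total, 2), level = level),
    class = "outlier_report"
  )
}

#' Count observations outside the 95% prediction bounds
#'
#' Fits OLS of predictions on targets (flattened across targets) and counts
#' observations whose prediction falls outside the two-sided t-based
#' prediction interval at the given level (standard prediction-interval
#' variance, including leverage).
#'
#' @param pred,target matrices or vectors of equal shape (>= 3 observations).
#' @param level confidence level (default 0.95).
#' @return an [outlier_report()].
#' @export
prediction_bound_outliers <- function(pred, target, level = 0.95) {
  p <- as.vector(as.matrix(pred)); t <- as.vector(as.matrix(target))
  stopifnot(length(p) == length(t), length(p) >= 3L)
  if (stats::var(t) < 1e-24) stop("degenerate fit: target has no variance")
  fit <- stats::lm(p ~ t, data = data.frame(p = p, t = t))
  if (any(!is.finite(stats::coef(fit)))) stop("degenerate fit")
  pi <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(t = t),
                   interval = "prediction", level = level)
  )
  out <- p < pi[, "lwr"] | p > pi[, "upr"]
  outlier_report(sum(out), length(p), level)
}

#' One-way ANOVA with Tukey HSD and compact letters
#'
#' @param values numeric response vector.
#' @param group factor (or coercible) of group labels (>= 2 groups, >= 2
#'   values each).
#' @param alpha significance level for the letter display (default 0.05).
#' @param letters compute the Tukey compact letter display? (`TRUE` by
#'   default; turn off to speed up large simulations that only need p-values).
#' @return list of class `group_comparison`: `table` (tibble with `group`,
#'   `n`, `mean`, `se`, `letter`), `f_statistic`, `p_value`, `alpha`.
#' @export
anova_tukey <- function(values, group, alpha = 0.05, letters = TRUE) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L, all(table(group) >= 2L),
            length(values) == length(group))
  n_per <- as.integer(table(group))
  mean_per <- as.numeric(tapply(values, group, mean))
  se_per <- as.numeric(tapply(values, group, stats::sd)) / sqrt(n_per)
  tab <- tibble::tibble(group = levels(group), n = n_per,
                        mean = mean_per, se = se_per)
  if (stats::var(values) < 1e-24) {
    # all values identical: nothing to distinguish
    tab$letter <- "a"
    return(structure(list(table = tab, f_statistic = 0, p_value = 1,
                          alpha = alpha), class = "group_comparison"))
  }
  df <- data.frame(v = values, g = group)
  fit <- stats::aov(v ~ g, data = df)
  an <- summary(fit)[[1]]
  f_stat <- an$`F value`[1]
  p_val <- an$`Pr(>F)`[1]
  lett <- if (letters) {
    tryCatch({
      cl <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")),
                          level = alpha)
      cl$mcletters$Letters[tab$group]
    }, error = function(e) rep(NA_character_, nrow(tab)))
  } else {
    rep(NA_character_, nrow(tab))
  }
  tab$letter <- unname(lett)
  structure(list(table = tab, f_statistic = f_stat, p_value = p_val,
                 alpha = alpha),
            class = "group_comparison")
}
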