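#' Calibration statistics (SEC, SECV, RSQ, 1-VR)
#'
#' Summarizes a fitted calibration the way NIRS calibration tables report it:
#' `SEC = sqrt(sum((y - yhat_fit)^2) / (n - rank - 1))` (degrees-of-freedom
#' corrected fit error), `SECV = sqrt(sum((y - yhat_cv)^2) / n)` (held-out
#' cross-validation error), `SD` the sample standard deviation of the
#' reference values, `1-VR = 1 - SECV^2 / SD^2` (the cross-validated
#' explained-variance analogue), `RSQ` the squared Pearson correlation of
#' reference and fitted values, and `slope` the OLS slope of reference on
#' fitted values.
#'
#' @param y reference values (g/100 g).
#' @param y_fit in-sample fitted values.
#' @param y_cv cross-validated (held-out) predictions.
#' @param rank number of PLS factors used.
#' @param n_outliers outliers removed before fitting (bookkeeping only).
#' @return a one-row tibble: `n`, `outliers`, `min`, `max`, `mean`, `rsq`,
#'   `slope`, `sd`, `sec`, `secv`, `one_minus_vr`.
#' @export
calibration_stats <- function(y, y_fit, y_cv, rank, n_outliers = 0) {
  n <- length(y)
  stopifnot(length(y_fit) == n, length(y_cv) == n)
  if (n <= rank + 1) abort("Need n > rank + 1 for SEC.")
  if (sd(y) == 0 || sd(y_fit) == 0) abort("Zero-variance reference or fitted values.")
  tibble::tibble(
    n = n,
    outliers = n_outliers,
    min = min(y), max = max(y), mean = mean(y),
    rsq = cor(y, y_fit)^2,
    slope = ols_slope(y, y_fit),
    sd = sd(y),
    sec = sqrt(sum((y - y_fit)^2) / (n - rank - 1)),
    secv = sqrt(sum((y - y_cv)^2) / n),
    one_minus_vr = 1 - sum((y - y_cv)^2) / n / var(y)
  )
}

# OLS slope of y on x (reference regressed on predicted, the NIRS reporting
# convention: slopes near 1 mean predictions track the reference 1:1).
ols_slope <- function(y, x) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' External validation statistics (bias, SEP(C), RPD)
#'
#' The prediction-assessment bundle: `bias = mean(pred - ref)`,
#' `SEP = sqrt(sum((pred - ref)^2) / n)` (raw prediction RMSE),
#' `SEP(C) = sqrt(sum((pred - ref - bias)^2) / (n - 1))` (bias-corrected
#' standard error of prediction), `SD` the sample sd of the reference values,
#' `RPD = SD / SEP(C)` (ratio of performance to deviation), `RSQ` the squared
#' Pearson correlation and `slope` the OLS slope of reference on predicted.
#' The RPD interpretation band from [classify_rpd()] is attached.
#'
#' @param y_ref reference values on the validation set.
#' @param y_pred model predictions.
#' @return a one-row tibble: `n`, `min`, `max`, `mean`, `rsq`, `slope`,
#'   `bias`, `sd`, `sep`, `sep_c`, `rpd`, `rpd_band`.
#' @examples
#' validation_stats(rnorm(40, 24, 1), rnorm(40, 24, 1))
#' @export
validation_stats <- function(y_ref, y_pred) {
  n <- length(y_ref)
  stopifnot(length(y_pred) == n)
  if (n < 3) abort("Validation statistics need at least 3 samples.")
  d <- y_pred - y_ref
  bias <- mean(d)
  sep_c <- sqrt(sum((d - bias)^2) / (n - 1))
  sdy <- sd(y_ref)
  if (sep_c <= 1e-10 * (abs(bias) + sdy)) {  # constant-offset predictions
    warn("SEP(C) is zero; RPD reported as Inf.")
    sep_c <- 0
    rpd <- Inf
  } else {
    rpd <- sdy / sep_c
  }
  tibble::tibble(
    n = n,
    min = min(y_ref), max = max(y_ref), mean = mean(y_ref),
    rsq = if (sd(y_pred) == 0) NA_real_ else cor(y_ref, y_pred)^2,
    slope = if (sd(y_pred) == 0) NA_real_ else ols_slope(y_ref, y_pred),
    bias = bias,
    sd = sdy,
    sep = sqrt(sum(d^2) / n),
    sep_c = sep_c,
    rpd = rpd,
    rpd_band = classify_rpd(rpd)
  )
}

#' Ratio of performance to deviation from its two ingredients
#'
#' `RPD = SD / SEP(C)`: the spread of the reference values over the
#' bias-corrected standard error of prediction. Exposed separately so
#' published SD / SEP(C) pairs can be re-checked directly.
#'
#' @param sd sample standard deviation of the reference values.
#' @param sep_c bias-corrected standard error of prediction.
#' @return the RPD value (vectorized).
#' @examples
#' rpd(1.101, 0.595)
#' @export
rpd <- function(sd, sep_c) {
  if (any(sep_c <= 0)) abort("`sep_c` must be positive.")
  sd / sep_c
}

#' RPD interpretation bands
#'
#' The conventional reading of the ratio of performance to deviation:
#' below 1.5 the model is unreliable; 1.5-2.0 is adequate for screening
#' (distinguishing high from low); 2.0-2.5 allows approximate quantitative
#' prediction; 2.5-3.0 is good; 3.0 and above is excellent.
#'
#' @param rpd non-negative RPD value (vectorized).
#' @return character: `unreliable`, `screening`, `approximate_quant`, `good`
#'   or `excellent`.
#' @examples
#' classify_rpd(c(1.2, 1.85, 2.15, 2.7, 4.03))
#' @export
classify_rpd <- function(rpd) {
  if (any(rpd < 0, na.rm = TRUE)) abort("RPD cannot be negative.")
  dplyr::case_when(
    rpd < 1.5 ~ "unreliable",
    rpd < 2.0 ~ "screening",
    rpd < 2.5 ~ "approximate_quant",
    rpd < 3.0 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Paired t-test between reference and predicted values
#'
#' Tests whether predictions differ systematically from the reference assay:
#' differences `d = ref - pred`, `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom, two-tailed p-value, and the symmetric
#' confidence interval `mean(d) +/- t_crit * SEM`. A large p-value means no
#' detectable systematic difference between the two measurement routes.
#'
#' `paired_t_from_summary()` computes the same bundle from a reported mean
#' difference, standard deviation of differences and n — useful for checking
#' published tables.
#'
#' @param y_ref,y_pred aligned numeric vectors.
#' @param confidence confidence level for the interval (default 0.95).
#' @return a one-row tibble: `n`, `mean_diff`, `sd_diff`, `sem`, `ci_low`,
#'   `ci_high`, `t`, `df`, `p`.
#' @examples
#' paired_t_from_summary(-0.0283, 0.102 * sqrt(35), 35)
#' @export
paired_t <- function(y_ref, y_pred, confidence = 0.95) {
  n <- length(y_ref)
  stopifnot(length(y_pred) == n)
  if (n < 2) abort("Paired t-test needs at least 2 pairs.")
  d <- y_ref - y_pred
  if (sd(d) == 0) {
    if (mean(d) != 0) {
      abort("All differences identical and non-zero: t statistic undefined.")
    }
    warn("All differences are exactly zero; t reported as 0.")
    return(paired_t_from_summary(0, 0, n, confidence, .zero_ok = TRUE))
  }
  paired_t_from_summary(mean(d), sd(d), n, confidence)
}

#' @rdname paired_t
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation of the differences (`sem * sqrt(n)`).
#' @param n number of pairs.
#' @param .zero_ok internal.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n, confidence = 0.95,
                                  .zero_ok = FALSE) {
  if (sd_diff == 0 && !(.zero_ok || mean_diff == 0)) {
    abort("Zero-variance differences with non-zero mean: t undefined.")
  }
  sem <- sd_diff / sqrt(n)
  df <- n - 1
  t <- if (sem == 0) 0 else mean_diff / sem
  crit <- qt(1 - (1 - confidence) / 2, df)
  tibble::tibble(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff, sem = sem,
    ci_low = mean_diff - crit * sem, ci_high = mean_diff + crit * sem,
    t = t, df = df,
    p = if (sem == 0) 1 else 2 * pt(-abs(t), df)
  )
}

#' Correlation and strict-parallel reliability
#'
#' Pearson correlation of reference and predicted values, and the reliability
#' of the pair treated as strictly parallel measurements of the same quantity:
#' their common correlation is estimated as
#' `rbar = cov(ref, pred) / ((var(ref) + var(pred)) / 2)` (covariance over the
#' pooled variance) and stepped up to the reliability of the two-measure
#' composite, `reliability = 2 * rbar / (1 + rbar)` (the Spearman-Brown
#' formula at length 2).
#'
#' @param y_ref,y_pred aligned numeric vectors, both non-constant, n >= 3.
#' @return a one-row tibble: `n`, `pearson_r`, `reliability`.
#' @examples
#' x <- rnorm(30)
#' correlation_reliability(x, x + rnorm(30, sd = 0.2))
#' @export
correlation_reliability <- function(y_ref, y_pred) {
  n <- length(y_ref)
  stopifnot(length(y_pred) == n)
  if (n < 3) abort("Reliability needs at least 3 pairs.")
  if (sd(y_ref) == 0 || sd(y_pred) == 0) abort("Constant input: correlation undefined.")
  rbar <- stats::cov(y_ref, y_pred) / ((var(y_ref) + var(y_pred)) / 2)
  tibble::tibble(
    n = n,
    pearson_r = cor(y_ref, y_pred),
    reliability = 2 * rbar / (1 + rbar)
  )
}
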