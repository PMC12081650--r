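#' Fit a (modified) PLS1 regression on a spectral matrix
#'
#' Extracts latent factors for a single response by the sequential NIPALS
#' construction: X and y are mean-centered; each factor takes its weight
#' vector proportional to the covariance of the current X residuals with the
#' current y residuals, scores as the projection of the X residuals on that
#' weight, and x/y loadings by least squares, after which both residual
#' matrices are deflated. With `modified = TRUE` (MPLS, the
#' Shenk-Westerhaus variant) the X residual at each wavelength is additionally
#' divided by its standard deviation across samples after every factor, so
#' later factors weight all wavelengths' remaining information equally; the
#' scaling vectors are stored and replayed exactly at prediction time. The
#' y residuals are never scaled.
#'
#' Regression coefficient vectors on the original (centered) spectra are
#' composed for every rank up to the extracted rank, so a fitted model can
#' predict either by factor replay or by a single inner product; the two
#' agree to numerical precision.
#'
#' @param x numeric matrix (samples x wavelengths), already preprocessed.
#' @param y numeric response vector, g/100 g.
#' @param max_rank maximum number of factors (default `min(16, floor(n / 5))`,
#'   a desk-scale overfitting guard). Extraction stops early if the residual
#'   covariance vanishes; the achieved rank is recorded.
#' @param modified logical: MPLS residual standardization (default `TRUE`).
#' @param compute_coefs logical; skip the coefficient composition (used
#'   internally by cross-validation, where factor replay is cheaper).
#' @return an object of class `pls1_fit`: centering, per-factor `weights`,
#'   `x_loadings`, `y_loadings`, `resid_sds` (MPLS only), `rank`, and
#'   `coefs`/`intercepts` per rank.
#' @examples
#' x <- matrix(rnorm(200), 20)
#' y <- x[, 3] * 2 + rnorm(20, sd = 0.01)
#' fit <- fit_pls1(x, y, max_rank = 3)
#' fit$rank
#' @export
fit_pls1 <- function(x, y, max_rank = NULL, modified = TRUE,
                     compute_coefs = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n)
  if (sd(y) == 0) abort("Response has zero variance.")
  max_rank <- max_rank %||% max(1L, min(16L, n %/% 5L))
  if (n <= max_rank + 1) abort("Need n > max_rank + 1 samples.")
  x_center <- colMeans(x)
  y_center <- mean(y)
  xr <- sweep(x, 2, x_center)
  yr <- y - y_center
  scale0 <- sqrt(sum(xr^2) / n) * sd(y)
  w_all <- p_all <- s_all <- matrix(0, p, max_rank)
  q_all <- numeric(max_rank)
  rank <- 0L
  for (a in seq_len(max_rank)) {
    wv <- crossprod(xr, yr)[, 1]
    nw <- sqrt(sum(wv^2))
    if (!is.finite(nw) || nw <= 1e-12 * max(scale0, 1e-300)) break
    wv <- wv / nw
    tv <- xr %*% wv
    tt <- sum(tv^2)
    if (tt <= 1e-24) break
    pv <- crossprod(xr, tv)[, 1] / tt
    qv <- sum(yr * tv) / tt
    xr <- xr - tv %*% t(pv)
    yr <- yr - qv * tv[, 1]
    if (modified) {
      sv <- sqrt(colSums(sweep(xr, 2, colMeans(xr))^2) / (n - 1))
      sv[sv < 1e-12] <- 1
      xr <- sweep(xr, 2, sv, `/`)
      s_all[, a] <- sv
    }
    w_all[, a] <- wv
    p_all[, a] <- pv
    q_all[a] <- qv
    rank <- a
  }
  if (rank == 0L) abort("No PLS factor could be extracted (zero covariance).")
  keep <- seq_len(rank)
  fit <- structure(list(
    x_center = x_center, y_center = y_center, modified = modified,
    weights = w_all[, keep, drop = FALSE],
    x_loadings = p_all[, keep, drop = FALSE],
    y_loadings = q_all[keep],
    resid_sds = if (modified) s_all[, keep, drop = FALSE] else NULL,
    rank = rank, n = n
  ), class = "pls1_fit")
  if (compute_coefs) {
    cf <- pls_compose_coefs(fit)
    fit$coefs <- cf$coefs
    fit$intercepts <- cf$intercepts
  }
  fit
}

# Compose, for every rank, the coefficient vector on the original centered
# spectrum by propagating the (linear) deflation-and-rescaling map.
pls_compose_coefs <- function(fit) {
  p <- length(fit$x_center)
  k <- fit$rank
  tm <- diag(p)
  coefs <- matrix(0, p, k)
  beta <- numeric(p)
  for (a in seq_len(k)) {
    v <- tm %*% fit$weights[, a]
    beta <- beta + fit$y_loadings[a] * v[, 1]
    coefs[, a] <- beta
    if (a < k) {
      tm <- tm - v %*% t(fit$x_loadings[, a])
      if (fit$modified) tm <- sweep(tm, 2, fit$resid_sds[, a], `/`)
    }
  }
  intercepts <- fit$y_center - drop(crossprod(coefs, fit$x_center))
  list(coefs = coefs, intercepts = intercepts)
}

#' Predict from a PLS1 fit at one or all ranks
#'
#' `pls_predict()` replays the stored factor sequence (centering, score,
#' deflation and, for MPLS, the per-wavelength residual rescaling) on new
#' spectra. `rank = 0` returns the calibration mean for every sample.
#'
#' @param fit a [fit_pls1()] object.
#' @param x numeric matrix on the fit's wavelength grid.
#' @param rank number of factors to use (default: all extracted).
#' @param all_ranks if `TRUE`, return an `n x (rank + 1)` matrix of
#'   predictions at ranks `0..rank`.
#' @return numeric vector (or matrix when `all_ranks = TRUE`).
#' @export
pls_predict <- function(fit, x, rank = fit$rank, all_ranks = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != length(fit$x_center)) {
    abort(sprintf("Spectrum length %d does not match the model grid (%d).",
                  ncol(x), length(fit$x_center)))
  }
  rank <- min(rank, fit$rank)
  r <- sweep(x, 2, fit$x_center)
  yhat <- rep(fit$y_center, nrow(x))
  out <- if (all_ranks) matrix(yhat, nrow(x), rank + 1) else NULL
  for (a in seq_len(rank)) {
    tv <- r %*% fit$weights[, a]
    yhat <- yhat + fit$y_loadings[a] * tv[, 1]
    if (all_ranks) out[, a + 1] <- yhat
    if (a < rank) {
      r <- r - tv %*% t(fit$x_loadings[, a])
      if (fit$modified) r <- sweep(r, 2, fit$resid_sds[, a], `/`)
    }
  }
  if (all_ranks) out else yhat
}

#' Cross-validated factor selection for PLS1
#'
#' Splits the samples into `n_groups` contiguous-size groups by a seeded
#' shuffle, fits the model with each group held out, and scores every rank by
#' the standard error of cross-validation,
#' `SECV(r) = sqrt(sum (y_i - yhat_i^(-g(i)))^2 / n)` (group-held-out
#' predictions; set `secv_denominator = "df"` for the `n - 1 - r`
#' alternative). The chosen rank is the smallest whose SECV is within
#' `parsimony_tol` (default 2%) of the minimum, preferring fewer factors.
#'
#' @inheritParams fit_pls1
#' @param n_groups number of cross-validation groups (default 5).
#' @param seed integer seed for the group assignment.
#' @param parsimony_tol relative SECV tolerance for preferring a smaller rank.
#' @param secv_denominator `"n"` (default) or `"df"` for `n - 1 - rank`.
#' @return an object of class `pls_cv`: tibble `secv_by_rank` (rank, secv,
#'   plus both denominator variants `secv_n` and `secv_df`),
#'   `chosen_rank`, `assignment`, `cv_predictions` (matrix, ranks 0..max in
#'   columns), `n_groups`.
#' @examples
#' x <- matrix(rnorm(600), 30)
#' y <- x %*% rnorm(20) + rnorm(30, sd = 0.1)
#' cross_validate(x, drop(y), max_rank = 5, seed = 1)$chosen_rank
#' @export
cross_validate <- function(x, y, max_rank = NULL, n_groups = 5, seed = NULL,
                           modified = TRUE, parsimony_tol = 0.02,
                           secv_denominator = c("n", "df")) {
  x <- as.matrix(x)
  n <- nrow(x)
  secv_denominator <- match.arg(secv_denominator)
  if (n_groups < 2) abort("`n_groups` must be at least 2.")
  if (n < 2 * n_groups) abort("Need at least 2 samples per cross-validation group.")
  max_rank <- max_rank %||% max(1L, min(16L, n %/% 5L))
  max_rank <- max(1L, min(max_rank, n - as.integer(ceiling(n / n_groups)) - 2L))
  assignment <- local_seed(seed, sample(rep(seq_len(n_groups), length.out = n)))
  pred <- matrix(NA_real_, n, max_rank + 1)
  for (g in seq_len(n_groups)) {
    hold <- assignment == g
    fit <- fit_pls1(x[!hold, , drop = FALSE], y[!hold], max_rank = max_rank,
                    modified = modified, compute_coefs = FALSE)
    ph <- pls_predict(fit, x[hold, , drop = FALSE], rank = fit$rank,
                      all_ranks = TRUE)
    if (fit$rank < max_rank) {   # early stop in a fold: carry the last rank on
      ph <- cbind(ph, ph[, rep(fit$rank + 1, max_rank - fit$rank), drop = FALSE])
    }
    pred[hold, ] <- ph
  }
  press <- colSums((y - pred)^2)
  secv_n <- sqrt(press / n)
  secv_df <- sqrt(press / pmax(n - 1 - (0:max_rank), 1))
  secv <- if (secv_denominator == "n") secv_n else secv_df
  chosen <- min(which(secv <= (1 + parsimony_tol) * min(secv))) - 1L
  structure(list(
    secv_by_rank = tibble::tibble(rank = 0:max_rank, secv = secv,
                                  secv_n = secv_n, secv_df = secv_df),
    chosen_rank = chosen,
    n_groups = n_groups,
    assignment = assignment,
    cv_predictions = pred,
    secv_denominator = secv_denominator
  ), class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv: %d groups, chosen rank %d, SECV %.4g>\n",
              x$n_groups, x$chosen_rank,
              x$secv_by_rank$secv[x$chosen_rank + 1]))
  invisible(x)
}
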