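#' Calibrate one trait from NIR spectra
#'
#' The single-trait calibration pipeline: preprocess the spectra with the
#' requested scatter correction and math treatment, screen spectral outliers
#' by GH/NH on the preprocessed calibration spectra, select the number of PLS
#' factors by cross-validated SECV, and fit the final (modified) PLS model on
#' the kept samples. The result carries everything needed to predict new
#' spectra and to report calibration statistics.
#'
#' @param spectra calibration spectra tibble.
#' @param reference reference tibble holding the `trait` column (g/100 g).
#' @param trait name of the trait to model.
#' @param treatment math treatment string `"d,g,s1,s2"`.
#' @param scatter scatter correction, as in [apply_treatment()].
#' @param detrend_degree detrend polynomial degree.
#' @param gh_threshold,nh_threshold outlier limits (use `Inf` to disable
#'   screening).
#' @param max_rank,modified,n_groups,parsimony_tol,secv_denominator passed to
#'   [fit_pls1()] and [cross_validate()].
#' @param seed integer seed for the cross-validation group assignment.
#' @return an object of class `mpls_fit` with components `pls` (the factor
#'   model), `n_factors` (cross-validated choice), `cv`, `screen`, `stats`
#'   (one-row calibration statistics tibble), `calibration` (per-sample
#'   reference, fitted and cross-validated values) and the preprocessing
#'   recipe (`treatment`, `scatter`, `detrend_degree`, `grid`).
#' @examples
#' s <- simulate_nirs(60, seed = 7)
#' fit <- nirs_calibrate(s$spectra, s$reference, "starch",
#'                       treatment = "2,8,8,1", seed = 1)
#' glance(fit)
#' @export
nirs_calibrate <- function(spectra, reference, trait, treatment = "2,4,4,1",
                           scatter = c("snv_dt", "snv", "none"),
                           detrend_degree = 2,
                           gh_threshold = 2.5, nh_threshold = 0.6,
                           max_rank = NULL, modified = TRUE, n_groups = 5,
                           parsimony_tol = 0.02,
                           secv_denominator = c("n", "df"), seed = NULL) {
  scatter <- match.arg(scatter)
  secv_denominator <- match.arg(secv_denominator)
  t <- parse_treatment(treatment)
  al <- align_ids(spectra, reference)
  if (!trait %in% names(al$reference)) {
    abort(sprintf("Trait '%s' not found in the reference table.", trait))
  }
  pre <- apply_treatment(al$spectra, t, scatter = scatter,
                         detrend_degree = detrend_degree)
  scr <- screen_outliers(pre, al$reference, gh_threshold = gh_threshold,
                         nh_threshold = nh_threshold)
  n_out <- sum(scr$report$flag != "keep")
  if (nrow(scr$spectra) < 10) {
    abort(sprintf("Only %d samples left after outlier screening; need at least 10.",
                  nrow(scr$spectra)))
  }
  x <- spectra_matrix(scr$spectra)
  y <- scr$reference[[trait]]
  cv <- cross_validate(x, y, max_rank = max_rank, n_groups = n_groups,
                       seed = seed, modified = modified,
                       parsimony_tol = parsimony_tol,
                       secv_denominator = secv_denominator)
  n_factors <- cv$chosen_rank
  pls <- fit_pls1(x, y, max_rank = max(1L, n_factors), modified = modified)
  y_fit <- pls_predict(pls, x, rank = n_factors)
  y_cv <- cv$cv_predictions[, n_factors + 1]
  stats <- calibration_stats(y, y_fit, y_cv, rank = n_factors,
                             n_outliers = n_out)
  structure(list(
    trait = trait,
    treatment = t,
    scatter = scatter,
    detrend_degree = detrend_degree,
    grid = spectra_wavelengths(scr$spectra),
    pls = pls,
    n_factors = n_factors,
    cv = cv,
    screen = scr,
    stats = dplyr::bind_cols(tibble::tibble(trait = trait,
                                            treatment = format(t)), stats),
    calibration = tibble::tibble(sample_id = scr$spectra$sample_id,
                                 reference = y, fitted = y_fit, cv = y_cv)
  ), class = "mpls_fit")
}

#' @export
print.mpls_fit <- function(x, ...) {
  cat(sprintf("<mpls_fit: %s | treatment %s + %s | %d factors | n = %d (%d outliers)>\n",
              x$trait, format(x$treatment), x$scatter, x$n_factors,
              x$stats$n, x$stats$outliers))
  cat(sprintf("  RSQ %.3f  SEC %.4g  SECV %.4g  1-VR %.3f\n",
              x$stats$rsq, x$stats$sec, x$stats$secv, x$stats$one_minus_vr))
  invisible(x)
}

# Preprocess new spectra with a fitted model's recipe and check the grid.
preprocess_for_model <- function(object, spectra) {
  spectra <- validate_spectra(spectra)
  pre <- suppressMessages(
    apply_treatment(spectra, object$treatment, scatter = object$scatter,
                    detrend_degree = object$detrend_degree))
  wl <- spectra_wavelengths(pre)
  if (length(wl) != length(object$grid) || any(wl != object$grid)) {
    abort(sprintf(
      "Preprocessed grid does not match the model (expected treatment %s + %s on the model's wavelength range).",
      format(object$treatment), object$scatter))
  }
  pre
}

#' Predict trait values for new spectra
#'
#' Applies the fitted model's preprocessing recipe to raw spectra and runs the
#' stored (M)PLS factors at the cross-validated rank.
#'
#' @param object an `mpls_fit`.
#' @param spectra a raw spectra tibble on the model's original wavelength
#'   range.
#' @param ... unused.
#' @return a tibble `sample_id`, `.pred` (g/100 g).
#' @export
predict.mpls_fit <- function(object, spectra, ...) {
  pre <- preprocess_for_model(object, spectra)
  tibble::tibble(
    sample_id = pre$sample_id,
    .pred = pls_predict(object$pls, spectra_matrix(pre), rank = object$n_factors)
  )
}

#' @rdname predict.mpls_fit
#' @param x an `mpls_fit`.
#' @method tidy mpls_fit
#' @export
tidy.mpls_fit <- function(x, ...) {
  k <- max(1L, x$n_factors)
  tibble::tibble(
    wavelength = x$grid,
    coefficient = if (x$n_factors == 0) 0 else x$pls$coefs[, x$n_factors]
  )
}

#' @rdname predict.mpls_fit
#' @method glance mpls_fit
#' @export
glance.mpls_fit <- function(x, ...) {
  x$stats
}

#' @rdname predict.mpls_fit
#' @method autoplot mpls_fit
#' @export
autoplot.mpls_fit <- function(object, ...) {
  ggplot2::ggplot(object$calibration,
                  ggplot2::aes(.data$fitted, .data$reference)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s calibration (%s, %d factors)", object$trait,
                      format(object$treatment), object$n_factors),
      x = "Fitted (g/100 g)", y = "Reference (g/100 g)") +
    ggplot2::theme_minimal()
}

#' Validate a fitted model on an external sample set
#'
#' Predicts the validation spectra and assembles the external-validation
#' statistics (bias, SEP(C), RPD with its interpretation band), the paired
#' t-test between reference and predicted values, and the
#' correlation/strict-parallel reliability bundle.
#'
#' @param fit an `mpls_fit`.
#' @param spectra validation spectra tibble.
#' @param reference validation reference tibble.
#' @param confidence confidence level of the paired-test interval.
#' @return an object of class `nirs_validation`: tibbles `stats`, `paired`,
#'   `reliability` and per-sample `predictions`.
#' @examples
#' s <- simulate_nirs(80, seed = 7)
#' sp <- rank_ordered_split(s$reference, "starch", 20)
#' fit <- nirs_calibrate(split_subset(sp, s$spectra), split_subset(sp, s$reference),
#'                       "starch", "2,8,8,1", seed = 1)
#' val <- nirs_validate(fit, split_subset(sp, s$spectra, "val"),
#'                      split_subset(sp, s$reference, "val"))
#' val$stats$rpd
#' @export
nirs_validate <- function(fit, spectra, reference, confidence = 0.95) {
  al <- align_ids(spectra, reference)
  if (!fit$trait %in% names(al$reference)) {
    abort(sprintf("Trait '%s' not found in the validation reference.", fit$trait))
  }
  pred <- predict(fit, al$spectra)
  y_ref <- al$reference[[fit$trait]]
  y_pred <- pred$.pred
  lead <- tibble::tibble(trait = fit$trait, treatment = format(fit$treatment))
  structure(list(
    trait = fit$trait,
    stats = dplyr::bind_cols(lead, validation_stats(y_ref, y_pred)),
    paired = dplyr::bind_cols(lead, paired_t(y_ref, y_pred, confidence)),
    reliability = dplyr::bind_cols(lead, correlation_reliability(y_ref, y_pred)),
    predictions = tibble::tibble(sample_id = pred$sample_id,
                                 trait = fit$trait,
                                 reference = y_ref, predicted = y_pred)
  ), class = "nirs_validation")
}

#' @export
print.nirs_validation <- function(x, ...) {
  cat(sprintf("<nirs_validation: %s | n = %d | RSQ %.3f  SEP(C) %.4g  RPD %.2f (%s)>\n",
              x$trait, x$stats$n, x$stats$rsq, x$stats$sep_c, x$stats$rpd,
              x$stats$rpd_band))
  invisible(x)
}

#' @rdname nirs_validate
#' @param x,object an `nirs_validation`.
#' @param ... unused.
#' @method tidy nirs_validation
#' @export
tidy.nirs_validation <- function(x, ...) {
  x$predictions
}

#' @rdname nirs_validate
#' @method glance nirs_validation
#' @export
glance.nirs_validation <- function(x, ...) {
  x$stats
}

#' @rdname nirs_validate
#' @method autoplot nirs_validation
#' @export
autoplot.nirs_validation <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$predicted, .data$reference)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(title = sprintf("%s external validation (RPD %.2f)",
                                  object$trait, object$stats$rpd),
                  x = "Predicted (g/100 g)", y = "Reference (g/100 g)") +
    ggplot2::theme_minimal()
}

#' Save and load a fitted model as structured text
#'
#' Serializes an `mpls_fit` to JSON (wavelength grid, treatment code,
#' centering, per-factor arrays, MPLS scaling vectors, chosen rank and
#' statistics) at full double precision, so a saved and reloaded model
#' reproduces predictions exactly.
#'
#' @param fit an `mpls_fit`.
#' @param path file path (`.json`).
#' @return `read_mpls()` returns the restored `mpls_fit`.
#' @export
write_mpls <- function(fit, path) {
  stopifnot(inherits(fit, "mpls_fit"))
  payload <- list(
    format = "nirscal_mpls", version = 1L,
    trait = fit$trait,
    treatment = format(fit$treatment),
    scatter = fit$scatter,
    detrend_degree = fit$detrend_degree,
    grid = fit$grid,
    n_factors = fit$n_factors,
    pls = list(
      x_center = fit$pls$x_center, y_center = fit$pls$y_center,
      modified = fit$pls$modified, rank = fit$pls$rank, n = fit$pls$n,
      weights = fit$pls$weights, x_loadings = fit$pls$x_loadings,
      y_loadings = fit$pls$y_loadings, resid_sds = fit$pls$resid_sds,
      coefs = fit$pls$coefs, intercepts = fit$pls$intercepts
    ),
    stats = fit$stats
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(fit)
}

#' @rdname write_mpls
#' @export
read_mpls <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "nirscal_mpls")) {
    abort(sprintf("%s is not a nirscal model file.", basename(path)))
  }
  pls <- x$pls
  as_mat <- function(m) if (is.null(m)) NULL else as.matrix(m)
  pls$weights <- as_mat(pls$weights)
  pls$x_loadings <- as_mat(pls$x_loadings)
  pls$resid_sds <- as_mat(pls$resid_sds)
  pls$coefs <- as_mat(pls$coefs)
  class(pls) <- "pls1_fit"
  structure(list(
    trait = x$trait,
    treatment = parse_treatment(x$treatment),
    scatter = x$scatter,
    detrend_degree = x$detrend_degree,
    grid = x$grid,
    pls = pls,
    n_factors = x$n_factors,
    cv = NULL, screen = NULL,
    stats = tibble::as_tibble(x$stats),
    calibration = NULL
  ), class = "mpls_fit")
}
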