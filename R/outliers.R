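#' Principal-component score model for Mahalanobis screening
#'
#' Fits the score space in which Global H (GH) and Neighbourhood H (NH)
#' distances are computed: spectra are mean-centered, decomposed into
#' principal components, and the smallest number of components reaching
#' `variance_target` (capped at `k_max`) is retained. Scores on each retained
#' component are standardized by that component's calibration score standard
#' deviation, which puts the squared distances on the scale on which the
#' conventional thresholds (GH 2.5, NH 0.6) are defined.
#'
#' @param spectra a spectra tibble (normally preprocessed, n >= 3 samples).
#' @param variance_target fraction of spectral variance the retained
#'   components must explain (default 0.99).
#' @param k_max cap on the component count (default `min(20, n - 2)`).
#' @return an object of class `pc_model`: list with `center`, `loadings`
#'   (wavelengths x k, orthonormal), `score_sds`, `k`, `explained_fraction`,
#'   and the model `grid`.
#' @examples
#' spc <- simulate_nirs(12, seed = 1)$spectra
#' fit_pc_model(spc)$k
#' @export
fit_pc_model <- function(spectra, variance_target = 0.99, k_max = NULL) {
  spectra <- validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  n <- nrow(m)
  if (n < 3) abort("PC model needs at least 3 samples.")
  k_max <- k_max %||% min(20L, n - 2L)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total == 0) abort("Degenerate spectra: zero total variance.")
  cum <- cumsum(ev) / total
  k <- min(which(cum >= variance_target - 1e-12), length(ev))
  k <- max(1L, min(k, k_max))
  if (pc$sdev[k] == 0) k <- max(1L, sum(pc$sdev > 0))
  structure(list(
    center = pc$center,
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    score_sds = pc$sdev[seq_len(k)],
    k = k,
    explained_fraction = cum[k],
    grid = spectra_wavelengths(spectra)
  ), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model: %d components, %.1f%% variance, %d wavelengths>\n",
              x$k, 100 * x$explained_fraction, length(x$center)))
  invisible(x)
}

model_scores <- function(model, m) {
  sweep(m, 2, model$center) %*% model$loadings
}

check_grid <- function(model_grid, grid, what = "model") {
  if (length(model_grid) != length(grid) || any(model_grid != grid)) {
    abort(sprintf("Wavelength grid does not match the %s grid (%d vs %d points).",
                  what, length(grid), length(model_grid)))
  }
}

#' Global H and Neighbourhood H spectral distances
#'
#' `global_h()` is the standardized Mahalanobis distance of each spectrum from
#' the calibration population mean, averaged over the retained components:
#' `GH = (1/k) * sum_i (t_i / s_i)^2`, where `t_i` is the score on component
#' `i` and `s_i` the calibration score sd. On the fitting set its mean is
#' `(n-1)/n`, so GH is approximately 1 on average and the conventional cutoff
#' GH > 2.5 flags spectra far from the population. `neighborhood_h()` is the
#' same standardized squared score distance to each sample's nearest
#' neighbour; NH > 0.6 flags isolated spectra with no close companion.
#'
#' @param model a [fit_pc_model()] object.
#' @param spectra a spectra tibble on the model's grid.
#' @return a tibble `sample_id`, `gh` (or `nh`).
#' @examples
#' spc <- simulate_nirs(12, seed = 1)$spectra
#' pc <- fit_pc_model(spc)
#' mean(global_h(pc, spc)$gh)  # ~ (n-1)/n
#' @export
global_h <- function(model, spectra) {
  spectra <- validate_spectra(spectra)
  check_grid(model$grid, spectra_wavelengths(spectra))
  t <- model_scores(model, spectra_matrix(spectra))
  z <- sweep(t, 2, model$score_sds, `/`)
  tibble::tibble(sample_id = spectra$sample_id, gh = unname(rowMeans(z^2)))
}

#' @rdname global_h
#' @export
neighborhood_h <- function(model, spectra) {
  spectra <- validate_spectra(spectra)
  if (nrow(spectra) < 2) abort("NH needs at least 2 samples.")
  check_grid(model$grid, spectra_wavelengths(spectra))
  t <- model_scores(model, spectra_matrix(spectra))
  z <- sweep(t, 2, model$score_sds, `/`)
  d2 <- as.matrix(stats::dist(z))^2 / model$k
  diag(d2) <- Inf
  tibble::tibble(sample_id = spectra$sample_id, nh = unname(apply(d2, 1, min)))
}

#' Screen spectral outliers by GH and NH
#'
#' Fits the PC score model on the given spectra and removes every sample whose
#' Global H exceeds `gh_threshold` or whose Neighbourhood H exceeds
#' `nh_threshold` (large NH = isolated spectrum; typically a scanning
#' artefact). Screening is performed once on the spectra as given — normally
#' the preprocessed calibration set — and the paired reference table is
#' filtered identically so the two stay aligned.
#'
#' @param spectra a spectra tibble.
#' @param reference optional reference tibble aligned by `sample_id`.
#' @param gh_threshold,nh_threshold flag limits (defaults 2.5 and 0.6; use
#'   `Inf` to disable either test).
#' @param nh_mode `"isolate"` (default) flags samples whose nearest-neighbour
#'   distance exceeds `nh_threshold` — the scanning-artefact reading;
#'   `"redundant"` instead prunes near-duplicates, greedily flagging any
#'   sample closer than `nh_threshold` to an already-kept one.
#' @param passes `1` (default) screens once; `2` re-fits the score model on
#'   the kept samples and screens a second time.
#' @param variance_target,k_max passed to [fit_pc_model()].
#' @return a list of class `outlier_screen`: `spectra` and `reference` (kept
#'   rows), `report` (tibble `sample_id`, `gh`, `nh`, `flag` in
#'   `keep`/`gh_outlier`/`nh_outlier`), `model`, and the thresholds.
#' @examples
#' s <- simulate_nirs(20, seed = 1)
#' scr <- screen_outliers(s$spectra, s$reference)
#' table(scr$report$flag)
#' @export
screen_outliers <- function(spectra, reference = NULL, gh_threshold = 2.5,
                            nh_threshold = 0.6,
                            nh_mode = c("isolate", "redundant"), passes = 1,
                            variance_target = 0.99, k_max = NULL) {
  nh_mode <- match.arg(nh_mode)
  stopifnot(passes %in% 1:2)
  spectra <- validate_spectra(spectra)
  if (!is.null(reference)) {
    al <- align_ids(spectra, reference)
    reference <- al$reference
  }
  model <- fit_pc_model(spectra, variance_target, k_max)
  report <- screen_once(model, spectra, gh_threshold, nh_threshold, nh_mode)
  keep <- report$flag == "keep"
  if (!any(keep)) {
    abort("All samples flagged as outliers; refusing to return an empty calibration set.")
  }
  if (passes == 2 && any(!keep) && sum(keep) >= 3) {
    kept_spc <- spectra[keep, , drop = FALSE]
    model <- fit_pc_model(kept_spc, variance_target, k_max)
    second <- screen_once(model, kept_spc, gh_threshold, nh_threshold, nh_mode)
    if (!any(second$flag == "keep")) {
      abort("Second screening pass flagged every remaining sample.")
    }
    report$flag[match(second$sample_id, report$sample_id)] <- second$flag
    keep <- report$flag == "keep"
  }
  structure(list(
    spectra = spectra[keep, , drop = FALSE],
    reference = if (is.null(reference)) NULL else reference[keep, , drop = FALSE],
    report = report,
    model = model,
    gh_threshold = gh_threshold,
    nh_threshold = nh_threshold
  ), class = "outlier_screen")
}

screen_once <- function(model, spectra, gh_threshold, nh_threshold, nh_mode) {
  gh <- global_h(model, spectra)$gh
  nh <- neighborhood_h(model, spectra)$nh
  if (nh_mode == "isolate") {
    flag <- dplyr::case_when(
      gh > gh_threshold ~ "gh_outlier",
      nh > nh_threshold ~ "nh_outlier",
      TRUE ~ "keep"
    )
  } else {
    flag <- ifelse(gh > gh_threshold, "gh_outlier", "keep")
    z <- sweep(model_scores(model, spectra_matrix(spectra)), 2,
               model$score_sds, `/`)
    d2 <- as.matrix(stats::dist(z))^2 / model$k
    kept <- integer(0)
    for (i in seq_along(flag)) {
      if (flag[i] != "keep") next
      if (length(kept) > 0 && min(d2[i, kept]) < nh_threshold) {
        flag[i] <- "nh_outlier"
      } else {
        kept <- c(kept, i)
      }
    }
  }
  tibble::tibble(sample_id = spectra$sample_id, gh = gh, nh = nh, flag = flag)
}

#' @export
print.outlier_screen <- function(x, ...) {
  n <- nrow(x$report)
  cat(sprintf("<outlier_screen: %d of %d samples kept (GH > %s: %d, NH > %s: %d)>\n",
              sum(x$report$flag == "keep"), n,
              format(x$gh_threshold), sum(x$report$flag == "gh_outlier"),
              format(x$nh_threshold), sum(x$report$flag == "nh_outlier")))
  invisible(x)
}

#' @rdname screen_outliers
#' @param x an `outlier_screen` object.
#' @param ... unused.
#' @method tidy outlier_screen
#' @export
tidy.outlier_screen <- function(x, ...) {
  x$report
}

#' @rdname screen_outliers
#' @param object an `outlier_screen` object.
#' @method autoplot outlier_screen
#' @export
autoplot.outlier_screen <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(.data$gh, .data$nh,
                                              colour = .data$flag)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$gh_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$nh_threshold, linetype = 2) +
    ggplot2::labs(x = "Global H", y = "Neighbourhood H", colour = NULL) +
    ggplot2::theme_minimal()
}
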