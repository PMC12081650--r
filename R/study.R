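#' Run the complete multi-trait calibration study
#'
#' End-to-end replica of a multi-trait NIRS calibration campaign: for every
#' trait, the samples are rank-order split into calibration and validation
#' sets on that trait, each candidate math treatment is calibrated
#' ([nirs_calibrate()]: preprocessing, GH/NH screening, cross-validated MPLS),
#' the best treatment is selected, and the winning model is externally
#' validated on the held-out set. The four result tables mirror the standard
#' reporting layout of NIRS studies: calibration statistics, external
#' validation statistics, paired t-tests, and correlation/reliability.
#'
#' Treatment selection defaults to the smallest cross-validated SECV, which
#' never looks at the validation set; `select_by = "validation"` instead picks
#' the treatment with the smallest validation SEP(C), reproducing the common
#' (but leaky) practice of choosing on external performance.
#'
#' @param spectra spectra tibble for all samples.
#' @param reference reference tibble for all samples.
#' @param traits trait columns to model (default: every non-id column of
#'   `reference`).
#' @param treatments candidate math treatments (default the three classic
#'   codes `"2,4,4,1"`, `"2,8,8,1"`, `"3,4,4,1"`).
#' @param n_validation validation-set size per trait (default 40).
#' @param select_by `"secv"` (default) or `"validation"`.
#' @param seed master seed; all randomness (cross-validation grouping) is
#'   drawn from one stream seeded here.
#' @inheritParams nirs_calibrate
#' @return an object of class `nirs_study`: tibbles `calibration`,
#'   `validation`, `paired`, `reliability`, `outliers`, `splits`,
#'   `predictions`; named lists `models` and `validations`; and `config`.
#' @examples
#' \donttest{
#' s <- simulate_nirs(139, seed = 11)
#' study <- nirs_study(s$spectra, s$reference, treatments = "2,4,4,1", seed = 11)
#' study$validation
#' }
#' @export
nirs_study <- function(spectra, reference,
                       traits = NULL,
                       treatments = c("2,4,4,1", "2,8,8,1", "3,4,4,1"),
                       n_validation = 40,
                       scatter = c("snv_dt", "snv", "none"),
                       detrend_degree = 2,
                       gh_threshold = 2.5, nh_threshold = 0.6,
                       max_rank = NULL, modified = TRUE, n_groups = 5,
                       parsimony_tol = 0.02, select_by = c("secv", "validation"),
                       seed = NULL) {
  scatter <- match.arg(scatter)
  select_by <- match.arg(select_by)
  al <- align_ids(spectra, reference)
  traits <- traits %||% setdiff(names(al$reference), "sample_id")
  missing <- setdiff(traits, names(al$reference))
  if (length(missing) > 0) {
    abort(paste0("Trait(s) not in the reference table: ",
                 paste(missing, collapse = ", ")))
  }
  treatments <- vapply(treatments, function(t) format(parse_treatment(t)), "")
  local_seed(seed, {
    results <- purrr::map(traits, function(trait) {
      sp <- rank_ordered_split(al$reference, trait, n_validation)
      cal_spc <- split_subset(sp, al$spectra, "cal")
      cal_ref <- split_subset(sp, al$reference, "cal")
      val_spc <- split_subset(sp, al$spectra, "val")
      val_ref <- split_subset(sp, al$reference, "val")
      candidates <- purrr::map(treatments, function(tr) {
        fit <- tryCatch(
          suppressMessages(nirs_calibrate(
            cal_spc, cal_ref, trait, treatment = tr, scatter = scatter,
            detrend_degree = detrend_degree, gh_threshold = gh_threshold,
            nh_threshold = nh_threshold, max_rank = max_rank,
            modified = modified, n_groups = n_groups,
            parsimony_tol = parsimony_tol)),
          error = function(e) {
            warn(sprintf("Trait '%s', treatment %s failed: %s",
                         trait, tr, conditionMessage(e)))
            NULL
          })
        if (is.null(fit)) return(NULL)
        list(fit = fit, val = nirs_validate(fit, val_spc, val_ref))
      })
      candidates <- purrr::compact(candidates)
      if (length(candidates) == 0) {
        warn(sprintf("Trait '%s': no treatment succeeded; skipping.", trait))
        return(NULL)
      }
      score <- vapply(candidates, function(cand) {
        if (select_by == "secv") cand$fit$stats$secv else cand$val$stats$sep_c
      }, numeric(1))
      best <- candidates[[which.min(score)]]
      list(trait = trait, split = sp, fit = best$fit, val = best$val)
    })
    results <- purrr::compact(results)
    build_study(results, list(
      traits = traits, treatments = treatments, n_validation = n_validation,
      scatter = scatter, detrend_degree = detrend_degree,
      gh_threshold = gh_threshold, nh_threshold = nh_threshold,
      max_rank = max_rank, modified = modified, n_groups = n_groups,
      parsimony_tol = parsimony_tol, select_by = select_by, seed = seed
    ))
  })
}

build_study <- function(results, config) {
  grab <- function(f) purrr::map(results, f)
  structure(list(
    calibration = dplyr::bind_rows(grab(function(r) r$fit$stats)),
    validation = dplyr::bind_rows(grab(function(r) r$val$stats)),
    paired = dplyr::bind_rows(grab(function(r) r$val$paired)),
    reliability = dplyr::bind_rows(grab(function(r) r$val$reliability)),
    outliers = dplyr::bind_rows(grab(function(r) {
      dplyr::mutate(r$fit$screen$report, trait = r$trait, .before = 1)
    })),
    splits = dplyr::bind_rows(grab(function(r) {
      tibble::tibble(trait = r$trait, sample_id = r$split$sample_id,
                     set = r$split$set)
    })),
    predictions = dplyr::bind_rows(grab(function(r) r$val$predictions)),
    models = stats::setNames(grab(function(r) r$fit),
                             vapply(results, function(r) r$trait, "")),
    validations = stats::setNames(grab(function(r) r$val),
                                  vapply(results, function(r) r$trait, "")),
    config = config
  ), class = "nirs_study")
}

#' @export
print.nirs_study <- function(x, ...) {
  cat(sprintf("<nirs_study: %d trait(s), treatments %s, selection by %s>\n",
              nrow(x$validation), paste(x$config$treatments, collapse = " / "),
              x$config$select_by))
  print(dplyr::select(x$validation, "trait", "treatment", "n", "rsq", "bias",
                      "sep_c", "rpd", "rpd_band"))
  invisible(x)
}

#' @rdname nirs_study
#' @param x,object an `nirs_study`.
#' @param ... unused.
#' @method glance nirs_study
#' @export
glance.nirs_study <- function(x, ...) {
  x$validation
}

#' @rdname nirs_study
#' @method autoplot nirs_study
#' @export
autoplot.nirs_study <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$predicted, .data$reference)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "Predicted (g/100 g)", y = "Reference (g/100 g)") +
    ggplot2::theme_minimal()
}

#' Write a study's result tables, models and provenance to a directory
#'
#' Exports the four statistics tables, per-sample validation predictions,
#' outlier report and split assignments as CSV, the four tables again as one
#' combined JSON report, each fitted model as a JSON file, and a provenance
#' record (seed, configuration, package version) sufficient to reproduce the
#' run.
#'
#' @param study an `nirs_study`.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "nirs_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("calibration", "validation", "paired", "reliability",
              "outliers", "splits", "predictions")
  for (t in tables) {
    readr::write_csv(study[[t]], file.path(dir, paste0(t, ".csv")))
  }
  jsonlite::write_json(study[c("calibration", "validation", "paired",
                               "reliability")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", dataframe = "rows")
  for (trait in names(study$models)) {
    write_mpls(study$models[[trait]], file.path(dir, paste0("model_", trait, ".json")))
  }
  prov <- list(
    package = "nirscal",
    version = as.character(utils::packageVersion("nirscal")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = study$config$seed,
    config = study$config[setdiff(names(study$config), "seed")],
    config_hash = rlang::hash(study$config)
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Write a synthetic study to disk
#'
#' Generates a seeded synthetic data set ([simulate_nirs()]) and writes the
#' spectra CSV, reference CSV and a provenance JSON recording the seed and
#' generator parameters.
#'
#' @inheritParams simulate_nirs
#' @param dir output directory.
#' @return list with the file paths, invisibly.
#' @export
write_simulation <- function(dir, n_samples = 139, traits = horsegram_traits(),
                             seed = NULL, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_nirs(n_samples, traits, seed = seed, ...)
  paths <- list(spectra = file.path(dir, "spectra.csv"),
                reference = file.path(dir, "reference.csv"),
                provenance = file.path(dir, "provenance.json"))
  write_spectra(sim$spectra, paths$spectra)
  write_reference(sim$reference, paths$reference)
  prov <- list(
    package = "nirscal",
    version = as.character(utils::packageVersion("nirscal")),
    seed = seed, n_samples = n_samples,
    traits = dplyr::select(traits, -"bands"),
    bands = stats::setNames(traits$bands, traits$name),
    extra = list(...)
  )
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(paths)
}
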