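#' Spectra tables
#'
#' `nirscal` stores a set of NIR spectra as a plain wide tibble: a `sample_id`
#' character column followed by one numeric column per wavelength, the column
#' name being the wavelength in nanometres (e.g. `"400"`, `"402"`, ...).
#' Absorbance is apparent absorbance, log(1/R). These helpers build and
#' validate such tables and convert between the tibble and matrix views.
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm),
#'   one per matrix column.
#' @param sample_ids unique character vector, one per matrix row.
#' @return `new_spectra()` returns a spectra tibble; `spectra_matrix()` a
#'   numeric matrix with sample ids as row names; `spectra_wavelengths()` the
#'   numeric wavelength grid.
#' @examples
#' spc <- new_spectra(matrix(rnorm(6), 2), c(400, 402, 404), c("a", "b"))
#' spectra_wavelengths(spc)
#' @export
new_spectra <- function(absorbance, wavelengths, sample_ids) {
  absorbance <- as.matrix(absorbance)
  if (length(wavelengths) != ncol(absorbance)) {
    abort("`wavelengths` must have one entry per absorbance column.")
  }
  if (length(sample_ids) != nrow(absorbance)) {
    abort("`sample_ids` must have one entry per absorbance row.")
  }
  check_wavelengths(wavelengths)
  check_sample_ids(sample_ids)
  if (any(!is.finite(absorbance))) {
    abort("Absorbance values must all be finite.")
  }
  out <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(out) <- format_wavelength(wavelengths)
  dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
}

#' @rdname new_spectra
#' @param spectra a spectra tibble as produced by [new_spectra()] or
#'   [simulate_spectra()].
#' @export
spectra_matrix <- function(spectra) {
  spectra <- validate_spectra(spectra)
  m <- as.matrix(spectra[, -1, drop = FALSE])
  rownames(m) <- spectra$sample_id
  colnames(m) <- names(spectra)[-1]
  m
}

#' @rdname new_spectra
#' @export
spectra_wavelengths <- function(spectra) {
  spectra <- validate_spectra(spectra)
  as.numeric(names(spectra)[-1])
}

format_wavelength <- function(wl) {
  format(wl, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

check_wavelengths <- function(wl) {
  if (any(!is.finite(wl)) || any(diff(wl) <= 0)) {
    abort("Wavelengths must be finite and strictly increasing.")
  }
  invisible(wl)
}

check_sample_ids <- function(ids) {
  ids <- as.character(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("Sample ids must be non-missing, non-empty strings.")
  }
  invisible(ids)
}

validate_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra) || !identical(names(spectra)[1], "sample_id")) {
    abort(sprintf("`%s` must be a data frame whose first column is `sample_id`.", arg))
  }
  if (ncol(spectra) < 2) {
    abort(sprintf("`%s` has no wavelength columns.", arg))
  }
  wl <- suppressWarnings(as.numeric(names(spectra)[-1]))
  if (anyNA(wl)) {
    abort(sprintf("`%s` column names after `sample_id` must be wavelengths in nm.", arg))
  }
  check_wavelengths(wl)
  check_sample_ids(spectra$sample_id)
  tibble::as_tibble(spectra)
}

validate_reference <- function(reference, arg = "reference") {
  if (!is.data.frame(reference) || !identical(names(reference)[1], "sample_id")) {
    abort(sprintf("`%s` must be a data frame whose first column is `sample_id`.", arg))
  }
  check_sample_ids(reference$sample_id)
  tibble::as_tibble(reference)
}

# Align a spectra table and a reference table on sample_id, preserving the
# spectra's row order; errors on any mismatch.
align_ids <- function(spectra, reference) {
  spectra <- validate_spectra(spectra)
  reference <- validate_reference(reference)
  missing <- setdiff(spectra$sample_id, reference$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Sample id(s) in spectra but not in reference: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  reference <- reference[match(spectra$sample_id, reference$sample_id), ]
  list(spectra = spectra, reference = reference)
}

#' Read and write spectra and reference tables
#'
#' Delimited-text (CSV) round trip for the two study tables. Spectra files are
#' wide: `sample_id` then one column per wavelength, the header carrying the
#' wavelength in nm. Reference files are `sample_id` plus one numeric column
#' per trait (g/100 g). Both readers validate the invariants (unique ids,
#' strictly increasing wavelengths, all-numeric cells) and report the offending
#' row/column on failure; writes preserve full double precision so a
#' write/read cycle is lossless.
#'
#' @param spectra,reference the table to write.
#' @param path file path.
#' @return the readers return a validated tibble; the writers return the
#'   input, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  spectra <- validate_spectra(spectra)
  readr::write_csv(spectra, path)
  invisible(spectra)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  validate_spectra(read_numeric_csv(path), arg = basename(path))
}

#' @rdname write_spectra
#' @export
write_reference <- function(reference, path) {
  reference <- validate_reference(reference)
  readr::write_csv(reference, path)
  invisible(reference)
}

#' @rdname write_spectra
#' @export
read_reference <- function(path) {
  validate_reference(read_numeric_csv(path), arg = basename(path))
}

# Strict CSV reader: first column character, all others numeric; non-numeric
# cells are reported with row/column coordinates.
read_numeric_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"sample_id" %in% names(x)) {
    abort(sprintf("%s: missing `sample_id` column in header.", basename(path)))
  }
  for (j in setdiff(names(x), "sample_id")) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    bad <- which(is.na(v) & !is.na(x[[j]]))
    if (anyNA(v)) {
      i <- if (length(bad) > 0) bad[1] else which(is.na(v))[1]
      abort(sprintf("%s: non-numeric value %s at data row %d, column `%s`.",
                    basename(path),
                    if (length(bad) > 0) paste0("'", x[[j]][i], "'") else "(missing)",
                    i, j))
    }
    x[[j]] <- v
  }
  x
}

#' Plot a set of spectra
#'
#' Draws every spectrum as a line over wavelength, the standard first look at
#' a NIR data set (raw or preprocessed).
#'
#' @param spectra a spectra tibble.
#' @param alpha line transparency.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra, alpha = 0.4) {
  spectra <- validate_spectra(spectra)
  long <- tidyr::pivot_longer(spectra, -"sample_id",
                              names_to = "wavelength", values_to = "absorbance")
  long$wavelength <- as.numeric(long$wavelength)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)", y = "log(1/R)") +
    ggplot2::theme_minimal()
}
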