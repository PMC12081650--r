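#' Trait specifications for the synthetic generator
#'
#' A trait specification couples the target distribution of a constituent
#' (mean, sd, hard min/max, all in g/100 g) with the NIR absorption bands
#' through which it shows up in the spectrum. Bands are Gaussian in
#' wavelength: a band of `center` c, `width` w and `strength` s contributes
#' `s * exp(-(lambda - c)^2 / (2 w^2))` absorbance units per g/100 g of the
#' trait.
#'
#' `horsegram_traits()` returns the default five-trait panel of a horse gram
#' (*Macrotyloma uniflorum*) flour study: protein, starch, total soluble
#' sugars (TSS), phenols and phytic acid, with the observed germplasm
#' distributions and band centers placed at the seven absorption maxima seen
#' in legume flour spectra (1196, 1468, 1736, 1934, 2100, 2310, 2482 nm).
#' Band assignments follow the usual functional-group attributions (protein
#' C-O/N-H around 2000-2222 nm, phenols O-H first overtone near 1430-1470 nm,
#' polysaccharides near 1934 nm, C-H overtones at 1196/1736 nm); strengths and
#' widths are generator parameters with defaults sized like real NIR
#' combination bands (FWHM roughly 50-80 nm) so that gap-segment derivatives
#' retain band-level signal well above instrument noise.
#'
#' @param name trait name (syntactic, used as a column name).
#' @param mean,sd,min,max distribution parameters, g/100 g. Sampling is
#'   normal(mean, sd) truncated to \[min, max\].
#' @param bands a data frame with columns `center` (nm), `width` (nm),
#'   `strength` (absorbance per g/100 g); at least one row.
#' @return a one-row (or, for `horsegram_traits()`, five-row) tibble with a
#'   `bands` list-column.
#' @examples
#' horsegram_traits()
#' @export
trait_spec <- function(name, mean, sd, min, max, bands) {
  if (!(min <= mean && mean <= max)) {
    abort(sprintf("Trait '%s': need min <= mean <= max.", name))
  }
  if (sd < 0) abort(sprintf("Trait '%s': sd must be >= 0.", name))
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) == 0) abort(sprintf("Trait '%s': at least one band required.", name))
  stopifnot(all(c("center", "width", "strength") %in% names(bands)))
  if (any(bands$width <= 0) || any(!is.finite(bands$strength))) {
    abort(sprintf("Trait '%s': band widths must be > 0 and strengths finite.", name))
  }
  tibble::tibble(name = name, mean = mean, sd = sd, min = min, max = max,
                 bands = list(bands))
}

band <- function(center, width, strength) {
  tibble::tibble(center = center, width = width, strength = strength)
}

#' @rdname trait_spec
#' @export
horsegram_traits <- function() {
  dplyr::bind_rows(
    trait_spec("protein", 23.7, 0.99, 21.8, 26.7,
               band(c(2100, 2310), c(30, 26), c(0.020, 0.006))),
    trait_spec("starch", 29.8, 1.36, 26.2, 33.0,
               band(c(1934, 2482), c(32, 28), c(0.020, 0.008))),
    trait_spec("tss", 5.61, 2.50, 0.86, 12.1,
               band(c(1736, 2100), c(26, 22), c(0.022, 0.004))),
    trait_spec("phenols", 0.701, 0.17, 0.340, 1.13,
               band(1468, 22, 0.15)),
    trait_spec("phytic_acid", 1.02, 0.44, 0.110, 2.12,
               band(c(1196, 1934), c(22, 20), c(0.060, 0.015)))
  )
}

validate_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("name", "mean", "sd", "min", "max", "bands") %in% names(traits)))
  check_sample_ids(traits$name)
  for (i in seq_len(nrow(traits))) {
    trait_spec(traits$name[i], traits$mean[i], traits$sd[i],
               traits$min[i], traits$max[i], traits$bands[[i]])
  }
  traits
}

# Evaluate code with a locally-set RNG state; NULL seed leaves the global
# stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rtruncnorm <- function(n, mean, sd, min, max) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

#' Simulate reference trait concentrations
#'
#' Draws each trait independently from a normal distribution truncated to the
#' trait's \[min, max\] range (rejection sampling, so the bounds are hard).
#'
#' @param n_samples number of samples (>= 2).
#' @param traits a trait-spec tibble, see [trait_spec()].
#' @param seed integer; fixes all randomness when supplied.
#' @param id_prefix prefix for the generated sample ids.
#' @return a reference tibble: `sample_id` plus one numeric column per trait.
#' @examples
#' simulate_reference(5, seed = 1)
#' @export
simulate_reference <- function(n_samples, traits = horsegram_traits(),
                               seed = NULL, id_prefix = "HG") {
  if (n_samples < 2) abort("`n_samples` must be at least 2.")
  traits <- validate_traits(traits)
  local_seed(seed, {
    vals <- purrr::map(seq_len(nrow(traits)), function(i) {
      rtruncnorm(n_samples, traits$mean[i], traits$sd[i],
                 traits$min[i], traits$max[i])
    })
    names(vals) <- traits$name
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("%s%03d", id_prefix, seq_len(n_samples))),
      tibble::as_tibble(vals)
    )
  })
}

# Clean mixture spectrum: sum over traits and bands of concentration *
# Gaussian(center, width) * strength, plus the polynomial baseline.
band_design <- function(traits, wavelengths) {
  cols <- purrr::map(seq_len(nrow(traits)), function(i) {
    b <- traits$bands[[i]]
    rowSums(vapply(seq_len(nrow(b)), function(k) {
      b$strength[k] * exp(-(wavelengths - b$center[k])^2 / (2 * b$width[k]^2))
    }, numeric(length(wavelengths))))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- traits$name
  m
}

#' Simulate NIR spectra from reference concentrations
#'
#' Builds log(1/R) spectra on a regular wavelength grid as a linear
#' Beer-Lambert-style mixture of the traits' Gaussian absorption bands plus a
#' smooth polynomial baseline, then degrades each spectrum with multiplicative
#' and additive scatter (`(1 + m) * A + o`, per-sample `m`, `o`) and additive
#' Gaussian noise. The scatter terms are exactly the artefacts SNV-DT
#' preprocessing is designed to remove; `noise_sd` represents residual noise
#' after the instrument's scan averaging.
#'
#' @param reference a reference tibble ([simulate_reference()] or
#'   [read_reference()]); its trait columns must match `traits$name`.
#' @param traits trait-spec tibble.
#' @param wavelength_start,wavelength_end,step grid in nm (default 400-2500 at
#'   2 nm, i.e. 1051 points).
#' @param baseline numeric length 3: offset, slope per nm and curvature per
#'   nm^2 of the baseline polynomial in (lambda - wavelength_start).
#' @param scatter numeric length 2: sd of the multiplicative slope `m` and of
#'   the additive offset `o`; `c(0, 0)` disables scatter.
#' @param noise_sd sd of the additive noise in absorbance units (default
#'   1e-4, the order of the RMS noise a scanning monochromator reaches after
#'   32-scan averaging).
#' @param seed integer; fixes all randomness when supplied.
#' @return a spectra tibble (see [new_spectra()]).
#' @examples
#' ref <- simulate_reference(3, seed = 1)
#' spc <- simulate_spectra(ref, seed = 1)
#' dim(spc)
#' @export
simulate_spectra <- function(reference, traits = horsegram_traits(),
                             wavelength_start = 400, wavelength_end = 2500,
                             step = 2,
                             baseline = c(0.3, 1.5e-4, -3e-8),
                             scatter = c(0.05, 0.02),
                             noise_sd = 1e-4, seed = NULL) {
  traits <- validate_traits(traits)
  reference <- validate_reference(reference)
  missing <- setdiff(traits$name, names(reference))
  if (length(missing) > 0) {
    abort(paste0("Reference table lacks trait column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (step <= 0 || wavelength_end <= wavelength_start) {
    abort("Need step > 0 and wavelength_end > wavelength_start.")
  }
  if (any(scatter < 0) || noise_sd < 0) abort("Scatter sds and noise_sd must be >= 0.")
  wl <- seq(wavelength_start, wavelength_end, by = step)
  conc <- as.matrix(reference[, traits$name, drop = FALSE])
  design <- band_design(traits, wl)          # n_wl x n_traits
  x <- wl - wavelength_start
  base <- baseline[1] + baseline[2] * x + baseline[3] * x^2
  clean <- conc %*% t(design) + matrix(base, nrow(conc), length(wl), byrow = TRUE)
  local_seed(seed, {
    n <- nrow(clean)
    m <- rnorm(n, 0, scatter[1])
    o <- rnorm(n, 0, scatter[2])
    noisy <- (1 + m) * clean + o
    if (noise_sd > 0) {
      noisy <- noisy + matrix(rnorm(length(noisy), 0, noise_sd), nrow = n)
    }
    new_spectra(noisy, wl, reference$sample_id)
  })
}

#' Simulate a complete synthetic NIRS study
#'
#' Convenience wrapper generating a reference table and matching spectra in
#' one seeded call. Defaults reproduce the study conditions this package's
#' examples are built around: 139 flour samples, five traits, 400-2500 nm at
#' 2 nm.
#'
#' @inheritParams simulate_reference
#' @param ... passed on to [simulate_spectra()].
#' @return a list with elements `reference` and `spectra`.
#' @examples
#' study <- simulate_nirs(10, seed = 42)
#' nrow(study$spectra)
#' @export
simulate_nirs <- function(n_samples = 139, traits = horsegram_traits(),
                          seed = NULL, ...) {
  local_seed(seed, {
    reference <- simulate_reference(n_samples, traits)
    spectra <- simulate_spectra(reference, traits, ...)
    list(reference = reference, spectra = spectra)
  })
}
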