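#' WinISI-style math treatment codes
#'
#' Derivative preprocessing of NIR spectra is conventionally written as a
#' four-number code `"d,g,s1,s2"`: derivative order `d`, gap `g` (points)
#' over which each difference is taken, and two boxcar smoothing segment
#' lengths `s1` (applied before the derivative) and `s2` (after). `"0,1,1,1"`
#' is the identity; the treatments used for legume flour calibrations in this
#' package's worked examples are `"2,4,4,1"`, `"2,8,8,1"` and `"3,4,4,1"`.
#'
#' Even segment lengths are normalized up to the next odd number so the
#' smoothing window is symmetric; the normalization is signalled as a message
#' (class `nirscal_segment_normalized`) when the treatment is applied.
#'
#' @param x a treatment string `"d,g,s1,s2"`, or an object already parsed by
#'   `parse_treatment()`.
#' @return `parse_treatment()` returns a `math_treatment` object (a list with
#'   fields `derivative`, `gap`, `smooth1`, `smooth2`);
#'   `format()` renders it back to the `"d,g,s1,s2"` string.
#' @examples
#' parse_treatment("2,4,4,1")
#' @export
parse_treatment <- function(x) {
  if (inherits(x, "math_treatment")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    parts <- x
  } else {
    if (!is.character(x) || length(x) != 1) {
      abort("A math treatment must be a single string like \"2,4,4,1\".")
    }
    parts <- suppressWarnings(as.numeric(strsplit(trimws(x), ",")[[1]]))
  }
  if (length(parts) != 4 || anyNA(parts) || any(parts != round(parts)) ||
      parts[1] < 0 || any(parts[2:4] < 1)) {
    abort(sprintf(
      "Invalid math treatment '%s': need \"d,g,s1,s2\" with integer d >= 0 and g, s1, s2 >= 1.",
      paste(x, collapse = ",")))
  }
  structure(list(derivative = as.integer(parts[1]), gap = as.integer(parts[2]),
                 smooth1 = as.integer(parts[3]), smooth2 = as.integer(parts[4])),
            class = "math_treatment")
}

#' @rdname parse_treatment
#' @param ... unused.
#' @export
format.math_treatment <- function(x, ...) {
  paste(x$derivative, x$gap, x$smooth1, x$smooth2, sep = ",")
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math treatment ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Standard normal variate and detrend
#'
#' Per-spectrum scatter corrections. `snv()` standardizes one spectrum to
#' mean 0 and (sample) standard deviation 1, removing additive offsets and
#' multiplicative path-length effects. `detrend()` subtracts the least-squares
#' polynomial of `degree` in wavelength, removing smooth baseline curvature.
#' `snv_detrend()` is their composition in the conventional order, SNV first.
#'
#' @param x numeric spectrum (absorbance vector), length >= 2.
#' @param wavelengths numeric wavelength (nm) vector matching `x`.
#' @param degree polynomial degree for the detrend fit (default 2, i.e.
#'   quadratic baseline).
#' @return the corrected spectrum, same length as `x`.
#' @examples
#' snv(c(1, 2, 3))
#' detrend(c(1, 4, 9, 16), c(1, 2, 3, 4), degree = 1)
#' @export
snv <- function(x) {
  if (length(x) < 2) abort("SNV needs at least 2 points.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("SNV undefined for a constant spectrum (sd = 0).")
  }
  (x - mean(x)) / s
}

#' @rdname snv
#' @export
detrend <- function(x, wavelengths, degree = 2) {
  if (degree < 0) abort("`degree` must be >= 0.")
  if (degree >= length(x)) abort("`degree` must be below the number of points.")
  stopifnot(length(x) == length(wavelengths))
  q <- detrend_basis(wavelengths, degree)
  drop(x - q %*% crossprod(q, x))
}

#' @rdname snv
#' @export
snv_detrend <- function(x, wavelengths, degree = 2) {
  detrend(snv(x), wavelengths, degree)
}

# Orthonormal polynomial basis over the (rescaled) wavelength grid; the
# detrend residual is the projection onto its orthogonal complement.
detrend_basis <- function(wavelengths, degree) {
  z <- scale_unit(wavelengths)
  v <- outer(z, 0:degree, `^`)
  qr.Q(qr(v))
}

scale_unit <- function(w) {
  r <- range(w)
  if (r[1] == r[2]) return(rep(0, length(w)))
  2 * (w - r[1]) / (r[2] - r[1]) - 1
}

normalize_segment <- function(s, signal = TRUE) {
  s <- as.integer(s)
  if (s <= 1) return(1L)
  if (s %% 2 == 0) {
    if (signal) {
      inform(sprintf("Smoothing segment %d normalized to %d for a symmetric window.",
                     s, s + 1L),
             class = "nirscal_segment_normalized")
    }
    s <- s + 1L
  }
  s
}

# Boxcar (moving mean) smoothing of the rows of m with an odd segment;
# trims (s-1)/2 points at each end. s = 1 is a no-op.
boxcar_rows <- function(m, wl, s) {
  if (s <= 1) return(list(m = m, wl = wl))
  h <- (s - 1L) %/% 2L
  p <- ncol(m)
  if (p < s) abort("Grid too short for the smoothing segment.")
  sm <- stats::filter(t(m), rep(1 / s, s), sides = 2)
  keep <- (1L + h):(p - h)
  list(m = t(sm[keep, , drop = FALSE]), wl = wl[keep])
}

# One centered gap difference of the rows: D[i] = x[i + ceil(g/2)] - x[i - floor(g/2)].
gap_diff_rows <- function(m, wl, g) {
  hl <- g %/% 2L
  hr <- g - hl
  p <- ncol(m)
  if (p <= g) abort("Grid too short for the derivative gap.")
  d <- m[, (1L + hl + hr):p, drop = FALSE] - m[, 1L:(p - hl - hr), drop = FALSE]
  list(m = d, wl = wl[(1L + hl):(p - hr)])
}

#' Gap-segment derivative of a spectra set
#'
#' Applies a math treatment's derivative pipeline to every spectrum: boxcar
#' smoothing with segment `s1`, then `d` successive applications of the
#' centered gap difference `D[i] = x[i + ceil(g/2)] - x[i - floor(g/2)]`
#' (so a linear ramp with slope `a` per point maps to the constant `a * g`),
#' then boxcar smoothing with segment `s2`. Only indices whose windows lie
#' fully inside the grid are kept, so the wavelength grid of the result is
#' trimmed symmetrically; no values are fabricated at the spectrum ends. All
#' samples are trimmed identically.
#'
#' @param spectra a spectra tibble.
#' @param treatment a `"d,g,s1,s2"` string or [parse_treatment()] object.
#' @return a spectra tibble on the trimmed grid.
#' @examples
#' spc <- simulate_nirs(3, seed = 1)$spectra
#' ncol(gap_derivative(spc, "2,4,4,1"))
#' @export
gap_derivative <- function(spectra, treatment) {
  t <- parse_treatment(treatment)
  spectra <- validate_spectra(spectra)
  out <- gap_derivative_matrix(spectra_matrix(spectra), spectra_wavelengths(spectra), t)
  new_spectra(out$m, out$wl, spectra$sample_id)
}

gap_derivative_matrix <- function(m, wl, t, signal = TRUE) {
  s1 <- normalize_segment(t$smooth1, signal)
  s2 <- normalize_segment(t$smooth2, signal)
  st <- boxcar_rows(m, wl, s1)
  if (t$derivative > 0) {
    for (i in seq_len(t$derivative)) st <- gap_diff_rows(st$m, st$wl, t$gap)
  }
  boxcar_rows(st$m, st$wl, s2)
}

#' Apply a full preprocessing treatment to a spectra set
#'
#' The standard preprocessing chain for NIRS calibration: a per-spectrum
#' scatter correction (none, SNV, or SNV followed by detrend) followed by the
#' gap-segment derivative math treatment. Scatter correction always precedes
#' the derivative.
#'
#' @param spectra a spectra tibble.
#' @param treatment `"d,g,s1,s2"` math treatment (default `"0,1,1,1"`, no
#'   derivative).
#' @param scatter one of `"snv_dt"`, `"snv"`, `"none"`.
#' @param detrend_degree polynomial degree of the detrend step.
#' @return a spectra tibble on the (possibly trimmed) grid.
#' @examples
#' spc <- simulate_nirs(3, seed = 1)$spectra
#' pre <- apply_treatment(spc, "2,4,4,1", scatter = "snv_dt")
#' @export
apply_treatment <- function(spectra, treatment = "0,1,1,1",
                            scatter = c("snv_dt", "snv", "none"),
                            detrend_degree = 2) {
  scatter <- match.arg(scatter)
  t <- parse_treatment(treatment)
  spectra <- validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  wl <- spectra_wavelengths(spectra)
  if (scatter != "none") {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("SNV undefined for constant spectrum of sample(s): ",
                   paste(spectra$sample_id[sds == 0], collapse = ", ")))
    }
    m <- (m - rowMeans(m)) / sds
    if (scatter == "snv_dt") {
      q <- detrend_basis(wl, detrend_degree)
      m <- m - (m %*% q) %*% t(q)
    }
  }
  out <- gap_derivative_matrix(m, wl, t)
  new_spectra(out$m, out$wl, spectra$sample_id)
}
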