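test_that("snv standardizes each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(1051, 0.4, 0.1)
  out <- snv(x)
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(sd(out) - 1), 1e-12)
  expect_equal(snv(snv(x)), snv(x))
  expect_error(snv(rep(2, 10)), "constant spectrum")
})

test_that("detrend is the least-squares polynomial projection", {
  wl <- seq(400, 2500, 2)
  quad <- 0.3 + 1e-4 * wl + 2e-8 * wl^2
  expect_lt(max(abs(detrend(quad, wl, 2))), 1e-9)
  set.seed(2)
  x <- rnorm(length(wl))
  d1 <- detrend(x, wl, 2)
  expect_equal(detrend(d1, wl, 2), d1, tolerance = 1e-9)
  expect_equal(d1, detrend_oracle(x, wl, 2), tolerance = 1e-9)
  # residual orthogonal to the polynomial basis
  v <- outer(2 * (wl - 400) / 2100 - 1, 0:2, `^`)
  expect_lt(max(abs(t(v) %*% d1)) / length(wl), 1e-9)
  expect_error(detrend(1:3, 400:402, 3), "below the number of points")
})

test_that("snv_detrend composes snv then detrend and removes scatter", {
  wl <- seq(400, 2500, 2)
  set.seed(3)
  x <- rnorm(length(wl), 0.5, 0.05)
  expect_equal(snv_detrend(x, wl), detrend(snv(x), wl, 2))
  # scatter family (1+m)*A + o collapses after SNV-DT on noiseless spectra
  ref <- simulate_reference(6, seed = 4)
  clean <- simulate_spectra(ref, scatter = c(0, 0), noise_sd = 0)
  scattered <- simulate_spectra(ref, scatter = c(0.08, 0.04), noise_sd = 0,
                                seed = 4)
  spread <- function(spc) {
    m <- spectra_matrix(apply_treatment(spc, "0,1,1,1", scatter = "snv_dt"))
    max(dist(m))
  }
  raw_spread <- max(dist(spectra_matrix(scattered)))
  expect_lt(spread(scattered), raw_spread)
  expect_equal(spread(scattered), spread(clean), tolerance = 1e-8)
})

test_that("treatment codes parse, render and validate", {
  t <- parse_treatment("2,4,4,1")
  expect_equal(t$derivative, 2L)
  expect_equal(t$gap, 4L)
  expect_equal(format(t), "2,4,4,1")
  expect_error(parse_treatment("2,4"), "Invalid math treatment")
  expect_error(parse_treatment("2,0,1,1"), "Invalid math treatment")
  expect_error(parse_treatment("a,b,c,d"), "Invalid math treatment")
})

test_that("gap derivative matches the literal loop oracle", {
  set.seed(5)
  m <- matrix(rnorm(3 * 80), 3)
  spc <- make_spectra_tbl(m)
  for (code in list(c(2, 4, 4, 1), c(1, 3, 1, 1), c(2, 8, 8, 1), c(0, 1, 5, 3))) {
    out <- suppressMessages(
      gap_derivative(spc, paste(code, collapse = ",")))
    got <- spectra_matrix(out)
    for (i in 1:3) {
      want <- gap_deriv_oracle(m[i, ], code[1], code[2], code[3], code[4])
      expect_equal(unname(got[i, ]), want, tolerance = 1e-12)
    }
  }
})

test_that("gap derivative basics: identity, ramp, linearity, even segments", {
  spc <- make_spectra_tbl(matrix(rnorm(2 * 50), 2))
  expect_equal(gap_derivative(spc, "0,1,1,1"), spc)
  # linear ramp maps to the constant a*g for odd and even gaps
  a <- 0.7
  ramp <- make_spectra_tbl(matrix(a * (1:60), 1))
  for (g in c(2, 3, 4, 8)) {
    out <- spectra_matrix(gap_derivative(ramp, sprintf("1,%d,1,1", g)))
    expect_equal(unname(out[1, ]), rep(a * g, ncol(out)), tolerance = 1e-12)
  }
  # linearity: T(a x + b y) = a T(x) + b T(y)
  set.seed(6)
  x <- rnorm(70); y <- rnorm(70)
  tr <- function(v) spectra_matrix(suppressMessages(
    gap_derivative(make_spectra_tbl(matrix(v, 1)), "2,4,4,1")))[1, ]
  expect_equal(tr(2 * x - 3 * y), 2 * tr(x) - 3 * tr(y), tolerance = 1e-12)
  # even smoothing segments are normalized up with a message
  expect_message(gap_derivative(spc, "1,2,4,1"), "normalized to 5",
                 class = "nirscal_segment_normalized")
  expect_error(gap_derivative(make_spectra_tbl(matrix(1:4, 1)), "2,8,1,1"),
               "too short")
})

test_that("apply_treatment composes scatter correction and derivative uniformly", {
  s <- simulate_nirs(5, seed = 7)
  expect_equal(apply_treatment(s$spectra, "0,1,1,1", scatter = "none"),
               s$spectra)
  out <- suppressMessages(
    apply_treatment(s$spectra, "2,8,8,1", scatter = "snv_dt"))
  expect_lt(ncol(out) - 1, 1051)
  expect_equal(nrow(out), 5)
  # all three classic treatments run on the default synthetic fixture
  for (tr in c("2,4,4,1", "2,8,8,1", "3,4,4,1")) {
    res <- suppressMessages(apply_treatment(s$spectra, tr, scatter = "snv_dt"))
    expect_true(all(is.finite(spectra_matrix(res))))
    expect_equal(nrow(res), 5)
  }
  # constant spectrum is named in the SNV error
  bad <- s$spectra
  bad[2, -1] <- as.list(rep(1, 1051))
  expect_error(apply_treatment(bad, "0,1,1,1"), bad$sample_id[2])
})
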