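test_that("pc model recovers rank and matches an eigendecomposition oracle", {
  # rank-1 data: one component explains everything
  set.seed(8)
  base <- rnorm(30)
  m <- outer(rnorm(8, 0, 2), base) + 1
  pc1 <- fit_pc_model(make_spectra_tbl(m))
  expect_equal(pc1$k, 1L)
  expect_gt(pc1$explained_fraction, 1 - 1e-12)
  # full-rank reconstruction with k = n - 1
  m2 <- rand_matrix(10, 20, seed = 9)
  pc_full <- fit_pc_model(make_spectra_tbl(m2), variance_target = 1,
                          k_max = 9)
  scores <- sweep(m2, 2, pc_full$center) %*% pc_full$loadings
  recon <- sweep(scores %*% t(pc_full$loadings), 2, pc_full$center, `+`)
  expect_equal(unname(recon), m2, tolerance = 1e-8)
  # loadings and score variances match eigen(cov(X))
  eig <- eigen(cov(m2), symmetric = TRUE)
  pc <- fit_pc_model(make_spectra_tbl(m2), variance_target = 0.99, k_max = 5)
  expect_equal(pc$score_sds^2, eig$values[seq_len(pc$k)], tolerance = 1e-8)
  for (j in seq_len(pc$k)) {
    expect_equal(abs(sum(pc$loadings[, j] * eig$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("global H has the standardized-score algebra", {
  s <- simulate_nirs(25, seed = 10)
  pc <- fit_pc_model(s$spectra)
  n <- nrow(s$spectra)
  # the population mean spectrum has GH = 0
  mean_spc <- new_spectra(matrix(pc$center, 1), pc$grid, "mean")
  expect_equal(global_h(pc, mean_spc)$gh, 0, tolerance = 1e-12)
  # mean GH over the fitting set is (n-1)/n
  expect_equal(mean(global_h(pc, s$spectra)$gh), (n - 1) / n,
               tolerance = 1e-9)
  # invariant to adding a constant vector to every spectrum (model re-fit)
  shifted <- s$spectra
  shifted[, -1] <- shifted[, -1] + 0.25
  pc2 <- fit_pc_model(shifted)
  expect_equal(global_h(pc2, shifted)$gh, global_h(pc, s$spectra)$gh,
               tolerance = 1e-6)
})

test_that("neighbourhood H matches the all-pairs brute-force scan", {
  s <- simulate_nirs(15, seed = 11)
  pc <- fit_pc_model(s$spectra)
  nh <- neighborhood_h(pc, s$spectra)$nh
  z <- sweep(spectra_matrix(s$spectra), 2, pc$center) %*% pc$loadings
  z <- sweep(z, 2, pc$score_sds, `/`)
  brute <- vapply(seq_len(nrow(z)), function(i) {
    min(vapply(setdiff(seq_len(nrow(z)), i), function(j) {
      sum((z[i, ] - z[j, ])^2) / pc$k
    }, 0))
  }, 0)
  expect_equal(nh, brute, tolerance = 1e-12)
  # a duplicated sample gives NH = 0 for both copies, symmetrically
  dup <- dplyr::bind_rows(s$spectra, dplyr::mutate(s$spectra[3, ],
                                                   sample_id = "copy"))
  pc_d <- fit_pc_model(dup)
  nh_d <- neighborhood_h(pc_d, dup)$nh
  expect_equal(nh_d[c(3, 16)], c(0, 0), tolerance = 1e-12)
})

test_that("screening flags an injected gross baseline artefact by GH", {
  s <- simulate_nirs(30, seed = 12)
  spiked <- s$spectra
  wl <- spectra_wavelengths(spiked)
  bump <- 0.5 * exp(-(wl - 800)^2 / (2 * 30^2))
  spiked[7, -1] <- spiked[7, -1] + as.list(bump)
  scr <- screen_outliers(spiked, s$reference)
  expect_equal(scr$report$flag[7], "gh_outlier")
  expect_true(all(scr$report$flag[-7] != "gh_outlier"))
  # hand recomputation of the flagged sample's GH
  z <- (sweep(spectra_matrix(spiked)[7, , drop = FALSE], 2,
              scr$model$center) %*% scr$model$loadings) / scr$model$score_sds
  expect_equal(scr$report$gh[7], mean(z^2), tolerance = 1e-12)
  expect_gt(scr$report$gh[7], 2.5)
  # kept spectra and reference stay id-aligned
  expect_equal(scr$spectra$sample_id, scr$reference$sample_id)
})

test_that("screening honours thresholds, modes and determinism", {
  s <- simulate_nirs(20, seed = 13)
  open <- screen_outliers(s$spectra, s$reference, gh_threshold = Inf,
                          nh_threshold = Inf)
  expect_equal(nrow(open$spectra), 20)
  expect_true(all(open$report$flag == "keep"))
  a <- screen_outliers(s$spectra)
  b <- screen_outliers(s$spectra)
  expect_identical(a$report, b$report)
  # redundancy mode prunes one of a duplicated pair instead of isolates
  dup <- dplyr::bind_rows(s$spectra, dplyr::mutate(s$spectra[5, ],
                                                   sample_id = "copy"))
  red <- screen_outliers(dup, gh_threshold = Inf, nh_threshold = 1e-6,
                         nh_mode = "redundant")
  expect_equal(sum(red$report$flag == "nh_outlier"), 1)
  expect_true(red$report$flag[red$report$sample_id == "copy"] == "nh_outlier")
  # refusing to empty the calibration set
  expect_error(screen_outliers(s$spectra, gh_threshold = -1),
               "refusing to return an empty calibration set")
})
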