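test_that("single-factor noise-free relations are fitted exactly", {
  # mean-zero orthonormal columns, so one factor isolates the active wavelength
  x <- qr.Q(qr(cbind(1, rand_matrix(40, 25, seed = 17))))[, 2:26]
  y <- 3 * x[, 5]
  for (mod in c(TRUE, FALSE)) {
    fit <- fit_pls1(x, y, max_rank = 1, modified = mod)
    expect_equal(pls_predict(fit, x), y, tolerance = 1e-8)
  }
})

test_that("standard PLS1 matches the textbook NIPALS oracle at every rank", {
  x <- rand_matrix(30, 50, seed = 18)
  set.seed(19)
  y <- drop(x[, 1:6] %*% runif(6, -1, 1)) + rnorm(30, sd = 0.2)
  fit <- fit_pls1(x, y, max_rank = 10, modified = FALSE)
  oracle <- nipals_oracle(x, y, 10)
  xnew <- rand_matrix(7, 50, seed = 20)
  for (r in 1:10) {
    expect_equal(fit$coefs[, r], oracle$coefs(r), tolerance = 1e-6)
    expect_equal(pls_predict(fit, xnew, rank = r), oracle$predict(xnew, r),
                 tolerance = 1e-6)
  }
})

test_that("coefficient path reproduces factor replay, also for MPLS", {
  x <- rand_matrix(28, 45, seed = 21)
  set.seed(22)
  y <- drop(x[, 1:4] %*% c(1, -2, 0.5, 1)) + rnorm(28, sd = 0.1)
  for (mod in c(TRUE, FALSE)) {
    fit <- fit_pls1(x, y, max_rank = 6, modified = mod)
    for (r in 1:fit$rank) {
      via_coef <- drop(x %*% fit$coefs[, r]) + fit$intercepts[r]
      expect_equal(pls_predict(fit, x, rank = r), via_coef, tolerance = 1e-8)
    }
  }
})

test_that("rank 0 predicts the calibration mean and SEC decreases with rank", {
  x <- rand_matrix(30, 25, seed = 23)
  set.seed(24)
  y <- rnorm(30, 10, 2)
  fit <- fit_pls1(x, y, max_rank = 5)
  expect_equal(pls_predict(fit, x, rank = 0), rep(mean(y), 30))
  sec_by_rank <- vapply(0:5, function(r) {
    sqrt(sum((y - pls_predict(fit, x, rank = r))^2))
  }, 0)
  expect_true(all(diff(sec_by_rank) <= 1e-10))
})

test_that("mpls residuals and scores obey the deflation geometry", {
  x <- rand_matrix(26, 30, seed = 25)
  set.seed(26)
  y <- drop(x[, 1:3] %*% c(2, 1, -1)) + rnorm(26, sd = 0.3)
  fit <- fit_pls1(x, y, max_rank = 5, modified = TRUE)
  # recompute scores by replaying the stored factors
  r <- sweep(x, 2, fit$x_center)
  scores <- matrix(0, 26, fit$rank)
  for (a in seq_len(fit$rank)) {
    scores[, a] <- r %*% fit$weights[, a]
    r <- r - scores[, a] %*% t(fit$x_loadings[, a])
    r <- sweep(r, 2, fit$resid_sds[, a], `/`)
  }
  for (r_ in seq_len(fit$rank)) {
    resid <- y - pls_predict(fit, x, rank = r_)
    for (a in seq_len(r_)) {
      expect_lt(abs(sum(resid * scores[, a])) / sqrt(sum(scores[, a]^2)), 1e-8)
    }
  }
})

test_that("prediction is affine in the spectrum", {
  x <- rand_matrix(20, 30, seed = 27)
  set.seed(28)
  y <- rnorm(20)
  fit <- fit_pls1(x, y, max_rank = 3)
  u <- rand_matrix(1, 30, seed = 29)
  v <- rand_matrix(1, 30, seed = 30)
  f <- function(m) pls_predict(fit, m)
  # affine: f(a u + (1-a) v) = a f(u) + (1-a) f(v)
  expect_equal(f(0.3 * u + 0.7 * v), 0.3 * f(u) + 0.7 * f(v),
               tolerance = 1e-10)
})

test_that("cross-validation scores ranks by held-out SECV", {
  x <- rand_matrix(40, 30, seed = 31)
  set.seed(32)
  y <- rnorm(40, 5, 1.5)
  cv <- cross_validate(x, y, max_rank = 4, n_groups = 5, seed = 99)
  # rank-0 SECV equals the closed-form held-out-mean oracle
  expect_equal(cv$secv_by_rank$secv[1], secv0_oracle(y, cv$assignment),
               tolerance = 1e-12)
  expect_true(all(cv$secv_by_rank$secv >= 0))
  # determinism under the seed
  cv2 <- cross_validate(x, y, max_rank = 4, n_groups = 5, seed = 99)
  expect_identical(cv$assignment, cv2$assignment)
  expect_identical(cv$secv_by_rank, cv2$secv_by_rank)
  # identifiable rank-1 structure is chosen at tolerance 0
  y1 <- drop(x %*% rnorm(30))
  w <- rnorm(30)
  y1 <- 2 * drop(x %*% w)
  cv1 <- cross_validate(x, y1, max_rank = 4, n_groups = 5, seed = 1,
                        modified = FALSE, parsimony_tol = 0)
  expect_equal(cv1$chosen_rank, which.min(cv1$secv_by_rank$secv) - 1L)
  expect_error(cross_validate(x, y, n_groups = 1), "at least 2")
})

test_that("degenerate fits are refused or truncated cleanly", {
  x <- rand_matrix(12, 8, seed = 33)
  expect_error(fit_pls1(x, rep(1, 12)), "zero variance")
  # exactly rank-1 x: extraction stops early and records the achieved rank
  x1 <- outer(rnorm(12), rnorm(8))
  y <- drop(x1[, 1]) + 0
  fit <- fit_pls1(x1, y, max_rank = 5, modified = FALSE)
  expect_lt(fit$rank, 5)
  expect_equal(pls_predict(fit, x1), y, tolerance = 1e-8)
})
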