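test_that("calibration statistics match their defining formulas", {
  set.seed(34)
  y <- rnorm(50, 24, 1)
  # perfect fit
  cs <- calibration_stats(y, y, y, rank = 3)
  expect_equal(cs$rsq, 1)
  expect_equal(cs$sec, 0)
  expect_equal(cs$slope, 1)
  # mean-only cross-validated predictor: 1-VR collapses to 1 - (n-1)/n
  y_fit <- y + rnorm(50, sd = 0.2)
  cs2 <- calibration_stats(y, y_fit, rep(mean(y), 50), rank = 2)
  expect_equal(cs2$one_minus_vr, 1 - (50 - 1) / 50, tolerance = 1e-12)
  # literal-formula recomputation on a random fixture
  y_cv <- y + rnorm(50, sd = 0.3)
  cs3 <- calibration_stats(y, y_fit, y_cv, rank = 4, n_outliers = 2)
  n <- 50
  expect_equal(cs3$sec, sqrt(sum((y - y_fit)^2) / (n - 4 - 1)), tolerance = 1e-12)
  expect_equal(cs3$secv, sqrt(sum((y - y_cv)^2) / n), tolerance = 1e-12)
  expect_equal(cs3$sd, sd(y), tolerance = 1e-12)
  expect_equal(cs3$one_minus_vr, 1 - (sum((y - y_cv)^2) / n) / var(y),
               tolerance = 1e-12)
  expect_equal(cs3$rsq, cor(y, y_fit)^2, tolerance = 1e-12)
  expect_equal(cs3$slope, unname(coef(lm(y ~ y_fit))[2]), tolerance = 1e-12)
  expect_error(calibration_stats(y, rep(1, 50), y_cv, 2), "Zero-variance")
})

test_that("validation statistics obey the SEP decomposition identity", {
  set.seed(35)
  y <- rnorm(40, 30, 1.5)
  p <- y + rnorm(40, 0.1, 0.4)
  vs <- validation_stats(y, p)
  n <- 40
  expect_equal(vs$sep^2, vs$sep_c^2 * (n - 1) / n + vs$bias^2, tolerance = 1e-9)
  expect_equal(vs$rpd, vs$sd / vs$sep_c, tolerance = 1e-9)
  expect_equal(vs$bias, mean(p - y), tolerance = 1e-12)
  expect_equal(vs$slope, unname(coef(lm(y ~ p))[2]), tolerance = 1e-12)
  # pure offset: all error is bias, SEP(C) = 0, RPD = Inf with a warning
  expect_warning(vs0 <- validation_stats(y, y + 2), "RPD reported as Inf")
  expect_equal(vs0$bias, 2)
  expect_equal(vs0$sep_c, 0)
  expect_equal(vs0$rpd, Inf)
})

test_that("rpd bands follow the conventional cutoffs", {
  expect_equal(classify_rpd(c(1.2, 1.85, 2.15, 2.7, 4.03)),
               c("unreliable", "screening", "approximate_quant", "good",
                 "excellent"))
  expect_equal(classify_rpd(c(1.5, 2.0, 2.5, 3.0)),
               c("screening", "approximate_quant", "good", "excellent"))
  expect_error(classify_rpd(-0.1), "negative")
  expect_equal(rpd(1.101, 0.595), 1.101 / 0.595)
  expect_error(rpd(1, 0), "positive")
})

test_that("paired t-test agrees with stats::t.test and the quantile formula", {
  set.seed(36)
  y <- rnorm(35, 24, 1)
  p <- y + rnorm(35, 0.05, 0.2)
  pt_ <- paired_t(y, p)
  ref <- t.test(y, p, paired = TRUE, conf.level = 0.95)
  expect_equal(pt_$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pt_$p, ref$p.value, tolerance = 1e-12)
  expect_equal(c(pt_$ci_low, pt_$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-9)
  expect_equal(pt_$df, 34)
  # direct quantile-formula oracle
  d <- y - p
  expect_equal(pt_$ci_high, mean(d) + qt(0.975, 34) * sd(d) / sqrt(35),
               tolerance = 1e-9)
  # shift invariance
  pt_shift <- paired_t(y + 5, p + 5)
  expect_equal(pt_shift$p, pt_$p, tolerance = 1e-12)
  # degenerate differences
  expect_equal(paired_t(c(1, -1), c(0, 0))$t, 0)
  expect_error(paired_t(c(1, 2), c(0, 1)), "undefined")
  expect_warning(paired_t(1:3, 1:3), "exactly zero")
})

test_that("strict-parallel reliability steps up the pooled correlation", {
  x <- rnorm(30)
  expect_equal(correlation_reliability(x, x)$reliability, 1)
  expect_equal(correlation_reliability(x, x)$pearson_r, 1)
  # equal variances with r = 0.5 give reliability 2/3 exactly
  a <- rep(c(1, 1, -1, -1), 5)
  b <- rep(c(1, -1, 1, -1), 5)
  y2 <- 0.5 * a + sqrt(0.75) * b
  out <- correlation_reliability(a, y2)
  expect_equal(out$pearson_r, 0.5, tolerance = 1e-12)
  expect_equal(out$reliability, 2 / 3, tolerance = 1e-12)
  # orthogonal fixture: r = 0, reliability = 0
  out0 <- correlation_reliability(a, b)
  expect_equal(out0$pearson_r, 0, tolerance = 1e-12)
  expect_equal(out0$reliability, 0, tolerance = 1e-12)
  expect_error(correlation_reliability(a, rep(1, 20)), "Constant input")
})
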