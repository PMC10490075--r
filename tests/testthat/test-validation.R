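test_that("method_comparison validates its inputs", {
  expect_error(method_comparison(1:3, 1:2), "equal length")
  expect_error(method_comparison(1, 1), "at least 2")
  expect_error(method_comparison(c(1, NA), c(1, 2)), "NA")
  expect_error(method_comparison(1:4, 1:4, df = 0), ">= 1")
  cmp <- method_comparison(1:5, 2:6)
  expect_equal(cmp$df, 3)     # n - 2 default
})

test_that("rmse, mae, rse reproduce hand-computed values", {
  cmp <- method_comparison(c(1, 2, 3), c(1, 2, 4))
  expect_equal(rmse(cmp), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(mae(cmp), 1 / 3, tolerance = 1e-12)
  cmp2 <- method_comparison(c(1, 2, 3, 4), c(1, 2, 3, 6), df = 2)
  expect_equal(rse(cmp2), sqrt(4 / 2), tolerance = 1e-12)
  ident <- method_comparison(c(2, 5, 9), c(2, 5, 9))
  expect_equal(c(rmse(ident), mae(ident), rse(ident)), c(0, 0, 0))
  # constant offset: rmse = mae = |c|
  off <- method_comparison(c(1, 2, 3) + 0.7, c(1, 2, 3))
  expect_equal(rmse(off), 0.7)
  expect_equal(mae(off), 0.7)
  # symmetry of mae
  expect_equal(mae(method_comparison(c(1, 2, 3), c(3, 1, 2))),
               mae(method_comparison(c(3, 1, 2), c(1, 2, 3))))
})

test_that("rmse >= mae with equality iff one residual magnitude", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    o <- rnorm(n); s <- rnorm(n)
    cmp <- method_comparison(o, s)
    expect_gte(rmse(cmp) + 1e-12, mae(cmp))
  }
  same_mag <- method_comparison(c(1, 2, 3), c(1 + 0.5, 2 - 0.5, 3 + 0.5))
  expect_equal(rmse(same_mag), mae(same_mag))
})

test_that("rse = rmse * sqrt(n / df) identity", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    df <- sample(seq_len(n - 1), 1)
    cmp <- method_comparison(rnorm(n), rnorm(n), df = df)
    expect_equal(rse(cmp), rmse(cmp) * sqrt(n / df), tolerance = 1e-12)
  }
})

test_that("metrics are translation-invariant and percent forms scale-free", {
  set.seed(53)
  o <- rnorm(10, 5); s <- rnorm(10, 5)
  c0 <- method_comparison(o, s)
  c1 <- method_comparison(o + 11.3, s + 11.3)
  expect_equal(rmse(c0), rmse(c1))
  expect_equal(mae(c0), mae(c1))
  expect_equal(rse(c0), rse(c1))
  k <- 7.7
  expect_equal(percent_metrics(method_comparison(k * o, k * s)),
               percent_metrics(c0), tolerance = 1e-12)
})

test_that("percent metrics normalise by the standard mean", {
  # rmse of 0.05 on a standard mean of 5 -> 1%
  s <- c(4, 5, 6)
  o <- s + c(0.05, -0.05, 0.05)
  pm <- percent_metrics(method_comparison(o, s))
  expect_equal(unname(pm["rmse_pct"]), 1, tolerance = 1e-12)
  expect_equal(unname(pm["mae_pct"]), 1, tolerance = 1e-12)
  ident <- method_comparison(s, s)
  expect_true(all(percent_metrics(ident) == 0))
  expect_error(percent_metrics(method_comparison(c(-1, 1), c(-1, 1))), "zero")
})

test_that("linear_fit matches closed forms and the lm() oracle", {
  s <- c(1, 2, 3, 5, 8)
  f <- linear_fit(method_comparison(s, s))
  expect_equal(unname(f), c(1, 1, 0), tolerance = 1e-12)
  f2 <- linear_fit(method_comparison(2 * s + 3, s))
  expect_equal(unname(f2), c(1, 2, 3), tolerance = 1e-12)
  set.seed(54)
  for (i in 1:10) {
    sv <- rnorm(5, 10, 3); ov <- 1.2 * sv + rnorm(5)
    f3 <- linear_fit(method_comparison(ov, sv))
    ora <- stats::lm(ov ~ sv)
    expect_equal(unname(f3["slope"]), unname(coef(ora)[2]), tolerance = 1e-9)
    expect_equal(unname(f3["intercept"]), unname(coef(ora)[1]), tolerance = 1e-9)
    expect_equal(unname(f3["r2"]), summary(ora)$r.squared, tolerance = 1e-9)
  }
  expect_error(linear_fit(method_comparison(1:4, rep(2, 4))), "degenerate")
  expect_error(linear_fit(method_comparison(1:2, 1:2)), "at least 3")
})

test_that("near-identity methods give slope ~1 and r2 > 0.95", {
  set.seed(55)
  s <- runif(100, 4, 9)
  o <- s + rnorm(100, 0, 0.05)
  f <- linear_fit(method_comparison(o, s))
  expect_gt(f["r2"], 0.95)
  expect_true(f["slope"] > 0.95 && f["slope"] < 1.05)
})

test_that("fit_bands brackets the fitted line and matches predict.lm", {
  set.seed(56)
  s <- runif(20, 0, 10); o <- 2 + 0.9 * s + rnorm(20, 0, 0.3)
  cmp <- method_comparison(o, s)
  at <- c(1, 5, 9)
  bands <- fit_bands(cmp, at = at)
  fit <- stats::lm(o ~ s)
  conf <- stats::predict(fit, data.frame(s = at), interval = "confidence")
  pred <- stats::predict(fit, data.frame(s = at), interval = "prediction")
  expect_equal(bands$fit, unname(conf[, "fit"]), tolerance = 1e-9)
  expect_equal(bands$conf_lo, unname(conf[, "lwr"]), tolerance = 1e-9)
  expect_equal(bands$conf_hi, unname(conf[, "upr"]), tolerance = 1e-9)
  expect_equal(bands$pred_lo, unname(pred[, "lwr"]), tolerance = 1e-9)
  expect_equal(bands$pred_hi, unname(pred[, "upr"]), tolerance = 1e-9)
})

test_that("compare_methods assembles the full report consistently", {
  set.seed(57)
  s <- runif(30, 4, 9); o <- s + rnorm(30, 0, 0.02)
  rep_ <- compare_methods(o, s)
  cmp <- method_comparison(o, s)
  expect_equal(rep_$rmse, rmse(cmp))
  expect_equal(rep_$rse, rse(cmp))
  expect_equal(rep_$rse, rep_$rmse * sqrt(rep_$n / rep_$df))
  expect_equal(rep_$rmse_pct, 100 * rep_$rmse / mean(s))
  expect_gte(rep_$rmse, rep_$mae)
})
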