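test_that("p0 point estimate matches the null-class formula", {
  # frozen from high-precision evaluation of -log(n_neg/n_total)/d
  expect_equal(p0_estimate(37, 100, 1e10)$point, 9.94252273e-11,
               tolerance = 1e-8)
  expect_equal(p0_estimate(50, 100, 1e8)$point, log(2) / 1e8)
  expect_equal(p0_estimate(100, 100, 1e10)$point, 0)
})

test_that("divisions per culture come from mean titer minus inoculum", {
  expect_equal(total_divisions(c(1e8, 1e8), 1e2), 99999900)
  expect_equal(total_divisions(c(9e7, 1.1e8), 1e2), 99999900)
  expect_equal(total_divisions(1e2, 1e2), 0)
  expect_error(p0_estimate(37, 100, total_divisions(1e2, 1e2)),
               "divisions")
  expect_error(total_divisions(numeric(0), 1e2), "non-empty")
  expect_error(total_divisions(c(10, 1e8), 1e2), ">=")
})

test_that("confidence intervals are Clopper-Pearson mapped through -ln/d", {
  for (x in c(10, 37, 63, 90)) {
    fit <- p0_estimate(x, 100, 1e8)
    cp <- stats::binom.test(x, 100)$conf.int  # independent CP interval
    expect_equal(fit$ci_low, -log(cp[[2]]) / 1e8, tolerance = 1e-12)
    expect_equal(fit$ci_high, -log(cp[[1]]) / 1e8, tolerance = 1e-12)
    expect_true(fit$ci_low <= fit$point && fit$point <= fit$ci_high)
  }
})

test_that("boundary well counts return bounds, never silent infinities", {
  none <- p0_estimate(0, 100, 1e8)
  expect_identical(none$point, Inf)
  expect_true(is.finite(none$ci_low) && none$ci_low > 0)
  expect_identical(none$ci_high, Inf)
  # one-sided bound: rate exceeds -ln(CP upper limit of p0)/d
  expect_equal(none$ci_low, -log(1 - 0.05^(1 / 100)) / 1e8)

  all_neg <- p0_estimate(100, 100, 1e8)
  expect_identical(all_neg$point, 0)
  expect_equal(all_neg$ci_high, -log(0.05^(1 / 100)) / 1e8)
})

test_that("estimate decreases in n_negative and scales inversely with d", {
  pts <- vapply(1:99, function(x) p0_estimate(x, 100, 1e8)$point, 0)
  expect_true(all(diff(pts) < 0))

  f1 <- p0_estimate(37, 100, 1e8)
  f2 <- p0_estimate(37, 100, 2e8)
  expect_equal(f2$point, f1$point / 2)
  expect_equal(f2$ci_low, f1$ci_low / 2)
  expect_equal(f2$ci_high, f1$ci_high / 2)
})

test_that("summed convention divides by total divisions across cultures", {
  per <- p0_estimate(37, 100, 1e8, convention = "per_culture")
  summed <- p0_estimate(37, 100, 1e8, convention = "summed")
  expect_equal(summed$point, per$point / 100)
  expect_equal(summed$ci_low, per$ci_low / 100)
})

test_that("expected estimate matches brute-force outcome enumeration", {
  # enumerate all Bernoulli outcome vectors of 5 cultures; compare the
  # probability-weighted mean estimate (finite outcomes only) with a
  # Monte Carlo mean over full simulator + estimator runs
  mu <- 2e-9; m <- 1
  d <- round(m / mu)
  q <- exp(-mu * d)  # per-culture P(negative)
  n <- 5L
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))  # 1 = negative well
  probs <- apply(grid, 1L, function(v) prod(ifelse(v == 1, q, 1 - q)))
  ests <- apply(grid, 1L, function(v) {
    k <- sum(v)
    if (k == 0) NA_real_ else -log(k / n) / d
  })
  keep <- !is.na(ests)
  expected <- sum(probs[keep] * ests[keep]) / sum(probs[keep])

  des <- design_for(mu, m, n_wells = n)
  sims <- vapply(1:4000, function(i) {
    w <- simulate_fluctuation_experiment(des, seed = i)
    k <- sum(w$outcome == "negative")
    if (k == 0) NA_real_ else p0_estimate(k, n, des$culture_model$divisions)$point
  }, 0)
  mc <- mean(sims, na.rm = TRUE)
  se <- stats::sd(sims, na.rm = TRUE) / sqrt(sum(!is.na(sims)))
  expect_lt(abs(mc - expected), 4 * se)
})

test_that("fold ratios reproduce published rate comparisons", {
  expect_equal(fold_ratio(3, 3), 1)
  expect_equal(fold_ratio(1.42e-8, 1.11e-10), 127.92793, tolerance = 1e-6)
  expect_equal(fold_ratio(1.11e-8, 2.40e-9), 4.625)
  expect_error(fold_ratio(1, 0), "> 0")
})

test_that("estimate_rate wires well tables into the estimator", {
  des <- fluctuation_design(culture_model = culture_model(1e2, 1e8, 1e-8))
  w <- simulate_fluctuation_experiment(des, seed = 3)
  fit <- estimate_rate(w, initial_cells = 1e2)
  expect_s3_class(fit, "p0_fit")
  expect_equal(fit$divisions, 1e8 - 1e2)
  expect_equal(fit$n_total, 100)
  expect_equal(fit$n_negative, sum(w$outcome == "negative", na.rm = TRUE))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_equal(glance(fit)$p0, fit$n_negative / 100)
})
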