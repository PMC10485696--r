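test_that("Cochran's Q matches the direct-summation oracle and its algebraic identity", {
  for (s in 1:8) {
    ins <- random_instruments(5 + s, seed = 400 + s)
    wr <- wald_ratio(ins)
    beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
    q_direct <- sum(wr$weight * (wr$ratio - beta)^2)
    h <- mr_heterogeneity(ins, method = "ivw")
    expect_equal(h$Q, q_direct, tolerance = 1e-10)
    # expansion identity: Q = sum(w r^2) - beta^2 sum(w)
    expect_equal(h$Q, sum(wr$weight * wr$ratio^2) - beta^2 * sum(wr$weight),
                 tolerance = 1e-8)
    expect_equal(h$df, nrow(ins) - 1L)
    expect_equal(h$pval, pchisq(h$Q, h$df, lower.tail = FALSE))
  }
})

test_that("identical ratios give Q = 0, p = 1 and undefined I2", {
  ins <- make_instruments(bx = c(0.1, 0.2, 0.5), sx = 0.01,
                          by = c(0.03, 0.06, 0.15), sy = 0.02)
  h <- mr_heterogeneity(ins)
  expect_equal(h$Q, 0)
  expect_equal(h$pval, 1)
  expect_true(is.na(h$i_squared))
})

test_that("I2 reproduces the published sensitivity table from its own Q and df", {
  expect_equal(i_squared(2.148, 6), -1.7933, tolerance = 1e-4)
  expect_equal(i_squared(2.143, 5), -1.3332, tolerance = 1e-4)
  expect_equal(abs(i_squared(2.148, 6)), 1.793, tolerance = 5e-4)
  expect_equal(abs(i_squared(2.143, 5)), 1.333, tolerance = 5e-4)
  expect_true(all(i_squared(c(0.5, 3, 100), 2) <= 1))
})

test_that("packaged set: IVW Q from recomputation is ~5.65, not the published 2.148", {
  ins <- fixture_instruments()
  h <- mr_heterogeneity(ins, method = "ivw")
  expect_equal(h$Q, 5.65, tolerance = 0.01)
  expect_equal(h$df, 6L)
  expect_gt(abs(h$Q - 2.148), 3) # the published Q is not recoverable
  he <- mr_heterogeneity(ins, method = "egger")
  expect_equal(he$df, 5L)
  # Egger Q is the weighted RSS: phi^2 * (L - 2)
  e <- mr_egger(ins)
  expect_equal(he$Q, e$phi^2 * 5, tolerance = 1e-10)
})

test_that("Egger intercept test: exact fit, recovery, and calibration", {
  bx <- seq(0.05, 0.2, length.out = 5)
  ins <- make_instruments(bx = bx, sx = 0.01, by = 0.02 + 0.3 * bx,
                          sy = 0.015)
  t1 <- egger_intercept_test(ins)
  expect_equal(t1$intercept, 0.02, tolerance = 1e-10)

  # directional pleiotropy 0.01 on every instrument, InSIDE holding:
  # the mean intercept over replicates recovers the pleiotropy mean
  reps <- 200
  icpt <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    ins_r <- simulate_instruments(n_snps = 30, true_beta = 0.2,
                                  pleiotropy_mean = 0.01,
                                  pleiotropy_sd = 0.002,
                                  invalid_fraction = 1, seed = 500 + r)
    t_r <- egger_intercept_test(ins_r)
    icpt[r] <- t_r$intercept
    se[r] <- t_r$se
  }
  mc_se <- sd(icpt) / sqrt(reps)
  expect_lt(abs(mean(icpt) - 0.01), 3 * mc_se)
  expect_lt(abs(mean(icpt) - 0.01), 1.96 * mean(se)) # inside a typical CI

  # balanced pleiotropy: intercept rejection near the nominal 5%
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    ins_r <- simulate_instruments(n_snps = 30, true_beta = 0.2,
                                  pleiotropy_mean = 0,
                                  pleiotropy_sd = 0.005,
                                  invalid_fraction = 1, seed = 900 + r)
    rej[r] <- egger_intercept_test(ins_r)$pval < 0.05
  }
  expect_lt(mean(rej), 0.12) # 200-rep binomial bound around 0.05
})

test_that("leave-one-out produces L + 1 IVW rows in input order", {
  ins <- fixture_instruments()
  loo <- mr_leave_one_out(ins)
  expect_equal(nrow(loo), 8L)
  expect_equal(loo$variant_id, c(ins$variant_id, "All"))
  expect_equal(loo$beta[8], mr_ivw(ins)$beta)
  # no single variant drives the effect: every LOO estimate stays negative
  expect_true(all(loo$beta < 0))
  # each row equals IVW on the reduced set
  drop3 <- ins[-3, , drop = FALSE]
  class(drop3) <- c("mr_instruments", "data.frame")
  expect_equal(loo$beta[3], mr_ivw(drop3)$beta)
})

test_that("leave-one-out degenerates correctly for identical instruments", {
  ins <- make_instruments(bx = c(0.1, 0.1, 0.1), sx = 0.01,
                          by = c(0.05, 0.05, 0.05), sy = 0.02)
  loo <- mr_leave_one_out(ins)
  expect_true(all(abs(loo$beta - 0.5) < 1e-12))
})

test_that("dropping an outlier moves the estimate toward the consensus ratio", {
  ins <- make_instruments(bx = c(0.1, 0.1, 0.1), sx = 0.01,
                          by = c(0.05, 0.05, 0.30), sy = 0.02)
  loo <- mr_leave_one_out(ins)
  full <- loo$beta[4]
  without_outlier <- loo$beta[3]
  expect_lt(abs(without_outlier - 0.5), abs(full - 0.5))
  expect_equal(without_outlier, 0.5)
})

test_that("diagnostic tables carry every plotted number", {
  ins <- fixture_instruments()
  fit <- mr_fit(ins, n_boot = 50)
  d <- mr_diagnostics(ins, fit)
  expect_equal(sum(d$forest$kind == "snp"), 7L)
  expect_equal(sum(d$forest$kind == "combined"), 3L)
  expect_equal(nrow(d$scatter), 7L)
  expect_equal(nrow(d$lines), 3L)
  # the Egger line keeps its intercept; the others pass through the origin
  expect_equal(d$lines$intercept[d$lines$method == "Egger"],
               fit$pleiotropy$intercept)
  expect_equal(d$lines$intercept[d$lines$method != "Egger"], c(0, 0))
  expect_equal(d$funnel$precision, 1 / wald_ratio(ins)$se_first_order)

  # single instrument, single fit
  one <- make_instruments(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.02)
  d1 <- mr_diagnostics(one, mr_ivw(one))
  expect_equal(nrow(d1$funnel), 1L)

  # symmetric construction: funnel points balance around the IVW line
  bx <- rep(0.1, 10)
  dev <- c(-5:-1, 1:5) * 0.001
  sym <- make_instruments(bx = bx, sx = 0.01, by = 0.02 + dev, sy = 0.02)
  ds <- mr_diagnostics(sym, mr_ivw(sym))
  ivw_line <- ds$lines$slope[1]
  signs <- sign(ds$funnel$ratio - ivw_line)
  expect_lte(abs(sum(signs > 0) - sum(signs < 0)), 1)
})

test_that("plot functions render the diagnostic tables without error", {
  ins <- fixture_instruments()
  fit <- mr_fit(ins, n_boot = 20)
  d <- mr_diagnostics(ins, fit)
  path <- tempfile(fileext = ".png")
  png(path)
  expect_no_error({
    mr_plot_forest(d)
    mr_plot_scatter(d)
    mr_plot_funnel(d)
    mr_plot_loo(mr_leave_one_out(ins))
    plot(fit, which = "scatter")
  })
  dev.off()
  expect_true(file.size(path) > 0)
})
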