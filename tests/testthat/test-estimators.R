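test_that("Wald ratios reproduce direct division of the packaged values", {
  ins <- fixture_instruments()
  wr <- wald_ratio(ins)
  r1 <- wr[wr$variant_id == "rs10455872", ]
  expect_equal(r1$ratio, -0.00682856 / 0.0133593, tolerance = 1e-10)
  expect_equal(r1$ratio, -0.51114, tolerance = 1e-4)
  expect_equal(r1$weight, (0.0133593 / 0.00376191)^2, tolerance = 1e-10)
  expect_equal(r1$weight, 12.611, tolerance = 1e-4)
  expect_equal(wr$weight * wr$se_first_order^2, rep(1, 7))
})

test_that("Wald ratio handles zero numerator, rejects zero denominator, and is sign-symmetric", {
  ins <- make_instruments(bx = c(0.1, 0.2), sx = 0.01,
                          by = c(0, 0.05), sy = 0.02)
  wr <- wald_ratio(ins)
  expect_equal(wr$ratio[1], 0)
  expect_true(all(wr$se_first_order > 0))
  flipped <- make_instruments(bx = c(-0.1, -0.2), sx = 0.01,
                              by = c(0, -0.05), sy = 0.02)
  expect_equal(wald_ratio(flipped)$ratio, wr$ratio)
  expect_equal(wald_ratio(flipped)$weight, wr$weight)
  bad <- make_instruments(bx = c(0, 0.1), sx = 0.01, by = 0.1, sy = 0.02)
  expect_error(wald_ratio(bad), "zero")
  # second-order SE is never smaller than first-order
  wr2 <- wald_ratio(ins, se_order = "second")
  expect_true(all(wr2$se >= wr$se_first_order))
})

test_that("IVW equals the hand-computed closed form on simple cases", {
  # ratios 1 and 3 with equal weights: bx = 1, sy = 1 gives weight 1
  ins <- make_instruments(bx = c(1, 1), sx = 0.1, by = c(1, 3), sy = 1)
  e <- mr_ivw(ins, variance_model = "fixed")
  expect_equal(e$beta, 2)
  expect_equal(e$se, 1 / sqrt(2))
  expect_equal(e$df, 1L)
  # identical ratios: zero dispersion
  ins2 <- make_instruments(bx = c(0.1, 0.2, 0.4), sx = 0.01,
                           by = c(0.05, 0.10, 0.20), sy = 0.02)
  e2 <- mr_ivw(ins2)
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$phi, 0)
})

test_that("IVW equals the zero-intercept WLS oracle over random instances", {
  for (L in c(2, 3, 5, 8, 13, 20)) {
    ins <- random_instruments(L, seed = 100 + L)
    e <- mr_ivw(ins, variance_model = "fixed")
    o <- oracle_wls_through_origin(ins$beta_exposure, ins$beta_outcome,
                                   1 / ins$se_outcome^2)
    expect_equal(e$beta, o$beta, tolerance = 1e-12)
    expect_equal(e$se, o$se, tolerance = 1e-12)
  }
})

test_that("IVW variance models relate by the dispersion factor and respect the floor", {
  ins <- fixture_instruments()
  fx <- mr_ivw(ins, variance_model = "fixed")
  re <- mr_ivw(ins)
  expect_equal(re$beta, fx$beta)
  expect_equal(re$se, fx$se * re$phi)
  expect_lt(re$phi, 1) # this set is underdispersed
  floored <- mr_ivw(ins, allow_underdispersion = FALSE)
  expect_equal(floored$se, fx$se)
})

test_that("a single instrument degenerates to its Wald ratio", {
  ins <- make_instruments(bx = 0.1, sx = 0.01, by = 0.05, sy = 0.02)
  e <- mr_ivw(ins)
  expect_equal(e$method, "WaldRatio")
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
})

test_that("Egger recovers exact linear data and matches the WLS oracle", {
  bx <- c(0.05, 0.10, 0.15, 0.20)
  alpha <- 0.01; slope <- 0.4
  ins <- make_instruments(bx = bx, sx = 0.01, by = alpha + slope * bx,
                          sy = 0.02)
  e <- mr_egger(ins)
  expect_equal(e$intercept, alpha, tolerance = 1e-10)
  expect_equal(e$beta, slope, tolerance = 1e-10)
  expect_equal(e$phi, 0, tolerance = 1e-7)
  # no-pleiotropy limit
  ins0 <- make_instruments(bx = bx, sx = 0.01, by = slope * bx, sy = 0.02)
  expect_equal(mr_egger(ins0)$intercept, 0, tolerance = 1e-12)
  # noisy case against the independent normal-equations oracle
  ins2 <- random_instruments(9, seed = 42)
  s <- ifelse(ins2$beta_exposure < 0, -1, 1)
  o <- oracle_wls_intercept(ins2$beta_exposure * s, ins2$beta_outcome * s,
                            1 / ins2$se_outcome^2)
  e2 <- mr_egger(ins2)
  expect_equal(e2$beta, o$slope, tolerance = 1e-10)
  expect_equal(e2$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(e2$se, o$se_slope, tolerance = 1e-10)
  expect_equal(e2$intercept_se, o$se_intercept, tolerance = 1e-10)
})

test_that("Egger guards its preconditions", {
  expect_error(mr_egger(make_instruments(bx = c(1, 2), sx = 0.1,
                                         by = c(1, 2), sy = 0.1)),
               "at least 3")
  const <- make_instruments(bx = c(0.1, 0.1, 0.1), sx = 0.01,
                            by = c(0.1, 0.2, 0.3), sy = 0.1)
  expect_error(mr_egger(const), "unidentifiable")
})

test_that("Egger canonicalization makes the fit invariant to input orientation", {
  ins <- random_instruments(8, seed = 7)
  flip <- ins
  flip$beta_exposure[1:4] <- -flip$beta_exposure[1:4]
  flip$beta_outcome[1:4] <- -flip$beta_outcome[1:4]
  flip <- as_mr_instruments(as.data.frame(flip))
  a <- mr_egger(ins)
  b <- mr_egger(flip)
  expect_equal(a$beta, b$beta)
  expect_equal(a$intercept, b$intercept)
  expect_equal(a$se, b$se)
})

test_that("weighted median interpolation matches hand-derived and enumerated values", {
  # symmetric equal-weight case
  ins <- make_instruments(bx = c(1, 1, 1), sx = 0.1, by = c(1, 2, 3), sy = 1)
  expect_equal(mr_weighted_median(ins, n_boot = 10, seed = 1)$beta, 2)
  # two equal weights: p = (0.25, 0.75), interpolation gives the midpoint
  expect_equal(mrkit:::.weighted_median(c(1, 3), c(2, 2)), 2)
  expect_equal(mrkit:::.weighted_median(c(-1, 4), c(5, 5)), 1.5)
  # random cases against the enumeration oracle
  for (s in 1:5) {
    set.seed(s)
    r <- rnorm(7); w <- runif(7, 0.5, 2)
    expect_equal(mrkit:::.weighted_median(r, w), oracle_weighted_median(r, w))
  }
})

test_that("weighted median brackets the ratios and reduces to the unweighted median", {
  for (s in 1:10) {
    ins <- random_instruments(6, seed = 200 + s)
    wr <- wald_ratio(ins)
    est <- mrkit:::.weighted_median(wr$ratio, wr$weight)
    expect_gte(est, min(wr$ratio))
    expect_lte(est, max(wr$ratio))
    # equal weights: interpolated unweighted median
    expect_equal(mrkit:::.weighted_median(wr$ratio, rep(1, 6)),
                 oracle_weighted_median(wr$ratio, rep(1, 6)))
  }
})

test_that("bootstrap SE is reproducible under a fixed seed and varies across seeds", {
  ins <- fixture_instruments()
  a <- mr_weighted_median(ins, n_boot = 200, seed = 11)
  b <- mr_weighted_median(ins, n_boot = 200, seed = 11)
  c <- mr_weighted_median(ins, n_boot = 200, seed = 12)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_equal(a$beta, c$beta) # the point estimate never depends on the seed
})

test_that("or_ci reproduces published exp-scale conversions and the null", {
  v <- or_ci(-0.3742, 0.3809, 1.96)
  expect_equal(unname(round(v, 4)), c(0.6878, 0.3260, 1.4512))
  v2 <- or_ci(-0.4155, 0.1655, 1.96)
  expect_equal(unname(round(v2[c("or_point", "ci_lower")], 4)),
               c(0.6600, 0.4772))
  expect_equal(unname(or_ci(0, 0.5)["or_point"]), 1)
  expect_error(or_ci(0.1, 0), "positive")
})

test_that("all estimators are scale-equivariant in the outcome", {
  ins <- random_instruments(9, seed = 31)
  c_scale <- 3.7
  scaled <- ins
  scaled$beta_outcome <- scaled$beta_outcome * c_scale
  scaled$se_outcome <- scaled$se_outcome * c_scale
  scaled <- as_mr_instruments(as.data.frame(scaled))
  for (f in list(function(x) mr_ivw(x),
                 function(x) mr_egger(x),
                 function(x) mr_weighted_median(x, n_boot = 100, seed = 5))) {
    a <- f(ins); b <- f(scaled)
    expect_equal(b$beta, c_scale * a$beta, tolerance = 1e-8)
    expect_equal(b$se, c_scale * a$se, tolerance = 1e-8)
    expect_equal(b$or_point, exp(c_scale * a$beta), tolerance = 1e-8)
  }
})

test_that("IVW and weighted median are invariant to per-variant sign flips", {
  ins <- random_instruments(8, seed = 77)
  flip <- ins
  idx <- c(2, 5, 7)
  flip$beta_exposure[idx] <- -flip$beta_exposure[idx]
  flip$beta_outcome[idx] <- -flip$beta_outcome[idx]
  flip <- as_mr_instruments(as.data.frame(flip))
  expect_equal(mr_ivw(flip)$beta, mr_ivw(ins)$beta)
  expect_equal(mr_weighted_median(flip, n_boot = 1, seed = 1)$beta,
               mr_weighted_median(ins, n_boot = 1, seed = 1)$beta)
})

test_that("Egger with its intercept constrained to zero reproduces IVW", {
  # constraining the Egger regression through the origin is exactly the
  # IVW estimator; check against an explicit zero-intercept weighted lm
  for (s in 1:5) {
    ins <- random_instruments(10, seed = 300 + s)
    fit0 <- lm(beta_outcome ~ 0 + beta_exposure, data = ins,
               weights = 1 / ins$se_outcome^2)
    expect_equal(mr_ivw(ins, variance_model = "fixed")$beta,
                 unname(coef(fit0)), tolerance = 1e-12)
  }
})

test_that("mr_fit aggregates methods with working S3 methods", {
  ins <- fixture_instruments()
  fit <- mr_fit(ins, n_boot = 100)
  expect_s3_class(fit, "mr_fit")
  tab <- mr_estimates_table(fit)
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$method, c("IVW", "Egger", "WeightedMedian"))
  expect_true(all(tab$n_snps == 7L))
  expect_equal(unname(coef(fit)["IVW"]), fit$estimates$ivw$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_output(print(summary(fit)), "WeightedMedian")
  # Q is the squared norm of the IVW residual vector
  expect_equal(sum(residuals(fit)^2), fit$estimates$ivw$Q)
})
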