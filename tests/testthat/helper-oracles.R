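# Independent oracles, deliberately written from first principles so they
# share no code with the package implementation.

# zero-intercept weighted least squares of y on x, weights w, via the
# normal equation: beta = sum(w x y) / sum(w x^2); SE from (X'WX)^-1.
oracle_wls_through_origin <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  list(beta = beta, se = sqrt(1 / sum(w * x^2)))
}

# weighted least squares with intercept via explicit 2x2 normal equations
oracle_wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  coef <- solve(A, b)
  res <- y - X %*% coef
  s2 <- sum(w * res^2) / (length(y) - 2)
  V <- solve(A)
  list(intercept = coef[1], slope = coef[2],
       se_intercept = sqrt(s2 * V[1, 1]), se_slope = sqrt(s2 * V[2, 2]),
       rss_w = sum(w * res^2))
}

# interpolated weighted median by explicit enumeration of the cumulative
# weight grid
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  k <- max(which(p <= 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

# instruments straight from Table-like fields, bypassing harmonize()
make_instruments <- function(bx, sx, by, sy,
                             ids = sprintf("rs%03d", seq_along(bx))) {
  as_mr_instruments(data.frame(
    variant_id = ids, beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy, stringsAsFactors = FALSE))
}

# random instrument set for property-style tests
random_instruments <- function(L, seed) {
  set.seed(seed)
  make_instruments(
    bx = rnorm(L, 0.01, 0.004),
    sx = runif(L, 5e-4, 2e-3),
    by = rnorm(L, -0.003, 0.003),
    sy = runif(L, 1e-3, 8e-3))
}

# the packaged seven-variant example, loaded once per test file
fixture_instruments <- function() aspirin_hayfever()

# write a minimal sumstats TSV; cols as named list of vectors
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
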