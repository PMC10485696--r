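#' Per-variant Wald ratio estimates
#'
#' For each instrument the causal effect is estimated by the Wald ratio
#' `beta_outcome / beta_exposure`. The default standard error is the
#' first-order delta-method approximation `se_outcome / |beta_exposure|`,
#' giving the inverse-variance weight `(beta_exposure / se_outcome)^2`;
#' an optional second-order SE additionally propagates the exposure
#' uncertainty.
#'
#' @param instruments An `mr_instruments` data frame.
#' @param se_order `"first"` (default) or `"second"` order delta-method SE.
#'   Weights always use the first-order SE, which is what the downstream
#'   estimators combine.
#' @return Data frame with `variant_id`, `ratio`, `se` (per `se_order`),
#'   `se_first_order`, and `weight = 1/se_first_order^2`.
#' @export
#' @examples
#' wald_ratio(aspirin_hayfever())
wald_ratio <- function(instruments, se_order = c("first", "second")) {
  stopifnot(inherits(instruments, "mr_instruments"))
  se_order <- match.arg(se_order)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  if (any(bx == 0)) {
    stop("Wald ratio undefined: beta_exposure is zero for ",
         paste(instruments$variant_id[bx == 0], collapse = ", "),
         call. = FALSE)
  }
  se1 <- sy / abs(bx)
  se <- if (se_order == "second") sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4) else se1
  data.frame(
    variant_id = instruments$variant_id,
    ratio = by / bx,
    se = se,
    se_first_order = se1,
    weight = (bx / sy)^2,
    stringsAsFactors = FALSE
  )
}

.mr_estimate <- function(method, beta, se, pval, n_snps, df,
                         ci_z = stats::qnorm(0.975), extra = list()) {
  est <- c(list(method = method, beta = beta, se = se, pval = pval,
                n_snps = n_snps, df = df,
                or_point = exp(beta),
                ci_lower = exp(beta - ci_z * se),
                ci_upper = exp(beta + ci_z * se),
                ci_z = ci_z),
           extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(x$method, " estimate (", x$n_snps, " SNPs)\n", sep = "")
  cat("  beta = ", format(x$beta, digits = digits),
      "  SE = ", format(x$se, digits = digits),
      "  p = ", format(x$pval, digits = digits), "\n", sep = "")
  cat("  OR = ", format(x$or_point, digits = digits),
      " (", format(x$ci_lower, digits = digits), "-",
      format(x$ci_upper, digits = digits), ")\n", sep = "")
  if (!is.null(x$intercept)) {
    cat("  intercept = ", format(x$intercept, digits = digits),
        "  SE = ", format(x$intercept_se, digits = digits),
        "  p = ", format(x$intercept_pval, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' Combines the per-variant Wald ratios in a fixed-effect or multiplicative
#' random-effects meta-analysis: `beta = sum(w_j r_j) / sum(w_j)` with
#' first-order inverse-variance weights, equivalent to the zero-intercept
#' weighted regression of outcome on exposure effects with weights
#' `1/se_outcome^2`. The fixed-model SE is `1/sqrt(sum(w_j))`; the
#' multiplicative model inflates it by `phi = sqrt(Q/(L-1))`, floored at 1
#' unless `allow_underdispersion`.
#'
#' @param instruments An `mr_instruments` data frame with at least 2 rows
#'   (a single instrument degenerates to its Wald ratio).
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param allow_underdispersion Permit `phi < 1`? Default `TRUE`.
#' @param ci_z Normal quantile for the OR confidence bounds.
#' @return An `mr_estimate`: `beta`, `se`, two-sided normal `pval`,
#'   `n_snps`, `df = L-1`, OR and CI fields, and `phi`.
#' @export
#' @examples
#' mr_ivw(aspirin_hayfever())
mr_ivw <- function(instruments,
                   variance_model = c("multiplicative_random", "fixed"),
                   allow_underdispersion = TRUE,
                   ci_z = stats::qnorm(0.975)) {
  stopifnot(inherits(instruments, "mr_instruments"))
  variance_model <- match.arg(variance_model)
  L <- nrow(instruments)
  if (L < 1L) stop("IVW requires at least one instrument", call. = FALSE)
  wr <- wald_ratio(instruments)
  if (L == 1L) {
    return(.mr_estimate("WaldRatio", wr$ratio, wr$se_first_order,
                        2 * stats::pnorm(-abs(wr$ratio / wr$se_first_order)),
                        1L, 0L, ci_z,
                        extra = list(variance_model = "fixed", phi = 1)))
  }
  sw <- sum(wr$weight)
  beta <- sum(wr$weight * wr$ratio) / sw
  se_fixed <- 1 / sqrt(sw)
  q <- sum(wr$weight * (wr$ratio - beta)^2)
  phi <- sqrt(q / (L - 1))
  if (!allow_underdispersion) phi <- max(phi, 1)
  se <- if (variance_model == "fixed") se_fixed else se_fixed * phi
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("IVW", beta, se, pval, L, L - 1L, ci_z,
               extra = list(variance_model = variance_model, phi = phi,
                            Q = q,
                            allow_underdispersion = allow_underdispersion))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_outcome^2`. The slope estimates
#' the causal effect; the intercept estimates the average horizontal
#' pleiotropic effect and is consistent for it under the InSIDE assumption
#' even when every instrument is pleiotropic. Because the slope is not
#' invariant to per-variant sign conventions, instruments are first oriented
#' so every exposure effect is non-negative (default, per the estimator's
#' definition).
#'
#' @param instruments An `mr_instruments` data frame with at least 3 rows.
#' @param orient_exposure_positive Flip each `(beta_exposure, beta_outcome)`
#'   pair so `beta_exposure >= 0` before fitting? Default `TRUE`.
#' @param se_model `"t"` (default; p-values from Student t with `L-2` df) or
#'   `"normal"`.
#' @param allow_underdispersion Permit the residual scale
#'   `phi = sqrt(RSS_w/(L-2))` to fall below 1? Default `TRUE`.
#' @param ci_z Normal quantile for the OR confidence bounds.
#' @return An `mr_estimate` with slope fields plus `intercept`,
#'   `intercept_se`, `intercept_pval`, and `phi`; `df = L-2`.
#' @export
#' @examples
#' mr_egger(aspirin_hayfever())
mr_egger <- function(instruments,
                     orient_exposure_positive = TRUE,
                     se_model = c("t", "normal"),
                     allow_underdispersion = TRUE,
                     ci_z = stats::qnorm(0.975)) {
  stopifnot(inherits(instruments, "mr_instruments"))
  se_model <- match.arg(se_model)
  L <- nrow(instruments)
  if (L < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  if (orient_exposure_positive) {
    s <- ifelse(bx < 0, -1, 1)
    bx <- bx * s
    by <- by * s
  }
  if (stats::var(bx) == 0) {
    stop("zero variance in exposure effects: Egger slope unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  cs <- summary(fit)$coefficients
  phi <- summary(fit)$sigma          # sqrt(weighted RSS / (L - 2))
  # lm SEs already include phi; apply the floor by rescaling if disallowed
  infl <- if (allow_underdispersion || phi >= 1) 1 else 1 / phi
  slope <- cs["bx", "Estimate"]
  slope_se <- cs["bx", "Std. Error"] * infl
  icpt <- cs["(Intercept)", "Estimate"]
  icpt_se <- cs["(Intercept)", "Std. Error"] * infl
  pfun <- if (se_model == "t") {
    function(z) 2 * stats::pt(-abs(z), df = L - 2)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  .mr_estimate("Egger", slope, slope_se, pfun(slope / slope_se),
               L, L - 2L, ci_z,
               extra = list(
                 intercept = icpt, intercept_se = icpt_se,
                 intercept_pval = pfun(icpt / icpt_se),
                 phi = phi, se_model = se_model,
                 orient_exposure_positive = orient_exposure_positive,
                 allow_underdispersion = allow_underdispersion))
}

#' Weighted median of Wald ratios
#'
#' Computes the interpolated weighted median of the per-variant Wald
#' ratios: ratios are sorted ascending, standardized cumulative weights
#' `p_j = (S_j - w_j/2) / S_L` are formed from the running weight sums, and
#' the estimate linearly interpolates the ordered ratios at `p = 0.5`. The
#' estimator is consistent when valid instruments carry at least 50% of the
#' weight. The SE is the standard deviation of the estimate over `n_boot`
#' parametric-bootstrap replicates, each redrawing every exposure and
#' outcome effect from normal distributions centred at the observed values
#' with their reported SEs.
#'
#' @param instruments An `mr_instruments` data frame with at least 3 rows.
#' @param n_boot Number of bootstrap replicates for the SE; default 1000.
#' @param seed Integer seed for the bootstrap; default 20230825.
#' @param ci_z Normal quantile for the OR confidence bounds.
#' @return An `mr_estimate` with two-sided normal `pval` and `df = L-1`.
#' @export
#' @examples
#' mr_weighted_median(aspirin_hayfever(), n_boot = 200)
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 20230825,
                               ci_z = stats::qnorm(0.975)) {
  stopifnot(inherits(instruments, "mr_instruments"))
  L <- nrow(instruments)
  if (L < 3L) stop("weighted median requires at least 3 instruments",
                   call. = FALSE)
  stopifnot(n_boot >= 1)
  est <- .weighted_median(instruments$beta_outcome / instruments$beta_exposure,
                          (instruments$beta_exposure / instruments$se_outcome)^2)
  boots <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(L, instruments$beta_exposure, instruments$se_exposure)
    by <- stats::rnorm(L, instruments$beta_outcome, instruments$se_outcome)
    boots[b] <- .weighted_median(by / bx, (bx / instruments$se_outcome)^2)
  }
  se <- stats::sd(boots)
  .mr_estimate("WeightedMedian", est, se, 2 * stats::pnorm(-abs(est / se)),
               L, L - 1L, ci_z,
               extra = list(n_boot = n_boot, seed = seed))
}

# interpolated weighted median: the core order statistic
.weighted_median <- function(ratios, weights) {
  if (sum(weights) <= 0) stop("total weight must be positive", call. = FALSE)
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o]
  s <- cumsum(w)
  p <- (s - w / 2) / s[length(s)]
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Odds ratio and confidence bounds from a log-scale estimate
#'
#' @param beta Log-scale effect estimate.
#' @param se Standard error, positive.
#' @param level_z Normal quantile; default `qnorm(0.975)`. Published tables
#'   commonly round-trip with 1.96.
#' @return Named vector `or_point`, `ci_lower`, `ci_upper` =
#'   `exp(beta)`, `exp(beta - z*se)`, `exp(beta + z*se)`.
#' @export
#' @examples
#' or_ci(-0.3742, 0.3809, 1.96)
or_ci <- function(beta, se, level_z = stats::qnorm(0.975)) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  c(or_point = exp(beta),
    ci_lower = exp(beta - level_z * se),
    ci_upper = exp(beta + level_z * se))
}
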