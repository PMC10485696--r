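#' Cochran's Q heterogeneity statistics
#'
#' Quantifies heterogeneity among the per-variant causal estimates. For the
#' IVW model, `Q = sum(w_j (ratio_j - beta_IVW)^2)` with first-order
#' inverse-variance weights and `df = L - 1`; for MR-Egger, Q is the
#' weighted residual sum of squares of the intercept regression with
#' `df = L - 2` (slope and intercept both estimated). `I2 = (Q - df)/Q` is
#' stored signed — it is negative whenever `Q < df` — and is undefined when
#' `Q = 0`; the p-value is the upper chi-square tail of Q at `df`.
#'
#' @param instruments An `mr_instruments` data frame.
#' @param method `"ivw"` (default) or `"egger"`.
#' @param display_magnitude Report `|I2|` instead of the signed value?
#'   Default `FALSE`; some published tables display the magnitude.
#' @return An object of class `mr_heterogeneity`: list with `method`, `Q`,
#'   `df`, `i_squared`, `pval`.
#' @export
#' @examples
#' mr_heterogeneity(aspirin_hayfever())
mr_heterogeneity <- function(instruments, method = c("ivw", "egger"),
                             display_magnitude = FALSE) {
  instruments <- as_mr_instruments(instruments)
  method <- match.arg(method)
  L <- nrow(instruments)
  if (method == "ivw") {
    if (L < 2L) stop("IVW heterogeneity requires df >= 1 (L >= 2)",
                     call. = FALSE)
    wr <- wald_ratio(instruments)
    beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
    q <- sum(wr$weight * (wr$ratio - beta)^2)
    df <- L - 1L
  } else {
    if (L < 3L) stop("Egger heterogeneity requires df >= 1 (L >= 3)",
                     call. = FALSE)
    e <- mr_egger(instruments)
    bx <- instruments$beta_exposure
    by <- instruments$beta_outcome
    s <- ifelse(bx < 0, -1, 1)
    resid <- by * s - (e$intercept + e$beta * bx * s)
    q <- sum(resid^2 / instruments$se_outcome^2)
    df <- L - 2L
  }
  i2 <- i_squared(q, df)
  if (display_magnitude) i2 <- abs(i2)
  structure(list(method = toupper(method), Q = q, df = df,
                 i_squared = i2,
                 pval = if (q == 0) 1 else
                   stats::pchisq(q, df, lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' I-squared from Q and its degrees of freedom
#'
#' `I2 = (Q - df)/Q`, the fraction of variation attributable to
#' heterogeneity beyond chance. Returned signed (negative when `Q < df`,
#' bounded above by 1) and `NA` when `Q = 0`.
#'
#' @param Q Cochran's Q statistic, non-negative.
#' @param df Degrees of freedom, a positive integer.
#' @return Numeric; `NA` when `Q = 0`.
#' @export
#' @examples
#' i_squared(2.148, 6) # -1.7933: less spread than chance expects
i_squared <- function(Q, df) {
  stopifnot(all(Q >= 0), all(df >= 1))
  ifelse(Q == 0, NA_real_, (Q - df) / Q)
}

#' @export
print.mr_heterogeneity <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %s on %d df, p = %s\n", x$method,
              format(x$Q, digits = digits), x$df,
              format(x$pval, digits = digits)))
  cat("  I2 =", format(x$i_squared, digits = digits), "\n")
  invisible(x)
}

#' Egger-intercept test for directional pleiotropy
#'
#' Reports the MR-Egger regression intercept, its SE and its two-sided
#' p-value (Student t with `L - 2` df). The intercept estimates the average
#' horizontal pleiotropic effect across instruments; an intercept p-value
#' at or above 0.05 is conventionally read as no evidence of directional
#' pleiotropy.
#'
#' @param instruments An `mr_instruments` data frame with at least 3 rows.
#' @param ... Passed to [mr_egger()].
#' @return List with `intercept`, `se`, `pval`, and `evidence` (a short
#'   verdict string).
#' @export
#' @examples
#' egger_intercept_test(aspirin_hayfever())
egger_intercept_test <- function(instruments, ...) {
  e <- mr_egger(as_mr_instruments(instruments), ...)
  list(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval,
       evidence = if (e$intercept_pval >= 0.05)
         "no evidence of directional pleiotropy"
       else "evidence of directional pleiotropy")
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn, to
#' show whether any single variant drives the pooled effect. The final row
#' (`variant_id = "All"`) is the all-instrument estimate.
#'
#' @param instruments An `mr_instruments` data frame with at least 3 rows
#'   (each reduced set must still permit IVW).
#' @param ci_z Normal quantile for the confidence bounds.
#' @param ... Passed to [mr_ivw()].
#' @return Data frame of class `mr_loo` with `L + 1` rows: `variant_id`
#'   (input order, then `"All"`), `beta`, `se`, `ci_lower`, `ci_upper`
#'   (log scale).
#' @export
#' @examples
#' mr_leave_one_out(aspirin_hayfever())
mr_leave_one_out <- function(instruments, ci_z = stats::qnorm(0.975), ...) {
  instruments <- as_mr_instruments(instruments)
  L <- nrow(instruments)
  if (L < 3L) stop("leave-one-out requires at least 3 instruments",
                   call. = FALSE)
  one <- function(idx, label) {
    sub <- instruments[idx, , drop = FALSE]
    class(sub) <- c("mr_instruments", "data.frame")
    e <- mr_ivw(sub, ci_z = ci_z, ...)
    data.frame(variant_id = label, beta = e$beta, se = e$se,
               ci_lower = e$beta - ci_z * e$se,
               ci_upper = e$beta + ci_z * e$se,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(L), function(j)
    one(setdiff(seq_len(L), j), instruments$variant_id[j]))
  rows[[L + 1L]] <- one(seq_len(L), "All")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Plot-ready diagnostic tables
#'
#' Builds the numeric tables behind the standard MR diagnostic figures so
#' that every plotted number is testable: a forest table (per-variant Wald
#' ratio with CI plus one combined row per fitted method), a scatter table
#' (exposure vs outcome effects with per-axis CIs) with one regression line
#' per method, and a funnel table (per-variant ratio vs precision
#' `1/se_first_order`) with one vertical line per method.
#'
#' @param instruments An `mr_instruments` data frame.
#' @param fits A list of `mr_estimate` objects (e.g. `mr_fit(...)$estimates`),
#'   or an `mr_fit` object.
#' @param ci_z Normal quantile for the confidence bounds.
#' @return List of class `mr_diagnostics` with data frames `forest`,
#'   `scatter`, `lines`, `funnel`.
#' @export
#' @examples
#' fit <- mr_fit(aspirin_hayfever(), n_boot = 50)
#' names(mr_diagnostics(fit$instruments, fit))
mr_diagnostics <- function(instruments, fits, ci_z = stats::qnorm(0.975)) {
  instruments <- as_mr_instruments(instruments)
  if (inherits(fits, "mr_fit")) fits <- fits$estimates
  if (inherits(fits, "mr_estimate")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  wr <- wald_ratio(instruments)

  forest_snp <- data.frame(
    label = wr$variant_id, kind = "snp",
    beta = wr$ratio,
    ci_lower = wr$ratio - ci_z * wr$se_first_order,
    ci_upper = wr$ratio + ci_z * wr$se_first_order,
    stringsAsFactors = FALSE)
  forest_fit <- do.call(rbind, lapply(fits, function(e) data.frame(
    label = e$method, kind = "combined",
    beta = e$beta,
    ci_lower = e$beta - ci_z * e$se,
    ci_upper = e$beta + ci_z * e$se,
    stringsAsFactors = FALSE)))
  forest <- rbind(forest_snp, forest_fit)
  rownames(forest) <- NULL

  scatter <- data.frame(
    variant_id = instruments$variant_id,
    beta_exposure = instruments$beta_exposure,
    se_exposure = instruments$se_exposure,
    beta_outcome = instruments$beta_outcome,
    se_outcome = instruments$se_outcome,
    x_lower = instruments$beta_exposure - ci_z * instruments$se_exposure,
    x_upper = instruments$beta_exposure + ci_z * instruments$se_exposure,
    y_lower = instruments$beta_outcome - ci_z * instruments$se_outcome,
    y_upper = instruments$beta_outcome + ci_z * instruments$se_outcome,
    stringsAsFactors = FALSE)

  lines <- do.call(rbind, lapply(fits, function(e) data.frame(
    method = e$method, slope = e$beta,
    intercept = if (is.null(e$intercept)) 0 else e$intercept,
    stringsAsFactors = FALSE)))
  rownames(lines) <- NULL

  funnel <- data.frame(
    variant_id = wr$variant_id,
    ratio = wr$ratio,
    precision = 1 / wr$se_first_order,
    stringsAsFactors = FALSE)

  structure(list(forest = forest, scatter = scatter, lines = lines,
                 funnel = funnel),
            class = "mr_diagnostics")
}
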