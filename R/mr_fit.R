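#' Fit a two-sample Mendelian randomization model
#'
#' The main fitting function. Takes a harmonized instrument set and
#' estimates the causal effect of the exposure on the outcome with the
#' requested estimators, together with the heterogeneity and pleiotropy
#' sensitivity statistics. Returns a classed model object with `print`,
#' `summary`, `coef`, `confint` and `plot` methods.
#'
#' @param instruments An `mr_instruments` data frame from [harmonize()] /
#'   [select_instruments()], or a plain data frame with columns
#'   `variant_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @param methods Estimators to fit, a subset of `"ivw"`, `"egger"`,
#'   `"weighted_median"`.
#' @param n_boot,seed Bootstrap replicates and seed for the weighted-median
#'   SE (see [mr_weighted_median()]).
#' @param ci_z Normal quantile for the odds-ratio confidence bounds.
#' @param ... Further arguments passed to the individual estimators
#'   ([mr_ivw()], [mr_egger()]).
#' @return An object of class `mr_fit`: a list with `estimates` (named list
#'   of `mr_estimate`), `heterogeneity` (see [mr_heterogeneity()]),
#'   `pleiotropy` (the Egger intercept test, when Egger is fitted),
#'   `instruments`, `settings`, and `call`.
#' @export
#' @examples
#' fit <- mr_fit(aspirin_hayfever(), n_boot = 200)
#' summary(fit)
#' coef(fit)
mr_fit <- function(instruments,
                   methods = c("ivw", "egger", "weighted_median"),
                   n_boot = 1000, seed = 20230825,
                   ci_z = stats::qnorm(0.975), ...) {
  instruments <- as_mr_instruments(instruments)
  methods <- match.arg(methods, several.ok = TRUE)
  estimates <- list()
  if ("ivw" %in% methods) {
    estimates$ivw <- mr_ivw(instruments, ci_z = ci_z, ...)
  }
  if ("egger" %in% methods) {
    estimates$egger <- mr_egger(instruments, ci_z = ci_z, ...)
  }
  if ("weighted_median" %in% methods) {
    estimates$weighted_median <-
      mr_weighted_median(instruments, n_boot = n_boot, seed = seed,
                         ci_z = ci_z)
  }
  het <- list()
  if (nrow(instruments) >= 2 && "ivw" %in% methods) {
    het$ivw <- mr_heterogeneity(instruments, method = "ivw")
  }
  if (nrow(instruments) >= 3 && "egger" %in% methods) {
    het$egger <- mr_heterogeneity(instruments, method = "egger")
  }
  pleio <- if ("egger" %in% methods) {
    with(estimates$egger,
         list(intercept = intercept, se = intercept_se, pval = intercept_pval))
  } else NULL
  structure(list(
    estimates = estimates,
    heterogeneity = het,
    pleiotropy = pleio,
    instruments = instruments,
    settings = list(methods = methods, n_boot = n_boot, seed = seed,
                    ci_z = ci_z),
    call = match.call()
  ), class = "mr_fit")
}

#' Coerce a data frame to an instrument set
#'
#' @param x A data frame with at least `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`. `f_stat` is recomputed if
#'   absent.
#' @return An `mr_instruments` data frame.
#' @export
as_mr_instruments <- function(x) {
  if (inherits(x, "mr_instruments")) return(x)
  stopifnot(is.data.frame(x))
  need <- c("variant_id", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("instrument table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$variant_id)) {
    stop("duplicate variant ids in instrument set", call. = FALSE)
  }
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  if (is.null(x$f_stat)) {
    x$f_stat <- (x$beta_exposure / x$se_exposure)^2
  }
  class(x) <- c("mr_instruments", "data.frame")
  x
}

#' Tabulate the estimates of a fitted MR model
#'
#' @param fit An `mr_fit` object.
#' @return Data frame with one row per method: `method`, `n_snps`, `beta`,
#'   `se`, `pval`, `or`, `ci_lower`, `ci_upper`, and the Egger intercept
#'   triple (`NA` for other methods).
#' @export
mr_estimates_table <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  rows <- lapply(fit$estimates, function(e) {
    data.frame(method = e$method, n_snps = e$n_snps,
               beta = e$beta, se = e$se, pval = e$pval,
               or = e$or_point, ci_lower = e$ci_lower,
               ci_upper = e$ci_upper,
               intercept = if (is.null(e$intercept)) NA_real_ else e$intercept,
               intercept_se = if (is.null(e$intercept_se)) NA_real_ else e$intercept_se,
               intercept_pval = if (is.null(e$intercept_pval)) NA_real_ else e$intercept_pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample Mendelian randomization fit:",
      nrow(x$instruments), "instruments\n\n")
  tab <- mr_estimates_table(x)
  print(format(tab[, c("method", "n_snps", "beta", "se", "pval")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object, table = mr_estimates_table(object)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  cat("Two-sample Mendelian randomization\n")
  cat("Instruments:", nrow(fit$instruments), "\n\n")
  tab <- x$table
  tab$or_ci <- sprintf("%.4f (%.4f-%.4f)", tab$or, tab$ci_lower, tab$ci_upper)
  print(format(tab[, c("method", "n_snps", "beta", "se", "or_ci", "pval")],
               digits = digits), row.names = FALSE)
  if (!is.null(fit$pleiotropy)) {
    p <- fit$pleiotropy
    cat("\nEgger intercept (directional pleiotropy): ",
        format(p$intercept, digits = digits),
        " (SE = ", format(p$se, digits = digits),
        ", p = ", format(p$pval, digits = digits), ")\n", sep = "")
  }
  for (h in x$fit$heterogeneity) {
    cat(sprintf("Heterogeneity (%s): Q = %.4g on %d df, I2 = %.4g, p = %.4g\n",
                h$method, h$Q, h$df,
                ifelse(is.na(h$i_squared), NA, h$i_squared), h$pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  tab <- mr_estimates_table(object)
  stats::setNames(tab$beta, tab$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- mr_estimates_table(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(tab$beta - z * tab$se, tab$beta + z * tab$se)
  dimnames(out) <- list(tab$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' Residuals of a fitted MR model
#'
#' Weighted residuals of the per-variant Wald ratios around a method's
#' pooled estimate, `sqrt(w_j) * (ratio_j - beta)`; their squared sum is
#' Cochran's Q for the IVW fit.
#'
#' @param object An `mr_fit` object.
#' @param method Which fitted method's pooled estimate to centre on.
#' @param ... Unused.
#' @export
residuals.mr_fit <- function(object, method = c("ivw", "egger",
                                                "weighted_median"), ...) {
  method <- match.arg(method)
  if (is.null(object$estimates[[method]])) {
    stop("method '", method, "' was not fitted", call. = FALSE)
  }
  wr <- wald_ratio(object$instruments)
  stats::setNames(sqrt(wr$weight) * (wr$ratio - object$estimates[[method]]$beta),
                  wr$variant_id)
}
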