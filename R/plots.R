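#' Forest plot of per-variant and combined causal estimates
#'
#' @param diag An `mr_diagnostics` object (or the `instruments`/`fits` pair
#'   via [mr_diagnostics()] upstream).
#' @param main Plot title.
#' @export
mr_plot_forest <- function(diag, main = "Per-variant causal estimates") {
  stopifnot(inherits(diag, "mr_diagnostics"))
  f <- diag$forest
  y <- rev(seq_len(nrow(f)))
  graphics::plot(f$beta, y, xlim = range(f$ci_lower, f$ci_upper, 0),
                 ylim = c(0.5, nrow(f) + 0.5), yaxt = "n",
                 xlab = "Causal estimate (log OR)", ylab = "",
                 pch = ifelse(f$kind == "combined", 18, 16),
                 col = ifelse(f$kind == "combined", "red", "black"),
                 main = main)
  graphics::segments(f$ci_lower, y, f$ci_upper, y,
                     col = ifelse(f$kind == "combined", "red", "black"))
  graphics::axis(2, at = y, labels = f$label, las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  invisible(diag)
}

#' Scatter plot of outcome vs exposure effects with method lines
#'
#' @param diag An `mr_diagnostics` object.
#' @param main Plot title.
#' @export
mr_plot_scatter <- function(diag, main = "Exposure vs outcome effects") {
  stopifnot(inherits(diag, "mr_diagnostics"))
  s <- diag$scatter
  graphics::plot(s$beta_exposure, s$beta_outcome,
                 xlim = range(s$x_lower, s$x_upper),
                 ylim = range(s$y_lower, s$y_upper),
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 16, main = main)
  graphics::segments(s$x_lower, s$beta_outcome, s$x_upper, s$beta_outcome,
                     col = "grey60")
  graphics::segments(s$beta_exposure, s$y_lower, s$beta_exposure, s$y_upper,
                     col = "grey60")
  cols <- seq_len(nrow(diag$lines)) + 1L
  for (i in seq_len(nrow(diag$lines))) {
    graphics::abline(diag$lines$intercept[i], diag$lines$slope[i],
                     col = cols[i])
  }
  graphics::legend("topright", legend = diag$lines$method, col = cols,
                   lty = 1, cex = 0.8)
  invisible(diag)
}

#' Funnel plot of per-variant estimates against precision
#'
#' @param diag An `mr_diagnostics` object.
#' @param main Plot title.
#' @export
mr_plot_funnel <- function(diag, main = "Funnel plot") {
  stopifnot(inherits(diag, "mr_diagnostics"))
  f <- diag$funnel
  graphics::plot(f$ratio, f$precision, pch = 16,
                 xlab = "Per-variant causal estimate (Wald ratio)",
                 ylab = expression(Precision ~ (1 / SE)), main = main)
  cols <- seq_len(nrow(diag$lines)) + 1L
  graphics::abline(v = diag$lines$slope, col = cols)
  graphics::legend("topright", legend = diag$lines$method, col = cols,
                   lty = 1, cex = 0.8)
  invisible(diag)
}

#' Leave-one-out plot
#'
#' @param loo An `mr_loo` data frame from [mr_leave_one_out()].
#' @param main Plot title.
#' @export
mr_plot_loo <- function(loo, main = "Leave-one-out (IVW)") {
  stopifnot(inherits(loo, "mr_loo"))
  y <- rev(seq_len(nrow(loo)))
  all_row <- loo$variant_id == "All"
  graphics::plot(loo$beta, y, xlim = range(loo$ci_lower, loo$ci_upper, 0),
                 yaxt = "n", xlab = "IVW estimate excluding variant",
                 ylab = "", pch = ifelse(all_row, 18, 16),
                 col = ifelse(all_row, "red", "black"), main = main)
  graphics::segments(loo$ci_lower, y, loo$ci_upper, y,
                     col = ifelse(all_row, "red", "black"))
  graphics::axis(2, at = y, labels = loo$variant_id, las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  invisible(loo)
}

#' @export
plot.mr_fit <- function(x, which = c("scatter", "forest", "funnel"), ...) {
  which <- match.arg(which)
  d <- mr_diagnostics(x$instruments, x$estimates, ci_z = x$settings$ci_z)
  switch(which,
         scatter = mr_plot_scatter(d, ...),
         forest = mr_plot_forest(d, ...),
         funnel = mr_plot_funnel(d, ...))
  invisible(x)
}
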