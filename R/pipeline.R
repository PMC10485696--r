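#' Run the full two-sample MR pipeline
#'
#' One call from summary-statistics files to report tables and figures:
#' read, harmonize, select instruments, estimate with the requested
#' methods, run the sensitivity battery, and write every result table
#' (TSV), a versioned machine-readable JSON summary, and the diagnostic
#' figures. Row counts at every stage (read, matched, harmonized,
#' post-filter) are recorded in the summary so filter accounting sums
#' exactly.
#'
#' @param exposure,outcome Paths to summary-statistics files (or
#'   `sumstats` data frames already in memory).
#' @param exposure_map,outcome_map Column maps for [read_sumstats()].
#' @param p_threshold,r2_threshold,f_threshold Instrument filters; defaults
#'   5e-8, 0.1, 10.
#' @param ld_matrix Optional path to a TSV r-squared matrix (variant ids as
#'   first column and header), or a matrix.
#' @param methods Estimators to fit.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @param ci_z Normal quantile for OR confidence bounds.
#' @param out_dir Output directory; created if needed.
#' @param plots Write PNG figures? Default `TRUE`.
#' @param palindrome_eaf_window,drop_palindromic_ambiguous Harmonization
#'   policy (see [harmonize()]).
#' @return Invisibly, a list with the fitted `mr_fit`, the instrument set,
#'   all result tables, stage counts, and the summary written to
#'   `summary.json`. Errors of class `mr_io_error` (unreadable input,
#'   raised before any computation) and `mr_no_instruments` (empty set
#'   after filtering) are signalled for scripted callers.
#' @export
#' @examples
#' dir <- tempfile()
#' run_mr_pipeline(
#'   system.file("extdata", "aspirin_exposure.tsv", package = "mrkit"),
#'   system.file("extdata", "hayfever_outcome.tsv", package = "mrkit"),
#'   out_dir = dir, plots = FALSE, n_boot = 100)
run_mr_pipeline <- function(exposure, outcome,
                            exposure_map = default_column_map(),
                            outcome_map = default_column_map(),
                            p_threshold = 5e-8, r2_threshold = 0.1,
                            f_threshold = 10, ld_matrix = NULL,
                            methods = c("ivw", "egger", "weighted_median"),
                            n_boot = 1000, seed = 20230825,
                            ci_z = stats::qnorm(0.975),
                            out_dir = ".", plots = TRUE,
                            palindrome_eaf_window = 0.08,
                            drop_palindromic_ambiguous = TRUE) {
  for (p in c(if (is.character(exposure)) exposure,
              if (is.character(outcome)) outcome)) {
    if (!file.exists(p)) {
      stop(structure(class = c("mr_io_error", "error", "condition"),
                     list(message = paste0("input file not found: ", p),
                          call = sys.call())))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(structure(class = c("mr_io_error", "error", "condition"),
                   list(message = paste0("cannot create output directory: ",
                                         out_dir),
                        call = sys.call())))
  }

  exp_tab <- if (is.character(exposure))
    read_sumstats(exposure, exposure_map) else exposure
  out_tab <- if (is.character(outcome))
    read_sumstats(outcome, outcome_map) else outcome

  harmonized <- suppressWarnings(
    harmonize(exp_tab, out_tab,
              palindrome_eaf_window = palindrome_eaf_window,
              drop_palindromic_ambiguous = drop_palindromic_ambiguous))
  ld <- ld_matrix
  if (is.character(ld)) {
    ld <- as.matrix(utils::read.delim(ld, row.names = 1, check.names = FALSE))
  }
  instruments <- select_instruments(harmonized, p_threshold = p_threshold,
                                    ld_r2 = ld, r2_threshold = r2_threshold,
                                    f_threshold = f_threshold)

  fit <- mr_fit(instruments, methods = methods, n_boot = n_boot,
                seed = seed, ci_z = ci_z)
  estimates <- mr_estimates_table(fit)
  sens <- do.call(rbind, lapply(fit$heterogeneity, function(h)
    data.frame(method = h$method, Q = h$Q, df = h$df,
               i_squared = h$i_squared, i_squared_magnitude = abs(h$i_squared),
               pval = h$pval, stringsAsFactors = FALSE)))
  loo <- if (nrow(instruments) >= 3) mr_leave_one_out(instruments,
                                                      ci_z = ci_z) else NULL
  diag <- mr_diagnostics(instruments, fit, ci_z = ci_z)

  counts <- list(
    exposure_read = nrow(exp_tab), outcome_read = nrow(out_tab),
    matched = length(intersect(exp_tab$variant_id, out_tab$variant_id)),
    harmonized = nrow(harmonized),
    dropped_harmonization = nrow(attr(harmonized, "dropped")),
    selected = nrow(instruments))

  write_instruments(instruments, file.path(out_dir, "instruments.tsv"))
  wt <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(estimates, "estimates.tsv")
  if (!is.null(sens)) wt(sens, "sensitivity.tsv")
  if (!is.null(loo)) wt(as.data.frame(loo), "leave_one_out.tsv")

  summary <- list(
    schema_version = "1.0",
    settings = list(
      p_threshold = p_threshold, r2_threshold = r2_threshold,
      f_threshold = f_threshold, methods = methods, n_boot = n_boot,
      seed = seed, ci_z = ci_z,
      palindrome_eaf_window = palindrome_eaf_window,
      drop_palindromic_ambiguous = drop_palindromic_ambiguous,
      ivw_variance_model = "multiplicative_random",
      egger_orient_exposure_positive = TRUE,
      egger_se_model = "t",
      allow_underdispersion = TRUE,
      wald_se_order = "first"),
    counts = counts,
    estimates = estimates,
    pleiotropy = fit$pleiotropy,
    heterogeneity = if (is.null(sens)) NULL else sens,
    leave_one_out = if (is.null(loo)) NULL else as.data.frame(loo))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  if (plots) {
    fig <- function(name, expr) {
      grDevices::png(file.path(out_dir, name), width = 900, height = 700,
                     res = 120)
      on.exit(grDevices::dev.off())
      force(expr)
    }
    fig("forest.png", mr_plot_forest(diag))
    fig("scatter.png", mr_plot_scatter(diag))
    fig("funnel.png", mr_plot_funnel(diag))
    if (!is.null(loo)) fig("leave_one_out.png", mr_plot_loo(loo))
  }

  invisible(list(fit = fit, instruments = instruments,
                 estimates = estimates, sensitivity = sens, loo = loo,
                 diagnostics = diag, counts = counts, summary = summary,
                 out_dir = out_dir))
}

#' Recompute the packaged reference analysis and compare cell by cell
#'
#' Runs the pipeline on the packaged aspirin-use / allergic-rhinitis
#' instrument set with the published thresholds, then compares every
#' recomputed quantity against the published value, flagging each cell
#' `REPRODUCED` or `DOCUMENTED-DISCREPANCY`. Several published cells are
#' not recoverable from the published per-variant table itself (three F
#' statistics, the IVW and Egger estimates, and the Q statistics); these
#' are flagged as discrepancies with both values shown, which is the
#' expected output of this function, not a failure.
#'
#' @param out_dir Optional directory for the full pipeline outputs;
#'   defaults to a temporary directory.
#' @param tol Relative tolerance for calling a cell reproduced;
#'   default 0.005. Cells smaller than 0.01 in magnitude are compared
#'   absolutely at `tol`.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return Data frame of class `mr_reproduction`: `quantity`, `published`,
#'   `recomputed`, `status`.
#' @export
#' @examples
#' rep <- mr_reproduce_reference(n_boot = 200)
#' subset(rep, status == "REPRODUCED")
mr_reproduce_reference <- function(out_dir = tempfile("mr_reproduce_"),
                                   tol = 0.005, n_boot = 1000,
                                   seed = 20230825) {
  run <- run_mr_pipeline(
    system.file("extdata", "aspirin_exposure.tsv", package = "mrkit"),
    system.file("extdata", "hayfever_outcome.tsv", package = "mrkit"),
    out_dir = out_dir, plots = FALSE, n_boot = n_boot, seed = seed)
  ref <- .reference_results()
  est <- run$estimates
  het <- run$sensitivity

  cmp <- function(quantity, published, recomputed) {
    denom <- max(abs(published), 0.01)
    status <- if (abs(recomputed - published) / denom <= tol)
      "REPRODUCED" else "DOCUMENTED-DISCREPANCY"
    data.frame(quantity = quantity, published = published,
               recomputed = recomputed, status = status,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  ins <- run$instruments
  for (v in names(ref$f_stats)) {
    rows[[length(rows) + 1L]] <- cmp(
      paste0("F ", v), ref$f_stats[[v]],
      ins$f_stat[ins$variant_id == v])
  }
  for (i in seq_len(nrow(ref$estimates))) {
    m <- ref$estimates$method[i]
    e <- est[est$method == m, ]
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " beta"),
                                     ref$estimates$beta[i], e$beta)
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " SE"),
                                     ref$estimates$se[i], e$se)
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " OR"),
                                     ref$estimates$or[i], e$or)
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " CI lower"),
                                     ref$estimates$ci_lower[i], e$ci_lower)
  }
  pl <- run$fit$pleiotropy
  rows[[length(rows) + 1L]] <- cmp("Egger intercept",
                                   ref$intercept[["estimate"]], pl$intercept)
  for (i in seq_len(nrow(ref$heterogeneity))) {
    m <- ref$heterogeneity$method[i]
    h <- het[het$method == m, ]
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " Q"),
                                     ref$heterogeneity$Q[i], h$Q)
    rows[[length(rows) + 1L]] <- cmp(paste0(m, " I2 magnitude"),
                                     ref$heterogeneity$i2_magnitude[i],
                                     h$i_squared_magnitude)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_reproduction", "data.frame")
  out
}

#' @export
print.mr_reproduction <- function(x, ...) {
  n_rep <- sum(x$status == "REPRODUCED")
  cat("Reference reproduction: ", n_rep, "/", nrow(x),
      " cells reproduced\n\n", sep = "")
  df <- as.data.frame(x)
  df$published <- signif(df$published, 6)
  df$recomputed <- signif(df$recomputed, 6)
  print(df, row.names = FALSE)
  invisible(x)
}
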