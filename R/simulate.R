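# deterministic stream seeds: every random draw descends from one master
# seed, so any replicate is independently reproducible. Kept below 2^31-1.
.stream_seed <- function(master, stream, index = 0L) {
  as.integer((as.numeric(master) * 48271 + stream * 16807 + index * 69621) %%
               2147483647)
}

#' Simulate two-sample MR summary statistics with known ground truth
#'
#' Generates exposure and outcome GWAS summary-statistics tables under the
#' standard two-sample MR data model. True variant-exposure effects
#' `gamma_j` are drawn from a normal distribution (or supplied directly);
#' true variant-outcome effects are `true_beta * gamma_j + alpha_j`, where
#' `alpha_j` is a horizontal-pleiotropy effect carried by a configurable
#' fraction of instruments — directional when `pleiotropy_mean != 0`,
#' balanced when only `pleiotropy_sd > 0`, and correlated with instrument
#' strength (violating InSIDE) when `inside_violation` is on. Observed
#' effects add independent Gaussian estimation noise in each sample, with
#' SEs on the order of the defaults seen in large-biobank summary
#' statistics (~1e-3). Instruments are generated independent, matching the
#' post-clumping state.
#'
#' @param n_snps Number of instruments, at least 2.
#' @param true_beta The causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd Mean and SD of the true variant-exposure
#'   effects. Defaults 0.01 and 0.003, the magnitude of genome-wide
#'   significant effects in the packaged example.
#' @param gamma Optional explicit vector of true variant-exposure effects
#'   (overrides `gamma_mean`/`gamma_sd`).
#' @param se_exposure_scale,se_outcome_scale Scales of the per-variant SEs;
#'   each variant's SE is the scale times a uniform draw in `[0.8, 1.2]`.
#' @param pleiotropy_mean,pleiotropy_sd Mean (directional) and SD
#'   (balanced spread) of the pleiotropic effects `alpha_j`.
#' @param invalid_fraction Fraction of instruments receiving pleiotropy;
#'   the number of invalid instruments is `round(invalid_fraction * n_snps)`.
#' @param inside_violation If `TRUE`, `alpha_j` gains a component
#'   proportional to `gamma_j`, violating the InSIDE assumption.
#' @param maf_range Interval in (0, 0.5] from which effect-allele
#'   frequencies are drawn uniformly.
#' @param n_exposure,n_outcome Sample sizes recorded in the emitted tables.
#' @param seed Master seed; the whole draw is reproducible from it.
#' @return List with `exposure` and `outcome` (`sumstats` data frames in
#'   the same dialect [read_sumstats()] produces) and `truth` (config echo
#'   plus per-variant `gamma`, `alpha`, and `valid` flags).
#' @export
#' @examples
#' sim <- simulate_two_sample(n_snps = 10, true_beta = 0.3, seed = 1)
#' sim$truth$config$true_beta
simulate_two_sample <- function(n_snps = 50, true_beta = 0,
                                gamma_mean = 0.01, gamma_sd = 0.003,
                                gamma = NULL,
                                se_exposure_scale = 1e-3,
                                se_outcome_scale = 2.5e-3,
                                pleiotropy_mean = 0, pleiotropy_sd = 0,
                                invalid_fraction = 0,
                                inside_violation = FALSE,
                                maf_range = c(0.05, 0.5),
                                n_exposure = 337159, n_outcome = 83529,
                                seed = 1L) {
  stopifnot(n_snps >= 2, se_exposure_scale > 0, se_outcome_scale > 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(.stream_seed(seed, 1L))
  g <- if (is.null(gamma)) stats::rnorm(n_snps, gamma_mean, gamma_sd)
       else rep_len(gamma, n_snps)
  if (all(g == 0)) {
    stop("degenerate configuration: all true exposure effects are zero",
         call. = FALSE)
  }
  n_invalid <- round(invalid_fraction * n_snps)
  invalid <- seq_len(n_snps) %in% sample(n_snps, n_invalid)
  alpha <- rep(0, n_snps)
  if (n_invalid > 0) {
    a <- pleiotropy_mean + pleiotropy_sd * stats::rnorm(n_invalid)
    if (inside_violation) {
      # tie the direct effect to instrument strength
      a <- a + 0.5 * abs(pleiotropy_mean + pleiotropy_sd) *
        (g[invalid] - mean(g)) / max(stats::sd(g), .Machine$double.eps)
    }
    alpha[invalid] <- a
  }
  eaf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  sx <- se_exposure_scale * stats::runif(n_snps, 0.8, 1.2)
  sy <- se_outcome_scale * stats::runif(n_snps, 0.8, 1.2)

  set.seed(.stream_seed(seed, 2L))
  bx <- stats::rnorm(n_snps, g, sx)
  by <- stats::rnorm(n_snps, true_beta * g + alpha, sy)

  ids <- sprintf("sim%04d", seq_len(n_snps))
  mk <- function(beta, se, n) {
    df <- data.frame(
      variant_id = ids,
      chrom_pos = sprintf("1: %d", seq_len(n_snps) * 1000L),
      effect_allele = rep(c("A", "C"), length.out = n_snps),
      other_allele = rep(c("G", "T"), length.out = n_snps),
      eaf = eaf,
      beta = beta, se = se,
      pval = 2 * stats::pnorm(-abs(beta / se)),
      n = n, stringsAsFactors = FALSE)
    .as_sumstats(df, .empty_rejects())
  }
  truth <- list(
    config = list(n_snps = n_snps, true_beta = true_beta,
                  gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                  se_exposure_scale = se_exposure_scale,
                  se_outcome_scale = se_outcome_scale,
                  pleiotropy_mean = pleiotropy_mean,
                  pleiotropy_sd = pleiotropy_sd,
                  invalid_fraction = invalid_fraction,
                  inside_violation = inside_violation,
                  maf_range = maf_range, seed = seed),
    gamma = g, alpha = alpha, valid = !invalid)
  list(exposure = mk(bx, sx, n_exposure),
       outcome = mk(by, sy, n_outcome),
       truth = truth)
}

#' Instrument set straight from a simulation
#'
#' Convenience wrapper: simulate, harmonize (the simulated tables share
#' allele orientation, so this is the identity alignment) and return the
#' `mr_instruments` table.
#'
#' @param ... Passed to [simulate_two_sample()].
#' @return An `mr_instruments` data frame.
#' @export
simulate_instruments <- function(...) {
  sim <- simulate_two_sample(...)
  harmonize(sim$exposure, sim$outcome)
}

#' Parameter-recovery / type-I-error experiment
#'
#' Repeatedly simulates two-sample summary statistics under one
#' configuration and summarizes how well each estimator recovers the true
#' causal effect: mean bias, RMSE, empirical SE of the estimates, mean
#' model SE, 95% CI coverage, and the rejection rate of the null
#' `beta = 0` at the 5% level. Per-replicate seeds are derived
#' deterministically from the master seed, so any replicate can be re-run
#' in isolation. A replicate in which an estimator fails is counted and
#' excluded from that estimator's summaries, not fatal.
#'
#' @param n_reps Number of replicates, at least 1.
#' @param estimators Subset of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param n_boot Bootstrap replicates for the weighted-median SE; 0
#'   (default) skips the bootstrap, leaving that estimator's SE-based
#'   summaries (`mean_model_se`, `coverage`, `rejection_rate`) `NA`.
#' @param seed Master seed.
#' @param ... Simulation configuration passed to [simulate_two_sample()]
#'   (`true_beta`, `n_snps`, pleiotropy settings, ...).
#' @return Data frame with one row per estimator: `estimator`, `n_reps`,
#'   `n_fail`, `mean_bias`, `rmse`, `empirical_se`, `mean_model_se`,
#'   `coverage`, `rejection_rate`.
#' @export
#' @examples
#' recovery_experiment(n_reps = 20, true_beta = 0.2, n_snps = 20, seed = 7)
recovery_experiment <- function(n_reps = 200,
                                estimators = c("ivw", "egger",
                                               "weighted_median"),
                                n_boot = 0, seed = 1L, ...) {
  stopifnot(n_reps >= 1)
  estimators <- match.arg(estimators, several.ok = TRUE)
  cfg <- list(...)
  true_beta <- if (is.null(cfg$true_beta)) 0 else cfg$true_beta
  z <- stats::qnorm(0.975)

  est_mat <- matrix(NA_real_, n_reps, length(estimators),
                    dimnames = list(NULL, estimators))
  se_mat <- est_mat
  for (r in seq_len(n_reps)) {
    sim <- do.call(simulate_two_sample,
                   c(cfg, list(seed = .stream_seed(seed, 3L, r))))
    ins <- harmonize(sim$exposure, sim$outcome)
    for (m in estimators) {
      fit <- tryCatch(switch(
        m,
        ivw = mr_ivw(ins),
        egger = mr_egger(ins),
        weighted_median = {
          if (n_boot > 0) {
            mr_weighted_median(ins, n_boot = n_boot,
                               seed = .stream_seed(seed, 4L, r))
          } else {
            list(beta = .weighted_median(
              ins$beta_outcome / ins$beta_exposure,
              (ins$beta_exposure / ins$se_outcome)^2), se = NA_real_)
          }
        }), error = function(e) NULL)
      if (!is.null(fit)) {
        est_mat[r, m] <- fit$beta
        se_mat[r, m] <- fit$se
      }
    }
  }

  rows <- lapply(estimators, function(m) {
    b <- est_mat[, m]
    s <- se_mat[, m]
    ok <- !is.na(b)
    has_se <- ok & !is.na(s)
    data.frame(
      estimator = m,
      n_reps = n_reps,
      n_fail = sum(!ok),
      mean_bias = mean(b[ok]) - true_beta,
      rmse = sqrt(mean((b[ok] - true_beta)^2)),
      empirical_se = stats::sd(b[ok]),
      mean_model_se = if (any(has_se)) mean(s[has_se]) else NA_real_,
      coverage = if (any(has_se))
        mean(abs(b[has_se] - true_beta) <= z * s[has_se]) else NA_real_,
      rejection_rate = if (any(has_se))
        mean(abs(b[has_se] / s[has_se]) > z) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
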