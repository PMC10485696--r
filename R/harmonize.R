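#' Instrument-strength F statistic
#'
#' The single-variant F statistic for a variant-exposure association,
#' `(beta/se)^2`. Values above 10 are the conventional screen against weak
#' instruments in Mendelian randomization.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Non-negative numeric vector; invariant to the sign of `beta`.
#' @export
#' @examples
#' f_statistic(0.0133593, 0.00150604) # ~78.7, a strong instrument
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("se must be strictly positive", call. = FALSE)
  }
  (beta / se)^2
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & .complement[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect allele for every
#' variant present in both tables. Allele pairs that match directly are
#' copied through; swapped pairs have the outcome beta negated and the EAF
#' complemented; pairs matching only after strand complement (A<->T, C<->G)
#' are complemented first. Palindromic variants (A/T or C/G pairs), for which
#' strand cannot be resolved from the alleles, are oriented by allele-frequency
#' agreement when both EAFs fall outside the ambiguous band
#' `[0.5 - palindrome_eaf_window, 0.5 + palindrome_eaf_window]`, and are
#' otherwise dropped when `drop_palindromic_ambiguous` is set. Variants whose
#' allele pairs no rule resolves are dropped with a logged reason, never
#' silently kept.
#'
#' When the other allele is unknown in either table (as in tables that print
#' only the effect allele), harmonization falls back to effect-allele
#' equality alone, with `palindromic` recorded as `NA` and a warning.
#'
#' @param exposure,outcome `sumstats` data frames (see [read_sumstats()]).
#' @param palindrome_eaf_window Half-width of the ambiguous EAF band around
#'   0.5 for palindromic variants. Default 0.08 (band `[0.42, 0.58]`).
#' @param drop_palindromic_ambiguous Drop palindromic variants whose EAFs do
#'   not resolve the strand? Default `TRUE`.
#'
#' @return A data frame of class `mr_instruments` with one row per retained
#'   variant: `variant_id`, `chrom_pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta_exposure`, `se_exposure`, `pval_exposure`, `beta_outcome`,
#'   `se_outcome`, `pval_outcome`, `n_exposure`, `n_outcome`, `f_stat`
#'   (`(beta_exposure/se_exposure)^2`), `flipped`, `palindromic`. Dropped
#'   variants and reasons are attached as the `"dropped"` attribute.
#' @export
#' @examples
#' tabs <- read_sumstats_wide(system.file("extdata",
#'   "aspirin_hayfever_snps.tsv", package = "mrkit"))
#' suppressWarnings(harmonize(tabs$exposure, tabs$outcome))
harmonize <- function(exposure, outcome,
                      palindrome_eaf_window = 0.08,
                      drop_palindromic_ambiguous = TRUE) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  n <- length(shared)
  keep <- rep(TRUE, n)
  flip <- rep(FALSE, n)
  palin <- rep(NA, n)
  reason <- rep(NA_character_, n)
  fallback_used <- FALSE
  lo <- 0.5 - palindrome_eaf_window
  hi <- 0.5 + palindrome_eaf_window

  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (is.na(e2) || is.na(o2)) {
      # other allele unknown: effect-allele equality only
      fallback_used <- TRUE
      if (!is.na(e1) && !is.na(o1) && e1 == o1) {
        flip[i] <- FALSE
      } else if (!is.na(e1) && !is.na(e2) && !is.na(o1) && o1 == e2) {
        flip[i] <- TRUE
      } else {
        keep[i] <- FALSE
        reason[i] <- "effect alleles disagree and other allele unknown"
      }
      next
    }
    palin[i] <- .is_palindromic(e1, e2)
    if (palin[i]) {
      # alleles cannot distinguish strand; use EAF agreement
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      resolvable <- !is.na(fe) && !is.na(fo) &&
        (fe < lo || fe > hi) && (fo < lo || fo > hi)
      same_alleles <- (o1 == e1 && o2 == e2) || (o1 == e2 && o2 == e1) ||
        (o1 == .complement[e1] && o2 == .complement[e2]) ||
        (o1 == .complement[e2] && o2 == .complement[e1])
      if (!same_alleles) {
        keep[i] <- FALSE
        reason[i] <- "allele pair mismatch"
      } else if (resolvable) {
        flip[i] <- (fe < 0.5) != (fo < 0.5)
      } else if (drop_palindromic_ambiguous) {
        keep[i] <- FALSE
        reason[i] <- "palindromic with ambiguous EAF"
      } else {
        flip[i] <- FALSE
      }
      next
    }
    if (o1 == e1 && o2 == e2) {
      flip[i] <- FALSE
    } else if (o1 == e2 && o2 == e1) {
      flip[i] <- TRUE
    } else if (!is.na(.complement[o1]) && !is.na(.complement[o2]) &&
               .complement[o1] == e1 && .complement[o2] == e2) {
      flip[i] <- FALSE
    } else if (!is.na(.complement[o1]) && !is.na(.complement[o2]) &&
               .complement[o1] == e2 && .complement[o2] == e1) {
      flip[i] <- TRUE
    } else {
      keep[i] <- FALSE
      reason[i] <- "allele pair mismatch"
    }
  }

  if (fallback_used) {
    warning("other allele unknown for some variants; harmonized by ",
            "effect-allele equality only (palindromic status unknown)",
            call. = FALSE)
  }

  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  res <- data.frame(
    variant_id    = shared,
    chrom_pos     = ex$chrom_pos,
    effect_allele = ex$effect_allele,
    other_allele  = ex$other_allele,
    eaf           = ex$eaf,
    beta_exposure = ex$beta,
    se_exposure   = ex$se,
    pval_exposure = ex$pval,
    beta_outcome  = beta_out,
    se_outcome    = ou$se,
    pval_outcome  = ou$pval,
    n_exposure    = ex$n,
    n_outcome     = ou$n,
    f_stat        = (ex$beta / ex$se)^2,
    eaf_outcome   = eaf_out,
    flipped       = flip,
    palindromic   = palin,
    stringsAsFactors = FALSE
  )
  dropped <- data.frame(variant_id = shared[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mr_instruments", "data.frame")
  attr(res, "dropped") <- dropped
  res
}

#' Select instruments by significance, strength and LD independence
#'
#' Applies the conventional instrument filters to a harmonized table: keep
#' variants with exposure p-value below `p_threshold` and F statistic above
#' `f_threshold`, then greedily clump for linkage-disequilibrium
#' independence — candidates are visited in order of ascending exposure
#' p-value (ties broken by variant id) and a variant is retained iff its
#' pairwise r-squared with every already-retained variant is below
#' `r2_threshold`. The result is independent of input row order.
#'
#' @param harmonized An `mr_instruments` data frame from [harmonize()].
#' @param p_threshold Exposure p-value threshold; default `5e-8`
#'   (genome-wide significance).
#' @param ld_r2 Optional symmetric numeric matrix of pairwise r-squared
#'   values with variant ids as dimnames. Pairs absent from the matrix are
#'   treated as independent, with a warning. `NULL` (default) treats all
#'   pairs as independent.
#' @param r2_threshold Pairwise r-squared threshold; default 0.1.
#' @param f_threshold F-statistic threshold; default 10.
#'
#' @return An `mr_instruments` data frame ordered by ascending exposure
#'   p-value, with attribute `"selection"` recording the thresholds applied.
#'   If no variant survives, an error of class `mr_no_instruments` is
#'   raised (downstream estimation would be impossible); an empty *input*
#'   simply returns an empty set.
#' @export
#' @examples
#' select_instruments(aspirin_hayfever())
select_instruments <- function(harmonized,
                               p_threshold = 5e-8,
                               ld_r2 = NULL,
                               r2_threshold = 0.1,
                               f_threshold = 10) {
  stopifnot(inherits(harmonized, "mr_instruments"))
  stopifnot(p_threshold > 0, r2_threshold > 0, f_threshold >= 0)
  sel_meta <- list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                   f_threshold = f_threshold, ld_matrix = !is.null(ld_r2))

  x <- harmonized[!is.na(harmonized$pval_exposure) &
                    harmonized$pval_exposure < p_threshold &
                    harmonized$f_stat > f_threshold, , drop = FALSE]
  if (nrow(harmonized) > 0L && nrow(x) == 0L) {
    stop(structure(class = c("mr_no_instruments", "error", "condition"),
                   list(message = "no variant passes the instrument filters",
                        call = sys.call())))
  }
  x <- x[order(x$pval_exposure, x$variant_id), , drop = FALSE]

  if (nrow(x) > 1L) {
    pair_r2 <- function(a, b) {
      if (is.null(ld_r2)) return(0)
      if (a %in% rownames(ld_r2) && b %in% colnames(ld_r2)) {
        return(ld_r2[a, b])
      }
      warning("no LD entry for pair (", a, ", ", b,
              "); assuming independence", call. = FALSE)
      0
    }
    retained <- 1L
    for (i in seq_len(nrow(x))[-1]) {
      r2 <- vapply(retained, function(j)
        pair_r2(x$variant_id[i], x$variant_id[j]), numeric(1))
      if (all(r2 < r2_threshold)) retained <- c(retained, i)
    }
    x <- x[retained, , drop = FALSE]
  }

  if (anyDuplicated(x$variant_id)) {
    stop("duplicate variant ids in instrument set", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("mr_instruments", "data.frame")
  attr(x, "selection") <- sel_meta
  x
}
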