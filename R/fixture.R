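#' The packaged aspirin-use / allergic-rhinitis instrument set
#'
#' Returns the seven-variant harmonized instrument set from a published
#' two-sample MR analysis of aspirin use (exposure; GWAS n = 337,159) on
#' doctor-diagnosed hayfever or allergic rhinitis (outcome; GWAS
#' n = 83,529). The per-variant effects are shipped as plain-text summary
#' statistics under `inst/extdata` and harmonized on load; both blocks are
#' already expressed on the same effect allele, and only the effect allele
#' is published, so harmonization uses the effect-allele-equality fallback.
#' F statistics are recomputed from the exposure beta and SE.
#'
#' @param select Apply the published instrument filters
#'   (p < 5e-8, F > 10) via [select_instruments()]? Default `TRUE`.
#' @return An `mr_instruments` data frame with 7 rows.
#' @export
#' @examples
#' aspirin_hayfever()
aspirin_hayfever <- function(select = TRUE) {
  path <- system.file("extdata", "aspirin_hayfever_snps.tsv",
                      package = "mrkit")
  tabs <- read_sumstats_wide(path)
  h <- suppressWarnings(harmonize(tabs$exposure, tabs$outcome))
  if (select) h <- select_instruments(h) else h
}

# Published reference results for the aspirin -> hayfever/allergic-rhinitis
# analysis, used by mr_reproduce_reference() for side-by-side comparison.
# or/ci cells known to be internally inconsistent in the source table are
# omitted.
.reference_results <- function() {
  list(
    f_stats = c(rs10455872 = 78.68497578, rs117733303 = 41.97722735,
                rs1831733 = 76.55860496, rs2521501 = 30.66181305,
                rs583104 = 40.22202655, rs73015016 = 32.78123454,
                rs7412 = 38.51095695),
    estimates = data.frame(
      method = c("Egger", "WeightedMedian", "IVW"),
      n_snps = c(7L, 7L, 7L),
      beta = c(-0.3742, -0.4155, -0.349),
      se = c(0.3809, 0.1655, 0.1356),
      or = c(0.6878, 0.6600, 0.7054),
      ci_lower = c(0.3260, 0.4772, 0.5408),
      pval = c(0.371, 0.0121, 0.0101),
      stringsAsFactors = FALSE),
    intercept = c(estimate = 0.00021, se = 0.003, pval = 0.946),
    heterogeneity = data.frame(
      method = c("EGGER", "IVW"),
      Q = c(2.143, 2.148),
      i2_magnitude = c(1.333, 1.793),
      pval = c(0.8291, 0.9056),
      stringsAsFactors = FALSE)
  )
}
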