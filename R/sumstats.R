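#' Default column mapping for summary-statistics files
#'
#' Maps the internal field names to the column names expected in a
#' tab-separated GWAS summary-statistics file.
#'
#' @return Named character vector: internal field -> file column name.
#' @export
default_column_map <- function() {
  c(
    variant_id    = "SNP",
    chrom         = "chr",
    pos           = "pos",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    eaf           = "eaf",
    beta          = "beta",
    se            = "se",
    pval          = "pval",
    n             = "n"
  )
}

.required_fields <- c("variant_id", "effect_allele", "beta", "se", "pval")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated association table (one row per variant) into a
#' validated `sumstats` data frame. Rows with missing or unparseable `beta`
#' or `se`, or with `se <= 0`, are rejected with a logged reason rather than
#' aborting the read; the rejections are attached as the `"rejected"`
#' attribute. Row order is preserved.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to column names in the file. Fields absent
#'   from the map (or mapped to columns absent from the file) other than
#'   the required ones are filled with `NA`. Defaults to
#'   [default_column_map()].
#'
#' @return A data frame of class `sumstats` with columns `variant_id`,
#'   `chrom_pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, and attribute `rejected` (a data frame of dropped rows
#'   with reasons).
#' @seealso [read_sumstats_wide()] for the two-block exposure/outcome
#'   dialect, [harmonize()] for allele alignment.
#' @export
#' @examples
#' exp_path <- system.file("extdata", "aspirin_exposure.tsv", package = "mrkit")
#' head(read_sumstats(exp_path))
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  defaults <- default_column_map()
  missing_map <- setdiff(names(defaults), names(column_map))
  column_map <- c(column_map, defaults[missing_map])

  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  for (f in .required_fields) {
    if (!column_map[[f]] %in% names(raw)) {
      stop("mapped column '", column_map[[f]], "' (field '", f,
           "') not found in ", path, call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(.as_sumstats(.empty_sumstats(), .empty_rejects()))
  }

  get_col <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  out <- data.frame(
    variant_id    = get_col("variant_id"),
    chrom_pos     = .make_chrom_pos(get_col("chrom"), get_col("pos")),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele  = toupper(get_col("other_allele")),
    eaf           = num(get_col("eaf")),
    beta          = num(get_col("beta")),
    se            = num(get_col("se")),
    pval          = num(get_col("pval")),
    n             = num(get_col("n")),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$beta)] <- "missing or unparseable beta"
  reason[is.na(out$se)]   <- "missing or unparseable se"
  reason[!is.na(out$se) & out$se <= 0] <- "non-positive se"
  bad_p <- !is.na(out$pval) & (out$pval <= 0 | out$pval > 1)
  reason[is.na(reason) & bad_p] <- "p-value outside (0, 1]"

  rejected <- data.frame(row = which(!is.na(reason)),
                         variant_id = out$variant_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " row(s) rejected while reading ", path,
            call. = FALSE)
  }
  out <- out[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  .as_sumstats(out, rejected)
}

#' Read a two-block exposure/outcome summary-statistics table
#'
#' Reads the harmonized two-block dialect in which each row carries the
#' shared variant columns plus per-trait beta/SE/p blocks, and returns the
#' exposure and outcome as two `sumstats` data frames. Expected columns:
#' `snp`, `chrom_pos`, `effect_allele`, `eaf`, `beta_exposure`,
#' `se_exposure`, `pval_exposure`, `beta_outcome`, `se_outcome`,
#' `pval_outcome`, and optionally `n_exposure`, `n_outcome`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return List with elements `exposure` and `outcome`, each a `sumstats`
#'   data frame (the `other_allele` is unknown in this dialect).
#' @export
#' @examples
#' path <- system.file("extdata", "aspirin_hayfever_snps.tsv", package = "mrkit")
#' str(read_sumstats_wide(path), max.level = 1)
read_sumstats_wide <- function(path) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""))
  need <- c("snp", "chrom_pos", "effect_allele", "eaf",
            "beta_exposure", "se_exposure", "pval_exposure",
            "beta_outcome", "se_outcome", "pval_outcome")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("two-block table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  block <- function(trait) {
    df <- data.frame(
      variant_id    = as.character(raw$snp),
      chrom_pos     = as.character(raw$chrom_pos),
      effect_allele = toupper(as.character(raw$effect_allele)),
      other_allele  = NA_character_,
      eaf           = as.numeric(raw$eaf),
      beta          = as.numeric(raw[[paste0("beta_", trait)]]),
      se            = as.numeric(raw[[paste0("se_", trait)]]),
      pval          = as.numeric(raw[[paste0("pval_", trait)]]),
      n             = if (paste0("n_", trait) %in% names(raw))
        as.numeric(raw[[paste0("n_", trait)]]) else NA_real_,
      stringsAsFactors = FALSE
    )
    .as_sumstats(df, .empty_rejects())
  }
  list(exposure = block("exposure"), outcome = block("outcome"))
}

#' Write a harmonized-instrument table to TSV
#'
#' @param x An `mr_instruments` data frame from [harmonize()] or
#'   [select_instruments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(x, path) {
  stopifnot(inherits(x, "mr_instruments"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.make_chrom_pos <- function(chrom, pos) {
  out <- ifelse(is.na(chrom) & is.na(pos), NA_character_,
                paste0(ifelse(is.na(chrom), "", chrom), ": ",
                       ifelse(is.na(pos), "", pos)))
  # a single pre-joined "chr: pos" column may be mapped through `chrom`
  out[is.na(pos) & !is.na(chrom)] <- chrom[is.na(pos) & !is.na(chrom)]
  out
}

.empty_sumstats <- function() {
  data.frame(variant_id = character(), chrom_pos = character(),
             effect_allele = character(), other_allele = character(),
             eaf = numeric(), beta = numeric(), se = numeric(),
             pval = numeric(), n = numeric(), stringsAsFactors = FALSE)
}

.empty_rejects <- function() {
  data.frame(row = integer(), variant_id = character(),
             reason = character(), stringsAsFactors = FALSE)
}

.as_sumstats <- function(df, rejected) {
  class(df) <- c("sumstats", "data.frame")
  attr(df, "rejected") <- rejected
  df
}
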