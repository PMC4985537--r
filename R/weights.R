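#' Read a SNP-weights table
#'
#' A weights table carries, per variant, the GWAS effect allele and its
#' published per-allele beta — the inputs to dosage coding and weighted
#' scoring.  Accepted either as a path to a tab-separated file with header
#' columns \code{snp_id}, \code{effect_allele}, \code{other_allele},
#' \code{beta}, \code{trait} (an optional \code{gene} column is kept if
#' present), or as an equivalent data frame.
#'
#' @param weights Path to a TSV file, or a data frame.
#' @return A validated data frame of class \code{"snp_weights"}, one row
#'   per SNP.
#' @export
read_weights <- function(weights) {
  if (is.character(weights) && length(weights) == 1L) {
    if (!file.exists(weights)) stop("weights file not found: ", weights)
    weights <- utils::read.delim(weights, stringsAsFactors = FALSE)
  }
  w <- as.data.frame(weights, stringsAsFactors = FALSE)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "trait")
  missing_cols <- setdiff(required, names(w))
  if (length(missing_cols))
    stop("weights table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(w) == 0L) {
    warning("weights table is empty")
    class(w) <- c("snp_weights", "data.frame")
    return(w)
  }
  w$snp_id <- as.character(w$snp_id)
  w$effect_allele <- toupper(as.character(w$effect_allele))
  w$other_allele <- toupper(as.character(w$other_allele))
  w$trait <- as.character(w$trait)
  if (any(!nzchar(w$snp_id))) stop("empty snp_id")
  dup <- w$snp_id[duplicated(w$snp_id)]
  if (length(dup))
    stop("duplicate snp_id in weights table: ",
         paste(unique(dup), collapse = ", "))
  valid_base <- c("A", "C", "G", "T")
  if (any(!w$effect_allele %in% valid_base) ||
      any(!w$other_allele %in% valid_base))
    stop("allele codes must be single bases A/C/G/T")
  if (any(w$effect_allele == w$other_allele))
    stop("effect_allele equals other_allele for: ",
         paste(w$snp_id[w$effect_allele == w$other_allele], collapse = ", "))
  if (any(!is.finite(w$beta))) stop("non-finite beta")
  if (any(!w$trait %in% c("BMI", "WHR")))
    stop("trait must be 'BMI' or 'WHR'")
  class(w) <- c("snp_weights", "data.frame")
  w
}

#' Bundled synthetic GWAS weight panels
#'
#' Returns the packaged candidate panels: 23 BMI-associated and 12
#' WHR-associated variants with minor allele frequency above 15 %.
#' The rsIDs and gene labels come from the large BMI and waist-hip-ratio
#' GWAS literature, but the per-allele betas and allele assignments are a
#' synthetic reconstruction on the published scale (the original
#' supplementary weight table is not redistributable), so the panels are
#' suitable for exercising and testing the pipeline, not for scoring real
#' cohorts.
#'
#' @param trait \code{"BMI"} or \code{"WHR"}.
#' @return A \code{"snp_weights"} data frame (with a \code{gene} column).
#' @export
grs_panel <- function(trait = c("BMI", "WHR")) {
  trait <- match.arg(trait)
  file <- system.file("extdata",
                      if (trait == "BMI") "bmi_weights_synthetic.tsv"
                      else "whr_weights_synthetic.tsv",
                      package = "grsforest", mustWork = TRUE)
  read_weights(file)
}
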