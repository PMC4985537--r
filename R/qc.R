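#' Code genotypes as effect-allele dosages
#'
#' Converts genotypes to per-sample effect-allele counts (0 for no effect
#' alleles, 1 for heterozygotes, 2 for effect-allele homozygotes), the
#' coding the weighted risk score is built on.  Input is either a VCF
#' (records matched to weights by ID; the weight's effect allele must equal
#' REF or ALT — a mismatch is a hard error, never a silent strand flip,
#' because a flipped allele corrupts the direction of the risk score) or a
#' sample-by-SNP dosage table already holding effect-allele counts.
#'
#' @param genotypes Path to a VCF file, or a data frame / matrix of
#'   dosages in \{0, 1, 2, NA\} with a \code{sample_id} column or rownames
#'   and one column per SNP.
#' @param weights A \code{"snp_weights"} table (see [read_weights()]);
#'   every weight's \code{snp_id} must be present in the genotype source.
#' @return Integer matrix, samples in rows and \code{weights$snp_id} in
#'   columns; \code{NA} marks missing calls.
#' @export
code_dosages <- function(genotypes, weights) {
  weights <- read_weights(weights)
  if (is.character(genotypes) && length(genotypes) == 1L)
    return(.dosages_from_vcf(genotypes, weights))
  .dosages_from_table(genotypes, weights)
}

.dosages_from_vcf <- function(path, weights) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- ids
  out <- matrix(NA_integer_, ncol(gt), nrow(weights),
                dimnames = list(colnames(gt), weights$snp_id))
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    k <- which(ids == w$snp_id)
    if (length(k) == 0L) stop("SNP absent from VCF: ", w$snp_id)
    if (length(k) > 1L) stop("SNP duplicated in VCF: ", w$snp_id)
    ref <- toupper(fix[k, "REF"]); alt <- toupper(fix[k, "ALT"])
    if (grepl(",", alt))
      stop("multi-allelic record not supported: ", w$snp_id)
    if (w$effect_allele == alt) {
      effect_code <- "1"
    } else if (w$effect_allele == ref) {
      effect_code <- "0"
    } else {
      stop("effect allele ", w$effect_allele, " of ", w$snp_id,
           " matches neither REF (", ref, ") nor ALT (", alt,
           "); possible strand or allele mismatch - refusing to flip")
    }
    g <- gt[k, ]
    alleles <- strsplit(g, "[/|]")
    out[, i] <- vapply(alleles, function(a) {
      if (length(a) != 2L || any(a == ".") || anyNA(a)) return(NA_integer_)
      sum(a == effect_code)
    }, integer(1))
  }
  out
}

.dosages_from_table <- function(tab, weights) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(tab)) {
    rn <- as.character(tab$sample_id)
    tab <- tab[, setdiff(names(tab), "sample_id"), drop = FALSE]
  } else {
    rn <- rownames(tab)
  }
  missing_snps <- setdiff(weights$snp_id, names(tab))
  if (length(missing_snps))
    stop("SNP(s) absent from dosage table: ",
         paste(missing_snps, collapse = ", "))
  m <- as.matrix(tab[, weights$snp_id, drop = FALSE])
  storage.mode(m) <- "integer"
  ok <- is.na(m) | m %in% 0:2
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  rownames(m) <- rn
  m
}

#' Minor allele frequency from dosages
#'
#' The effect-allele frequency is the allele-count sum over twice the
#' number of called samples; the MAF is the smaller of that frequency and
#' its complement.
#'
#' @param counts Dosage vector in \{0, 1, 2, NA\} for one SNP.
#' @return MAF in \[0, 0.5\].
#' @export
maf <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L) stop("all calls missing; MAF undefined")
  p <- sum(counts) / (2 * length(counts))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of the observed genotype counts
#' against the proportions p^2, 2pq, q^2 implied by the observed allele
#' frequency.  A monomorphic SNP has nothing to test: statistic 0, p 1,
#' and the \code{monomorphic} flag set.
#'
#' @param n0,n1,n2 Counts of samples with 0, 1 and 2 effect alleles.
#' @return List with \code{statistic}, \code{p_value}, \code{monomorphic}.
#' @export
hwe_test <- function(n0, n1, n2) {
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
  n <- n0 + n1 + n2
  if (n < 1) stop("need at least one genotype")
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1)
    return(list(statistic = 0, p_value = 1, monomorphic = TRUE))
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Genotype counts from a dosage vector
#'
#' @param counts Dosage vector in \{0, 1, 2, NA\}.
#' @return Named vector \code{c(n0, n1, n2)} over called samples.
#' @export
genotype_counts <- function(counts) {
  counts <- counts[!is.na(counts)]
  c(n0 = sum(counts == 0), n1 = sum(counts == 1), n2 = sum(counts == 2))
}

#' Composite LD r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors over their shared
#' non-missing samples.  This genotype-based (composite) measure needs no
#' phase information.  A constant dosage vector has no defined correlation:
#' \code{NA} is returned with a warning.
#'
#' @param a,b Dosage vectors of equal length.
#' @return r^2 in \[0, 1\], or \code{NA}.
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need at least two shared called samples")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("constant dosage vector; LD r^2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' QC thresholds
#'
#' @param maf_min Minimum minor allele frequency (exclusive bound); SNPs at
#'   or below it are flagged.  Default 0.15, the panel inclusion criterion.
#' @param hwe_alpha Significance level for the HWE chi-square test.
#' @param ld_r2_max Maximum tolerated pairwise dosage r^2.
#' @param missing_max Maximum tolerated per-SNP missing-call rate.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(maf_min = 0.15, hwe_alpha = 0.05,
                          ld_r2_max = 0.2, missing_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min < 0.5, hwe_alpha > 0, hwe_alpha < 1,
            ld_r2_max >= 0, ld_r2_max <= 1, missing_max >= 0,
            missing_max < 1)
  list(maf_min = maf_min, hwe_alpha = hwe_alpha, ld_r2_max = ld_r2_max,
       missing_max = missing_max)
}

#' Run genotype quality control
#'
#' Computes, per SNP, the MAF, the HWE chi-square test and the missing-call
#' rate, and all pairwise composite-LD r^2 values, then flags violations of
#' the configured thresholds.  The default policy is warn-and-continue:
#' flags are reported, nothing is removed (the targeted cohort passed all
#' three checks, so a failure in new data deserves a human look rather than
#' silent dropping).
#'
#' @param dosages Dosage matrix from [code_dosages()].
#' @param thresholds A [qc_thresholds()] list.
#' @param warn Emit a warning when any SNP is flagged (default TRUE).
#' @return A list of class \code{"qc_report"}: \code{snps} (per-SNP table
#'   with maf, hwe statistic/p, missing rate and fail flags), \code{ld}
#'   (r^2 matrix), \code{thresholds}, \code{pass} (TRUE when nothing is
#'   flagged).
#' @export
run_qc <- function(dosages, thresholds = qc_thresholds(), warn = TRUE) {
  stopifnot(is.matrix(dosages))
  ids <- colnames(dosages)
  p <- ncol(dosages)
  mafs <- apply(dosages, 2, maf)
  hwe <- apply(dosages, 2, function(d) {
    gc <- genotype_counts(d)
    unlist(hwe_test(gc[1], gc[2], gc[3]))
  })
  miss <- colMeans(is.na(dosages))
  ld <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
      r2 <- suppressWarnings(ld_r2(dosages[, i], dosages[, j]))
      ld[i, j] <- ld[j, i] <- r2
    }
  }
  off <- ld  # self-correlation excluded from the per-SNP LD summary
  diag(off) <- NA_real_
  max_r2 <- apply(off, 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  diag(ld) <- 1
  if (p == 1L) max_r2 <- NA_real_
  snps <- data.frame(
    snp_id = ids, maf = mafs,
    hwe_statistic = hwe["statistic", ], hwe_p = hwe["p_value", ],
    monomorphic = as.logical(hwe["monomorphic", ]),
    missing_rate = miss, max_ld_r2 = max_r2,
    maf_fail = mafs <= thresholds$maf_min,
    hwe_fail = hwe["p_value", ] < thresholds$hwe_alpha,
    missing_fail = miss > thresholds$missing_max,
    ld_fail = !is.na(max_r2) & max_r2 > thresholds$ld_r2_max,
    row.names = NULL, stringsAsFactors = FALSE)
  pass <- !any(snps$maf_fail | snps$hwe_fail | snps$missing_fail |
                 snps$ld_fail)
  if (warn && !pass) {
    flagged <- snps$snp_id[snps$maf_fail | snps$hwe_fail |
                             snps$missing_fail | snps$ld_fail]
    warning("QC flags raised for: ", paste(flagged, collapse = ", "),
            " (warn-and-continue policy; nothing removed)")
  }
  structure(list(snps = snps, ld = ld, thresholds = thresholds,
                 pass = pass),
            class = "qc_report")
}

#' @method print qc_report
#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", nrow(x$snps), "SNPs;",
      if (x$pass) "all checks passed" else "flags raised", "\n")
  fails <- x$snps[x$snps$maf_fail | x$snps$hwe_fail | x$snps$missing_fail |
                    x$snps$ld_fail, ]
  if (nrow(fails)) print(fails[, c("snp_id", "maf", "hwe_p",
                                   "missing_rate", "max_ld_r2")])
  invisible(x)
}

#' Write a QC report to TSV and JSON
#'
#' @param report A \code{"qc_report"}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "qc_report.tsv")
  json <- file.path(dir, "qc_report.json")
  utils::write.table(report$snps, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(thresholds = report$thresholds,
                            pass = report$pass, snps = report$snps),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(tsv = tsv, json = json))
}

#' Mean-impute missing dosages
#'
#' Missing calls are replaced per SNP by the mean observed dosage, keeping
#' the sample size fixed across pipeline stages.  Columns with every call
#' missing cannot be imputed and raise an error.
#'
#' @param dosages Dosage matrix with \code{NA} for missing calls.
#' @return Numeric matrix without missing values.
#' @export
impute_dosages <- function(dosages) {
  out <- dosages
  storage.mode(out) <- "double"
  for (j in seq_len(ncol(out))) {
    col <- out[, j]
    if (all(is.na(col))) stop("SNP with all calls missing cannot be imputed")
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    out[, j] <- col
  }
  out
}
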