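#' Define a simulation scenario
#'
#' A scenario fixes everything the cohort generator needs: sample size, the
#' SNP panel with effect-allele frequencies and planted additive per-allele
#' effects on EBMIL, a covariate model, residual noise, and a seed.
#' Genotypes are drawn independently per SNP under Hardy-Weinberg
#' proportions; EBMIL is additive in dosages and covariates with Gaussian
#' residuals (the generator's assumption — variants are modelled without
#' linkage disequilibrium, matching the cohort the pipeline targets).
#'
#' @param n_samples Number of subjects (>= 2).
#' @param snps Data frame with columns \code{snp_id}, \code{maf}
#'   (effect-allele frequency, in (0, 0.5]), \code{effect} (planted
#'   per-allele effect on EBMIL, percent per allele), \code{beta}
#'   (published per-allele GWAS beta carried along as the weighting input),
#'   \code{effect_allele}, \code{other_allele}, and optionally \code{trait}
#'   and \code{gene}.
#' @param ebmil_mean Target population mean EBMIL in percent; the intercept
#'   is solved so the expected EBMIL equals this value under the scenario.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate model for age (years)
#'   and initial BMI (kg/m^2).  Ages are truncated at 18, initial BMI at 30
#'   (the cohort inclusion criterion, which also keeps EBMIL defined).
#' @param frac_female,frac_distal Bernoulli probabilities for sex and
#'   surgery type, drawn independently of genotype.
#' @param age_slope,bmi_slope Effect of (centred) age and initial BMI on
#'   EBMIL, percent per unit.
#' @param male_offset,distal_offset Additive EBMIL offsets for male sex and
#'   distal surgery, percent.
#' @param noise_sd Residual SD of EBMIL in percent (>= 0).
#' @param missing_rate Per-cell probability of a missing genotype call.
#' @param seed Integer seed; the same scenario always generates the same
#'   cohort.
#' @param on_implausible What to do when a drawn EBMIL implies a
#'   non-positive final BMI: \code{"error"} or \code{"resample"} (redraw
#'   the offending residuals, up to 100 rounds).
#' @return A list of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(n_samples = 238,
                         snps,
                         ebmil_mean = 83.8,
                         age_mean = 43.1, age_sd = 10.8,
                         bmi_mean = 45.1, bmi_sd = 6.2,
                         frac_female = 0.74, frac_distal = 0.735,
                         age_slope = 0, bmi_slope = 0,
                         male_offset = 0, distal_offset = 0,
                         noise_sd = 17.8,
                         missing_rate = 0,
                         seed = 1L,
                         on_implausible = c("error", "resample")) {
  on_implausible <- match.arg(on_implausible)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "maf", "effect", "beta", "effect_allele",
                "other_allele")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (anyDuplicated(snps$snp_id)) stop("snp_ids must be unique")
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("every maf must lie in (0, 0.5]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), snps = snps,
    ebmil_mean = ebmil_mean,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    frac_female = frac_female, frac_distal = frac_distal,
    age_slope = age_slope, bmi_slope = bmi_slope,
    male_offset = male_offset, distal_offset = distal_offset,
    noise_sd = noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed), on_implausible = on_implausible
  ), class = "sim_scenario")
}

#' The default calibrated scenario
#'
#' A 238-subject scenario calibrated to the demographic and clinical
#' marginals of the surgical cohort the pipeline targets: 74 % women, age
#' 43.1 (SD 10.8) years, initial BMI 45.1 (SD 6.2) kg/m^2, mean EBMIL
#' 83.8 %, 73.5 % distal procedures.  The SNP panel is the union of the
#' bundled 23-variant BMI and 12-variant WHR panels.  Per-allele effects of
#' \code{-0.32 * 100 * beta} (BMI variants) and \code{-0.59 * 100 * beta}
#' (WHR variants) are planted on the seven BMI and three WHR variants the
#' method is expected to recover, zero elsewhere; covariate slopes are
#' -0.23 %/year of age and -0.73 % per initial-BMI unit.  The residual SD
#' of 15.7 % brings the total simulated EBMIL SD to approximately 17.8 %.
#'
#' @param n_samples Cohort size; default 238.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_scenario()].
#' @return A \code{"sim_scenario"}.
#' @export
default_scenario <- function(n_samples = 238, seed = 1L, ...) {
  bmi <- grs_panel("BMI")
  whr <- grs_panel("WHR")
  causal_bmi <- c("rs571312", "rs3810291", "rs1555543", "rs206936",
                  "rs987237", "rs4836133", "rs2241423")
  causal_whr <- c("rs1443512", "rs4846567", "rs1011731")
  panel <- rbind(bmi, whr)
  panel$effect <- 0
  i <- match(causal_bmi, panel$snp_id)
  panel$effect[i] <- -0.32 * 100 * panel$beta[i]
  j <- match(causal_whr, panel$snp_id)
  panel$effect[j] <- -0.59 * 100 * panel$beta[j]
  sim_scenario(n_samples = n_samples,
               snps = panel[, c("snp_id", "maf", "effect", "beta",
                                "effect_allele", "other_allele", "trait",
                                "gene")],
               age_slope = -0.23, bmi_slope = -0.73,
               noise_sd = 15.7, seed = seed, ...)
}

.rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a genotype + phenotype cohort
#'
#' Draws genotypes per SNP i.i.d. with P(2) = p^2, P(1) = 2p(1-p),
#' P(0) = (1-p)^2 at the scenario's effect-allele frequency p, builds
#' EBMIL as intercept + sum(effect x dosage) + covariate terms + Gaussian
#' noise, and back-computes the final BMI by inverting the EBMIL formula
#' around the sampled initial BMI.  The intercept is solved so that the
#' expected EBMIL equals \code{scenario$ebmil_mean}.  Identical seeds give
#' bit-identical cohorts.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Optional override of the scenario seed.
#' @return A list of class \code{"sim_cohort"}: \code{dosages} (integer
#'   sample x SNP matrix of effect-allele counts, NA = missing call),
#'   \code{phenotypes} (cohort data frame with derived \code{ebmil} and
#'   \code{pct_bmi_loss}), and \code{truth} (the scenario, the solved
#'   intercept and the per-sample linear predictor).
#' @export
simulate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  set.seed(sc$seed)
  n <- sc$n_samples
  snps <- sc$snps
  p <- ncol_snps <- nrow(snps)

  dos <- matrix(NA_integer_, n, ncol_snps,
                dimnames = list(sprintf("S%03d", seq_len(n)), snps$snp_id))
  for (j in seq_len(ncol_snps))
    dos[, j] <- stats::rbinom(n, 2L, snps$maf[j])

  age <- .rtrunc_norm(n, sc$age_mean, sc$age_sd, lower = 18)
  bmi0 <- .rtrunc_norm(n, sc$bmi_mean, sc$bmi_sd, lower = 30)
  sex <- ifelse(stats::runif(n) < sc$frac_female, "female", "male")
  surgery <- ifelse(stats::runif(n) < sc$frac_distal, "distal", "proximal")

  # intercept solves E[EBMIL] = ebmil_mean under the scenario
  intercept <- sc$ebmil_mean -
    sum(snps$effect * 2 * snps$maf) -
    sc$male_offset * (1 - sc$frac_female) -
    sc$distal_offset * sc$frac_distal
  eta <- intercept +
    as.vector(dos %*% snps$effect) +
    sc$age_slope * (age - sc$age_mean) +
    sc$bmi_slope * (bmi0 - sc$bmi_mean) +
    sc$male_offset * (sex == "male") +
    sc$distal_offset * (surgery == "distal")

  ebmil <- eta + stats::rnorm(n, 0, sc$noise_sd)
  final <- invert_ebmil(bmi0, ebmil)
  tries <- 0L
  while (any(bad <- final <= 0)) {
    if (sc$on_implausible == "error")
      stop("scenario implies non-positive final BMI for ", sum(bad),
           " sample(s); the scenario is implausible")
    tries <- tries + 1L
    if (tries > 100L) stop("could not resample plausible final BMIs")
    ebmil[bad] <- eta[bad] + stats::rnorm(sum(bad), 0, sc$noise_sd)
    final <- invert_ebmil(bmi0, ebmil)
  }

  if (sc$missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol_snps) < sc$missing_rate,
                   n, ncol_snps)
    dos[mask] <- NA_integer_
  }

  ph <- data.frame(sample_id = rownames(dos), age = age, sex = sex,
                   initial_bmi = bmi0, final_bmi = final,
                   surgery_type = surgery, stringsAsFactors = FALSE)
  ph <- derive_outcomes(ph)
  structure(list(dosages = dos, phenotypes = ph,
                 truth = list(scenario = sc, intercept = intercept,
                              linear_predictor = eta)),
            class = "sim_cohort")
}

#' @method print sim_cohort
#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "SNPs\n")
  cat(sprintf("  mean EBMIL %.1f %% (SD %.1f)\n",
              mean(x$phenotypes$ebmil), stats::sd(x$phenotypes$ebmil)))
  invisible(x)
}

.write_minimal_vcf <- function(dosages, snps, path) {
  n <- nrow(dosages)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=grsforest",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(j) {
    d <- dosages[, snps$snp_id[j]]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c("1", j * 1000L, snps$snp_id[j], snps$other_allele[j],
            snps$effect_allele[j], ".", ".", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Genotypes are emitted as a minimal VCF 4.2 (one record per SNP, GT-only
#' FORMAT; REF is the scenario's other allele and ALT the effect allele, so
#' effect-allele dosages are recoverable on re-read), phenotypes as a
#' tab-separated table, and the scenario as a YAML file.  Reading the pair
#' back through [code_dosages()] reproduces the dosage matrix exactly,
#' including missing-call masks (written as \code{./.}).
#'
#' @param cohort A \code{"sim_cohort"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written
#'   (\code{vcf}, \code{phenotypes}, \code{scenario}).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, "genotypes.vcf")
  tsv <- file.path(dir, "phenotypes.tsv")
  yml <- file.path(dir, "scenario.yaml")
  .write_minimal_vcf(cohort$dosages, cohort$truth$scenario$snps, vcf)
  ph <- cohort$phenotypes[, c("sample_id", "age", "sex", "initial_bmi",
                              "final_bmi", "surgery_type")]
  ph$sex <- as.character(ph$sex)
  ph$surgery_type <- as.character(ph$surgery_type)
  utils::write.table(ph, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- cohort$truth$scenario
  sc_list <- unclass(sc)
  sc_list$snps <- lapply(seq_len(nrow(sc$snps)),
                         function(i) as.list(sc$snps[i, ]))
  yaml::write_yaml(sc_list, yml)
  invisible(list(vcf = vcf, phenotypes = tsv, scenario = yml))
}

#' Read a scenario back from YAML
#'
#' @param path Path to a scenario YAML written by [write_cohort()] or
#'   edited by hand.
#' @return A \code{"sim_scenario"}.
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  snps <- do.call(rbind, lapply(x$snps, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  sim_scenario(n_samples = x$n_samples, snps = snps,
               ebmil_mean = x$ebmil_mean,
               age_mean = x$age_mean, age_sd = x$age_sd,
               bmi_mean = x$bmi_mean, bmi_sd = x$bmi_sd,
               frac_female = x$frac_female, frac_distal = x$frac_distal,
               age_slope = x$age_slope, bmi_slope = x$bmi_slope,
               male_offset = x$male_offset, distal_offset = x$distal_offset,
               noise_sd = x$noise_sd, missing_rate = x$missing_rate,
               seed = x$seed, on_implausible = x$on_implausible)
}
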