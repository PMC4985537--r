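#' Fit a weighted genetic risk score model
#'
#' The package's central fitting function.  Runs the whole estimator for
#' one trait panel: effect-allele dosage coding, genotype QC
#' (warn-and-continue), beta-weighted scoring, random-forest permutation
#' importance with the percent-MSE cutoff, direction check with allele
#' inversion, risk-score construction, and the covariate-adjusted linear
#' model plus quartile analysis of the chosen outcome.
#'
#' @param genotypes VCF path, dosage table, or an already-coded dosage
#'   matrix (samples x SNPs, values 0/1/2/NA).
#' @param phenotypes Raw phenotype data frame (see [derive_outcomes()]) or
#'   an already-derived cohort.
#' @param weights A \code{"snp_weights"} table or TSV path for one trait
#'   panel.
#' @param outcome \code{"ebmil"} (default) or \code{"pct_bmi_loss"}.
#' @param forest A [forest_config()].
#' @param scale_factor GRS scale factor (default 100).
#' @param q_level BH Q-level for quartile contrasts.
#' @param qc Run genotype QC first (default TRUE, warn-and-continue).
#' @param qc_thresholds A [qc_thresholds()] list.
#' @param seed Optional integer overriding the forest seed.
#' @return An object of class \code{"grs_fit"} with components
#'   \code{importance}, \code{selected}, \code{inverted}, \code{grs},
#'   \code{association} (continuous model), \code{quartiles}, \code{qc},
#'   \code{cohort}, and the configuration used.  Standard methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}.
#' @examples
#' sc <- default_scenario(seed = 7)
#' cohort <- simulate_cohort(sc)
#' fit <- grs_fit(cohort$dosages, cohort$phenotypes, grs_panel("BMI"),
#'                forest = forest_config(n_trees = 300, seed = 7))
#' fit
#' coef(fit)["grs"]
#' @export
grs_fit <- function(genotypes, phenotypes, weights,
                    outcome = c("ebmil", "pct_bmi_loss"),
                    forest = forest_config(), scale_factor = 100,
                    q_level = 0.05, qc = TRUE,
                    qc_thresholds = grsforest::qc_thresholds(),
                    seed = NULL) {
  outcome <- match.arg(outcome)
  weights <- read_weights(weights)
  if (!is.null(seed)) forest$seed <- as.integer(seed)
  dosages <- if (is.matrix(genotypes)) {
    # already-coded matrix: subset to the panel, validating coverage
    missing_snps <- setdiff(weights$snp_id, colnames(genotypes))
    if (length(missing_snps))
      stop("dosage matrix lacks panel SNP(s): ",
           paste(missing_snps, collapse = ", "))
    m <- genotypes[, weights$snp_id, drop = FALSE]
    storage.mode(m) <- "integer"
    m
  } else {
    code_dosages(genotypes, weights)
  }
  cohort <- if ("ebmil" %in% names(phenotypes)) as.data.frame(phenotypes)
            else derive_outcomes(phenotypes)
  if (!is.null(rownames(dosages)) &&
        !identical(as.character(cohort$sample_id), rownames(dosages))) {
    i <- match(as.character(cohort$sample_id), rownames(dosages))
    if (anyNA(i)) stop("sample ids disagree between genotypes and phenotypes")
    dosages <- dosages[i, , drop = FALSE]
  }
  qc_report <- if (qc) run_qc(dosages, qc_thresholds) else NULL

  y <- cohort[[outcome]]
  scores <- weight_scores(dosages, weights)
  importance <- rf_importance(scores, y, forest)
  selected <- select_snps(importance, forest$importance_threshold)
  if (length(selected) == 0L)
    stop("no SNPs passed the ", forest$importance_threshold,
         " % MSE importance cutoff; no score can be built")
  inv <- check_direction_and_invert(dosages, weights, y, selected,
                                    importance)
  grs <- compute_grs(inv$dosages, weights, selected,
                     scale_factor = scale_factor)
  association <- fit_adjusted_model(y, grs, cohort, label = outcome)
  quartiles <- quartile_analysis(y, grs, cohort, q_level = q_level,
                                 label = outcome)
  structure(list(call = match.call(), outcome = outcome, weights = weights,
                 qc = qc_report, importance = inv$importance,
                 selected = selected, inverted = inv$inverted,
                 dosages = inv$dosages, grs = grs, cohort = cohort,
                 association = association, quartiles = quartiles,
                 forest = forest, scale_factor = scale_factor,
                 q_level = q_level),
            class = "grs_fit")
}

#' @method print grs_fit
#' @export
print.grs_fit <- function(x, ...) {
  cat("Weighted GRS fit (outcome: ", x$outcome, ")\n", sep = "")
  cat("  panel: ", nrow(x$weights), " SNPs; selected: ",
      length(x$selected), " (", paste(x$selected, collapse = ", "), ")\n",
      sep = "")
  if (length(x$inverted))
    cat("  inverted coding: ", paste(x$inverted, collapse = ", "), "\n",
        sep = "")
  cat(sprintf("  score range %.1f to %.1f (scale factor %g)\n",
              min(x$grs$grs), max(x$grs$grs), x$scale_factor))
  print(x$association)
  invisible(x)
}

#' @method summary grs_fit
#' @export
summary.grs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.grs_fit")
}

#' @method print summary.grs_fit
#' @export
print.summary.grs_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nImportance table (% increase in OOB MSE):\n")
  imp <- as.data.frame(f$importance)
  print(imp[order(-imp$pct_inc_mse),
            c("snp_id", "pct_inc_mse", "selected", "inverted")],
        row.names = FALSE, digits = 4)
  cat("\nAdjusted model coefficients:\n")
  print(f$association$coefficients, row.names = FALSE, digits = 4)
  cat("\n")
  print(f$quartiles)
  invisible(x)
}

#' @method coef grs_fit
#' @export
coef.grs_fit <- function(object, ...) stats::coef(object$association$fit)

#' @method fitted grs_fit
#' @export
fitted.grs_fit <- function(object, ...) stats::fitted(object$association$fit)

#' @method residuals grs_fit
#' @export
residuals.grs_fit <- function(object, ...)
  stats::residuals(object$association$fit)

#' Predict expected outcome for new subjects
#'
#' Applies the fitted selection and inversion to new genotypes, rebuilds
#' the score with the training scale factor, and evaluates the adjusted
#' linear model at the new covariates.
#'
#' @param object A \code{"grs_fit"}.
#' @param genotypes New dosage source (matrix/table/VCF) covering the
#'   panel SNPs, in the original (pre-inversion) coding.
#' @param phenotypes New covariate data frame (\code{age}, \code{sex},
#'   \code{initial_bmi}, \code{surgery_type}).
#' @param ... Unused.
#' @return Numeric vector of predicted outcome values (percent).
#' @method predict grs_fit
#' @export
predict.grs_fit <- function(object, genotypes, phenotypes, ...) {
  dosages <- if (is.matrix(genotypes)) {
    m <- genotypes[, object$weights$snp_id, drop = FALSE]
    storage.mode(m) <- "integer"
    m
  } else code_dosages(genotypes, object$weights)
  for (snp in object$inverted)
    dosages[, snp] <- 2L - dosages[, snp]
  grs <- compute_grs(dosages, object$weights, object$selected,
                     scale_factor = object$scale_factor)
  newdata <- data.frame(grs = grs$grs, age = phenotypes$age,
                        sex = factor(as.character(phenotypes$sex),
                                     levels = .sex_levels),
                        initial_bmi = phenotypes$initial_bmi,
                        surgery_type = factor(
                          as.character(phenotypes$surgery_type),
                          levels = .surgery_levels))
  unname(stats::predict(object$association$fit, newdata = newdata))
}

#' Plot a fitted risk-score model
#'
#' Two panels: outcome against the score with the adjusted-model trend
#' evaluated at reference covariates, and quartile mean outcomes with
#' standard-error bars.
#'
#' @param x A \code{"grs_fit"}.
#' @param which \code{1} (scatter), \code{2} (quartile bars) or both.
#' @param ... Passed to [graphics::plot()].
#' @method plot grs_fit
#' @export
plot.grs_fit <- function(x, which = c(1, 2), ...) {
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  y <- x$cohort[[x$outcome]]
  ylab <- if (x$outcome == "ebmil") "EBMIL (%)" else "BMI loss (%)"
  if (1 %in% which) {
    graphics::plot(x$grs$grs, y, xlab = "GRS", ylab = ylab,
                   pch = 19, col = "grey40", ...)
    cf <- stats::coef(x$association$fit)
    ref <- cf["(Intercept)"] + cf["age"] * mean(x$cohort$age) +
      cf["initial_bmi"] * mean(x$cohort$initial_bmi)
    graphics::abline(a = ref, b = cf["grs"], lwd = 2)
  }
  if (2 %in% which) {
    qm <- x$quartiles$quartile_means
    se <- tapply(y, x$grs$quartile,
                 function(v) stats::sd(v) / sqrt(length(v)))
    bp <- graphics::barplot(qm, ylim = c(0, max(qm + 2 * se) * 1.1),
                            ylab = ylab, xlab = "GRS quartile")
    graphics::arrows(bp, qm - se, bp, qm + se, angle = 90, code = 3,
                     length = 0.05)
  }
  invisible(x)
}
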