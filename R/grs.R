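#' Weighted genetic risk score
#'
#' For the selected variants (after direction inversion), the score is
#' \code{scale_factor x sum(dosage x |beta|)}.  Betas enter as magnitudes
#' because inversion has already oriented every coding so the risk allele
#' lowers weight loss; each additional risk allele therefore adds a
#' non-negative amount and "higher score = less expected weight loss" holds
#' by construction.  The default scale factor of 100 puts scores on an
#' integer-like scale; the unscaled sum is reported alongside.
#'
#' @param dosages Dosage matrix, post-inversion coding.
#' @param weights A \code{"snp_weights"} table.
#' @param selected Character vector of selected snp_ids (non-empty).
#' @param scale_factor Positive multiplier applied to the weighted sum.
#' @param impute Mean-impute missing calls (default TRUE).
#' @return Data frame of class \code{"grs_vector"}: \code{sample_id},
#'   \code{grs}, \code{grs_raw} (unscaled) and \code{quartile}
#'   (\code{Q1}..\code{Q4}).
#' @export
compute_grs <- function(dosages, weights, selected, scale_factor = 100,
                        impute = TRUE) {
  weights <- read_weights(weights)
  if (length(selected) == 0L)
    stop("empty selection: no SNPs passed the importance cutoff")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  missing_snps <- setdiff(selected, colnames(dosages))
  if (length(missing_snps))
    stop("selected SNP(s) absent from dosages: ",
         paste(missing_snps, collapse = ", "))
  betas <- weights$beta[match(selected, weights$snp_id)]
  if (anyNA(betas))
    stop("selected SNP(s) absent from weights: ",
         paste(selected[is.na(betas)], collapse = ", "))
  d <- dosages[, selected, drop = FALSE]
  if (impute) d <- impute_dosages(d) else storage.mode(d) <- "double"
  raw <- as.vector(d %*% abs(betas))
  grs <- scale_factor * raw
  out <- data.frame(sample_id = rownames(dosages), grs = grs,
                    grs_raw = raw, quartile = grs_quartile(grs),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("grs_vector", "data.frame")
  attr(out, "selected") <- selected
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Empirical quartile assignment
#'
#' Cut points are the empirical 25/50/75 % quantiles of the scores; a
#' sample exactly at a cut point goes to the lower quartile, which keeps
#' the assignment deterministic for heavily tied integer-like scores.
#'
#' @param grs Numeric score vector.
#' @return Factor with levels \code{Q1}..\code{Q4}.
#' @export
grs_quartile <- function(grs) {
  cuts <- stats::quantile(grs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q <- 1L + (grs > cuts[1]) + (grs > cuts[2]) + (grs > cuts[3])
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

.assoc_frame <- function(outcome, grs, covariates) {
  required <- c("age", "sex", "initial_bmi", "surgery_type")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols))
    stop("covariates lack column(s): ", paste(missing_cols, collapse = ", "))
  g <- if (inherits(grs, "grs_vector") || is.data.frame(grs)) grs$grs
       else as.numeric(grs)
  df <- data.frame(outcome = outcome, grs = g,
                   age = covariates$age,
                   sex = factor(as.character(covariates$sex),
                                levels = .sex_levels),
                   initial_bmi = covariates$initial_bmi,
                   surgery_type = factor(as.character(covariates$surgery_type),
                                         levels = .surgery_levels))
  if (anyNA(df)) stop("missing values in outcome, score or covariates")
  df
}

.check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Covariate-adjusted association of the risk score with an outcome
#'
#' Ordinary least squares of the outcome (EBMIL or percent BMI loss) on the
#' continuous risk score, adjusting for age, sex, initial BMI and surgery
#' type (two-level indicators).  The reported slope is unstandardised:
#' percent outcome per score unit.
#'
#' @param outcome Numeric outcome vector.
#' @param grs A \code{"grs_vector"} or numeric score vector.
#' @param covariates Data frame with \code{age}, \code{sex},
#'   \code{initial_bmi}, \code{surgery_type}.
#' @param label Optional model label carried into reports.
#' @return A list of class \code{"grs_assoc"}: \code{label}, \code{fit}
#'   (the \code{lm}), \code{coefficients} (estimate/SE/t/p table),
#'   \code{r_squared}, \code{n}.
#' @export
fit_adjusted_model <- function(outcome, grs, covariates, label = "EBMIL") {
  df <- .assoc_frame(outcome, grs, covariates)
  if (nrow(df) <= 6L) stop("need more samples than model parameters")
  X <- stats::model.matrix(
    ~ grs + age + sex + initial_bmi + surgery_type, df)
  .check_rank(X)
  fit <- stats::lm(outcome ~ grs + age + sex + initial_bmi + surgery_type,
                   data = df)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co, row.names = NULL)
  structure(list(label = label, fit = fit, coefficients = co,
                 r_squared = sm$r.squared, n = nrow(df)),
            class = "grs_assoc")
}

#' @method print grs_assoc
#' @export
print.grs_assoc <- function(x, ...) {
  cat("Adjusted association (", x$label, "), n = ", x$n, "\n", sep = "")
  g <- x$coefficients[x$coefficients$term == "grs", ]
  cat(sprintf("  GRS slope %.4g (SE %.3g), p = %.4g, R^2 = %.3f\n",
              g$estimate, g$se, g$p, x$r_squared))
  invisible(x)
}

#' Quartile analysis of the risk score
#'
#' Splits the cohort into score quartiles, fits the covariate-adjusted
#' model with the quartile as a 4-level factor (lowest quartile as
#' reference), and runs the post-hoc contrasts of Q1 against Q2, Q3 and Q4:
#' equal-variance two-sample t tests on the raw outcome (the primary
#' report), plus the covariate-adjusted factor-model contrasts, each family
#' Benjamini-Hochberg adjusted at the configured Q-level.
#'
#' @inheritParams fit_adjusted_model
#' @param q_level BH false-discovery Q-level (default 0.05).
#' @return A list of class \code{"grs_quartiles"}: \code{fit} (factor
#'   model), \code{contrasts} (raw-outcome t tests with \code{p_bh}),
#'   \code{adjusted_contrasts} (factor-model coefficient contrasts with
#'   \code{p_bh}), \code{quartile_means}, \code{q_level}, \code{n}.
#' @export
quartile_analysis <- function(outcome, grs, covariates, q_level = 0.05,
                              label = "EBMIL") {
  df <- .assoc_frame(outcome, grs, covariates)
  if (nrow(df) < 8L) stop("quartile analysis needs at least 8 samples")
  df$quartile <- if (inherits(grs, "grs_vector") &&
                       "quartile" %in% names(grs)) grs$quartile
                 else grs_quartile(df$grs)
  counts <- table(df$quartile)
  if (any(counts == 0L))
    stop("empty quartile after tie-breaking: pathological score ",
         "distribution (", paste(names(counts)[counts == 0], collapse = ", "),
         ")")
  X <- stats::model.matrix(
    ~ quartile + age + sex + initial_bmi + surgery_type, df)
  .check_rank(X)
  fit <- stats::lm(
    outcome ~ quartile + age + sex + initial_bmi + surgery_type, data = df)

  y1 <- df$outcome[df$quartile == "Q1"]
  tt <- lapply(c("Q2", "Q3", "Q4"), function(qk) {
    yk <- df$outcome[df$quartile == qk]
    ht <- stats::t.test(y1, yk, var.equal = TRUE)
    data.frame(contrast = paste0("Q1-", qk),
               mean_q1 = mean(y1), mean_qk = mean(yk),
               diff = mean(y1) - mean(yk),
               t = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  contrasts <- do.call(rbind, tt)
  contrasts$p_bh <- stats::p.adjust(contrasts$p, method = "BH")
  contrasts$significant <- contrasts$p_bh < q_level

  sm <- summary(fit)$coefficients
  qrows <- grep("^quartileQ", rownames(sm))
  adj <- data.frame(contrast = sub("quartile", "Q1-", rownames(sm)[qrows]),
                    estimate = sm[qrows, 1], se = sm[qrows, 2],
                    t = sm[qrows, 3], p = sm[qrows, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  adj$p_bh <- stats::p.adjust(adj$p, method = "BH")
  adj$significant <- adj$p_bh < q_level

  qm <- tapply(df$outcome, df$quartile, mean)
  structure(list(label = label, fit = fit, contrasts = contrasts,
                 adjusted_contrasts = adj,
                 quartile_means = qm, quartile_counts = counts,
                 q_level = q_level, n = nrow(df)),
            class = "grs_quartiles")
}

#' @method print grs_quartiles
#' @export
print.grs_quartiles <- function(x, ...) {
  cat("Quartile analysis (", x$label, "), n = ", x$n, "\n", sep = "")
  cat("  quartile means:",
      paste(sprintf("%s %.1f", names(x$quartile_means), x$quartile_means),
            collapse = ", "), "\n")
  print(x$contrasts[, c("contrast", "diff", "p", "p_bh", "significant")])
  invisible(x)
}

#' Run both trait panels through the full chain
#'
#' Independently per trait (BMI, WHR): weight the dosages, rank variants by
#' forest importance on EBMIL, select above the cutoff, check and invert
#' directions, build the score, and fit the adjusted continuous and
#' quartile models against EBMIL and — reusing the EBMIL-based selection —
#' against percent BMI loss as the confirmatory outcome.  A panel whose
#' selection is empty is skipped with an explicit notice rather than
#' silently omitted.
#'
#' @param cohort Cohort data frame from [derive_outcomes()].
#' @param dosages Dosage matrix covering both panels.
#' @param bmi_weights,whr_weights \code{"snp_weights"} tables.
#' @param forest A [forest_config()]; its seed is salted per trait.
#' @param scale_factor GRS scale factor.
#' @param q_level BH Q-level for quartile contrasts.
#' @return A list of class \code{"grs_panel_results"} with one entry per
#'   trait, each holding \code{importance}, \code{selected},
#'   \code{inverted} and \code{models} (continuous + quartile fits for both
#'   outcomes), or a \code{skipped} notice.
#' @export
run_both_scores <- function(cohort, dosages, bmi_weights, whr_weights,
                            forest = forest_config(), scale_factor = 100,
                            q_level = 0.05) {
  panels <- list(bmi = read_weights(bmi_weights),
                 whr = read_weights(whr_weights))
  out <- list()
  for (trait in names(panels)) {
    w <- panels[[trait]]
    cfg <- forest
    cfg$seed <- stage_seed(forest$seed, paste0("forest_", trait))
    scores <- weight_scores(dosages, w)
    imp <- rf_importance(scores, cohort$ebmil, cfg)
    sel <- select_snps(imp, cfg$importance_threshold)
    if (length(sel) == 0L) {
      message("panel '", trait, "': no SNPs selected at threshold ",
              cfg$importance_threshold, " % MSE; models skipped")
      out[[trait]] <- list(importance = imp, selected = character(0),
                           inverted = character(0),
                           skipped = TRUE, models = list())
      next
    }
    inv <- check_direction_and_invert(dosages, w, cohort$ebmil, sel, imp)
    grs <- compute_grs(inv$dosages, w, sel, scale_factor = scale_factor)
    try_quartile <- function(y, lab) {
      # a near-degenerate score (e.g. a single selected SNP) can leave a
      # quartile empty; record the reason instead of aborting the run
      tryCatch(quartile_analysis(y, grs, cohort, q_level = q_level,
                                 label = lab),
               error = function(e) {
                 message("panel '", trait, "': quartile model for ", lab,
                         " skipped: ", conditionMessage(e))
                 structure(list(label = lab,
                                reason = conditionMessage(e)),
                           class = "grs_skipped")
               })
    }
    models <- list(
      ebmil_continuous = fit_adjusted_model(
        cohort$ebmil, grs, cohort, label = paste0(toupper(trait), "/EBMIL")),
      ebmil_quartile = try_quartile(
        cohort$ebmil, paste0(toupper(trait), "/EBMIL")),
      pct_continuous = fit_adjusted_model(
        cohort$pct_bmi_loss, grs, cohort,
        label = paste0(toupper(trait), "/pct BMI loss")),
      pct_quartile = try_quartile(
        cohort$pct_bmi_loss, paste0(toupper(trait), "/pct BMI loss")))
    out[[trait]] <- list(importance = inv$importance, selected = sel,
                         inverted = inv$inverted, grs = grs,
                         skipped = FALSE, models = models)
  }
  structure(out, class = "grs_panel_results")
}
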