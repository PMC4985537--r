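#' Random forest configuration
#'
#' Hyperparameters for the importance-filtering forest.  The published
#' analysis grew 10,000 regression trees and kept predictors whose
#' permutation importance exceeded 10 % MSE; both are defaults here, with
#' the remaining hyperparameters at the regression-forest conventions
#' (features per split = ceiling(p/3), minimum leaf size 5, bootstrap with
#' replacement at full n).
#'
#' @param n_trees Number of trees (>= 1); default 10000.
#' @param mtry Features tried per split; \code{NULL} means
#'   \code{ceiling(p/3)}.
#' @param min_leaf_size Minimum terminal-node size; default 5.
#' @param importance_threshold Percent-MSE cutoff for selection (strict
#'   inequality); default 10.
#' @param importance_type \code{"relative"} for 100 x mean out-of-bag
#'   permutation MSE increase / overall out-of-bag MSE (the form the 10 %
#'   cutoff is read against), or \code{"scaled"} for the classic
#'   SE-normalised variant.
#' @param seed Integer seed for bootstrap and permutation draws.
#' @return A list of class \code{"forest_config"}.
#' @export
forest_config <- function(n_trees = 10000, mtry = NULL, min_leaf_size = 5,
                          importance_threshold = 10,
                          importance_type = c("relative", "scaled"),
                          seed = 1L) {
  importance_type <- match.arg(importance_type)
  stopifnot(n_trees >= 1, min_leaf_size >= 1, importance_threshold >= 0)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf_size = as.integer(min_leaf_size),
                 importance_threshold = importance_threshold,
                 importance_type = importance_type,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Beta-weighted SNP scores
#'
#' Multiplies each effect-allele dosage by its published per-allele beta.
#' Missing calls are mean-imputed per SNP first (so imputed cells carry
#' imputed-dosage x beta); set \code{impute = FALSE} to keep \code{NA}s.
#'
#' @param dosages Dosage matrix from [code_dosages()].
#' @param weights A \code{"snp_weights"} table covering columns of
#'   \code{dosages}.
#' @param impute Mean-impute missing calls first (default TRUE).
#' @return Numeric matrix of weighted scores, columns ordered as
#'   \code{weights$snp_id}.
#' @export
weight_scores <- function(dosages, weights, impute = TRUE) {
  weights <- read_weights(weights)
  missing_snps <- setdiff(weights$snp_id, colnames(dosages))
  if (length(missing_snps))
    stop("weights and dosage matrix misaligned; missing SNP(s): ",
         paste(missing_snps, collapse = ", "))
  d <- dosages[, weights$snp_id, drop = FALSE]
  if (impute) d <- impute_dosages(d)
  sweep(d, 2, weights$beta, `*`)
}

#' Random-forest permutation importance of weighted SNP scores
#'
#' Grows a regression forest with the weighted scores as predictors and
#' EBMIL (or another continuous outcome) as the target, then expresses each
#' predictor's permutation importance as a percent increase in mean squared
#' error: 100 x (mean over trees of the out-of-bag MSE increase after
#' permuting the predictor within the out-of-bag samples) / overall
#' out-of-bag MSE.  Identical seeds give identical importances.
#'
#' @param scores Weighted score matrix from [weight_scores()] (no missing
#'   values).
#' @param outcome Numeric outcome vector, one value per row of
#'   \code{scores}, no missing values.
#' @param config A [forest_config()].
#' @return A data frame of class \code{"importance_table"}: \code{snp_id},
#'   \code{pct_inc_mse}, \code{selected} (importance strictly above the
#'   configured threshold), \code{constant} (degenerate predictor flag),
#'   \code{direction_slope} and \code{inverted} (filled by
#'   [check_direction_and_invert()]).  The forest object is attached as
#'   attribute \code{"forest"}.
#' @export
rf_importance <- function(scores, outcome, config = forest_config()) {
  stopifnot(is.matrix(scores), nrow(scores) >= 2, ncol(scores) >= 1)
  if (length(outcome) != nrow(scores))
    stop("outcome length does not match score rows")
  if (anyNA(outcome)) stop("missing outcome values")
  if (anyNA(scores)) stop("missing predictor values; impute first")
  p <- ncol(scores)
  constant <- apply(scores, 2, function(s) stats::var(s) == 0)
  mtry <- if (is.null(config$mtry)) ceiling(p / 3) else config$mtry
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = scores, y = outcome, ntree = config$n_trees, mtry = mtry,
    nodesize = config$min_leaf_size, importance = TRUE)
  if (any(rf$oob.times == 0))
    warning("some samples were never out-of-bag; increase n_trees")
  if (config$importance_type == "relative") {
    oob_mse <- rf$mse[config$n_trees]
    pct <- 100 * rf$importance[, "%IncMSE"] / oob_mse
  } else {
    pct <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  }
  pct[constant] <- 0
  if (any(constant))
    warning("constant predictor(s), importance set to 0: ",
            paste(colnames(scores)[constant], collapse = ", "))
  out <- data.frame(snp_id = colnames(scores),
                    pct_inc_mse = unname(pct),
                    selected = unname(pct) > config$importance_threshold,
                    constant = unname(constant),
                    direction_slope = NA_real_,
                    inverted = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  attr(out, "threshold") <- config$importance_threshold
  attr(out, "forest") <- rf
  out
}

#' Select SNPs above the importance cutoff
#'
#' Strict inequality, reflecting the "above 10 % MSE" selection rule: a
#' variant at exactly the threshold is excluded.
#'
#' @param importance An \code{"importance_table"} (or any data frame with
#'   \code{snp_id} and \code{pct_inc_mse}).
#' @param threshold Percent-MSE cutoff; defaults to the table's own
#'   threshold attribute, else 10.
#' @return Character vector of selected snp_ids, ordered by decreasing
#'   importance.
#' @export
select_snps <- function(importance, threshold = NULL) {
  if (is.null(threshold))
    threshold <- attr(importance, "threshold")
  if (is.null(threshold)) threshold <- 10
  keep <- importance$pct_inc_mse > threshold
  ids <- importance$snp_id[keep]
  ids[order(importance$pct_inc_mse[keep], decreasing = TRUE)]
}

#' Direction check with allele-coding inversion
#'
#' For each selected SNP, a preliminary univariate regression of the
#' outcome on the SNP's weighted score determines its trajectory.  A
#' positive slope means the reported effect allele favours weight loss;
#' that SNP's coding is inverted (dosage n becomes 2 - n) and flagged, so
#' that after this step every selected variant's risk allele is the
#' weight-loss-lowering allele and the risk score accumulates harmful
#' alleles only.
#'
#' @param dosages Dosage matrix (original coding).
#' @param weights A \code{"snp_weights"} table.
#' @param outcome Numeric outcome vector (EBMIL).
#' @param selected Character vector of selected snp_ids.
#' @param importance Optional \code{"importance_table"} whose
#'   \code{direction_slope} and \code{inverted} columns are filled in.
#' @return List with \code{dosages} (recoded matrix), \code{inverted}
#'   (character vector of flipped snp_ids) and \code{importance} (updated
#'   table, or \code{NULL}).
#' @export
check_direction_and_invert <- function(dosages, weights, outcome, selected,
                                       importance = NULL) {
  weights <- read_weights(weights)
  inverted <- character(0)
  slopes <- stats::setNames(numeric(length(selected)), selected)
  for (snp in selected) {
    if (!snp %in% colnames(dosages)) stop("selected SNP not in dosages: ", snp)
    beta <- weights$beta[match(snp, weights$snp_id)]
    if (is.na(beta)) stop("selected SNP not in weights: ", snp)
    score <- dosages[, snp] * beta
    keep <- !is.na(score)
    if (stats::var(score[keep]) == 0)
      stop("degenerate direction regression: constant score for ", snp)
    slope <- unname(stats::coef(stats::lm(outcome[keep] ~ score[keep]))[2])
    slopes[snp] <- slope
    if (slope > 0) {
      dosages[, snp] <- 2L - dosages[, snp]
      inverted <- c(inverted, snp)
    }
  }
  if (!is.null(importance)) {
    i <- match(selected, importance$snp_id)
    importance$direction_slope[i] <- unname(slopes)
    importance$inverted[i] <- selected %in% inverted
  }
  list(dosages = dosages, inverted = inverted, importance = importance)
}

#' Write an importance/selection table
#'
#' TSV layout mirrors the published variant table: snp_id, gene label (if
#' the weights carry one), percent-MSE importance, selection and inversion
#' flags.
#'
#' @param importance An \code{"importance_table"}.
#' @param weights Optional weights table supplying a \code{gene} column.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_importance <- function(importance, path, weights = NULL) {
  tab <- as.data.frame(importance)
  tab$gene <- if (!is.null(weights) && "gene" %in% names(weights))
    weights$gene[match(tab$snp_id, weights$snp_id)] else NA_character_
  tab <- tab[order(-tab$pct_inc_mse),
             c("snp_id", "gene", "pct_inc_mse", "selected", "inverted")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Importance-versus-cutoff plot
#'
#' Dot chart of per-SNP percent-MSE importances with a dashed vertical line
#' at the selection cutoff, the visual check that motivated the 10 % rule.
#'
#' @param importance An \code{"importance_table"}.
#' @param threshold Cutoff to draw; defaults to the table's attribute.
#' @param main Plot title.
#' @export
plot_importance <- function(importance, threshold = NULL,
                            main = "Permutation importance") {
  if (is.null(threshold)) threshold <- attr(importance, "threshold")
  if (is.null(threshold)) threshold <- 10
  ord <- order(importance$pct_inc_mse)
  graphics::dotchart(importance$pct_inc_mse[ord],
                     labels = importance$snp_id[ord],
                     xlab = "% increase in OOB MSE", main = main,
                     pch = 19)
  graphics::abline(v = threshold, lty = 2)
  invisible(NULL)
}
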