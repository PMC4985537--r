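#' Deterministic per-stage seed derivation
#'
#' One pipeline-level seed fans out to the stochastic stages by salting
#' with the stage name, so adding a stage never shifts another stage's
#' random stream.  The derived seed stays within 32-bit integer range.
#'
#' @param seed Integer pipeline seed.
#' @param stage Stage name (e.g. \code{"simulate"}, \code{"forest_bmi"}).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  salt <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + salt * 10007) %% 2147483647)
}

#' Build and validate a pipeline configuration
#'
#' Exactly one genotype/phenotype source must be supplied: either a
#' simulation scenario or real input paths.  Every analysis constant
#' (trees, importance cutoff, QC thresholds, scale factor, Q-level) is a
#' named, defaulted key.
#'
#' @param scenario A \code{"sim_scenario"}, the string \code{"default"}
#'   for the calibrated 238-subject scenario, or a scenario YAML path.
#' @param genotypes,phenotypes Paths to a VCF (or dosage TSV) and a
#'   phenotype TSV, for real data.
#' @param bmi_weights,whr_weights Weights tables or TSV paths; default to
#'   the bundled synthetic panels.
#' @param forest A [forest_config()].
#' @param qc_thresholds A [qc_thresholds()] list.
#' @param scale_factor GRS scale factor.
#' @param q_level BH Q-level.
#' @param seed Pipeline seed.
#' @param outdir Optional output directory for [render_report()].
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(scenario = NULL, genotypes = NULL, phenotypes = NULL,
                       bmi_weights = NULL, whr_weights = NULL,
                       forest = forest_config(),
                       qc_thresholds = grsforest::qc_thresholds(),
                       scale_factor = 100, q_level = 0.05,
                       seed = 1L, outdir = NULL) {
  have_sim <- !is.null(scenario)
  have_real <- !is.null(genotypes) || !is.null(phenotypes)
  if (have_sim && have_real)
    stop("config invalid: supply either a simulation scenario or real ",
         "genotype/phenotype paths, not both")
  if (!have_sim && !(!is.null(genotypes) && !is.null(phenotypes)))
    stop("config invalid: supply a scenario, or both genotypes and ",
         "phenotypes")
  if (q_level <= 0 || q_level >= 1) stop("q_level must lie in (0, 1)")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  structure(list(scenario = scenario, genotypes = genotypes,
                 phenotypes = phenotypes,
                 bmi_weights = bmi_weights, whr_weights = whr_weights,
                 forest = forest, qc_thresholds = qc_thresholds,
                 scale_factor = scale_factor, q_level = q_level,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.coef_table <- function(models) {
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "grs_assoc")) {
      co <- m$coefficients
      co$model <- nm
      co$r_squared <- m$r_squared
      rows[[nm]] <- co[, c("model", "term", "estimate", "se", "t", "p",
                           "r_squared")]
    } else if (inherits(m, "grs_quartiles")) {
      co <- m$contrasts
      co$model <- nm
      rows[[nm]] <- data.frame(model = co$model, term = co$contrast,
                               estimate = co$diff, se = NA_real_,
                               t = co$t, p = co$p, r_squared = NA_real_,
                               p_bh = co$p_bh)
    }
  }
  rows <- lapply(rows, function(r) {
    if (!"p_bh" %in% names(r)) r$p_bh <- NA_real_
    r
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, QC, weighting, forest selection, inversion,
#' scoring and association for both trait panels, and assembles a run
#' manifest: the configuration snapshot, per-stage dimension bookkeeping,
#' selected variants with inversion flags, and all model summaries.
#' Re-running with the same configuration and seed reproduces every number
#' bit-for-bit.
#'
#' @param config A [run_config()], or a YAML path holding the scalar
#'   configuration keys.
#' @return A list of class \code{"run_manifest"}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- .config_from_yaml(config)
  stopifnot(inherits(config, "run_config"))
  bmi_w <- read_weights(if (is.null(config$bmi_weights)) grs_panel("BMI")
                        else config$bmi_weights)
  whr_w <- read_weights(if (is.null(config$whr_weights)) grs_panel("WHR")
                        else config$whr_weights)

  stages <- list()
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (is.character(sc) && identical(sc, "default"))
      sc <- default_scenario(seed = stage_seed(config$seed, "simulate"))
    else if (is.character(sc)) sc <- read_scenario(sc)
    else sc$seed <- stage_seed(config$seed, "simulate")
    sim <- simulate_cohort(sc)
    dosages <- sim$dosages
    cohort <- sim$phenotypes
    stages$simulate <- list(n_samples = nrow(dosages),
                            n_snps = ncol(dosages))
  } else {
    all_w <- rbind(bmi_w[, c("snp_id", "effect_allele", "other_allele",
                             "beta", "trait")],
                   whr_w[, c("snp_id", "effect_allele", "other_allele",
                             "beta", "trait")])
    class(all_w) <- c("snp_weights", "data.frame")
    dosages <- code_dosages(config$genotypes, all_w)
    raw_ph <- utils::read.delim(config$phenotypes,
                                stringsAsFactors = FALSE)
    cohort <- derive_outcomes(raw_ph)
    stages$ingest <- list(n_samples = nrow(dosages),
                          n_snps = ncol(dosages))
  }
  if (!identical(as.character(cohort$sample_id), rownames(dosages))) {
    i <- match(as.character(cohort$sample_id), rownames(dosages))
    if (anyNA(i)) stop("sample ids disagree between genotypes and phenotypes")
    dosages <- dosages[i, , drop = FALSE]
  }

  qc <- run_qc(dosages, config$qc_thresholds)
  stages$qc <- list(n_snps = nrow(qc$snps),
                    n_flagged = sum(qc$snps$maf_fail | qc$snps$hwe_fail |
                                      qc$snps$missing_fail | qc$snps$ld_fail))

  cfg_forest <- config$forest
  cfg_forest$seed <- config$seed
  results <- run_both_scores(cohort, dosages, bmi_w, whr_w,
                             forest = cfg_forest,
                             scale_factor = config$scale_factor,
                             q_level = config$q_level)
  stages$selection <- list(
    bmi_candidates = nrow(bmi_w), whr_candidates = nrow(whr_w),
    bmi_selected = length(results$bmi$selected),
    whr_selected = length(results$whr$selected))

  models <- list()
  for (trait in names(results)) {
    r <- results[[trait]]
    if (isTRUE(r$skipped)) next
    tab <- .coef_table(r$models)
    tab$trait <- toupper(trait)
    models[[trait]] <- tab[, c("trait", setdiff(names(tab), "trait"))]
  }
  model_table <- if (length(models))
    do.call(rbind, c(models, make.row.names = FALSE)) else NULL

  cohort_summary <- list(
    n = nrow(cohort),
    pct_female = 100 * mean(cohort$sex == "female"),
    age_mean = mean(cohort$age), age_sd = stats::sd(cohort$age),
    initial_bmi_mean = mean(cohort$initial_bmi),
    initial_bmi_sd = stats::sd(cohort$initial_bmi),
    final_bmi_mean = mean(cohort$final_bmi),
    final_bmi_sd = stats::sd(cohort$final_bmi),
    ebmil_mean = mean(cohort$ebmil), ebmil_sd = stats::sd(cohort$ebmil),
    pct_bmi_loss_mean = mean(cohort$pct_bmi_loss),
    pct_bmi_loss_sd = stats::sd(cohort$pct_bmi_loss),
    pct_distal = 100 * mean(cohort$surgery_type == "distal"))

  structure(list(
    config = config,
    version = as.character(utils::packageVersion("grsforest")),
    seed = config$seed,
    stages = stages,
    cohort_summary = cohort_summary,
    qc = qc,
    results = results,
    model_table = model_table),
    class = "run_manifest")
}

.config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    scenario = x$scenario, genotypes = x$genotypes,
    phenotypes = x$phenotypes,
    bmi_weights = x$bmi_weights, whr_weights = x$whr_weights,
    forest = do.call(forest_config,
                     x$forest %||% list()),
    qc_thresholds = do.call(qc_thresholds, x$qc_thresholds %||% list()),
    scale_factor = x$scale_factor %||% 100,
    q_level = x$q_level %||% 0.05,
    seed = x$seed %||% 1L, outdir = x$outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print run_manifest
#' @export
print.run_manifest <- function(x, ...) {
  cat("grsforest run manifest (package ", x$version, ", seed ", x$seed,
      ")\n", sep = "")
  cs <- x$cohort_summary
  cat(sprintf("  cohort: n = %d, %.0f %% female, EBMIL %.1f (SD %.1f) %%\n",
              cs$n, cs$pct_female, cs$ebmil_mean, cs$ebmil_sd))
  st <- x$stages$selection
  cat(sprintf("  BMI panel: %d candidates -> %d selected; WHR panel: %d -> %d\n",
              st$bmi_candidates, st$bmi_selected,
              st$whr_candidates, st$whr_selected))
  for (trait in names(x$results)) {
    r <- x$results[[trait]]
    if (isTRUE(r$skipped)) {
      cat("  ", toupper(trait), ": no SNPs selected\n", sep = "")
    } else {
      g <- r$models$ebmil_continuous$coefficients
      g <- g[g$term == "grs", ]
      cat(sprintf("  %s/EBMIL: slope %.4g, p = %.4g\n", toupper(trait),
                  g$estimate, g$p))
    }
  }
  invisible(x)
}

#' Serialise a run manifest to JSON
#'
#' @param manifest A \code{"run_manifest"}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_manifest <- function(manifest, path) {
  cfg <- manifest$config
  out <- list(
    version = manifest$version, seed = manifest$seed,
    config = list(
      scenario = if (is.character(cfg$scenario)) cfg$scenario
                 else if (!is.null(cfg$scenario)) "custom scenario object"
                 else NULL,
      genotypes = cfg$genotypes, phenotypes = cfg$phenotypes,
      forest = unclass(cfg$forest), qc_thresholds = cfg$qc_thresholds,
      scale_factor = cfg$scale_factor, q_level = cfg$q_level),
    stages = manifest$stages,
    cohort_summary = manifest$cohort_summary,
    selected = lapply(manifest$results, function(r)
      list(selected = r$selected, inverted = r$inverted,
           skipped = isTRUE(r$skipped))),
    models = manifest$model_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Render a human-readable report from a manifest
#'
#' Writes the cohort-characteristics table, the per-panel
#' importance/selection tables, the association coefficient table and —
#' optionally — quartile and importance figures into a directory.  A panel
#' with an empty selection is reported as such rather than silently
#' omitted.  Rendering the same manifest twice produces byte-identical
#' tables.
#'
#' @param manifest A \code{"run_manifest"}.
#' @param dir Output directory; defaults to the config's \code{outdir}.
#' @param figures Also write PNG figures (default FALSE).
#' @return Invisibly, a named list of the files written.
#' @export
render_report <- function(manifest, dir = NULL, figures = FALSE) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (is.null(dir)) dir <- manifest$config$outdir
  if (is.null(dir)) stop("no output directory given")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()

  cs <- manifest$cohort_summary
  cohort_tab <- data.frame(
    variable = c("Included patients, n", "Female, %", "Age, years (SD)",
                 "Initial BMI, kg/m2 (SD)", "Final BMI, kg/m2 (SD)",
                 "EBMIL, % (SD)", "BMI loss, % (SD)", "Distal RYGB, %"),
    value = c(sprintf("%d", cs$n), sprintf("%.1f", cs$pct_female),
              sprintf("%.1f (%.1f)", cs$age_mean, cs$age_sd),
              sprintf("%.1f (%.1f)", cs$initial_bmi_mean, cs$initial_bmi_sd),
              sprintf("%.1f (%.1f)", cs$final_bmi_mean, cs$final_bmi_sd),
              sprintf("%.1f (%.1f)", cs$ebmil_mean, cs$ebmil_sd),
              sprintf("%.1f (%.1f)", cs$pct_bmi_loss_mean,
                      cs$pct_bmi_loss_sd),
              sprintf("%.1f", cs$pct_distal)),
    stringsAsFactors = FALSE)
  files$cohort <- file.path(dir, "cohort_characteristics.tsv")
  utils::write.table(cohort_tab, files$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  for (trait in names(manifest$results)) {
    r <- manifest$results[[trait]]
    w <- if (trait == "bmi") manifest$config$bmi_weights else
      manifest$config$whr_weights
    if (is.null(w)) w <- grs_panel(toupper(trait))
    f <- file.path(dir, paste0("importance_", trait, ".tsv"))
    write_importance(r$importance, f, weights = read_weights(w))
    files[[paste0("importance_", trait)]] <- f
  }

  assoc_path <- file.path(dir, "associations.tsv")
  if (!is.null(manifest$model_table)) {
    utils::write.table(manifest$model_table, assoc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    writeLines("no SNPs selected in any panel; no models fitted",
               assoc_path)
  }
  files$associations <- assoc_path

  notes <- character(0)
  for (trait in names(manifest$results)) {
    r <- manifest$results[[trait]]
    if (isTRUE(r$skipped)) {
      notes <- c(notes, paste0("panel ", toupper(trait),
                               ": no SNPs selected; models skipped"))
      next
    }
    for (m in r$models)
      if (inherits(m, "grs_skipped"))
        notes <- c(notes, paste0("model ", m$label, " skipped: ", m$reason))
  }
  files$notes <- file.path(dir, "report_notes.txt")
  writeLines(if (length(notes)) notes else "all panels analysed", files$notes)

  files$manifest <- file.path(dir, "manifest.json")
  write_manifest(manifest, files$manifest)

  if (figures) {
    for (trait in names(manifest$results)) {
      r <- manifest$results[[trait]]
      if (isTRUE(r$skipped)) next
      f <- file.path(dir, paste0("quartiles_", trait, ".png"))
      grDevices::png(f, width = 900, height = 600)
      q <- r$models$ebmil_quartile
      qm <- q$quartile_means
      graphics::barplot(qm, ylab = "EBMIL (%)",
                        main = paste0("GRS quartiles (", toupper(trait),
                                      " panel)"))
      grDevices::dev.off()
      files[[paste0("fig_", trait)]] <- f
      f2 <- file.path(dir, paste0("importance_", trait, ".png"))
      grDevices::png(f2, width = 900, height = 600)
      plot_importance(r$importance,
                      main = paste0("Importance (", toupper(trait),
                                    " panel)"))
      grDevices::dev.off()
      files[[paste0("fig_imp_", trait)]] <- f2
    }
  }
  invisible(files)
}
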