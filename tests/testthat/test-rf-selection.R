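make_scored_cohort <- function(n = 238, n_noise = 10, causal_effect = 16,
                               noise_sd = 10, seed = 1) {
  # one causal SNP at MAF 0.3 among noise SNPs; effect 16 with noise SD 10
  # puts the causal variance share at ~52 %
  snps <- tiny_snps(n = n_noise + 1, maf = 0.3, beta = 0.1)
  snps$snp_id <- c("causal", paste0("noise", seq_len(n_noise)))
  snps$effect <- c(causal_effect, rep(0, n_noise))
  sc <- sim_scenario(n_samples = n, snps = snps, noise_sd = noise_sd,
                     seed = seed)
  cohort <- simulate_cohort(sc)
  w <- data.frame(snp_id = snps$snp_id, effect_allele = "A",
                  other_allele = "G", beta = snps$beta, trait = "BMI")
  list(scores = weight_scores(cohort$dosages, w),
       y = cohort$phenotypes$ebmil, weights = w,
       dosages = cohort$dosages)
}

test_that("weighted scores are dosage times beta", {
  d <- cbind(rs571312 = c(0L, 1L, 2L), rs2 = c(2L, 0L, 1L))
  w <- data.frame(snp_id = c("rs571312", "rs2"),
                  effect_allele = "A", other_allele = "C",
                  beta = c(0.23, 0), trait = "BMI")
  s <- weight_scores(d, w)
  expect_equal(s[, "rs571312"], c(0, 0.23, 0.46))
  expect_equal(s[, "rs2"], c(0, 0, 0))
  # column scores take at most 3 distinct values absent imputation
  expect_lte(length(unique(s[, 1])), 3L)
  w2 <- rbind(w, data.frame(snp_id = "rs9", effect_allele = "A",
                            other_allele = "C", beta = 1, trait = "BMI"))
  expect_error(weight_scores(d, w2), "misaligned")
})

test_that("forest importance is deterministic under a fixed seed", {
  f <- make_scored_cohort(n = 120, n_noise = 5)
  cfg <- forest_config(n_trees = 300, seed = 42)
  a <- rf_importance(f$scores, f$y, cfg)
  b <- rf_importance(f$scores, f$y, cfg)
  expect_identical(a$pct_inc_mse, b$pct_inc_mse)
  c2 <- rf_importance(f$scores, f$y, forest_config(n_trees = 300, seed = 43))
  expect_false(identical(a$pct_inc_mse, c2$pct_inc_mse))
})

test_that("a dominant planted predictor tops the importance ranking", {
  f <- make_scored_cohort(seed = 3)
  imp <- rf_importance(f$scores, f$y, forest_config(n_trees = 1000, seed = 3))
  expect_identical(imp$snp_id[which.max(imp$pct_inc_mse)], "causal")
  expect_gt(max(imp$pct_inc_mse), 10)
})

test_that("null outcomes keep importances inside the noise band", {
  set.seed(99)
  for (s in 1:3) {
    f <- make_scored_cohort(n = 150, n_noise = 9, causal_effect = 0,
                            noise_sd = 15, seed = s)
    imp <- rf_importance(f$scores, f$y,
                         forest_config(n_trees = 500, seed = s))
    expect_true(all(imp$pct_inc_mse < 10))
    expect_identical(select_snps(imp, 10), character(0))
  }
})

test_that("selection applies a strict threshold and descending order", {
  printed <- c(23.16, 19.65, 18.58, 17.58, 17.49, 17.12, 13.10)
  ids <- c("rs571312", "rs3810291", "rs1555543", "rs206936", "rs987237",
           "rs4836133", "rs2241423")
  imp <- data.frame(
    snp_id = c(sample(ids), "decoyA", "decoyB", "decoyC"),
    stringsAsFactors = FALSE)
  imp$pct_inc_mse <- c(printed[match(imp$snp_id[1:7], ids)], 9.99, 4.2, 0.3)
  expect_identical(select_snps(imp, 10), ids[order(-printed)])
  expect_identical(select_snps(imp, 10), ids)  # already printed descending

  at_boundary <- data.frame(snp_id = "rsX", pct_inc_mse = 10.00)
  expect_identical(select_snps(at_boundary, 10), character(0))
  expect_identical(select_snps(data.frame(snp_id = "rsX",
                                          pct_inc_mse = 3), 10),
                   character(0))
})

test_that("direction check inverts only beneficial effect alleles", {
  set.seed(8)
  n <- 300
  d <- cbind(up = rbinom(n, 2, 0.4), down = rbinom(n, 2, 0.4))
  y <- 80 + 4 * d[, "up"] - 4 * d[, "down"] + rnorm(n, 0, 2)
  w <- data.frame(snp_id = c("up", "down"), effect_allele = "A",
                  other_allele = "G", beta = 0.2, trait = "BMI")
  res <- check_direction_and_invert(d, w, y, c("up", "down"))
  expect_identical(res$inverted, "up")
  expect_identical(res$dosages[, "up"] + d[, "up"], rep(2L, n))
  expect_identical(res$dosages[, "down"], d[, "down"])
  # a second pass is a no-op: every slope now points downhill
  res2 <- check_direction_and_invert(res$dosages, w, y, c("up", "down"))
  expect_identical(res2$inverted, character(0))
  expect_identical(res2$dosages, res$dosages)
  # and the recode itself is an involution
  expect_identical(2L - (2L - d), d)
})

test_that("direction flags are recorded in the importance table", {
  set.seed(12)
  n <- 200
  d <- cbind(g1 = rbinom(n, 2, 0.3), g2 = rbinom(n, 2, 0.3))
  y <- 80 + 5 * d[, "g1"] + rnorm(n)
  w <- data.frame(snp_id = c("g1", "g2"), effect_allele = "A",
                  other_allele = "G", beta = 0.1, trait = "BMI")
  imp <- data.frame(snp_id = c("g1", "g2"), pct_inc_mse = c(20, 1),
                    selected = c(TRUE, FALSE), constant = FALSE,
                    direction_slope = NA_real_, inverted = FALSE)
  res <- check_direction_and_invert(d, w, y, "g1", imp)
  expect_true(res$importance$inverted[res$importance$snp_id == "g1"])
  expect_gt(res$importance$direction_slope[1], 0)
  expect_false(res$importance$inverted[2])
  # inverted implies selected
  expect_true(all(!res$importance$inverted | res$importance$selected))
})

test_that("an exactly duplicated predictor dilutes its own importance", {
  f <- make_scored_cohort(n = 200, n_noise = 6, seed = 5)
  cfg <- forest_config(n_trees = 800, seed = 5)
  lone <- rf_importance(f$scores, f$y, cfg)
  dup_scores <- cbind(f$scores, causal_copy = f$scores[, "causal"])
  dup <- rf_importance(dup_scores, f$y, cfg)
  lone_imp <- lone$pct_inc_mse[lone$snp_id == "causal"]
  expect_lt(dup$pct_inc_mse[dup$snp_id == "causal"], lone_imp)
  expect_lt(dup$pct_inc_mse[dup$snp_id == "causal_copy"], lone_imp)
})

test_that("adding a pure-noise column barely moves real importances", {
  f <- make_scored_cohort(n = 200, n_noise = 6, seed = 6)
  cfg <- forest_config(n_trees = 800, seed = 6)
  base <- rf_importance(f$scores, f$y, cfg)
  set.seed(606)
  aug_scores <- cbind(f$scores, extra = rnorm(nrow(f$scores)))
  aug <- rf_importance(aug_scores, f$y, cfg)
  expect_identical(select_snps(base, 10), select_snps(aug, 10))
})

test_that("constant predictors get zero importance with a warning", {
  f <- make_scored_cohort(n = 100, n_noise = 3, seed = 4)
  f$scores[, "noise1"] <- 0
  expect_warning(
    imp <- rf_importance(f$scores, f$y, forest_config(n_trees = 200,
                                                      seed = 4)),
    "constant")
  expect_identical(imp$pct_inc_mse[imp$snp_id == "noise1"], 0)
  expect_true(imp$constant[imp$snp_id == "noise1"])
})
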