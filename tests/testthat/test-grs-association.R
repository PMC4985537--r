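test_that("GRS matches hand arithmetic and is linear in dosage", {
  d <- rbind(s1 = c(a = 1L, b = 2L), s2 = c(a = 0L, b = 0L))
  w <- data.frame(snp_id = c("a", "b"), effect_allele = "A",
                  other_allele = "G", beta = c(0.1, 0.2), trait = "BMI")
  g <- compute_grs(d, w, c("a", "b"), scale_factor = 1)
  expect_equal(g$grs, c(0.5, 0))
  # one extra risk allele at SNP a adds exactly scale * |beta_a|
  d2 <- d; d2["s2", "a"] <- 1L
  g2 <- compute_grs(d2, w, c("a", "b"), scale_factor = 100)
  expect_equal(g2$grs[2] - 100 * g$grs_raw[2], 100 * 0.1)
  expect_error(compute_grs(d, w, character(0)), "empty selection")
  # negative betas contribute their magnitude
  w$beta <- c(-0.1, 0.2)
  g3 <- compute_grs(d, w, c("a", "b"), scale_factor = 1)
  expect_equal(g3$grs, c(0.5, 0))
})

test_that("GRS is invariant to SNP order and equivariant to sample order", {
  set.seed(20)
  d <- matrix(sample(0:2, 60, TRUE), 20, 3,
              dimnames = list(paste0("s", 1:20), c("x", "y", "z")))
  w <- data.frame(snp_id = c("x", "y", "z"), effect_allele = "A",
                  other_allele = "G", beta = c(0.1, 0.2, 0.3),
                  trait = "BMI")
  g1 <- compute_grs(d, w, c("x", "y", "z"))
  g2 <- compute_grs(d, w, c("z", "x", "y"))
  expect_equal(g1$grs, g2$grs)
  perm <- sample(20)
  g3 <- compute_grs(d[perm, ], w, c("x", "y", "z"))
  expect_equal(g3$grs, g1$grs[perm])
})

test_that("eight distinct scores split two per quartile", {
  q <- grs_quartile(c(3, 1, 8, 5, 2, 7, 4, 6))
  expect_identical(as.vector(table(q)), rep(2L, 4))
  # ties at a cut point fall to the lower quartile
  qt <- grs_quartile(c(1, 1, 1, 1, 2, 3, 4, 5))
  expect_identical(as.character(qt[1:4]), rep("Q1", 4))
})

test_that("adjusted OLS recovers a noise-free planted slope exactly", {
  cov <- make_covariates(120, seed = 31)
  set.seed(32)
  grs <- runif(120, 3, 37)
  y <- 95 - 0.32 * grs - 0.23 * cov$age - 0.73 * cov$initial_bmi +
    1.5 * (cov$sex == "male") - 0.8 * (cov$surgery_type == "distal")
  # noise-free data: lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(fit_adjusted_model(y, grs, cov))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["grs"]), -0.32, tolerance = 1e-10)
  expect_equal(unname(est["age"]), -0.23, tolerance = 1e-10)
  expect_equal(unname(est["sexmale"]), 1.5, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("adjusted OLS agrees with the normal-equations oracle", {
  for (s in 1:5) {
    cov <- make_covariates(60, seed = 100 + s)
    set.seed(200 + s)
    grs <- rnorm(60, 20, 5)
    y <- rnorm(60, 80, 15)
    fit <- fit_adjusted_model(y, grs, cov)
    X <- model.matrix(~ grs + age + sex + initial_bmi + surgery_type,
                      data.frame(grs = grs, age = cov$age,
                                 sex = factor(cov$sex),
                                 initial_bmi = cov$initial_bmi,
                                 surgery_type = factor(
                                   cov$surgery_type,
                                   levels = c("proximal", "distal"))))
    expect_equal(fit$coefficients$estimate, ols_oracle(X, y),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail with the offending column named", {
  cov <- make_covariates(50, seed = 41)
  y <- rnorm(50, 80, 10)
  expect_error(fit_adjusted_model(y, rep(5, 50), cov), "grs")
  cov1 <- cov; cov1$sex <- "female"
  expect_error(fit_adjusted_model(y, rnorm(50), cov1), "sex")
})

test_that("quartile contrasts use BH exactly as the brute-force oracle", {
  cov <- make_covariates(238, seed = 51)
  set.seed(52)
  grs <- rnorm(238, 20, 6)
  y <- 84 - 0.4 * grs + rnorm(238, 0, 15)
  qa <- quartile_analysis(y, grs, cov)
  expect_equal(qa$contrasts$p_bh, bh_oracle(qa$contrasts$p),
               tolerance = 1e-12)
  expect_equal(qa$adjusted_contrasts$p_bh,
               bh_oracle(qa$adjusted_contrasts$p), tolerance = 1e-12)
  expect_true(all(qa$contrasts$p_bh >= qa$contrasts$p))
  expect_identical(sum(qa$quartile_counts), 238L)
})

test_that("a planted lowest-quartile benefit is detected by all contrasts", {
  cov <- make_covariates(238, seed = 61)
  set.seed(62)
  grs <- runif(238, 3, 37)
  q <- grs_quartile(grs)
  resid_sd <- 5
  y <- 80 + 3 * resid_sd * (q == "Q1") + rnorm(238, 0, resid_sd)
  qa <- quartile_analysis(y, grs, cov)
  expect_true(all(qa$contrasts$significant))
  expect_true(all(qa$contrasts$p_bh < 0.05))
  expect_gt(qa$quartile_means["Q1"], max(qa$quartile_means[2:4]))
})

test_that("effect-free quartile families reject at most at the family level", {
  cov <- make_covariates(238, seed = 71)
  hits <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    grs <- rnorm(238, 20, 6)
    y <- rnorm(238, 84, 17)
    qa <- quartile_analysis(y, grs, cov)
    any(qa$contrasts$p_bh < 0.05)
  }, logical(1))
  # family-wise rate under the complete null is at most ~5 %
  expect_lt(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("the full two-panel chain fits eight models", {
  # two strong planted effects per panel so both clear the importance
  # cutoff and the score has enough levels for a quartile split
  snps <- tiny_snps(n = 6, maf = 0.3, beta = c(0.2, 0.1, 0.1, 0.05, 0.02,
                                               0.02))
  snps$effect <- c(-12, -8, 0, -12, -8, 0)
  snps$trait <- rep(c("BMI", "WHR"), each = 3)
  sc <- sim_scenario(n_samples = 238, snps = snps, noise_sd = 6, seed = 81)
  cohort <- simulate_cohort(sc)
  mk_w <- function(tr) {
    s <- snps[snps$trait == tr, ]
    data.frame(snp_id = s$snp_id, effect_allele = s$effect_allele,
               other_allele = s$other_allele, beta = s$beta, trait = tr)
  }
  res <- run_both_scores(cohort$phenotypes, cohort$dosages,
                         mk_w("BMI"), mk_w("WHR"),
                         forest = forest_config(n_trees = 500, seed = 81))
  expect_named(res, c("bmi", "whr"))
  n_models <- sum(lengths(lapply(res, `[[`, "models")))
  expect_identical(n_models, 8L)
  expect_true("rs1" %in% res$bmi$selected)
  expect_true("rs4" %in% res$whr$selected)

  # identical weights in both slots give identical paired results
  res2 <- run_both_scores(cohort$phenotypes, cohort$dosages,
                          mk_w("BMI"), mk_w("BMI"),
                          forest = forest_config(n_trees = 300, seed = 81))
  # same seed salt per slot name, so compare coefficients not forests
  expect_identical(res2$bmi$selected, res2$whr$selected)
  expect_equal(
    res2$bmi$models$ebmil_continuous$coefficients$estimate,
    res2$whr$models$ebmil_continuous$coefficients$estimate,
    tolerance = 1e-6)

  # a panel that selects nothing is skipped with a notice
  null_snps <- tiny_snps(n = 3, maf = 0.3)
  sc0 <- sim_scenario(n_samples = 100, snps = null_snps, noise_sd = 15,
                      seed = 82)
  c0 <- simulate_cohort(sc0)
  w0 <- data.frame(snp_id = null_snps$snp_id, effect_allele = "A",
                   other_allele = "G", beta = 0.1, trait = "BMI")
  expect_message(
    res0 <- run_both_scores(c0$phenotypes, c0$dosages, w0, w0,
                            forest = forest_config(n_trees = 300,
                                                   seed = 82)),
    "no SNPs selected")
  expect_true(res0$bmi$skipped)
  expect_length(res0$bmi$models, 0L)
})

test_that("grs_fit returns a coherent model object with working methods", {
  snps <- tiny_snps(n = 5, maf = 0.3, beta = c(0.2, 0.15, 0.1, 0.05, 0.05))
  snps$effect <- c(-14, 10, 0, 0, 0)  # one harmful, one beneficial allele
  sc <- sim_scenario(n_samples = 238, snps = snps, noise_sd = 8, seed = 91)
  cohort <- simulate_cohort(sc)
  w <- data.frame(snp_id = snps$snp_id, effect_allele = snps$effect_allele,
                  other_allele = snps$other_allele, beta = snps$beta,
                  trait = "BMI")
  fit <- grs_fit(cohort$dosages, cohort$phenotypes, w,
                 forest = forest_config(n_trees = 600, seed = 91))
  expect_s3_class(fit, "grs_fit")
  expect_true(all(c("rs1", "rs2") %in% fit$selected))
  expect_true("rs2" %in% fit$inverted)       # beneficial allele flipped
  expect_false("rs1" %in% fit$inverted)      # harmful allele untouched
  expect_true(all(fit$inverted %in% fit$selected))
  expect_lt(coef(fit)["grs"], 0)         # risk score lowers weight loss
  expect_length(residuals(fit), 238)
  expect_output(print(fit), "selected")
  expect_output(print(summary(fit)), "Importance table")

  # predictions on the training data reproduce the fitted values
  pred <- predict(fit, cohort$dosages, cohort$phenotypes)
  expect_equal(pred, unname(fitted(fit)), tolerance = 1e-10)

  f <- withr::local_tempfile(fileext = ".png")
  png(f); plot(fit); dev.off()
  expect_true(file.exists(f))
})
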