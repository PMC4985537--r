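# Shared fixtures and independent oracles.

# Small SNP table for scenarios; effects default to zero.
tiny_snps <- function(n = 3, maf = 0.3, effect = 0, beta = 0.1) {
  data.frame(snp_id = paste0("rs", seq_len(n)),
             maf = rep_len(maf, n),
             effect = rep_len(effect, n),
             beta = rep_len(beta, n),
             effect_allele = rep_len(c("A", "G", "C", "T"), n),
             other_allele = rep_len(c("G", "A", "T", "C"), n),
             stringsAsFactors = FALSE)
}

tiny_scenario <- function(n_samples = 50, snps = tiny_snps(), seed = 1,
                          ...) {
  sim_scenario(n_samples = n_samples, snps = snps, seed = seed, ...)
}

# Covariate frame with no planted structure.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = paste0("S", seq_len(n)),
    age = rnorm(n, 43, 10),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(.74, .26)),
    initial_bmi = rnorm(n, 45, 6),
    surgery_type = sample(c("proximal", "distal"), n, replace = TRUE,
                          prob = c(.265, .735)),
    stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up: sort, multiply by m/rank,
# enforce monotonicity from the largest p down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form OLS through the normal equations.
ols_oracle <- function(X, y) {
  as.vector(solve(crossprod(X), crossprod(X, y)))
}

# Minimal hand-written VCF fixture (3 samples x 2 SNPs) exercising
# effect-allele-on-REF coding and a missing call.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "P3", sep = "\t"),
    paste("1", "100", "rs100", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs200", "C", "T", ".", ".", ".", "GT",
          "0/1", "./.", "1/1", sep = "\t")), path)
  path
}
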