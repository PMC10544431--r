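test_that("configuration validation rejects out-of-range parameters", {
  expect_error(small_config(fst = c(-0.1, 0.1, 0.1)), "fst")
  expect_error(small_config(fst = c(1, 0.1, 0.1)), "fst")
  expect_error(small_config(dirichlet_alpha = c(0, 1, 1)), "dirichlet_alpha")
  expect_error(small_config(baseline_prev = 0), "baseline_prev")
  expect_error(small_config(n_cases = 0), "counts")
  expect_error(small_config(conf_anc_corr = 1.5), "conf_anc_corr")
  expect_error(small_config(beta_anc = Inf), "beta_anc")
})

test_that("subpopulation frequencies collapse to the ancestral value as drift vanishes", {
  cfg <- small_config(n_snps = 1000L, fst = c(1e-6, 1e-6, 1e-6))
  fr <- simulate_ancestral_frequencies(cfg)
  for (p in cfg$pop_names)
    expect_lt(max(abs(fr[[paste0("f_", p)]] - fr$p_ancestral)), 0.01)
})

test_that("identical configuration and seed give identical tables and bytes", {
  cfg <- small_config(seed = 1L)
  a <- simulate_mr_study(cfg)
  b <- simulate_mr_study(cfg)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$cohort$genotypes, b$cohort$genotypes)
  expect_identical(a$cohort$samples, b$cohort$samples)
  expect_identical(a$phewas, b$phewas)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_cohort_vcf(a$cohort$genotypes, a$freqs, f1)
  write_cohort_vcf(b$cohort$genotypes, b$freqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  write_samples_tsv(a$cohort, t1); write_samples_tsv(b$cohort, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("drifted frequencies keep the ancestral mean (law of total expectation)", {
  cfg <- sim_config(n_snps = 5000L, fst = c(0.1, 0.16, 0.2), seed = 7L)
  fr <- simulate_ancestral_frequencies(cfg)
  for (p in cfg$pop_names)
    expect_lt(abs(mean(fr[[paste0("f_", p)]]) - mean(fr$p_ancestral)), 0.01)
})

test_that("reference-panel dosages are degenerate at fixed alleles", {
  cfg <- small_config(n_snps = 5L, n_ref_per_pop = c(10L, 10L, 10L))
  fr <- manual_freqs(matrix(1, nrow = 5, ncol = 3))
  # fixed ALT allele: every dosage is 2
  pan <- simulate_reference_panel(fr, cfg)
  expect_true(all(vapply(pan, function(g) all(g == 2L), logical(1))))
  fr0 <- manual_freqs(matrix(0, nrow = 5, ncol = 3))
  pan0 <- simulate_reference_panel(fr0, cfg)
  expect_true(all(vapply(pan0, function(g) all(g == 0L), logical(1))))
})

test_that("panel genotypes respect Hardy-Weinberg proportions", {
  cfg <- sim_config(n_snps = 5000L, n_ref_per_pop = c(100L, 100L, 100L), seed = 3L)
  fr <- simulate_ancestral_frequencies(cfg)
  pan <- simulate_reference_panel(fr, cfg)
  g <- pan[[1]]
  n <- nrow(g)
  p_hat <- colMeans(g) / 2
  counts <- rbind(colSums(g == 0), colSums(g == 1), colSums(g == 2))
  expected <- rbind((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2) * n
  keep <- apply(expected, 2, min) > 1    # chi-square screen needs cell mass
  chi <- colSums((counts[, keep] - expected[, keep])^2 / expected[, keep])
  rej <- mean(chi > qchisq(0.99, df = 1))
  expect_lt(rej, 0.05)
})

test_that("degenerate Dirichlet concentrates ancestry on one population", {
  cfg <- small_config(dirichlet_alpha = c(1e6, 1e-6, 1e-6))
  cohort <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                    n = 50, genotypes = FALSE)
  expect_true(all(abs(cohort$true_q[, 1] - 1) < 1e-3))
})

test_that("ancestry vectors lie on the simplex and match the Dirichlet mean", {
  cfg <- small_config(dirichlet_alpha = c(2, 2, 1), seed = 11L)
  cohort <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                    n = 2000, genotypes = FALSE)
  expect_lt(max(abs(rowSums(cohort$true_q) - 1)), 1e-9)
  expect_true(all(abs(colMeans(cohort$true_q) - c(0.4, 0.4, 0.2)) < 0.02))
})

test_that("cohort dosages are integers in 0..2 given ancestry-weighted frequencies", {
  cfg <- small_config(seed = 4L)
  cohort <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                    n = 60, genotypes = TRUE)
  expect_true(all(cohort$genotypes %in% 0:2))
})

test_that("disease-model intercept calibration reproduces the target prevalence", {
  cfg <- small_config(beta_anc = 0, beta_conf = 0, n_pool = 20000L,
                      baseline_prev = 0.05, seed = 21L)
  pool <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                  genotypes = FALSE)
  pool <- simulate_outcome(pool, cfg, sample_cc = FALSE)
  prev <- mean(pool$samples$status)
  expect_lt(abs(prev - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("case-control sampling returns exactly the requested counts", {
  cfg <- small_config(n_cases = 150L, n_controls = 140L, seed = 5L)
  st <- simulate_mr_study(cfg)
  expect_identical(sum(st$cohort$samples$status == 1), 150L)
  expect_identical(sum(st$cohort$samples$status == 0), 140L)
  # clinical labels only where they belong
  s <- st$cohort$samples
  expect_true(all(is.na(s$age_at_diagnosis[s$status == 0])))
  expect_true(all(s$er[s$status == 1] %in% c("pos", "neg")))
  expect_true(all(is.na(s$er[s$status == 0])))
})

test_that("an undersized pool triggers the infeasible-case-count error", {
  cfg <- small_config(n_cases = 500L, n_pool = 600L, seed = 6L)
  pool <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                  genotypes = FALSE)
  expect_error(simulate_outcome(pool, cfg), "increase n_pool")
})

test_that("the disease model recovers the configured ancestry effect at scale", {
  cfg <- small_config(beta_anc = log(0.974), beta_conf = 0, conf_anc_corr = 0,
                      n_pool = 50000L, seed = 8L)
  pool <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                  genotypes = FALSE)
  pool <- simulate_outcome(pool, cfg, sample_cc = FALSE)
  fit <- glm(status ~ q_NA_pct + age, family = binomial(), data = pool$samples)
  expect_lt(abs(coef(fit)[["q_NA_pct"]] - log(0.974)), 0.004)
})

test_that("an ancestry-correlated confounder biases the naive observational slope", {
  cfg <- small_config(beta_anc = log(0.974), beta_conf = 0.5,
                      conf_anc_corr = -0.3, n_pool = 20000L, seed = 9L)
  pool <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                  genotypes = FALSE)
  pool <- simulate_outcome(pool, cfg, sample_cc = FALSE)
  fit <- glm(status ~ q_NA_pct, family = binomial(), data = pool$samples)
  slope <- coef(fit)[["q_NA_pct"]]
  mc_se <- sqrt(diag(vcov(fit)))[["q_NA_pct"]]
  expect_gt(abs(slope - log(0.974)), 3 * mc_se)
})

test_that("the PheWAS catalog respects the flagging fraction and thresholds", {
  ids <- sprintf("rs%04d", 1:1000)
  cfg0 <- small_config(frac_phewas_flagged = 0)
  expect_identical(nrow(simulate_phewas_catalog(ids, cfg0)), 0L)

  cfg1 <- small_config(frac_phewas_flagged = 1)
  cat1 <- simulate_phewas_catalog(ids, cfg1)
  sub <- tapply(cat1$pval, cat1$snp_id, min)
  expect_setequal(names(sub), ids)
  expect_true(all(sub < 5e-8))

  cfg01 <- small_config(frac_phewas_flagged = 0.1, seed = 5L)
  cat01 <- simulate_phewas_catalog(ids, cfg01)
  flagged <- unique(cat01$snp_id[cat01$pval < 5e-8])
  band <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(length(flagged), band[1])
  expect_lte(length(flagged), band[2])
  # benign rows never dip below the exclusion threshold
  benign <- setdiff(unique(cat01$snp_id), flagged)
  expect_true(all(cat01$pval[cat01$snp_id %in% benign] >= 5e-8))
})

test_that("optional block structure plants linkage disequilibrium", {
  cfg <- small_config(n_snps = 50L, ld_block_size = 5L, ld_flip_prob = 0.02,
                      seed = 13L)
  cohort <- simulate_admixed_cohort(simulate_ancestral_frequencies(cfg), cfg,
                                    n = 300, genotypes = TRUE)
  g <- cohort$genotypes
  within <- cor(g[, 1], g[, 2])^2       # same block
  across <- cor(g[, 1], g[, 6])^2       # different blocks
  expect_gt(within, 0.8)
  expect_lt(across, within)
})
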