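# independent interpolated weighted median (test oracle)
wm_oracle <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  p <- cumsum(w[ord]) / sum(w) - w[ord] / (2 * sum(w))
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  approx(p, b, xout = 0.5)$y
}

test_that("harmonization aligns alleles and drops mismatches", {
  exposure <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                         effect_allele = c("A", "A", "A"),
                         other_allele = c("G", "G", "G"),
                         eaf = c(0.3, 0.4, 0.5),
                         beta = c(1, 2, 3), se = c(0.1, 0.1, 0.1),
                         stringsAsFactors = FALSE)
  outcome <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                        effect_allele = c("A", "G", "A"),
                        other_allele = c("G", "A", "T"),
                        eaf = c(0.3, 0.6, 0.5),
                        beta = c(0.05, 0.08, 0.02), se = c(0.01, 0.01, 0.01),
                        stringsAsFactors = FALSE)
  expect_warning(inst <- harmonize(exposure, outcome), "mismatched")
  expect_setequal(inst$snp_id, c("rs1", "rs2"))
  expect_equal(inst$Gamma[inst$snp_id == "rs1"], 0.05)     # aligned: untouched
  expect_equal(inst$Gamma[inst$snp_id == "rs2"], -0.08)    # swapped: sign flip
  expect_equal(inst$ratio, inst$Gamma / inst$gamma)
  expect_equal(inst$w, (inst$se_Gamma / inst$gamma)^-2)
  expect_error(harmonize(exposure, data.frame(snp_id = "rs9", beta = 1, se = 1)),
               "no overlapping")
})

test_that("IVW reproduces the hand-computed weighted mean and WLS slope", {
  inst <- manual_instruments(gamma = c(0.1, 0.2, 0.4),
                             Gamma = c(-0.003, -0.005, -0.010),
                             se_Gamma = c(0.001, 0.001, 0.002))
  expect_equal(inst$ratio, c(-0.030, -0.025, -0.025), tolerance = 1e-12)
  expect_equal(inst$w, c(10000, 40000, 40000), tolerance = 1e-9)
  res <- ivw(inst)
  expect_equal(res$beta_hat, -2300 / 90000, tolerance = 1e-12)
  expect_equal(res$se, 1 / sqrt(90000), tolerance = 1e-12)
  # equivalence with the zero-intercept weighted regression of Gamma on gamma
  wls <- lm(inst$Gamma ~ 0 + inst$gamma, weights = inst$se_Gamma^-2)
  expect_equal(res$beta_hat, unname(coef(wls)), tolerance = 1e-10)
  # Cochran's Q against the hand computation
  expect_equal(res$cochran_q, 0.22222, tolerance = 1e-4)
  expect_identical(res$q_df, 2)
  expect_equal(res$q_pval, pchisq(res$cochran_q, 2, lower.tail = FALSE))
})

test_that("a single instrument returns its Wald ratio", {
  inst <- manual_instruments(0.2, -0.01, 0.002)
  res <- ivw(inst)
  expect_equal(res$beta_hat, -0.05)
  expect_equal(res$se, 0.002 / 0.2)
  expect_error(cochran_q(inst), "fewer than 2")
})

test_that("homogeneous ratios give the common value and zero heterogeneity", {
  inst <- manual_instruments(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3) * -0.02,
                             c(0.001, 0.002, 0.001))
  res <- ivw(inst)
  expect_equal(res$beta_hat, -0.02, tolerance = 1e-12)
  expect_equal(res$cochran_q, 0, tolerance = 1e-12)
  expect_equal(res$q_pval, 1)
})

test_that("Cochran's Q detects a planted outlier and decomposes exactly", {
  set.seed(71)
  k <- 15
  inst <- manual_instruments(rep(0.2, k),
                             c(rep(0.2 * 0.01, k - 1), 0.2 * 0.01 + 10 * 0.002),
                             rep(0.002, k))
  qq <- cochran_q(inst)
  expect_gt(qq[["Q"]], qchisq(0.99, k - 1))
  # Q equals the sum of the radial per-instrument contributions
  beta_hat <- sum(inst$w * inst$ratio) / sum(inst$w)
  expect_equal(qq[["Q"]], sum(inst$w * (inst$ratio - beta_hat)^2),
               tolerance = 1e-12)
})

test_that("radial filtering removes exactly the displaced instrument", {
  k <- 21L
  ratio_se <- 0.01
  Gamma <- rep(0.2 * 0.01, k)
  Gamma[k] <- 0.2 * (0.01 + 6 * ratio_se)
  inst <- manual_instruments(rep(0.2, k), Gamma, rep(0.2 * ratio_se, k))
  out <- radial_outlier_filter(inst, alpha = 0.1)
  expect_identical(out$removed, inst$snp_id[k])
  expect_identical(nrow(out$instruments), k - 1L)
  # identical ratios: nothing to remove
  none <- radial_outlier_filter(manual_instruments(rep(0.2, 5), rep(0.002, 5),
                                                   rep(0.001, 5)))
  expect_length(none$removed, 0)
  # alpha = 0 never removes anything
  out0 <- radial_outlier_filter(inst, alpha = 0)
  expect_length(out0$removed, 0)
  expect_error(radial_outlier_filter(inst[1:2, ]), "at least 3")
})

test_that("MR-Egger recovers slope and intercept in the designed limits", {
  set.seed(82)
  k <- 50
  gamma <- runif(k, 0.1, 0.6)
  Gamma <- -0.03 * gamma + rnorm(k, 0, 1e-4)
  inst <- manual_instruments(gamma, Gamma, rep(0.002, k))
  res <- mr_egger(inst)
  expect_lt(abs(res$beta_hat - -0.03), 1e-3)
  expect_gt(res$egger_intercept_pval, 0.05)
  # pure pleiotropy: constant outcome effect regardless of instrument strength
  instp <- manual_instruments(gamma, rep(0.01, k), rep(0.002, k))
  resp <- mr_egger(instp)
  expect_equal(resp$beta_hat, 0, tolerance = 1e-12)
  expect_equal(resp$egger_intercept, 0.01, tolerance = 1e-12)
  expect_error(mr_egger(inst[1:2, ]), "at least 3")
  degen <- manual_instruments(rep(0.2, 5), rnorm(5, 0, 0.01), rep(0.002, 5))
  expect_error(mr_egger(degen), "degenerate")
})

test_that("MR-Egger matches a weighted lm() fit after orientation", {
  set.seed(93)
  k <- 20
  gamma <- runif(k, 0.1, 0.5) * sample(c(-1, 1), k, TRUE)
  Gamma <- -0.02 * gamma + rnorm(k, 0, 0.002)
  se_G <- runif(k, 0.001, 0.004)
  inst <- manual_instruments(gamma, Gamma, se_G)
  res <- mr_egger(inst)
  fit <- lm(I(Gamma * sign(gamma)) ~ I(gamma * sign(gamma)),
            weights = se_G^-2)
  sm <- summary(fit)$coefficients
  expect_equal(res$beta_hat, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$se, sm[2, 2], tolerance = 1e-10)
  expect_equal(res$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  expect_equal(res$egger_intercept_pval, sm[1, 4], tolerance = 1e-10)
})

test_that("the weighted median is robust and matches an independent oracle", {
  inst <- manual_instruments(rep(1, 3), c(1, 2, 100), rep(1, 3))
  expect_equal(weighted_median(inst)$beta_hat, 2)
  set.seed(7)
  k <- 30
  inst2 <- manual_instruments(runif(k, 0.1, 0.5),
                              rnorm(k, -0.005, 0.002),
                              runif(k, 0.001, 0.003))
  expect_equal(weighted_median(inst2)$beta_hat,
               wm_oracle(inst2$ratio, inst2$w), tolerance = 1e-10)
  # identical ratios with tiny outcome noise: estimate exact, bootstrap SE tiny
  inst3 <- manual_instruments(rep(0.3, 5), rep(0.3 * -0.02, 5), rep(1e-9, 5))
  res3 <- weighted_median(inst3)
  expect_equal(res3$beta_hat, -0.02, tolerance = 1e-9)
  expect_lt(res3$se, 1e-6)
  # seeded bootstrap is reproducible
  expect_identical(weighted_median(inst2, seed = 99)$se,
                   weighted_median(inst2, seed = 99)$se)
})

test_that("all estimators are invariant to re-orienting instrument alleles", {
  set.seed(11)
  k <- 12
  gamma <- runif(k, 0.1, 0.5)
  Gamma <- -0.02 * gamma + rnorm(k, 0, 0.002)
  se_G <- runif(k, 0.001, 0.003)
  inst <- manual_instruments(gamma, Gamma, se_G)
  flip <- sample(c(-1, 1), k, replace = TRUE)
  inst_f <- manual_instruments(gamma * flip, Gamma * flip, se_G)
  expect_equal(ivw(inst)$beta_hat, ivw(inst_f)$beta_hat, tolerance = 1e-12)
  expect_equal(ivw(inst)$se, ivw(inst_f)$se, tolerance = 1e-12)
  expect_equal(cochran_q(inst), cochran_q(inst_f), tolerance = 1e-12)
  expect_equal(mr_egger(inst)$beta_hat, mr_egger(inst_f)$beta_hat,
               tolerance = 1e-12)
  expect_equal(mr_egger(inst)$egger_intercept,
               mr_egger(inst_f)$egger_intercept, tolerance = 1e-12)
  expect_equal(weighted_median(inst, seed = 5)$beta_hat,
               weighted_median(inst_f, seed = 5)$beta_hat, tolerance = 1e-12)
})

test_that("the correlation-aware IVW variance reduces to first order when uncorrelated", {
  inst <- manual_instruments(c(0.1, 0.2, 0.4), c(-0.003, -0.005, -0.010),
                             c(0.001, 0.001, 0.002))
  rho <- diag(3)
  dimnames(rho) <- list(inst$snp_id, inst$snp_id)
  res <- ivw(inst, rho = rho)
  expect_equal(res$se, res$se_first_order, tolerance = 1e-12)
  # positive equicorrelation inflates the variance, never deflates
  rho2 <- matrix(0.3, 3, 3); diag(rho2) <- 1
  dimnames(rho2) <- dimnames(rho)
  expect_gt(ivw(inst, rho = rho2)$se, res$se_first_order)
  expect_equal(ivw(inst, rho = rho2)$beta_hat, res$beta_hat)
})

test_that("odds-ratio conversions reproduce the published worked examples", {
  expect_equal(round(or_per_percent(log(0.974))[["percent_decrease"]], 1), 2.6)
  expect_equal(round(or_per_percent(log(0.988))[["percent_decrease"]], 1), 1.2)
  out <- or_per_percent(0, 0)
  expect_equal(out[["or"]], 1)
  expect_equal(out[["percent_decrease"]], 0)
  ci <- or_per_percent(log(0.974), 0.002)
  expect_equal(ci[["ci_low"]], exp(log(0.974) - 1.96 * 0.002))
  expect_equal(ci[["ci_high"]], exp(log(0.974) + 1.96 * 0.002))
})

test_that("quartile risk differences follow the published arithmetic", {
  expect_equal(quartile_risk_difference(2.6, 36, 49), 33.8)
  expect_equal(quartile_risk_difference(1.2, 54, 79), 30)
  expect_equal(quartile_risk_difference(5, 40, 40), 0)
  expect_error(quartile_risk_difference(2, 50, 40))
})

test_that("analytic power is alpha at the null and approaches 1 with n", {
  expect_equal(mr_power_binary(5000, 0.5, 0.1, 1), 0.05, tolerance = 1e-12)
  expect_gt(mr_power_binary(1e7, 0.5, 0.1, 0.9), 0.999)
  expect_lt(mr_power_binary(100, 0.5, 0.01, 0.99), 0.06)
  expect_error(mr_power_binary(1000, 0.5, 0, 0.9), "r2")
  expect_error(mr_power_binary(1000, 0.5, 1.2, 0.9), "r2")
})
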