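#' Harmonize exposure and outcome summary statistics
#'
#' Matches the two scans by SNP id and aligns the outcome effects to the
#' exposure's effect allele: when the outcome's effect/other alleles are
#' swapped relative to the exposure, the outcome beta changes sign and its
#' allele frequency becomes its complement; SNPs whose allele sets disagree
#' are dropped with a warning. Per-instrument Wald ratios
#' `beta_j = Gamma_j / gamma_j` and first-order weights
#' `w_j = (se_Gamma_j / gamma_j)^-2` are attached.
#'
#' @param exposure,outcome summary-statistics data.frames with `snp_id`,
#'   `beta`, `se` and optionally `effect_allele`, `other_allele`, `eaf`.
#'   Without allele columns both scans are assumed to share the effect-allele
#'   convention (as the in-house scans do: effect allele = VCF ALT).
#' @return data.frame of class `instrument_set`: `snp_id`, `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma`, `ratio`, `w`, `flipped`.
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop("no overlapping SNPs between exposure and outcome")
  e <- exposure[match(shared, exposure$snp_id), ]
  o <- outcome[match(shared, outcome$snp_id), ]
  flipped <- rep(FALSE, length(shared))
  have_alleles <- all(c("effect_allele", "other_allele") %in% names(e)) &&
    all(c("effect_allele", "other_allele") %in% names(o))
  if (have_alleles) {
    same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
    swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
    mism <- !(same | swap)
    if (any(mism)) {
      warning(sprintf("dropping %d SNP(s) with mismatched allele sets", sum(mism)))
      e <- e[!mism, ]; o <- o[!mism, ]
      same <- same[!mism]; swap <- swap[!mism]
    }
    o$beta[swap] <- -o$beta[swap]
    if ("eaf" %in% names(o)) o$eaf[swap] <- 1 - o$eaf[swap]
    flipped <- swap
    if (!nrow(e)) stop("no overlapping SNPs after allele harmonization")
  }
  inst <- data.frame(snp_id = e$snp_id, gamma = e$beta, se_gamma = e$se,
                     Gamma = o$beta, se_Gamma = o$se, stringsAsFactors = FALSE)
  if (any(inst$gamma == 0)) {
    warning(sprintf("dropping %d SNP(s) with zero exposure effect",
                    sum(inst$gamma == 0)))
    inst <- inst[inst$gamma != 0, ]
  }
  inst$ratio <- inst$Gamma / inst$gamma
  inst$w <- (inst$se_Gamma / inst$gamma)^-2
  inst$flipped <- flipped[match(inst$snp_id, e$snp_id)]
  class(inst) <- c("instrument_set", "data.frame")
  inst
}

.new_mr_result <- function(method, beta_hat, se, pval, n_iv,
                           q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                           egger_intercept = NA_real_,
                           egger_intercept_se = NA_real_,
                           egger_intercept_pval = NA_real_) {
  orci <- or_per_percent(beta_hat, se)
  out <- list(method = method, beta_hat = beta_hat, se = se,
              or = orci[["or"]], ci_low = orci[["ci_low"]],
              ci_high = orci[["ci_high"]], pval = pval,
              cochran_q = q, q_df = q_df, q_pval = q_pval,
              egger_intercept = egger_intercept,
              egger_intercept_se = egger_intercept_se,
              egger_intercept_pval = egger_intercept_pval,
              n_iv = n_iv, r2_cumulative = NA_real_, f_statistic = NA_real_)
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s estimate over %d instruments\n", x$method, x$n_iv))
  cat(sprintf("  OR per 1%% ancestry: %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$pval))
  if (is.finite(x$cochran_q))
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
                x$cochran_q, x$q_df, x$q_pval))
  if (is.finite(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4g, p = %.3g\n",
                x$egger_intercept, x$egger_intercept_pval))
  invisible(x)
}

#' Inverse-variance-weighted estimator
#'
#' Fixed-effect IVW with first-order weights:
#' `beta_hat = sum(w_j beta_j) / sum(w_j)`, `se = (sum w_j)^-1/2` — identical
#' to the slope of a zero-intercept weighted regression of Gamma on gamma.
#' With `random_effects = TRUE` the standard error is inflated by
#' `max(1, sqrt(Q / (k - 1)))` (multiplicative random effects); the default is
#' fixed-effect, appropriate when Cochran's Q shows no heterogeneity.
#'
#' @param instruments an `instrument_set` from [harmonize()].
#' @param random_effects inflate the SE under heterogeneity.
#' @param rho optional matrix of pairwise dosage correlations between the
#'   instruments in the outcome sample (dimnames = SNP ids). When supplied,
#'   the standard error accounts for the correlation between per-instrument
#'   ratio errors, `Var = w~' (S rho S * sigma sigma') w~` with
#'   `sigma_j = 1/sqrt(w_j)`, normalised weights `w~` and `S` the diagonal of
#'   exposure-effect signs. Instruments for one heritable exposure in an
#'   admixed cohort are mutually correlated through genome-wide ancestry even
#'   after linkage-based pruning, and the uncorrected first-order variance
#'   `1/sum(w)` can then understate the sampling variance several-fold; the
#'   point estimate is unaffected. The uncorrected value is kept in
#'   `se_first_order`.
#' @return an `mr_result`.
#' @export
ivw <- function(instruments, random_effects = FALSE, rho = NULL) {
  k <- nrow(instruments)
  if (is.null(k) || k < 1) stop("need at least one instrument")
  w <- instruments$w
  beta_hat <- sum(w * instruments$ratio) / sum(w)
  se_fo <- 1 / sqrt(sum(w))
  se <- se_fo
  if (!is.null(rho) && k >= 2) {
    if (is.null(dimnames(rho)) ||
        !all(instruments$snp_id %in% rownames(rho)))
      stop("rho must carry the instrument SNP ids as dimnames")
    r <- rho[instruments$snp_id, instruments$snp_id]
    sgn <- sign(instruments$gamma)
    sig <- 1 / sqrt(w)
    wt <- w / sum(w)
    v <- drop(t(wt * sig * sgn) %*% r %*% (wt * sig * sgn))
    se <- sqrt(max(v, se_fo^2))
  }
  q <- q_df <- q_pval <- NA_real_
  if (k >= 2) {
    qq <- cochran_q(instruments, beta_hat)
    q <- qq[["Q"]]; q_df <- qq[["df"]]; q_pval <- qq[["pval"]]
    if (random_effects) se <- se * max(1, sqrt(q / q_df))
  }
  res <- .new_mr_result("IVW", beta_hat, se, 2 * pnorm(-abs(beta_hat / se)), k,
                        q = q, q_df = q_df, q_pval = q_pval)
  res$se_first_order <- se_fo
  res
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (beta_j - beta_hat)^2` with first-order weights, compared to
#' a chi-square distribution on `n_iv - 1` degrees of freedom. Large Q flags
#' instrument heterogeneity, a proxy for pleiotropy.
#'
#' @param instruments an `instrument_set`.
#' @param beta_hat pooled estimate the deviations are taken from (defaults to
#'   the IVW estimate).
#' @return named vector `Q`, `df`, `pval`.
#' @export
cochran_q <- function(instruments, beta_hat = NULL) {
  k <- nrow(instruments)
  if (k < 2) stop("Cochran's Q is undefined for fewer than 2 instruments")
  w <- instruments$w
  if (is.null(beta_hat)) beta_hat <- sum(w * instruments$ratio) / sum(w)
  q <- sum(w * (instruments$ratio - beta_hat)^2)
  df <- k - 1
  c(Q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' Radial outlier exclusion
#'
#' Decomposes Cochran's Q into per-instrument contributions
#' `Q_j = w_j (beta_j - beta_hat)^2` at the current IVW estimate, referred to
#' a 1-df chi-square; instruments with `p_j < alpha` (default 0.1) are
#' removed, the estimate refitted, and the procedure iterated to a fixed
#' point (at most `max_rounds` rounds, never below 3 instruments).
#'
#' @param instruments an `instrument_set` with at least 3 instruments.
#' @param alpha per-instrument exclusion p-value threshold.
#' @param max_rounds iteration cap.
#' @return list with `instruments` (retained set), `removed` (SNP ids),
#'   `rounds`.
#' @export
radial_outlier_filter <- function(instruments, alpha = 0.1, max_rounds = 20L) {
  if (nrow(instruments) < 3) stop("radial filtering needs at least 3 instruments")
  removed <- character(0)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    w <- instruments$w
    beta_hat <- sum(w * instruments$ratio) / sum(w)
    q_j <- w * (instruments$ratio - beta_hat)^2
    p_j <- pchisq(q_j, 1, lower.tail = FALSE)
    out <- p_j < alpha
    if (!any(out) || rounds > max_rounds) break
    removed <- c(removed, instruments$snp_id[out])
    instruments <- instruments[!out, , drop = FALSE]
    if (nrow(instruments) <= 3) break
  }
  if (!nrow(instruments)) stop("all instruments removed; inspect the ratios")
  list(instruments = instruments, removed = removed, rounds = rounds)
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with a
#' free intercept (weights `se_Gamma^-2`), after orienting every instrument so
#' its exposure effect is positive. The slope is the causal estimate; a
#' non-zero intercept indicates directional horizontal pleiotropy. P-values
#' use the t distribution on `n_iv - 2` degrees of freedom.
#'
#' @param instruments an `instrument_set` with at least 3 instruments.
#' @return an `mr_result` with the intercept fields filled.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(instruments$gamma)
  g <- instruments$gamma * flip
  G <- instruments$Gamma * flip
  if (max(g) - min(g) < 1e-12 * max(abs(g)))
    stop("degenerate design: all exposure effects equal")
  w <- instruments$se_Gamma^-2
  x <- cbind(intercept = 1, gamma = g)
  xtwx <- crossprod(x * sqrt(w))
  cf <- drop(solve(xtwx, crossprod(x * w, G)))
  resid <- G - drop(x %*% cf)
  rdf <- k - 2
  sigma2 <- sum(w * resid^2) / rdf
  ses <- sqrt(diag(solve(xtwx)) * sigma2)
  tvals <- cf / ses
  pvals <- 2 * pt(-abs(tvals), rdf)
  qq <- sum(w * resid^2)
  .new_mr_result("Egger", cf[["gamma"]], ses[[2]], pvals[[2]], k,
                 q = qq, q_df = rdf,
                 q_pval = pchisq(qq, rdf, lower.tail = FALSE),
                 egger_intercept = cf[["intercept"]],
                 egger_intercept_se = ses[[1]],
                 egger_intercept_pval = pvals[[1]])
}

# interpolated weighted median of ratio estimates
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  hi <- which(s >= 0.5)[1]
  lo <- hi - 1
  b[lo] + (b[hi] - b[lo]) * (0.5 - s[lo]) / (s[hi] - s[lo])
}

#' Weighted-median estimator
#'
#' The interpolated median of the ordered per-instrument ratio estimates
#' under normalised inverse-variance weights; consistent when at least half
#' the weight comes from valid instruments. The standard error is obtained by
#' parametric bootstrap: `ratio_j* ~ Normal(ratio_j, 1 / sqrt(w_j))`.
#'
#' @param instruments an `instrument_set` with at least 3 instruments.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed bootstrap seed (reported with the result for reproducibility).
#' @return an `mr_result`.
#' @export
weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  k <- nrow(instruments)
  if (k < 3) stop("the weighted median needs at least 3 instruments")
  est <- .weighted_median_point(instruments$ratio, instruments$w)
  sd_j <- 1 / sqrt(instruments$w)
  set.seed(seed %% .Machine$integer.max)
  boots <- vapply(seq_len(n_boot), function(b) {
    .weighted_median_point(instruments$ratio + rnorm(k) * sd_j, instruments$w)
  }, numeric(1))
  se <- sd(boots)
  res <- .new_mr_result("WM", est, se, 2 * pnorm(-abs(est / se)), k)
  res$wm_seed <- seed
  res
}

#' Odds ratio per 1% ancestry with confidence interval
#'
#' Converts a log-OR (per percentage point of ancestry) and its standard
#' error to the odds-ratio scale with a normal-approximation 95% interval,
#' and to the "percent decrease in risk per 1% increase in ancestry"
#' phrasing: `100 * (1 - OR)`.
#'
#' @param beta_hat causal log-OR per 1% ancestry.
#' @param se its standard error (0 gives a degenerate interval).
#' @return named vector `or`, `ci_low`, `ci_high`, `percent_decrease`.
#' @export
or_per_percent <- function(beta_hat, se = 0) {
  or <- exp(beta_hat)
  c(or = or, ci_low = exp(beta_hat - 1.96 * se),
    ci_high = exp(beta_hat + 1.96 * se),
    percent_decrease = 100 * (1 - or))
}

#' Expected risk difference between ancestry quantiles
#'
#' Linearised difference in risk between two points of the ancestry
#' distribution: `(q_high - q_low) * percent_decrease_per_1pct`, e.g. between
#' the first and third quartiles of the control ancestry distribution.
#'
#' @param percent_decrease_per_1pct percent decrease in risk per 1% ancestry.
#' @param q_low,q_high ancestry percentages (q_high >= q_low).
#' @return percent difference in risk.
#' @export
quartile_risk_difference <- function(percent_decrease_per_1pct, q_low, q_high) {
  stopifnot(q_high >= q_low)
  (q_high - q_low) * percent_decrease_per_1pct
}

#' Analytic power for Mendelian randomization with a binary outcome
#'
#' Closed-form two-sided power of the Wald test at significance `alpha` for a
#' causal odds ratio `or_per_sd` per standard deviation of the exposure, with
#' instruments explaining a fraction `r2` of the exposure variance in a
#' sample of `n` with case fraction `K`: the non-centrality is
#' `z = |log or| * sqrt(n r2 K (1 - K))` and
#' `power = Phi(z - z_{1-alpha/2}) + Phi(-z - z_{1-alpha/2})`.
#'
#' @param n total sample size.
#' @param case_fraction proportion of cases.
#' @param r2 variance in the exposure explained by the instruments, in (0,1).
#' @param or_per_sd causal odds ratio per exposure standard deviation.
#' @param alpha type-I error rate (default 0.05).
#' @return power in \[alpha, 1\].
#' @export
mr_power_binary <- function(n, case_fraction, r2, or_per_sd, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie strictly in (0, 1)")
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1, or_per_sd > 0,
            alpha > 0, alpha < 1)
  b <- log(or_per_sd)
  z <- abs(b) * sqrt(n * r2 * case_fraction * (1 - case_fraction))
  zc <- qnorm(1 - alpha / 2)
  pnorm(z - zc) + pnorm(-z - zc)
}
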