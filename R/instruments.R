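#' Per-SNP exposure association scan (linear, age-adjusted)
#'
#' Ordinary least squares of the ancestry percentage on each SNP's dosage with
#' age as covariate, fitted among controls (sample 1 of the two-sample
#' design). Betas are changes in exposure percentage per effect-allele copy;
#' two-sided p-values come from the t distribution with n - 3 degrees of
#' freedom. Monomorphic SNPs are dropped with a warning. The scan is
#' vectorised across SNPs by residualising exposure and dosages on the
#' intercept and age (Frisch-Waugh), which reproduces `lm()` exactly.
#'
#' @param genotypes control dosage matrix, individuals x SNPs.
#' @param q_pct exposure: ancestry on the 0-100 percent scale.
#' @param age age covariate in years.
#' @return data.frame of summary statistics: `snp_id`, `effect_allele`,
#'   `other_allele` placeholders filled by the caller when allele labels are
#'   known, `eaf`, `beta`, `se`, `pval`, `n`.
#' @export
linear_scan_ancestry <- function(genotypes, q_pct, age) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  stopifnot(length(q_pct) == n, length(age) == n)
  if (n < 3) stop("need at least 3 controls")
  keep <- .col_vars(g) > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d monomorphic SNP(s)", sum(!keep)))
    g <- g[, keep, drop = FALSE]
  }
  Z <- cbind(1, age)
  QZ <- qr(Z)
  y_res <- qr.resid(QZ, q_pct)
  g_res <- qr.resid(QZ, g)
  sgg <- colSums(g_res^2)
  beta <- colSums(g_res * y_res) / sgg
  rss <- sum(y_res^2) - beta^2 * sgg
  df <- n - 3
  se <- sqrt(pmax(rss, 0) / df / sgg)
  tval <- beta / se
  data.frame(snp_id = colnames(g),
             eaf = colMeans(g) / 2,
             beta = beta, se = se,
             pval = 2 * pt(-abs(tval), df),
             n = n, stringsAsFactors = FALSE, row.names = NULL)
}

# column variances, vectorised
.col_vars <- function(x) {
  m <- colMeans(x)
  colMeans(x^2) - m^2
}

#' Per-SNP outcome association scan (logistic, age-adjusted)
#'
#' Logistic regression of case-control status on dosage and age, one SNP at a
#' time (iteratively reweighted least squares via `glm.fit`), giving Wald
#' betas (log-OR per effect-allele copy), standard errors and normal
#' two-sided p-values. SNPs showing quasi-complete separation (non-finite or
#' exploding estimates) are flagged and dropped.
#'
#' @param genotypes dosage matrix for cases and controls, individuals x SNPs.
#' @param status 0/1 outcome vector (1 = case).
#' @param age age covariate in years, or `NULL` for an unadjusted scan.
#' @return data.frame: `snp_id`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @export
logistic_scan_outcome <- function(genotypes, status, age = NULL) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  stopifnot(length(status) == n, is.null(age) || length(age) == n)
  if (length(unique(status)) < 2)
    stop("degenerate input: both cases and controls must be present")
  res <- lapply(seq_len(ncol(g)), function(j) {
    x <- if (is.null(age)) cbind(1, g[, j]) else cbind(1, g[, j], age)
    fit <- suppressWarnings(glm.fit(x, status, family = binomial()))
    cf <- fit$coefficients[2]
    # Wald covariance from the final IRLS weights
    w <- fit$weights
    xtwx <- crossprod(x * sqrt(w))
    v <- tryCatch(solve(xtwx)[2, 2], error = function(e) NA_real_)
    if (!is.finite(cf) || !is.finite(v) || abs(cf) > 15 || v <= 0)
      return(NULL)   # separation or degenerate fit: drop
    se <- sqrt(v)
    data.frame(snp_id = colnames(g)[j], eaf = mean(g[, j]) / 2,
               beta = unname(cf), se = se,
               pval = 2 * pnorm(-abs(cf / se)), n = n,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("dropping %d SNP(s) with separated or degenerate fits", dropped))
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("no SNP could be fitted")
  rownames(out) <- NULL
  out
}

#' Exclude SNPs with catalogued confounder-phenotype associations
#'
#' A SNP is removed when any catalog row links it to a phenotype with
#' p-value below the threshold — the phenome-wide screen standing in for an
#' MR-Base query over menopause, pregnancy outcomes, smoking, alcohol,
#' education, contraceptives, hormone-replacement therapy, diabetes, body
#' circumferences and breast cancer.
#'
#' @param snp_ids candidate SNP ids.
#' @param catalog data.frame with `snp_id`, `phenotype`, `pval` (may be empty).
#' @param threshold exclusion p-value threshold (default 5e-8).
#' @return character vector of retained SNP ids.
#' @export
phewas_filter <- function(snp_ids, catalog, threshold = 5e-8) {
  if (is.null(catalog) || nrow(catalog) == 0) return(snp_ids)
  required <- c("snp_id", "phenotype", "pval")
  if (!all(required %in% names(catalog)))
    stop("malformed catalog: need columns snp_id, phenotype, pval")
  bad <- which(!is.finite(catalog$pval) | catalog$pval < 0 | catalog$pval > 1 |
                 is.na(catalog$snp_id) | catalog$snp_id == "")
  if (length(bad))
    stop(sprintf("malformed catalog row(s): %s", paste(bad, collapse = ", ")))
  flagged <- unique(catalog$snp_id[catalog$pval < threshold])
  setdiff(snp_ids, flagged)
}

#' Per-SNP explained variance
#'
#' The single-variant contribution `beta^2 * 2 * MAF * (1 - MAF)` with
#' `MAF = min(eaf, 1 - eaf)`. The scale of the result is the square of the
#' exposure scale of `beta`; the pipeline supplies betas on the 0-1 ancestry
#' proportion scale (see the methods vignette for why).
#'
#' @param beta additive per-allele effect.
#' @param eaf effect-allele frequency in (0,1).
#' @return numeric vector of variance contributions.
#' @export
explained_variance <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0, 1)")
  maf <- pmin(eaf, 1 - eaf)
  beta^2 * 2 * maf * (1 - maf)
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors (composite LD,
#' phase-free). Invariant to allele relabelling.
#'
#' @param a,b dosage vectors of equal length.
#' @return squared correlation.
#' @export
ld_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance dosage vector")
  cor(a, b)^2
}

#' Greedy LD pruning with retention of the highest explained variance
#'
#' Candidates are processed in decreasing order of explained variance (ties
#' broken by SNP id); a SNP is retained iff its squared dosage correlation
#' with every already-retained SNP is at or below the threshold. With the
#' paper-default threshold, pairs with r^2 > 0.01 cannot co-occur and the
#' member with the higher explained variance wins.
#'
#' @param snp_ids candidate SNP ids.
#' @param expl_var their explained-variance values (same order).
#' @param genotypes dosage matrix (individuals x SNPs) covering the
#'   candidates; LD is measured in these samples (the controls, per the
#'   two-sample design).
#' @param r2_threshold retention threshold (default 0.01).
#' @return character vector of retained SNP ids (in processing order).
#' @export
greedy_ld_prune <- function(snp_ids, expl_var, genotypes, r2_threshold = 0.01) {
  stopifnot(length(snp_ids) == length(expl_var))
  ord <- order(-expl_var, snp_ids)
  g <- as.matrix(genotypes[, snp_ids, drop = FALSE])
  # standardise once; r^2 is then a crossprod
  gs <- scale(g)
  n1 <- nrow(g) - 1
  retained <- integer(0)
  for (j in ord) {
    if (length(retained)) {
      r <- crossprod(gs[, retained, drop = FALSE], gs[, j]) / n1
      if (any(r^2 > r2_threshold)) next
    }
    retained <- c(retained, j)
  }
  snp_ids[retained]
}

#' Instrument-strength summary
#'
#' Cumulative explained variance (the plain sum of per-variant contributions)
#' and the multi-instrument F-statistic
#' `F = ((n - k - 1) / k) * (R2 / (1 - R2))`. A mean per-instrument F
#' (average squared Wald statistic of the exposure scan, when supplied) is
#' reported alongside, since published instrument-strength figures are
#' sometimes of that form.
#'
#' @param expl_var per-instrument explained-variance contributions.
#' @param n exposure-sample size.
#' @param per_iv_t optional per-instrument t statistics from the exposure scan.
#' @return list of class `instrument_report`: `n_iv`, `r2_cumulative`,
#'   `f_statistic`, `f_mean_per_iv`.
#' @export
instrument_strength <- function(expl_var, n, per_iv_t = NULL) {
  k <- length(expl_var)
  if (k < 1) stop("need at least one instrument")
  r2 <- sum(expl_var)
  if (r2 >= 1)
    stop("cumulative explained variance >= 1; betas are probably mis-scaled")
  out <- list(n_iv = k, r2_cumulative = r2,
              f_statistic = ((n - k - 1) / k) * (r2 / (1 - r2)),
              f_mean_per_iv = if (!is.null(per_iv_t)) mean(per_iv_t^2) else NA_real_)
  class(out) <- "instrument_report"
  out
}
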