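#' Supervised ancestry estimation for one individual (EM)
#'
#' Maximum-likelihood estimate of the K admixture proportions q of a single
#' individual given fixed reference-panel allele frequencies, by
#' expectation-maximisation of the binomial likelihood
#' `sum_i [ g_i log x_i + (2 - g_i) log(1 - x_i) ]` with
#' `x_i = sum_k q_k f_ik`. The likelihood is concave in q for fixed f, so a
#' single deterministic run from the uniform start suffices; the
#' log-likelihood is non-decreasing at every EM step. Panel frequencies are
#' clipped to `\[1e-6, 1 - 1e-6\]` to protect panel-fixed alleles; missing
#' dosages are skipped.
#'
#' @param g dosage vector over M SNPs (0/1/2, NA allowed).
#' @param f M x K matrix of reference-panel effect-allele frequencies.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap; non-convergence is flagged, not hidden.
#' @param trace keep the per-iteration log-likelihood trace.
#' @return list with `q` (named simplex vector), `loglik`, `n_iter`,
#'   `converged` and optionally `trace`.
#' @export
supervised_ancestry_em <- function(g, f, tol = 1e-6, max_iter = 2000L,
                                   trace = FALSE) {
  f <- as.matrix(f)
  if (length(g) != nrow(f)) stop("dosage vector and frequency matrix disagree")
  if (all(is.na(g))) stop("individual has no non-missing genotypes")
  fit <- .em_cohort_cpp(matrix(as.numeric(g), ncol = 1), .clip01(f),
                        tol, as.integer(max_iter), trace)
  q <- drop(fit$q)
  names(q) <- colnames(f)
  out <- list(q = q, loglik = fit$loglik[1], n_iter = fit$n_iter[1],
              converged = fit$converged[1])
  if (trace) out$trace <- fit$trace[[1]]
  if (!out$converged)
    warning("EM did not converge within max_iter; result flagged")
  out
}

#' Supervised ancestry estimation for a cohort
#'
#' Applies the per-individual supervised EM over the intersection of the
#' cohort's SNPs, a reference frequency table and an optional restriction set
#' (typically the preselected ancestry-informative markers). Optimisations are
#' decoupled across individuals because the panel frequencies are fixed.
#'
#' @param genotypes dosage matrix, individuals x SNPs.
#' @param panel_freqs data.frame with `snp_id` and `f_<pop>` columns (e.g.
#'   from [allele_frequencies()]).
#' @param restrict_to optional character vector of SNP ids.
#' @param pop_names subpopulations to use (default: all `f_*` columns).
#' @param tol,max_iter EM controls, as in [supervised_ancestry_em()].
#' @return list of class `ancestry_fit`: `q` (n x K matrix), `q_NA_percent`
#'   (first-population percentage), `loglik`, `n_iter`, `converged`,
#'   `n_snps_used`, and `controls_summary` (filled by callers that know the
#'   phenotypes).
#' @export
estimate_cohort_ancestry <- function(genotypes, panel_freqs, restrict_to = NULL,
                                     pop_names = NULL, tol = 1e-6,
                                     max_iter = 2000L) {
  if (is.null(pop_names))
    pop_names <- sub("^f_", "", grep("^f_", names(panel_freqs), value = TRUE))
  snps <- intersect(colnames(genotypes), panel_freqs$snp_id)
  if (!is.null(restrict_to)) snps <- intersect(snps, restrict_to)
  if (!length(snps)) stop("no SNPs shared between cohort, panel and restriction set")
  f <- as.matrix(panel_freqs[match(snps, panel_freqs$snp_id),
                             paste0("f_", pop_names)])
  colnames(f) <- pop_names
  G <- t(genotypes[, snps, drop = FALSE])   # M x N for the C++ core
  fit <- .em_cohort_cpp(unname(G), .clip01(f), tol, as.integer(max_iter), FALSE)
  q <- fit$q
  dimnames(q) <- list(rownames(genotypes), pop_names)
  if (any(!fit$converged))
    warning(sprintf("EM did not converge for %d individual(s)", sum(!fit$converged)))
  out <- list(q = q, q_NA_percent = 100 * q[, 1], loglik = fit$loglik,
              n_iter = fit$n_iter, converged = fit$converged,
              n_snps_used = length(snps))
  class(out) <- "ancestry_fit"
  out
}

#' Median and interquartile range of an ancestry percentage
#'
#' @param q_pct numeric vector of ancestry percentages (0-100 scale).
#' @return named vector `median`, `q1`, `q3`.
#' @export
ancestry_summary <- function(q_pct) {
  qq <- quantile(q_pct, c(0.5, 0.25, 0.75), names = FALSE)
  c(median = qq[1], q1 = qq[2], q3 = qq[3])
}

#' Eigenstrat-style principal components of genotype data
#'
#' Columns (SNPs) are centred by twice the sample allele frequency and scaled
#' by `sqrt(p (1 - p))`; scores come from the singular value decomposition of
#' the normalised matrix. Monomorphic SNPs are dropped. The default frequency
#' estimate is the plain `p = mean(dosage) / 2`; `bayes = TRUE` switches to
#' the smoothed `(1 + sum g) / (2 + 2n)` variant.
#'
#' @param genotypes dosage matrix, individuals x SNPs (cohort plus panels for
#'   QC plots).
#' @param n_components number of components to return (>= 1).
#' @param bayes use the smoothed frequency estimate.
#' @return list of class `pca_result`: `scores` (n x n_components),
#'   `explained` (variance fraction per component, non-increasing),
#'   `n_snps_used`.
#' @export
eigenstrat_pca <- function(genotypes, n_components = 3L, bayes = FALSE) {
  g <- as.matrix(genotypes)
  n <- nrow(g)
  if (n_components >= n)
    stop("fewer samples than requested components")
  p <- if (bayes) (1 + colSums(g)) / (2 + 2 * n) else colMeans(g) / 2
  poly <- apply(g, 2, function(col) length(unique(col)) > 1)
  if (sum(poly) < 2) stop("need at least 2 polymorphic SNPs")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(x, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(n_components)))
  explained <- sv$d^2 / sum(sv$d^2)
  out <- list(scores = scores, explained = explained[seq_len(n_components)],
              n_snps_used = ncol(g))
  class(out) <- "pca_result"
  out
}
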