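#' Reference-panel allele frequencies
#'
#' Computes the effect (ALT) allele frequency per SNP in each labelled
#' reference panel, `p = sum(dosages) / (2 n)`, together with the unweighted
#' average frequency across panels — the ingredients of the informativeness
#' for assignment measure. SNPs with all genotypes missing in any panel are
#' dropped with a warning.
#'
#' @param panels named list of dosage matrices (individuals x SNPs), one per
#'   subpopulation, with identical SNP columns.
#' @return data.frame with `snp_id`, one column `f_<pop>` per panel and
#'   `p_bar` (unweighted mean across panels).
#' @export
allele_frequencies <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1)
  snps <- colnames(panels[[1]])
  freqs <- vapply(panels, function(g) {
    stopifnot(identical(colnames(g), snps))
    colMeans(g, na.rm = TRUE) / 2
  }, numeric(length(snps)))
  freqs <- matrix(freqs, nrow = length(snps),
                  dimnames = list(snps, names(panels)))
  bad <- !is.finite(freqs)
  drop <- apply(bad, 1, any)
  if (any(drop)) {
    warning(sprintf("dropping %d SNP(s) with all genotypes missing in a panel",
                    sum(drop)))
    freqs <- freqs[!drop, , drop = FALSE]
    snps <- snps[!drop]
  }
  out <- data.frame(snp_id = snps, stringsAsFactors = FALSE)
  for (k in seq_along(panels)) out[[paste0("f_", names(panels)[k])]] <- freqs[, k]
  out$p_bar <- rowMeans(freqs)
  rownames(out) <- out$snp_id
  out
}

# 0 * log(0) := 0
.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Informativeness for assignment (I_n)
#'
#' Entropy-based measure of how much a biallelic marker reveals about an
#' individual's subpopulation of origin, in nats:
#' `I_n = sum_j ( -p_j log p_j + sum_i (p_ij / K) log p_ij )`,
#' where `p_ij` is the frequency of allele j in subpopulation i and `p_j` the
#' unweighted average over the K subpopulations, with the convention
#' `0 log 0 = 0`. `I_n` is zero when all subpopulations share identical
#' frequencies and reaches `log K` for fixed differences.
#'
#' @param p matrix of effect-allele frequencies with one row per SNP and one
#'   column per subpopulation (a vector is treated as a single SNP).
#' @return numeric vector of I_n values (nats), one per SNP.
#' @export
informativeness <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("invalid input: allele frequencies must lie in [0, 1]")
  K <- ncol(p)
  res <- numeric(nrow(p))
  for (allele in 1:2) {
    pa <- if (allele == 1) p else 1 - p
    p_bar <- rowMeans(pa)
    res <- res - .xlogx(p_bar) + rowSums(.xlogx(pa)) / K
  }
  pmax(res, 0)   # guard against -eps from floating point
}

#' Preselect ancestry-informative markers
#'
#' For each ordered pair of subpopulations, ranks SNPs by the two-population
#' I_n (descending, ties broken by SNP id) and retains the `top_k` best; the
#' returned panel is the union of the per-comparison top lists, mirroring the
#' practice of keeping markers present in at least one comparison.
#'
#' @param freqs output of [allele_frequencies()] (or the simulator's frequency
#'   table; any data.frame with `snp_id` and `f_<pop>` columns).
#' @param comparisons list of length-2 character vectors naming subpopulation
#'   pairs, e.g. `list(c("NAM", "EUR"), c("NAM", "AFR"))`.
#' @param top_k markers retained per comparison (default 20000).
#' @return list of class `aim_panel`: `rankings` (data.frame with `snp_id`,
#'   `comparison`, `I_n`, `rank`) and `union` (character vector of retained
#'   SNP ids, in `snp_id` order).
#' @export
preselect_aims <- function(freqs, comparisons, top_k = 20000L) {
  stopifnot(top_k >= 1)
  rankings <- list()
  union_set <- character()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2)
    cols <- paste0("f_", cmp)
    if (!all(cols %in% names(freqs)))
      stop("frequency table lacks columns for comparison ", paste(cmp, collapse = "-"))
    p <- as.matrix(freqs[, cols])
    i_n <- informativeness(p)
    ord <- order(-i_n, freqs$snp_id)
    k <- min(top_k, length(ord))
    if (top_k > length(ord))
      message(sprintf("top_k = %d exceeds the %d available SNPs; retaining all",
                      top_k, length(ord)))
    sel <- ord[seq_len(k)]
    rankings[[paste(cmp, collapse = "-")]] <-
      data.frame(snp_id = freqs$snp_id[sel],
                 comparison = paste(cmp, collapse = "-"),
                 I_n = i_n[sel], rank = seq_len(k), stringsAsFactors = FALSE)
    union_set <- union(union_set, freqs$snp_id[sel])
  }
  out <- list(rankings = do.call(rbind, c(rankings, list(make.row.names = FALSE))),
              union = freqs$snp_id[freqs$snp_id %in% union_set])
  class(out) <- "aim_panel"
  out
}
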