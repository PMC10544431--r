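# Small in-code fixtures shared across test files.

# a fast, small simulation configuration
small_config <- function(seed = 1L, ...) {
  args <- list(n_snps = 400L, n_ref_per_pop = c(40L, 40L, 40L),
               n_cases = 100L, n_controls = 100L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# a frequency table built by hand (one row per SNP)
manual_freqs <- function(f_mat, pop_names = c("NAM", "EUR", "AFR")) {
  m <- nrow(f_mat)
  out <- data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
                    chr = "1", pos = seq_len(m) * 1000L,
                    ref = "A", alt = "G", p_ancestral = rowMeans(f_mat),
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(f_mat)))
    out[[paste0("f_", pop_names[k])]] <- f_mat[, k]
  rownames(out) <- out$snp_id
  out
}

# an instrument set assembled directly from effect vectors
manual_instruments <- function(gamma, Gamma, se_Gamma,
                               se_gamma = rep(0.1, length(gamma))) {
  exposure <- data.frame(snp_id = sprintf("iv%03d", seq_along(gamma)),
                         beta = gamma, se = se_gamma, stringsAsFactors = FALSE)
  outcome <- data.frame(snp_id = exposure$snp_id, beta = Gamma, se = se_Gamma,
                        stringsAsFactors = FALSE)
  harmonize(exposure, outcome)
}

# binomial 99% acceptance interval for a proportion
binom99 <- function(n, p) qbinom(c(0.005, 0.995), n, p) / n

# minimal Dirichlet draw for test construction
.rdirichlet_test <- function(alpha) {
  x <- rgamma(length(alpha), alpha)
  x / sum(x)
}
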