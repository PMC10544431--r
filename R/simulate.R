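#' Simulation configuration for an admixed case-control study
#'
#' Bundles every parameter of the synthetic-data generator: a Balding-Nichols
#' model for reference-panel allele frequencies, Dirichlet-distributed
#' individual admixture proportions, and a logistic disease model with a
#' causal per-1%-ancestry effect, an unobserved non-genetic confounder and a
#' small age effect.
#'
#' Defaults emulate the scale of a Latin American breast-cancer case-control
#' study: three ancestral populations (Native American, European, African),
#' `dirichlet_alpha = c(3.6, 1.7, 0.4)` giving a median Native American
#' proportion near 65% with interquartile range roughly 54-79% (the spread
#' observed in Mexican controls), drift parameters `fst = c(0.15, 0.09, 0.075)`
#' typical of common genotyping-array variants segregating in all three
#' source populations (and calibrated so the instrument-selection cascade
#' yields on the order of hundreds of genome-wide-significant markers thinning
#' to roughly a hundred instruments, the regime of published ancestry-MR
#' analyses), 700 cases and 700 controls, and a protective causal odds ratio
#' of 0.974 per percentage point of Native American ancestry.
#'
#' @param n_snps number of biallelic SNPs.
#' @param n_ref_per_pop integer vector, reference-panel size per subpopulation.
#' @param fst per-subpopulation Balding-Nichols drift parameter, each in (0,1).
#' @param dirichlet_alpha positive Dirichlet concentration parameters, one per
#'   subpopulation; individual ancestry vectors are drawn from this law.
#' @param n_cases,n_controls study sample sizes after case-control sampling.
#' @param beta_anc causal log-odds ratio per 1 percentage point of Native
#'   American ancestry (first subpopulation).
#' @param beta_conf log-odds ratio per standard deviation of the unobserved
#'   confounder.
#' @param conf_anc_corr correlation in \[-1, 1\] between the confounder and the
#'   (standardised) Native American ancestry percentage.
#' @param baseline_prev population disease prevalence in (0,1); the disease
#'   model intercept is calibrated to it by bisection.
#' @param beta_age log-odds ratio per year of age (small by design).
#' @param er_pos_share probability that a case at reference covariates is
#'   oestrogen-receptor positive.
#' @param beta_anc_er_pos,beta_anc_er_neg optional subtype-specific causal
#'   log-OR per 1% ancestry; default `NULL` uses `beta_anc` for both subtypes.
#' @param subtype_anc_slope log-odds change in the probability of an ER-positive
#'   subtype per 1% Native American ancestry among cases (0 = no dependence).
#' @param fam_history_prob probability of a positive first-degree family
#'   history of breast/ovarian cancer.
#' @param frac_phewas_flagged fraction of SNPs flagged in the synthetic
#'   phenome-wide association catalog.
#' @param n_pool size of the source population pool from which cases and
#'   controls are sampled; `NULL` picks a size large enough for the requested
#'   counts with a 30% margin.
#' @param ld_block_size if > 1, consecutive SNPs are grouped in blocks of this
#'   size and non-anchor block members are noisy copies of the anchor genotype,
#'   creating linkage disequilibrium for pruning exercises. Default 1 (unlinked).
#' @param ld_flip_prob per-allele flip probability used for block copies.
#' @param pop_names subpopulation labels; the first is the exposure ancestry.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce byte-identical outputs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_snps = 5000,
                       n_ref_per_pop = c(100, 107, 108),
                       fst = c(0.15, 0.09, 0.075),
                       dirichlet_alpha = c(3.6, 1.7, 0.4),
                       n_cases = 700, n_controls = 700,
                       beta_anc = log(0.974),
                       beta_conf = 0.5,
                       conf_anc_corr = -0.3,
                       baseline_prev = 0.05,
                       beta_age = 0.01,
                       er_pos_share = 0.65,
                       beta_anc_er_pos = NULL,
                       beta_anc_er_neg = NULL,
                       subtype_anc_slope = 0,
                       fam_history_prob = 0.15,
                       frac_phewas_flagged = 0.05,
                       n_pool = NULL,
                       ld_block_size = 1,
                       ld_flip_prob = 0.05,
                       pop_names = c("NAM", "EUR", "AFR"),
                       seed = 1L) {
  K <- length(pop_names)
  stopifnot(K >= 2)
  if (length(fst) != K || length(dirichlet_alpha) != K || length(n_ref_per_pop) != K)
    stop("fst, dirichlet_alpha and n_ref_per_pop must have one entry per subpopulation")
  if (any(fst <= 0) || any(fst >= 1))
    stop("invalid parameter: every fst must lie in (0, 1)")
  if (any(dirichlet_alpha <= 0)) stop("invalid parameter: dirichlet_alpha must be positive")
  if (any(c(n_snps, n_ref_per_pop, n_cases, n_controls) <= 0))
    stop("invalid parameter: counts must be positive")
  if (baseline_prev <= 0 || baseline_prev >= 1)
    stop("invalid parameter: baseline_prev must lie in (0, 1)")
  if (abs(conf_anc_corr) > 1) stop("invalid parameter: conf_anc_corr must lie in [-1, 1]")
  if (frac_phewas_flagged < 0 || frac_phewas_flagged > 1)
    stop("invalid parameter: frac_phewas_flagged must lie in [0, 1]")
  if (!is.finite(beta_anc)) stop("invalid parameter: beta_anc must be finite")
  if (is.null(n_pool))
    n_pool <- ceiling(1.3 * max(n_cases / baseline_prev,
                                n_controls / (1 - baseline_prev)))
  cfg <- list(n_snps = as.integer(n_snps),
              n_ref_per_pop = as.integer(n_ref_per_pop),
              fst = fst, dirichlet_alpha = dirichlet_alpha,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              beta_anc = beta_anc, beta_conf = beta_conf,
              conf_anc_corr = conf_anc_corr, baseline_prev = baseline_prev,
              beta_age = beta_age, er_pos_share = er_pos_share,
              beta_anc_er_pos = beta_anc_er_pos, beta_anc_er_neg = beta_anc_er_neg,
              subtype_anc_slope = subtype_anc_slope,
              fam_history_prob = fam_history_prob,
              frac_phewas_flagged = frac_phewas_flagged,
              n_pool = as.integer(n_pool),
              ld_block_size = as.integer(ld_block_size),
              ld_flip_prob = ld_flip_prob,
              pop_names = pop_names, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Stage-specific deterministic seeds derived from the configuration seed.
.stage_seed <- function(config, stage) {
  offsets <- c(freqs = 101L, panel = 202L, cohort = 303L, outcome = 404L,
               phewas = 505L, genotypes = 606L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

.clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Draw ancestral and subpopulation allele frequencies (Balding-Nichols)
#'
#' Each SNP receives an ancestral frequency uniform on \[0.05, 0.95\]; the
#' frequency in subpopulation k is then drawn from
#' `Beta(p (1 - F_k) / F_k, (1 - p) (1 - F_k) / F_k)`, so that drift is
#' governed by the per-population parameter F_k while the expectation stays at
#' the ancestral frequency.
#'
#' @param config a [sim_config()].
#' @return a data.frame with `snp_id`, `chr`, `pos`, `ref`, `alt`,
#'   `p_ancestral` and one frequency column `f_<pop>` per subpopulation
#'   (frequency of the ALT allele, the effect allele throughout the package).
#' @export
simulate_ancestral_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "freqs"))
  M <- config$n_snps
  p <- runif(M, 0.05, 0.95)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  out <- data.frame(snp_id = sprintf("rs%06d", seq_len(M)),
                    chr = "1", pos = seq_len(M) * 1000L,
                    ref = ref, alt = alt, p_ancestral = p,
                    stringsAsFactors = FALSE)
  for (k in seq_along(config$pop_names)) {
    Fk <- config$fst[k]
    a <- p * (1 - Fk) / Fk
    b <- (1 - p) * (1 - Fk) / Fk
    out[[paste0("f_", config$pop_names[k])]] <- .clip01(rbeta(M, a, b))
  }
  rownames(out) <- out$snp_id
  out
}

.freq_matrix <- function(freqs, pop_names) {
  f <- as.matrix(freqs[paste0("f_", pop_names)])
  dimnames(f) <- list(freqs$snp_id, pop_names)
  f
}

#' Simulate labelled reference panels
#'
#' Draws `n_ref_per_pop[k]` diploid individuals per subpopulation with dosages
#' Binomial(2, f_k) independently per SNP, standing in for the external
#' reference panels (e.g. 1000 Genomes IBS/YRI plus Native American panels)
#' used to anchor ancestry estimation.
#'
#' @param freqs output of [simulate_ancestral_frequencies()].
#' @param config a [sim_config()].
#' @return named list of dosage matrices (individuals x SNPs), one per
#'   subpopulation.
#' @export
simulate_reference_panel <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "panel"))
  f <- .freq_matrix(freqs, config$pop_names)
  M <- nrow(f)
  panels <- list()
  for (k in seq_along(config$pop_names)) {
    n <- config$n_ref_per_pop[k]
    g <- matrix(rbinom(n * M, 2L, rep(f[, k], each = n)), nrow = n,
                dimnames = list(sprintf("%s_%03d", config$pop_names[k], seq_len(n)),
                                rownames(f)))
    panels[[config$pop_names[k]]] <- g
  }
  panels
}

.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# genotype draw for admixed individuals: dosage ~ Binomial(2, q %*% f')
.draw_admixed_genotypes <- function(q, f, flip_prob = 0, block_size = 1L) {
  x <- q %*% t(f)               # n x M individual-specific allele frequencies
  n <- nrow(x); M <- ncol(x)
  g <- matrix(rbinom(n * M, 2L, x), nrow = n,
              dimnames = list(rownames(q), rownames(f)))
  if (block_size > 1L) {
    anchor <- ((seq_len(M) - 1L) %/% block_size) * block_size + 1L
    copies <- which(anchor != seq_len(M))
    if (length(copies))
      g[, copies] <- .noisy_copy(g[, anchor[copies], drop = FALSE], flip_prob)
  }
  g
}

# copy a dosage matrix, resampling each of the two alleles with prob flip_prob
.noisy_copy <- function(g, flip_prob) {
  n <- length(g)
  a1 <- (g >= 1) + 0L; a2 <- (g == 2) + 0L
  fl1 <- rbinom(n, 1L, flip_prob) == 1L
  fl2 <- rbinom(n, 1L, flip_prob) == 1L
  a1[fl1] <- 1L - a1[fl1]
  a2[fl2] <- 1L - a2[fl2]
  out <- a1 + a2
  dim(out) <- dim(g)
  dimnames(out) <- dimnames(g)
  out
}

#' Simulate an admixed cohort (genotypes and true ancestry)
#'
#' Individual ancestry vectors are Dirichlet-distributed; dosages are drawn
#' Binomial(2, sum_k q_k f_k) per SNP, so global admixture proportions (the
#' exposure of interest) are exact by construction.
#'
#' @param freqs output of [simulate_ancestral_frequencies()].
#' @param config a [sim_config()].
#' @param n number of individuals (defaults to the configured pool size).
#' @param genotypes draw the dosage matrix (set `FALSE` to simulate ancestry
#'   and phenotypes for a large pool cheaply; genotypes can be filled in later
#'   for the sampled study with [fill_genotypes()]).
#' @return an `admix_cohort` list with elements `true_q` (n x K matrix),
#'   `genotypes` (n x M dosage matrix or `NULL`) and `samples` (data.frame
#'   skeleton with `sample_id`).
#' @export
simulate_admixed_cohort <- function(freqs, config, n = config$n_pool,
                                    genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "cohort"))
  K <- length(config$pop_names)
  q <- .rdirichlet(n, config$dirichlet_alpha)
  dimnames(q) <- list(sprintf("IND_%05d", seq_len(n)), config$pop_names)
  g <- NULL
  if (genotypes) {
    f <- .freq_matrix(freqs, config$pop_names)
    g <- .draw_admixed_genotypes(q, f, config$ld_flip_prob, config$ld_block_size)
  }
  cohort <- list(true_q = q, genotypes = g,
                 samples = data.frame(sample_id = rownames(q),
                                      stringsAsFactors = FALSE),
                 freqs = freqs)
  class(cohort) <- "admix_cohort"
  cohort
}

#' Fill in genotypes for a (sub)cohort simulated without them
#'
#' @param cohort an `admix_cohort` with `genotypes = NULL`.
#' @param config the generating [sim_config()].
#' @return the cohort with a dosage matrix attached.
#' @export
fill_genotypes <- function(cohort, config) {
  stopifnot(inherits(cohort, "admix_cohort"))
  set.seed(.stage_seed(config, "genotypes"))
  f <- .freq_matrix(cohort$freqs, config$pop_names)
  cohort$genotypes <- .draw_admixed_genotypes(cohort$true_q, f,
                                              config$ld_flip_prob,
                                              config$ld_block_size)
  cohort
}

# subtype linear predictors for the competing ER+/ER- disease model;
# returns an n x 2 matrix of per-subtype logits without intercepts
.subtype_eta <- function(q_pct, U, age, config) {
  b_pos <- if (is.null(config$beta_anc_er_pos)) config$beta_anc else config$beta_anc_er_pos
  b_neg <- if (is.null(config$beta_anc_er_neg)) config$beta_anc else config$beta_anc_er_neg
  shared <- config$beta_conf * U + config$beta_age * (age - 50)
  cbind(pos = b_pos * q_pct + shared,
        neg = b_neg * q_pct + shared)
}

# population prevalence of any-case at shared intercept offset cc
.prevalence_at <- function(cc, eta, a_share) {
  p_pos <- plogis(cc + a_share[1] + eta[, 1])
  p_neg <- plogis(cc + a_share[2] + eta[, 2])
  mean(1 - (1 - p_pos) * (1 - p_neg))
}

#' Assign disease status and clinical attributes, then sample a study
#'
#' Implements the disease model: an unobserved confounder
#' `U = rho * standardised(q_NA%) + sqrt(1 - rho^2) * N(0, 1)`, age drawn
#' N(50, 8^2) truncated to \[25, 80\], and two competing tumour subtypes
#' (ER-positive / ER-negative) whose shared intercept is calibrated by
#' bisection (tolerance 1e-6) so the population prevalence of disease equals
#' `baseline_prev`. Cases receive age at diagnosis, family history and
#' ER/PR/HER2 labels; triple-negative status is ER-, PR- and HER2-.
#'
#' @param cohort an `admix_cohort` (typically the population pool).
#' @param config a [sim_config()].
#' @param sample_cc if `TRUE` (default) sample exactly `n_cases` cases and
#'   `n_controls` controls from the pool; if `FALSE` return the full pool with
#'   status assigned (useful for checking the disease model itself).
#' @return an `admix_cohort` whose `samples` data.frame carries `status`
#'   (1 = case), `age`, `age_at_diagnosis`, `family_history`, `er`, `pr`,
#'   `her2`, plus hidden generator columns `confounder` and `q_NA_pct`.
#' @export
simulate_outcome <- function(cohort, config, sample_cc = TRUE) {
  stopifnot(inherits(cohort, "admix_cohort"), inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "outcome"))
  n <- nrow(cohort$true_q)
  q_pct <- 100 * cohort$true_q[, 1]
  z <- (q_pct - mean(q_pct)) / sd(q_pct)
  rho <- config$conf_anc_corr
  U <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  age <- qnorm(runif(n, pnorm(25, 50, 8), pnorm(80, 50, 8)), 50, 8)

  eta <- .subtype_eta(q_pct, U, age, config)
  a_share <- c(pos = qlogis(config$er_pos_share) / 2,
               neg = qlogis(1 - config$er_pos_share) / 2)
  lo <- -30; hi <- 10
  repeat {
    cc <- (lo + hi) / 2
    prev <- .prevalence_at(cc, eta, a_share)
    if (hi - lo < 1e-6) break
    if (prev < config$baseline_prev) lo <- cc else hi <- cc
  }
  p_pos <- plogis(cc + a_share[1] + eta[, 1])
  p_neg <- plogis(cc + a_share[2] + eta[, 2])
  case_pos <- rbinom(n, 1L, p_pos) == 1L
  case_neg <- rbinom(n, 1L, p_neg) == 1L
  status <- as.integer(case_pos | case_neg)

  # subtype of a case: whichever competing tumour occurred (ties resolved in
  # proportion to the two risks); optional extra ancestry dependence
  er <- rep(NA_character_, n)
  both <- case_pos & case_neg
  er[case_pos & !case_neg] <- "pos"
  er[case_neg & !case_pos] <- "neg"
  if (any(both)) {
    pr_pos <- p_pos[both] / (p_pos[both] + p_neg[both])
    er[both] <- ifelse(runif(sum(both)) < pr_pos, "pos", "neg")
  }
  if (config$subtype_anc_slope != 0) {
    idx <- which(status == 1L)
    p_er <- plogis(qlogis(config$er_pos_share) +
                     config$subtype_anc_slope * (q_pct[idx] - mean(q_pct)))
    er[idx] <- ifelse(runif(length(idx)) < p_er, "pos", "neg")
  }
  pr <- ifelse(er == "pos",
               ifelse(runif(n) < 0.85, "pos", "neg"),
               ifelse(runif(n) < 0.10, "pos", "neg"))
  her2 <- ifelse(er == "pos",
                 ifelse(runif(n) < 0.15, "pos", "neg"),
                 ifelse(runif(n) < 0.30, "pos", "neg"))
  pr[status == 0L] <- NA_character_
  her2[status == 0L] <- NA_character_
  fam <- rbinom(n, 1L, config$fam_history_prob) == 1L

  samples <- data.frame(sample_id = cohort$samples$sample_id,
                        status = status, age = age,
                        age_at_diagnosis = ifelse(status == 1L, age, NA_real_),
                        family_history = fam, er = er, pr = pr, her2 = her2,
                        confounder = U, q_NA_pct = q_pct,
                        stringsAsFactors = FALSE)
  cohort$samples <- samples
  cohort$disease_intercept <- cc

  if (!sample_cc) return(cohort)

  cases <- which(status == 1L)
  controls <- which(status == 0L)
  if (length(cases) < config$n_cases)
    stop(sprintf(paste("only %d cases generated but %d requested;",
                       "increase n_pool or baseline_prev"),
                 length(cases), config$n_cases))
  if (length(controls) < config$n_controls)
    stop(sprintf("only %d controls generated but %d requested; increase n_pool",
                 length(controls), config$n_controls))
  keep <- c(sample(cases, config$n_cases), sample(controls, config$n_controls))
  cohort$true_q <- cohort$true_q[keep, , drop = FALSE]
  cohort$samples <- cohort$samples[keep, , drop = FALSE]
  rownames(cohort$samples) <- NULL
  if (!is.null(cohort$genotypes))
    cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  cohort
}

# phenotype exclusion list used by the synthetic phenome-wide catalog
.phewas_phenotypes <- c("menopause", "pregnancy outcomes", "tobacco smoking",
                        "alcohol consumption", "educational level",
                        "contraceptives", "hormone-replacement therapy",
                        "diabetes", "body circumference", "breast cancer")

#' Simulate a PheWAS exclusion catalog
#'
#' A configurable fraction of SNPs is flagged: each flagged SNP receives at
#' least one catalog row with a confounder-list phenotype and a p-value drawn
#' log-uniformly below 5e-8. A random tenth of the unflagged SNPs receive
#' benign rows with p-values at or above 5e-8 (these must survive filtering).
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param config a [sim_config()].
#' @return data.frame with columns `snp_id`, `phenotype`, `pval`.
#' @export
simulate_phewas_catalog <- function(snp_ids, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, "phewas"))
  flagged <- snp_ids[rbinom(length(snp_ids), 1L, config$frac_phewas_flagged) == 1L]
  rows <- list()
  if (length(flagged)) {
    n_rows <- 1L + rbinom(length(flagged), 1L, 0.3)
    ids <- rep(flagged, n_rows)
    rows[[1]] <- data.frame(
      snp_id = ids,
      phenotype = sample(.phewas_phenotypes, length(ids), replace = TRUE),
      pval = 10^runif(length(ids), -30, log10(5e-8) - 1e-9),
      stringsAsFactors = FALSE)
  }
  benign <- if (config$frac_phewas_flagged > 0) setdiff(snp_ids, flagged)
            else character(0)
  benign <- benign[runif(length(benign)) < 0.1]
  if (length(benign)) {
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = benign,
      phenotype = sample(.phewas_phenotypes, length(benign), replace = TRUE),
      pval = 10^runif(length(benign), log10(5e-8), -2),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), phenotype = character(),
                      pval = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$snp_id, out$pval), , drop = FALSE]
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper running the whole generator: ancestral and panel
#' frequencies, labelled reference panels, a population pool with ancestry and
#' disease status, case-control sampling, genotype draw for the sampled study
#' and a PheWAS catalog. Genotypes are drawn only for sampled individuals
#' (dosages are independent of status given ancestry, so this is
#' distributionally identical to genotyping the whole pool).
#'
#' @param config a [sim_config()].
#' @return list with `freqs`, `panels`, `cohort` (sampled case-control study
#'   with genotypes), `phewas` and `config`.
#' @export
simulate_mr_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- simulate_ancestral_frequencies(config)
  panels <- simulate_reference_panel(freqs, config)
  pool <- simulate_admixed_cohort(freqs, config, genotypes = FALSE)
  cohort <- simulate_outcome(pool, config)
  cohort <- fill_genotypes(cohort, config)
  phewas <- simulate_phewas_catalog(freqs$snp_id, config)
  list(freqs = freqs, panels = panels, cohort = cohort, phewas = phewas,
       config = config)
}
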