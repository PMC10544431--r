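#' Pipeline thresholds and options
#'
#' All tunable thresholds of the instrument-selection and MR stages, with the
#' published defaults: genome-wide significance 5e-8 for the exposure scan,
#' 5e-8 for the PheWAS exclusion, r^2 > 0.01 for LD pruning, p < 0.1 for
#' radial outlier exclusion, and 20000 top markers per ancestry comparison.
#'
#' @param gwas_p exposure-association threshold.
#' @param phewas_p PheWAS exclusion threshold.
#' @param ld_r2 LD pruning threshold (retain at or below).
#' @param radial_p radial outlier exclusion threshold.
#' @param top_k ancestry-informative markers retained per comparison.
#' @param max_ivs optional cap on the number of instruments carried into the
#'   MR stage; when the LD-pruned candidate list is longer, the markers with
#'   the highest explained variance are kept (the same device used in
#'   published sensitivity analyses that limit the instrument count, and a
#'   guard against cumulative explained variance reaching 1 in very large
#'   cohorts). Default `Inf` (no cap).
#' @param wm_seed seed for the weighted-median bootstrap.
#' @param ld_adjust_ancestry assess LD between candidate instruments on
#'   dosages residualised on the estimated ancestry percentage. Admixture
#'   makes every ancestry-informative marker correlate with every other one
#'   genome-wide; that structure is the signal the instruments share, not
#'   linkage, so pruning on raw dosage correlation at a strict threshold
#'   would discard almost all instruments. The partial correlation given
#'   ancestry isolates genuine (physical) linkage. Set `FALSE` for raw
#'   composite LD.
#' @param ancestry_samples estimate individual ancestry for `"controls"`
#'   (the exposure sample — all the MR needs) or `"all"` cohort members
#'   (for QC plots).
#' @param strata named list of case-stratum predicates (functions of the
#'   samples data.frame returning a logical over rows); `NULL` uses the
#'   standard clinical strata (diagnosis at 45 or earlier, familial,
#'   ER-positive, ER-negative, triple-negative), `FALSE` disables them.
#' @return list of class `mr_pipeline_config`.
#' @export
mr_pipeline_config <- function(gwas_p = 5e-8, phewas_p = 5e-8, ld_r2 = 0.01,
                               radial_p = 0.1, top_k = 20000L, max_ivs = Inf,
                               wm_seed = 1L,
                               ld_adjust_ancestry = TRUE,
                               ancestry_samples = c("controls", "all"),
                               strata = NULL) {
  for (p in c(gwas_p, phewas_p, radial_p))
    if (p <= 0 || p > 1) stop("thresholds must lie in (0, 1]")
  if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must lie in [0, 1]")
  out <- list(gwas_p = gwas_p, phewas_p = phewas_p, ld_r2 = ld_r2,
              radial_p = radial_p, top_k = as.integer(top_k),
              max_ivs = max_ivs, wm_seed = as.integer(wm_seed),
              ld_adjust_ancestry = isTRUE(ld_adjust_ancestry),
              ancestry_samples = match.arg(ancestry_samples), strata = strata)
  class(out) <- "mr_pipeline_config"
  out
}

#' Standard clinical case strata
#'
#' @param samples the cohort samples data.frame.
#' @return named list of logical vectors over its rows (cases only).
#' @export
default_strata <- function(samples) {
  list(
    diag_le_45 = samples$status == 1 & !is.na(samples$age_at_diagnosis) &
      samples$age_at_diagnosis <= 45,
    familial = samples$status == 1 & samples$family_history %in% TRUE,
    er_pos = samples$status == 1 & samples$er %in% "pos",
    er_neg = samples$status == 1 & samples$er %in% "neg",
    triple_negative = samples$status == 1 & samples$er %in% "neg" &
      samples$pr %in% "neg" & samples$her2 %in% "neg"
  )
}

# attach VCF allele labels to a scan's summary statistics
.add_alleles <- function(stats, freqs) {
  idx <- match(stats$snp_id, freqs$snp_id)
  stats$effect_allele <- freqs$alt[idx]
  stats$other_allele <- freqs$ref[idx]
  stats$chr <- freqs$chr[idx]
  stats$pos <- freqs$pos[idx]
  stats[, c("snp_id", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")]
}

# shared MR tail: harmonize, radial filtering, estimators; rho = dosage
# correlation of the candidate instruments in the outcome sample, used for
# the correlation-aware IVW variance
.mr_from_scans <- function(exposure_stats, outcome_stats, pconfig,
                           methods = c("IVW", "Egger", "WM"), rho = NULL) {
  inst <- harmonize(exposure_stats, outcome_stats)
  rad <- radial_outlier_filter(inst, alpha = pconfig$radial_p)
  inst <- rad$instruments
  res <- list()
  if ("IVW" %in% methods) res$ivw <- ivw(inst, rho = rho)
  if ("Egger" %in% methods && nrow(inst) >= 3) res$egger <- mr_egger(inst)
  if ("WM" %in% methods && nrow(inst) >= 3)
    res$wm <- weighted_median(inst, seed = pconfig$wm_seed)
  list(instruments = inst, removed = rad$removed, results = res)
}

#' Run the full ancestry-MR pipeline on a study bundle
#'
#' Orchestrates the flowchart end-to-end: ancestry-informative-marker
#' preselection from the reference panels, supervised ancestry estimation for
#' the cohort, age-adjusted exposure scan among controls (sample 1),
#' PheWAS exclusion, explained-variance-ranked LD pruning, age-adjusted
#' outcome scan among cases and controls (sample 2) for the preliminary
#' instruments, radial outlier exclusion, and the IVW / MR-Egger /
#' weighted-median estimates, plus the clinical strata. Per-stage SNP counts
#' (the selection waterfall) and the control ancestry median/IQR are recorded.
#'
#' @param study a bundle from [simulate_mr_study()] (or an equivalent list
#'   with `freqs`, `panels`, `cohort`, `phewas`).
#' @param pconfig an [mr_pipeline_config()].
#' @return list of class `mr_report`.
#' @export
run_pipeline <- function(study, pconfig = mr_pipeline_config()) {
  cohort <- study$cohort
  samples <- cohort$samples
  pop_names <- names(study$panels)

  panel_freqs <- allele_frequencies(study$panels)
  comparisons <- lapply(pop_names[-1], function(p) c(pop_names[1], p))
  aims <- preselect_aims(panel_freqs, comparisons, top_k = pconfig$top_k)

  is_control <- samples$status == 0
  anc_rows <- if (pconfig$ancestry_samples == "all") rep(TRUE, nrow(samples)) else is_control
  anc <- estimate_cohort_ancestry(cohort$genotypes[anc_rows, , drop = FALSE],
                                  panel_freqs, restrict_to = aims$union)
  q_pct_ctrl <- anc$q_NA_percent[is_control[anc_rows]]
  anc_ctrl <- ancestry_summary(q_pct_ctrl)

  g_ctrl <- cohort$genotypes[is_control, aims$union, drop = FALSE]
  exposure_all <- linear_scan_ancestry(g_ctrl, q_pct_ctrl,
                                       samples$age[is_control])
  exposure_all <- .add_alleles(exposure_all, study$freqs)
  candidates <- exposure_all[exposure_all$pval < pconfig$gwas_p, , drop = FALSE]
  if (!nrow(candidates))
    stop("pipeline stage 'exposure scan': no SNP passed the significance threshold")

  kept_phewas <- phewas_filter(candidates$snp_id, study$phewas,
                               threshold = pconfig$phewas_p)
  candidates <- candidates[candidates$snp_id %in% kept_phewas, , drop = FALSE]

  # explained variance on the 0-1 ancestry-proportion scale
  candidates$expl_var <- explained_variance(candidates$beta / 100, candidates$eaf)
  g_prune <- g_ctrl[, candidates$snp_id, drop = FALSE]
  if (pconfig$ld_adjust_ancestry)
    g_prune <- qr.resid(qr(cbind(1, q_pct_ctrl)), g_prune)
  pruned_ids <- greedy_ld_prune(candidates$snp_id, candidates$expl_var,
                                g_prune, r2_threshold = pconfig$ld_r2)
  prelim <- candidates[match(pruned_ids, candidates$snp_id), , drop = FALSE]
  if (is.finite(pconfig$max_ivs) && nrow(prelim) > pconfig$max_ivs) {
    keep_iv <- order(-prelim$expl_var, prelim$snp_id)[seq_len(pconfig$max_ivs)]
    prelim <- prelim[sort(keep_iv), , drop = FALSE]
  }

  outcome_prelim <- logistic_scan_outcome(
    cohort$genotypes[, prelim$snp_id, drop = FALSE],
    samples$status, samples$age)
  outcome_prelim <- .add_alleles(outcome_prelim, study$freqs)
  rho_out <- cor(cohort$genotypes[, prelim$snp_id, drop = FALSE])

  main <- .mr_from_scans(prelim, outcome_prelim, pconfig, rho = rho_out)
  final <- prelim[prelim$snp_id %in% main$instruments$snp_id, , drop = FALSE]
  strength <- instrument_strength(final$expl_var, n = sum(is_control),
                                  per_iv_t = final$beta / final$se)
  for (m in names(main$results)) {
    main$results[[m]]$r2_cumulative <- strength$r2_cumulative
    main$results[[m]]$f_statistic <- strength$f_statistic
  }

  stage_counts <- c(preselected_aims = length(aims$union),
                    exposure_significant = sum(exposure_all$pval < pconfig$gwas_p),
                    after_phewas = length(kept_phewas),
                    preliminary_ivs = nrow(prelim),
                    final_ivs = nrow(main$instruments))

  strata_defs <- pconfig$strata
  if (is.null(strata_defs)) strata_defs <- default_strata(samples)
  strata_res <- list()
  if (!identical(strata_defs, FALSE)) {
    if (is.function(strata_defs)) strata_defs <- strata_defs(samples)
    for (s in names(strata_defs)) {
      strata_res[[s]] <- tryCatch(
        stratified_run(cohort, strata_defs[[s]], prelim, pconfig,
                       freqs = study$freqs),
        error = function(e) {
          message(sprintf("stratum '%s' skipped: %s", s, conditionMessage(e)))
          NULL
        })
    }
  }

  out <- list(stage_counts = stage_counts,
              ancestry = anc, ancestry_controls = anc_ctrl,
              exposure_stats = exposure_all,
              preliminary_ivs = prelim,
              outcome_stats = outcome_prelim,
              instruments = main$instruments,
              radial_removed = main$removed,
              strength = strength,
              results = main$results,
              strata = strata_res,
              pconfig = pconfig,
              seed = study$config$seed)
  class(out) <- "mr_report"
  out
}

#' Stratified MR analysis
#'
#' Re-runs the outcome scan and the MR tail for one case stratum (cases in
#' the stratum plus all controls, per the two-sample design in which controls
#' are reused unchanged); the exposure scan and the preliminary instrument
#' list are shared with the main analysis, so instrument counts differ across
#' strata only through radial exclusion.
#'
#' @param cohort the study cohort (`admix_cohort`).
#' @param stratum logical vector over the cohort samples selecting the
#'   stratum's cases (controls are ignored and always included).
#' @param prelim preliminary-instrument summary statistics from the main run.
#' @param pconfig an [mr_pipeline_config()].
#' @param freqs the SNP table carrying allele labels.
#' @return list with `results` (IVW and sensitivity estimates), `instruments`,
#'   `n_cases`, `strength`.
#' @export
stratified_run <- function(cohort, stratum, prelim, pconfig, freqs) {
  samples <- cohort$samples
  stratum_cases <- stratum & samples$status == 1
  if (sum(stratum_cases) < 30)
    stop(sprintf("stratum has %d cases (< 30): estimates would be unstable",
                 sum(stratum_cases)))
  keep <- stratum_cases | samples$status == 0
  outcome_s <- logistic_scan_outcome(
    cohort$genotypes[keep, prelim$snp_id, drop = FALSE],
    samples$status[keep], samples$age[keep])
  outcome_s <- .add_alleles(outcome_s, freqs)
  rho_s <- cor(cohort$genotypes[keep, prelim$snp_id, drop = FALSE])
  fit <- .mr_from_scans(prelim, outcome_s, pconfig, methods = "IVW", rho = rho_s)
  final <- prelim[prelim$snp_id %in% fit$instruments$snp_id, , drop = FALSE]
  strength <- instrument_strength(final$expl_var, n = sum(samples$status == 0),
                                  per_iv_t = final$beta / final$se)
  for (m in names(fit$results)) {
    fit$results[[m]]$r2_cumulative <- strength$r2_cumulative
    fit$results[[m]]$f_statistic <- strength$f_statistic
  }
  list(results = fit$results, instruments = fit$instruments,
       n_cases = sum(stratum_cases), strength = strength)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Ancestry-MR pipeline report\n")
  cat("  stage counts: ",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  control Native American ancestry: median %.1f%% (IQR %.1f-%.1f%%)\n",
              x$ancestry_controls["median"], x$ancestry_controls["q1"],
              x$ancestry_controls["q3"]))
  cat(sprintf("  cumulative explained variance %.1f%%, F = %.2f\n",
              100 * x$strength$r2_cumulative, x$strength$f_statistic))
  for (r in x$results) print(r)
  if (length(x$strata)) {
    cat("  strata:\n")
    for (s in names(x$strata)) {
      r <- x$strata[[s]]
      if (is.null(r)) next
      cat(sprintf("    %-16s n_cases=%4d  ", s, r$n_cases))
      iv <- r$results$ivw
      cat(sprintf("IVW OR %.4f (%.4f-%.4f), #IV=%d\n",
                  iv$or, iv$ci_low, iv$ci_high, iv$n_iv))
    }
  }
  invisible(x)
}

#' Flatten an `mr_report` into a table of estimates
#'
#' One row per (analysis, method), mirroring the columns of a published MR
#' results table: instrument count, explained variance (%), OR with 95% CI,
#' p-value, Cochran's Q p-value and Egger intercept p-value.
#'
#' @param report an `mr_report`.
#' @return data.frame.
#' @export
mr_report_table <- function(report) {
  row_of <- function(analysis, r) {
    data.frame(analysis = analysis, method = r$method, n_iv = r$n_iv,
               expl_var_pct = 100 * r$r2_cumulative, or = r$or,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               q_pval = r$q_pval, intercept_pval = r$egger_intercept_pval,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(report$results, function(r) row_of("main", r))
  for (s in names(report$strata)) {
    r <- report$strata[[s]]
    if (!is.null(r)) rows <- c(rows, lapply(r$results, function(x) row_of(s, x)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
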