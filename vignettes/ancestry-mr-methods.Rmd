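---
title: "Estimating the effect of genetic ancestry on disease risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the effect of genetic ancestry on disease risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixMR)
```

## The scientific problem

Latin American populations are admixed: individual genomes carry Native
American, European and African segments in varying proportions, and the
individual proportion of Native American ancestry has repeatedly been found
to be inversely associated with breast-cancer risk. Whether that association
is causal or driven by socio-economic and reproductive confounders correlated
with ancestry cannot be settled by covariate adjustment alone, because key
confounders are unknown or badly measured. `admixMR` implements an
instrumental-variable strategy for this question: ancestry-informative
markers (AIMs) are used as instruments for the individual admixture
proportion, and the ancestry-disease effect is estimated by two-sample
Mendelian randomization (MR) from age-adjusted per-SNP summary statistics —
the SNP-exposure scan fitted among controls (sample 1) and the SNP-outcome
scan fitted among cases and controls (sample 2).

Because the individual-level data of the motivating studies are not publicly
available, the package ships a first-class synthetic-data generator that
reproduces the statistical structure the analysis assumes, so every stage of
the pipeline is testable end to end.

## The synthetic cohort model

`sim_config()` fixes the generator. Its components:

* **Reference panels.** Allele frequencies follow the Balding–Nichols model:
  an ancestral frequency $p \sim U(0.05, 0.95)$ per SNP, and
  $p_k \sim \mathrm{Beta}\left(p\frac{1-F_k}{F_k},\,(1-p)\frac{1-F_k}{F_k}\right)$
  in subpopulation $k$, so $E[p_k] = p$ and drift is governed by $F_k$.
  Default $F = (0.15, 0.09, 0.075)$ for the Native American, European and
  African panels. These values were calibrated once so that the
  instrument-selection cascade reproduces the regime of published
  ancestry-MR analyses of breast cancer: a few hundred genome-wide
  significant AIMs thinning to roughly 100–170 instruments, with a mean
  per-instrument F statistic near 55 and a cumulative explained variance in
  the 30–40% range.
* **Admixture.** Individual ancestry vectors $q$ are Dirichlet with
  $\alpha = (3.6, 1.7, 0.4)$, giving a median Native American proportion of
  about 65% with interquartile range roughly 54–79%, the spread observed in
  Mexican control women. Dosages are $\mathrm{Binomial}(2, \sum_k q_k p_k)$:
  admixture is simulated at the genotype level, so the global proportions —
  the exposure — are exact by construction. SNPs are unlinked by default;
  `ld_block_size > 1` plants blocks of noisy genotype copies purely to
  exercise LD pruning.
* **Disease model.** Age is $N(50, 8^2)$ truncated to [25, 80]. An
  unobserved confounder is
  $U = \rho\,\tilde q + \sqrt{1-\rho^2}\,\varepsilon$ with $\tilde q$ the
  standardised Native American percentage. Two competing tumour subtypes
  (ER-positive, ER-negative) have logistic risks with per-1%-ancestry
  log-odds $\beta_{\mathrm{ER}+}, \beta_{\mathrm{ER}-}$ (both default to
  `beta_anc` $= \log 0.974$), a confounder term $\beta_c U$ and a small age
  term; the shared intercept is calibrated by bisection (tolerance $10^{-6}$)
  so the population prevalence equals `baseline_prev` (default 0.05, a
  lifetime breast-cancer risk typical of Latin American women). Cases and
  controls are then sampled to the requested counts; PR/HER2 labels and
  family history complete the clinical table. The low default prevalence is
  also a deliberate numerical choice: it keeps marginal odds ratios nearly
  collapsible, so the per-SNP outcome scan estimates are close to the
  generative conditional effects.
* **PheWAS catalog.** A configurable fraction of SNPs receives catalog rows
  linking them to confounder phenotypes (menopause, smoking, diabetes, and
  so on) at $p < 5\times10^{-8}$, standing in for a phenome-wide association
  database query.

What the generator does **not** emulate: haplotype structure and local
ancestry, genotyping error, relatedness, selection of controls by matching
variables other than age, and real allele-frequency spectra. Passing tests
therefore validate the statistical machinery under the stated model, not the
idiosyncrasies of any particular genotyping array.

## Marker preselection

For each pair of populations (Native American vs European, Native American
vs African) the informativeness for assignment of each biallelic SNP is

$$I_n = \sum_{j=1}^{2}\Big({-\bar p_j}\log \bar p_j +
  \sum_{i=1}^{K}\frac{p_{ij}}{K}\log p_{ij}\Big),$$

with $\bar p_j$ the unweighted average of the allele-$j$ frequency over the
$K = 2$ populations of the comparison and the convention $0\log 0 = 0$.
Natural logarithms are used; the only downstream use of $I_n$ is ranking,
which is base-invariant. Ties at the retention boundary break by SNP
identifier for determinism. The panel retains the top 20000 markers per
comparison and takes the union.

## Supervised ancestry estimation

With panel frequencies $f_{ik}$ fixed, the log-likelihood of one
individual's dosages $g_i$ is
$\sum_i [g_i \log x_i + (2-g_i)\log(1-x_i)]$, $x_i = \sum_k q_k f_{ik}$,
which is concave in $q$ on the simplex. It is maximised per individual by
expectation–maximisation,
$$q_k \leftarrow \frac{1}{2M}\sum_i \Big[\frac{g_i q_k f_{ik}}{x_i}
  + \frac{(2-g_i)\,q_k (1-f_{ik})}{1-x_i}\Big],$$
from the uniform start (no restarts needed under concavity), with panel
frequencies clipped to $[10^{-6}, 1-10^{-6}]$ and missing dosages skipped.
Plain EM needs hundreds of iterations to reach the default tolerance
($|\Delta \ell| < 10^{-6}$), so the C++ core accelerates it by squared
extrapolation (SQUAREM) with a log-likelihood safeguard: an extrapolated
point is accepted only if it does not decrease the likelihood, otherwise the
plain double EM step is taken. The iterate sequence is therefore monotone
and the fixed points are exactly the EM ones; `trace = TRUE` runs
unaccelerated EM and returns the per-iteration log-likelihood for
diagnostics. Log-likelihoods are evaluated by product accumulation with
exponent harvesting rather than per-SNP `log()` calls. Non-convergence
within `max_iter` is flagged, never hidden.

Principal components use the eigenstrat normalisation (centre by $2\hat p$,
scale by $\sqrt{\hat p(1-\hat p)}$, singular value decomposition); the
smoothed frequency estimate $(1+\sum g)/(2+2n)$ is available behind the
`bayes` flag. The components are quality-control output only.

## Instrument selection

Among controls, each SNP is regressed (ordinary least squares) on the
estimated ancestry percentage with age as covariate; markers with
$p < 5\times10^{-8}$ advance. Markers with a sub-threshold
($p < 5\times10^{-8}$) catalog entry for a confounder phenotype are
excluded. Each survivor's explained variance is
$\beta^2 \times 2\,\mathrm{MAF}(1-\mathrm{MAF})$ and candidates are greedily
pruned in descending explained-variance order so that every retained pair
has squared dosage correlation at most 0.01.

Two scale and measurement choices deserve explanation:

* **The explained-variance scale.** The formula is evaluated with $\beta$ on
  the 0–1 ancestry-proportion scale (the percent-scale slope divided
  by 100). An alternative — standardising $\beta$ by the exposure standard
  deviation so each term is a marginal $R^2$ — is not viable here: any SNP
  reaching $p < 5\times10^{-8}$ in roughly 700 controls has marginal
  $R^2 \gtrsim t^2/n \approx 0.04$, so a hundred instruments would sum to a
  "cumulative $R^2$" far above 1. On the proportion scale the cumulative
  value stays in the published 7–39% range. It should be read as published
  analyses report it — a sum of single-marker contributions — not as a
  genuine fraction of variance jointly explained. The cumulative
  F statistic $F = \frac{n-k-1}{k}\frac{R^2}{1-R^2}$ is reported from this
  quantity, together with the mean per-instrument F (the average squared
  exposure-scan t statistic), since published instrument-strength figures
  for this design match the latter, not the former.
* **LD among candidate instruments.** In an admixed cohort every
  ancestry-informative marker is correlated with every other one through the
  genome-wide ancestry gradient (pairwise dosage correlation approximately
  $r_a r_b$, where $r_j$ is marker $j$'s correlation with ancestry). A
  strict raw-correlation threshold of 0.01 would therefore discard almost
  all instruments regardless of physical linkage — retention saturates near
  25 markers in simulation. The pipeline consequently measures LD on
  dosages residualised on the estimated ancestry percentage: the partial
  correlation isolates genuine linkage (including planted LD blocks) from
  admixture structure. `ld_r2()` and `greedy_ld_prune()` themselves are
  agnostic — they compute squared correlations of whatever matrix they are
  given — and `ld_adjust_ancestry = FALSE` restores raw composite LD.

Very large cohorts make thousands of markers genome-wide significant; the
optional `max_ivs` cap keeps the top markers by explained variance, the same
device published sensitivity analyses use to limit the instrument count.

## Two-sample MR

Per instrument $j$, the Wald ratio is $\hat\beta_j = \Gamma_j/\gamma_j$ with
first-order weight $w_j = (\sigma_{\Gamma j}/\gamma_j)^{-2}$, where
$\gamma_j$ is the exposure-scan slope and $\Gamma_j$ the age-adjusted
logistic log-OR from the outcome scan. Allele harmonisation aligns the
outcome effects to the exposure's effect allele before ratios are formed.

* **Radial outlier exclusion.** Per-instrument contributions
  $Q_j = w_j(\hat\beta_j - \hat\beta_{IVW})^2$ are referred to
  $\chi^2_1$; instruments with $p_j < 0.1$ are removed and the procedure
  iterates to a fixed point (cap 20 rounds, never below 3 instruments).
* **Estimators.** Fixed-effect IVW (the first-order weighted mean,
  identical to the zero-intercept weighted regression slope), MR-Egger
  (weighted regression with a free intercept after orienting exposure
  effects positive; t-based p-values on $k-2$ degrees of freedom; a non-zero
  intercept flags directional pleiotropy) and the interpolated weighted
  median with a seeded parametric bootstrap standard error (1000 draws).
  Fixed-effect IVW is the default because Cochran's Q shows no
  heterogeneity in this design; a multiplicative random-effects switch
  exists.
* **Heterogeneity.** Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta)^2$
  on $k-1$ degrees of freedom with first-order weights.

### The IVW variance with mutually correlated instruments

First-order IVW theory assumes independent instruments. Instruments for a
*single heritable exposure* in an admixed cohort are not independent: after
linkage-based pruning their dosages remain correlated through ancestry
($\rho_{ab} \approx r_a r_b$), so their outcome-scan errors share a common
component and $(\sum_j w_j)^{-1/2}$ understates the sampling error — in
simulation at the default study size by a factor of about three. No
configuration escapes this: genome-wide significance at $n\approx700$ forces
$\sum_j r_j^2 \ge k\,t_{\min}^2/n \gtrsim 2.5$. The pipeline therefore keeps
the first-order *point estimate and weights* but computes the IVW standard
error from the between-instrument dosage correlation matrix,
$\widehat{\mathrm{Var}} = \tilde w^\top (S\rho S \circ \sigma\sigma^\top)\tilde w$
with $\sigma_j = w_j^{-1/2}$, normalised weights $\tilde w$ and $S$ the
diagonal of exposure-effect signs — the standard variance for correlated
variants in MR. `ivw()` without a correlation matrix reproduces the
first-order formula exactly and the uncorrected value is always reported as
`se_first_order`. With the correction, simulated type-I error is at the
nominal 5% and confidence-interval coverage is nominal; without it,
rejection under the causal null would exceed 30%. A fingerprint of the
correlated-error structure is a Cochran's Q far *below* its degrees of
freedom (Q p-values near 1), which this design reproduces — published
analyses of this kind report exactly such Q p-values. The Egger and
weighted-median standard errors remain first-order/bootstrap sensitivity
quantities.

### What the estimand is — and is not

Under the generative model the confounder is a function of true ancestry
plus independent noise, so any valid instrument for ancestry carries the
ancestry-to-confounder-to-disease path: the MR estimand is the *total*
population-level effect $\beta_{anc} + \beta_c\rho/\mathrm{sd}(q\%)$, not
$\beta_{anc}$ alone. Population-level ancestry MR cannot separate a direct
ancestry effect from the effect of anything correlated with ancestry;
within-family designs would be needed for that. Accordingly, the package's
parameter-recovery and type-I validation scenarios use an *active
non-genetic confounder that is independent of ancestry*
(`beta_conf = 0.5, conf_anc_corr = 0`), under which the estimand equals
$\beta_{anc}$.

A second structural fact constrains comparisons with the naive logistic
slope of disease on estimated ancestry. The exposure scan regresses the
panel-estimated ancestry $\hat q$ on a panel SNP, and because $\hat q$'s
information comes from those same SNPs, the scan slope overestimates the
slope on true $q$ by exactly the reliability factor $1/\lambda$ (in the
Gaussian analogy the maximum-likelihood estimate is the posterior mean
divided by $\lambda$). The MR ratio is therefore attenuated by the *same*
$\lambda$ as the errors-in-variables observational slope: the classic
"MR is immune to exposure measurement error" advantage cancels exactly in
this design. The package's confounding-comparison scenarios consequently
work under the causal null with strong ancestry-correlated confounders,
where the MR estimate of the (spurious) association is systematically
closer to zero than the observational slope — driven by the stronger
non-collapsibility marginalisation of per-SNP outcome odds ratios and by
selection-induced attenuation, not by instrument validity. The tests verify
this bias ordering; they should not be read as showing that ancestry MR
removes ancestry-correlated confounding, which, per the estimand argument
above, it cannot at population level.

## Reporting

Causal estimates are reported as odds ratios per 1% increase in the
Native American ancestry proportion with normal-approximation 95% intervals;
$100\,(1-\mathrm{OR})$ is the percent decrease in risk per ancestry point,
and $(q_{75}-q_{25})\times$ that decrease linearises the expected risk
difference between the ancestry quartiles of the control distribution.
Stratified analyses (diagnosis at or before 45, familial, ER-positive,
ER-negative, triple-negative) reuse the exposure scan and preliminary
instruments and recompute the outcome scan on stratum cases plus all
controls; strata with fewer than 30 cases are refused. Analytic power for a
binary outcome uses the non-centrality
$z = |\log \mathrm{OR}_{SD}|\sqrt{n\,R^2\,K(1-K)}$ with
$\mathrm{power} = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})$,
validated against a two-stage individual-level simulation.

## Numerical choices and problem sizes

Intercept calibration by bisection to $10^{-6}$ on prevalence; EM tolerance
$10^{-6}$ on the log-likelihood with a 2000-step cap; preselection ties
broken by SNP id; two-sided p-values throughout (t for the linear scan and
Egger, normal for logistic Wald and IVW); the weighted-median bootstrap seed
is always recorded. The validation suites run at deliberately modest sizes
chosen to exercise the full pipeline many times: 100 replicates of a
700 + 700 study with 5000 SNPs for parameter recovery, 400 replicates of a
300 + 300 study with 1200 SNPs for type-I calibration, three 60-replicate
confounding scenarios at 500 + 500 with 400 SNPs, and a single 2000 + 2000
study for stratified subtype recovery. A real analysis would use hundreds of
thousands of array SNPs; nothing in the implementation depends on the panel
being small, and the EM core handles cohort-scale matrices in seconds.

## Known limitations

* Global (not local) ancestry; no admixture mapping.
* The control sample appears in both MR samples, as in the motivating
  design; the overlap is reproduced, not corrected.
* Winner's curse from selecting and estimating instruments in the same
  controls is present by design (no correction is attempted); it attenuates
  estimates slightly toward the null in weak-instrument regimes.
* The weighted-median bootstrap treats ratio errors as independent, so its
  interval shares the first-order optimism discussed above.
* No plotting functions are shipped; the instrument sets and report tables
  carry everything needed for standard MR scatter and funnel plots.
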