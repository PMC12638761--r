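---
title: "Methods: coherence networks, polygenic scores and regularized mediation"
author: "BrainNetMed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherence networks, polygenic scores and regularized mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainNetMed)
```

# What the package computes

BrainNetMed implements a triad analysis: does resting-state EEG functional
connectivity mediate the association between a polygenic score for general
intelligence (the independent variable X) and the psychometric g factor
(the outcome Y)? The pipeline runs from region-of-interest (ROI) time
series to mediator maps:

1. **Connectivity.** ROI time series from two eyes-closed recordings are
   segmented into 8-s epochs with 50% overlap, Hann-tapered and
   demeaned per epoch; cross-spectra are averaged across epochs
   (Welch-style), and magnitude coherence
   $w_{ij} = |S_{ij}| / \sqrt{S_{ii} S_{jj}}$ is averaged over the FFT
   bins of each band (delta 2--3, theta 4--7, low alpha 8--10, high alpha
   11--13, beta 16--30 Hz). The two sessions are averaged elementwise into
   one 82 x 82 network per band.
2. **Graph metrics.** Group-level Holm-Bonferroni pruning tests every edge
   one-tailed against zero using the pooled variance of all upper-triangle
   weights across participants ($\alpha = 0.01$); real coherence is
   strictly positive, so on coherence cohorts this prunes nothing -- it is
   a guard against spurious connections, not a density threshold.
   Distances are inverse weights with Dijkstra shortest paths; nodal
   efficiency is the mean inverse shortest-path length
   $E_i = \frac{1}{n-1}\sum_{j \ne i} d_{ij}^{-1}$, global efficiency its
   mean; local clustering uses geometric-mean (Onnela) weighted triangles
   $C_i = 2 t_i^w / (k_i (k_i - 1))$, global clustering its mean.
   Participants deviating more than 3 interquartile ranges from the median
   on any global metric or on g are excluded.
3. **g factor.** Fifteen cognitive scores are residualized on age, sex,
   age x sex, age$^2$ and age$^2$ x sex, z-standardized, and fitted by a
   fixed second-order confirmatory factor model (verbal memory, attention,
   working memory, verbal fluency under a single g; the vocabulary test
   cross-loads on working memory and verbal fluency). Estimation is
   maximum likelihood on the discrepancy
   $F = \log|\Sigma(\theta)| + tr(S\Sigma^{-1}) - \log|S| - p$ with all
   latent variances fixed at 1, so every loading is standardized.
   Fit is summarized by $\chi^2$, RMSEA, SRMR, CFI and TLI; participant
   g scores are regression (Thurstone) factor scores.
4. **Polygenic scoring.** SNP QC (MAF $\ge$ 0.05, HWE $p \ge 10^{-6}$,
   missingness $\le$ 2%), sample QC (missingness, |F| $\le$ 0.2),
   relatedness pruning (method-of-moments kinship, pi-hat > 0.2), and
   removal of participants beyond 4.5 SD on any of the first 20 genotype
   PCs; the first 4 PCs join the covariates. Scores are weighted allele
   sums over SNPs below a GWAS p threshold; the threshold grid
   ($5\times10^{-5}$ to 1 in $5\times10^{-5}$ steps) is searched for the
   largest $R^2$ increment over a covariate-only model, and the winner's
   p value is corrected by permuting the phenotype and repeating the whole
   search (default 1,000 permutations, configurable to 10,000).
5. **Mediation.** Partial correlations and single-mediator models
   (two OLS equations, Sobel SE, optional bootstrap) handle the global
   metrics. The region-specific screen (`xmed`) residualizes covariates
   out of X, Y and all 82 nodal metrics, z-scores everything, fits an
   elastic net ($\alpha = 0.5$) for path a (each metric on X, one shared
   penalty chosen by pooled 10-fold CV) and for path b (Y on all metrics,
   penalty by 10-fold CV), and selects ROIs with $|a| > 0.01$,
   $|b| > 0.01$ and $|ab| > 0.001$. Selected mediators are re-estimated
   without penalty (jointly for path b) because penalized effects are
   biased toward zero. Ten models are run per group (5 bands x
   {nodal efficiency, local clustering}) for young (age $\le$ 40), older
   (> 40) and the whole sample.
6. **Reliability.** ICC(3,1) -- two-way mixed, consistency, single
   measurement -- between the two recordings for every global and nodal
   metric, labelled poor/moderate/good/excellent at 0.5/0.75/0.9.

# The synthetic cohort generator

No participant-level data are distributed with the analysis, so the
package ships a seeded generator whose defaults are the study conditions
the pipeline assumes: 434 participants aged 20--70 (the 40-year cutoff
splits the default cohort roughly 40/60), Hardy-Weinberg genotypes at
2,000 common SNPs of which 200 are causal, a true polygenic score
explaining 4% of g variance, five bands at 200 Hz with 30 8-s epochs per
recording, and a cross-session edge reliability of 0.85 (chosen to
reproduce the observed good-to-excellent global ICCs).

Two network routes exist:

* **Direct (logit-normal).** Edge weights are
  $w = \mathrm{logit}^{-1}(\mu + \sigma L)$ with a participant-level
  standardized latent $L$ mixed with fresh session noise as
  $\sqrt{\rho} L + \sqrt{1-\rho} E_s$, so the cross-session latent
  correlation is exactly the configured reliability. The planted effect
  lives on the edges of the mediator clique (both endpoints mediator
  ROIs): those edges carry the standardized genetic score with a loading
  chosen in closed form (first-order linearization of nodal efficiency,
  session attenuation $\sqrt{2\rho/(1+\rho)}$, and a fixed 0.92
  correction for the logistic and shortest-path nonlinearities) so that
  each mediator ROI's nodal efficiency carries a standardized genetic
  effect close to `aEffect`. Restricting the plant to the clique keeps
  every other ROI genuinely null -- essential for interpreting
  false-selection rates of the mediator screen. The clique edges get a
  3-fold amplified logit SD so that four edges can carry a 0.4
  standardized nodal effect at all.
* **Time series.** Each ROI is a sum of band-limited oscillators (FFT
  brick-wall noise) plus broadband noise; per band, a shared source is
  mixed into every ROI with participant-specific couplings that persist
  across sessions up to the configured reliability. Mediator ROIs couple
  to the mediator band's shared source with a slope proportional to the
  genetic score, so their pairwise coherence is score-dependent. This
  route exercises the full spectral estimator; it makes no claim to 1/f
  spectra, volume conduction or source-leakage realism.

The outcome is composed as
$g = c\,\mathrm{score} + b\,z\!\left(\sum_r z(E_r)\right) + e$:
`bEffect` is the standardized effect of the *mediator composite* on g.
The implied per-ROI coefficient, `bEffect`/SD(composite) (about 0.13 at
the defaults, because clique-coupled mediator metrics are positively
correlated), is recorded in the planted truth. A per-ROI effect of 0.4
for five correlated mediators would require more than 100% of g variance
and is not representable. The direct coefficient $c$ and the residual SD
are solved from empirical moments so that Var(g) = 1 and
cor(score, g)$^2$ equals `h2Pgs` exactly in expectation.

The cognitive battery uses first-order loadings between 0.50 and 0.80
and second-order loadings 0.90/0.85/0.88/0.82. These were chosen once,
analytically, so that the regression g-score determinacy is about 0.92 --
a strong-g battery, which is what a 15-test battery spanning four domains
is designed to be. Age, age$^2$ and sex nuisance effects (-0.3, -0.2 and
0.2 SD) are added to the raw scores so that the residualization stage has
real work to do.

What passing tests on these cohorts shows -- and what it does not: the
generator produces exactly the covariance structures the estimators
assume (independent SNPs, logit-normal edges, linear factor model,
Gaussian noise). Recovery there demonstrates correctness of the
statistical machinery, not robustness to LD structure, artifacts,
source leakage, non-Gaussian traits or model misspecification in real
data.

# Numerical choices

* **Spectral estimator.** Hann taper, one FFT per 8-s epoch (0.125 Hz
  resolution), per-epoch mean removal, cross-spectra averaged across
  epochs before forming coherence; band bins are selected by a closed
  interval on bin center frequencies. Magnitude (not squared) coherence
  by default. The delta band starts at 2 Hz by default (configurable to
  1 Hz, a convention that also appears in the literature).
* **Graph metrics.** Unreachable pairs contribute 0 to efficiency
  (the $d \to \infty$ limit); isolated nodes get $E_i = C_i = 0$; nodes
  with fewer than two neighbors get $C_i = 0$. Coherence weights are
  already in [0, 1], so triangle weights are not max-normalized (a flag
  exists). Pruning uses a z test with the pooled variance (very large
  pooled df) rather than per-edge t tests.
* **CFA.** Quasi-Newton (PORT) optimization over free loadings,
  tanh-parameterized second-order loadings and log-parameterized unique
  variances; up to 5 random restarts; the gradient norm at the solution
  is reported, and Heywood tendencies (unique variance < 0.001, |second
  order loading| > 0.999) are flagged, never truncated. With
  2-indicator factors the second-order structure supplies
  identification. Factor scores use the regression method (the
  extraction method is not uniquely standard; Bartlett scores are the
  main alternative), with g oriented positively on the mean indicator.
* **Elastic net.** Cyclic coordinate descent in covariance form,
  objective $\frac{1}{2N}\|y-X\beta\|^2 + \lambda(\alpha\|\beta\|_1 +
  \frac{1-\alpha}{2}\|\beta\|_2^2)$, fixed column order, warm starts
  along a 100-point log-spaced grid from $\lambda_{max}$ down to
  $10^{-4}\lambda_{max}$, convergence at a $10^{-7}$ maximum coefficient
  change (tunable; the OLS-reduction tests tighten it). The CV choice is
  the error-minimizing lambda, not the 1-SE rule. Path a shares one
  lambda across the 82 single-predictor fits via the pooled CV error,
  mirroring one regularized multivariate model; those single-predictor
  solutions are closed-form soft thresholds.
* **Covariates in the penalized models.** Residualized out of X, M and Y
  beforehand rather than carried unpenalized inside the fits; under OLS
  geometry the two are equivalent, and residualization keeps the
  0.01/0.001 selection thresholds on a standardized scale.
* **Re-estimation.** Joint unpenalized OLS of Y on all selected
  mediators plus X (one-at-a-time available); per-mediator OLS for path
  a; Sobel SEs for the re-estimated products.
* **Relatedness.** Method-of-moments genomic-relationship kinship
  ($\sum_m (x_{jm}-2p_m)(x_{km}-2p_m) / \sum_m 2p_m(1-p_m)$) on a
  high-quality SNP subset; one member of each flagged pair is dropped at
  random under the run seed. With few SNPs this estimator is noisy --
  stable behavior needs several hundred markers.
* **Permutation correction.** $p = (1 + \#\{\max R^2_{perm} \ge
  \max R^2_{obs}\})/(B+1)$; phenotype permutations re-enter the full
  threshold search. The search itself is computed incrementally over
  p-sorted SNPs, with the $R^2$ increment obtained from the squared
  partial correlation times $(1 - R^2_{cov})$ -- algebraically identical
  to refitting the two regressions at every threshold.
* **ICC.** One-sided p (H1: ICC > 0); consistency form, so additive
  session shifts are ignored by design.
* **Seeding.** One master seed per cohort; deterministic sub-streams per
  stage (and per participant in the time-series route), all below
  $2^{31}$. Identical configurations are bit-identical, including the
  pipeline manifest hashes.

# Problem sizes used by the test and acceptance suites

Simulation-based checks run at sizes chosen to give stable Monte-Carlo
estimates on a single CPU: 200 random graphs for the metric oracles;
500 null cohorts (50 participants, 20 ROIs) for the pruning
family-wise-error check; 50 seeds per reliability level for the ICC
monotonicity sweep; n = 5,000 for loading recovery and n = 500 for
g-score recovery; 200 replicate cohorts (B = 200 permutations) for the
null uniformity of the corrected PGS p value and 20 seeds at n = 2,000
for threshold recovery; 25 recovery and 25 null seeds at n = 500 with 82
ROIs for the mediator screen; and an end-to-end time-series pipeline at
n = 60 with 1,000 SNPs run twice to verify bit-identical manifests.
The acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities at comparable sizes under a caller-supplied seed.

# Known limitations

* Sensor-space preprocessing, source localization and atlas parcellation
  are out of scope; the pipeline starts at ROI time series.
* The factor structure is fixed; exploratory factor discovery is not
  reimplemented. DS_total is the sum of DS_f and DS_b, so the indicator
  set is nearly collinear by construction; the ML fit tolerates this,
  but unique variances for these indicators should not be
  over-interpreted.
* LD structure, genotype imputation and X-chromosome checks are not
  modeled; synthetic SNPs are independent, so the optional greedy
  clumping is a no-op on them.
* Selection inference: the thresholded elastic-net screen is exploratory
  and hypothesis-generating; re-estimated effects carry no
  post-selection p values, by design.
* The spectral estimator is one standard choice (Hann, 8-s epochs,
  epoch-averaged cross-spectra); other taper families or multitapers
  would give slightly different absolute coherence levels.
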