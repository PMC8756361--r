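---
title: "Case-case interaction GWAS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-case interaction GWAS: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Treatment-resistant schizophrenia (TRS) is usually studied without a single
large case-case cohort: what exist are two case-control GWASs — resistant
cases against one set of healthy controls, non-resistant cases against
another. `gwasdiff` implements the indirect route to a case-case GWAS from
those two sets of summary statistics, together with everything needed to
interrogate the result: inflation diagnostics, LD score regression for
SNV-based heritability and genetic correlation, and clumping + thresholding
polygenic risk scores (PRS) validated in held-out cases. A
liability-threshold simulator generates all inputs with the causal
structure the analysis presumes, so the whole chain is testable end to end.

# The interaction statistic

For each variant shared by the two studies, with log odds ratios
$\hat\beta_1$ (TRS vs controls) and $\hat\beta_2$ (non-TRS vs controls) and
standard errors $s_1, s_2$ **on the log scale**:

$$d = \hat\beta_1 - \hat\beta_2,\qquad
  \mathrm{SE}(d) = \sqrt{s_1^2 + s_2^2},\qquad
  z = d/\mathrm{SE}(d),\qquad
  p = 2\{1 - \Phi(|z|)\}.$$

This is the classical test for the equality of two estimated effects (the
fixed-effect moderator test of meta-analysis). Its assumptions, all of
which the simulator reproduces and the tests probe:

* the two studies are computed on **disjoint samples** (independent cases
  *and* independent controls), so the variances add;
* both estimates are Wald-normal, which holds at GWAS sample sizes;
* between-study heterogeneity beyond the modelled difference is not
  modelled — the statistic is a contrast, not a random-effects model.

Positive $z$ means a stronger association in study 1; the pipeline fixes
study 1 = TRS so that sign convention is stable downstream. P values are
floored at the smallest positive double rather than reported as zero.

# Harmonization

The two studies are aligned to a common effect-allele frame with the
standard lattice: allele swap (negate $\beta$, $f \to 1-f$), strand flip
(complement both alleles), or both. Three exclusion rules apply, in
precedence order:

1. `allele_mismatch` — no action reconciles the allele pairs;
2. `palindromic_ambiguous` — A/T and C/G variants whose minor-allele
   frequency is in $[0.4, 0.5]$ in both studies. For these, strand cannot
   be resolved from frequency, and a silent strand error would corrupt $d$
   with the wrong sign — exclusion is the only safe choice;
3. `maf_diff` — post-alignment effect-allele frequency difference above
   0.20 (the conventional pre-imputation QC mirror). The difference is
   computed as $|f_1 - f_2|$ on the aligned frame.

All excluded rows stay in the harmonized table with a reason, so input =
retained + excluded is checkable and tallies are reported.

# LD score regression

Under a polygenic model, the expected association chi-square grows linearly
in the LD score $\ell_j$ (the sum of $r^2$ of variant $j$ with its
neighbourhood, itself included):

$$E[\chi^2_j] = a + \frac{N h^2}{M}\,\ell_j,$$

with free intercept $a$ (1 in the absence of confounding). `estimate_h2`
fits this by weighted least squares with weights
$1/\{\ell_j\,\hat\mu_j^2\}$, where $\hat\mu_j$ is the fitted mean from a
preliminary unweighted pass (clamped below at 0.1, with the preliminary
slope clamped to $[0,1]$ for weighting only). The $1/\ell$ factor corrects
over-counting of variants tagged repeatedly through LD; $1/\hat\mu^2$ is
inverse-variance weighting for $\mathrm{Var}(\chi^2) \approx 2\mu^2$. The
weights are updated **once**, not iterated: at the problem sizes this
package targets a second update changes estimates by far less than a
jackknife SE, and a single deterministic step keeps the estimator exactly
reproducible.

Standard errors come from a delete-a-block jackknife over contiguous
blocks of variants in panel order (default 200 blocks, automatically
reduced to $\lfloor m/10 \rfloor$ for small panels; below 20 variants the
estimator refuses to run). For the genetic correlation, the cross-trait
regression of $z_1 z_2$ on $\sqrt{N_1 N_2}\,\ell/M$ gives the genetic
covariance, $r_g = \widehat{\mathrm{cov}}/\sqrt{\hat h^2_1 \hat h^2_2}$,
and the jackknife recomputes the *whole ratio* per deleted block so the SE
propagates all three regressions. No sample-overlap intercept constraint
is imposed, because the intended design has disjoint samples. When either
$\hat h^2 \le 0$ the correlation is reported as undefined (`NA` with a
flag) rather than as an unstable number.

One identifiability caveat: with a constant LD score (no LD at all) the
regressor $N\ell/M$ is constant and slope and intercept cannot be
separated; `estimate_h2` raises a classed error for such degenerate panels
rather than returning an arbitrary split. LD-score heterogeneity is what
identifies the model — the simulator therefore draws variable block sizes.

The observed-to-liability conversions use the standard normal-threshold
transforms; because no canonical population prevalence exists for TRS
(epidemiologically 20%–30% *of schizophrenia cases*), every
liability-scale quantity is reported over a prevalence grid
(default $K \in \{0.20, 0.25, 0.30\}$ for the within-case contrast) rather
than anchored to a single hard-coded constant.

# Association scan and polygenic scores

The discovery scan on simulated cohorts uses the allelic 2×2 (Woolf) test:
odds ratio from the allele-count table, $\mathrm{SE} =
\sqrt{1/a+1/b+1/c+1/d}$, Haldane–Anscombe +0.5 on zero cells. Without
covariates this is asymptotically the same Wald test as per-variant
logistic regression (the tests check agreement within 5% on moderate
tables) and is orders of magnitude faster over a scan; it is the package's
stand-in for an external regression-based GWAS stage.

PRS construction is clumping + thresholding: greedy selection by ascending
P, discarding variants with $r^2 > 0.1$ to an already-kept variant within
250 kb (PRSice-style defaults; both are parameters). Scores are weighted
allele sums over variants with $p \le$ threshold, on a grid of eight
cutoffs ending at $p \le 1$ (the "all LD-independent variants" profile).
Per threshold, the score (z-standardized) enters a logistic model with sex
and top dosage principal components as covariates; reported are the OR per
score SD with 95% Wald CI, Nagelkerke and liability-scale $R^2$, AUC (rank
statistic), and Benjamini–Hochberg q values computed *within* the scan —
one training/testing pairing is one multiple-testing family. Perfect
separation is a classed error, not an estimate.

# What the simulator emulates

`sim_config()` encodes the study design as data:

* **Genotypes.** Variants in LD blocks; block sizes drawn uniformly from
  $1..(2b-1)$ (mean `block_size`) so LD scores vary; one allele frequency
  per block drawn from `maf_range`; within a block, haplotypes share a
  latent draw with copy probability $s$, giving pairwise dosage $r^2 =
  s^4$ exactly — hence calibration $s = r^{2\,(1/4)}$ — and Hardy–Weinberg
  marginals. This is exchangeable block LD, not a human LD map.
* **Phenotypes.** Two-layer liability threshold model. Schizophrenia
  liability $L_1 = \sum_j b_j (g_j - 2p_j) + e_1$ with
  $\mathrm{Var(genetic)} = h^2_{\text{shared}}$ (default 0.24, the
  conventional common-variant estimate for schizophrenia) and case status
  $L_1 > \Phi^{-1}(1-K)$. Among cases, an independent resistance liability
  $L_2$ with variance $h^2_{\text{specific}}$ sets TRS status at the
  threshold for a TRS share of 0.25 (the middle of the epidemiological
  20%–30% range). Effects are infinitesimal (Gaussian per standardized
  variant); per-seed effect vectors and per-individual liabilities are
  stored with the cohort so tests can recompute everything exactly.
* **Design.** Disjoint control sets for the two discovery GWASs (so the
  interaction variances add and no overlap intercept is needed), and a
  held-out validation set of cases only, labelled TRS/non-TRS.
* **Sampling.** Cases are obtained by rejection sampling with a draw cap
  of six times the expected requirement; the compiled sampler keeps only
  individuals still needed for a quota, so the rejection pool costs RNG
  time but no memory. Configurations that differ only in a variance
  component consume identical RNG draws, so seed-matched runs are
  counterfactual pairs — the tests exploit this to isolate the
  resistance-specific signal. Sex is simulated as pure noise to exercise
  covariate plumbing.

The defaults use a population prevalence of $K = 0.01$; the test suite
runs at $K = 0.05$, which preserves the liability structure while keeping
rejection sampling fast. What the simulator deliberately does **not**
have: realistic human LD maps and allele-frequency spectra, ancestry
structure or admixture, genotyping/imputation error, MAF-dependent
architectures, indels or multi-allelics. Passing tests therefore show the
*methods* are correct under the stated model, not that any particular
real-data estimate is reproduced.

# Numerical choices

* Log odds ratios are differenced as `log(a*d) - log(b*c)`, so exchanging
  the groups negates the effect exactly in floating point.
* Clumping ties in P are broken by (chromosome, position); with a fixed
  seed the whole pipeline is byte-reproducible, and every staged output
  carries a provenance header (version, seed, configuration hash).
* Missing dosages are mean-imputed per variant at scoring time.
* `-0` is normalized to `0` on serialization so round-trips are
  byte-stable.
* Jackknife blocks are contiguous in variant order, matching the LD
  block layout.

# Problem sizes in the test suite

The statistical tests run at sizes chosen once, as experimental design,
from pilot power calculations: null-calibration chains use 5,000
independent variants with 2,000 individuals per group (independent
variants because the calibration yardstick is a binomial interval, which
presumes independence); genetic-correlation chains use 2,000 variants in
LD blocks with 1,500 per group; the PRS directionality study uses 2,000
variants, 2,500 per discovery group and 800 validation cases, where the
piloted mean Wald z of the interaction-trained score is about 2.4 —
comfortably detectable over 20 seeds. The heritability-monotonicity
property uses four seed-paired chains at 2,500 per group. Monte-Carlo
checks state their decision rules (pooled binomial CI, coverage counts)
in the test source.

# Known limitations

* The Woolf stand-in cannot adjust the discovery GWAS for covariates; a
  real-data pipeline would run a regression-based GWAS upstream and feed
  its summary statistics through the same interfaces.
* LD score regression here is the plain univariate model: no partitioned
  heritability, no annotation stratification, and not the
  MAF-coupled-architecture family of estimators (whose point estimates
  would differ systematically; they answer a different weighting of the
  same signal).
* Liability-scale conversions are threshold-model approximations and
  inherit the usual sensitivity to the assumed prevalence — hence the
  grid.
* The genetic-correlation ratio is undefined when a heritability estimate
  is non-positive; at very small sample sizes this happens by sampling
  noise, and the package reports it as such instead of truncating.
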