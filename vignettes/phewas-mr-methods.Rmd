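---
title: "Methods: phenome-wide screening and two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenome-wide screening and two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational associations between blood biomarkers (for instance the blood
levels of iron and copper) and clinical outcomes are routinely distorted by
confounding and reverse causation. Mendelian randomization (MR) sidesteps
both by using genetic variants as instrumental variables: alleles are
allocated at conception, before any disease process, so a variant that
raises the exposure can only associate with an outcome through the exposure
— provided the instrument assumptions hold. `phewasmr` implements the full
workflow of a phenome-wide MR study: a hypothesis-free screen of a
diagnosis phenome for candidate outcomes, followed by two-sample MR causal
estimation with a complete sensitivity suite, plus a synthetic-cohort
generator so that every stage is testable without access to individual-level
biobank data.

## Instruments

An instrument set is a small table of SNPs with their per-allele effects on
the exposure ($\beta_X$, with SE), effect-allele frequencies, the variance
fraction $R^2$ each SNP explains, and the discovery-GWAS sample size $N$.
Instrument strength is summarized by

$$F = (N - 2)\,\frac{R^2}{1 - R^2},$$

with $F > 10$ the conventional bound below which weak-instrument bias is a
concern. This form of the F statistic reproduces, to the printed integer
under round-half-away-from-zero, the strengths published for the iron and
copper instruments shipped in `inst/extdata` (645, 445, 796 for the three
iron SNPs; 38 and 85 for the two copper SNPs), which is why it was adopted;
it is the single-regressor ANOVA F expressed through $R^2$.

Harmonization aligns outcome summary statistics to the instrument's effect
allele. Identical allele pairs pass through; swapped pairs negate the
outcome beta and flip the EAF; complementary-strand pairs are treated as
strand reads of the same orientation. Palindromic (A/T, G/C) SNPs are
undecidable from labels alone and are resolved by allele frequency: the
orientation whose outcome EAF is closer to the instrument EAF wins, and
SNPs with either EAF within 0.08 of 0.5 are dropped as unresolvable. The
0.08 window is a configurable compromise: tight enough to keep common
palindromic instruments (the shipped G/C iron SNP has EAF 0.15), wide
enough that sampling noise in a typical EAF estimate cannot silently flip
an orientation.

## The PheWAS screen

Diagnoses (ICD-10, matched case- and dot-insensitively) are grouped into
phecodes; a diagnosis mapping to a child phecode also counts as a case of
all its ancestors, following phecode-system convention. For each target
phecode the cohort is partitioned into cases, controls, and an excluded
group: non-cases carrying any phecode inside the target's exclusion range
(similar or overlapping conditions) are removed from the control group so
that controls are genuinely unaffected. Sex-specific phecodes restrict the
analyzable cohort to that sex, and the sex covariate is then structurally
constant and omitted.

The screening statistic is the logistic regression of case status on the
weighted genetic risk score (GRS; dosages weighted by the instrument
betas), adjusted for covariates. Per-SNP regressions are fitted alongside
and feed the MR stage. We screen on the GRS rather than the per-SNP minimum
p because a single screening statistic gives a well-defined FDR unit per
phenotype; the per-SNP option remains available. GRS p-values are adjusted
by the Benjamini–Hochberg step-up across phecodes, with a 5% cutoff by
default.

Phenotypes are pre-filtered by approximate MR power: with $N$ analyzable
participants, case fraction $K$ and instrument strength $R^2$, the causal
log-odds SE is approximated by $1/\sqrt{N R^2 K (1-K)}$, and the two-sided
normal power to detect an odds ratio `or_detect` is computed from it;
phenotypes below 80% power are dropped. We use the exact two-sided power
(both rejection tails) rather than the one-tail shortcut so that the
null-effect limit equals the test level; the difference is invisible
(< 1e−6) anywhere near the 80% threshold. The default detectable OR of 1.2
per SD suits biobank-scale cohorts; at the tens-of-thousands scale of the
test suite a detectable OR of 2 is the realistic setting, and the filter
can be disabled.

## MR estimators

All estimators act on a harmonized table $(b_{Xj}, s_{Xj}, b_{Yj},
s_{Yj})$. The per-SNP Wald ratio is $b_{Yj}/b_{Xj}$ with first-order SE
$s_{Yj}/|b_{Xj}|$ (a second-order correction is available behind a flag).

**IVW.** The inverse-variance-weighted estimate is the weighted regression
of $b_Y$ on $b_X$ through the origin with weights $1/s_Y^2$,
$$\hat\theta = \frac{\sum_j b_{Xj} b_{Yj}/s_{Yj}^2}{\sum_j b_{Xj}^2/s_{Yj}^2},$$
algebraically the precision-weighted average of Wald ratios. Inference uses
the multiplicative random-effects model: the fixed-effect SE is inflated by
$\max(1, \sqrt{Q/(J-1)})$, with $Q$ Cochran's heterogeneity statistic. The
$\max(1,\cdot)$ truncation means heterogeneity can widen but never narrow
the interval; degrees of freedom are $J-1$ for IVW (no intercept) and
$J-2$ for Egger. A consequence worth knowing: under a perfect null with few
instruments the truncation makes p-values mildly conservative (with $J=3$
the null p-value distribution sits about 0.05 in Kolmogorov distance above
uniform), which is visible in calibration experiments at high replicate
counts.

**Weighted median.** Wald ratios are weighted by their first-order inverse
variances $(b_{Xj}/s_{Yj})^2$, normalized; with ratios sorted and
cumulative midpoints $s_j = \sum_{k\le j} w_k - w_j/2$, the estimate
interpolates the ratios linearly in $s$ at 0.5. It is consistent when
instruments carrying more than half the weight are valid. The SE is a
parametric bootstrap (default 1000 draws, seeded) redrawing both $b_X$ and
$b_Y$ from their sampling distributions.

**MR-Egger.** After reorienting SNPs so all $b_X \ge 0$, a weighted
regression with free intercept is fitted. The intercept estimates the
average directional pleiotropy (the intercept test), the slope a
pleiotropy-robust causal effect. Both SEs carry the multiplicative
random-effects inflation.

**Multivariable MR.** For $K$ exposures with pooled instruments, weighted
least squares of the shared-outcome betas on the $K$ columns of exposure
betas, without intercept, weighted by $1/s_Y^2$. Each slope is a direct
effect conditioning on the other exposures. Two conventions are exposed
behind flags because the choice is genuinely ambiguous in the literature:
an intercept can be included (mirroring an R formula default), and the
weights can be a literal $1/s_Y$ instead of $1/s_Y^2$; the defaults
(no intercept, inverse-variance) follow the standard multivariable-MR
framework.

**Scaling.** Estimates are multiplied by `exposure_sd` to express them per
SD of exposure. The shipped instrument tables carry betas in measurement
units whose implied SD scale is not published; the default `exposure_sd =
1` treats the betas as SD-scaled, and the attribute is overridable per
exposure when a cohort SD is available.

## Sensitivity suite

- **Cochran's Q** against the IVW fit, $\chi^2_{J-1}$ upper tail.
- **$I^2_{GX}$** quantifies violation of the no-measurement-error (NOME)
  assumption on the exposure betas: $\max(0, (Q_{GX} - (J-1))/Q_{GX})$ with
  $Q_{GX}$ the $1/s_X^2$-weighted heterogeneity of the reoriented exposure
  betas. Values above 0.9 mean Egger attenuation is negligible. The
  weighting variant (exposure-SE vs outcome-SE-centred mean) is a flag;
  exposure-SE is the default.
- **SIMEX** corrects Egger attenuation when NOME fails: for each $\lambda$
  in a grid (default 0, 0.5, 1, 1.5, 2) Gaussian noise of variance
  $\lambda s_X^2$ is added to the exposure betas, the mean Egger slope per
  $\lambda$ is fitted with a quadratic and extrapolated to $\lambda = -1$;
  the SE is a jackknife over simulation replicates. One numerical choice
  matters: the Egger reorientation is fixed once from the observed data and
  not re-applied per perturbed replicate — re-flipping SNPs whose perturbed
  $b_X$ crosses zero bends the $\lambda$ profile non-monotonically and can
  push the extrapolation the wrong way.
- **Leave-one-out** IVW re-estimates per omitted SNP.
- **Instrument lookup** against a local secondary-phenotype catalog (a
  stand-in for GWAS-catalog/PhenoScanner queries, which are out of scope):
  SNPs with secondary hits at $p < 5\times10^{-8}$ are flagged and trigger
  exclusion-sensitivity reruns.

The pipeline reports a mineral–outcome pair as causal only when it passes
the FDR screen **and** shows no evidence of heterogeneity (Q $p \ge 0.05$)
or directional pleiotropy (intercept $p \ge 0.05$). Sex-stratified IVW
reruns the per-SNP outcome regressions within each sex (sex dropped from
the covariates); a pair is labeled sex-specific when significant (two-sided
$p < 0.05$, configurable) in exactly one stratum and not in the combined
sample. For continuous lipid outcomes the weighted median is reported as
the headline method whenever IVW heterogeneity is significant, because the
median is robust while the mean is not.

## The synthetic cohort: what it emulates, and what it does not

The generator states a world with the structure the analysis assumes:

- genotypes per SNP as Binomial(2, EAF) — Hardy–Weinberg, **no LD** (the
  shipped instruments are on different loci or treated as independent);
- exposure $X = \sum_j \beta_j G_j + \varepsilon$, with
  $\mathrm{Var}(\varepsilon)$ set so each SNP explains its configured $R^2$
  and $\mathrm{Var}(X) = \mathrm{exposure\_sd}^2$ (configurations implying
  genetic variance at or above the total are rejected);
- binary outcomes from a logistic model in $X$/SD, per-SNP direct
  (pleiotropic) effects, and optional age/sex terms, with the intercept
  solved by bisection (tolerance 1e−6) so the sample-average probability
  hits the target prevalence;
- one ICD-10 code per case, sampled uniformly from the phecode's mapped
  codes; continuous biomarkers as Gaussian models where the configured `sd`
  is the residual SD;
- demographics matching a middle-aged European-ancestry biobank: age
  Normal(56.86, 8) truncated to 40–69 via inverse-CDF sampling, 53.5%
  female; ten standard-normal principal components as pure nuisance;
  genotyping array and assessment centre as constants (which the
  association code drops with a warning).

Default prevalences are biobank-realistic choices fixed once: 2% iron
deficiency anemia, 3% other anemia, 10% hyperlipidemia, 12%
hypercholesterolemia, 2.5% varicose veins, 5% type-2 diabetes, 8%
osteoarthrosis, 4% uterine leiomyoma (female-only); lipid biomarkers with
means/SDs around typical population values (e.g. LDL 3.56 ± 0.87 mmol/L);
17% statin use, independent of the lipids.

A fixed seed makes the cohort bit-reproducible (R's Mersenne-Twister with
inversion sampling, the defaults since R 3.6). The generator does **not**
emulate LD structure, imputation uncertainty, relatedness, multi-code
diagnosis histories, statin-by-LDL correlation, or non-linear
exposure-outcome relationships. A green test therefore establishes that the
estimators and the screening logic behave correctly in a world satisfying
the MR assumptions by construction — not that those assumptions hold in any
particular real cohort. One structural property worth noting: because a
common outcome makes the logistic model non-collapsible, marginal per-SNP
effects are very slightly attenuated relative to the structural log-odds;
at the prevalences and effect sizes used here the attenuation is a
sub-percent effect, far inside the tolerance of the recovery checks.

## Numerical choices and degenerate inputs

- Weighted least squares is solved via QR on the $\sqrt{w}$-scaled design;
  coefficient covariance from `chol2inv` of the R factor.
- Logistic fits flag (rather than fail on) non-convergence or separation
  (|beta| ≥ 15 or SE ≥ 100); flagged SNPs are excluded downstream with a
  warning. Constant and linearly dependent covariate columns are dropped
  with a warning; a predictor collinear with covariates is an error.
- The weighted-median interpolation clamps to the extreme ratio when the
  0.5 midpoint falls outside the cumulative-weight bracket.
- `bh_fdr` restores input order and is stable under ties; it agrees with
  `stats::p.adjust(method = "BH")`, which the tests use as the oracle.
- Monomorphic SNPs get HWE p = 1 with a warning; `i2_gx` returns 0 with a
  warning when the exposure betas have no spread; Wald ratios reject
  $b_X = 0$.
- p-values are two-sided normal for estimates and upper-tail chi-square for
  heterogeneity statistics, throughout.

## Known limitations

Mode-based estimators, MR-PRESSO outlier correction, Steiger filtering and
non-linear MR are deliberately out of scope, as are LD-aware operations
(clumping, proxy lookup) and real data access. With as few as 2–3
instruments per exposure, Egger and the weighted median have little power
and their role is directional consistency, not confirmation; the truncated
random-effects inflation makes small-$J$ null inference conservative, as
noted above.
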