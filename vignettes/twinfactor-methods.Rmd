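---
title: "Latent-factor genetic association in twin families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor genetic association in twin families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfactor)
```

## The model

`twinfactor` analyses repeatedly measured quantitative phenotypes — the
motivating application is anxious-depression (A/D) sum scores — in
twin-family samples, asking whether a SNP shifts the *stable* part of the
trait rather than any single measurement.

A single latent factor $F_i$ with variance fixed to 1 loads on all of
person $i$'s measures. For sex $s$, indicator $t$ (an occasion, or an
age-by-rater combination in children), the observed value is

$$
y_{it} = \mu_t + \beta_{\mathrm{age}}\,\mathrm{age}_{it}
       + \beta_{\mathrm{sex}}\,\mathrm{sex}_i
       + \lambda_{t,s}\,(F_i + \beta_{\mathrm{snp},s}\, g_i)
       + \varepsilon_{it},
$$

where $g_i \in \{0,1,2\}$ counts minor alleles. The SNP enters the *mean
only*, routed through the loadings: a one-allele difference shifts every
indicator proportionally to how well that indicator measures the factor.
Familial resemblance is carried by correlations between relatives' latent
factors (sex-specific MZ, DZ/sibling, parent-offspring, and spousal
correlations); because the SNP contributes latent-trait variance, these
correlations are re-estimated whenever a SNP effect is in the model.

Two cohort schemas are built in. Adults have five occasions; twins can
have all five, parents one, siblings three; residuals are independent.
Children have seven indicators (maternal and paternal ratings at ages 7,
10, 12, one adolescent self-report); their residuals carry extra structure:
one residual factor per age, loading on both parents' ratings of the same
child, correlated across co-twins with a zygosity-specific correlation,
plus rating-specific noise. This is the minimal topology that produces both
cross-rater and age-specific cross-twin residual covariance; the residual
factor's share of each rating's residual variance is the per-age
`rho.raters` parameter, so setting it to zero switches the whole structure
off.

## Estimation

Estimation is full-information maximum likelihood on raw data: each
family contributes the multivariate-normal log-density of exactly its
observed entries under the implied mean vector and covariance matrix
(`fiml_loglik()`), so partially observed people stay in the analysis and
missingness is assumed ignorable (missing completely at random in the
generator). Optimization is quasi-Newton (`nlminb`) over an unconstrained
parameterization — variances on the log scale, correlations on the atanh
scale — with non-positive-definite assemblies rejected by returning
$-\infty$. Standard errors come from the finite-difference observed
information at the optimum. Tests are likelihood-ratio by default (per-sex
1-df, joint 2-df); Wald versions are available.

Association follows a two-stage protocol (`two_stage_protocol()`,
`test_snp()`): stage 1 estimates the measurement model (intercepts,
covariate effects, loadings, residual structure, familial correlations) on
the full phenotyped sample; stage 2 fixes loadings and residual terms at
those estimates and re-estimates means, covariate effects, familial
correlations and the sex-specific SNP effects in the genotyped subsample.
Within stage 2 the dosage is centered at the analysis-sample mean — the
same convention applied to ages. Centering changes only the intercepts,
keeps members with a missing genotype at the average (their SNP term is
omitted), and makes flipping the dosage orientation an exact sign change
of $\beta$, which the shared-intercept mean model would not otherwise
guarantee.

The stratification analysis (`between_within_test()`) replaces
$\beta g_i$ for offspring with
$\beta_b \bar g_{\mathrm{fam}} + \beta_w (g_i - \bar g_{\mathrm{fam}})$,
the family mean being taken over genotyped offspring; genotyped parents
enter through their own dosage in the between channel, which — like any
ancestry-level dosage information — is the component stratification can
confound. Sex differences are not included here: one coefficient per
component, and a 1-df LRT of $\beta_b = \beta_w$ is the stratification
test. The recessive re-analysis (`recessive_test()`) reruns the additive
machinery on `code_recessive()` dosages (minor-homozygote indicator).

## The synthetic cohort: what it emulates, and what a green test shows

No individual-level data from the motivating study are public, so
`simulate_cohort()` generates cohorts with exactly the structure the model
assumes: family rosters by configuration (MZ/DZ/DOS pairs, optional
parents and up to one brother and one sister for adults; twin pairs only
for children), Hardy-Weinberg founder genotypes with Mendelian
transmission (latent founders are synthesized for parent-less pedigrees so
DZ dosage correlations stay 0.5), latent factors drawn from the familial
correlation matrix, and per-occasion missing-completely-at-random
participation.

Defaults are the published total-sample estimates: loadings are square
roots of the printed per-indicator variance-explained fractions, latent
twin correlations are the printed values (adults .69/.70 MZ, .31/.30/.29
DZ; children .77/.74 MZ, .40/.43/.48 DZ). Values the study never printed
were fixed once at field-typical levels and are not tuned: parent-offspring
latent correlations 0.30 (the additive expectation, about the DZ level),
spousal correlation 0 (exposed as `r.sp`), child residual rater share 0.20
and cross-twin residual correlations 0.25 (MZ) / 0.15 (DZ), covariate
effects `beta.age = 0.005` per year (adults; 0.05 for the adolescent
self-report) and `beta.sex = 0.3` standardized units (0.1 in children),
and ages drawn around the printed occasion means. The generator emulates
the *statistical* structure only: it makes no attempt at item-level
questionnaire scores, linkage disequilibrium between SNPs, or
ascertainment effects, so green tests certify the estimation machinery and
the model algebra, not robustness to features real cohorts may add.

A deliberate dual route guards the algebra: the generator draws latent and
residual factors explicitly, while `implied_cov()` assembles moments
analytically; tests require the empirical covariance of up to $10^6$
simulated families to match the implied matrix within three Monte-Carlo
standard errors, and the FIML likelihood to match a direct
`solve()`/`determinant()` density oracle to $10^{-8}$.

## Rank-based normalization

Skewed sum scores are replaced by expected normal order statistics before
modeling (`normal_scores()`): Blom's approximation
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, ties averaged over their tied
positions, then a linear rescale back to the observed mean and SD. The
exact normal-scores variant used historically by LISREL is not documented;
downstream results depend only weakly on the variant, and Blom is the
standard choice. The transform is applied to the pooled total sample
before any subsetting (a per-group option exists; pooling is the default
because nothing indicates a within-sex transform).

## Power analysis and heritability

`ncp_power()` implements the Satorra-Saris procedure. A hypothesized SNP
explaining proportion $q$ of latent-trait variance is translated to
$\beta$ through $q = \beta^2 2p(1-p) / (1 + \beta^2 2p(1-p))$ (with
`maf = 0.5` by default; in this parameterization the result is invariant
to the assumed allele frequency, which the tests verify). The null model
(no SNP effect, latent correlations free) is fitted to the alternative's
implied family moments by the FIML discrepancy; genotype mixing enters the
mean term exactly through the dosage covariance matrix ($2pq$, scaled by
the kinship-determined dosage correlations: 1 for MZ pairs, 0.5 for
DZ/siblings). Occasion intercepts profile to zero exactly because
missingness and genotype are independent, so they are dropped from the
numerical minimization. The minimized weighted discrepancy is the
noncentrality parameter; power follows from the noncentral chi-square, and
`min_detectable_ve()` inverts it by bisection to $10^{-4}$ in power.
Monte-Carlo rejection rates of the same simulate-and-refit LRT
(`mc_power()`) validate the noncentrality route within binomial error.

Reconstructed designs (`adult_power_design()`, `child_power_design()`)
rebuild the genotyped samples from printed information: 520/853 unique
adult genotypes with 42/89 complete MZ pairs, 382/392 unique child
genotypes with 144/160 MZ pairs, printed loadings and latent twin
correlations. Each MZ pair is modeled as a genuine pair sharing one
genotype; remaining unique genotypes are singletons. Two readings of the
printed information were possible: thinning each occasion to the
genotyped-sample participation counts, or giving every unique genotype
complete data. The study states that only the number of unique genotypes
entered its power calculations, and the complete-data reading reproduces
all of the printed multivariate thresholds (about 1.5% vs 1.4% for adult
women, 2.5% vs 2.3% for adult men, 3.1% vs 3.1% for children) while the
participation reading overshoots them; complete data is therefore the
default, with `participation = "occasion"` available. The child designs
zero the unpublished residual correlation structure — the printed
information set contains loadings and latent correlations only.

The univariate comparison design measures each person once (adult default:
the 2002 occasion; children: the age-7 maternal rating) with that
indicator's loading and residual. It always needs a larger effect than the
multivariate design — the central methodological point — but its computed
children's threshold (about 4.8%) exceeds the printed 3.9%. The printed
value is close to what one obtains by treating all genotyped children as
independent singletons, which double-counts MZ twins; the package reports
the pair-correct value and makes no attempt to match the printed number.

`falconer_h2()` gives the "rough" heritability of the latent factor from
pooled twin correlations: $a^2 = 2(r_{MZ} - r_{DZ})$,
$c^2 = 2 r_{DZ} - r_{MZ}$, $e^2 = 1 - r_{MZ}$, with an AE fallback
($c^2 = 0$, $a^2 = r_{MZ}$) when the shared-environment estimate is
negative — the rule that reproduces both published round-number estimates
(70% adults via the fallback, 60% children via the plain arithmetic).

```{r h2}
falconer_h2(r_mz = c(0.69, 0.70), r_dz = c(0.31, 0.30, 0.29))
falconer_h2(r_mz = c(0.77, 0.74), r_dz = c(0.40, 0.43, 0.48))
```

## Genotype quality control

`qc_summary()` mirrors a standard genotyping report: minor allele
frequency and the Hardy-Weinberg chi-square test with one individual per
fully genotyped MZ pair (first co-twin by ID sort, a deterministic
tie-break; deduplication can be disabled, and a Wigginton-style exact test
is available since the original tool's default is unspecified), Mendelian
error checks against both parents' observed dosages plus MZ genotype
discordance, missingness per SNP and call rate per sample. SNPs failing
HWE at $p < 0.01$ are flagged but *not* excluded, matching the source
study's practice of keeping them so that patterns across SNPs are not
overlooked. `unique_genotype_count()` implements the MZ-aware sample-size
accounting used throughout the power analyses.

## Numerical choices and degenerate inputs

* Convergence: relative change in $-2\ln L$ below $10^{-9}$ (nlminb's
  `rel.tol`); boundary solutions (correlations at $|\tanh^{-1} r| > 4$,
  residual variances near zero) are flagged rather than silently accepted.
* Correlation parameters are kept interpretable (the printed familial
  correlations are the parameters); positive semi-definiteness is enforced
  at evaluation time by rejection rather than by reparameterizing the
  whole matrix.
* A negative LRT statistic beyond $10^{-6}$ warns and is floored at zero —
  it signals an under-converged full fit.
* Monomorphic SNPs error in `test_snp()`; a recessive recode without
  minor-allele homozygotes returns `NA` with a diagnostic instead.
* `normal_scores()` refuses fewer than three observations and returns
  constant vectors unchanged with a warning.
* Tests with stochastic content fix their seeds; three-Monte-Carlo-SE
  tolerances are used where a closed-form target exists.

## Scaling choices in the test suite

The type-I-error calibration of the per-sex LRT runs 2000 null replicates
of a reduced design (180 families, the last three adult occasions,
intercepts and MZ correlations free) so the suite fits its time budget;
per-replicate data are simulated at the truth and each replicate performs
the full/reduced fits of the real protocol. The chi-square
distribution-shape check uses 300 replicates of the joint 2-df test.
Parameter-recovery and moment-matching checks run at their stated sizes
(800 and $10^6$ families).

## Known limitations

* The latent factor's ACE decomposition is not a fitted model — only the
  correlation-based rough estimate is provided.
* No dominance or epistatic SNP terms; the recessive analysis is a
  recoding of the mean model, not a genotypic two-parameter model.
* Families are assumed multivariate normal after normalization; no robust
  or sandwich corrections are provided.
* The power machinery expresses effects as shares of latent-trait
  variance; designs not expressible as family-configuration rosters (and
  power for the stratification or recessive tests) are out of scope.
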