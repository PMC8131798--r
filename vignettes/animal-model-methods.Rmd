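---
title: "Sex-specific animal models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific animal models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexqg)
```

## The model

`sexqg` fits, per trait, a Gaussian animal model in which a shared trait is
allowed a different genetic basis in the two sexes. A record $y_{ij}$ of
individual $i$ with sex $s$ is

$$y_{ij} = \mu_s + a_{i,s} + c e_{f(i),s} + p e_i + c_{k(ij)} + e_{ij}$$

* $\mu_f$, $\mu_m$ — per-sex means (the only fixed effects; the reported
  sex contrasts of means require them).
* $a_i = (a_{i,f}, a_{i,m})$ — the breeding-value *pair* of individual $i$:
  the additive effect its genotype would have if expressed in a female and in
  a male. Only the own-sex component enters the individual's records; the
  other-sex component is latent. Across individuals
  $\mathrm{cov}(a_{i,s}, a_{j,t}) = A_{ij} G_{st}$, where $A$ is the additive
  (numerator) relationship matrix from the pedigree and
  $G = \begin{pmatrix} V_{A,f} & COV_{A,mf} \\ COV_{A,mf} & V_{A,m} \end{pmatrix}$
  is unstructured (the "us" cross-sex structure).
* $ce$ — common environment/maternal effect: one level per clutch (dam)
  *and* sex, with sex-specific variances $V_{CE/M,f}$, $V_{CE/M,m}$ and no
  cross-sex covariance (the "idh" structure). Field-collected founders have
  no known clutch and carry no $ce$ level. The sex-diagonal choice follows
  the per-sex $V_{CE/M}$ estimates this model family reports; a pooled
  clutch effect is a special case users can approximate by constraining the
  prior.
* $pe$ — permanent environment: one level per individual, sex-specific
  variance, identified by the repeated measures of the parental generation.
* $c$ — contest effect, dyadic traits only (aggression): one level shared by
  exactly the two same-sex contestants of a trial, pooled variance $V_C$
  (the reported tables print no per-sex contest variance; a sex-specific
  version is a one-line change in the sampler but is not exposed).
* $e$ — residual, sex-specific variance, no cross-sex covariance.

Latency traits scored in a novel environment (activity, exploration) are
analysed on the natural-log scale; the log is applied when the model frame
is built, so phenotype files always store observation-scale values.
Right-censored latencies (300 s assay limit) enter as plain clipped values —
the censoring is a property of the assay that the generative model
reproduces, not a censored likelihood, matching how such scores are analysed
in this literature.

## Relationship matrices

`additive_relationship()` uses the tabular method with inbreeding
($A_{ii} = 1 + \tfrac12 A_{d_i s_i}$), founders unrelated and non-inbred;
one known parent contributes half its row. `inverse_relationship()`
assembles $A^{-1}$ directly and sparsely by Henderson's rules with exact
inbreeding coefficients in the Mendelian-sampling variances
($d_i = \tfrac12 - \tfrac14 (F_d + F_s)$, $\tfrac34 - \tfrac14 F_p$, or $1$).
Tests verify both against a gene-dropping Monte-Carlo oracle and dense
numerical inversion.

## Priors and parameter expansion

Default priors are weakly informative and conjugate: scaled inverse
chi-square with scale $V_P/2$ (per-sex phenotypic variance halves) and
belief 0.002 for every diagonal variance, $N(0, 10^8)$ for fixed effects.

The additive block needs more care. A plain inverse-Wishart
$IW(\mathrm{diag}(V_P/2), 2.002)$ prior on $G$ contains a factor
$\exp(-\Psi_{ss}/2V_{A,s})$ that repels the sampler from additive variances
far below the prior scale. Behavioural traits routinely put only a few
percent of $V_P$ into $V_A$ — the very regime this package targets — and
under that prior simulation studies showed the posterior for a small true
$V_{A,f}$ essentially never reaching it. The default sampler therefore uses
parameter expansion: working pairs $\eta_i$ carry an $IW(I_2, 2)$ working
matrix $\Psi$ and per-sex scale parameters $\alpha_s \sim N(0, V_{P,s}/2)$,
with $G = \mathrm{diag}(\alpha)\,\Psi\,\mathrm{diag}(\alpha)$. The induced
marginal prior on each $V_{A,s}$ is a scaled-F-type distribution with
positive density at zero, so additive variances can collapse when the data
demand it. `prior_spec(px = FALSE)` restores the plain conjugate update.

## Gibbs sampler

`animal_model()` runs a systematic-scan Gibbs sampler (C++ core, R RNG, so
`set.seed`-reproducible): Gaussian full conditionals for $\mu_s$ and every
random-effect level; each individual's breeding-value pair is updated
jointly from its 2x2 Gaussian conditional using the sparse rows of $A^{-1}$
(single-site scan in pedigree order); $G$ (or $\Psi$) from the
inverse-Wishart conditional driven by the $A^{-1}$-weighted cross-products
of pairs; every diagonal variance from its scaled-inverse-chi-square
conditional; under parameter expansion, $\alpha_s$ from a Gaussian
regression conditional. All draws of $G$ are positive semi-definite by
construction and variances are non-negative in every draw; no floor is
applied, so draws may be arbitrarily small (summaries print `<0.001`).

Chain profiles: `"full"` 130,000 iterations / 30,000 burn-in / thin 100 and
`"test"` 13,000 / 3,000 / 10, both retaining 1,000 draws. The single-site
C++ scan makes even full-profile fits of the default design (351
individuals, ~412 records) a matter of seconds, so the test profile is a
convenience, not a compromise forced by the sampler. Near-degenerate inputs
(phenotypic variance ~ 0) are flagged with a warning — the conditionals are
then barely proper and results are not meaningful — rather than crashing.

## Synthetic data

`simulate_study()` emulates the breeding design the analysis was built for:
~30 founder dams and ~31 sires measured twice per test, dyadic same-sex
aggression contests, assortative pairing of mates by their observed mean
aggression score (rank matching, ties by id), 29 monogamous full-sib
families aiming at 5 daughters + 5 sons each measured once, latencies
right-censored at 300 s, log-normal latency traits. Founder phenotypes are
simulated first, pairing is decided from those records, and offspring
breeding-value pairs are drawn as the parental average plus a
Mendelian-sampling deviate with covariance $G/2$ — so the phenotypes used
for mate choice are exactly the ones analysed. Optional binomial sex-ratio
jitter reproduces sex-biased clutches (off by default: the realized family
size distribution of the original sample is not recoverable from summary
statistics).

Trait presets (`trait_preset()`) use published by-sex posterior means of the
four behaviours as generating values, so recovery experiments run at
empirically realistic magnitudes; trait means are chosen consistent with the
published mean-standardized coefficients and mean contrasts, and the
aggression contest variance (never printed) is set to 5. The generator is
deliberately Gaussian on the analysis scale: it reproduces the statistical
signatures the model assumes (variance structure, censoring, transforms,
dyads) and none of the behavioural mechanics. Passing recovery tests
therefore shows the estimator is correct *under its own assumptions* — not
that real spider behaviour is Gaussian.

## Derived statistics

All derived quantities are computed per retained draw, never as ratios of
posterior means:

* $h^2 = V_A / (V_A + V_{CE/M} + V_{PE} + V_R)$ per sex, with $V_C$ added to
  the denominator for dyadic traits.
* $r_{mf} = COV_{A,mf} / \sqrt{V_{A,f} V_{A,m}}$. When the additive variance
  of either sex tends to zero this ratio is not estimable. The bare function
  flags draws with $V_{A,f} V_{A,m}$ below an absolute floor (1e-12,
  units^4) — a numerical guard only. The pipeline's operational refusal rule
  (`cross_sex_summary()`) counts a draw as defined only when each sex's
  $V_A$ draw exceeds 5% of that sex's phenotypic variance — the conventional
  negligible-heritability scale — and withholds the point estimate when
  fewer than half the draws are defined, reporting the defined fraction
  instead. The 5% floor was chosen once to operationalize "additive variance
  close to zero"; an absolute floor cannot do this job because posterior
  variance draws are bounded away from machine zero by the prior scale.
* Mean-standardized evolvabilities $CV_A = \sqrt{V_A}/\bar z$,
  $I_A = V_A/\bar z^2$, and $CV_{CE/M}$, $CV_{PE}$, $CV_R$ analogously.
  Means are raw-scale phenotypic means pooled across generations and
  sex-specific by default (switchable to pooled). Because these
  coefficients only make sense for raw-scale variances, `run_study()`
  refits log-transformed traits untransformed for the evolvability table.
* Female-minus-male contrasts are per-draw differences; by linearity the
  summary mean equals the difference of the by-sex means exactly, which the
  pipeline cross-checks at emit time. `pMCMC` is the two-tailed sign
  fraction $2\min(P(d>0), P(d<0))$, floored at $1/n$ and capped at 1.

Summaries report the posterior mean with a 95% highest-posterior-density
interval by default (matching the reporting style of the tables this model
family produces); equal-tailed quantile intervals are available by flag.
For *coverage* evaluation in the recovery tests the quantile interval is
used: HPD intervals of skewed, zero-bounded variance posteriors pin their
lower end at zero and systematically undercover truths in the upper tail.

## Convergence diagnostics

`heidelberger_welch()` implements the classical two-part check:
stationarity via the Cramer-von Mises statistic of the Brownian-bridge
functional of standardized cumulative sums (spectral density at zero from an
AIC-selected autoregressive approximation, estimated on the second half of
the chain), dropping leading 10% increments up to 50% until non-significant;
then the halfwidth test $z_{1-\alpha/2}\sqrt{S(0)/n}/|\bar x| \le \epsilon$
on the retained segment. Defaults $\alpha = 0.05$, $\epsilon = 0.1$ (the
conventional values). A constant chain passes trivially and is flagged. The
report represents "stationarity passed, halfwidth failed" outcomes — the
characteristic result for weakly identified cross-sex covariance chains.
`effective_sample_size()` uses Geyer's initial monotone sequence estimator;
`autocorrelation()` uses the standard biased normalization. Tests pin these
against closed forms (AR(1): $ESS = n(1-\rho)/(1+\rho)$) and against an
independent reference implementation.

## Problem sizes and known limitations

Tests and the acceptance script run the full emulated design (351
individuals, 412 activity records) with test-profile chains, and 20-replicate
recovery experiments at that size; these are the package's chosen default
experiment sizes and complete in a few minutes on one core.

Limitations worth knowing:

* Per-trait models only; among-trait genetic covariances are out of scope.
* Gaussian likelihood only; censored latencies are treated as clipped
  values, not via a censored likelihood.
* The single-site breeding-value scan mixes more slowly than a joint block
  update when $h^2$ is large and pedigrees are deep; the long default chains
  absorb this for designs of the emulated size.
* $V_{CE/M}$ and $V_A$ are only weakly separated by a one-generation
  full-sib design; expect strong posterior dependence between them, and
  interpret small-component contrasts through their intervals, not their
  point estimates.
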