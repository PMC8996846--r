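---
title: "Two-step reaction norms for genotype-by-environment interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step reaction norms for genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rngxe)
```

## The scientific setting

Dual-purpose cattle in alpine regions are kept under heterogeneous
management: farm altitude (plain / hill / mountain), housing (loose vs tie
stall), feeding (total mixed ration vs traditional hay-and-concentrate) and
summer pasture together define an *environmental group* (EG; 3 x 2 x 2 x 2 =
24 possible combinations).  Genotype-by-environment interaction (GxE) means
a sire's daughters do not keep the same relative merit across these
environments: selection decisions made on a single average breeding value
then transfer poorly to the farms at either end of the management spectrum.

A reaction norm describes each sire's merit as a function of a continuous
environmental quality `x`: the intercept is merit in the average
environment, the slope is environmental sensitivity.  The difficulty is
that no continuous covariate is observed — only herd membership and the
categorical descriptors.  The two-step procedure implemented here
manufactures the covariate from the data.

## Step 1: the herd-environment gradient

Each herd crossed with its EG label forms a herd-environmental group (HEG).
A repeatability animal model

$$ y = \mathrm{HEG} + \mathrm{fixed\ classes} + htd + a + Pe + e $$

is fitted by Gibbs sampling, with `htd` (herd-test-day) an IID
contemporary-group effect, `a` the additive genetic effect structured by
the inverse numerator relationship matrix (Henderson's rules, with
Meuwissen–Luo inbreeding), and `Pe` the cow permanent environment.  For
single-record type traits the model drops `Pe` and replaces `htd` with a
herd-year-classifier group.  The posterior means of the fixed HEG solutions
— contrasts against a reference group under the first-level-zero constraint
— order herds from poor to good environments.  Min-max scaled to
$x \in [-1, 1]$, they become the gradient; skewness, kurtosis and a
Shapiro–Wilk p-value are reported as the customary normality diagnostics.

## Step 2: the random-regression sire model

$$ y = \mathrm{fixed\ classes} + \beta_0 + \beta_1 x + htd + Pe +
   (s_0 + s_1 x)_{\mathrm{sire}} + e $$

The fixed order-0/1 Legendre regression $\beta_0 + \beta_1 x$ absorbs the
general environmental trend; each sire's $(s_0, s_1)$ pair is a correlated
random effect with unstructured covariance

$$ G_0 = \begin{pmatrix} \sigma^2_G & \sigma_{G,GxE} \\
   \sigma_{G,GxE} & \sigma^2_{GxE} \end{pmatrix}, $$

relationship-structured across sires through the pedigree (IID available as
a switch).  Plain (unnormalized) Legendre polynomials are used throughout,
so the order-1 basis is literally `x` and variance components keep the
covariate's scale; normalized bases would silently rescale every slope
variance.  Residual variance is heterogeneous over five classes formed by
the quantiles of each record's herd gradient value, with ties assigned to
the lower class.  A companion model with an intercept-only sire term (same
residual structure) quantifies what the GxE term changes.

Genetic variance along the norm is the quadratic form
$ZGZ' = z' G_0 z$, $z = (1, x)$, and per-level sire heritability uses the
residual variance of the level's quantile class.  Because a linear norm
makes $ZGZ'$ quadratic in $x$, extreme gradient levels produce extreme
variances; level comparisons therefore trim estimates outside mean ± 2 SD
(computed over all HEG levels of the trait) before the one-way
least-square-means analysis, while the plain per-level averages stay
untrimmed.  Pairwise contrasts are unadjusted by default (a Tukey option
exists), as no multiplicity adjustment is standard in this literature.

## The Gibbs sampler

All models run through one compiled sampler: single-site conjugate updates
for location parameters, scaled inverse chi-square updates for scalar
variances, class-specific inverse chi-squares for the residual classes, and
an inverse-Wishart update for $G_0$.  Two details matter in practice.

**Blocked pair updates.**  When a sire's daughters sit in few herds, the
covariate barely varies within family and single-site updates of $(s_0,
s_1)$ mix catastrophically (effective sample sizes in the single digits).
Each sire's pair is therefore drawn jointly from its bivariate full
conditional.

**An ancillarity rescaling move.**  The slope solutions and
$\sigma^2_{GxE}$ form the classic funnel: small variance pins the slopes
near zero, which keeps the variance small.  Once per iteration a joint
Metropolis move proposes $s_1 \to c\,s_1$, $G_0 \to D G_0 D$ with
$D = \mathrm{diag}(1, c)$, which keeps the standardized slopes fixed; the
group-move Jacobian cancels against the prior terms so the acceptance ratio
is essentially the likelihood ratio.  Without this move the slope-variance
chain can sit at a small fraction of the restricted-maximum-likelihood
estimate for tens of thousands of iterations; with it the posterior agrees
with REML on matched data.

**Priors.**  Scalar variances use the flat scaled-inverse-chi-square
(df = -2, scale 0).  $G_0$ uses the flat matrix analogue (inverse-Wishart
df = -3, zero scale).  This choice is deliberate: an inverse-Wishart with
small positive df and near-zero scale is proportional to a negative power
of $\det G_0$ and measurably drags slope variances toward zero when
per-sire slope information is modest — on calibration data the posterior
mean sat an order of magnitude below the REML estimate under that prior and
on top of it under the flat one.

Chain bookkeeping follows the usual convention: `floor((n_iter - burn_in) /
thin)` retained samples (220,000 / 20,000 / 100 retains exactly 2,000).
Convergence is left to effective-sample-size diagnostics (reported by
`posterior_summary()`) and exported chains; there is no automatic stopping.
Posterior summaries report mean, SD (as SE), `z = mean/SE` and the
two-tailed normal p — a pragmatic significance screen for variance
components, not a test with guaranteed frequentist coverage.

## The synthetic herd-book generator

`sim_config()` defaults describe the calibration conditions used throughout
the package's tests: 60 herds, 100 sires with on average 8 daughters each,
about 10 test-day records per cow (~8,000 records), true
$G_0 = \begin{pmatrix} 0.06 & 0.01 \\ 0.01 & 0.04 \end{pmatrix}$ on the
transmitting-ability scale, $\sigma^2_{Pe} = 0.1$, $\sigma^2_{htd} = 0.05$,
and residual classes $(0.8, 0.9, 1.0, 1.1, 1.2)$ keyed to the quintiles of
the true herd effect.  Herd environmental effects are uniform on
$[-1.5, 1.5]$ — wide relative to herd-solution estimation noise at these
record counts, as in real data where herd effects dominate.  Environmental
categories are drawn from area-conditional probability tables whose
defaults make lowland farms mostly loose-housing/TMR/no-pasture and
mountain farms mostly tie-stall/traditional/pasture, so realized EGs
cluster on a handful of common combinations.

Sire transmitting abilities are propagated through a three-generation
pedigree (founders $N(0, G_0)$, descendants parent-average plus Mendelian
sampling), so the relationship-structured sire term of the estimation model
is correctly specified; `correlate_sires = FALSE` switches to independent
draws.  Each daughter adds a within-family deviation
$N(0, \tfrac34 \sigma^2_A)$ with $\sigma^2_A = 4\sigma^2_G$, constant
across her records, which makes the sire-model identity
$h^2_{sire} = 4\sigma^2_G/\sigma^2_P$ internally consistent.  Dams are
recorded as unknown: the analysis models no dam-side structure, and a
dam-side pedigree would only enlarge the step-1 equations without changing
what the sire model can estimate.

What the generator does **not** emulate: seasonal lactation-curve shapes
(fixed effects are simple class effects), herds migrating between EGs over
time (real herd-books have more HEG levels than herds; constructed fixtures
cover that path), climate covariates, and genomic marker data.  Passing
tests therefore certify the estimation machinery and the pipeline's
plumbing under a known architecture — not robustness to every real-data
pathology.

## Editing rules and their scale

Records are edited before fitting: any level of a modelled class effect
with fewer than 2 observations is dropped (iterated to a fixed point, which
also makes the edit idempotent), and whole EGs are dropped unless they have
enough herd levels and records (defaults: 6 levels / 6,000 records for
repeated-record milk-type data, 5 / 300 for single-record type data).
Those group thresholds are calibrated to a source study of ~164,000 records
over 114 farms; applied verbatim to a few-thousand-record dataset they
delete everything, since no EG can hold 6,000 of 8,000 records.
`edit_thresholds_scaled()` keeps the rules' intent by scaling level
thresholds with the herd ratio and record thresholds with the record ratio
(3 levels / ~290 records at the calibration scale).

## Calibration results and a known small-scale limitation

Across 10 replicate herd-books at the default scale, fitted with 20,000
iterations (4,000 burn-in, thinning 10), the central 99% posterior
intervals cover the generating values in at least 8 of 10 replicates for
every component — each checked in the stage where the generating value is
the estimand: $\sigma^2_{Pe}$, $\sigma^2_a$ and $\sigma^2_{htd}$ in the
step-1 animal model; $G_0$, $\sigma^2_{htd}$ and the five residual classes
in the step-2 sire model (`tests/testthat/test-acceptance.R` recomputes
this).

The step-2 permanent-environment term deserves a note.  To a sire model,
a cow's within-family additive deviation is permanent environment, so its
estimand is $\sigma^2_{Pe} + \tfrac34\sigma^2_A = 0.28$ here, not 0.1.  At
desk scale a further effect appears: with only ~13 cows per herd, a
fraction of each cow's permanent effect leaks into her herd's step-1 HEG
solution, and the step-2 regression on that gradient removes it from the
cow term — deflating step-2 Pe by roughly $0.04$ at these conditions
(restricted-maximum-likelihood fits of the same data agree with the
posterior, so this is a property of the two-step design, not of the
sampler).  The leakage shrinks like one over the number of cows per herd
and is negligible at realistic herd-book sizes (~90 cows per herd).  This
is why the calibration checks Pe in step 1, where herd effects are fixed
HEG classes and no leakage can occur.

Other numerical choices: fixed-effect identifiability by first-level-zero
constraints (HEG solutions are contrasts against a reference group); the
fixed-effect block is checked for rank deficiency up front and confounded
columns are named in the error; a constant covariate is refused rather than
scaled; non-PSD $G_0$ inputs to `zgz_gradient()` clamp negative variances
with a warning; `build_matrices()` errors on non-positive-definite G or P,
naming the offending leading minor, with an opt-in eigenvalue-clipping
repair.

## EBV diagnostics and selection response

EBVs along the gradient are `intercept + slope * x`; accuracies use
$\sqrt{1 - \mathrm{PEV}/\sigma^2_G}$ with PEV the posterior variance of the
sire solution — the standard Bayesian prediction-error variance, which
keeps accuracy in $[0, 1]$.  A published shortcut that squares the EBV
itself is available behind `method = "literal"` for comparability, but it
ties accuracy to EBV magnitude and can leave the square root undefined
(such sires are clamped and flagged), so it is not the default.

Per-environment selection response uses the multivariate breeder's
equation in index form: weights $b = P^{-1} G a_s$ with economic weights
$a_s = a\,\sigma_a$ (relative emphasis times genetic SD; default emphasis
0.65 on milk yield traits split 3:1 protein:fat, 0.20 on udder factor
scores split equally, 0.15 on performance-test traits split 0.45/0.55, and
0 on somatic cell score), index SD $\sigma_i = \sqrt{b'Pb}$, and response
$R = (i/\sigma_i)\, G b$, standardized as $R/\sigma_P$ per trait.  A
sometimes-printed variant of the response formula ending in $b'P^{-1}$ is
dimensionally inconsistent for a per-trait response vector and is not
implemented; the $G b$ form is validated in the tests against a
200,000-individual truncation-selection Monte Carlo.  Environment-specific
$G$ and $P$ take the mean ZGZ' of the environment's HEG levels as the
genetic variance of reaction-norm traits, phenotypic variance as the sum of
all components (class-averaged residual), and correlations supplied by the
user; performance-test traits, recorded under standardized station
conditions, keep identical variances in every environment.

Selection intensity comes from the truncated normal,
$i = \phi(\Phi^{-1}(1-p))/p$, e.g. $i = 1.755$ at $p = 0.10$.

## Problem sizes used in the tests

Module tests run on 25–40-herd herd-books with short chains (a few
thousand iterations); the calibration study runs ten replicates of the
default 60-herd scale at 20,000 iterations, a few minutes in total.  These
sizes were chosen so the whole suite doubles as a quick regression check;
the estimation code itself has no scale assumptions beyond sparse-matrix
memory.
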