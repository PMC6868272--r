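---
title: "Quantitative genetics of hip-dysplasia screening data: models and methods"
author: "felhip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of hip-dysplasia screening data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Feline hip dysplasia (FHD) is scored in screening programmes on a 4-grade
ordinal scale (0 = normal to 3 = severe), separately for each hip, from a
ventrodorsal radiograph. A cat's *maximum hip score* — the worse of its two
hips — is the working phenotype: breeding recommendations exclude cats with
grade 2 or 3 on either hip and restrict grade-1 cats to grade-0 partners.
`felhip` implements the quantitative-genetic analysis of such programmes:
how heritable the score is, how it is genetically tied to body mass, and
how fast selective breeding reduces it.

# Models

## Threshold (liability) animal model

The ordinal score is modelled through a continuous latent liability

$$\ell_i = x_i'\beta + a_i + pe_i + e_i, \qquad e_i \sim N(0, 1),$$

with the observed grade $y_i = k$ when $\gamma_k < \ell_i \le \gamma_{k+1}$
($\gamma_0 = -\infty$, $\gamma_4 = \infty$). Breeding values follow
$a \sim N(0, A\,V_A)$ where $A$ is the additive relationship matrix derived
from the pedigree, and $pe$ is a permanent-environment effect per
individual ($N(0, I\,V_{PE})$) absorbing repeated-measure covariance. For
identification the residual variance is fixed at 1, the first cutpoint at
0, and the intercept is free; the remaining two cutpoints are estimated.
Latent-scale heritability is $h^2 = V_A/(V_A + V_{PE} + 1)$, computed per
posterior draw and summarised afterwards.

Estimation is by Gibbs sampling with data augmentation: liabilities are
drawn from truncated normals given the linear predictor; all location
effects are drawn jointly from the sparse mixed-model equations (the
pedigree enters through the sparse $A^{-1}$ built by Henderson's rules with
the inbreeding adjustment, inbreeding itself by the Meuwissen–Luo
algorithm); $V_A$ and $V_{PE}$ have conjugate scaled-inverse-chi-square
full conditionals; the free cutpoints move by a random-walk Metropolis step
on their log-increments whose acceptance uses the liability-integrated
(marginal) likelihood, with the liabilities refreshed afterwards. A
group-scale move (jointly rescaling liabilities, location effects and
cutpoints by a factor drawn from the scale-group conditional, then
refreshing the variance components) improves mixing along the weakly
identified total-latent-scale direction and is needed for well-calibrated
heritability intervals.

The joint location draw uses the perturbed-right-hand-side construction
$\theta = C^{-1}(W'R^{-1}\ell + e)$ with $e \sim N(0, C)$ assembled from
the square roots of the individual precision terms; the square root of
$A^{-1}$ is available analytically from Henderson's decomposition
$A^{-1} = T' D^{-1} T$, so each iteration costs one sparse Cholesky update
and solve.

## Observed-scale heritability

Latent-scale $h^2$ of an ordinal trait is not comparable with estimates on
the data scale. With probit link, the conditional mean score given the
non-residual liability $\ell \sim N(\mu, V_A + V_{PE})$ is
$\psi(\ell) = \sum_{k=1}^{3} \Phi(\ell - \gamma_k)$, and

$$V_{P,\mathrm{obs}} = \mathrm{Var}[\psi(\ell)] + E[v(\ell)], \qquad
  V_{A,\mathrm{obs}} = V_A\,(E[\psi'(\ell)])^2, \qquad
  h^2_{\mathrm{obs}} = V_{A,\mathrm{obs}}/V_{P,\mathrm{obs}},$$

where $v(\ell)$ is the conditional categorical variance. Expectations are
taken by Gauss–Hermite quadrature (48 nodes by default; the integrand is
smooth and 32+ nodes are already at machine accuracy for the scales
involved), per posterior draw. In the binary limit this reduces to the
classical threshold-model back-transformation
$h^2_{\mathrm{obs}} = h^2_{\mathrm{lat}} z^2 / (p(1-p))$, which the test
suite verifies, along with a fully simulation-based Monte-Carlo oracle.

## Bivariate model and genetic correlation

The bivariate sampler couples the ordinal score with a second trait
(residual body mass, or the other hip's score) through bivariate breeding
values $(a_1, a_2) \sim N(0, G \otimes A)$; $G$ has an inverse-Wishart full
conditional $IW(\nu_0 + m, \Lambda_0 + S)$, $S_{rs} = a_r'A^{-1}a_s$. The
residual covariance between traits is fixed at 0: with one record per cat
and trait it is only weakly identified on the liability scale. The genetic
correlation $r_G = \mathrm{COV}_A/\sqrt{V_{A1} V_{A2}}$ is computed per
draw; draws with a non-positive genetic variance are excluded and counted.

## Priors

Variance components use conjugate scaled-inverse-chi-square priors with
$\nu = 0.002$, $s^2 = 1$ (the field-standard weakly informative default for
animal models), and $G$ an inverse-Wishart with $\nu_0 = 3$ and scale
$10^{-3} I$; all are configurable. At the information content of the
datasets this package targets (thousands of phenotyped cats) the prior
contribution is negligible; parameter-expanded priors mainly matter near
$V_A = 0$, a regime covered by the null-recovery tests, which pass with
the conjugate defaults.

## Residual body mass

Body mass is strongly sex- and age-dependent, so analyses use *residual
mass*: observed minus expected mass from a per-sex Gompertz growth curve
$m(a) = A e^{-b e^{-ca}}$ fitted by nonlinear least squares ($A$ = adult
mass in kg, $b$ dimensionless displacement, $c$ growth rate per day). The
Gompertz form is the standard saturating mammalian growth curve: monotone,
three parameters, sensible asymptote. If the nonlinear fit fails, a
quadratic in log-age is used and flagged; residuals are always reported in
kg (negative = lighter than expected for sex and age).

## Selection-response regressions

Because scores are small bounded counts, the score is regressed on
covariates with a log-link Poisson model *right-truncated* at $K = 3$:
$P(k) \propto \lambda^k/k!$ renormalised over $k \in \{0,\dots,3\}$
(truncation, not censoring: the support simply ends at 3). The MLE uses
Newton–Raphson with the analytic score $(y_i - E[Y_i])x_i$ and
expected-information Hessian, with step-halving so the log-likelihood never
decreases; credible intervals for derived curves come from an adaptive
random-walk Metropolis posterior under flat priors started at the MLE.
Covariates are standardised internally and coefficients back-transformed.

The *mean ancestor score* quantifies generations of selection behind each
cat: $g(x) = 0$ if ancestor $x$ is unknown or was not screened before the
focal cat's assessment, else $g(x) = 1 + (g(\mathrm{sire}) +
g(\mathrm{dam}))/2$; the maternal and paternal values are averaged. The
half-weight recursion discounts chains broken by unscreened ancestors and
returns integer generation counts on fully screened pedigrees; a strict
variant (minimum instead of mean, counting only unbroken fully-screened
generations) is available because the operational definition admits both
readings. "Previously screened" is strict inequality on assessment dates;
ties do not count.

The correlated response of body mass is a Gaussian linear model of
residual mass on the mean ancestor score (plus age and sex), whose slope is
the change in kg per generation of selection.

## Demography

Score tables, prevalence (share of cats with maximum score ≥ 1) and
laterality are plain counts. Laterality can also be recovered from
published marginal tables by inclusion–exclusion: bilateral = |left
affected| + |right affected| − |max affected|; the package can further
expand such marginal tables into individual records whose left, right and
maximum marginals all match exactly (the joint allocation is a
deterministic completion pairing equal grades where possible). Year trends
in category proportions use multinomial logistic regression (reference
category 0, year continuous since programme start) because the
proportional-odds assumption of a cumulative-logit model fails on such
data; `proportional_odds_check()` quantifies this by a likelihood-ratio
comparison of the two fits.

# The synthetic programme generator

`simulate_programme()` emulates a closed 20-year screening-and-selection
programme so that every estimator can be validated against known truth:
discrete generations; per-cat liability = founder mean + breeding value +
permanent-environment effect; each hip adds its own unit-normal residual
before cutting at the thresholds (so unilateral/bilateral expression
emerges purely from per-hip sampling, reproducing the observation that
bilateral cases are the more severe ones); mass = Gompertz(sex, age) +
correlated genetic effect + environmental noise; parents are drawn only
from screened cats passing the breeding rule (exclude maximum score ≥ 2;
grade-1 cats only with grade-0 partners), with a popular-sire effect
(a configurable fraction of eligible males actually sires litters).

The default configuration *is* the study condition set: latent
heritability 0.5 ($V_A = 4$, $V_{PE} = 3$, unit per-hip residual — the
large between-cat share, 7/8, is what produces a realistic bilateral
fraction), mass heritability 0.57 ($V_{A} = 0.2$, $V_E = 0.15$ kg²),
genetic correlation 0.285, cutpoints $(0, 1.9, 3.86)$ taken from the
published per-hip marginal quantiles at total SD $\sqrt{8}$, founder mean
liability 0.8 and 35% of eligible males used as sires — chosen once, by
simulation, so that the programme shows a generation-1 mean maximum score
near 0.85–0.95, overall prevalence near 34%, about 38–41% unilateral cases
among affected cats, and a 65–71% reduction in mean score by generation 8;
300 founders plus 8 generations of 770 births with female-biased
submission (males submitted with probability 0.53) give roughly 4950
records, two-thirds female. Assessment ages are log-normal with median 520
days; ~43% of submitted cats carry a body mass.

What the generator does **not** emulate: overlapping generations,
litter-shared environments, year-to-year drift in the composition of
submitted cats, import of outside breeding stock, and observer drift in
grading. Passing recovery tests therefore shows the estimators are correct
under the stated generative model, not that real programme data are free
of those complications.

# Numerical and design choices

- Unknown parents are unrelated, non-inbred founders; no genetic groups.
- Pedigree files: CSV (or whitespace-delimited), `""`/`"0"` = unknown,
  header required; cycles and duplicate ids are hard errors, unlisted
  parents are an error unless `permissive = TRUE` inserts them as
  founders.
- Maximum score is always recomputed from left/right, never read.
- The sparse normal-equation Cholesky is analysed once on the union
  sparsity pattern and only numerically updated per iteration (for the
  bivariate sampler the pattern must include the cross-trait blocks from
  the start).
- Degenerate inputs: all-founder pedigrees give $A^{-1} = I$; ordinal fits
  require ≥ 2 observed categories; with unrelated individuals, single
  records and free cutpoints even the total latent variance is only
  weakly identified (the cutpoint scale absorbs it); the sampler remains
  proper, with the weakly informative prior governing that direction; an empty candidate pool after selection is an explicit
  error suggesting a weaker threshold.
- Chain defaults (`n_iter = 3000`, `burn = 1000`, `thin = 2`,
  `n_chains = 2`) suit exploratory fits; the validation suite uses single
  chains of 700–1200 iterations on programmes of ~3000 cats, sizes chosen
  so the full suite runs on a laptop core in well under half an hour.
  Convergence is judged by split-$\hat R$ < 1.01 and ESS > 200
  (`mcmc_diagnostics()`); the pipeline flags fits whose variance
  components exceed $\hat R$ = 1.1.

# Known limitations

- With a single record per cat the latent total variance is identified
  only through relatedness, so $V_A$ and $V_{PE}$ individually carry much
  more posterior (and between-dataset) spread than $h^2$; the genetic
  correlation inherits some of this through $\sqrt{V_{A1}}$. This is a
  property of the design, not the sampler — expect $r_G$ point estimates
  on single programmes to scatter by ±0.1 around truth.
- The maximum of two hip scores is itself a nonlinear observation of the
  liability; fitting a single-liability probit to it slightly inflates
  latent-scale components (the data-scale transform is unaffected in the
  tests because it is applied to the same fitted scale).
- The truncated-Poisson model treats an ordinal grade as a bounded count,
  as the source analyses do; it is a pragmatic regression surface, not a
  generative claim.
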