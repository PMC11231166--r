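---
title: "Modelling lymphatic metastatic progression in oropharyngeal cancer"
author: "lymphspread authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lymphatic metastatic progression in oropharyngeal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphspread)
```

## The clinical problem

Radiotherapy for oropharyngeal squamous cell carcinoma (OPSCC) electively
irradiates lymph node levels (LNLs) of the neck that look healthy on
imaging, because they may harbor *occult* (microscopic) metastases.
Current guidelines base this choice on population-level prevalence of
involvement per level.  `lymphspread` implements a probabilistic model of
ipsilateral lymphatic spread that instead quantifies the occult-disease
risk for an *individual* patient, given their T-category and the pattern
of clinically detected metastases.

## The hidden Markov model

The true involvement of the $V$ levels (here I, II, III, IV, V, VII) is a
binary vector $\mathbf{X}[t] = (X_v[t])$ that evolves in discrete,
abstract time-steps starting from all-healthy at tumor formation.  A
directed acyclic *spread graph* carries one parameter per arc:

* $b_v$ — probability per time-step that the primary tumor seeds level
  $v$ (every level has a direct tumor arc: levels are observed metastatic
  in isolation, which a model without direct seeding would assign zero
  probability);
* $t_{r\to v}$ — probability per time-step that an involved parent level
  $r$ seeds its child $v$.

Transitions factorize over levels.  An involved level never heals, and a
healthy level escapes infection in one step only if neither the tumor nor
any involved parent seeds it, so

$$P(X_v[t+1]=1 \mid X_v[t]=0, \mathrm{pa}(v)) =
  1 - (1-b_v) \prod_{r \in \mathrm{pa}(v) \,:\, X_r[t]=1} (1-t_{r\to v}).$$

Collecting all $2^V$ states gives the transition matrix
$A_{ij} = P(\mathbf{X}[t+1]=\xi_i \mid \mathbf{X}[t]=\xi_j)$.  We store
$A$ with **columns as source states**, so every column sums to one and a
column distribution evolves as $A \pi$; the all-involved state is
absorbing.  States are enumerated in binary counting order with the first
listed level as the most significant bit (index 1 = all healthy).  Any
bijection would do; this one is reproducible and cheap to invert.  At
$V=6$ the matrix is $64\times64$, so dense linear algebra is used
throughout — sparse machinery would add complexity without benefit.

### Diagnosis time and T-category

The number of steps elapsed at diagnosis is unobserved.  It is
marginalized over a binomial prior $\mathcal{B}(t_{\max}, p)$ with mean
$t_{\max}\,p$: patients with advanced (T3/T4) tumors were probably
diagnosed later than early-T (T0–T2) patients, so the model uses
$p_{\text{early}}$ and $p_{\text{late}}$.  Defaults are
$t_{\max} = 10$ and $p_{\text{early}} = 0.3$ **fixed**, with
$p_{\text{late}}$ inferred.  Only the product $t_{\max} p$ is effectively
identified when a single T-category is considered, which is why fixing
the early parameter is harmless and removes a flat direction from the
posterior.  The sampled parameter vector is therefore
$\theta = (\{b_v\}, \{t_{r \to v}\}, p_{\text{late}})$ with
$k = V + |\text{arcs}| + 1$ dimensions (11 for the winning graph).

### Observation model

A diagnostic modality reports each level with sensitivity
$s_N = P(Z_v{=}1 \mid X_v{=}1)$ and specificity
$s_P = P(Z_v{=}0 \mid X_v{=}0)$; complete diagnoses factorize into a
$2^V \times 2^V$ matrix $B$.  The built-in registry carries literature
values (CT 76/81, PET 86/79, MRI 63/81, FNA 98/80 as
specificity/sensitivity percent) plus a perfect `pathology`/`consensus`
modality.

Two conventions are worth spelling out:

* **Fitting** uses the perfect modality: the per-level consensus of all
  available modalities (with pathology overruling) is treated as an
  observation of the true hidden state.  Literature sensitivities around
  80% are hard to reconcile with observed clinical level-II involvement
  rates near 80% — taken at face value they would imply nearly universal
  true involvement — so the consensus-as-truth assumption is the
  pragmatic choice, and imperfect modalities enter only at prediction
  time.  Both uses share one code path through the per-call `mod`
  argument.
* **Risk prediction** uses the CT confusion table exactly as registered:
  sensitivity 0.81, specificity 0.76.  Published attributions of these
  two numbers to "sensitivity" and "specificity" are not always
  consistent with the tables they cite; this package pins the registry
  values and reproduces published occult-risk estimates under this
  reading (swapping the two shifts the early-T cN0 level-II risk by more
  than four percentage points).

### Likelihood

For a T-category the vector of probabilities of all complete diagnoses is
$\ell = B^\top \sum_t P(t)\, A^t \pi_0$.  A cohort's log-likelihood sums
$\log P(Z = d_i)$ over patients; levels with *unknown* status (empty CSV
cells) are marginalized exactly by dropping their factors from the
observation product, which equals summing $\ell$ over all completions.
Zero-probability records yield `-Inf` rather than an error so samplers
can reject.  The hot path is compiled: each transition-matrix column is
the Kronecker product of $V$ per-level 2-vectors and is assembled by
iterated doubling, and the cohort is collapsed to unique
(T-category, diagnosis pattern) counts once per run.

## Posterior inference

The prior is uniform on $[0,1]^k$ with no reparameterization, so the
unnormalized log-posterior is just the log-likelihood inside the cube.
Sampling uses an affine-invariant ensemble of $W = 20k$ walkers with
differential-evolution proposals: a walker moves along the difference of
two random walkers from the complementary half-ensemble, scaled by
$\gamma = 2.38/\sqrt{2k}$ with small jitter, and with 10% probability by
$\gamma = 1$ (full-length jumps between modes).  Because proposals come
from the ensemble's own geometry, rescaling any axis leaves the sampler's
behaviour unchanged.  Walkers start uniformly in the cube; the fixed
schedule is 1000 burn-in steps, then 200 steps of which every 10th is
retained, for $S = 20\,W$ draws.  Acceptance fractions are returned for
inspection but nothing adapts to them — fixed schedules keep runs exactly
reproducible from one master seed, and every stochastic stage derives its
stream from that seed.

## Model evidence and graph comparison

Which arcs between levels to include is a model-selection question.  The
log model evidence is computed by thermodynamic integration over power
posteriors $p_\beta(\theta) \propto L(\theta)^\beta p(\theta)$:

$$\ln E = \int_0^1 \mathbb{E}_{p_\beta}\!\left[\ln L(\theta)\right]\,
  d\beta,$$

evaluated on the fifth-order ladder $\beta_j = (j/R)^5$ (default
$R = 63$), which concentrates rungs where the integrand changes fastest.
Each rung is sampled with the same fixed schedule, warm-started from the
previous rung's final walker positions; because of this chaining the
$i$-th retained draw at consecutive rungs forms a matched pair, and the
trapezoidal rule is applied *per sample index*, giving $S$ integrals
$\ln\hat{E}_i$ whose mean and standard deviation are the estimate and its
error bar.  The uniform prior is proper on the cube, so the $\beta = 0$
endpoint contributes no correction term.  The error bar ignores
autocorrelation between draws and is known to be somewhat optimistic; it
is still the right scale for ranking graphs.  `bic()` provides the
cheaper $-\mathrm{BIC}/2$ approximation and `interpret_bayes_factor()`
the conventional qualitative scale (substantial / strong / decisive ...)
for evidence differences.

The shipped `base_graph()` (tumor to every level, II→III, III→IV along
the main lymphatic pathway) and `winning_graph()` (adding I→II and IV→V)
are the canonical structures for this disease site; the winning graph is
the evidence-maximizing structure on a 686-patient multi-institutional
cohort, and `winning_graph_params()` carries its posterior-mean
parameters as the package's reference parameter set.

## Risk prediction

For a new patient with diagnosis $\zeta$, Bayes' theorem gives
$P(\xi_k \mid \zeta) \propto P(\zeta \mid \xi_k) P(\xi_k \mid \theta)$,
and any involvement question is a dot product with an indicator
(marginalization) vector over compatible states.  "Occult risk in level
$v$" means $P(X_v = 1 \mid \zeta)$ for a diagnosis in which $v$ is
clinically negative; `occult_risk()` makes that convention explicit by
treating unmentioned levels as clinically negative.  Point risks quoted
in the documentation are computed at the posterior-mean parameters,
accepting the small Jensen gap relative to averaging risks over draws;
`risk_over_samples()` does the latter (by default on a random tenth of
the draws) when the spread of the prediction matters.
`risk_scenarios()` bundles the four standard presentations: cN0, II
only, II+III, and II+III+IV.

```{r}
g <- winning_graph()
p <- winning_graph_params()
ct <- modality("CT")
round(100 * c(
  II_cN0_early  = occult_risk(g, p, "II", c(), "early", ct),
  III_cN0_late  = occult_risk(g, p, "III", c(), "late", ct),
  IV_late_IIIII = occult_risk(g, p, "IV", c(II = 1, III = 1), "late", ct)), 2)
```

`predicted_prevalence()` gives the model's prior probability of an
involvement pattern (the quantity to compare against cohort frequencies),
and `beta_posterior_prevalence()` the matching Beta posterior over an
observed frequency under a uniform prior.

## The cohort simulator

`simulate_cohort()` draws patients from the generative model itself:
T-category (late with probability `fraction_late`, default 0.5 — close to
the early/advanced split of real OPSCC cohorts), a diagnose time from the
matching binomial prior, a hidden state evolved through that many Markov
steps, and observations corrupted by the modality's confusion table.  Its
defaults *are* the study conditions (`p_early = 0.3`, `t_max = 10`,
perfect observation for fitting); it emulates exactly what the likelihood
assumes — independent patients, level-VII-style missingness only if you
blank entries yourself, no institution effects, no HPV status, no
pathology-vs-clinical discrepancy.  Passing tests on simulated cohorts
therefore demonstrate the *internal* consistency of likelihood, sampler
and evidence machinery, not that real necks follow the model.

## Numerical choices and test scales

* Probabilities are kept in linear space ($64$-state vectors are far from
  underflow); only per-patient probabilities are logged.
* Likelihood normalization and column stochasticity hold to $10^{-10}$ or
  better and are asserted property-style over 1000 random parameter
  draws.
* Exact likelihood ties in the consensus rule resolve to *involved*, the
  clinically conservative choice.
* The test suite checks the sampler against the conjugate
  Beta closed form (Kolmogorov–Smirnov distance < 0.05 on
  $\ge 2000$ draws), thermodynamic integration against
  $\ln B(n{+}1, m{-}n{+}1)$ on a Bernoulli–uniform toy, and the full
  pipeline by parameter recovery on a 5000-patient simulated cohort and
  by model selection (winning vs pruned graph, $R = 15$ ladder) on a
  2000-patient cohort — sizes chosen so the whole suite runs on a desk
  machine in a few minutes while leaving the checks well-powered.
* A coarser ladder or shorter burn-in is used in some unit tests of the
  evidence code where only agreement within the reported error bar is
  asserted; the acceptance-grade checks use the full schedule.

## Limitations

Only ipsilateral spread is modelled; contralateral involvement,
trinary (micro/macro) states, HPV status, time-inhomogeneous rates and
joint inference of sensitivity/specificity are out of scope.  The
consensus-as-truth assumption for fitting means the inferred parameters
describe consensus involvement, not pathology-confirmed involvement; the
reported occult-risk estimates inherit whatever bias that introduces.
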