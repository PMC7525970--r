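---
title: "Choosing among ACE predictor characterizations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing among ACE predictor characterizations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aceselect)
```

## The problem

Large health surveys carry a standard battery of 11 retrospective items on
Adverse Childhood Experiences (ACEs): five household-dysfunction items
answered *yes/no* (household mental illness, alcoholism, drug abuse,
incarceration, parental divorce) and six abuse/violence items answered
*never / once / more than once* (household violence, physical abuse,
emotional abuse, and three sexual-adversity items). Before any of this can
predict an adult outcome, an analyst has to make several coding decisions
that the literature makes inconsistently:

* **Exposure threshold.** For the frequency items, does "once" count as
  exposed, or only "more than once"?
* **Item count.** Keep the three sexual items separate (11 items) or
  collapse them into a single *Sexual Abuse* indicator (9 items)?
* **Predictor family.** Enter the count of exposures as a continuous
  score (**CRCn**, one slope per additional ACE, optionally with a
  quadratic term), as a reference-cell-coded categorical score (**CRCat**,
  one coefficient per count level versus zero), or enter all event
  indicators jointly so each event keeps its own adjusted coefficient
  (the multiple-individual-risk model, **MIR**).

For a binary outcome all three are ordinary logistic regressions with the
same covariate block, differing only in the adversity block:

$$\mathrm{logit}\, p_i = \beta_0 + \beta_1\,\mathrm{Score}_i \quad (\text{CRCn}),$$
$$\mathrm{logit}\, p_i = \beta_0 + \textstyle\sum_{s\ge 1} \beta_s\,[\mathrm{Score}_i = s] \quad (\text{CRCat}),$$
$$\mathrm{logit}\, p_i = \beta_0 + \textstyle\sum_{j=1}^{11} \beta_j E_{ij} \quad (\text{MIR}),$$

each plus identical covariate terms. Because the adversity blocks cannot
be obtained from one another by parameter restrictions while the covariate
block is shared, the families are *partially non-nested*, and the
likelihood-ratio test does not apply between them.

## The two-step Vuong procedure

The package compares two fitted candidates through the per-observation
log-likelihood differences $m_i = \ell_i^{(A)} - \ell_i^{(B)}$.

**Step 1 — distinguishability (variance) test.** If the two models are
equivalent in population, the variance
$\omega^2 = \mathrm{Var}(m_i)$ is zero. The statistic $n\hat\omega^2$
(with $\hat\omega^2$ the maximum-likelihood variance of the $m_i$) is
referred to its asymptotic null distribution
$\sum_j \lambda_j^2\,\chi^2_1$, where the $\lambda_j$ are the eigenvalues
of a $(k_A + k_B)$-square matrix assembled from each model's mean score
cross-products $B = n^{-1}\sum_i s_i s_i'$, the cross-model block
$B_{AB}$, and mean Hessians $A$:

$$W = \begin{pmatrix} -B_A A_A^{-1} & -B_{AB} A_B^{-1} \\ B_{AB}' A_A^{-1} & B_B A_B^{-1} \end{pmatrix}.$$

Swapping the two models negates the spectrum of $W$, so the squared
weights — and hence the test — are symmetric in the pair. If this test
does not reject, the models are declared **indistinguishable** and no fit
comparison is attempted.

**Step 2 — closeness test.** For distinguishable pairs,
$z = \sum_i m_i / (\sqrt{n}\,\hat\omega)$ is asymptotically standard
normal under equal closeness to the truth; a significant positive $z$
favors model A, negative favors B, and a non-significant $z$ is reported
as *distinguishable, non-different fit* (NDF). The closeness statistic is
the unadjusted one (no AIC/BIC penalty correction), matching the common
reference implementation of the two-step test; penalty-adjusted variants
were deliberately not made the default.

**AIC fallback.** When the two-step test is silent (indistinguishable or
NDF), selection falls back to the smaller AIC, flagged *substantial* only
when the difference exceeds 50 — a deliberately conservative
rule of thumb for very large survey samples; ties within numerical
tolerance go to the model with fewer parameters.

**Nested pairs.** The covariate-only baseline *is* nested in every ACE
model. For fidelity to the usual comparison-matrix layout these pairs run
through the same two-step machinery (with a warning), and a classical
likelihood-ratio chi-square is attached alongside for reference.

### Numerical choices

* Logistic fits run IRLS (`stats::glm.fit`) followed by Newton polishing
  with step halving until the Euclidean norm of the score vector is below
  `1e-8` (at most 100 iterations). Per-observation log-likelihoods,
  scores and the observed information are retained on the fit object.
* Complete or quasi-complete separation (`|beta| > 15` with exploding
  standard error), non-convergence, and rank-deficient designs are hard
  errors naming the offending column — every downstream Vuong quantity
  needs finite per-observation log-likelihoods.
* The weighted-chi-square tail probability is evaluated by seeded Monte
  Carlo (default $10^6$ draws) in `vuong_variance_test()`; an Imhof-type
  numerical inversion of the characteristic function is implemented as a
  deterministic alternative (`method = "imhof"`, accurate to roughly
  `1e-4`, and property-tested against the Monte Carlo route to `1e-3`).
  The selection workflow uses the inversion route by default so that full
  reports are deterministic without a tail seed.
* Eigenvalues of $W$ are real asymptotically; tiny imaginary parts from
  finite-sample asymmetry are dropped (with a warning if they are not
  tiny).
* $\hat\omega^2 < 10^{-14}$ short-circuits to a tail probability of 1:
  numerically identical fits are indistinguishable at any level.
* The quadratic CRCn term uses the mean-centered squared score to limit
  collinearity with the linear term.
* VIFs are computed by unweighted OLS of each ACE column on all other
  design columns (the common practice); an information-weighted variant
  is available behind `vif_ace(fit, weighted = TRUE)`.

## Screening and predictor construction

Rows with any missing covariate or outcome are dropped; rows with two or
more missing ACE items are dropped; rows with exactly one missing item
are retained with the item imputed to its unexposed level ("no" /
"never"), so that all candidates are fitted to the identical row set.
Input codes such as "don't know"/"refused" are mapped to missing at read
time (`read_ace_dataset()`, configurable).

`check_cell_counts()` cross-tabulates the ACE score against the outcome
and each covariate and flags cells with fewer than 20 cases. The default
CRCat scheme is the identity (one category per observed count, reference
0); the workflow collapses top categories into an open-ended level (e.g.
"4+") only when the cell-count check fails, and then by the minimal
collapse that restores compliance. Frequency-weighted (non-binary)
exposure scoring is out of scope.

The within-family candidate set is the full permutation grid: threshold
× item count (4 candidates for CRCat and MIR; × quadratic for CRCn,
8 candidates). Within-family selection is champion-versus-challenger in
enumeration order; the order is a declared convention, logged in the
decision trail so sensitivity can be audited. All pairwise decisions, the
rule that resolved each (Vuong verdict or AIC), and the final choice are
recorded in the `ace_selection` object and exportable with
`write_selection_report()`.

## The synthetic-data generator

Real ACE items are strongly positively correlated, so independent
Bernoulli draws would be an unrealistic test bed. The generator draws one
latent 11-variate normal vector per respondent with an exchangeable
correlation `rho` (default 0.4; a full matrix is accepted) and thresholds
each coordinate at the quantile cut-points implied by the item marginals;
three-level items use two ordered thresholds. This Gaussian-copula
construction reproduces arbitrary marginals with monotone inter-item
association in `rho`.

Defaults are package choices, not estimates from any survey: exposure
probabilities (at the "once" threshold) between 0.10 and 0.35 across
items, ordered like typical ACE prevalences, and plausible covariate
margins. Covariates are independent of items by default; a shared-latent
`covariate_item_link` flag induces confounding for experiments.

Outcomes are Bernoulli draws from a logistic linear predictor assembled
under a declared `truth_spec()`: `mir` (per-item log-ORs), `cr_linear`
(slope and optional quadratic in the raw count), `cr_categorical`
(step effects per count), or `null`. Generative exposure is defined at
the "once" threshold by default (configurable), since the threshold is an
empirical choice downstream. Missingness is MCAR per item cell; no
informative missingness mechanism is modelled.

What the generator does **not** emulate: survey sampling design, weights,
state structure, within-household clustering, or recall bias. Passing
selection-power tests on these data therefore shows the machinery is
sound under the declared truths, not that any particular substantive ACE
finding generalizes.

## Validation via simulation (problem sizes used)

The test suite validates the pipeline at sizes chosen to balance
statistical resolution against a few minutes of runtime:

* **Oracle checks** — the 2×2 slope equals $\ln 4$; the c-statistic
  matches exhaustive pair enumeration for $n \le 30$; AIC/Nagelkerke
  identities hold to `1e-8`; coefficients match an independent `optim()`
  fit to `1e-6`; all Vuong quantities match a finite-difference oracle.
* **Null calibration** — 500 replicates at $n = 2000$ with two
  pure-noise single-predictor models: the distinguishability step rejects
  at a rate inside the exact binomial 95% band around 0.05.
* **Selection power** — 100 replicates at $n = 5000$ under a
  heterogeneous MIR truth: the workflow picks MIR in at least 90%; under
  a linear CR truth, CRCn is not rejected against CRCat in at least 90%.
* **Coverage** — 95% Wald intervals for MIR log-ORs cover the generating
  values within [0.93, 0.97] over 500 replicates at $n = 5000$ (and
  likewise for the CRCn slope).

`scripts/acceptance.R` re-runs these computations from scratch against
the installed package and writes the resulting rates as JSON.

## A worked run

```{r example}
cfg <- ace_sim_config(
  n = 5000, seed = 7, missing_rate = 0.01,
  truth = truth_spec("mir", intercept = -1.5,
                     mir_betas = c(1.2, 0.1, 0, 0.9, 0.05, 0,
                                   0.7, 0.15, 0, 0.8, 0)))
d <- simulate_ace_data(cfg)
sel <- run_ace_selection(d)
sel
```

The printout mirrors the usual reporting layout: best fit per family with
Nagelkerke $R^2$, AIC and c-statistic ("(by AIC)" marks families whose
internal comparisons were statistically tied); the comparison matrix with
the variance statistic and closeness $z$ per cell (positive $z$ favors
the column model, NDF marks distinguishable pairs of equal fit); and the
MIR table of adjusted versus single-item "unadjusted" odds ratios with
the VIF range.

## Known limitations

* Survey design weights are intentionally unsupported; estimates are
  conditional on the analytic sample.
* The two-step machinery assumes the candidates are fitted to identical
  rows and outcomes; comparisons across row sets are refused, and no
  multiple-testing correction is applied across the comparison matrix.
* Separation is an error, not a penalized fallback; rare exposures in
  small samples may require coarser schemes or larger data.
* The Imhof inversion is accurate to about `1e-4`, which is ample for
  verdicts at conventional levels but not for extreme tail p-values;
  those are reported as computed.
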