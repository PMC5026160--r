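---
title: "Optimizing forced-choice odor identification panels for Parkinson's disease screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing forced-choice odor identification panels for Parkinson's disease screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniffsel)
```

## The problem

Odor identification is measured with forced-choice tests: the subject
smells a pen and picks one of four listed descriptors, so even an anosmic
subject scores correctly 25% of the time per item. PD patients score far
below healthy controls and below patients with atypical parkinsonism or
essential tremor, which makes a sum score over 16 odors (SS-16) an
attractive, cheap diagnostic aid — if it can be shortened without losing
discrimination. This package implements the complete shortening-and-
validation pipeline: sparse odor selection on a discovery cohort, nested
subset evaluation on independent validation cohorts, cutoff-based accuracy,
and prevalence transport of predictive values.

## The response model behind the simulator

No patient-level data ship with the package; cohorts are simulated from a
latent-trait item-response model with a guessing floor. Subject $i$ of a
diagnostic group draws an olfactory ability $\theta_i \sim N(\mu,
\sigma^2)$ on the logit scale and identifies odor $j$ independently with
probability
$$p_{ij} = \gamma + (1-\gamma)\,\mathrm{logistic}(\theta_i + b_j),$$
where $\gamma = 0.25$ is the 4-alternative chance rate and $b_j$ a
per-odor difficulty offset (zero by default, i.e. exchangeable odors).

The latent trait is structurally necessary, not a flourish: with
independent items the sum-score SD cannot exceed the binomial bound
$\sqrt{m/4} = 2$ at $m = 16$, whereas published PD cohorts show SDs of 3.1
on 16 items. The shared $\theta_i$ supplies exactly that between-subject
overdispersion:
$$\mathrm{Var}(S) = \mathbb{E}_\theta\!\Big[\sum_j p_j(1-p_j)\Big] +
  \mathrm{Var}_\theta\!\Big(\sum_j p_j\Big).$$

`calibrate_profile(target_mean, target_sd, panel_size)` inverts these two
moments for $(\mu, \sigma)$. Moments are evaluated by 60-node
Gauss–Hermite quadrature (no Monte-Carlo), and the solver nests two
monotone root searches: $\mu$ is solved for the mean at fixed $\sigma$
(the mean is strictly increasing in $\mu$; the bracket auto-extends for
large $\sigma$), then $\sigma$ is solved for the SD. Calibration is
therefore exactly reproducible and independent of any seed. Infeasible
targets — a mean outside $(\gamma m, m)$, or an SD below the binomial
floor at that mean — raise an error reporting the feasible range.

The default study configuration reproduces the published three-center
design: center A with 336 HC, 134 PD, 23 MSA, 23 PSP and 29 ET subjects on
16 items (HC calibrated to 12.7 ± 2.7, PD to 6.8 ± 3.1, the mimic groups
to their printed rows), center B with 150 HC / 400 PD (12.6 ± 2.3,
7.4 ± 3.0), center C with 120 controls / 112 PD on a 12-item panel
(10.3 ± 1.9, 6.5 ± 2.7), and a prospective iRBD arm of 24 subjects of whom
8 convert to PD. Converters draw baseline responses from the PD profile —
the premise that hyposmia precedes conversion — and non-converters from a
profile calibrated to the published iRBD row (9.9 ± 4.4). Ages, sexes and
disease durations are drawn from normal/Bernoulli approximations of the
same table; they are metadata only and never enter any classifier. All
randomness flows from one master seed through a deterministic
multiplicative stream-splitter, so identical configurations give
byte-identical studies.

**What the generator does not emulate.** Odors are exchangeable by default
(zero offsets), so the default study contains no "intrinsically best"
8-odor subset: subset sweeps on it show how much discrimination any
k-odor subscore retains, not which odors matter. Recovery experiments
plant a signal explicitly via `item_offsets`. The model also omits
item-level covariance beyond the shared trait, cultural familiarity
effects, age/sex effects on olfaction, and longitudinal decline. Passing
tests therefore certify the pipeline's statistical machinery on data with
the published first and second moments — not clinical performance on real
cohorts.

## The path solver

`lasso_path()` minimizes the penalized average negative log-likelihood
with unpenalized intercept by cyclic coordinate descent over a descending
grid of 100 log-spaced penalties from $\lambda_{\max}$ (the smallest
penalty with an all-zero solution, computed in closed form from the
standardized score equations) down to $10^{-3}\lambda_{\max}$ (both
configurable). Items are standardized internally to zero mean and unit
$1/n$-variance so binary items of different prevalence face equal
effective penalties; reported coefficients are back-transformed.

Each coordinate step uses the quadratic majorization of the logistic loss
with the global curvature bound $1/4$ — a proximal update
$\beta_j \leftarrow 4\,S(\beta_j/4 - g_j,\ \lambda)$ with the exact
current gradient $g_j$ — which makes every update provably non-increasing
in the objective. This fixed-Hessian variant is deliberately simpler than
IRLS reweighting; warm starts across the grid and active-set inner loops
(iterate the nonzero set to convergence, then certify with a full sweep)
keep it fast. Convergence is declared when the largest standardized
coefficient change in a sweep falls below $10^{-7}$; each grid point also
satisfies the KKT subgradient conditions to $10^{-6}$ or is flagged
unconverged (`kkt_check()` recomputes the certificate from data). Perfect
separation at tiny penalties is flagged, never an exception. A relative
threshold slack of $10^{-12}$ absorbs the floating-point boundary case
$|g_j| = \lambda_{\max}$.

Entry order is defined by first entry (drop-and-re-entry events later on
the path do not move an item); simultaneous entries at one grid point are
broken by larger absolute coefficient at entry, then by panel index.
Items that never enter are appended last and flagged, so the length-$k$
prefix is always well defined up to the panel size.

## Diagnostics

The clinical direction is fixed throughout: low scores indicate PD, a
subject is test-positive when the integer subscore is at or below the
cutoff. AUC is computed by the tie-corrected rank formula —
$P(\text{case} < \text{control}) + \tfrac12 P(\text{tie})$ — with DeLong
structural-component confidence intervals truncated to $[0,1]$; the
interval method for the published figures is unstated, and DeLong was
chosen as the standard deterministic option. Youden cutoffs scan all
achievable integer cutoffs plus the all-negative boundary; exact ties in
$J$ go to the higher-sensitivity cutoff (screening use), with a
`ties = "specificity"` alternative.

Published analyses applied lower cutoffs against the diagnostic mimics
without stating their derivation; the pipeline exposes this as an integer
offset below the discovery Youden cutoff (`dd_cutoff_delta`, default 1).

Proportions carry Clopper–Pearson intervals from the beta-quantile closed
form; at the boundaries these reduce to $(\alpha/2)^{1/n}$ and its mirror.
For 8/8 this gives a lower bound of 63.1% — published worked examples
print 62.8%, an interval whose generating method does not match any
standard closed form; the package reports Clopper–Pearson and matches
printed values only where they are method-independent. Metrics with empty
margins are reported as undefined, never imputed. Predictive values
transport to other case mixes by Bayes' rule; the two shipped scenarios
are a general neurological service (PD prevalence 91.8%) and a
movement-disorder clinic (69.0%).

## The study design

`run_full_study()` splits center A's PD and HC subjects 50/50 stratified
by group (odd strata randomize the remainder subject), assigns all mimic
groups to validation, and asserts at every evaluation that no subject id
crosses the discovery/validation boundary. Cutoffs are computed exactly
once, on discovery; validation results change only through data. The
minimal adequate subset size is the smallest $k$ whose AUC reaches the
lower 95% CI bound of the same cohort's full-test AUC — the literal
reading of the published rule — with a CI-overlap alternative behind
`rule = "ci_overlap"`; the optimal size is the smallest $k$ attaining the
maximum AUC. The early-disease reanalysis drops patients with more than 3
years of disease duration (controls, who carry no duration, are kept) and
errors loudly if a required stratum empties. For the 12-item center, whose
odors nest inside the 16-item inventory, a separate 12-item-restricted
selection is run on the same discovery subjects, mirroring the published
two-row design.

## Group comparisons

`mann_whitney_test()` uses exact enumeration when the smaller sample has
fewer than 8 observations — the full permutation distribution of the rank
sum, computed by dynamic programming over doubled mid-ranks so ties are
handled exactly — and otherwise a normal approximation with tie-corrected
variance and no continuity correction (none is stated for the published
tables). The exact two-sided p doubles the smaller tail, the standard
convention. These two branches genuinely differ near the crossover: by
enumeration of the full null distribution at $n = m = 8$ the worst-case
gap is 0.0465, which is what the test suite asserts against; a continuity
correction would shrink it but is deliberately not applied. Chi-square
tests are Pearson without Yates correction; Bonferroni adjustment is
$\min(1, mp)$ with the family defined per variable as the set of
versus-PD comparisons within a cohort.

## Problem sizes and test design

The test suite cross-checks every estimator against an independent route:
the path solver against a reference solver on random instances and
against an unpenalized Newton fit at $\lambda \to 0$ ($\le 10^{-4}$); AUC
against exhaustive pair counting; Youden against a brute-force cutoff
scan; the exact rank-sum branch against complete enumeration of label
assignments; Clopper–Pearson against its boundary closed forms and a
coverage simulation (n = 20, 10,000 replicates). Monte-Carlo checks use
100,000 subjects for calibration recovery (tolerances 0.05 on the mean,
0.1 on the SD) and 20 replicates of 2,000 + 2,000 subjects for
planted-signal recovery (8 informative odors expected as the first 8 path
entries in at least 90% of replicates). Pipeline tests run a scaled-down
three-center study; the full-size default configuration is exercised
end-to-end once.

## Known limitations

Real cohort accuracy is not reproducible from this package: the
patient-level data behind the published tables are not deposited, and all
cohort-level results here are qualitative mirrors on calibrated synthetic
data. The simulator's exchangeable-odor default makes subset *identity*
arbitrary on default studies. The DeLong and Clopper–Pearson choices may
differ from the unstated published interval methods by fractions of a
percentage point. The iRBD arm is evaluated as a fixed 2×2 at follow-up;
no time-to-conversion modeling is attempted.
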