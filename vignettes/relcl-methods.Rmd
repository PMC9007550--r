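---
title: "Random effects latent class logit models for ranked choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random effects latent class logit models for ranked choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relcl)
```

## The model

`relcl` analyses ranked responses from discrete choice experiments (DCEs)
in which each task presents three multi-attribute alternatives and the
respondent reports a best and a second-best option. The motivating
application is HIV-testing preferences: testing options are described by a
testing venue (home / health facility / VCT center), availability
(weekdays only / every day), the sample type (venipuncture / finger prick
/ oral swab), additional services (none / health check / STI examination),
and a compound of pre-test counseling with partner notification. The
compound attribute exists because some counseling and notification pairs
are infeasible — couples counseling implies the partner automatically
learns the result — so the two conceptual attributes collapse to the 5
feasible pairs and the scheme totals 16 levels.

The utility of alternative $m$ in task $t$ for respondent $i$ of latent
class $x$ with random-effect scores $F_i \in \mathbb{R}^D$ is

$$\eta_{m|x,F_i} = \sum_p \beta_{xp} z_{itmp} + \sum_{d=1}^{D} \sum_p \lambda_{dp} F_{id} z_{itmp},$$

where $z_{itmp}$ is the effects coding of attribute level $p$ (so each
attribute's per-level coefficients sum to zero), $\beta_{xp}$ are
class-specific utility weights, and $\lambda_{dp}$ are loadings that tie
each of $D$ independent standard-normal random effects to one attribute
*domain*: (1) privacy and confidentiality (venue,
counseling/notification), (2) invasiveness and perceived accuracy
(sample), (3) accessibility and value (availability, services). Loadings
are class-independent and masked to their domain, so the random effects
add within-domain, between-person heterogeneity on top of the class
profiles. Loadings are indexed by attribute level only — not by
alternative — since unlabeled alternatives give an alternative-specific
loading no identifiable meaning; with $D < 3$ the domains are used in
index order (privacy first). Alternative-specific constants are excluded: choices are
unlabeled and presentation order is randomized.

A ranking is modeled as sequential (exploded) logit choices: the best of
three with softmax probabilities over the three utilities, then the
better of the remaining two with the same utilities. Latent class
membership follows a multinomial logit on the cohort indicator
(barworker/porter), with the last class as reference. The marginal
likelihood integrates the random effects against the standard normal and
sums over classes:

$$\ell_i = \log \sum_x \pi_x(c_i) \int \prod_t
P(\text{ranking}_{it} \mid x, F)\, d\Phi(F).$$

## Estimation

The integral uses tensor-product Gauss–Hermite quadrature (default 7
nodes per dimension, 343 nodes at $D=3$); a Halton-sequence simulated
likelihood is available as an alternative (`integration = "halton"`).
All accumulation is in log space with log-sum-exp; with 8 classes and
hundreds of nodes the unlogged products underflow.

Each random start runs an EM phase followed by quasi-Newton (L-BFGS-B)
refinement of the full marginal likelihood. The E-step forms joint
posteriors over (class × node); the M-step performs a partial L-BFGS-B
update of the weighted exploded-logit objective in $(\beta, \lambda)$ and
a Newton-type update of the membership coefficients — a generalized EM,
so the marginal log-likelihood is non-decreasing. The refinement phase
uses analytic scores obtained from the posterior weights (Fisher's
identity). Default control values mirror common practice for these
models: 250 EM iterations, 50 quasi-Newton iterations, 16 random starts
(150 when re-estimating a selected model), tolerance $10^{-4}$ on the
log-likelihood change. The simulation studies shipped in the tests use
scaled-down schedules (2–4 EM iterations, 50–80 quasi-Newton iterations,
2 starts), which on the well-separated scenarios reach the same optima
from every start.

Two indeterminacies are fixed after fitting: classes are ordered by
decreasing posterior share (ties by the first utility contrast), and each
random effect's loading vector is negated if its largest-magnitude
expanded loading is negative (the standard normal is symmetric, so the
likelihood is invariant). Membership coefficients are re-referenced
exactly under class permutation.

The two-level availability attribute is flagged as ordered: estimation
constrains the *every day* coefficient to be non-negative via a box
constraint (off with `order_constraint = FALSE`). Whether such a
constraint binds during estimation or only shapes presentation is a
modeling choice; the constraint is exposed because a boundary estimate of
zero is a legitimate solution under it.

BIC is $-2\ell + k \log N$ with $N$ = number of participants by default —
the mixture-model convention for repeated measures — with $N$ = exploded
choices selectable (`bic_n = "choices"`). The free-parameter count is
$X \sum_a (L_a - 1)$ for the utility weights, the domain-masked loadings
of the first $D$ domains, and $(X-1)(1 + \text{covariates})$ membership
coefficients; for the default scheme at $X=8, D=3$ with one covariate
this is $88 + 11 + 14 = 113$.

## The synthetic-data generator

No individual-level survey data are distributed with the package, so the
generator stands in for them in every simulation study. It emulates the
study's dimensions: 740 participants (300 female barworkers, 440 male
porters) × 12 tasks × 3 alternatives, i.e. 8,880 rankings and 17,760
exploded choice records. Covariates (age, secondary education, marriage,
HIV-testing history) are drawn independently from cohort-specific
marginals matching the study sample's descriptive table; the joint
covariate distribution is not published, so marginals-only simulation is
a deliberate simplification. Classes are drawn from the membership logit
given cohort; random-effect scores are i.i.d. standard normal; rankings
are drawn sequentially with logit probabilities (Gumbel errors are never
drawn explicitly — the exploded-logit likelihood is exactly the implied
sampling distribution).

The default experimental design is a level-balanced random design: each
attribute's levels are allocated in exactly balanced counts over the 360
alternatives, shuffled, and within-task duplicate alternatives repaired
by balance-preserving swaps. A D-efficiency-optimized design would need
priors and a dedicated search; estimation correctness does not depend on
D-efficiency, and the balance tolerance (every level within 20% of
uniform frequency) is our convention.

`example_params()` provides the fixed, well-separated 2- and 3-class
profiles used across the simulation studies (class utility gaps around
1–2 on the expanded scale, loadings up to 1.8 in magnitude, membership
slope 0.5 on cohort). What passing recovery tests on these scenarios
shows is that the estimator is consistent and well-implemented under the
model's own assumptions at the study's scale; it does not show that real
survey responses satisfy those assumptions (no attribute
non-attendance, no scale heterogeneity, no task-order effects).

## Simulation studies and problem sizes

The shipped studies are sized to document behavior, not to exhaust it:

* **Recovery**: 2 classes, 1 random effect, $n = 1000$, 10 replicates;
  expanded utility weights recovered within ±0.15 and loadings within
  ±0.2 after class matching and sign alignment in at least 8 of 10.
* **Model selection**: BIC over $X \in \{1,2,3\} \times D \in \{0,1\}$ at
  $n = 500$, 10 replicates; the generating (2, 1) cell selected in at
  least 7. The full 1–10 × 0–3 sweep at $n = 740$ is the same code at 40
  cells and is left to the user.
* **Quadrature accuracy**: 15-node Gauss–Hermite vs 200,000-draw
  Monte-Carlo integration on a 20-participant instance, agreement within
  3 Monte-Carlo standard errors. This oracle comparison runs at half the
  example loading scale, where the 15-node rule is converged; at the full
  scale its truncation error (~0.2 log-likelihood units) exceeds the MC
  band and the comparison would measure node count, not implementation
  agreement. The recovery fits use 11 nodes per dimension for the same
  reason.
* **Three-step**: 2 weakly separated classes (separation multiplier 0.3,
  modal classification accuracy ≈ 0.9), membership slope 1.0 on cohort,
  $n = 2000$; the bias-adjusted estimator recovers the slope within ±0.2
  on the mean of 6 seeded replicates while the naive estimator is
  attenuated. The separation is chosen so classification error is
  material — with near-perfect classification there is nothing to
  adjust. The corrected estimator is consistent (slope estimates
  approach 1.0 as $n$ grows to 20,000) but carries a small upward
  finite-sample bias (~0.1) at $n = 2000$, which is why the check
  averages replicates.

## Posterior analyses

Posterior class probabilities combine the covariate-specific prior with
the integrated conditional likelihood; empirical-Bayes random-effect
scores are posterior means over the quadrature grid (posterior SDs are
also returned). Individual-level preference values — the modal class's
expanded coefficient plus loading-weighted scores — reproduce the
structure used for within/between-class density plots: within a class and
domain, the spread of values across levels is proportional to the
magnitude of the expanded loading.

For the three-step covariate analysis, class assignment and the
misclassification matrix are computed from the *measurement-only*
posterior, i.e. with marginal class shares replacing the
covariate-specific prior. This matters: if the assignment itself uses the
covariate-dependent prior, the classification error depends on the
covariates, the naive step-3 slope is inflated rather than attenuated,
and the maximum-likelihood correction (which treats the assignment as an
error-prone class indicator with fixed error rates) is no longer
consistent. The correction inverts the estimated
$P(\text{assigned} \mid \text{true})$ matrix implicitly through the
step-3 likelihood; a singular matrix triggers a warning and a fallback to
the uncorrected logit. Random-effect scores are regressed on covariates
by ordinary least squares.

Aggregate and group-specific fits are compared by cross-tabulating modal
assignments and maximizing diagonal agreement over class relabelings
(exhaustive assignment matching, instantaneous for up to 8 classes).

## Numerical choices and limitations

* Quadrature error is not monotone in the node count on this likelihood
  (it oscillates before decaying); use 7+ nodes per dimension, and 15 for
  reference computations.
* Ties in modal assignment go to the lower class index; canonical class
  order ties break on the first contrast.
* The M-step is partial (bounded L-BFGS-B iterations); monotonicity of
  the EM phase is preserved, convergence is declared on the marginal
  log-likelihood change.
* Standard errors (optional, `compute_se = TRUE`) come from central
  finite differences of the observed information at the optimum; cost is
  quadratic in the parameter count and the Hessian may be singular at
  boundary solutions of the order constraint.
* Degenerate inputs: a single participant fits without error (boundary
  estimates tolerated); empty classes in over-specified grids surface as
  non-converged cells, recorded and skipped by the grid.
* Class labels have no substantive identity across separate fits; any
  cross-fit comparison must go through the relabeling matcher.
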