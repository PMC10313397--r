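---
title: "Methods: Bayesian within-subjects analysis of shape-taste ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian within-subjects analysis of shape-taste ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment and the question

The package analyses a crossmodal-correspondence experiment in the
Bouba-Kiki tradition: do rounded ("Bouba") chocolate shapes taste
sweeter than angular ("Kiki") ones, when the shapes are actually eaten
rather than merely looked at? Twenty-four participants each consume
four chocolate samples — a basic rounded shape (Bouba-A6), a basic
angular shape (Kiki-A6), and one minor geometric variant of each
(Bouba-S6, Kiki-A10) — and rate sweetness, sourness and bitterness on a
0-100 visual analogue scale (VAS). Consumption order is counterbalanced
over all 4! = 24 permutations of the shapes, one per participant.

Six directional hypotheses are preregistered: H1 (Bouba-A6 sweeter than
Kiki-A6), H2 and H3 (Kiki-A6 more sour / more bitter than Bouba-A6),
and H4-H6, the corresponding minor-shape-change comparisons (Bouba-S6
vs Bouba-A6 for sweetness; Kiki-A10 vs Kiki-A6 for sourness and
bitterness).

## The model

Each taste is modeled separately. Writing $y_p \in \mathbb{R}^4$ for
participant $p$'s four condition scores on one taste,

$$y_p \sim \mathcal{N}_4(\mu, \Sigma), \qquad
  \Sigma = \mathrm{diag}(\sigma)\, R \,\mathrm{diag}(\sigma),$$

with priors

$$\mu_i \sim \mathrm{Uniform}(0, 100), \quad
  \sigma_i \sim \mathrm{Uniform}(0, 50), \quad
  R \sim \mathrm{LKJ}(\eta),$$

where the LKJ density is proportional to $\det(R)^{\eta-1}$. The
package evaluates the LKJ term without its normalizing constant — MCMC
and all reported quantities only ever compare densities at fixed
$\eta$ — and `lkj_log_density()` documents this.

Decisions taken where the protocol leaves latitude:

* **$\eta = 1$ by default.** The LKJ shape is not part of the protocol;
  $\eta = 1$ is uniform over correlation matrices, the least-informative
  member of the named family. It is exposed via `prior_spec()`.
* **Independent per-taste fits.** Results are reported per taste and
  the model describes one mean vector over the four samples; cross-taste
  correlation is deliberately not modeled.
* **Untruncated likelihood.** VAS scores live in [0, 100] but the
  likelihood is a plain multivariate normal; only the priors are
  bounded. This mirrors the analysis protocol and keeps all posterior
  quantities interpretable as ordinary MVN functionals.

All quantities of interest are functionals of the posterior draws:

* **EAP** (posterior mean), **posterior SD** (sample, $n-1$
  convention — the reporting convention is not stated, so the package
  documents its choice), and the **95% HDI**.
* **Directional probabilities** $p(\mu_i - \mu_j > 0)$, the mean over
  retained draws $t$ of the indicator
  $u_{\mu_i > \mu_j}^{(t)} = 1\{\mu_i^{(t)} - \mu_j^{(t)} > 0\}$. Ties
  count as failures of the strict inequality. The 4x4 collection of
  these is `probability_matrix()`, with a zero diagonal by reporting
  convention.
* **Compound comparisons**: the probability that *both* shapes of one
  family beat *both* shapes of the other,
  $u_{\mu_i>\mu_k} u_{\mu_i>\mu_l} u_{\mu_j>\mu_k} u_{\mu_j>\mu_l}$
  averaged draw-wise (`joint_probability()`). The product of the four
  marginal probabilities (`marginal_product()`) is also reported
  because published compound summaries print exactly that arithmetic.
  The two differ whenever the mean draws are dependent — which they
  always are, since the four events share coordinates — so the package
  reports both rather than silently choosing. A useful calibration
  point: for four i.i.d. mean draws the joint probability is exactly
  $2!\,2!/4! = 1/6$ while the marginal product is $1/16$.

## Sampling

The posterior is explored on an unconstrained 14-dimensional space:
scaled-logit transforms for the four means (onto (0, 100)) and four SDs
(onto (0, 50)), and hyperbolic-tangent canonical partial correlations
(CPCs) assembled into a Cholesky factor for the six correlation degrees
of freedom. The CPC parameterization makes the unconstrained space
rectangular — every finite vector maps to a valid correlation matrix —
and the full log-Jacobian (logistic terms plus
$\sum_{i>j} (1 + (d-j-1)/2)\log(1-z_{ij}^2)$ for the correlation block)
is added to the target. Deep `tanh` saturation can make the
reconstructed matrix numerically singular even though it is positive
definite in exact arithmetic; `to_constrained()` then shrinks toward
the identity by the smallest of an escalating sequence of factors
(1e-10 to 1e-4) until a Cholesky factorization succeeds. The density
out there is vanishingly small, so sampling is unaffected.

The kernel is a mixture of two Metropolis components:

* a **random-walk** proposal whose global scale adapts by a
  Robbins-Monro recursion toward 0.234 acceptance and whose shape is
  re-estimated from the chain history during burn-in (Haario-style
  adaptive Metropolis), and
* an **independence** proposal, a multivariate Student-t (df = 10,
  covariance inflated by 1.05) refined in two pilot stages: a Laplace
  approximation at the posterior mode seeds a short pilot run, whose
  posterior moments rebuild the proposal for a second pilot, whose
  moments fix the final proposal. Pilot stages use 3 chains of 2,500
  iterations (500 burn-in). The independence component is chosen with
  probability 0.85 per update.

All adaptation happens before retention begins; the retained draws come
from a fixed kernel. Each protocol iteration composes five Metropolis
updates (`updates_per_iteration` in `chain_config()`), which lowers
autocorrelation at a fixed retained-draw count the same way gradient
samplers spend many leapfrog steps per stored draw. The official
protocol itself is five chains of 5,000 iterations with per-chain
burn-in 1,000 — hence 5 x 4,000 = 20,000 retained draws — with chain
$c$ seeded as `seed + c - 1` and the official chains warm-started from
pilot posterior draws.

Convergence is assessed with the split Gelman-Rubin statistic
(`split_r_hat()`): each chain is halved, and with $W$ the mean
within-half-chain variance and $B = n \cdot \mathrm{Var}(\text{half-chain
means})$, $\hat R = \sqrt{\{(n-1)W/n + B/n\}/W}$. Splitting detects
within-chain trends that the plain statistic misses and can only make
the check stricter. The pipeline treats $|\hat R - 1| \ge 0.01$ as a
logged warning, not an error, matching the statistic's diagnostic role.
Zero within-chain variance yields `NaN` plus a warning rather than a
spurious pass.

## The synthetic-data generator

No raw ratings are distributed with the study, so `simulate_ratings()`
generates them: for each participant and taste a 4-vector from
$\mathcal{N}_4(\mu, \mathrm{diag}(\sigma) R \,\mathrm{diag}(\sigma))$,
with presentation orders from `generate_orders()` (the full
lexicographic 4! enumeration, shuffled by seed, cycled over
participants — at $n = 24$ each permutation appears exactly once and
each shape occupies each serial position six times). Three bounds modes:

* `"unbounded"` — scores as drawn. The only mode whose moments match
  the inference model exactly; parameter-recovery calibration uses it.
* `"clipped"` (default) — clamp to [0, 100], emulating the hard ends of
  a VAS slider.
* `"truncated"` — redraw a participant's 4-vector until all components
  are in range.

`make_study_dataset()` fixes the study conditions: $n = 24$, the three
tastes' reference EAP point estimates as true means, a common
$\sigma = 20$ VAS points and exchangeable correlation $\rho = 0.5$,
clipped. The common SD and correlation are round mid-range values
consistent with the reported posterior SDs (3.4-5.9 VAS points for
means at $n = 24$, which implies per-condition SDs in the high teens to
twenties); they are generator conventions, not estimates. Scores are
continuous by default with an optional integer `rounding` flag, since
the slider's granularity is not stated.

What the generator does *not* emulate: order and carry-over effects,
participant-level rating styles (scale compression, end-aversion),
demographic structure, and the mild mean-variance dependence clipping
induces. Passing recovery tests therefore certify the inference
machinery on data satisfying the model's assumptions, not robustness of
the model to real VAS artifacts.

## Numerical and testing choices

* **HDI**: sort the pooled draws and take the narrowest window of
  $\lceil 0.95\,n \rceil$ consecutive draws; ties break to the smallest
  lower endpoint. Assumes unimodality, which holds for every marginal
  this model produces.
* **Problem sizes.** Test and calibration runs scale the protocol down
  where full fidelity adds nothing: pipeline behavior tests use 2-3
  chains of 1,000-2,000 iterations, and the recovery study uses 20
  replicate datasets of $n = 200$ participants fitted with 3 chains of
  1,500 iterations. Convergence acceptance runs use the full official
  protocol.
* **Recovery calibration.** Over the 20 replicates, every EAP is
  checked against generator truth (spot-checked at 3 posterior SDs) and
  95% HDI coverage of truth across all 14 parameters x 20 replicates is
  required to land in a binomial-with-slack band around 0.95.
* **Determinism.** Every stochastic step (order shuffle, score
  generation, per-chain sampling, pilot stages) derives its stream from
  the master seed by fixed offsets; identical seeds give byte-identical
  tables, draws and reports.

## Known limitations

* The likelihood ignores the [0, 100] bounds, so fits to heavily
  clipped data (means near the scale ends with large SDs) inherit a
  small bias; the study-like regime (means 25-55, SD ~20) clips mildly.
* The split-$\hat R$ threshold of 0.01 is a demanding target for any
  non-gradient sampler at 20,000 retained draws; the mixture kernel
  meets it with margin on study-sized problems, but pathological
  posteriors far outside this regime would deserve a gradient sampler.
* No effective-sample-size or rank-normalized diagnostics are computed,
  and no order effects are modeled — both deliberate scope choices.
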