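# boubataste

Bayesian analysis of a within-subjects "Bouba-Kiki" taste experiment:
do rounded (Bouba) chocolate shapes taste sweeter than angular (Kiki)
ones when actually eaten? Twenty-four participants each consume four
chocolate samples — Bouba-A6, Kiki-A6 and two minor geometric variants
(Bouba-S6, Kiki-A10) — in fully counterbalanced order and rate
sweetness, sourness and bitterness on a 0-100 visual analogue scale
(VAS). The package is aimed at sensory/psychophysics researchers who
want the complete analysis pipeline — data model, Bayesian fit,
convergence diagnostics, hypothesis probabilities, reports — as tested,
reusable functions, together with a synthetic-data generator so
everything runs with no external data.

## Model

Per taste, participant score vectors $y_p \in \mathbb{R}^4$ follow

$$y_p \sim \mathcal{N}_4\!\left(\mu,\ \mathrm{diag}(\sigma)\,R\,\mathrm{diag}(\sigma)\right),
\qquad \mu_i \sim \mathrm{U}(0,100),\ \ \sigma_i \sim \mathrm{U}(0,50),\ \ R \sim \mathrm{LKJ}(1).$$

The posterior is sampled with five chains of 5,000 iterations
(burn-in 1,000; 20,000 retained draws) using an adaptive
Metropolis kernel mixed with a pilot-tuned independence proposal, on an
unconstrained parameterization (scaled logits; tanh canonical partial
correlations). Convergence is checked with the split Gelman-Rubin
statistic at $|\hat R - 1| < 0.01$. Reported quantities are EAP,
posterior SD, 95% HDI, draw-wise directional probabilities
$p(\mu_i - \mu_j > 0)$ (Eq. form: mean of the indicator
$1\{\mu_i^{(t)} > \mu_j^{(t)}\}$ over retained draws $t$), and compound
shape-family probabilities — both the draw-wise joint form and the
product-of-marginals arithmetic.

See `vignettes/shape-taste-methods.Rmd` for assumptions, tuning
parameters and limitations.

## Worked example

```r
library(boubataste)

tab <- make_study_dataset(seed = 1)      # 24 participants x 4 shapes x 3 tastes
fit <- fit_taste(tab, "sweetness", chains = chain_config(seed = 1))
fit$convergence
s <- summarize_draws(fit$draws)
format_estimate(s$eap[1], s$sd[1], s$hdi_lower[1], s$hdi_upper[1])
probability_matrix(sapply(paste0("mu", 1:4), pooled_draws, draws = fit$draws))
```

which prints (numbers from this exact seed):

```
convergence: max |R-hat - 1| = 0.000996 (threshold 0.01) PASS
[1] "40.96 (5.07) [30.83, 50.80]"
         Bouba-A6 Kiki-A6 Bouba-S6 Kiki-A10
Bouba-A6   0.0000 0.98110  0.23710  0.98610
Kiki-A6    0.0189 0.00000  0.00215  0.46870
Bouba-S6   0.7629 0.99785  0.00000  0.99705
Kiki-A10   0.0139 0.53130  0.00295  0.00000
```

The first line is the sampler's convergence check (all 14 parameters of
the sweetness fit). The quoted string is the estimate for the Bouba-A6
population mean in the reporting convention "EAP (posterior SD) [95%
HDI]" — the generator's true value is 38.52. The matrix entry (i, j) is
the posterior probability that shape i was rated sweeter than shape j;
for example row Bouba-A6, column Kiki-A6 says the basic rounded shape
beats the basic angular one with probability 0.981 on this synthetic
dataset (hypothesis H1).

The full study pipeline is laid out as numbered driver scripts:

```sh
Rscript analysis/01_simulate.R    # synthetic ratings -> results/ratings.csv
Rscript analysis/02_fit.R         # three taste fits  -> results/draws/*.csv
Rscript analysis/03_hypotheses.R  # summaries, H1-H6, compound -> results/*.csv
Rscript analysis/04_report.R      # results/report.md, results/report.json
```

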