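#!/usr/bin/env Rscript
# Stage 3: posterior summaries and hypothesis probabilities.
#
# From the stored draws this stage computes, per taste: EAP / posterior
# SD / 95% HDI summaries for every parameter, the 4x4 matrix of
# directional probabilities P(mu_i > mu_j) evaluated draw-wise, the six
# preregistered hypotheses (H1: Bouba-A6 sweeter than Kiki-A6, H2/H3:
# Kiki-A6 more sour/bitter than Bouba-A6, H4-H6: minor-shape-change
# analogues), and the compound Bouba-vs-Kiki comparison in both its
# draw-wise joint form and the product-of-marginals form.

suppressPackageStartupMessages(library(boubataste))

draws <- lapply(setNames(taste_levels(), taste_levels()), function(tst)
  load_draws(file.path("results/draws", paste0(tst, ".csv"))))

for (tst in taste_levels()) {
  s <- summarize_draws(draws[[tst]])
  write.csv(s, file.path("results", paste0("summary_", tst, ".csv")),
            row.names = FALSE)
  pm <- probability_matrix(boubataste:::mu_draw_matrix(draws[[tst]]))
  write.csv(round(pm, 3),
            file.path("results", paste0("probmatrix_", tst, ".csv")))
  mu1 <- s[s$parameter == "mu1", ]
  message(sprintf("%s: Bouba-A6 mean %s", tst,
                  format_estimate(mu1$eap, mu1$sd, mu1$hdi_lower,
                                  mu1$hdi_upper)))
}

hyp <- evaluate_hypotheses(draws)
write.csv(hyp, "results/hypotheses.csv", row.names = FALSE)
message("hypothesis probabilities:")
for (r in seq_len(nrow(hyp)))
  message(sprintf("  %s (%s, %s): %.3f", hyp$id[r], hyp$taste[r],
                  hyp$comparison[r], hyp$probability[r]))

cmp <- compound_report(draws)
write.csv(cmp, "results/compound.csv", row.names = FALSE)
message("compound shape-family comparisons (joint | marginal product):")
for (r in seq_len(nrow(cmp)))
  message(sprintf("  %s (%s): %.3f | %.3f", cmp$taste[r], cmp$direction[r],
                  cmp$joint_probability[r], cmp$marginal_product[r]))
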