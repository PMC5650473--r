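#!/usr/bin/env Rscript
# Protein accumulation across interphase on a simulated sorted-fraction
# SILAC dataset (2,000 proteins, four biological replicates, CV 0.15,
# 2% dropout).
#
# What it finds: the proteome-wide mean profile fits the exponential
# growth model y = e^(mx) with a fold over the cycle close to 1.9 rather
# than the idealized 2.0 — sorted gates average cells across their whole
# age window, which flattens the apparent accumulation relative to
# point evaluation on the timeline. Mitotic-peaking proteins (AURKA-like,
# 8-fold) pass the fold + ANOVA screen; ordinary accumulating proteins do
# not, since the Z cutoff is calibrated on the bulk fold distribution.

library(primmus)

res <- run_interphase_pipeline(list(seed = 1), out_dir = "results/interphase")

cat("\nGrowth fit on the simulated bulk proteome:\n")
print(res$fit)

v <- res$verdicts
gt <- res$dataset$ground_truth
cls <- gt$class_label[match(v$protein_id, gt$protein_id)]
cat("\nSignificant candidates by true trajectory class:\n")
print(table(class = cls, significant = v$significant))
cat(sprintf("\nRealized fold cutoff: %.2f-fold\n", attr(v, "z_threshold")))
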