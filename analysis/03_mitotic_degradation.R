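#!/usr/bin/env Rscript
# Screen for proteins degraded during mitotic progression, on a simulated
# mitotic-subpopulation dataset: Pro / PM1 (cyclin A+) / PM2 (cyclin A-) /
# Ana sorted gates, three biological replicates (two SILAC + one TMT
# 6-plex through the isotope-impurity forward model), 2,000 unchanged
# proteins and 60 planted degradation targets (47 PM1, 3 PM2, 10 Ana —
# the 79/5/16% split seen among mitotically degraded proteins).
#
# What it finds: the max-fold-change Z cutoff lands near 1.7-fold; the
# fold + replicate-correlation screen recovers essentially all planted
# targets at a false-discovery proportion well under 10%; k-means
# clusters of the significant profiles agglomerate into PM1/PM2/Ana
# trough groups that match the planted ground truth.

library(primmus)

res <- run_mitotic_pipeline(list(seed = 1, k = 12),
                            out_dir = "results/mitotic")

v <- res$verdicts
gt <- res$dataset$ground_truth
truth <- gt$regulated[match(v$protein_id, gt$protein_id)]
sens <- mean(v$significant[truth])
fdp <- sum(v$significant & !truth) / max(1, sum(v$significant))
cat(sprintf("\nSensitivity %.3f, false-discovery proportion %.3f, cutoff %.2f-fold\n",
            sens, fdp, attr(v, "z_threshold")))

pg <- attr(res$trough_groups, "protein_groups")
tr <- gt$trough[match(names(pg), gt$protein_id)]
cat("\nTrough group vs planted degradation phase:\n")
print(table(assigned = pg, planted = ifelse(is.na(tr), "flat", tr)))
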