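#!/usr/bin/env Rscript
# Phosphosite dynamics across the cell cycle on a simulated site table
# (500 sites, duplicate measurement, planted early risers / late risers /
# flat sites; residue frequencies 83.2% pS, 15.8% pT, 1.0% pY).
#
# What it finds: k-means (k = 6) isolates the mitotically rising clusters;
# sites already significantly elevated in the G2-enriched fraction are
# classified as early risers with high balanced accuracy against the
# planted labels; early risers reach higher M-phase phosphorylation than
# late risers; and their sequence windows are strongly enriched for the
# full CDK consensus [S/T]-P-x-[K/R] (Fisher exact test).

library(primmus)

dir.create("results/phospho", showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_replicates = 2, seed = 1)
ph <- simulate_phosphosites(cfg)
rep <- phospho_dynamics_report(ph$sites, seed = 1)

cat("Residue frequencies:\n")
print(round(unlist(rep$summary$residue_freq), 3))
cat(sprintf("Proline-directed: %.1f%%; full CDK consensus: %.1f%%\n",
            100 * rep$summary$proline_directed_fraction,
            100 * rep$summary$full_cdk_fraction))

truth <- ph$ground_truth$class_label[
  match(rep$risers$site_id, ph$ground_truth$site_id)]
cat("\nRiser classification vs planted truth:\n")
print(table(classified = rep$risers$label, planted = truth))

labels <- setNames(rep$risers$label, rep$risers$site_id)
cmp <- compare_early_late(site_profile_matrix(ph$sites), labels)
cat("\nM-phase log2 ratios (mean +/- sem):\n")
print(cmp)

# CDK-consensus enrichment among early risers vs all classified sites
early_ids <- rep$risers$site_id[rep$risers$label == "early"]
bg_ids <- rep$risers$site_id
cdk <- rep$motifs$full_cdk_consensus
enr <- fisher_enrichment(
  early_ids, bg_ids,
  data.frame(id = ph$sites$site_id[cdk], label = "full_cdk"))
cat("\nCDK-consensus enrichment among early risers:\n")
print(enr)

write.csv(rep$risers, "results/phospho/risers.csv", row.names = FALSE)
write.csv(enr, "results/phospho/cdk_enrichment.csv", row.names = FALSE)
jsonlite::write_json(rep$summary, "results/phospho/summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("\nwrote results/phospho/\n")
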