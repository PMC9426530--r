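#!/usr/bin/env Rscript
# Stage 4 — pathogen analysis. Genomes are labelled from their Biosample
# free text by the keyword rule, genera capped at 100 genomes, the pathogen
# group tested against the unassigned group, and the genus contribution
# resolved by leave-one-out and by the per-shared-genus comparison.

library(prophagecomp)

cat1 <- filter_predictions(load_catalog("results/simulated/prophages.tsv",
                                        "results/simulated/hosts.tsv"))
capped <- cap_per_genus(cat1, cap = 100, seed = 101)
labels <- classify_pathogens(capped)
write.table(labels, "results/pathogen_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("labels: %d pathogen, %d unassigned\n",
            sum(labels$label == "pathogen"),
            sum(labels$label == "unassigned")))

counts <- per_genome_counts(capped$hosts, capped$prophages)
ge <- group_enrichment(counts[labels$label == "pathogen"],
                       counts[labels$label == "unassigned"])
cat(sprintf("pathogen mean %.2f (median %d) vs unassigned %.2f (median %d); p = %.3g\n",
            ge$mean_pathogen, ge$median_pathogen, ge$mean_unassigned,
            ge$median_unassigned, ge$p_value))

loo <- loo_contribution(labels, capped)
write.table(loo$loo, "results/pathogen_loo.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
flip <- loo$loo$left_out_genus[!loo$loo$undefined &
                                 loo$loo$p_value >= 0.05]
cat(sprintf("full-data p = %.3g; removals flipping significance: %s\n",
            loo$full_p, if (length(flip)) paste(flip, collapse = ", ")
            else "none (excess is distributed)"))

shared <- shared_genus_comparison(labels, capped)
write.table(shared, "results/pathogen_shared_genera.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d shared genera tested; significant after Bonferroni: %s\n",
            nrow(shared),
            paste(shared$genus[shared$p_adjusted < 0.05], collapse = ", ")))
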