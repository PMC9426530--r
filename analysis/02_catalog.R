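#!/usr/bin/env Rscript
# Stage 2 — load the simulated catalog back through the public interface,
# apply the prediction filters (>= 10 kb replicons, categories 1-2, plasmid
# predictions dropped), and write the catalog summary, the prophage length
# histogram, and the genome-size versus abundance relation.

library(prophagecomp)

cat0 <- load_catalog("results/simulated/prophages.tsv",
                     "results/simulated/hosts.tsv")
cat1 <- filter_predictions(cat0)
cat(sprintf("filtering kept %d of %d prophages\n",
            nrow(cat1$prophages), nrow(cat0$prophages)))

s <- summarize_catalog(cat1)
print(s)
write.table(data.frame(metric = names(unclass(s)),
                       value = unlist(lapply(unclass(s), format))),
            "results/catalog_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ld <- length_distribution(cat1)
cat(sprintf("mean prophage length %.0f bp; modal bins at %s kb\n",
            ld$mean_length, paste(ld$modal_bins_kb, collapse = " and ")))
write.table(ld$histogram, "results/length_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sa <- size_abundance(cat1)
cat(sprintf("genome size vs prophage count: Spearman rho %.3f (p = %.2g)\n",
            sa$rho, sa$p_value))
write.table(sa$bins, "results/size_abundance_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
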