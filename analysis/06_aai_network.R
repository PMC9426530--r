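#!/usr/bin/env Rscript
# Stage 6 — AAI relatedness. ORFs are called on cluster representatives from
# two planted sequence families plus unrelated singletons; reciprocal best
# hits give per-pair AAI; edges at AAI >= 80 form the relatedness network,
# summarised per taxonomy rank and by shared-ortholog counts.

library(prophagecomp)

set.seed(303)
fam <- simulate_cluster_families(2, 4, divergence = 0.03,
                                 length_bp = 12000, seed = 303)
lone <- setNames(vapply(1:2, function(i) random_dna(12000), character(1)),
                 c("L01_S00", "L02_S00"))
seqs <- c(fam$seqs, lone)
orfs <- setNames(lapply(names(seqs), function(n)
  find_orfs(seqs[[n]], id = n)), names(seqs))
cat(sprintf("ORFs per sequence: median %.0f\n",
            median(vapply(orfs, function(o) nrow(o$proteins), numeric(1)))))

li <- data.frame(
  prophage_id = names(seqs),
  genus = c(rep(c("gA", "gB"), each = 4), "gC", "gD"),
  family = c(rep(c("fA", "fB"), each = 4), "fC", "fD"),
  order = "o1", class = "c1",
  phylum = c(rep(c("pA", "pB"), each = 4), "pA", "pB"),
  stringsAsFactors = FALSE)
net <- build_network(orfs, li, threshold = 80)
write_network(net, "results/aai_edges.tsv", "results/aai_nodes.tsv")
cat(sprintf("network: %d nodes, %d edges at AAI >= 80\n",
            nrow(net$nodes), nrow(net$edges)))

fr <- fraction_by_rank(net, li)
write.table(fr, "results/aai_fraction_by_rank.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("fraction of edges with hosts differing at each rank:\n")
print(fr[, c("rank", "fraction_different")])

so <- shared_ortholog_summary(net, "pA", "pB")
cat(sprintf("cross-phylum edges: %d (mean shared orthologs %s)\n",
            so$n_edges, format(so$mean_orthologs)))
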