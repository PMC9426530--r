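# prophagecomp

Comparative analysis of prophage catalogs predicted from prokaryotic genome
collections. Given a table of prophage predictions (host genome, replicon,
coordinates, predictor confidence category, plasmid flag), host metadata
(taxonomy to genus level, genome size, Biosample free text) and optionally
the prophage sequences, the package answers the questions a prophage survey
asks after prediction:

* **Catalog structure** — filtering (≥ 10 kb replicons, confidence
  categories 1–2, plasmid predictions removed), lysogen fraction,
  per-lysogen count statistics, bimodal length distribution.
* **Taxon enrichment** — per-rank one-sided Wilcoxon tests of each taxon's
  per-genome prophage counts against the remaining genomes (Bonferroni
  adjusted, large taxa subsampled), plus a bootstrap scheme: repeatedly
  draw 10 genomes per genus and test each genus against the pooled
  remainder, yielding a per-genus p-value distribution.
* **Pathogen analysis** — keyword classification of Biosample text into
  pathogen / unassigned, per-genus capping, the group comparison, a
  leave-one-out (LOO) genus-contribution analysis, and per-shared-genus
  tests.
* **Viral clusters (vOTUs)** — greedy representative-based clustering at
  ≥ 90 % nucleotide identity over ≥ 80 % of the shorter sequence, and a
  host-range classifier that reports `same-genus` or the highest taxonomy
  rank at which a cluster's member hosts differ.
* **AAI relatedness** — six-frame ORF calling, reciprocal-best-hit protein
  pairs under BLOSUM62, average amino-acid identity (AAI), the AAI ≥ 80
  network, per-rank edge fractions, shared-ortholog counts, and a host-ANI
  versus prophage-AAI co-structure score.
* **K-mer usage bias** — observed/expected k-mer ratios (k = 1–4, maximal-
  order Markov expectation by default), profile distances, and co-clustering
  of phage and host profiles for composition-based host association.

A synthetic-data module generates complete catalogs with planted,
recoverable structure — enriched genera, pathogen excess, divergence-
controlled sequence families, host-like phage composition — so every stage
is tested end-to-end without downloads. The statistical core is expressed as

> W = Σᵢ rank(xᵢ) over the focal group, tested one-sided (greater) against
> the background; AAI(A,B) = 100 · mean{ id(a,b) : (a,b) ∈ RBH(A,B) };
> B(w) = f_obs(w) / f_exp(w), with f_exp from the sub-word frequencies.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `07_kmer_bias.R`); each script states what it found and
writes its tables under `results/`. Running stages 1–3:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_catalog.R
Rscript analysis/03_enrichment.R
```

prints (seed 20260928, 20 genera × 50 genomes, genus `g07` planted at
four-fold enrichment):

```
Prophage catalog: 1000 genomes, 769 lysogens (76.90%), 3284 prophages
  per-lysogen count: mean 4.27, mode 1, CV 116.0%
mean prophage length 42779 bp; modal bins at 25 and 65 kb
genus rank: 1/20 taxa significant after Bonferroni: g07
bootstrap median p by genus:
   g07    g06    g09    g11    ...
0.0005 0.3455 0.3504 0.4212  ...
genera with median bootstrap p < 0.05: g07
```

Reading this: three-quarters of the genomes are lysogens; the per-lysogen
count distribution has mode 1 and a long tail (the planted enrichment and
pathogen multiplier inflate mean and CV); the length histogram shows the two
planted modes near 30 kb and 70 kb; and both the per-rank test and the
bootstrap single out exactly the planted genus, with no false positives
after Bonferroni. Stage 4 finds the pathogen group significantly enriched
(p ≈ 7 × 10⁻⁸) with no single genus driving it (the planted excess is
uniform, and the LOO confirms that); stage 5 recovers the planted sequence
families exactly and classifies the shipped multi-host cluster compositions;
stages 6–7 build the AAI network over planted protein families and recover
each phage's source clade from its k-mer profile with 100 % accuracy at
composition weight 0.8.

In code, the same clustering + host-range step on your own data is:

```r
library(prophagecomp)
cat1 <- filter_predictions(load_catalog("prophages.tsv", "hosts.tsv",
                                        "prophages.fasta"))
vcs  <- greedy_cluster(cat1)                       # 90% id / 80% cov
ph   <- setNames(cat1$prophages$genome_id, cat1$prophages$prophage_id)
host_range_report(vcs, cat1$hosts, ph)$fraction_same_genus
```

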