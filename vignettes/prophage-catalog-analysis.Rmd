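---
title: "Comparative analysis of prophage catalogs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of prophage catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prophagecomp implements the comparative stages that follow prophage
prediction in large genome surveys: filtering the raw predictions, asking
which host taxa are enriched in prophages, whether pathogens carry more of
them, how prophages group into viral clusters and how wide those clusters'
host ranges are, how related the clustered prophages are at the protein
level, and whether a prophage's nucleotide composition points back at its
host. This vignette explains each model, the tunable parameters, the
synthetic data the package tests itself on, and the design choices made
where the underlying procedures are conventionally underspecified.

## The catalog and its filters

A catalog is a pair of tables plus optional sequences: host genomes (one row
per replicon, with a phylum-to-genus lineage, the genome size and free-text
Biosample metadata) and prophage predictions (host and replicon linkage,
1-based inclusive coordinates, a predictor confidence category, and a
plasmid flag). Catalogs are restricted to genomes assigned at least to genus
level; lineage nestedness (same genus implies same family, and so on up) is
validated at load time because taxonomy tables assembled from heterogeneous
sources routinely violate it, and every downstream host-range statement
depends on it.

Filtering keeps predictions on replicons of at least 10 kb (shorter
replicons are unreliable substrates for prophage prediction), with predictor
category 1 or 2 (the high-confidence classes), and drops predictions tagged
as plasmids, which otherwise masquerade as integrated phages. All three
thresholds are arguments; the filter is idempotent and order-preserving.

A *lysogen* is a genome with at least one retained prophage. The catalog
summary reports the lysogen fraction and per-lysogen count statistics; the
mean uses lysogens as denominator by default (an `all`-genomes denominator
is an option), the mode resolves ties to the smallest count so output is
deterministic, and the coefficient of variation uses the sample (n−1)
standard deviation — the conventional default where no definition is
stated. The length histogram reports up to two modal bins (local maxima of
the binned counts); no formal bimodality test is attempted because the
scientific claim attached to bimodal prophage lengths is descriptive.

## Enrichment testing

The per-taxon test is a one-sided Wilcoxon rank-sum: the focal taxon's
per-genome counts against a background, with the alternative that the focal
counts are greater (the claim under test is enrichment, never depletion).
Two conventions required decisions:

* **Background membership.** Whether the focal taxon's own genomes belong in
  the background is usually not stated in survey methods. The default here
  excludes them — comparing a group partly against itself biases the test
  toward the null — and `background = "include"` restores the
  entire-distribution convention. With many taxa the two differ little; with
  a dominant taxon they do not.
* **P-value computation.** Counts are small integers, so ties are massive.
  Exact enumeration of the rank-sum distribution conditional on the observed
  values is used whenever both groups have at most eight observations
  (`choose(16, 8)` assignments at worst), and the mid-rank normal
  approximation with tie correction — without continuity correction —
  otherwise. This keeps small-sample p-values oracle-checkable while
  matching `stats::wilcox.test(exact = FALSE, correct = FALSE)` exactly in
  the large-sample regime.

Taxa need at least five genomes to be tested; taxa above 50 genomes are
first subsampled to 10 so that heavily sequenced genera do not dominate by
sample size alone. Both the trigger and the sample size are arguments, since
the two natural readings of such a rule (cap only the big taxa vs. cap
everything eligible) appear in the literature. Bonferroni adjustment is
across the taxa tested at one rank.

The bootstrap scheme addresses the same imbalance differently: at each of
100 iterations, 10 genomes are drawn *without replacement* from every genus
with at least 50 genomes, and each genus is tested against the pooled
remainder of that iteration's sample. The eligibility threshold of 50 is
part of the procedure, not an implementation convenience: with much smaller
genera the iterations repeatedly resample the same realized genus means, and
the conditional per-genus significance rate inflates well above the nominal
level even under a perfectly exchangeable null (the one-sided rate is convex
in the realized mean shift, so luck does not average out). At the stated
genus size the calibration suite observes a type-I rate within 0.05 ± 0.02.
Iterations draw from named substreams of one master seed, so runs are
reproducible and a single iteration is exactly reproducible as a direct test
on its subsample.

## Pathogen labels and the leave-one-out analysis

Pathogen status is assigned by scanning six Biosample fields (general
description, isolation source, isolation site, host, environmental medium,
sample type) for case-insensitive keyword matches; the first match, in a
fixed field order, is recorded as the trigger. The keyword list ships as
YAML configuration and is deliberately an explicit, editable approximation:
the underlying judgement ("was this isolate associated with disease?") is a
manual curation that cannot be reproduced verbatim, and a rule engine with a
visible word list is the testable surrogate. Genomes with no match are
*unassigned*, not "non-pathogen" — absence of metadata is not evidence of
lifestyle.

Genera are capped at 100 genomes before the group comparison, again to stop
heavily sequenced pathogens from carrying the test alone. The group test is
the same one-sided Wilcoxon. Because both groups mix many genera, the genus
contribution is resolved two ways: leave-one-out (drop one genus from both
groups, re-test, report the p-value shift; a removal that empties a group is
flagged undefined rather than failing) and the per-shared-genus comparison
(only genera with genomes in *both* groups, Bonferroni across exactly those
genera — the comparisons actually multiple-tested).

## Sequence comparison primitives

Nucleotide identity/coverage uses local affine-gap alignment (Gotoh) with
match +2, mismatch −3, and gap cost 5 + 2L — blastn-style defaults.
*Identity* is matches over aligned columns, counting internal gaps and
excluding terminal ones; *coverage* is the aligned span of the shorter
sequence over its length. These are the operational semantics of the common
greedy clustering tools, stated here explicitly because published thresholds
("90% similarity over 80% of the length") are meaningless without them.

Small problems (up to 4 × 10⁶ cells) run the full dynamic program, which on
sequences ≤ 200 bp is verified in the test suite against an independent
implementation to exact score equality. Longer pairs are aligned in a band
(default half-width 200) around the best shared-11-mer diagonal; words
occurring more than 16 times per sequence are masked when voting, because
low-complexity words flood the diagonal table without positional signal. A
long pair whose best diagonal collects fewer than 8 shared words reports an
empty alignment — unrelated 30 kb sequences share only scattered words,
while any pair near a 90%/80% threshold shares hundreds, so the shortcut
cannot change a clustering decision. The banded heuristic assumes
colinearity; large rearrangements between near-identical sequences would be
under-aligned, which is the standard limitation of every seeded aligner.

ANI follows the classic fragment recipe: chop one genome into 1 kb
fragments, align each locally to the other genome, keep fragments with at
least 30% identity over at least 70% of the fragment, and average the kept
identities. With no passing fragment ANI is undefined (`NA`), never zero.

ORF calling scans all six frames for start-to-stop runs of at least 33
codons under genetic code 11, ATG starts by default (GTG/TTG can be added).
Overlapping and nested ORFs are all reported. This deliberately simple
caller replaces whatever gene caller fed the original protein comparisons —
that step is conventionally unstated — so absolute AAI values carry a
method caveat, while AAI *differences* across pairs, which drive every
conclusion here, are insensitive to the caller.

Putative orthologs are reciprocal best hits under BLOSUM62 local alignment
(gap cost 10 + L), thresholded at 30% identity and 70% coverage of the
shorter protein; score ties resolve by identity and then lexicographic ORF
id, making the pairing deterministic and symmetric. AAI is the mean RBH
identity × 100, undefined with zero pairs.

## Viral clusters and host range

Clustering is greedy and representative-based: sequences in decreasing
length order (ties lexicographic) join the first cluster whose
*representative* they match at 90% identity and 80% coverage, else found a
new cluster. This reproduces the incremental semantics of cd-hit-like tools,
is O(n·k), and makes membership evidence verifiable — every member's stored
identity/coverage against its representative is re-checked in the test
suite. A bottom-64 minhash sketch over complexity-filtered 11-mers acts as a
candidate filter (pairs sharing fewer than 3 sketch values are not aligned);
near-threshold pairs share tens of values, so the filter only removes
hopeless work.

A cluster's *host range rank* is `same-genus` when all member hosts share
the genus, otherwise the highest rank at which the member lineages differ:
different genera in one family → `genus`, different families in one order →
`family`, …, different phyla → `phylum`. The headline narrow-host-range
fraction is reported over clusters; the fraction over clustered prophages is
emitted alongside, because the two denominators are both defensible readings
and differ when large clusters are the multi-host ones.

## The AAI network

All-vs-all AAI over the dereplicated set (cluster representatives — the
convention for protein-level relatedness after nucleotide dereplication; an
all-members mode exists) gives a network with edges at AAI ≥ 80, the
conventional genus-level relatedness cut for phages. Per rank, the fraction
of edges whose endpoint hosts differ at that rank is reported; under nested
taxonomy these fractions are non-increasing from genus to phylum, a theorem
the property suite asserts on every generated network. The fraction is
edge-based by default; a node-based variant (prophages with at least one
cross-rank edge) can be derived from the exported edge list, and the
edge/node ambiguity is documented rather than silently resolved.
Shared-ortholog counts per edge support the gene-pool interpretation of
sparse cross-phylum connections.

The ANI-vs-AAI co-structure analysis clusters hosts by fragment-ANI
dissimilarity and their prophages by AAI dissimilarity (average linkage,
configurable cut heights, defaults 0.05 and 0.2 — 95% ANI and 80% AAI) and
scores congruence as the fraction of prophage pairs whose AAI comembership
matches their hosts' ANI comembership. The congruence score itself is
package plumbing that turns a visual heat-map comparison into a number a
test can assert; its chance level is estimated by permuting the
prophage-to-host assignment.

## K-mer usage bias

For word sizes 2–4, the bias of a word is its observed frequency over all
overlapping single-strand windows divided by an expectation composed from
sub-word frequencies of the same sequence. The default expectation is the
maximal-order Markov form — product of the two (k−1)-mer frequencies over
the interior (k−2)-mer frequency — the standard contrast-word statistic.
The literal product of all (k−1)-mer frequencies is kept as an option
because the verbal description of such normalizations is genuinely ambiguous
between the two; at k = 2 they coincide exactly, and the di- plus
tri-nucleotide profiles driving the host-association use are barely affected
by the choice. At k = 1 no sub-word expectation exists and the profile
stores raw frequencies. Words with zero expectation are reported `NA`,
never dropped silently; profile distances are Euclidean over the shared
finite log-bias entries. Counting is single-strand by default (prophages
are profiled in their reported orientation) with a both-strand option that
makes profiles reverse-complement invariant.

On a 100 kb i.i.d. sequence the bias is flat by construction; the binomial
standard deviation of the log-bias ratio is about 0.0095 at k = 2, 0.019 at
k = 3 and 0.038 at k = 4, so a flat ±0.05 band is a comfortable assertion at
k = 2 but not over 256 words at k = 4 — the calibration tests therefore use
the analytic standard deviation (4.5σ) for k ≥ 3.

## The synthetic catalog generator

Everything above is exercised on generated data with planted, recoverable
structure; no stage requires downloads. The generator emulates:

* a nested taxonomy (phyla → families → genera) with a configurable number
  of genomes per genus;
* log-normal genome sizes clamped to 1–10 Mb (meanlog log 4 Mb, sdlog 0.35);
* negative-binomial per-genome prophage counts, mean 2.45 and dispersion
  1.4 — chosen once so that the implied lysogen fraction (~75%) and
  per-lysogen count spread (CV around 60–80%) resemble large survey
  catalogs — with named genera scalable by a planted fold;
* bimodal prophage lengths: a 0.7/0.3 mixture of N(30 kb, 5 kb²) and
  N(70 kb, 10 kb²), floored at 5 kb;
* Biosample free text with a configurable pathogen fraction, where planted
  pathogen rows always contain a trigger phrase and unassigned rows never
  do, so label recovery is exact by construction;
* prophage sequences drawn from a first-order Markov model mixing the host
  clade's composition (weight `composition_w`, clades get distinct GC and
  dinucleotide structure) with a phage-family composition — the planted
  signal the k-mer module recovers, with recovery power rising in the
  weight (checked at w = 0, 0.4, 0.8);
* divergence-controlled sequence families: an ancestor plus descendants at
  an i.i.d. per-site substitution rate (indels optional, off by default so
  identities are analytically predictable). The family size counts the
  ancestor, which sorts first among equal-length members, so the greedy
  representative is the ancestor and member identities to it are ~(1 − d);
  at d = 0.05 that is 95%, safely above the 90% threshold, whereas
  member-to-member identities (~90.3%) would sit on the threshold edge.

All randomness flows from one master seed through named substreams, so any
component can be regenerated alone, byte-identically.

What the generator does *not* emulate — real gene content, attachment
sites, GC skew, rearrangements, incomplete or contaminated assemblies —
bounds what green tests mean: they certify the statistics and the recovery
machinery, not robustness to the full mess of real catalogs.

## Problem sizes and numerical conventions

The shipped analyses and tests run at desk scale, chosen as the smallest
sizes at which each statistical property is cleanly visible: calibration at
20 genera × 50 genomes × 100 iterations; planted-enrichment recovery at 20
genera × 20 genomes; clustering recovery at 30 kb × 20 sequences; k-mer
calibration at 100 kb. Ties in the count mode and in RBH pairing resolve
deterministically (smallest value; higher identity then lexicographic id).
Zero-lysogen catalogs summarise to `NA` markers rather than errors;
undefined ANI/AAI propagate as `NA` and are excluded, never coerced to 0,
except in the co-structure dissimilarities where a missing similarity is
treated as maximal dissimilarity (documented there).

## Known limitations

Absolute AAI depends on the unstated upstream gene caller; the banded
aligner assumes colinearity; the keyword classifier inherits every bias of
Biosample free text; the bootstrap's calibration statement is conditional on
the eligibility rule (small genera inflate it, which is why they are
excluded); and the greedy clustering, like the tools it mirrors, is
order-dependent in principle — the fixed length-then-id ordering makes it
deterministic, not canonical.
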