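---
title: "Cross-species lncRNA inference: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species lncRNA inference: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntelnc)
```

# The problem

Long non-coding RNAs (lncRNAs) are mRNA-like transcripts longer than 200 nt
with no protein product. Most are expressed at low levels and with high
tissue specificity, so de novo assembly from RNA-seq samples them
stochastically: two closely related species sequenced across similar tissue
panels will each capture a different subset of a largely shared lncRNA
complement. `syntelnc` implements a pipeline that exploits this: it filters
candidate lncRNAs from assembled transcript models, finds genomic regions
where gene order is conserved between two species, and uses global sequence
alignment to look for the missing member of each cross-species pair inside
the corresponding conserved intergenic interval. Around that core it
provides the expression-side characterisation used to show that inferred
lncRNAs are real: tissue-specificity statistics, co-expression clustering,
and randomisation tests for enhancer-like lncRNA/mRNA proximity.

Everything is validated on synthetic genomes and expression matrices with
known ground truth; the package makes no claim to reproduce any particular
species' catalogue.

# Candidate filtering

`build_longlist()` retains an assembled gene model when all of the following
hold, and otherwise records the first failing rule as the exclusion reason
(order: `too_short`, `single_exon_too_short`, `overlaps_coding`,
`multi_transcript`, `previously_coding`):

* summed exon length over 200 bp for multi-exon models, at least 500 bp for
  mono-exon models. The stricter mono-exon bound exists because a single
  read pair can otherwise satisfy the 200 bp bound. Length is transcript
  length, not genomic span: the lncRNA definition is about the transcript.
  The 500 bp boundary is treated as non-strict ("a threshold of 500 bp");
  both thresholds are arguments.
* no overlap of more than 1 bp, on the same strand, with any protein-coding
  or pseudogene span. Mono-exonic models assembled from unspliced alignments
  carry unknown strand (`"*"`); these are screened against both strands,
  the conservative choice (fewer false lncRNAs).
* exactly one transcript model for the gene (multi-transcript loci are more
  often assembly artefacts in this setting).
* not on an explicit exclusion list of ids previously classified as
  protein-coding. This is an input list rather than a homology search, so
  the provenance of that classification stays outside the package.

`build_shortlist()` then requires three independent non-coding
classifications plus the absence of protein homology: CPC score strictly
below −0.5, a CPAT verdict at the 0.58 probability cut-off, a PLEK label of
`noncoding`, and no blastp or HMMER hit at E ≤ 1e−5. One reading ambiguity
is worth stating: the source convention for CPAT reports a *coding*
probability, so the default here treats values **below** 0.58 as
non-coding; `cpat_higher_is_noncoding = TRUE` honours the opposite reading.
Both the thresholds and the direction are arguments with these defaults.

`find_longest_orf()` supports the homology step: the longest ATG..stop span
(stop included in the extent, ties to the 5'-most start), searched on both
strands for unknown-strand models.

# Positional classification

`classify_lncrnas()` assigns each model exactly one label. Overlap with a
known gene gives `sense`/`antisense` by strand, or `overlap_strand_unknown`
when the model strand is unknown. Otherwise classification is by distance to
the nearest transcription start site (TSS): below 5 kb the model is
upstream or downstream of that gene — upstream meaning 5' of the gene's TSS
in the gene's reading direction — with a `_same`/`_opposite` strand suffix
(unknown-strand models take `_same`; the positional half of the label is
the informative part). At or beyond 5 kb the model is intergenic, binned
into half-open intervals [5,10), [10,20), [20,50), [50,100), [100,500) kb,
[500 kb, 1 Mb), [1 Mb, ∞). Half-openness is a choice the bin edges
themselves do not dictate; it makes the partition total. The TSS set comes
from per-transcript starts when the reference provides transcripts
(Ensembl-style), else from gene starts (NCBI-style); `tss_source`
overrides. Distance is the minimum over both model endpoints, zero if the
TSS falls inside the model span.

# Synteny blocks

`enumerate_triples()` slides a window across each chromosome in gene order
and emits (first upstream gene, focal gene, first downstream gene) for
every focal gene with both neighbours, irrespective of strand. Only
protein-coding genes carrying a symbol participate: symbols are the
cross-species matching key, and a gene without one can neither anchor nor
be matched. Symbol-less genes are *skipped* rather than adjacency-breaking
— the alternative would make the triple set depend on the annotation's
completeness for genes that play no further role; both the biotype set and
the skipping are arguments.

`match_blocks()` intersects the two species' triple sets on the ordered,
upper-cased symbol key. Duplicated keys (tandem paralogue arrays) are
ambiguous and dropped with a warning. By default only identical order
matches; `allow_reversed = TRUE` also accepts the reverse-ordered key
(opposite assembly orientation), flagged in the output. Each block stores
the two intergenic intervals per species in *symbol space* — the upstream
interval lies between the first-symbol gene and the focal gene whatever
their genomic order — so "upstream" means the same thing in both species
and the cross-mapper needs no orientation bookkeeping.

`assign_lncrnas_to_blocks()` places a lncRNA in a block position when its
genomic span is fully contained in the interval (containment fraction 1.0
by default, relaxable). `synteny_report()` counts a "positionally conserved"
lncRNA instance once per (block, position) occupied in both species, and
reports the percentage of blocks with at least one such instance.

# Cross-species mapping

`needleman_wunsch()` is a global aligner with the classic nucleotide
parameterisation of the EMBOSS `needle` tool, pinned explicitly so results
do not depend on an external binary: match +5, mismatch −4, affine gaps
with open 10 and extend 0.5 (a gap of length L costs open + L·extend), and
*unpenalised end gaps*. Free end gaps matter: the query is a transcript of
a few hundred nt and the target an intergenic interval of kilobases, so the
optimum is a fit alignment inside the interval. Traceback is deterministic
(diagonal, then gap-in-target, then gap-in-query), implemented in C++ with
the full dynamic-programming matrix — correctness over speed at these
problem sizes. The test suite checks the scores against exhaustive
enumeration over all alignments for short pairs and against an independent
ends-free implementation for longer ones.

Acceptance is decided by `longest_identity_run()`: the alignment must
contain a run of at least 20 columns that are exact base matches with no
gap in either row. The transcript is effectively used as a CAGE-tag-like
anchor; the chance that a random 20-mer matches inside a pre-specified
interval is ~4^−20 per position pair, so a 20-run is strong evidence of
homology. `N` never matches anything, including `N`, and breaks runs: a
run is evidence of sequence identity, which an ambiguity code cannot
provide.

`map_lncrna_into_interval()` aligns the query against the interval on both
strands (the higher run wins, ties to the plus strand) and, on acceptance,
reports the target extract covered by the alignment after trimming terminal
gap columns, converted to genome coordinates. The extract-boundary rule is
implementation-defined — the alternative of reporting only the span of the
accepted run would systematically truncate diverged orthologues.
`crossmap_lncrnas()` drives this over every one-sided (block, position)
instance: source species occupies it, target does not.

# Expression characterisation

`aggregate_to_genes()` sums member-transcript TPM per sample. Downstream
statistics work on per-tissue replicate means:

* **tau** = Σ(1 − x/max(x)) / (N − 1): 0 for flat (housekeeping) profiles,
  1 for single-tissue expression. Computed on untransformed mean TPM; no
  transformation is prescribed by the definition, and a log option exists
  on the graph side instead.
* **mean/median ratio**: mean TPM over all samples divided by the median of
  per-tissue means, the median floored at 0.01 to avoid division by zero.
* **PEM**: per-tissue means are floored at 1, log2-transformed (S), and
  centred by their across-tissue mean (A); PEM(t) = S_t − A sums to zero
  across tissues by construction. Replicates are collapsed to the tissue
  mean before flooring and transforming.
* **Level bins** on the average TPM over all samples: the printed bin edges
  leave TPM = 10 unassigned, so half-open bins [0,1), [1,10), [10,50),
  [50,∞) are adopted to make the partition total.
* **Categories** (Human-Protein-Atlas style), evaluated in a fixed order:
  `not_detected` (all tissues < 1 TPM), `tissue_specific` (top tissue
  five-fold above all others and all others at 0), `tissue_enriched`
  (five-fold above every other tissue), `group_enriched` (a group of ≥ 2
  tissues, *each* five-fold above *every* out-group tissue — the strictest
  reading of "five-fold higher in a group"; a group-mean variant would be a
  config change), `tissue_enhanced` (five-fold above the mean of tissues
  with detectable expression), `expressed_in_all` (> 1 TPM everywhere),
  else `mixed`.
* **Reproducibility**: either at least one read (est_counts ≥ 1) in every
  replicate of the top-mean-TPM tissue (ties broken lexicographically), or
  TPM > 0.01 in every individual.

# Co-expression network and MCL

`build_coexpression_graph()` correlates per-sample TPM (Pearson, untransformed
by default) and keeps edges with signed r ≥ 0.95 — "below the threshold" is
read on the signed scale, so negative correlations never survive.
`mcl_cluster()` is a standard Markov clustering implementation: edge weights
plus unit self-loops, column normalisation, then alternating expansion
(power 2) and inflation (default 2.2, the granularity knob) with pruning at
1e−5, until the matrix change falls below 1e−6 or 100 iterations. Clusters
are read as connected components of the limit matrix's non-zero pattern.
The self-loop, pruning and convergence settings are implementation-defined
(the published analyses delegate them to a GUI tool); they are exposed as
arguments and the defaults are the ones every test uses. Nodes are
processed in sorted order so clustering is independent of input order.

# Proximity randomisation tests

For a lncRNA co-clustered with y same-chromosome protein-coding genes,
`cluster_distance_test()` compares the observed distance to the nearest
cluster member against s = 1000 random subsets of size y drawn, without
replacement, from all protein-coding genes on that chromosome. Two p-values
are reported deliberately. The published formula, p = (s − q + 1)/(s + 1)
with q the number of subsets whose distance exceeds... is evaluated exactly
as printed (`p_literal`) — note that it approaches 1, not 0, when the
lncRNA is closer than chance, i.e. its direction is inverted relative to
the usual convention. `p_empirical` is the standard add-one permutation
p-value for "observed distance unusually small", with ties counted as
extreme (conservative); it is bounded in [1/(s+1), 1] and is what the
package's own power and calibration checks use. Surfacing both keeps
fidelity to the source without silently "fixing" it.

Per-test RNG streams are derived from the global seed plus the lncRNA id,
so results are reproducible independently of execution order. Distances are
full-span gap distances (0 on overlap or abutment). The companion tests
(`nearest_gene_correlation()`, `correlation_randomization_test()`,
`spearman_distance_correlation()`) follow the same conventions.

# Reconstruction across individuals

With n individuals there are 2^n − 1 non-empty ways to pool their
assemblies; `subset_reproducibility()` enumerates them in canonical binary
order (bit i = individual i in sorted-id order), merges each pool with a
StringTie-merge-like convention (`merge_models()`: identical intron chains
collapse to outermost termini; mono-exon models single-link at ≥ 95%
reciprocal overlap into their union), and asks whether each reference model
is *fully* reconstructed (`is_reconstructed()`): exact intron-chain
identity for multi-exon models, ≥ 95% reciprocal overlap for mono-exon
models — the precise-reconstruction notion is undefined for mono-exon
models in the source convention, so the threshold is explicit and
configurable. Enumeration is refused above n = 16. The merge is
deliberately a simplified re-implementation rather than a call to an
external assembler: determinism and zero external dependencies, with the
convention documented here.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; all generators derive
their RNG streams from `seed` plus a per-generator offset, so outputs are
byte-identical under a fixed seed and adding one generator never reshuffles
another's stream.

`simulate_genome_pair()` builds two genomes sharing gene symbols in
conserved order: per chromosome, genes (1–3 kb, 1–4 exons) alternate with
intergenic gaps (1.5–4 kb), all sequence i.i.d. uniform A/C/G/T and
independent between species except the planted lncRNAs. Each planted lncRNA
(default 500–1500 nt, mono-exonic, unknown strand — the realistic state of
assembled single-exon models; the length floor clears the mono-exon filter
threshold so planted models are clean candidates) occupies one intergenic
gap; its species-B copy is substituted at `divergence_mu` (indels optional,
default 0: substitution-only divergence is the clean recovery regime for a
gapless-run criterion). Capture is an independent Bernoulli per species
(`p_capture`), so one-sided instances arise naturally. Rearrangement is
implemented as segmental translocation with per-boundary cut probability
rate/2: each cut breaks the two gene triples spanning it, so the conserved
triple fraction declines roughly linearly in the rate; rate 1 applies a
perfect shuffle that provably leaves no conserved triple.

`simulate_expression()` emulates a 13-tissue atlas (11 core tissues plus a
macrophage cell type under two conditions, six replicates each) at the
transcript level: housekeeping genes flat across tissues, tissue-specific
genes expressed in exactly one tissue, enhancer-like lncRNA/mRNA pairs
placed within ~200 bp of their partner gene and sharing a per-sample latent
profile (spike in one programme tissue, within-tissue lognormal latent sd
1.2), everything else moderate "mixed" background. Distinct pairs get
distinct partner genes. Multiplicative measurement noise is lognormal with
sd 0.15 (a ~15% replicate CV, typical for moderately expressed genes);
with the latent spread above this keeps planted pairs almost always above
the r ≥ 0.95 edge threshold, which is what makes the planted structure
*recoverable* rather than trivially disconnected. TPM columns are
normalised to 1e6 and est_counts are consistent with tpm × eff_length up
to a per-sample depth scale. One in five coding genes carries two
transcripts so gene-level aggregation is actually exercised.

`simulate_coding_scores()` gives clean candidates scores passing all five
shortlist criteria and planted contaminants one or two violated criteria.
`simulate_library_captures()` drops or truncates transcripts per individual
at `dropout_p` (absent vs truncated with equal probability; truncation
removes a terminal exon or shrinks a mono-exon model to 70%, both of which
defeat the full-reconstruction criterion), recording full presence as
truth.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic base composition, repeats and
paralogy (background is uniform i.i.d., so the false-acceptance rate of
the 20-run criterion on real genomes, with their repeat content, will be
higher than on synthetic ones); indel divergence by default; splice-graph
complexity beyond simple exon chains; read-level noise (no FASTQ, no
coverage model); and annotation errors in the reference species.

# Problem sizes

The validation suite uses deliberately desk-scale conditions, chosen once:
genome pairs of 2–5 chromosomes with 12–60 genes each; 200 planted
orthologue pairs at 5% divergence for the recovery measurement (and the
same pairs against fully randomised targets for the false-acceptance
bound); 10,000 random profiles for the category-rule cross-check; 500 null
lncRNAs at s = 1000 for permutation-test calibration; six individuals (63
pool combinations) for the reconstruction analysis. `run_demo_pipeline()`
chains every stage on one such configuration in well under a minute.

# Known limitations

* Symbol identity is the only orthology notion; paralogue arrays are
  dropped rather than resolved.
* The co-optimal-alignment tie-break can shift run boundaries by a column
  or two between equivalent tracebacks; the acceptance decision is stable
  but the reported run length for *unrelated* sequences can vary between
  mathematically equivalent alignments (the strand-consistency tests
  therefore assert decision-level agreement for random sequences and exact
  agreement for homologous ones).
* MCL on graphs with many singletons reports each as its own cluster;
  composition tables are most informative on the thresholded graph's
  connected part.
* `p_literal` is reported for fidelity but should not be used for
  inference; use `p_empirical`.
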