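---
title: "Methods: GC-skew replication architecture, stable-RNA density, codon bias and 16S phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-skew replication architecture, stable-RNA density, codon bias and 16S phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BacArch)
```

BacArch analyzes the architecture of small circular bacterial genomes — the
kind of replicon where replication starts at a single origin (oriC) and two
replichores are copied in opposite directions to a terminus roughly half way
around the circle. This vignette explains the models behind each analysis,
the tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the underlying literature
leaves the procedure open.

## GC skew and the replication origin

Replication introduces strand-asymmetric mutation pressure: the leading
strand accumulates an excess of G over C. In windows of `window` bases
(default 10,000), anchored every `step` bases (default 200) and wrapping
across the circular junction, `windowedProfile()` reports

* GC fraction, (G+C)/(A+C+G+T), and
* GC skew, (G−C)/(G+C),

where ambiguity codes (N and the other IUPAC letters) are excluded from both
denominators and a window with no G or C gets skew 0 by convention. Window
centers are reported at `start + floor(window/2)`; windows are anchored at
1, 1+step, 2·step+1, … so a circular sequence yields `ceiling(L/step)`
windows. Both sign conventions occur in the literature — (G−C)/(G+C) and its
negation (C−G)/(C+G) — so the convention is an explicit argument, is stored
in every result object, and negating it swaps the predicted origin and
terminus exactly.

`cumulativeSkew()` walks the genome base by base, adding +1 for G and −1 for
C. Under the G−C convention the walk decreases along the replichore ending
at the origin and increases along the other, so its global minimum marks
oriC and its global maximum the terminus; `predictOriTer()` reports exactly
these extrema (ties broken toward the smallest genomic position, for
determinism). When annotations are supplied, the prediction is labelled
"dnaA-supported" if an annotated dnaA gene (gene name `dnaA`, or a product
mentioning the chromosomal replication initiator) starts within 20 kb
(configurable) of the predicted origin — the classical corroboration, since
DnaA and its binding boxes cluster at oriC.

**How precisely can the extremum localize oriC?** The cumulative skew is a
random walk with drift ±δ (the per-base G−C frequency difference) and
per-base variance ≈ the GC fraction σ². The extremum of such a walk is the
maximum-likelihood change point, but its localization error has
characteristic scale σ²/δ² with an exponential tail of rate δ²/(2σ²). At
δ = 0.05 and σ² = 0.35 that scale is ≈140 bases: typical errors are tens to
hundreds of bases, and *no* estimator can guarantee 200-base accuracy with
high probability at these signal strengths. The package therefore treats the
prediction's resolution as the profile window (10 kb): the acceptance-level
checks require the extrema to fall within one window of the planted truth,
and the per-run median errors (tens to a few hundred bases in practice) are
computed and reported by the acceptance script rather than asserted as
guarantees.

Two further numerical caveats. First, on a circular genome the cumulative
walk is only shift-equivariant up to the total G−C imbalance of the whole
sequence: rotating the genome moves the junction, offsets one arc of the
walk by that total, and can therefore move the extremum between nearby
competing minima. Rotation invariance of the prediction is consequently
exact only for a perfectly balanced genome and approximate (within the
localization scale above) otherwise; the tests check it against the planted
truth in both frames. Second, a sequence with no G/C signal at all (e.g.
poly-A) has a flat walk and yields a "no skew signal" error rather than an
arbitrary position.

`rotateToOrigin()` re-bases the circle so a chosen origin becomes base 1
(the convention for deposited genomes). Feature coordinates are remapped
modulo the length; a feature that now spans the junction is stored with
`end > L` and a wrap flag — never with `end < start` — and
`annotationSegments()` splits such features into two in-bounds segments for
interval arithmetic. `strandBias()` then reports, per replichore, the
fraction of CDSs coded on the leading strand (replichore 1 runs origin to
terminus in increasing coordinates; its leading strand is `+`) plus an
exact binomial test of the pooled fraction against 0.5; a CDS belongs to
the replichore containing its start.

## DnaA boxes

`scanIUPAC()` reports every exact match of an IUPAC consensus (degenerate
positions expanded in the pattern; sequence letters matched literally, so an
N in the genome is not a wildcard), on both strands — a minus-strand hit is
the reverse complement of the consensus matched against the forward
sequence, reported at its forward coordinate. Overlapping hits all count,
and circular scans find junction-spanning sites. Matching is delegated to
`Biostrings::matchPattern(fixed = "subject")`; the tests verify it against
an independent regular-expression oracle and against the closed-form
expected hit rate on uniform sequence (2·L·d/4^k for a length-k consensus of
degeneracy d scanned on both strands).

`dnaABoxReport()` specializes the scan to the DnaA box TTATNCACA around the
origin: region (a) is the intergenic stretch upstream of dnaA — from the end
of the nearest upstream feature to the base before dnaA, capped at 1,000
bases (configurable), strand-aware — and region (b) is the stretch strictly
between dnaA and dnaN. "Upstream of dnaA" has no standard formal
definition, so the annotation-driven capped region is the package's choice;
both strands are counted because DnaA binds its box in either orientation.

## rRNA operon density and the survey

`groupRrnaOperons()` chains rRNA genes single-linkage along the circle:
consecutive rRNA features separated by at most `max_gap` bases (default
3,000) form one operon, intervening tRNAs do not break a chain (only
rRNA-to-rRNA gaps are inspected), and a chain split across the junction is
merged into one wrapped operon. There is no universal operon-calling rule;
the 3 kb default comfortably exceeds the internal 16S–23S and 23S–5S spacers
(which often carry tRNAs) while staying far below inter-operon distances,
and it is exposed as a parameter. Increasing `max_gap` can only merge
chains, so the operon count is monotonically non-increasing in it.

`rrnDensity()` is operons per Mbp. `surveyRrnaDensity()` implements the
cross-genome ranking rules: genomes flagged *Candidatus* or not free-living
are dropped first (lifestyle is metadata, not computable from sequence —
hence the TSV input); species represented by several genomes keep only
their highest-density representative; the density threshold (default 2.9
per Mbp) is strict (`>`); ranking is by descending density with ties broken
by genome id. The survey is idempotent by construction.

## Codon usage bias

No single "codon usage bias" statistic is canonical, but the construction
used here is the classical reference-set adaptation index. From a reference
set of genes — by default those whose product matches "ribosomal protein",
the standard proxy for the highly expressed set — pooled codon counts give
each codon a relative adaptiveness w = count / max(count over synonyms), so
every amino acid has at least one codon with w = 1 (its *major* codon).
Codons absent from the reference get a floor (default 0.01) so geometric
means stay positive. A gene's score is the geometric mean of w over its
codons, excluding stop codons and the single-codon amino acids (ATG, TGG
under the bacterial code, table 11), which carry no synonymous information;
a gene built solely of major codons scores exactly 1. Genes whose length is
not a codon multiple or that contain an internal in-frame stop are flagged
invalid and excluded from ranking rather than scored misleadingly. Per-gene
RSCU vectors (observed over expected-uniform synonymous usage) are also
available for inspection. `rankOptimized()` sorts by score (ties by gene
id) and counts user-supplied category labels within the top slice (default
top 80). The tests cross-check the index against the independent seqinr
implementation.

## 16S phylogeny

`pDistanceMatrix()` computes uncorrected p-distances with pairwise deletion:
for each pair, columns where either row has a gap, N or any other ambiguity
are discarded and the distance is the mismatch fraction over what remains
("unknown bases discarded"). An uncorrected distance is the default because
16S similarity matrices in the typing literature are typically uncorrected;
a Jukes–Cantor option (−3/4·log(1 − 4p/3)) is provided. A pair with zero
comparable sites is an error naming the pair.

`neighborJoining()` is the classical agglomerative algorithm: join the pair
minimizing Q(i,j) = (m−2)·d(i,j) − r(i) − r(j), with the standard
branch-length and distance-update formulas. Two deliberate numerical
choices: Q-ties are broken toward the lexicographically smallest joined
taxon-pair label (each cluster is labelled by its smallest leaf name), so
results are deterministic and independent of input order; and a negative
branch length is clamped to zero with the deficit moved to the sister edge,
preserving the path length through the joined pair. On an additive matrix
the output reproduces the input path lengths exactly (tested to 1e−9 on
random 5–8 taxon trees, and cross-checked against ape's independent NJ).

`bootstrapSupport()` resamples alignment columns with replacement, rebuilds
a tree per replicate, and scores each internal bipartition of the main tree
by the percentage of replicate trees containing it (taxa are put in a
canonical order first so supports do not depend on input order). A
replicate that leaves some pair with no comparable sites is skipped and
tallied with a warning; supports are percentages of the replicates that
produced a tree. The conventional "show supports above 50%" rule is a
display choice and deliberately not applied to the stored values. An
alignment of identical rows has no resolvable structure, so supports are
left absent. Trees are ape `phylo` objects throughout; `writeNewick()`
serializes branch lengths and supports (quoting labels that contain Newick
metacharacters), and `readNewick()` wraps the standard ape parser.

## The synthetic-data generator

`simulateGenome()` builds genomes in which every planted quantity is known:

* **Skew.** Background bases are i.i.d. with freq(G) − freq(C) = `skew_delta`
  on the leading strand (P(G) = (gc+δ)/2, P(C) = (gc−δ)/2, A and T equal),
  switching sign at the terminus, placed at `ori + floor(L/2)`. The
  parameterization makes the generator invariant "empirical leading-strand
  G−C difference equals skew_delta" hold by construction on intergenic
  sequence.
* **Genes.** CDSs are packed without overlap at multinomially distributed
  gaps, coded on the leading strand with probability `strand_bias`
  (default 0.8). Codons are drawn from a mixture: with probability
  `codon_bias_strength · expression/max(expression)` the amino acid's major
  codon (a fixed table: the synonym most probable under the skew-free
  genome composition, ties alphabetical), otherwise a synonym weighted by
  the coding strand's base composition. The second component is what gives
  coding regions their realistic, mostly wobble-position, replication
  strand bias — without it a gene-dense genome would dilute the skew signal
  far below what real genomes show, since most of a real genome's skew is
  carried within coding sequence. By default 30% of genes are highly
  expressed (level 1, annotated as ribosomal proteins so the codon-bias
  reference set can find them) and the rest draw expression from U(0, 0.3).
* **Origin region.** A dnaA–dnaN cassette sits at the origin with
  `TTATNCACA` instances planted non-overlapping, on random strands, in the
  500 b upstream region and the 300 b dnaA–dnaN intergap. Background can
  create chance extra matches, so ground truth for box counts is defined by
  rescanning the regions (the tests do this with an independent
  regex-based matcher).
* **Stable RNAs and pseudogenes.** rRNA operons are 16S–23S–5S blocks with
  150 b and 80 b internal spacers (far below the operon-calling gap);
  `pseudogene_fraction` of the CDSs (default 0.106, a realistic
  reductive-evolution load) receive one internal single-base deletion and
  the pseudogene feature type, which also makes them invalid for codon
  statistics — as frameshifted genes should be.

All randomness flows from the mandatory seed; equal arguments give
byte-identical FASTA/GFF3/truth output. What the generator does *not*
emulate: real rRNA/tRNA sequence content (their bodies are background
composition), insertion elements and repeats, operon-internal tRNAs,
plasmids, amelioration gradients, or indels in alignments. Passing tests on
synthetic genomes therefore demonstrate the correctness of the computations
under the stated generative model, not the biological accuracy of any
particular real-genome annotation.

`simulateAlignment()` evolves i.i.d. uniform root sites down a given tree
under Jukes–Cantor (substitution probability 3/4·(1 − e^{−4b/3}) per branch)
with no indels, recording the generating tree and the closed-form expected
pairwise p-distances as truth.

## Pipeline, formats and problem sizes

`runPipeline()` chains the stages over a flat key = value config
(`readPipelineConfig()`/`writePipelineConfig()`), writes a bedGraph skew
track (internal 1-based inclusive coordinates are converted to the format's
0-based half-open intervals), a genome-statistics TSV, the codon-usage
ranking, the ranked survey and the Newick tree, and aggregates everything
in a `summary.json` stamped with a config hash, the package version and the
seed; identical config and seed give byte-identical summaries. Stage
failures abort with the stage named. The pipeline is exposed as R functions
rather than a shell binary: the package's users drive analyses from R, and
`scripts/acceptance.R` shows the scripted entry point.

Input formats: FASTA via Biostrings; GFF3 via rtracklayer; GenBank flat
files via a minimal built-in feature-table parser (LOCUS topology/length,
CDS/rRNA/tRNA keys, `/pseudo`, `/product`, `complement()`, and
`join(a..L,1..b)` wrap locations) — sufficient for single-record bacterial
flat files, not a general GenBank reader. Coordinates are 1-based inclusive
everywhere (GenBank convention); two coding-density variants (interval
union and summed lengths) are reported because the descriptive literature
uses both without always saying which.

The shipped tests run the generator at 30–100 kb with 10–100 genes, 20
seeded genomes for origin recovery, 50 random trees for NJ consistency,
100 bootstrap replicates on quartets, and 0.2–1 Mb of random sequence for
the motif-rate checks — sizes chosen so the whole suite exercises every
stage in well under a minute each on a single core. Known limitations: no
Z-curve or oligomer-skew origin predictors, no PWM motif scoring, no
maximum-likelihood or Bayesian phylogenetics, no multiple-sequence
alignment construction (the phylogeny module consumes pre-aligned FASTA),
and the survey engine deliberately works from metadata tables rather than
re-annotating genomes.
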