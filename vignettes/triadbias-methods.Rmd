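---
title: "Methods: homoeolog expression bias and genome features in phased triploid assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog expression bias and genome features in phased triploid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadbias)
library(dplyr)
```

## The problem

Triploid crops such as Cavendish-type banana carry three homoeologous
copies of most genes, one per haplotype. With a haplotype-resolved assembly
the three copies can be paired into **allele triads** (1:1:1 groups, one
gene per haplotype) and their relative expression asked a simple question:
do the three homoeologs contribute equally to the triad's transcript
output, or is one copy dominant or suppressed? Genome-level summaries of
that question — the fraction of balanced triads per tissue, the selective
pressure on biased versus balanced triads, and the physical distribution of
biased genes — are the core analyses this package implements, together with
the genome-feature characterizations that accompany a phased assembly:
telomere tracts (hence telomere-to-telomere status per chromosome),
centromeric tandem-array candidates, and disease-resistance (NLR) locus
clusters with their genic/intergenic status.

Because the motivating datasets are large and access-controlled, the
package includes a first-class synthetic-data generator that plants every
structure the pipeline consumes — triads with controlled coding divergence,
telomere and centromere tracts, NLR loci, and tissue expression with
controlled bias proportions — and records a truth table, so every stage is
testable end to end with no download.

## Triad construction

Protein-level similarity hits among the three haplotypes (12-column
tabular, the classic `outfmt 6` dialect) are reduced to **reciprocal best
hits** (RBH): per query and target haplotype the best subject is kept
(highest percent identity; ties by bit score, then lexicographic subject
ID), and a pair survives only when each member is the other's best hit. A
triad is a *closed triangle* of RBH pairs; genes joined by a single
surviving link form a 2-gene group; everything else is a singleton. Open
chains (A–B and B–C without A–C) are resolved by discarding the
lower-identity link, never by transitive closure, which would risk merging
paralogous families. The partition is checked on every run to be exhaustive
and disjoint over the gene inventory.

Defaults: minimum identity 60%, minimum query coverage 0.5 (alignment
length / query protein length). These are deliberately permissive — the
haplotypes of a polyploid cultivar can be substantially diverged — and both
are arguments of `best_hits()`. An optional anchoring step
(`anchor_to_reference()`) labels each triad with the reference-assembly
gene that a majority (2 of 3) of its members hit best.

## Expression standardization and the seven bias groups

Counts are converted to TPM per sample
(`TPM_g = (c_g/L_g) / \sum_h (c_h/L_h) \times 10^6`), replicates averaged
per tissue, and a triad is **expressed** when at least one homoeolog
exceeds 0.5 TPM (strict inequality) in at least one tissue; the filter is
applied at triad level so whole triads are kept or dropped. Each expressed
triad's TPM vector is standardized to ternary coordinates

\[
e_{Hk} = \frac{TPM_{Hk}}{TPM_{H1}+TPM_{H2}+TPM_{H3}},
\]

a point on the 2-simplex. The cross-tissue ("combined") profile averages
per-homoeolog TPM across tissues before standardizing; `sum` and `median`
are selectable alternatives (`combine_tissues()`), since the choice of
aggregate is a genuine open question — the mean is the most common
reading of "integrating data across tissues".

Classification is nearest-centroid in the simplex with seven centroids:

| group | centroid |
|---|---|
| balanced | (1/3, 1/3, 1/3) |
| HkD (dominant) | 1 on axis *k*, 0 elsewhere |
| HkS (suppressed) | 0 on axis *k*, 1/2 elsewhere |

Euclidean distance in the embedding 3-space is used; it differs from the
in-plane ternary distance by a constant factor, so the argmin — and hence
every classification — is identical. Ties break in the fixed order
balanced, H1D, H2D, H3D, H1S, H2S, H3S. Every expressed triad is assigned:
no distance cutoff or no-call band is applied, matching an exhaustive
seven-way partition of the ternary diagram. A no-call band would be easy to
add on top of the reported `distance`/`margin` diagnostics, but any
threshold would be arbitrary without a reference definition, so none is
baked in.

The classifier satisfies two properties the tests enforce: scale invariance
(classification depends only on the standardized vector) and equivariance
under the six permutations of haplotype labels.

## Ka/Ks by the Nei–Gojobori method

Selection on homoeolog pairs is quantified with the NG86 counting method,
fully specified and implemented in the package:

* **Sites.** For each sense codon, each of the nine single-nucleotide
  changes is synonymous or not under the standard genetic code; changes to
  stop codons count as nonsynonymous. The synonymous site count of a codon
  is the summed synonymous fraction over its three positions, so
  `n + s = 3` exactly. Alignment totals average the two sequences.
* **Differences.** For a codon pair differing at *k* positions, all *k!*
  single-step pathway orderings are enumerated; steps are classified
  synonymous/nonsynonymous and averaged over pathways that avoid stop
  codons. If every pathway passes through a stop, all steps count as
  nonsynonymous — conventions differ between implementations, so this one
  is stated explicitly. `nd + sd = k` always.
* **Rates.** Jukes–Cantor correction,
  `Ka = -3/4 \log(1 - 4/3\, pN)` and likewise `Ks`. Proportions at or
  above 3/4 are flagged saturated; a pair with `Sd = 0` has an undefined
  ratio rather than an infinite one.

Gapped or ambiguous codon columns are dropped pairwise. A triad is
summarized by the mean of its three pairwise ratios (a designated pairing
is selectable). Group-wise comparison reports per-category distribution
summaries plus a Wilcoxon rank-sum statistic (normal approximation) of
balanced versus pooled non-balanced triads, as a descriptive companion to
the violin/box views — not as a hypothesis-testing pipeline.

The test suite pins this implementation to an independently written
brute-force oracle (explicit permutation matrices, translation through a
different library) on all 61×61 sense-codon pairs and on random codon
alignments, to 1e-9.

## Genome features

**Telomeres.** Chromosome ends are scanned for tracts of the plant
telomere seven-mer: `CCCATTT` from the 5′ end, `TTTAGGG` toward the 3′
end. Exact unit matches at most two corrupted units apart are chained; a
tract must start within `max_offset` (default 10 kb) of its chromosome end
but may extend arbitrarily far inward, must reach `min_copies` (default
100) and unit-level purity ≥ 0.9 (a unit either matches exactly or it does
not; N counts as mismatch). The motivating assemblies report tracts from
~2 kb to ~45 kb, which sit comfortably inside these defaults. A chromosome
with calls at both ends is classified T2T.

**Centromere candidates.** A deliberately simple periodicity scanner
stands in for full tandem-repeat discovery: for each candidate unit length
*u* the sequence is compared with itself at lag *u*, and maximal intervals
with ≥ 80% per-base periodic identity (rolling windows of length *u*)
become candidate arrays; overlaps across unit lengths are resolved greedily
longest-first (ties: smaller unit, leftmost). The longest array per
chromosome is the centromere candidate. This is not a reimplementation of
alignment-scored tandem-repeat finders — the pipeline only needs planted
high-copy arrays found reliably, which the tests verify against the
generator's truth table and against seeded random sequence (no spurious
arrays ≥ 10 kb).

**NLR loci.** Loci arrive as BED intervals from an upstream annotator.
A locus is *genic* when it overlaps any annotated gene span by ≥ 1 bp,
strand-blind, at gene (not CDS) resolution; the largest-overlap gene is
recorded, ties to the lexicographically smaller ID. An optional allowlist
restricts which genes count. Clusters are single-linkage chains with gaps
≤ 200 kb holding ≥ 5 loci, summarised in the conventional
"n genic / n loci" form with Mb-scale locations — intergenic-only clusters
are the signature of pseudogenized resistance-gene arrays.

## The synthetic generator

`sim_config()` fixes the study conditions; `simulate_triploid()` builds
three haploid assemblies; `simulate_expression()` adds tissue counts.
Per chromosome the layout is: 5′ telomere tract, genes, a centromeric
tandem array mid-chromosome, more genes, NLR loci (genic ones inside gene
spans, intergenic ones between genes, plus one tight cluster per
haplotype), and the 3′ telomere tract, with i.i.d. uniform random spacers
filling the remaining length. Planted features never overlap; packing that
exceeds the chromosome length errors naming the budget.

Coding divergence: each triad gets an ancestral CDS and two evolved copies
with target (Ka, Ks) drawn from configured ranges. Substitutions are
placed one per previously untouched codon (never creating stops), so
realized NG86 counts are integers; the realized rates must land within 10%
of target or the generator errors with the realized values. Because a
single substitution moves Ka by ~1/N, small targets need enough codons to
be representable — the default length range (250–450 codons) guarantees
this for the default target ranges (Ka 0.01–0.05, Ks 0.05–0.20, giving
Ka/Ks < 1 throughout: purifying selection). Hit-table identities are exact
protein identities of the simulated sequences, so pairing thresholds act on
true values and triad recovery can be asserted at 100%.

Expression: each triad draws per-tissue relative expression from a
Dirichlet distribution centred on its planted category centroid,
`alpha = concentration * centroid + 0.3` (the floor keeps vertex centroids
proper); `concentration = Inf` plants centroids exactly. Triad abundance is
log-normal (meanlog log 20, sdlog 1, arbitrary TPM-scale units), expected
counts follow from gene length and library size, and Poisson noise is
applied (negative binomial with configurable overdispersion available to
stress the classifier). Default proportions are mostly balanced
(52% balanced, 4% per dominant group, 12% per suppressed group), the
pattern reported for triploid and hexaploid crops; default concentration
100 keeps draws well inside their centroid's cell; default library size
2×10⁶ reads makes counting noise small relative to the biological
dispersion. Four tissues (root, leaf, flower, fruit) are simulated.

What the generator does **not** emulate: realistic repeat landscapes,
intron structure (genes are single-exon), mapping ambiguity between
near-identical homoeologs, isoform variation, and between-replicate
biological variance. Recovery results on synthetic data therefore
demonstrate the correctness of the computations, not robustness to
multi-mapping or annotation error in real data.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed everywhere; BED is converted at the
  boundary (+1 to start) and back exactly.
* Zero-sum triad/tissue TPM vectors are flagged undefined, not dropped
  silently; the classifier refuses them.
* All-zero count samples give all-zero TPM with a warning.
* A gene spanning a window boundary counts once, by span midpoint.
* All randomness flows from explicit integer seeds; the same seed gives
  byte-identical generator output.

## Problem sizes

The shipped defaults (3 chromosomes × 400 kb per haplotype, 300 triads,
4 tissues) were chosen so a full simulate → triads → TPM → bias → Ka/Ks →
features run completes in well under a minute on a single core while
keeping every per-category count large enough for the 3σ multinomial
recovery checks. Classifier-recovery experiments use
`simulate_triad_truth()` (truth table only, no sequence evolution) to reach
1,000 triads in seconds.

## Limitations

* The pairing rule is RBH triangles; synteny is not used, so tandem
  duplicates that out-score the true homoeolog can steal a link (the
  generator does not plant such cases; real data can contain them).
* NG86 with Jukes–Cantor correction is the canonical counting method but
  not a codon-model ML estimate; saturated pairs are flagged, not rescued.
* The centromere scanner reports periodicity, not satellite identity; unit
  phase is not resolved (calls can be offset by up to one unit).
* "NLR genes" counts loci overlapping *any* annotated gene unless an
  allowlist is supplied; with sparse annotations this overestimates
  genic status.
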