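---
title: "Evolutionary linkage scoring of conserved noncoding elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary linkage scoring of conserved noncoding elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnelink)
```

## The problem

Enhancers can regulate genes across hundreds of kilobases. Because a
rearrangement that separates an enhancer from its target is deleterious,
negative selection keeps functional enhancer–gene pairs physically
linked over evolutionary time, while neutral neighbourhoods break apart
at the background rearrangement rate. `cnelink` exploits this signature:
it detects conserved noncoding elements (CNEs) in a multi-species
alignment and scores, for every CNE and every gene in its neighbourhood,
how consistently the two have remained within a bounded genomic distance
across vertebrate genomes. The gene with the strongest maintained
linkage is the predicted regulatory target.

## CNE detection

The scanner consumes MAF alignment blocks, with the reference species
defining the coordinate frame. Exonic and repetitive reference positions
are masked out. A column is **conserved** when

* at least `min_species_beyond_ref` (default 7) non-reference species
  are aligned (non-gap) at it, and
* the number of bases differing from the reference does not exceed
  `ceiling(0.12 * n)`, `n` counting all aligned rows including the
  reference.

The ceiling form is chosen so the minimal 8-row situation tolerates
exactly one substitution: one mismatch among eight rows is 12.5%, which
a strict 12% cut-off would reject, yet one substitution must pass in
that situation. `ceiling(0.12 * 8) = 1` reproduces this while keeping
the threshold proportional for deeper columns.

Elements are seeded by **core windows** of 10 columns containing at
least 90% conserved columns, then extended outward, crossing
non-conserved runs of up to 3 columns and stopping at masked columns or
longer runs; trailing non-conserved columns are trimmed so elements end
on conserved columns. One deliberate refinement: a core window may not
intersect a *barrier* — a masked column, or a non-conserved run longer
than the extension step can cross. Without this rule a window could
swallow the first column of a blocking run, and seeding plus extension
would no longer agree with the closed-form decomposition of a block into
barrier-delimited stretches; with it, the two formulations are provably
identical, which the test suite checks against a brute-force enumerator
on a thousand random inputs.

Elements conserved in the same species subset, adjacent in every shared
genome (no third called element between their orthologous locations)
and separated by less than 100 bp in the reference are fused.
"Consecutive in each genome" is not defined more precisely in the
method's description, so the package uses the weakest testable reading
(no intervening called element, same chromosome); per-species identity
counts are summed during fusion so percent identities of fused elements
remain exact. Scoring happens after fusion.

Each element's **conservation score** summarises alignment depth: the
per-species percent identity (matches over columns where both reference
and species are ungapped, rounded to integers) is reduced to a maximum
within each of five phylogenetic groups — Boreoeutheria, Atlantogenata,
Monotremes/Marsupials, Sauropsids/Amphibians, Teleosts — and the group
maxima are summed. Per-group maxima of 97, 68, 62, 54 and 49 therefore
give 330. Excluding double-gap columns from the identity denominator is
the least biased convention where gap treatment is unspecified, and
integer rounding matches the integer example values the rule is defined
by.

## Linkage scoring

For a CNE *i* aligned in a set of species, candidate targets are the
gene families whose reference gene lies within `d_ref` (default 1 Mb,
closest-edge distance) of the element. In every species *e* the
ortholog of a candidate is classified against the element's orthologous
location:

| status | meaning |
|--------|---------|
| S1 | present within the scaled radius `d_e` |
| S2 | same chromosome, beyond `d_e` |
| S3 | different chromosome or scaffold |
| S0 | not annotated (absent or mis-annotated) |

`d_e = d_ref × genome_size_e / genome_size_ref`, so a genome at 80% of
the reference size is searched within 0.8 Mb. With paralogs the most
favourable status applies — one preserved copy suffices to preserve
regulation. Species flagged as excluded (over-fragmented assemblies) are
skipped entirely.

Two per-species corrections temper the evidence:

* `R_e`, the synteny level: the fraction of adjacent reference gene
  pairs whose orthologs are still direct neighbours in species *e*
  (1 for the reference against itself, 0 for a fully shuffled genome).
* `C_e`, the sequencing-coverage factor in [0,1], down-weighting
  absence evidence from low-coverage assemblies whose annotations
  cannot be trusted (a documented default maps finished or
  high-coverage assemblies to 1.0 and ~2x drafts to 0.5; values are
  supplied in the species metadata).

The raw score sums per-species weights: `+s1·(1 − R_e)` for S1 —
maintained linkage in a highly rearranged genome is strong evidence,
and the reference genome itself (R_e = 1) contributes nothing —
`s2·C_e` for S2, `s3·C_e` for S3 and `s0·C_e` for S0, with defaults
`s1 = 1, s2 = −0.5, s3 = −1, s0 = −0.25`. The method's original
description fixes the ingredients of this score and its worked
behaviours but not closed-form coefficients; the weight scheme is
therefore specified here as a contract
— signs, bounds, and strict monotonicity of the raw score along
S3 → S2 → S1 for `C_e > 0` — with every constant exposed in
`linkage_weights()`, so the exact published coefficients can be dropped
in without code changes. Downstream behaviour (ranking, ties, fusion)
depends only on this monotone structure.

Raw scores of a run are mapped to the **linkage score**
`S_A = 1 / (1 + exp(−k (raw − m)))`, `k = 1` and `m` the run median by
default: strictly monotone, hence rank-preserving, with values in
(0,1). All families attaining the maximal `S_A` are kept as targets
(ties are "multiple targets"); the **relative score** is the gap
between the top and the second *distinct* `S_A`, undefined when no
second distinct value exists. CNEs with identical target sets less than
100 bp apart are fused into regulatory elements.

## Functional overlap and interaction consistency

A signal peak overlapping an element by at least 1 bp contributes its
value weighted by the covered fraction of the element — a 100-bp
element overlapped over 40 bp by a peak of value 12 scores
12 × (40/100) = 4.8 — and peak contributions are additive. A fused
element overlaps a track when any constituent CNE has a positive score.
`enrichment_by_score()` bins elements into equal-count `S_A` quantile
bins (10 by default; equal-count bins stabilise the per-bin
proportions in the absence of canonical bin edges) and reports per-bin
overlap proportions; empty bins are reported as missing, not zero. An
optional stratification supports computing the curve within
conservation-score classes, separating the linkage-score effect from
plain conservation. `fold_change()` compares the extreme non-empty
bins, the simplest summary of a rising curve.

`consistency()` compares the best-scoring targets of elements that
overlap promoter-interaction anchors with the interacting genes
(any-match rule). `permutation_test()` builds the null by re-drawing,
per element and resample, the same number of best-scoring genes
uniformly without replacement from the genes in a 2-Mb window centred
on the element; sampling is without replacement because a gene *set*
is compared. The number of matching genes drawn then follows a
hypergeometric law in (m matching, g window genes, k draws), and the
implementation samples that sufficient statistic directly with
`rhyper`; the marginal law of the consistency indicator is identical to
explicit gene-set sampling, and the suite cross-checks the null against
the analytic probabilities on small cases. Each element owns an RNG
stream derived from (seed, element id), so subsetting or reordering
elements never shifts other elements' draws and results are
bit-reproducible. The empirical bound is `p = (r+1)/(n+1)`; when no
resample reaches the observed count the result is reported as
`p < 1/n`, the usual convention for an empirical bound at its floor.

## The synthetic genome generator

Real chromosome-scale inputs (a 46-way alignment, curated ortholog
families, functional tracks) cannot ship with a package, so
`simulate_bundle()` builds complete toy datasets with known ground
truth. The generator emulates exactly the statistical structure the
scoring assumes:

* an ancestral reference chromosome (default 6 Mb) with 60 genes and
  100 CNEs placed in intergenic space; half the CNEs are enhancers with
  a planted target among their flanking genes;
* descendant genomes per species (20 by default across the five
  phylogenetic groups) derived by inversions, transpositions and
  translocations at `rearrangement_rate` (default 2 operations per Mb);
  reference adjacencies on the chain between an enhancer and its target
  are protected from cuts — the negative-selection premise — except in
  a 5% violation fraction of species per pair;
* enhancers co-located in one intergenic region share one target side.
  Independently chosen sides would create crossing protected chains
  that weld both flanking genes to the region in every species, making
  the planted label unidentifiable even in principle; the shared-side
  rule is also the natural genome-regulatory-block structure, where
  co-located enhancers serve one gene;
* genome sizes scaled by a per-species factor (0.7–1.05), with gaps and
  locus lengths both scaled so distances shrink exactly the way the
  linkage radius does;
* coverage-dependent annotation dropout
  (`0.02 + 0.3 × (1 − C_e)` per gene), with a quarter of species
  emulating 2x drafts (`C_e = 0.5`);
* one alignment block per CNE: i.i.d. per-column substitutions at
  group-specific identities (defaults 96/92/90/87/83% from
  Boreoeutheria to Teleosts), low uniform gap rates, poorly conserved
  25-bp flanks, ~8% per-species alignment dropout, and negative-strand
  rows for loci inverted an odd number of times;
* signal peaks planted on 85% of true enhancers versus 5% of other
  CNEs, and promoter-interaction pairs for 70% of enhancers (90% of
  them naming the true target).

`audit_bundle()` re-reads every emitted file through the package
readers and re-derives the ground-truth summaries (round-trip identity,
family counts, planted adjacency fractions against `synteny_level()`,
peak labels against `weighted_overlap()`, protected linkage within the
scaled radius), failing loudly on any mismatch.

What the generator does **not** emulate: realistic indel processes
(columns, not evolutionary realism, are what the scanner consumes),
duplication-driven paralogy, chromatin-domain structure, or
non-uniform breakpoint landscapes. Passing the recovery tests therefore
shows that the scoring machinery identifies planted linkage under the
model's own assumptions — not that those assumptions hold for any real
chromosome.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; MAF and
  BED-family formats already use them, and 1-based converters are
  exercised both ways in the tests.
* Negative-strand alignment rows keep native coordinates but all
  per-species locations are exposed on the forward strand; conservation
  is evaluated in reference column space, so strand never affects the
  scanner.
* Elements are confined to single alignment blocks — multiZ blocks are
  syntenic units and stitching rules across blocks are unspecified.
* The global "minimal length and identity" post-filters of the original
  scanner are not numerically stated anywhere; they are left off by
  default (the core/extension rules are the operative definition).
* Distance between an element and a gene is the closest-edge gap, 0
  when overlapping; radius comparisons use strict `<`.
* Whether the reference gene-pair count `H` is chromosome-wide or
  genome-wide is unspecified; the package counts adjacent pairs within
  each chromosome of the supplied reference set, summed over
  chromosomes.
* Ties at the maximal `S_A` are kept (multiple targets); the relative
  score uses distinct score values, so a two-way tie has no relative
  score rather than zero.
* The test suite runs the generator at reduced sizes chosen for a
  laptop-class budget: 20-gene/24-CNE bundles for module tests, the
  default 60-gene/100-CNE bundle for end-to-end recovery, 600-element
  scenes with 2,000 resampling draws for the permutation-null
  calibration, and a thousand random ≤1-kb alignments for
  scanner-vs-brute-force equivalence.

## Known limitations

* The weight coefficients and sigmoid constants are specified as
  contracts (signs, bounds, monotonicity) rather than canonical
  numbers; alternative coefficient sets can be injected via
  `linkage_weights()` and `normalize_scores()` arguments.
* The permutation p-value is the standard tie-inclusive
  `(r+1)/(n+1)` bound and is therefore slightly conservative for the
  integer-valued consistency count.
* The scanner is a faithful desk-scale implementation, not a
  whole-genome-optimised one; blocks are processed independently and
  in memory.
* Probabilistic conservation models (phastCons/SiPhy-style) are out of
  scope; externally derived element sets can be merged through
  `merge_external()`, which unions intervals and flags elements lacking
  species data.
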