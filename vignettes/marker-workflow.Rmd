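---
title: "Evaluating a protein-coding barcode and analysing amplicon communities with glompipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a protein-coding barcode and analysing amplicon communities with glompipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glompipe)
```

## The problem

Community surveys of arbuscular mycorrhizal fungi (AMF, phylum
*Glomeromycota*) have traditionally relied on nuclear ribosomal markers,
which are polymorphic *within* a single fungal organism and therefore
blur the line between intra-organism variants and genuine taxa. A
single-copy protein-coding marker such as RPB1 (the largest subunit of
RNA polymerase II) avoids this: it is monomorphic within an isolate,
shows a usable barcode gap between species, and — being protein-coding —
lets homopolymer sequencing errors be repaired against the reading
frame.

`glompipe` implements the full computational side of such a study:

1. **Marker evaluation** — Kimura two-parameter (K2P) distances,
   sliding-window variability and diagnostic-nucleotide profiles,
   barcode-gap analysis, and derivation of the OTU clustering threshold
   from the gap.
2. **Read processing** — demultiplexing, length/ambiguity filtering, a
   60% reference-alignment screen, greedy preclustering at 99.7%
   identity, de novo two-parent chimera detection, and homopolymer
   frame-shift correction validated by stop-codon-free translation.
3. **OTUs and taxonomy** — greedy OTU picking at the derived K2P
   threshold (default 0.8%), taxonomy assignment by three independent
   methods with a consensus rule, and aggregation of OTUs into
   species-level molecular taxa (MTs).
4. **Community statistics** — rarefaction to equal depth, unweighted and
   weighted UniFrac on an OTU tree, PCoA, and ANOSIM permutation tests.
5. **A synthetic-data generator** with per-read ground truth, so each of
   the stages above can be validated quantitatively without access to
   the original sequencing run.

## Distances and the barcode gap

All distances are K2P:
`d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`, with `P` and `Q` the
transition and transversion proportions over comparable sites. Columns
where either sequence carries a gap, an `N`, or no coverage are excluded
*pairwise*; reference sets mix fragment lengths, and complete deletion
would discard most of the alignment. Whether the original analyses used
pairwise or complete deletion is not documented; we fix pairwise and
state it here. Where the logarithm's argument is non-positive (saturated
pairs) the distance is *undefined*: it is reported as `NA`, never as
infinity, and all downstream minima/maxima skip it.

The barcode gap of a sequence is its minimum K2P distance to
heterospecifics minus its maximum distance to conspecifics (zero for
species represented by a single sequence). The OTU threshold is one
resolution step (0.1 K2P percentage points, mirroring the
0.9% → 0.8% step in the source study) below the floored minimum gap
over non-excluded records; an unresolved species complex (the
*Gigaspora* situation, gap 0.1–0.2%) is excluded explicitly, and the
derivation refuses to produce a threshold when no usable gap remains.
If the derived threshold falls below the maximum intraspecific distance,
a warning object travels with the result — clustering at that threshold
will split species into several OTUs, which is exactly what produced the
105-OTU / 20-MT discrepancy in the field data.

Sliding-window profiles use a 50 bp window at step 1 (the sources state
only the window size; step 1 gives maximal resolution). Within a
window, a pair with fewer than 10 comparable columns is treated as
undefined. A column is *diagnostic* for a species if all its members
share one unambiguous base there and no non-member carries that base.

## The read-processing cascade

The stage order is fixed: demultiplex → length/ambiguity filter →
alignment screen → precluster → chimera detection → frame correction.
Every stage reports reads in/out, and the funnel can only shrink.

* **Demultiplexing** allows one barcode mismatch; the barcode design
  (9 bp, every pair ≥ 4 mismatches apart) makes the nearest barcode
  unique at that radius.
* **Length filter**: the 200 bp cutoff applies to the *raw* read
  including barcode, primer and adapter — this is how the printed
  sequence accounting is phrased — with a flag to use the trimmed length
  instead. Any ambiguous base removes a read.
* **Alignment screen**: each distinct sequence is matched to its best
  reference by shared 8-mers and globally aligned to it (free end gaps
  on the reference side, via `Biostrings::pairwiseAlignment`); identity
  is matches over aligned read columns, cutoff 60%. Kept reads are
  projected into reference-alignment coordinates, which turns every
  later comparison into a column operation.
* **Preclustering** is greedy, abundance-sorted centroid clustering at
  99.7% identity (ties: longer sequence, then smaller id). Centroids
  *extend* their column coverage with the reads that join them, so an
  abundant centroid quickly spans the whole amplicon even though
  individual reads are partial. Without this, chimera detection cannot
  model queries longer than a centroid's seed read.
* **Chimera detection** scans centroids in ascending abundance for
  two-parent single-crossover models built from centroids at least 2×
  more abundant. A centroid is flagged when the best model reaches 99%
  identity, beats the best single parent by ≥ 1 percentage point, and
  both parents contribute ≥ 30 positions. This is a deliberate
  simplification of de novo chimera scoring; the thresholds are exposed
  in the configuration.
* **Frame correction** compares each centroid with its best reference
  inside annotated exon regions only. Where a reference homopolymer run
  of length ≥ 3 differs by exactly one base in the read, the base is
  re-inserted or removed; intron columns are never edited, and
  multi-base or non-homopolymer discrepancies are not repaired —
  conservative, matching the dominant error mode of pyrosequencing.
  After correction the exon translation is computed in the annotated
  frame; centroids with remaining frame shifts or in-frame stop codons
  are discarded.

## Taxonomy and molecular taxa

OTUs are picked by the same greedy centroid algorithm at K2P distance
0.008 (the derived threshold). Three assignment methods then run per
OTU representative:

* a naive-Bayes classifier over 8-mer presence with bootstrap
  confidence (100 subsamples of 1/8 of the query k-mers; lineage
  truncated at the deepest rank with ≥ 80% support). Queries sharing
  almost no k-mers with the references abstain rather than letting the
  priors pick a winner;
* parsimony placement on the reference tree: the query is attached to
  every edge in turn and scored by Fitch parsimony; the assignment is
  the shared lineage of the smallest labelled clade containing the
  winning edge. Parsimony cannot distinguish attachments around the
  root (they are unrooted-equivalent), so ties break towards the clade
  whose sequences are closest to the query. This is a deterministic
  surrogate for likelihood-based evolutionary placement;
* bootstrapped neighbour joining on K2P distances (100 column
  resamples by default, scaled down from the original 1000 for
  runtime): the first enclosing clade with ≥ 70% support provides the
  assignment.

The consensus prefers the tree-based methods: when placement and NJ
agree (one lineage a prefix of the other), the deeper tree lineage may
refine the classifier; when they disagree, placement outranks NJ; when
the classifier *contradicts* the preferred tree lineage, the result is
truncated to the deepest rank on which the non-overruled assignments
agree. "Compatible" always means prefix-of-lineage, and empty
assignments are ignored rather than vetoing. One consequence we accept:
when placement overrules NJ, the consensus can contradict NJ at the
ranks where they disagreed — the alternative (always falling back to the
common sublevel) would make the placement preference meaningless.

The final check removes singleton OTUs, OTUs flagged by an OTU-level
chimera re-scan (the re-scan is more reliable than the centroid-level
scan because its candidate set no longer contains error variants that
inflate the best single-parent identity), and OTUs whose consensus
phylum is not the target phylum. Surviving OTUs merge into molecular
taxa by their deepest named lineage; an OTU resolved only to genus or
family becomes a "`<taxon> sp.`" MT, and an alias table can merge
sibling species indistinguishable on short fragments into a single MT.

Reported primer specificity is computed at read level: the share of
length-passing reads whose best screening reference belongs to a
non-target phylum (singleton off-target reads never reach OTU-level
taxonomy, so OTU-level accounting alone would undercount).

## Community statistics

Samples (one per field plot, matching the pooling design) are rarefied
to 1400 reads; rarefaction is plain subsampling without replacement,
deterministic given a seed, and samples below the depth are dropped with
a warning. UniFrac distances are computed on a neighbour-joining K2P
tree of the OTU representatives (the method used for the original OTU
tree is not documented; NJ on the analysis metric is the natural
choice). The weighted variant defaults to the normalized form so values
stay in [0, 1]; both raw and normalized are available because the
original normalization choice is unstated. PCoA is classical scaling;
negative eigenvalues are reported, never dropped. ANOSIM uses mid-ranks
and 2000 permutations, with the permutation seed a required argument;
the grouped contrast (disturbed treatments versus no-tillage) is
computed alongside the three-way test.

## What the generator emulates — and what it does not

`sim_config()` defines the study conditions: 8 target species with 2
isolates each, a 677-column marker (three exons totalling 507 coding
bases, two introns evolving 4× faster, invariant 20 bp primer sites at
the ends), mean between-species exon divergence 8% with a floor of 25%
of that target on the closest species pair, within-species divergence
1.5% (the field data showed up to 2.1% within one species complex, with
isolate-level divergence much lower), triangular read lengths
(145, 254, 515) bp matching the printed minimum/mean/maximum, three
treatments × four plots at 1800 reads per plot (yielding post-filter
depths in the printed 1425–2770 range), 5% single-crossover chimeras
formed between two earlier reads of the same sample, 0.1% substitution
errors, ambiguous bases at 1e-4, homopolymer indels at
`0.002 × (run length − 1)` per run (capped at 0.5; indels only arise in
runs of length ≥ 2 and change the run by exactly one base), and 0.06%
off-target reads from a deeply divergent outgroup — the non-target share
the primers showed in the field. The sequencing-error rates are not
printed in the source study; they are this package's choices, set to
the error structure typical of the platform, and are configurable.
Community compositions are Dirichlet-multinomial: each treatment has a
mean composition (the default rotates a common abundance profile so each
treatment has different dominants) and each plot draws around it with
concentration 40.

Deliberately *not* modelled: flowgram-level sequencer behaviour, PCR
cycle dynamics, indels outside homopolymers, chimeras with more than one
crossover, and intragenomic marker variation (the marker is single-copy
by premise). Passing tests on synthetic data therefore show that the
pipeline's logic recovers a known truth under the stated error model —
not that the error model captures everything a real run produces.

## Numerical choices and known limitations

* Threshold derivation guards against floating-point flooring
  (`floor(x/res + 1e-9)`).
* Greedy clustering ties are broken by abundance, then covered length,
  then id, making every stage deterministic; re-running with the same
  seed is byte-identical.
* NJ assignment replaces rare undefined distances by 1.2× the largest
  defined one so the tree can be built; queries with *all* distances
  undefined are unassigned.
* **Chimera recall is bounded by the margin rule.** Flagging requires
  the two-parent model to beat the best single parent by one percentage
  point of identity, i.e. about `0.01 × L` mismatches on the minor side
  of the crossover. For parents a few percent apart this is only
  achievable with mid-read crossovers; with crossover positions uniform
  along the read, the detector's recall on distinct chimeric sequences
  with parents ≥ 2% divergent plateaus around 0.65–0.70 (false-positive
  rate ≈ 0). The escaped chimeras are nearly identical to one parent and
  are almost all absorbed into that parent's OTU and MT, so the
  species-level summary is unaffected; rarely, a recurrent escaped
  chimera forms its own shallow-rank MT. Raising recall further would
  mean relaxing the margin rule, which is kept as specified.
* The classifier is trained on the supplied reference set only; taxa
  without references can at best be assigned to an enclosing clade by
  the tree methods, exactly as in the original study's family-level
  molecular taxa.

## Problem sizes

The validation suite runs the full default study (21,600 reads, 12
samples) once, the ANOSIM null calibration with 200 simulations × 2000
permutations, and smaller per-module scenarios (4 species, a few hundred
reads) chosen so the complete suite finishes in a few minutes on one
core. The same sizes are used by `scripts/acceptance.R`.
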