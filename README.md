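# glompipe

Barcode-gap evaluation and amplicon community analysis for a single-copy
protein-coding marker gene, built for surveys of arbuscular mycorrhizal
fungi (AMF, phylum *Glomeromycota*) with RPB1-style markers.

Ribosomal markers are polymorphic within a single AMF organism, which
confounds species delimitation in deep-sequencing surveys. A single-copy
protein-coding marker is monomorphic within an isolate, shows a clean
barcode gap between species, and its reading frame lets homopolymer
sequencing errors be repaired. `glompipe` implements the computational
workflow end to end:

* **Marker evaluation** — Kimura two-parameter distances
  (`d = -1/2·ln[(1-2P-Q)·sqrt(1-2Q)]`, pairwise deletion, undefined
  distances reported as `NA`), 50-bp sliding-window variability and
  diagnostic-nucleotide profiles, per-sequence barcode gaps
  (min interspecific − max intraspecific K2P), and derivation of the OTU
  threshold as one 0.1-point step below the floored minimum usable gap
  (a 0.9 % minimum gap yields the 0.8 % threshold).
* **Read processing** — demultiplexing (9-bp barcodes, ≥4 mismatches
  apart, 1 allowed), 200-bp length / ambiguity filter, 60 %
  reference-alignment screen with projection into alignment coordinates,
  greedy 99.7 % preclustering, de novo two-parent chimera detection, and
  homopolymer frame-shift correction validated by stop-free translation.
* **OTUs & taxonomy** — greedy OTU picking at 0.8 % K2P, taxonomy by a
  bootstrapped k-mer naive-Bayes classifier, parsimony placement on a
  reference tree, and bootstrapped neighbour joining, combined by
  consensus rules that prefer the tree methods (placement over NJ) and
  fall back to the deepest agreeing rank; OTUs then merge into
  species-level molecular taxa (MTs).
* **Community statistics** — rarefaction to 1400 reads, unweighted and
  weighted UniFrac on an NJ tree of OTU representatives, PCoA, and
  ANOSIM with 2000 permutations.
* **A synthetic-data generator** that emulates the study design
  (intron/exon marker, faster introns, barcoded primer-anchored reads of
  triangular length, homopolymer indels, single-crossover chimeras,
  treatment × plot Dirichlet-multinomial communities) with per-read
  ground truth, so every stage is testable quantitatively.

## A worked example

Simulate a small four-species study, evaluate the marker, and run the
pipeline:

```r
library(glompipe)

cfg  <- sim_config(n_species = 4, isolates_per_species = 2,
                   reads_per_sample = 400, plots_per_treatment = 2,
                   seed = 11)
rsim <- simulate_reference_set(cfg)
sim  <- simulate_community_reads(cfg, rsim)

eval_marker(rsim$refset)$threshold
#> OTU threshold: 0.012 (min gap 0.0139 )
#> warning: threshold 0.012 is below the maximum intraspecific distance
#> 0.0426; species will be split across OTUs

rep <- run_pipeline(sim$reads, sim$sample_map, rsim$refset, rsim$tree,
                    config = pipeline_config(seed = 11,
                                             rarefy_depth = 300))
rep
#> Pipeline run (seed 11)
#>                stage reads_in reads_out
#>          demultiplex     2400      2400
#>     length_ambiguity     2400      2288
#>     alignment_screen     2288      2288
#>           precluster     2288      2288
#>      chimera_removal     2288      2221
#>     frame_correction     2221      2160
#>  singleton_offtarget     2160      2129
#> reads analysed: 2129; OTUs: 8; MTs: 4
#> specificity: 99.96% (off-target 0.04%)
#> ANOSIM (chisel vs no_tillage vs tillage): R = 0.556, p = 0.1333 (2000 permutations)

rep$state$mts$mts
#>     mt_name    rank n_otus n_reads
#> 1 Species02 species      2     665
#> 2 Species01 species      2     570
#> 3 Species04 species      2     449
#> 4 Species03 species      2     445
```

Reading the output: the derived threshold sits below the simulated
within-species divergence, so each of the four species splits into two
OTUs (one per isolate) — the funnel then shows reads lost to the length
filter, chimera removal and frame correction, and the final check drops
singletons, escaped chimeras and off-target reads (specificity 99.96 %).
MT aggregation recovers exactly the four true species. With only two
plots per treatment the ANOSIM has little power (p = 0.13); the default
design (four plots) detects its treatment effect clearly.

A command-line wrapper over the same stage functions is installed at
`inst/scripts/glompipe`
(`simulate | eval-marker | process-reads | cluster-assign | community |
report | run`).

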