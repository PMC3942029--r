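---
title: "Discovering Mutator-like transposable elements with mulekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Mutator-like transposable elements with mulekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulekit)
```

## The problem

DDE transposases of the Mutator superfamily (MULEs) are among the most
diverse and least conserved mobile-element proteins in prokaryotes: family
members can fall below 25% pairwise identity, so single similarity
searches miss most of the superfamily, and the elements they mobilize range
from 1 kb insertion sequences (ISs) to >50 kb integrative and conjugative
elements (ICEs). mulekit implements the comparative-genomics workflow used
to delineate prokaryotic Mutator-like transposase (p-MULT) families and to
characterize their elements, as a set of composable R functions:

1. **cascade** -- iterative profile-based homolog expansion
   (`run_cascade()`): each round filters hits at E-value <= 0.005 and
   query coverage >= 60%, builds a position-specific profile from the
   retained hits, re-searches, and re-queries from the hit most distant on
   a BLOSUM62 average-distance (UPGMA) tree, for up to seven rounds.
2. **netclust** -- all-against-all Smith-Waterman similarities
   (`all_vs_all_similarity()`), a network keeping edges with E < 1e-4
   weighted `-log10(E)` (`build_network()`), and Markov clustering with
   inflation 1.2 (`mcl_cluster()`) to delineate families.
3. **bounds** -- element boundary calling from multi-copy evidence
   (`annotate_te()`): the transposase CDS with 400 bp flanks is mapped
   genome-wide by a seed-and-extend aligner, boundaries are the modal HSP
   start/end (automatic only with more than three copies), the window
   grows while hits touch its edges, and calls are validated by terminal
   inverted repeat (IR, 18-39 bp, conserved terminal cytosine read into
   the element on each strand), direct repeat (DR, 8 or 9 bp target-site
   duplication) and -1 programmed-frameshift detection.
4. **sitespec** -- insertion-site specificity (`extract_junction_flanks()`,
   `scan_sigma_promoters()`, `positional_enrichment()`): 300 bp junction
   flanks, deduplicated before counting, scanned with paired -35/-10
   weight matrices at spacers 15-19 bp; the per-position ratio of promoter
   detections within 30 bp of the junction, IR-left side negative and
   IR-right side positive.
5. **consmotif** -- windowed alignment conservation in the plotcon style
   (`windowed_conservation()`, windows 15 aa for domain views and 10 aa
   for differential views), DDE-triad anchoring with the C/D(2)H signature
   11-19 aa downstream of D2 (`anchor_triad()`, `scan_cdh_motif()`), and
   differential-conservation signatures between targeting and
   non-targeting family groups (`differential_conservation()`).

Because live searches of public databases are out of scope, a first-class
synthetic-data generator (**synthcom**) produces protein families,
genomes and planted insertions with complete ground truth, so every stage
is tested end to end offline.

## The synthetic model and what it does (not) emulate

`generate_protein_families()` evolves each family from one ancestor by
i.i.d. per-site substitution (uniform among the 19 alternatives); the
catalytic D, D, E residues, the C/D(2)H motif and two N-terminal anchor
blocks (N1, N2 -- stand-ins for the conserved N-terminal and IR-binding
domains) are exempt. Defaults place the triad at 130/200/321 with a
120 aa insert between D2 and E (the observed insert range is 99-138 aa)
and the C/D(2)H motif 14 aa downstream of D2 (observed range 11-19 aa).
There are no indels by default, which keeps truth coordinates valid
without alignment; an indel mode exists (`indel_rate`) but truth mapping
is then only approximate.

`plant_insertions()` writes elements into an i.i.d. background genome
(default GC 0.40, in the spirit of the AT-rich Firmicute hosts). Three
site models mirror the observed specificities:

* `promoter_offset` -- a -35/-10 promoter (consensus TTGACA/TATAAT with
  per-base corruption 0.1, spacer drawn from 15-19 bp) is written into the
  background, and the element lands so that the sampled number of bases
  separates its junction from the -35 box. The default offset
  distribution puts mass 0.25/0.5/0.25 on 15/16/17 bp, matching the
  observed preferential insertion 15-17 bp upstream of the -35 box with a
  characteristic 16 bp mode. Orientation follows `irr_toward_promoter`
  (IR-right faces the promoter) or `unbiased`.
* `at_rich_motif` -- insertion into sites matching an IUPAC motif
  (default `AANATNTT`); the duplicated target is then the DR, so DR length
  equals motif length (8 bp). When the random background contains too few
  motif matches, concrete instances are written in first (reported in the
  documentation as resampled background composition).
* `uniform` -- spaced random sites, random orientation.

Every insertion duplicates its target site, so planted elements are
flanked by identical DRs by construction; insertion sites are kept at
least 400 bp apart so junction flanks are distinct and the identical-
insertion deduplication in `extract_junction_flanks()` can be tested
separately. What the generator does **not** emulate: real promoter
sequence diversity beyond consensus corruption (field scanners are often
HMMs trained on curated sigma-A binding sites; such training alignments
are rarely available, so mulekit ships consensus-seeded weight matrices
and the matrices are user-replaceable), compositional heterogeneity and repeats of
real genomes, passenger-gene content of ICEs, and conjugation machinery.
Passing tests therefore demonstrate correctness of the machinery, not
performance on real genomes.

## Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere in the R API, matching
  GFF3 output directly. Promoter offsets are reported as intervening bp
  between the junction and the -35 box start.
* **Terminal cytosine rule**: each IR's outward terminus is a C read into
  the element on its own strand; equivalently the element's top strand
  starts with C and ends with G. This convention is strand-symmetric,
  which the tests exercise.
* **E-values** use the Karlin-Altschul form `E = K m n exp(-lambda S)`
  with published gapped-BLOSUM62 constants (lambda 0.267, K 0.041) for
  sequence queries; profile-score E-values come from a Gumbel
  (method-of-moments) fit on shuffled decoys, a cheap calibration that is
  adequate for a 0.005 cutoff at desk scale.
* **Profiles** are star alignments onto the query with Henikoff
  position-based weights and a pseudocount blend against a uniform
  background, in half-bit units; no compositional adjustment is applied.
  This is deliberately simpler than full iterative PSSM search and is
  treated as an approximation throughout.
* **MCL** adds self-loops equal to each node's maximum incident weight,
  prunes entries below 1e-5 after each inflation, converges on a maximum
  absolute change below 1e-6, and breaks ties (a node attracted to two
  clusters) toward the lexicographically smallest attractor label, making
  the partition independent of node input order. Edge weights use
  `-log10(E)`; the choice of logarithm base only rescales weights
  monotonically.
* **IR detection** scores candidate pairs +1 per match and -3 per
  mismatch within a 17% mismatch ceiling; the mismatch penalty stops the
  repeat from extending into chance-complementary flanking bases. When a
  detected IR sits a short distance inside the called window, boundaries
  are snapped to the IR termini -- conserved target motifs (e.g. the
  AT-rich 8-mer) otherwise let alignment HSPs creep into the target-site
  duplication.
* **"More than three hits"** is read literally: automatic boundary
  calling needs at least four copies; with fewer the result is flagged
  `insufficient_copies` so related isolates can be brought in.
* **DR matching** is exact by default (a 1-mismatch mode exists but is
  off); with both 8 and 9 bp matching, the longer wins.
* **Conservation profiles** score gap-vs-residue pairs -4 and exclude
  gap-vs-gap pairs from the column average; windows shrink at alignment
  edges rather than truncating the profile. Differential signatures are
  projected onto a shared reference row's residue coordinates before
  subtraction; regions require the difference to exceed `delta_min` for at
  least `run_min = 8` consecutive positions. `delta_min` defaults to 1.0
  matrix unit, calibrated on synthetic truth so that exchangeable groups
  (independent same-rate families) produce no spurious region while a
  planted group-specific block is recovered.
* **-1 frameshift detection** looks for two same-strand ORFs in relative
  frames 0/-1 that overlap or abut such that re-reading one base at some
  codon boundary joins them into a single stop-free product. The reported
  junction is the first compatible slip position; within the ORF overlap
  the exact slip site is inherently ambiguous.
* **Promoter scan threshold** defaults to 14 bits (combined -35 plus -10
  log2 odds), which accepts consensus boxes with about one corrupted base
  pair while keeping background detections rare in AT-rich sequence.

## Problem sizes used in the packaged checks

The bundled tests and the acceptance script run entirely on synthetic
data sized for a laptop: 5 families x 6-10 members of ~400 aa for
clustering and conservation checks; 500 promoter-model insertions in a
400 kb background for the junction-enrichment profile; 50 motif-model
insertions (5 elements x 10 copies) in 200 kb for boundary/DR recovery;
20-node graphs for the clustering cross-check against an independent
reference implementation; and 10 replicates of an 18-protein
transitive-homology chain for cascade sensitivity.

## A worked example

```{r example, eval = FALSE}
library(mulekit)

## five synthetic families -> similarity network -> MCL
fam <- generate_protein_families(
  lapply(1:5, function(i) family_spec(sprintf("fam%d", i), n_members = 6,
                                      substitution_rate = 0.18)),
  seed = 11)
hits <- all_vs_all_similarity(fam$proteins)
net <- mcl_cluster(build_network(hits, nodes = names(fam$proteins)))
table(unname(net$clusters))

## promoter-targeted insertions -> junction enrichment profile
te <- random_te("TEp", tpase_aa_length = 300)
pl <- plant_insertions(400000, te, site_model("promoter_offset"),
                       n_insertions = 500, seed = 7)
flanks <- extract_junction_flanks(pl$truth, pl$genome)
prof <- positional_enrichment(scan_junction_flanks(flanks),
                              n_junctions = nrow(flanks))
prof$peak_position   # 16: bp from the IR-right junction to the -35 box
```

## Known limitations

* The promoter model is a pair of position weight matrices, not a trained
  HMM; absolute detection rates differ from HMM-based scanners even
  though positional enrichment (a ratio) is robust to the threshold.
* The seed-and-extend mapper targets high-identity multi-copy elements;
  it is not a general-purpose aligner and accepts standard 12-column hit
  tables as a drop-in replacement for external mappers.
* Profile search E-values are calibrated per search on a small decoy set;
  they rank hits reliably but are not comparable across databases.
* Secondary-structure prediction, maximum-likelihood phylogenies and
  network rendering are out of scope; graph files (GraphML, edge lists)
  are exported for external tools instead.
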