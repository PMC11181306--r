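---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panplastome)
```

This vignette documents the statistical models, numerical conventions and
design decisions behind `panplastome`. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The problem

A pan-plastome study sequences the complete chloroplast genome of many
accessions of one species, aligns them, and asks: how is the quadripartite
architecture conserved; where and of what kind are the nucleotide variants;
how do accessions partition into maternal haplotypes and genetic clusters;
how differentiated are those clusters; and which loci are informative
enough to serve as intraspecific barcodes. `panplastome` implements that
analysis chain as composable, seeded, testable functions.

## Quadripartite structure detection

Land-plant plastomes are circles of roughly 150–160 kb with two
near-identical inverted repeats (IRa/IRb, ~26 kb) separating a large
(LSC, ~86 kb) and a small (SSC, ~19 kb) single-copy region.
`detect_quadripartite()` finds the longest pair of disjoint inverted
repeats by exact k-mer seeding (k = min(25, `min_ir_len`)) between the
doubled sequence — doubling honors circularity — and its reverse
complement; collinear seeds merge along anti-diagonals into maximal exact
matches. Conventions:

* **Canonical rotation.** Position 0 is the first LSC base; regions are
  reported in the order LSC, IRb, SSC, IRa. The literature fixes no
  coordinate frame; one frame makes outputs comparable.
* **`min_ir_len`** defaults to 1000 bp (real IRs are tens of kb; chance
  inverted matches of this length are essentially impossible). The hard
  floor accepted by the function is 8 bp so that miniature test genomes
  remain analyzable; plastome-scale work should stay at hundreds of bp or
  more.
* **Mismatch tolerance** between the IR copies defaults to 0 (exact);
  `max_mismatch_rate` up to 0.1% merges collinear exact matches across
  isolated differences, since real IR copies can differ by a handful of
  bases. Copy asymmetry is always reported (`ir_mismatches`).
* **Ties** between equally long repeat pairs break toward the smallest
  start coordinate; a best pair that overlaps itself (degenerate,
  palindromic or low-complexity input) is a structural-anomaly error, as
  is an input with no repeat at all.
* **Ambiguity codes** count toward region lengths but are excluded from
  both numerator and denominator of GC content.

`canonicalize_orientation()` enumerates the four quadripartite-preserving
isomers (LSC flipped or not × SSC flipped or not; flipping both equals the
whole-molecule strand flip) and keeps the isomer whose LSC and SSC
maximize positional identity with a reference, preferring fewer flips on
ties. This reproduces the common manual step of re-orienting single-copy
regions for collinearity.

## Variant events and the four-way typology

Variants are called from a gapped multiple alignment, not from reads.
`scan_columns()` classifies each column: *gap* if any row holds `-`;
*substitution* if gap-free with ≥ 2 distinct unambiguous bases;
*invariant* otherwise — columns whose only variation involves N or IUPAC
ambiguity are invariant, mirroring workflows that eliminate missing data.
`call_variant_events()` merges every maximal run of contiguous
non-invariant columns into one event:

| run composition | category |
|---|---|
| one substitution column | SNV |
| ≥ 2 columns, all substitution | block substitution |
| gap columns only | InDel |
| substitution and gap columns | mixed |

The merge rule is the smallest realization of the published category
definitions ("two or more consecutive nucleotide variants"; "two or more
of the preceding three variants at a given site"); events are therefore
disjoint and separated by at least one invariant column. Multi-allelic
columns count as one event (events, not alleles, are tallied).
Events are placed into LSC/SSC/IR by the reference position of their first
column and into CDS/intron/IGS by the genic-context index;
boundary-spanning events keep the first-column label and are flagged.
Because both IR copies are distinct alignment loci, a mutation present in
both copies yields two events; `collapse_ir_events()` optionally merges
mirror-position pairs, since published totals do not state their
convention.

tRNA/rRNA exons fall into the exonic ("CDS") bucket by default so the
three-way genic partition stays comparable; `rna_exon_separate = TRUE`
reports them as a fourth bucket. At overlaps the context priority is
CDS > intron > IGS. For trans-spliced genes only the exons are marked;
the genome-wide gaps between their segments are not introns (marking them
would swallow every gene in between).

## Haplotypes, diversity, distances, Fst

* **Complete deletion** (drop any column with a gap or ambiguity in any
  analyzed sample) precedes haplotype collapsing, Hd and Pi — the DnaSP
  convention; **pairwise deletion** is used for TN93/p distances — the
  MEGA convention.
* **Hd** `= n(1 − Σ p_i²)/(n − 1)`; the tests verify it equals the
  exhaustive unordered-pair mismatch probability on every instance.
* **Pi** is the mean pairwise per-site difference over retained columns,
  computed over all retained sites by default with an `snv_only` switch
  (published methods do not state which was used).
* **TN93** is the closed-form maximum-likelihood distance with base
  frequencies estimated from the pooled pair and separate purine (P1) and
  pyrimidine (P2) transition proportions. A nonpositive logarithm argument
  raises a `tn93_saturation` error; an input pool with only purines or
  only pyrimidines falls back to p-distance with a warning (after the
  saturation check, so all-A-vs-all-G still saturates). One correction to
  the build contract: TN93 collapses to the Jukes–Cantor closed form
  −(3/4)·ln(1 − 4p/3) when pooled frequencies are equal **and
  P1 = P2 = Q/4** — every unordered substitution pair equiprobable — not
  at P1 = P2 = Q/2 as the contract stated; the limit check runs at the
  mathematically correct condition.
* **Fst** is the Hudson-style distance form `1 − Hw/Hb` on SNV columns,
  with `Hw` the mean within-cluster pairwise distance averaged over the two
  clusters and `Hb` the mean between-cluster distance. The source workflow
  names only "Tamura-Nei distances … to calculate Fst", so the estimator
  choice is surfaced in the documentation and output metadata, and exact
  numeric reproduction of published Fst values is not promised. Small
  negative estimates are floored at 0 and flagged; `Hb = 0` yields `NA`.
  Under TN93, saturated pairs fall back to p-distance (warned) so boundary
  cases — e.g. clusters fixed for haplotypes differing at every SNV
  column — stay defined and give exactly 1.
* **PCA** uses indicator encoding (major allele 0, one 0/1 column per
  minor allele, ties for "major" broken alphabetically), column centering,
  and sign-fixing by making each component's largest-magnitude loading
  positive. A `--pcoa`-style reading (classical MDS of the distance
  matrix) was considered and not implemented: on centered indicator
  encodings with Hamming-compatible distances the two coincide up to
  scaling, and one deterministic convention is easier to test.
* **Neighbor joining** wraps the standard agglomeration (`ape::nj`) and
  floors negative branch lengths at 0, transferring the deficit to the
  sister edge so leaf-to-leaf path lengths are preserved where possible.

## Haplotype networks

The minimum spanning network is the union of all minimum spanning trees of
the complete Hamming-distance graph (an edge survives iff it connects two
different components of the strictly-lighter subgraph). Median joining
iterates: build the (epsilon-relaxed) MSN; form the per-column majority
median of every mutually connected node triplet; add the candidate that
most reduces the minimum-spanning cost (ties broken toward the
lexicographically smallest sequence); repeat to fixpoint; finally remove
unsampled medians of MSN-degree < 3, re-linking after each removal.
Majority votes with three distinct states take the state of the
earliest-created node — determinism where the original algorithm allows
arbitrary choice. Characters are unordered states; no
transition/transversion weighting (the default of the network tools in
this field). Epsilon defaults to 0, the PopART default assumption.
Statistical-parsimony (TCS) networks are out of scope.

## Hypervariable windows and diagnostic sites

`sliding_window_diversity()` tiles the reference coordinates (default
window 600 bp, step 200 bp — typical barcode-scanning granularity; the
source names no scheme) and computes per-window Pi under complete deletion
restricted to the window, plus the count of variant events starting in the
window. `clade_diagnostic_sites()` reports a column/state pair as
diagnostic for a cluster set S when the state is carried by every member
of every cluster in S and nobody else; singleton S is preferred at a
column when available. Sites at gap-bearing columns are `InDel` sites.
Locus labels come from the annotation: inside a gene, the gene name;
between genes, `"<leftGene>-<rightGene>"`, wrapping around the circle at
the ends.

## The simulator: a stated world

`sim_config()` defaults describe a desk-scale analogue of a real
pan-plastome panel:

* genome `86,200 + 26,400 + 19,000 + 26,400 = 158,000` bp with exactly
  mirrored IRs; bases flanking the IR boundaries are fixed so the repeat
  match cannot extend by chance, keeping planted and detected partitions
  identical;
* 112 unique genes — 78 protein-coding, 30 tRNA, 4 rRNA; 83 in the LSC,
  13 in the SSC, 16 duplicated across the IRs; 18 genes carry introns, 3
  of them two. (The published per-region listing implies 79 PCGs against
  a stated total of 78; the defaults keep the category totals and assign
  61 PCG + 22 tRNA to the LSC.);
* six genetic clusters of uneven size (6, 12, 10, 4, 4, 12) on a balanced
  binary genealogy; every branch plants 46 SNV, 20 InDel, 2 block
  substitution and 1 mixed event — with 10 branches this is about 690
  events in roughly the published proportions (2/3 SNV, ~29% InDel);
* event positions are drawn region-first (LSC 0.695 / SSC 0.236 /
  IR 0.069) and context-first (IGS 0.559 / CDS 0.323 / intron 0.118),
  emulating the observed concentration of variation in LSC and IGS —
  a uniform draw would instead follow region lengths;
* InDel and block-substitution lengths follow bounded geometric laws
  (p = 0.5, maxima 12 and 8), spacing between events is ≥ 5 columns
  (≥ 3 guarantees exact recoverability), and events keep 2 columns clear
  of region boundaries by default;
* per-sample private SNV counts `(0, 2, 1, 0, 0, 1)` per cluster create
  the uneven haplotype diversity seen between wild-like and
  monomorphic clades.

Indels are deletions from the ancestor only, so alignment columns coincide
with ancestor coordinates and the emitted "true alignment" needs no
aligner; the ancestor is the alignment's first row and its coordinate
reference. IR-planted events are **not** mirrored into the partner copy:
each planted event is one alignment locus, keeping truth bookkeeping
exact (the `collapse_ir_events()` path is exercised by constructed
fixtures instead). One RNG stream keyed by the seed drives all sampling
in documented order; the same seed yields byte-identical outputs.

What a green test does *not* establish: the generator has no coalescent,
recombination, sequencing error, alignment error, insertion-type indels,
or rate heterogeneity; recovery being exact shows the classifier realizes
its definitions on well-separated events, not that a real aligner's output
would be this clean.

## Pipeline and determinism

`run_pipeline()` executes structure → annotation → variants → popgen →
network → markers on either a simulation or user inputs; stages with
missing dependencies are skipped with a logged reason, hard input errors
abort. Reports exclude timestamps and carry a config hash (output
directory excluded) plus the seed, so identical configs re-produce
byte-identical report bodies. Within the pipeline, windows and events for
the marker stage are computed on the sample-only alignment so both share
one coordinate frame.

## Known limitations

* GenBank parsing is a minimal feature-table reader (CDS/tRNA/rRNA keys,
  `join`/`complement` locations, `/gene` qualifiers); GFF3 is the
  first-class annotation path.
* Intron counting for a trans-spliced gene sums exons across its segment
  groups; a gene that is simultaneously trans-spliced *and* IR-duplicated
  would be over-counted.
* The median-joining implementation targets the haplotype-count scale of
  intraspecific panels (tens of haplotypes); it is quadratic-plus in the
  node count and not meant for thousands of sequences.
* Fst is one estimator among several; published values from other
  software are expected to differ in the second decimal or more.
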