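---
title: "Methods: SSR mining, variant calling and NJ phylogeny for fungal mitogenomes"
author: "mitokit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR mining, variant calling and NJ phylogeny for fungal mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokit)
```

This vignette records the models, rules and numerical choices behind
`mitokit`, in the spirit of a methods section: what each stage assumes,
which parameters matter, and where the design was genuinely open.

## The data model

A `mitogenome` is one uppercase DNA string over `A`, `C`, `G`, `T`, `N`
with an id and a circularity flag. All coordinates at package interfaces
are 1-based inclusive. Although the molecules are circular, sequence
indexing never wraps the origin: features or repeats spanning the
assembly junction are rejected rather than silently unwrapped, because
curated annotations of these genomes place no feature across the origin
and silent wrapping would make printed coordinates ambiguous.

A `feature_table` holds `CDS`/`tRNA`/`rRNA` intervals with strand, an
exon count and, optionally, exon sub-intervals. The optionality is
deliberate: published annotation tables for these genomes give each
gene's span and exon count but not exon coordinates, so the package must
work in both regimes (see *Positional classification*). Duplicate gene
names — several `LAGLIDADG endonuclease` and `Hypothetical protein` ORFs
per genome are normal in fungal mitochondria — are disambiguated by an
appended ordinal (`#2`, `#3`, ...).

Protein effects are computed under NCBI translation table 4 (the
mold/protozoan mitochondrial code; notably `TGA` = Trp), the appropriate
code for fungal mitochondria. The code id is a parameter of
`translate_mito()` should another clade be analysed.

One documented inconsistency in the source annotations is carried as-is:
the per-genome overview table reports 16 tRNAs while the gene list
enumerates 12. The package follows the enumerated gene list (12), which
is the only machine-readable form; the discrepancy is surfaced here
rather than resolved.

## SSR detection and the three-tier classification

`find_tandem_repeats()` enumerates **perfect** (exact-copy) tandem
repeats of primitive units of 1–10 bp. For each unit length `u` it
compares the sequence with itself shifted by `u`; maximal runs of
matches of length `L` correspond to repeat tracts with `floor((L+u)/u)`
full copies and a trailing partial of `(L+u) mod u` bases. Records are:

* **maximal** — extendable by no full unit on either side;
* **left-anchored** — `start` is the first base of the first full copy,
  and the unit is reported in the phase observed there (no rotational
  canonicalization: `TA` and `AT` tracts are distinct units, as in
  published catalogs);
* **primitive** — a unit that is itself a repetition of a shorter unit
  is re-expressed by the shorter one (`ATAT × k` becomes `AT × 2k`);
* `N`-free — an ambiguous base terminates any run.

Classification (`classify_ssr()`) implements the three-tier scheme used
for organelle genomes: units of 1–6 bp whose tract reaches
`min_total_length_normal` (default **10 bp**) are *normal*; units of
7–10 bp at ≥ 2 copies are *extended*; 5–6 bp units at exactly 2 copies
are *potential*. The implied minimum copy numbers for normal SSRs are
therefore 10/5/4/3/3/3 for mono→hexa units. The threshold is read as
**inclusive** (≥ 10 bp): catalogs produced under this scheme contain
10 bp records (a mononucleotide run of 10; dinucleotides at 5 copies),
so a strict reading ("exceeds") would contradict the published record
structure. The threshold is configurable.

Overlap policy: accepted records are ranked by total length
(descending), then unit length (ascending), then start; a record whose
span overlaps an already accepted record is suppressed. This subsumes
the suppression of records nested inside an accepted span. The exact tie
rules of the database pipeline the scheme originates from are not
published; greedy longest-first is the simplest deterministic rule
consistent with the published catalogs, and determinism is guaranteed by
the fixed ranking. Catalog ids use per-type prefixes (`M`, `D`, `T`,
`Te`, `P`, `H`, `cHp`, `O`, plus `N`/`De` for nona/deca by extension)
with zero-padded ordinals in start order.

## Positional classification

`classify_interval()` uses any-overlap semantics: an interval is *genic*
if it shares at least one exon base with a top-level feature (tRNA and
rRNA count as genic); *intronic-ORF* if it overlaps a CDS nested inside
another gene's intron (the homing-endonuclease pattern); *intronic* if
it touches only intron bases; *intergenic* otherwise. Precedence is
total — genic > intronic-ORF > intronic > intergenic — so exactly one
class is assigned. The any-overlap rule (rather than containment) is the
behaviour consistent with published catalogs, which attribute a repeat
to a gene it overlaps by a single base.

Nestedness comes from the explicit `nested_in_intron_of` field when
present; otherwise, when exon sub-intervals are available, a feature
whose span lies inside another feature's span without touching its exons
is inferred to be nested. When any multi-exon feature lacks exon detail
the classifier **degrades to a two-class mode** (gene spans act as
exonic; only genic/intergenic can be distinguished) and flags results
`approximate` — this is exactly the regime in which published span-only
tables can be cross-checked.

## Variant calling from strain alignments

`call_variants()` consumes an externally produced whole-genome multiple
sequence alignment (the aligner is out of scope; aligned multi-FASTA is
the contract). Per column the consensus is the **majority residue**,
with gap as a residue and `N` abstaining; ties break toward the
designated reference strain, then alphabetically (`-` before bases).
Majority-as-reference matches the published convention in which an
insertion carried by 2 of 5 strains is reported as the variant.

* A gap-free polymorphic column yields one SNP per distinct minority
  allele (multi-allelic columns emit several events).
* Maximal runs of consecutive columns with the same polarity and carrier
  set merge into one insertion (consensus gapped) or deletion (carriers
  gapped); merging is content-independent, so no two reported events of
  the same type and carriers are adjacent.
* `N` never creates a SNP and never makes a strain an INDEL carrier.

Coverage percentages divide by the aligned length in columns; SNP counts
are event counts while the INDEL numerator is the **column** count
(`indel_column_count()`), the combination under which published coverage
ratios check out arithmetically. Values are kept at full precision and
rounded only by report writers.

Effect annotation maps alignment columns to reference coordinates by
skipping reference gaps, classifies the position, and for CDS SNPs
recomputes the affected codon in transcript orientation under
translation table 4, reporting `X to Y in <gene>` or
`synonymous in <gene>`; other events get `Intergenic` or the overlapped
gene list.

## Supermatrix and neighbor joining

`extract_conserved_pcgs()` splices each requested gene per taxon
(reverse-strand genes are reverse-complemented) after normalizing gene
names: case, punctuation, long descriptive forms
(`NADH dehydrogenase subunit 4 L` → `NAD4L`) and common synonyms
(`CO2` → `COX2`). The default gene set is *ATP8*, *COX2*, *NAD2*,
*NAD3*, *NAD4L* — the conserved five that remain reliably annotated
across the family (one public relative's annotation omits intron-bearing
genes); the source text lists the set inconsistently in two places, so
the list is a runtime parameter with this as the default. A taxon
missing a gene is dropped from that gene's block only, with a warning.

`concatenate_blocks()` column-concatenates externally aligned blocks,
padding absent taxa with gaps and emitting a partition table; slicing a
partition returns the original block, and a PHYLIP + partition-TSV
export supports external ML/Bayesian analyses (deliberately out of
scope here, as is model testing).

`distance_matrix()` offers uncorrected p-distance (default) and JC69
`−(3/4)·ln(1 − 4p/3)`; the distance model behind published NJ trees of
this kind is typically a tool default and unstated, so the simplest
model is the default and both are available. Gap/`N` sites are excluded
pairwise (complete deletion by flag). A pair with zero comparable sites
or `p ≥ 0.75` under JC69 is an error, not an `NA`.

`nj_tree()` is classic agglomerative neighbor joining on the Q
criterion with the Studier–Keppler update, deterministic tie-break by
smallest index, and negative branch lengths clamped to zero. On additive
matrices it provably reproduces the generating tree, which the tests
exercise against independent implementations. `bootstrap_nj()` resamples
columns with replacement under a mandatory seed (defaulting to 1000
replicates, the convention in this literature) and scores each internal
edge by the percentage of replicates containing the same bipartition;
`is_monophyletic()` roots at a stated outgroup before testing.

## The synthetic-data generator

The generator exists so that every stage has a ground-truth oracle
without downloads. Its defaults emulate the study conditions this
package was built around: genomes of tens of kilobases at ~30.7% GC
(i.i.d. bases — no codon structure, gene content or intron architecture,
so passing tests demonstrate algorithmic correctness, not biological
realism); SSR tracts planted between **screened** flanks; five-strain
panels with 2 SNPs, three insertions of 2/10/1 bp and two deletions of
2/3 bp, each carried by a strict minority of strains; Jukes–Cantor
site-independent evolution along a binary tree for supermatrices (no
indels, no rate heterogeneity).

Screening is iterative repair rather than rejection sampling of whole
genomes: a random 55 kb AT-rich sequence inevitably contains dozens of
accidental two-copy penta/hexa repeats, so after planting, the scanner
is run and each accidental record is destroyed by a point mutation
outside the planted spans, repeating until the scan returns exactly the
planted set (budget 100 iterations; an error, never a silent pass, on
non-convergence). Bases flanking each tract are forced off the repeat
phase so planted records stay maximal and left-anchored at their
recorded coordinates. Panels are built directly in alignment space —
events are known, so the true alignment is exact by construction and no
aligner ambiguity enters.

## Problem sizes and reproducibility

The shipped tests run the scanner against a brute-force enumerator on
100 random sequences up to 2 kb, recover 100 random planted panels
exactly, verify NJ on additive matrices up to 8 taxa and on 100
simulated strong-signal supermatrices (400 bp, 10 taxa), and scan a full
55,393 bp synthetic genome carrying a published catalog's unit/copy
profile. These sizes were chosen so the whole suite completes in a few
minutes on one core while still exercising mitogenome scale. Every
stochastic step takes an explicit integer seed; identical seeds give
byte-identical genomes, panels, bootstrap supports and reports.

## Known limitations

* Perfect repeats only: no mismatch-tolerant SSRs, compound-SSR merging
  or primer design.
* Origin-wrapping repeats and features are not scanned.
* The variant caller assumes a trustworthy input alignment; alignment
  errors masquerade as variants.
* NJ only; ML/Bayesian inference is export-only by design.
* The intronic/intronic-ORF classes require exon detail or explicit
  nesting metadata; with span-only annotations the classifier is
  honestly two-class and says so.
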