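# mitokit

Comparative analysis of small organellar genomes in R, built around the
mitochondria of yeast-like fungal endosymbionts (Ophiocordycipitaceae)
carried by planthoppers. These AT-rich molecules (~30% GC, 25–160 kb)
are circular, dense with group-I introns and homing-endonuclease ORFs,
and vary only minutely within a species — which makes three desk-scale
analyses unusually informative:

1. **SSR mining.** Perfect tandem repeats with primitive units of
   1–10 bp are detected and classified under a three-tier scheme used
   for organelle genomes: *normal* SSRs (units 1–6 bp, total length
   ≥ 10 bp, so mono ≥ 10, di ≥ 5, tri ≥ 4, tetra/penta/hexa ≥ 3
   copies), *extended* SSRs (units 7–10 bp, ≥ 2 copies), and
   *potential* SSRs (5–6 bp units at exactly 2 copies).
2. **Positional classification.** Each interval (an SSR, a variant) is
   labelled genic, intronic-ORF, intronic or intergenic against a gene
   feature table, with any-overlap semantics (one shared exon base makes
   it genic) and precedence genic > intronic-ORF > intronic > intergenic.
3. **Intraspecific variant calling.** From a whole-genome multiple
   sequence alignment of strains, SNPs and INDELs are called against the
   per-column majority consensus; maximal gap runs with a common carrier
   set merge into single insertion/deletion events; SNPs inside a CDS are
   re-translated under the mold mitochondrial genetic code
   (transl_table 4, TGA = Trp) to report effects like `L to Q in <gene>`.
   Coverage percentages are counts over the aligned length (columns).
4. **Phylogeny.** Conserved protein-coding genes (default set: *ATP8*,
   *COX2*, *NAD2*, *NAD3*, *NAD4L*) are spliced out per taxon,
   externally aligned blocks are concatenated into a partitioned
   supermatrix, and neighbor-joining trees are built from p or JC69
   distances (`Q(i,j) = (n-2)d(i,j) - r_i - r_j`), with column-resampling
   bootstrap supports and monophyly tests.

A synthetic-data module generates mitogenome-like fixtures with
ground-truth manifests — planted SSRs between screened SSR-free flanks,
strain panels built directly as true alignments, and supermatrices
simulated on known trees — so every stage is testable offline.

## Worked example

```r
library(mitokit)

# a 55.4 kb, 30.7% GC synthetic mitogenome with four planted SSRs
g  <- generate_genome(55393, 0.307, seed = 11, id = "demo")
pl <- plant_ssrs(g, data.frame(unit = c("C", "AT", "AAATAT", "AATTATA"),
                               copy_number = c(11, 7, 3, 2)), seed = 12)
find_ssrs(pl$genome)
#> <ssr_catalog> genome demo: 4 records (3 normal, 1 extended, 0 potential)
#>       ssr_id category ssr_type    unit copy_number start   end genome_id
#> 1 cHp0000001 extended    hepta AATTATA           2  2234  2247      demo
#> 2   D0000001   normal       di      AT           7 17705 17718      demo
#> 3   H0000001   normal     hexa  AAATAT           3 42141 42158      demo
#> 4   M0000001   normal     mono       C          11 53724 53734      demo

# a five-strain panel with the study-like event mix (2 SNP + 3 ins + 2 del)
panel <- derive_strain_panel(g, default_panel_spec(g$length, seed = 13),
                             seed = 14)
ev <- call_variants(panel$alignment, reference = "KR")
ev[, c("vtype", "msa_start", "msa_end", "carriers", "base_changes")]
#>       vtype msa_start msa_end   carriers    base_changes
#> 1       SNP       717     717 KR.5D, WGS          A to G
#> 2 insertion      2693    2693     KR.11D          - to C
#> 3 insertion      5991    6000      KR.5D - to GTGGCTATTC
#> 4       SNP     16142   16142    KR, WGS          A to T
#> 5  deletion     23900   23902      KR.5D        TTT to -
#> 6 insertion     37124   37125     KR.11D         - to CC
#> 7  deletion     50109   50110  KR, KR.1D         AA to -

summarize_variation(panel$alignment)
#> <variation_summary> 5 genomes, 55,406 columns: 2 SNPs (0.004%),
#> 18 INDEL columns (0.03%)
```

The catalog shows each repeat's tier and per-type id (`M`/`D`/`H`/`cHp`
prefixes for mono/di/hexa/hepta units); the variant table gives events in
1-based alignment columns with `consensus to carrier` base-change
strings; the summary divides counts by the aligned length.

Published annotation tables ship as plain-text fixtures under
`inst/extdata/` and can be loaded with `read_feature_table()` and
`read_ssr_tsv()`; for example
`summarize_annotation(read_feature_table(system.file("extdata",
"features_wbph_kr.tsv", package = "mitokit")))` returns 28 CDS, 12 tRNA
and 2 rRNA.

A command-line driver (`inst/scripts/mitokit.R`) wraps the same
functions as subcommands (`ssr-scan`, `ssr-annotate`, `variants`,
`var-summary`, `annotate-summary`, `phylo`, `simulate`), writing TSV
reports plus a JSON run log per output.

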