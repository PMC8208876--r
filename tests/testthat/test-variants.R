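mini_aln <- function(...) {
  rows <- c(...)
  strain_alignment(names(rows), unname(rows))
}

test_that("identical rows yield no variants; constructor validates", {
  aln <- mini_aln(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  expect_equal(nrow(call_variants(aln)), 0L)
  expect_equal(indel_column_count(aln), 0L)
  expect_error(strain_alignment(c("a", "b"), c("ACGT", "ACG")), "ragged")
  expect_error(strain_alignment(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(call_variants(strain_alignment("a", "ACGT")), ">= 2")
})

test_that("gap-free polymorphic columns yield one SNP per minority allele", {
  aln <- mini_aln(r1 = "AAAA", r2 = "ACAA", r3 = "AGAA", r4 = "AAAA")
  ev <- call_variants(aln)
  expect_equal(ev$vtype, c("SNP", "SNP"))
  expect_equal(ev$msa_start, c(2L, 2L))
  expect_setequal(ev$carrier_allele, c("C", "G"))
  expect_equal(unique(ev$consensus_allele), "A")
  expect_setequal(ev$carriers, c("r2", "r3"))
  expect_equal(ev$base_changes[ev$carrier_allele == "C"], "A to C")
})

test_that("consensus ties break toward the reference strain", {
  aln <- mini_aln(x = "AT", y = "AC", z = "GT", w = "GC")
  ev1 <- call_variants(aln, reference = "x")
  # column 1 tied A/G -> consensus A; carriers of G are z, w
  snp1 <- ev1[ev1$msa_start == 1, ]
  expect_equal(snp1$consensus_allele, "A")
  expect_equal(snp1$carriers, "w, z")
  ev2 <- call_variants(aln, reference = "z")
  expect_equal(ev2[ev2$msa_start == 1, "consensus_allele"], "G")
})

test_that("INDEL runs merge maximally by carrier set and polarity", {
  aln <- mini_aln(a = "ACGTACGTACGTAC",
                  b = "AC----GTACGTAC",
                  c = "ACGTACGTACGTAC")
  ev <- call_variants(aln)
  expect_equal(ev$vtype, "deletion")
  expect_equal(c(ev$msa_start, ev$msa_end), c(3L, 6L))
  expect_equal(ev$base_changes, "GTAC to -")

  # insertion: consensus gapped, carrier holds bases
  aln2 <- mini_aln(a = "AC--GT", b = "ACTAGT", c = "AC--GT")
  ev2 <- call_variants(aln2)
  expect_equal(ev2$vtype, "insertion")
  expect_equal(ev2$base_changes, "- to TA")
  expect_equal(ev2$carriers, "b")
  expect_equal(indel_column_count(aln2), 2L)

  # a 10-column single-strain insertion counts 10 columns
  ins <- strrep("T", 10)
  aln3 <- mini_aln(a = paste0("ACGT", strrep("-", 10), "ACGT"),
                   b = paste0("ACGT", ins, "ACGT"),
                   c = paste0("ACGT", strrep("-", 10), "ACGT"))
  expect_equal(indel_column_count(aln3), 10L)
  ev3 <- call_variants(aln3)
  expect_equal(c(ev3$msa_start, ev3$msa_end), c(5L, 14L))

  # adjacent events with different carriers stay separate
  aln4 <- mini_aln(a = "ACGTACGT", b = "AC--ACGT", c = "ACG-ACGT")
  ev4 <- call_variants(aln4)
  expect_equal(nrow(ev4), 2L)
  no_adjacent_same <- function(ev) {
    ind <- ev[ev$vtype != "SNP", ]
    ind <- ind[order(ind$msa_start), ]
    if (nrow(ind) < 2) return(TRUE)
    !any(ind$msa_start[-1] == ind$msa_end[-nrow(ind)] + 1L &
           ind$vtype[-1] == ind$vtype[-nrow(ind)] &
           ind$carriers[-1] == ind$carriers[-nrow(ind)])
  }
  expect_true(no_adjacent_same(ev4))
})

test_that("N is missing data: never a SNP, never an INDEL carrier", {
  aln <- mini_aln(a = "ANGT", b = "AAGT", c = "AAGT")
  expect_equal(nrow(call_variants(aln)), 0L)
  aln2 <- mini_aln(a = "A-GT", b = "ANGT", c = "AAGT", d = "AAGT")
  ev <- call_variants(aln2)
  expect_equal(ev$vtype, "deletion")
  expect_equal(ev$carriers, "a")
})

test_that("calling is invariant under row order and round-trips", {
  set.seed(17)
  for (i in 1:20) {
    g <- generate_genome(1500, 0.3, seed = 100 + i)
    k <- sample(2:8, 1)
    skel <- data.frame(vtype = sample(c("SNP", "insertion", "deletion"),
                                      k, replace = TRUE),
                       length = sample(1:6, k, replace = TRUE))
    skel$length[skel$vtype == "SNP"] <- 1L
    spec <- random_panel_spec(skel, 1500, c("s1", "s2", "s3", "s4", "s5"),
                              seed = 200 + i)
    panel <- derive_strain_panel(g, spec, c("s1", "s2", "s3", "s4", "s5"),
                                 seed = 300 + i)
    ev <- call_variants(panel$alignment)
    # recovery: called events equal the manifest
    cols <- c("vtype", "msa_start", "msa_end", "carriers",
              "consensus_allele", "carrier_allele")
    expect_equal(as.data.frame(ev)[cols],
                 as.data.frame(panel$manifest)[cols],
                 info = paste("panel", i))
    # row-reorder invariance
    perm <- sample(length(panel$alignment$strain_ids))
    aln_p <- strain_alignment(panel$alignment$strain_ids[perm],
                              unname(panel$alignment$rows[perm]))
    ev_p <- call_variants(aln_p, reference = "s1")
    expect_equal(as.data.frame(ev_p)[cols], as.data.frame(ev)[cols])
    # applying events to the consensus reconstructs every row
    expect_identical(apply_variants(panel$alignment, ev),
                     panel$alignment$rows)
  }
})

test_that("variation summaries use aligned-length denominators", {
  s <- variation_summary(3, 157606, 16, 144)
  expect_equal(round(s$snp_coverage_pct, 3), 0.010)
  expect_equal(s$indel_coverage_pct, 100 * 144 / 157606)
  expect_equal(variation_summary(2, 500, 0, 0)$snp_coverage_pct, 0)
  expect_error(variation_summary(2, 0, 0, 0))

  aln <- mini_aln(a = "ACGTACGTAC", b = "ACCTACGTAC", c = "AC-TACGTAC")
  vs <- summarize_variation(aln)
  expect_equal(vs$aligned_length, 10L)
  expect_equal(vs$n_indels, 1L)
  expect_equal(vs$indel_coverage_pct, 10)
})

test_that("SNP effects are annotated via codon recomputation", {
  # reverse-strand CDS whose transcript begins ATG CTA ...; an A->T
  # change at the genomic position pairing with codon position 2
  tx <- paste0("ATGCTATGA")                  # M L *
  pad <- "GGGG"
  gseq <- paste0(pad, mitokit:::revcomp(tx), pad)
  g <- mitogenome("ref", gseq)
  ft <- feature_table("ref", gene_feature("atpF0", "CDS", 5, 13, "reverse"))
  # genomic position of transcript position 5 (codon 2, pos 2):
  # tx pos p maps to genome pos end - p + 1 = 13 - 5 + 1 = 9; transcript
  # T -> A means genomic A -> T
  spec <- data.frame(vtype = "SNP", genome_pos = 9L, length = 1L,
                     alt = "T", ref = NA, stringsAsFactors = FALSE)
  spec$carriers <- list("s2")
  panel <- derive_strain_panel(g, spec, strains = c("ref", "s2", "s3"),
                               seed = 1)
  ev <- call_variants(panel$alignment, reference = "ref")
  ann <- annotate_variants(ev, panel$alignment, ft, g, reference = "ref")
  expect_equal(ann$position_note, "L to Q in atpF0")

  # synonymous third-position change: CTA -> CTT is still Leu; transcript
  # pos 6 -> genome pos 8, transcript A->T means genomic T->A
  spec2 <- data.frame(vtype = "SNP", genome_pos = 8L, length = 1L,
                      alt = "A", ref = NA, stringsAsFactors = FALSE)
  spec2$carriers <- list("s2")
  panel2 <- derive_strain_panel(g, spec2, strains = c("ref", "s2", "s3"),
                                seed = 1)
  ev2 <- call_variants(panel2$alignment, reference = "ref")
  ann2 <- annotate_variants(ev2, panel2$alignment, ft, g, reference = "ref")
  expect_equal(ann2$position_note, "synonymous in atpF0")

  # event outside any feature
  spec3 <- data.frame(vtype = "SNP", genome_pos = 2L, length = 1L,
                      alt = NA, ref = NA, stringsAsFactors = FALSE)
  spec3$carriers <- list("s2")
  panel3 <- derive_strain_panel(g, spec3, strains = c("ref", "s2", "s3"),
                                seed = 3)
  ev3 <- call_variants(panel3$alignment, reference = "ref")
  ann3 <- annotate_variants(ev3, panel3$alignment, ft, g, reference = "ref")
  expect_equal(ann3$position_note, "Intergenic")
})
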