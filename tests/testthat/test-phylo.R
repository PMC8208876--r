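three_genomes <- function(seed = 71) {
  genes <- c("ATP8", "COX2", "NAD2", "NAD3", "NAD4L")
  long_names <- c("ATP synthase F0 subunit 8",
                  "Cytochrome c oxidase subunit II",
                  "NADH dehydrogenase subunit 2",
                  "NADH dehydrogenase subunit 3",
                  "NADH dehydrogenase subunit 4 L")
  gs <- list(); fts <- list()
  set.seed(seed)
  for (tx in c("tax1", "tax2", "tax3")) {
    seqlen <- 4000
    g <- mitogenome(tx, random_dna(seqlen))
    starts <- seq(101, by = 600, length.out = 5)
    rows <- do.call(rbind, lapply(seq_along(genes), function(i)
      gene_feature(long_names[i], "CDS", starts[i], starts[i] + 299,
                   sample(c("forward", "reverse"), 1))))
    gs[[tx]] <- g
    fts[[tx]] <- feature_table(tx, rows)
  }
  list(genomes = gs, features = fts)
}

test_that("conserved-gene extraction splices every gene per taxon", {
  fx <- three_genomes()
  blocks <- extract_conserved_pcgs(fx$genomes, fx$features)
  expect_named(blocks, c("ATP8", "COX2", "NAD2", "NAD3", "NAD4L"))
  expect_true(all(vapply(blocks, length, 0L) == 3L))
  # compositional check against splice_feature, long-name normalization
  ft1 <- fx$features$tax1
  idx <- which(ft1$name == "ATP synthase F0 subunit 8")
  expect_identical(blocks$ATP8[["tax1"]],
                   splice_feature(fx$genomes$tax1, ft1[idx, ]))
  # synonym spelling CO2 resolves to the same gene as COX2
  b2 <- extract_conserved_pcgs(fx$genomes, fx$features, gene_list = "CO2")
  expect_identical(b2$COX2, blocks$COX2)
})

test_that("a taxon missing a gene is dropped from that block only", {
  fx <- three_genomes()
  ft <- fx$features$tax2
  fx$features$tax2 <- feature_table(
    "tax2", as.data.frame(ft[ft$name != "NADH dehydrogenase subunit 3", ]))
  expect_warning(blocks <- extract_conserved_pcgs(fx$genomes, fx$features),
                 "absent in taxon tax2")
  expect_equal(length(blocks$NAD3), 2L)
  expect_equal(length(blocks$ATP8), 3L)
})

test_that("concatenation tiles partitions and pads missing taxa", {
  b1 <- gene_block("g1", c(a = strrep("A", 30), b = strrep("C", 30)))
  b2 <- gene_block("g2", c(a = strrep("G", 60), b = strrep("T", 60),
                           c = strrep("A", 60)))
  sm <- concatenate_blocks(list(b1, b2))
  expect_equal(nchar(sm$rows[["a"]]), 90L)
  expect_equal(sm$partitions$start_col, c(1L, 31L))
  expect_equal(sm$partitions$end_col, c(30L, 90L))
  # taxon c absent from block 1: gap padding
  expect_equal(substr(sm$rows[["c"]], 1, 30), strrep("-", 30))
  # slicing is the inverse of concatenation
  expect_equal(slice_partition(sm, "g1")$rows[c("a", "b")], b1$rows)
  expect_equal(slice_partition(sm, "g2")$rows, b2$rows)
  expect_error(gene_block("bad", c(a = "AC", a = "GT")), "duplicate")
})

test_that("random blocks survive a concatenate/slice round-trip", {
  set.seed(33)
  for (rep in 1:10) {
    nb <- sample(2:4, 1)
    taxa <- paste0("t", 1:sample(3:6, 1))
    blocks <- lapply(seq_len(nb), function(i) {
      w <- sample(10:50, 1)
      keep <- sample(taxa, max(2, sample(length(taxa), 1)))
      gene_block(paste0("g", i),
                 setNames(vapply(keep, function(x) random_dna(w), ""), keep))
    })
    sm <- concatenate_blocks(blocks)
    for (i in seq_len(nb)) {
      back <- slice_partition(sm, paste0("g", i))
      expect_equal(back$rows[blocks[[i]]$taxa], blocks[[i]]$rows)
    }
  }
})

test_that("p and JC69 distances match closed forms and an independent count", {
  rows <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  expect_equal(distance_matrix(rows)["a", "b"], 0)
  rows2 <- rows
  substr(rows2[["b"]], 1, 1) <- "G"
  D <- distance_matrix(rows2)
  expect_equal(D["a", "b"], 0.01)
  DJ <- distance_matrix(rows2, model = "JC69")
  expect_equal(DJ["a", "b"], -0.75 * log(1 - 4 * 0.01 / 3))

  set.seed(13)
  tr6 <- ape::rtree(6)
  tr6$edge.length <- tr6$edge.length * 0.2  # keep p well below saturation
  sim <- simulate_supermatrix(tr6, c(x = 400), seed = 5)
  rows3 <- sim$supermatrix$rows
  D3 <- distance_matrix(rows3)
  expect_true(isSymmetric(D3))
  expect_equal(unname(diag(D3)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D3[i, j], bf_pdist(rows3[[i]], rows3[[j]]))
  # JC69 >= p elementwise
  DJ3 <- distance_matrix(rows3, model = "JC69")
  expect_true(all(DJ3 >= D3 - 1e-12))
  # gaps: pairwise deletion excludes the gapped site for that pair only
  rows4 <- c(a = "ACGTACGTAC", b = "-CGTACGTAC", c = "ACGTACGTAC")
  expect_equal(distance_matrix(rows4)["a", "b"], 0)
  expect_error(distance_matrix(c(a = "----", b = "AAAA")), "comparable")
})

test_that("NJ recovers additive trees exactly", {
  set.seed(55)
  for (n in 4:8) for (rep in 1:5) {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
    D <- stats::cophenetic(tr)
    est <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
    # path lengths reproduce the input distances (additivity)
    expect_equal(stats::cophenetic(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("NJ agrees with an established implementation on noisy data", {
  set.seed(29)
  for (rep in 1:5) {
    tr <- ape::rtree(7)
    sim <- simulate_supermatrix(tr, c(x = 500), seed = 400 + rep)
    D <- distance_matrix(sim$supermatrix)
    expect_equal(as.numeric(ape::dist.topo(nj_tree(D), ape::nj(D))), 0)
  }
})

test_that("two-taxon matrices give a single split of d/2 + d/2", {
  D <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("a", "b"))
  expect_equal(sum(tr$edge.length), 0.3)
})

test_that("bootstrap supports are reproducible and strong under strong signal", {
  tr <- ape::read.tree(
    text = "((((A:.05,B:.05):.3,(C:.05,D:.05):.3):.05,E:.4):.1,OUT:.5);")
  sim <- simulate_supermatrix(tr, c(g = 600), seed = 9)
  b1 <- bootstrap_nj(sim$supermatrix, n_reps = 60, seed = 123)
  b2 <- bootstrap_nj(sim$supermatrix, n_reps = 60, seed = 123)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_true(is_monophyletic(b1, c("A", "B", "C", "D"), "OUT"))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 50))
  expect_error(is_monophyletic(b1, c("A", "B"), "nope"), "not a leaf")
})

test_that("newick and phylip exports round-trip", {
  tr <- ape::unroot(ape::rtree(5))
  tmp <- tempfile(fileext = ".nwk")
  write_newick(tr, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)

  sm <- concatenate_blocks(list(
    gene_block("g1", c(a = "ACGT", b = "ACGA")),
    gene_block("g2", c(a = "TTTT", b = "TTTA"))))
  tmp2 <- tempfile(fileext = ".phy")
  write_phylip(sm, tmp2)
  lines <- readLines(tmp2)
  expect_match(lines[1], "^ 2 8$")
  parts <- read.delim(paste0(tmp2, ".partitions.tsv"))
  expect_equal(parts$end_col, c(4L, 8L))
})
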