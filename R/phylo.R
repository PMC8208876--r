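## gene-name normalization: uppercase, strip punctuation/spaces, map the
## common mitochondrial synonym spellings onto one canonical symbol
normalize_gene_name <- function(x) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", x))
  syn <- c(CO1 = "COX1", COI = "COX1", COXI = "COX1",
           CO2 = "COX2", COII = "COX2", COXII = "COX2",
           CO3 = "COX3", COIII = "COX3", COXIII = "COX3",
           CYTB = "COB", COB = "COB", CYTOCHROMEB = "COB",
           ATP6 = "ATP6", ATP8 = "ATP8", ATP9 = "ATP9")
  long <- function(k) {
    m <- regmatches(k, regexec("^NADHDEHYDROGENASESUBUNIT([0-9]+L?)$", k))[[1]]
    if (length(m)) return(paste0("NAD", m[2]))
    m <- regmatches(k, regexec("^CYTOCHROMECOXIDASESUBUNIT(I{1,3})$", k))[[1]]
    if (length(m)) return(paste0("COX", nchar(m[2])))
    m <- regmatches(k, regexec("^ATPSYNTHASEF0SUBUNIT([0-9]+|[A-C])$", k))[[1]]
    if (length(m)) return(paste0("ATP", toupper(m[2])))
    m <- regmatches(k, regexec("^NAD([0-9]+L?)$", k))[[1]]
    if (length(m)) return(paste0("NAD", m[2]))
    NA_character_
  }
  vapply(key, function(k) {
    if (!is.na(syn[k])) return(unname(syn[k]))
    lg <- long(k)
    if (!is.na(lg)) lg else k
  }, "", USE.NAMES = FALSE)
}

#' Extract conserved protein-coding genes across genomes
#'
#' Pulls the spliced, orientation-corrected nucleotide sequence of each
#' requested gene from each genome. Gene names are matched after
#' normalization (case, punctuation, and common mitochondrial synonyms
#' such as `CO2`/`COX2` or long forms like `NADH dehydrogenase subunit
#' 4 L`). A taxon lacking a gene is dropped from that gene's block with a
#' warning, not from the whole analysis.
#'
#' @param genomes Named list of [mitogenome()] objects (names = taxa).
#' @param feature_tables Named list of [feature_table()]s, same names.
#' @param gene_list Canonical gene symbols to extract; the default is the
#'   conserved five-gene set `ATP8`, `COX2`, `NAD2`, `NAD3`, `NAD4L`.
#' @return Named list (per gene) of named character vectors (per taxon)
#'   of unaligned sequences.
#' @export
extract_conserved_pcgs <- function(genomes, feature_tables,
                                   gene_list = c("ATP8", "COX2", "NAD2",
                                                 "NAD3", "NAD4L")) {
  stopifnot(identical(sort(names(genomes)), sort(names(feature_tables))))
  gene_list <- normalize_gene_name(gene_list)
  out <- stats::setNames(vector("list", length(gene_list)), gene_list)
  for (g in gene_list) {
    seqs <- character(0)
    for (taxon in names(genomes)) {
      ft <- feature_tables[[taxon]]
      hit <- which(normalize_gene_name(ft$name) == g & ft$type == "CDS")
      if (!length(hit)) {
        warning("gene ", g, " absent in taxon ", taxon,
                "; dropped from that block", call. = FALSE)
        next
      }
      seqs[taxon] <- splice_feature(genomes[[taxon]], ft[hit[1L], ])
    }
    out[[g]] <- seqs
  }
  out
}

#' Build a gene alignment block
#'
#' @param gene_name Gene symbol.
#' @param rows Named character vector of equal-length gapped sequences
#'   (taxa as names), i.e. an externally produced alignment.
#' @return A list of class `gene_block` with `gene_name`, `taxa`, `rows`.
#' @export
gene_block <- function(gene_name, rows) {
  if (anyDuplicated(names(rows)))
    stop("duplicate taxon in block ", gene_name)
  if (length(unique(nchar(rows))) > 1L)
    stop("unequal row lengths in block ", gene_name)
  structure(list(gene_name = gene_name, taxa = names(rows),
                 rows = rows), class = "gene_block")
}

#' Concatenate aligned gene blocks into a supermatrix
#'
#' Column-wise concatenation; a taxon absent from a block is padded with
#' gaps over that block's columns. The partition table records each
#' gene's column range.
#'
#' @param blocks List of [gene_block()]s (or named character vectors,
#'   coerced with names as gene names).
#' @return A list of class `supermatrix` with `taxa`, `rows` (named
#'   character vector) and `partitions` (`data.frame` with `gene_name`,
#'   `start_col`, `end_col`).
#' @export
concatenate_blocks <- function(blocks) {
  if (!length(blocks)) stop("no blocks")
  blocks <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "gene_block")) b
    else gene_block(names(blocks)[i] %||% paste0("block", i), b)
  })
  taxa <- unique(unlist(lapply(blocks, `[[`, "taxa")))
  widths <- vapply(blocks, function(b) nchar(b$rows[[1L]]), 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxa, function(tx) {
    paste(vapply(blocks, function(b) {
      if (tx %in% b$taxa) b$rows[[tx]]
      else strrep("-", nchar(b$rows[[1L]]))
    }, ""), collapse = "")
  }, "")
  structure(list(
    taxa = taxa, rows = rows,
    partitions = data.frame(
      gene_name = vapply(blocks, `[[`, "", "gene_name"),
      start_col = starts, end_col = ends, stringsAsFactors = FALSE)),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %s columns, %d partitions\n",
              length(x$taxa), format(nchar(x$rows[[1L]]), big.mark = ","),
              nrow(x$partitions)))
  invisible(x)
}

#' Slice one partition back out of a supermatrix
#'
#' @param sm A [concatenate_blocks()] supermatrix.
#' @param gene_name Partition to extract.
#' @return A [gene_block()] (gap-padded taxa included).
#' @export
slice_partition <- function(sm, gene_name) {
  p <- sm$partitions[sm$partitions$gene_name == gene_name, ]
  if (nrow(p) != 1L) stop("unknown partition: ", gene_name)
  gene_block(gene_name,
             vapply(sm$rows, substr, "", p$start_col, p$end_col))
}

#' Pairwise distances from aligned sequences
#'
#' Computes uncorrected p-distances (proportion of differing sites among
#' pairwise comparable sites) or Jukes-Cantor distances
#' `-(3/4) log(1 - 4p/3)`. Sites with a gap or `N` in either member of a
#' pair are excluded for that pair (pairwise deletion); with
#' `pairwise_deletion = FALSE` any column containing a gap/`N` in any
#' taxon is excluded for all pairs (complete deletion).
#'
#' @param x A `supermatrix`, [strain_alignment()], or named character
#'   vector of equal-length aligned sequences.
#' @param model `"p"` (default) or `"JC69"`.
#' @param pairwise_deletion Logical, default `TRUE`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(x, model = c("p", "JC69"),
                            pairwise_deletion = TRUE) {
  model <- match.arg(model)
  rows <- aligned_rows(x)
  if (length(rows) < 2L) stop("need >= 2 taxa")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  if (!pairwise_deletion) {
    keep <- colSums(ok) == nrow(m)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("no comparable sites between ", rownames(m)[i], " and ",
           rownames(m)[j])
    p <- sum(m[i, comp] != m[j, comp]) / nc
    d <- if (model == "p") p else {
      if (p >= 0.75)
        stop("JC69 undefined for p >= 0.75 (pair ", rownames(m)[i], ", ",
             rownames(m)[j], ")")
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

aligned_rows <- function(x) {
  if (inherits(x, "supermatrix")) x$rows
  else if (inherits(x, "strain_alignment")) x$rows
  else if (is.character(x)) x
  else stop("cannot interpret input as aligned rows")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining on the Q criterion
#' (Saitou-Nei with the Studier-Keppler update). At each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined; ties are
#' broken by the smallest row index then column index, so output is
#' deterministic. Negative branch lengths are clamped to zero. A 2-taxon
#' matrix yields a single split with the distance shared equally between
#' the two pendant edges.
#'
#' @param D Symmetric distance matrix with taxon dimnames.
#' @return An [ape::read.tree()]-style `phylo` object (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 taxa")
  labels <- rownames(D)
  fmt <- function(x) format(max(x, 0), digits = 12, scientific = FALSE,
                            trim = TRUE)
  node <- labels  # current newick representation of each cluster
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    new_lab <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    node <- c(node[keep], new_lab)
    rownames(D2) <- colnames(D2) <- seq_len(n - 1L)
    D <- D2
    n <- n - 1L
  }
  nwk <- if (n == 2L) {
    sprintf("(%s:%s,%s:%s);", node[1L], fmt(D[1, 2] / 2),
            node[2L], fmt(D[1, 2] / 2))
  } else {
    ## final three clusters joined at the central node
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", node[1L], fmt(la), node[2L], fmt(lb),
            node[3L], fmt(lc))
  }
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples supermatrix columns with replacement, rebuilds the NJ tree
#' for each pseudoreplicate, and scores each internal edge of the
#' original tree by the percentage of replicates containing the same
#' bipartition (via [ape::prop.clades()]). Fixing `seed` makes the
#' resampling, and hence the supports, reproducible bit for bit.
#'
#' @param sm A `supermatrix` (or any object [distance_matrix()] accepts).
#' @param n_reps Number of pseudoreplicates (>= 1); published organelle
#'   analyses typically use 1000.
#' @param seed Integer random seed (required).
#' @param model Distance model passed to [distance_matrix()].
#' @return The NJ tree on the full matrix with `node.label` set to
#'   support percentages (root label empty).
#' @export
bootstrap_nj <- function(sm, n_reps = 1000L, seed, model = "p") {
  if (missing(seed)) stop("seed is required for bootstrap resampling")
  stopifnot(n_reps >= 1L)
  rows <- aligned_rows(sm)
  main <- nj_tree(distance_matrix(rows, model = model))
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  L <- ncol(m)
  set.seed(as.integer(seed))
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    rb <- stats::setNames(apply(mb, 1L, paste, collapse = ""), rownames(m))
    boots[[b]] <- nj_tree(distance_matrix(rb, model = model))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / n_reps, 1))
  main$node.label[1L] <- ""
  main
}

#' Test whether a taxon set is monophyletic
#'
#' Roots the tree at the outgroup and asks whether `taxa` form a complete
#' clade.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels.
#' @param outgroup Tip label to root at.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object (node labels, e.g. bootstrap supports,
#'   are preserved).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a supermatrix for external phylogenetics tools
#'
#' Writes relaxed sequential PHYLIP plus a tab-separated partition table
#' (`gene_name`, `start_col`, `end_col`), so maximum-likelihood or
#' Bayesian analyses can be run outside this package.
#'
#' @param sm A `supermatrix`.
#' @param path Output PHYLIP path; the partition table goes to
#'   `<path>.partitions.tsv`.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(sm$taxa), nchar(sm$rows[[1L]])), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$rows), con)
  utils::write.table(sm$partitions, paste0(path, ".partitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
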