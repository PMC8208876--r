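#' Generate a random mitogenome-like sequence
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc_target` (split equally between
#' G and C, and between A and T), emulating the base composition of
#' AT-rich fungal mitochondria (~30% GC). For sequences of 10 kb and
#' more the realized GC lands within about one percentage point of the
#' target.
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc_target GC fraction in (0, 1); 0 is allowed and yields a pure
#'   AT sequence.
#' @param seed Integer random seed.
#' @param id Sequence id.
#' @return A [mitogenome()].
#' @export
generate_genome <- function(length, gc_target = 0.307, seed, id = "synth") {
  if (length < 1000L) stop("length must be >= 1000")
  if (gc_target < 0 || gc_target >= 1) stop("gc_target must be in [0, 1)")
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p),
             collapse = "")
  mitogenome(id, s, circular = TRUE)
}

#' Plant perfect SSRs into a genome with screened flanks
#'
#' Overwrites segments of the input genome with the requested repeat
#' tracts at randomly chosen, well-separated positions, then screens the
#' rest of the sequence: any accidental SSR that the scanner would report
#' at the given configuration is destroyed by point mutation (outside the
#' planted spans) and the scan repeated, until the scanner detects
#' exactly the planted set. The bases flanking each tract are forced to
#' break the repeat phase so planted records stay maximal and
#' left-anchored at the recorded coordinates.
#'
#' @param genome A [mitogenome()] to plant into (its sequence is the
#'   background).
#' @param ssr_specs `data.frame` with columns `unit` (primitive DNA unit,
#'   1-10 bp) and `copy_number`.
#' @param seed Integer random seed.
#' @param config [ssr_config()] used for the screening scan.
#' @param max_retries Screening iterations before giving up (default 100).
#' @return A list with `genome` (the edited [mitogenome()]) and
#'   `manifest` (`data.frame`: `unit`, `copy_number`, `start`, `end`,
#'   `category`, `ssr_type`, sorted by `start`).
#' @export
plant_ssrs <- function(genome, ssr_specs, seed, config = ssr_config(),
                       max_retries = 100L) {
  stopifnot(all(c("unit", "copy_number") %in% names(ssr_specs)))
  set.seed(as.integer(seed))
  units <- toupper(ssr_specs$unit)
  if (any(!is_primitive_unit(units)))
    stop("non-primitive unit(s) in specs")
  copies <- as.integer(ssr_specs$copy_number)
  tract_len <- nchar(units) * copies
  margin <- pmax(nchar(units), 10L) + 2L
  n <- genome$length
  if (sum(tract_len + 2L * margin) > n)
    stop("specs do not fit in genome with screened flanks")

  ## place tracts left to right with random gaps
  slack <- n - sum(tract_len + 2L * margin)
  kk <- length(units)
  cuts <- sort(sample.int(slack + 1L, kk, replace = TRUE)) - 1L
  starts <- integer(kk)
  pos <- 1L
  ord <- sample.int(kk)  # random order of specs along the genome
  prev_cut <- 0L
  for (r in seq_len(kk)) {
    i <- ord[r]
    pos <- pos + (cuts[r] - prev_cut) + margin[i]
    starts[i] <- pos
    pos <- pos + tract_len[i] + margin[i]
    prev_cut <- cuts[r]
  }
  ends <- starts + tract_len - 1L

  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  other_base <- function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  for (i in seq_len(kk)) {
    tract <- strrep(units[i], copies[i])
    chars[starts[i]:ends[i]] <- strsplit(tract, "", fixed = TRUE)[[1]]
    u <- nchar(units[i])
    last_u <- substr(units[i], u, u)
    first_u <- substr(units[i], 1L, 1L)
    if (starts[i] > 1L && chars[starts[i] - 1L] == last_u)
      chars[starts[i] - 1L] <- other_base(c(last_u, "N"))
    if (ends[i] < n && chars[ends[i] + 1L] == first_u)
      chars[ends[i] + 1L] <- other_base(c(first_u, "N"))
  }

  manifest <- data.frame(unit = units, copy_number = copies,
                         start = starts, end = ends,
                         category = classify_ssr(nchar(units), copies, config),
                         ssr_type = ssr_type_names[nchar(units)],
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$start), , drop = FALSE]
  rownames(manifest) <- NULL
  if (any(is.na(manifest$category)))
    stop("spec(s) would be rejected by the classifier at this config")

  in_planted <- logical(n)
  for (i in seq_len(kk))
    in_planted[max(1L, starts[i] - 1L):min(n, ends[i] + 1L)] <- TRUE

  key <- function(df) paste(df$unit, df$copy_number, df$start, df$end)
  want <- sort(key(manifest))
  for (try in seq_len(max_retries)) {
    g <- mitogenome(genome$id, paste(chars, collapse = ""),
                    circular = genome$circular)
    got <- find_ssrs(g, config)
    if (identical(sort(key(got)), want))
      return(list(genome = g, manifest = manifest))
    extra <- got[!key(got) %in% key(manifest), , drop = FALSE]
    if (nrow(extra) == 0L)
      stop("planted SSR lost during screening; specs may conflict")
    for (e in seq_len(nrow(extra))) {
      span <- extra$start[e]:extra$end[e]
      span <- span[!in_planted[span]]
      if (!length(span))
        stop("accidental SSR inseparable from a planted span")
      pmut <- span[ceiling(length(span) / 2)]
      chars[pmut] <- other_base(chars[pmut])
    }
  }
  stop("screening did not converge within ", max_retries, " retries")
}

#' Default five-strain variant panel specification
#'
#' Mimics the structure of the study panel this package was built
#' around: five strains, two SNPs, three insertions (2, 10 and 1 bp) and
#' two deletions (2 and 3 bp), each carried by one or two strains.
#' Positions and carriers are drawn at random when not supplied.
#'
#' @param genome_length Ancestor length, used to place events.
#' @param strains Strain ids (first is the reference).
#' @param seed Integer random seed.
#' @return An event-spec `data.frame` accepted by [derive_strain_panel()].
#' @export
default_panel_spec <- function(genome_length,
                               strains = c("KR", "KR.1D", "KR.5D",
                                           "KR.11D", "WGS"),
                               seed = 1L) {
  specs <- data.frame(
    vtype = c("SNP", "SNP", "insertion", "insertion", "insertion",
              "deletion", "deletion"),
    length = c(1L, 1L, 2L, 10L, 1L, 2L, 3L),
    stringsAsFactors = FALSE)
  random_panel_spec(specs, genome_length, strains, seed)
}

#' Randomize positions, carriers and alleles of an event-spec skeleton
#'
#' @param specs `data.frame` with columns `vtype` and `length`.
#' @param genome_length Ancestor length.
#' @param strains Strain ids; carriers are drawn as strict minorities
#'   (at most `floor((n - 1) / 2)` strains).
#' @param seed Integer random seed.
#' @return Completed spec with `genome_pos`, `carriers` (list column) and
#'   `alt` filled.
#' @export
random_panel_spec <- function(specs, genome_length, strains, seed) {
  set.seed(as.integer(seed))
  k <- nrow(specs)
  gap <- 20L
  repeat {
    pos <- sort(sample.int(genome_length - max(specs$length) - gap, k))
    if (k == 1L || all(diff(pos) > max(specs$length) + gap)) break
  }
  specs <- specs[sample.int(k), , drop = FALSE]  # decouple order from type
  specs$genome_pos <- pos
  maxc <- max(1L, (length(strains) - 1L) %/% 2L)
  specs$carriers <- lapply(seq_len(k), function(i)
    sample(strains, sample.int(maxc, 1L)))
  specs$alt <- vapply(seq_len(k), function(i) {
    if (specs$vtype[i] == "insertion")
      paste(sample(c("A", "C", "G", "T"), specs$length[i], replace = TRUE),
            collapse = "")
    else NA_character_  # SNP alt chosen against the ancestor base later
  }, "")
  rownames(specs) <- NULL
  specs
}

#' Build a strain panel alignment with a known variant manifest
#'
#' Constructs the true alignment directly from the ancestral genome and
#' an event specification, so no aligner is involved: insertion columns
#' are opened in the consensus, carrier rows receive the inserted bases
#' or gaps, SNP carriers the alternate base. The consensus of the
#' returned alignment equals the ancestral genome.
#'
#' @param genome Ancestral [mitogenome()]; also the reference strain's
#'   sequence.
#' @param event_specs `data.frame` with columns `vtype` (`SNP`,
#'   `insertion`, `deletion`), `genome_pos` (SNP/deletion: first affected
#'   ancestor base; insertion: the gap opens after this base), `length`,
#'   `carriers` (list column of strain-id vectors) and optional `alt`
#'   (SNP alternate base or inserted string) and `ref` (forces the
#'   ancestor base(s) at the site). Event footprints must be disjoint and
#'   separated by at least two ancestor bases.
#' @param strains Strain ids; the first is the reference and should not
#'   carry events in a majority pattern.
#' @param seed Integer random seed (used for any unfilled `alt` alleles).
#' @return List with `alignment` (a [strain_alignment()]) and `manifest`
#'   (a `variant_table`-shaped `data.frame` of the planted events in
#'   alignment coordinates, sorted by column).
#' @export
derive_strain_panel <- function(genome, event_specs,
                                strains = c("KR", "KR.1D", "KR.5D",
                                            "KR.11D", "WGS"),
                                seed = 1L) {
  set.seed(as.integer(seed))
  sp <- event_specs
  stopifnot(all(c("vtype", "genome_pos", "length", "carriers") %in% names(sp)))
  if (length(strains) < 2L) stop("need >= 2 strains")
  sp <- sp[order(sp$genome_pos), , drop = FALSE]
  if (nrow(sp) == 0L) {
    aln <- strain_alignment(strains, rep(genome$sequence, length(strains)))
    manifest <- data.frame(vtype = character(), msa_start = integer(),
                           msa_end = integer(), carriers = character(),
                           consensus_allele = character(),
                           carrier_allele = character(),
                           base_changes = character(),
                           stringsAsFactors = FALSE)
    return(list(alignment = aln, manifest = manifest))
  }
  foot_end <- sp$genome_pos + ifelse(sp$vtype == "deletion", sp$length - 1L, 0L)
  if (nrow(sp) > 1L) {
    if (any(sp$genome_pos[-1L] <= foot_end[-nrow(sp)]))
      stop("event footprints overlap")
    ## same-polarity indels with identical carriers would merge if adjacent
    same_kind <- sp$vtype[-1L] == sp$vtype[-nrow(sp)] & sp$vtype[-1L] != "SNP"
    same_carriers <- vapply(seq_len(nrow(sp) - 1L), function(i)
      setequal(sp$carriers[[i]], sp$carriers[[i + 1L]]), TRUE)
    too_close <- sp$genome_pos[-1L] - foot_end[-nrow(sp)] < 2L
    if (any(same_kind & same_carriers & too_close))
      stop("adjacent same-type events with identical carriers would merge")
  }
  if (max(foot_end) > genome$length) stop("event beyond genome end")
  bad <- !vapply(sp$carriers, function(cc)
    length(cc) >= 1L && all(cc %in% strains) && length(cc) < length(strains),
    TRUE)
  if (any(bad)) stop("carriers must be a nonempty strict subset of strains")

  anc <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  if (!"alt" %in% names(sp)) sp$alt <- NA_character_
  ## force requested reference bases, draw missing SNP alternates
  for (i in seq_len(nrow(sp))) {
    p <- sp$genome_pos[i]
    if ("ref" %in% names(sp) && !is.na(sp$ref[i]) && nzchar(sp$ref[i]))
      anc[p:(p + nchar(sp$ref[i]) - 1L)] <-
        strsplit(toupper(sp$ref[i]), "", fixed = TRUE)[[1]]
    if (sp$vtype[i] == "SNP" && (is.na(sp$alt[i]) || !nzchar(sp$alt[i])))
      sp$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1L)
    if (sp$vtype[i] == "insertion" && (is.na(sp$alt[i]) || !nzchar(sp$alt[i])))
      sp$alt[i] <- paste(sample(c("A", "C", "G", "T"), sp$length[i],
                                replace = TRUE), collapse = "")
  }

  ins <- which(sp$vtype == "insertion")
  ins_off <- function(p) {
    if (!length(ins)) return(0L)
    sum(sp$length[ins][sp$genome_pos[ins] < p])
  }
  ## consensus row: ancestor with gap blocks after each insertion anchor
  pieces <- character(0)
  last <- 0L
  for (i in ins) {
    pieces <- c(pieces, paste(anc[(last + 1L):sp$genome_pos[i]], collapse = ""),
                strrep("-", sp$length[i]))
    last <- sp$genome_pos[i]
  }
  pieces <- c(pieces, if (last < genome$length)
    paste(anc[(last + 1L):genome$length], collapse = "") else "")
  cons <- paste(pieces, collapse = "")

  rows <- stats::setNames(rep(cons, length(strains)), strains)
  rowsc <- strsplit(rows, "", fixed = TRUE)
  manifest <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    p <- sp$genome_pos[i]
    if (sp$vtype[i] == "insertion") {
      a <- p + ins_off(p) + 1L
      b <- a + sp$length[i] - 1L
      for (s in sp$carriers[[i]])
        rowsc[[s]][a:b] <- strsplit(sp$alt[i], "", fixed = TRUE)[[1]]
      cons_allele <- "-"; carr_allele <- sp$alt[i]
    } else if (sp$vtype[i] == "deletion") {
      a <- p + ins_off(p)
      b <- a + sp$length[i] - 1L
      for (s in sp$carriers[[i]]) rowsc[[s]][a:b] <- "-"
      cons_allele <- paste(anc[p:(p + sp$length[i] - 1L)], collapse = "")
      carr_allele <- "-"
    } else {
      a <- b <- p + ins_off(p)
      for (s in sp$carriers[[i]]) rowsc[[s]][a] <- sp$alt[i]
      cons_allele <- anc[p]; carr_allele <- sp$alt[i]
    }
    manifest[[i]] <- data.frame(
      vtype = sp$vtype[i], msa_start = a, msa_end = b,
      carriers = paste(sort(sp$carriers[[i]]), collapse = ", "),
      consensus_allele = cons_allele, carrier_allele = carr_allele,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  manifest <- manifest[order(manifest$msa_start), , drop = FALSE]
  manifest$base_changes <- paste(manifest$consensus_allele, "to",
                                 manifest$carrier_allele)
  rownames(manifest) <- NULL
  aln <- strain_alignment(strains,
                          vapply(rowsc, paste, "", collapse = ""))
  list(alignment = aln, manifest = manifest)
}

#' Simulate aligned gene blocks on a tree
#'
#' Evolves gap-free sequences along a binary tree under the Jukes-Cantor
#' model: on an edge of length `t` (expected substitutions per site,
#' scaled by `subst_rate`) each site stays with probability
#' `1/4 + 3/4 exp(-4t/3)` and otherwise changes to one of the other
#' three bases uniformly. One independent block is produced per entry of
#' `block_lengths`.
#'
#' @param tree A rooted binary `phylo` object with branch lengths.
#' @param block_lengths Integer vector of block widths (bp); names become
#'   gene names.
#' @param subst_rate Positive rate multiplier applied to branch lengths.
#' @param seed Integer random seed.
#' @return List with `blocks` (list of [gene_block()]s) and `supermatrix`
#'   (their concatenation).
#' @export
simulate_supermatrix <- function(tree, block_lengths, subst_rate = 1,
                                 seed = 1L) {
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (subst_rate <= 0) stop("subst_rate must be > 0")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  if (is.null(names(block_lengths)))
    names(block_lengths) <- paste0("block", seq_along(block_lengths))
  blocks <- vector("list", length(block_lengths))
  for (bi in seq_along(block_lengths)) {
    L <- block_lengths[[bi]]
    seqs <- matrix(NA_integer_, ntip + nnode, L)
    seqs[root, ] <- sample.int(4L, L, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      d <- subst_rate * tr$edge.length[e]
      p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
      x <- seqs[par, ]
      change <- stats::runif(L) > p_same
      nc <- sum(change)
      if (nc) {
        shift <- sample.int(3L, nc, replace = TRUE)
        x[change] <- ((x[change] - 1L + shift) %% 4L) + 1L
      }
      seqs[child, ] <- x
    }
    rows <- stats::setNames(
      vapply(seq_len(ntip), function(i)
        paste(bases[seqs[i, ]], collapse = ""), ""),
      tree$tip.label)
    blocks[[bi]] <- gene_block(names(block_lengths)[bi], rows)
  }
  list(blocks = blocks, supermatrix = concatenate_blocks(blocks))
}
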