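#' Call SNPs and INDELs from a multi-strain alignment
#'
#' The per-column consensus is the majority residue (gap counts as a
#' residue; `N` is missing and never votes); ties are broken in favor of
#' the designated reference strain's residue, then alphabetically (`-`
#' sorts before bases). A gap-free polymorphic column yields one SNP
#' event per distinct minority allele. Maximal runs of consecutive
#' columns with the same carrier set and gap polarity are merged into a
#' single insertion (consensus gapped, carriers hold bases) or deletion
#' (consensus holds bases, carriers gapped) event. Events are reported in
#' 1-based alignment coordinates, sorted by column.
#'
#' @param aln A [strain_alignment()] of at least two strains.
#' @param reference Strain id used for consensus tie-breaks (default:
#'   first strain).
#' @return A `variant_table`: `data.frame` with columns `vtype` (`SNP`,
#'   `insertion`, `deletion`), `msa_start`, `msa_end`, `carriers`
#'   (comma-joined strain ids), `consensus_allele`, `carrier_allele`,
#'   `base_changes` (`"A to T"` / `"- to CC"` style) and `position_note`
#'   (empty until [annotate_variants()]).
#' @export
call_variants <- function(aln, reference = aln$strain_ids[1L]) {
  if (length(aln$strain_ids) < 2L) stop("need >= 2 strains")
  if (!reference %in% aln$strain_ids) stop("unknown reference: ", reference)
  m <- alignment_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  cons <- consensus_row(m, reference)

  events <- list()
  ## SNPs: gap-free polymorphic columns, one event per minority allele
  has_gap <- colSums(m == "-") > 0L
  for (j in which(!has_gap)) {
    col <- m[, j]
    obs <- col[col != "N"]
    alleles <- setdiff(unique(obs), cons[j])
    for (a in alleles) {
      events[[length(events) + 1L]] <- data.frame(
        vtype = "SNP", msa_start = j, msa_end = j,
        carriers = paste(sort(rownames(m)[col == a]), collapse = ", "),
        consensus_allele = cons[j], carrier_allele = a,
        stringsAsFactors = FALSE)
    }
  }

  ## INDELs: merge runs of identical (polarity, carrier set)
  key <- rep(NA_character_, L)
  polarity <- rep(NA_character_, L)
  for (j in which(has_gap)) {
    col <- m[, j]
    if (cons[j] == "-") {
      carriers <- rownames(m)[col != "-" & col != "N"]
      if (!length(carriers)) next
      polarity[j] <- "insertion"
    } else {
      carriers <- rownames(m)[col == "-"]
      if (!length(carriers)) next
      polarity[j] <- "deletion"
    }
    key[j] <- paste(polarity[j], paste(sort(carriers), collapse = ","),
                    sep = "|")
  }
  j <- 1L
  while (j <= L) {
    if (is.na(key[j])) { j <- j + 1L; next }
    k <- j
    while (k < L && identical(key[k + 1L], key[j])) k <- k + 1L
    carriers <- strsplit(sub("^[a-z]+\\|", "", key[j]), ",", fixed = TRUE)[[1]]
    cols <- j:k
    if (polarity[j] == "insertion") {
      carrier_allele <- paste(m[carriers[1L], cols], collapse = "")
      consensus_allele <- "-"
    } else {
      carrier_allele <- "-"
      consensus_allele <- paste(cons[cols], collapse = "")
    }
    events[[length(events) + 1L]] <- data.frame(
      vtype = polarity[j], msa_start = j, msa_end = k,
      carriers = paste(carriers, collapse = ", "),
      consensus_allele = consensus_allele,
      carrier_allele = carrier_allele, stringsAsFactors = FALSE)
    j <- k + 1L
  }

  out <- if (length(events)) do.call(rbind, events) else
    data.frame(vtype = character(), msa_start = integer(),
               msa_end = integer(), carriers = character(),
               consensus_allele = character(), carrier_allele = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$msa_start, out$msa_end, out$vtype), , drop = FALSE]
  out$base_changes <- if (nrow(out))
    paste(out$consensus_allele, "to", out$carrier_allele) else character(0)
  out$position_note <- character(nrow(out))
  rownames(out) <- NULL
  structure(out, reference = reference,
            class = c("variant_table", "data.frame"))
}

## majority consensus per column; ties -> reference residue, then
## alphabetical ('-' sorts first); N never votes
consensus_row <- function(m, reference) {
  apply_cols <- seq_len(ncol(m))
  ref_row <- m[reference, ]
  vapply(apply_cols, function(j) {
    col <- m[, j]
    obs <- col[col != "N"]
    if (!length(obs)) return("N")
    tab <- table(obs)
    winners <- sort(names(tab)[tab == max(tab)])
    if (ref_row[j] %in% winners) ref_row[j] else winners[1L]
  }, "")
}

#' Count alignment columns involved in INDELs
#'
#' Number of columns whose gap pattern is polymorphic (at least one
#' strain gapped and at least one holding a base, `N` excluded). This is
#' the column-level INDEL count used as the numerator of INDEL coverage.
#'
#' @param aln A [strain_alignment()].
#' @return Integer count of columns.
#' @export
indel_column_count <- function(aln) {
  if (length(aln$strain_ids) < 2L) stop("need >= 2 strains")
  m <- alignment_matrix(aln)
  gaps <- colSums(m == "-")
  bases <- colSums(m != "-" & m != "N")
  sum(gaps > 0L & bases > 0L)
}

#' Per-panel variation summary with coverage percentages
#'
#' Coverage is the count divided by the aligned length (alignment
#' columns), times 100. Values are kept at full precision; round only
#' when printing.
#'
#' @param n_genomes Number of strains in the panel.
#' @param aligned_length Alignment width in columns.
#' @param n_snps SNP count.
#' @param n_indels INDEL column count.
#' @return An object of class `variation_summary` with fields
#'   `n_genomes`, `aligned_length`, `n_snps`, `snp_coverage_pct`,
#'   `n_indels`, `indel_coverage_pct`.
#' @examples
#' s <- variation_summary(3, 157606, 16, 144)
#' round(s$snp_coverage_pct, 3)
#' @export
variation_summary <- function(n_genomes, aligned_length, n_snps, n_indels) {
  if (aligned_length < 1L) stop("aligned_length must be >= 1")
  structure(list(
    n_genomes = as.integer(n_genomes),
    aligned_length = as.integer(aligned_length),
    n_snps = as.integer(n_snps),
    snp_coverage_pct = 100 * n_snps / aligned_length,
    n_indels = as.integer(n_indels),
    indel_coverage_pct = 100 * n_indels / aligned_length),
    class = "variation_summary")
}

#' @export
print.variation_summary <- function(x, ...) {
  cat(sprintf(
    "<variation_summary> %d genomes, %s columns: %d SNPs (%.3f%%), %d INDEL columns (%.2f%%)\n",
    x$n_genomes, format(x$aligned_length, big.mark = ","), x$n_snps,
    x$snp_coverage_pct, x$n_indels, x$indel_coverage_pct))
  invisible(x)
}

#' Summarize variation in an alignment
#'
#' Calls [call_variants()] for SNP events and [indel_column_count()] for
#' the INDEL column count, and wraps them in a [variation_summary()].
#'
#' @param aln A [strain_alignment()].
#' @param reference Reference strain for consensus tie-breaks.
#' @return A [variation_summary()].
#' @export
summarize_variation <- function(aln, reference = aln$strain_ids[1L]) {
  if (aln$aligned_length < 1L) stop("zero-length alignment")
  ev <- call_variants(aln, reference)
  variation_summary(length(aln$strain_ids), aln$aligned_length,
                    sum(ev$vtype == "SNP"), indel_column_count(aln))
}

#' Annotate variant events with positional and protein effects
#'
#' Maps each event's alignment columns to ungapped coordinates of the
#' reference strain, classifies the position with [classify_interval()],
#' and, for a SNP falling in a CDS with exon detail, recomputes the
#' affected codon in transcript orientation under the mold mitochondrial
#' genetic code: the note becomes `"L to Q in <gene>"` when the amino
#' acid changes and `"synonymous in <gene>"` otherwise. Non-CDS or INDEL
#' events get `"Intergenic"` or the overlapped gene list as the note.
#'
#' @param events A `variant_table` from [call_variants()].
#' @param aln The [strain_alignment()] the events came from.
#' @param ft [feature_table()] for the reference genome.
#' @param genome [mitogenome()] of the reference strain (ungapped).
#' @param reference Reference strain id (default: attribute stored by
#'   [call_variants()]).
#' @return `events` with `position_note` filled.
#' @export
annotate_variants <- function(events, aln, ft, genome,
                              reference = attr(events, "reference")) {
  if (!reference %in% aln$strain_ids) stop("unknown reference: ", reference)
  if (!identical(ungapped_sequence(aln, reference), genome$sequence))
    stop("reference row of alignment does not reconstruct genome '",
         genome$id, "'")
  map <- msa_to_genome_map(aln, reference)
  notes <- vapply(seq_len(nrow(events)), function(i) {
    cols <- events$msa_start[i]:events$msa_end[i]
    g <- map[cols]
    g <- g[!is.na(g)]
    if (!length(g)) {
      ## event lies entirely in reference gaps (pure insertion):
      ## anchor to the nearest reference base to the left
      left <- map[seq_len(events$msa_start[i] - 1L)]
      left <- left[!is.na(left)]
      g <- if (length(left)) max(left) else 1L
    }
    cls <- classify_interval(min(g), max(g), ft, genome$length)
    if (events$vtype[i] == "SNP") {
      if (is.na(map[events$msa_start[i]]))
        stop("SNP column ", events$msa_start[i], " maps into a reference gap")
      note <- snp_effect_note(map[events$msa_start[i]],
                              events$carrier_allele[i], ft, genome)
      if (!is.null(note)) return(note)
    }
    if (cls$klass == "intergenic") "Intergenic"
    else paste(cls$genes, collapse = ", ")
  }, "")
  events$position_note <- notes
  events
}

## codon-level effect of a SNP at reference position g; NULL when the
## position is not inside CDS exon bases with usable exon structure
snp_effect_note <- function(g, alt, ft, genome) {
  cds <- which(ft$type == "CDS")
  for (i in cds) {
    f <- as_feature_row(ft[i, ])
    if (g < f$start || g > f$end) next
    ex <- tryCatch(feature_exons(f), error = function(e) NULL)
    if (is.null(ex)) next
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    in_ex <- which(ex[, 1L] <= g & ex[, 2L] >= g)
    if (!length(in_ex)) next
    ## transcript position in forward (genomic) concatenation
    before <- if (in_ex > 1L)
      sum(ex[seq_len(in_ex - 1L), 2L] - ex[seq_len(in_ex - 1L), 1L] + 1L)
    else 0L
    fwd_pos <- before + (g - ex[in_ex, 1L] + 1L)
    tx <- splice_feature(genome, f)
    L <- nchar(tx)
    if (L %% 3L != 0L) next
    if (identical(f$strand, "reverse")) {
      pos <- L - fwd_pos + 1L
      alt_tx <- chartr("ACGTN", "TGCAN", alt)
    } else {
      pos <- fwd_pos
      alt_tx <- alt
    }
    codon_i <- (pos - 1L) %/% 3L
    codon <- substr(tx, codon_i * 3L + 1L, codon_i * 3L + 3L)
    off <- pos - codon_i * 3L
    mut <- codon
    substr(mut, off, off) <- alt_tx
    aa_ref <- translate_mito(codon)
    aa_alt <- translate_mito(mut)
    return(if (identical(aa_ref, aa_alt))
      paste0("synonymous in ", f$name)
      else paste0(aa_ref, " to ", aa_alt, " in ", f$name))
  }
  NULL
}

#' Reconstruct strain rows from the consensus plus called events
#'
#' Utility used to verify that calling is lossless: applying every event
#' to the consensus row must reproduce each strain's aligned row exactly
#' (`N` positions excepted).
#'
#' @param aln A [strain_alignment()].
#' @param events A `variant_table` from [call_variants()] on `aln`.
#' @param reference Reference strain id.
#' @return A named character vector of reconstructed rows.
#' @export
apply_variants <- function(aln, events, reference = attr(events, "reference")) {
  m <- alignment_matrix(aln)
  cons <- consensus_row(m, reference)
  out <- vapply(aln$strain_ids, function(s) {
    row <- cons
    for (i in seq_len(nrow(events))) {
      carriers <- strsplit(events$carriers[i], ", ", fixed = TRUE)[[1]]
      if (!s %in% carriers) next
      cols <- events$msa_start[i]:events$msa_end[i]
      repl <- if (events$vtype[i] == "deletion") strrep("-", length(cols))
      else events$carrier_allele[i]
      row[cols] <- strsplit(repl, "", fixed = TRUE)[[1]]
    }
    paste(row, collapse = "")
  }, "")
  out
}
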