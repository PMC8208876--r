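#' Construct a mitogenome object
#'
#' A `mitogenome` is a single (typically circular) DNA sequence with an
#' identifier. Sequences are stored uppercase over the alphabet
#' `A`, `C`, `G`, `T`, `N`. Circular topology is recorded but coordinates
#' never wrap the origin: features or scans that would cross the junction
#' must be handled by the caller (no gene in the systems this package was
#' built around spans the origin).
#'
#' @param id Sequence identifier (single string).
#' @param sequence DNA sequence as a single string; lowercase input is
#'   uppercased.
#' @param circular Logical; is the molecule circular? Default `TRUE`.
#' @param source_accession Optional database accession the sequence was
#'   loaded from.
#' @return An object of class `mitogenome` with fields `id`, `sequence`,
#'   `length`, `circular`, `source_accession`.
#' @examples
#' g <- mitogenome("toy", "ACGTACGT")
#' g$length
#' @export
mitogenome <- function(id, sequence, circular = TRUE, source_accession = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  id <- unname(id)
  sequence <- unname(toupper(sequence))
  if (nchar(sequence) < 1L)
    stop("mitogenome sequence must have length >= 1")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("non-IUPAC DNA characters in sequence for '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular), source_accession = source_accession),
    class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %s, GC %.1f%%\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              gc_content(x)))
  invisible(x)
}

#' Read DNA sequences from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns one [mitogenome()]
#' per record. RNA input (`U`) and ambiguity codes other than `N` are
#' rejected; ids must be unique.
#'
#' @param path Path to a FASTA file (may contain multiple records).
#' @param circular Logical, stored on every returned genome.
#' @return A named list of `mitogenome` objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  ## read raw (B) strings: DNA parsing would silently drop letters like U,
  ## which must instead be rejected
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  out <- lapply(seq_along(ids), function(i)
    mitogenome(ids[i], seqs[i], circular = circular,
               source_accession = ids[i]))
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `mitogenome` or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC content of a sequence
#'
#' Percentage of `G`+`C` bases. `N` bases never count as G/C but remain in
#' the denominator, so a fully ambiguous sequence has GC 0.
#'
#' @param x A `mitogenome` or a DNA string.
#' @param digits Rounding for the returned value; `NULL` (default) keeps
#'   full precision. The paper-style report uses 1 decimal place.
#' @return GC percentage (0-100).
#' @examples
#' gc_content("ATGC") # 50
#' @export
gc_content <- function(x, digits = NULL) {
  s <- if (inherits(x, "mitogenome")) x$sequence else toupper(x)
  n <- nchar(s)
  if (length(s) != 1L || n < 1L) stop("gc_content needs one nonempty sequence")
  gc <- nchar(gsub("[^GC]", "", s))
  val <- 100 * gc / n
  if (is.null(digits)) val else round(val, digits)
}

## reverse complement on plain character strings (A/C/G/T/N and gaps kept)
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
           "", USE.NAMES = FALSE))
}

#' Extract the (spliced) transcript sequence of a feature
#'
#' Concatenates the feature's exon sequences and returns them in
#' transcript orientation: reverse-strand features are
#' reverse-complemented. For single-exon features the exon is the full
#' span; multi-exon features must carry explicit exon sub-intervals.
#'
#' @param genome A [mitogenome()].
#' @param feature One row of a [feature_table()] (a list or 1-row
#'   data.frame with `start`, `end`, `strand`, `n_exons` and, when
#'   `n_exons > 1`, an `exons` two-column matrix of 1-based inclusive
#'   sub-intervals).
#' @return The nucleotide sequence, 5'->3' in transcript orientation.
#' @export
splice_feature <- function(genome, feature) {
  f <- as_feature_row(feature)
  if (f$end > genome$length || f$start < 1L)
    stop("feature ", f$name, " [", f$start, ", ", f$end,
         "] outside genome '", genome$id, "' (1..", genome$length, ")")
  ex <- feature_exons(f)
  if (any(ex[, 1L] < f$start | ex[, 2L] > f$end))
    stop("exon outside feature span for ", f$name)
  ex <- ex[order(ex[, 1L]), , drop = FALSE]
  parts <- substring(genome$sequence, ex[, 1L], ex[, 2L])
  out <- paste(parts, collapse = "")
  if (identical(f$strand, "reverse")) revcomp(out) else out
}

## normalize a feature given as list / 1-row data.frame into a plain list
as_feature_row <- function(feature) {
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    f <- as.list(feature)
    if (!is.null(f$exons)) f$exons <- f$exons[[1L]]
  } else {
    f <- feature
  }
  if (is.null(f$name)) f$name <- "<feature>"
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  if (is.na(f$start) || is.na(f$end) || f$start > f$end)
    stop("invalid feature span for ", f$name)
  f
}

## exon matrix of a feature; single-exon features default to the full span
feature_exons <- function(f) {
  ex <- f$exons
  if (is.null(ex) || (is.atomic(ex) && all(is.na(ex)))) {
    if (!is.null(f$n_exons) && f$n_exons > 1L)
      stop("feature ", f$name, " claims ", f$n_exons,
           " exons but carries no exon sub-intervals")
    return(matrix(c(f$start, f$end), nrow = 1L))
  }
  ex <- matrix(as.integer(ex), ncol = 2L)
  if (any(ex[, 1L] > ex[, 2L])) stop("exon with start > end in ", f$name)
  ex
}

#' Translate a coding sequence under the mold mitochondrial code
#'
#' Uses NCBI translation table 4 (mold / protozoan mitochondrial code) by
#' default, in which `TGA` encodes tryptophan. Codons containing `N` are
#' translated as `X`.
#'
#' @param cds_sequence In-frame coding sequence (length a multiple of 3),
#'   already in transcript orientation.
#' @param code NCBI genetic code id as a string (default `"4"`).
#' @return Amino-acid string; stop codons are `*`.
#' @examples
#' translate_mito("TGACTTCAA") # "WLQ"
#' @export
translate_mito <- function(cds_sequence, code = "4") {
  s <- toupper(cds_sequence)
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("coding sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return("")
  tab <- Biostrings::getGeneticCode(code)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
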