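#' Construct a multi-strain alignment
#'
#' Holds a whole-genome multiple sequence alignment of closely related
#' strains: equal-length gapped rows over `A`, `C`, `G`, `T`, `N`, `-`.
#'
#' @param strain_ids Character vector of unique strain names.
#' @param rows Character vector of aligned sequences, one per strain.
#' @return An object of class `strain_alignment` with fields
#'   `strain_ids`, `rows` (named by strain) and `aligned_length`.
#' @export
strain_alignment <- function(strain_ids, rows) {
  stopifnot(is.character(strain_ids), is.character(rows),
            length(strain_ids) == length(rows))
  if (anyDuplicated(strain_ids))
    stop("duplicate strain ids: ",
         paste(unique(strain_ids[duplicated(strain_ids)]), collapse = ", "))
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L)
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ", "))
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad))
    stop("non-ACGTN- characters in row(s): ",
         paste(strain_ids[bad], collapse = ", "))
  names(rows) <- strain_ids
  structure(list(strain_ids = strain_ids, rows = rows,
                 aligned_length = widths[1L]),
            class = "strain_alignment")
}

#' @export
print.strain_alignment <- function(x, ...) {
  cat(sprintf("<strain_alignment> %d strains x %s columns: %s\n",
              length(x$strain_ids), format(x$aligned_length, big.mark = ","),
              paste(x$strain_ids, collapse = ", ")))
  invisible(x)
}

#' Read an aligned multi-FASTA
#'
#' @param path Aligned FASTA; all records must be the same width.
#' @return A [strain_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs >= 2 records: ", path)
  strain_alignment(sub("\\s.*$", "", names(set)), as.character(set))
}

#' Write an alignment as aligned multi-FASTA
#'
#' @param aln A [strain_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Drop gaps from one strain's row
#'
#' @param aln A [strain_alignment()].
#' @param strain Strain id.
#' @return The ungapped genome sequence of that strain.
#' @export
ungapped_sequence <- function(aln, strain) {
  if (!strain %in% aln$strain_ids) stop("unknown strain: ", strain)
  gsub("-", "", aln$rows[[strain]], fixed = TRUE)
}

## alignment as a character matrix (strains x columns)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$strain_ids
  m
}

#' Map alignment columns to ungapped reference coordinates
#'
#' @param aln A [strain_alignment()].
#' @param reference Strain id whose ungapped coordinates are wanted.
#' @return Integer vector of length `aligned_length`; entry `i` is the
#'   1-based reference position of column `i`, or `NA` where the
#'   reference row is gapped.
#' @export
msa_to_genome_map <- function(aln, reference) {
  row <- strsplit(aln$rows[[reference]], "", fixed = TRUE)[[1]]
  isbase <- row != "-"
  out <- ifelse(isbase, cumsum(isbase), NA_integer_)
  as.integer(out)
}
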