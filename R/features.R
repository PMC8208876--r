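#' Construct a gene feature
#'
#' @param name Gene name (need not be unique; [feature_table()]
#'   disambiguates duplicates).
#' @param type One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param start,end 1-based inclusive genomic span, `start <= end`.
#' @param strand `"forward"` or `"reverse"` (also accepts `"+"`/`"-"`).
#' @param n_exons Number of exons (default 1).
#' @param exons Optional two-column matrix of 1-based inclusive exon
#'   sub-intervals (required by splicing and intron-aware classification
#'   when `n_exons > 1`; the printed annotation tables this package
#'   mirrors give exon counts but not exon coordinates, so the field is
#'   optional).
#' @param nested_in_intron_of Optional name of a host gene within whose
#'   intron this feature (typically a homing-endonuclease ORF) resides.
#' @return A one-row `data.frame` in [feature_table()] layout.
#' @export
gene_feature <- function(name, type = c("CDS", "tRNA", "rRNA"),
                         start, end, strand = c("forward", "reverse"),
                         n_exons = 1L, exons = NULL,
                         nested_in_intron_of = NA_character_) {
  type <- match.arg(type)
  strand <- normalize_strand(strand[1L])
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid span for feature '", name, "': start=", start, " end=", end)
  n_exons <- as.integer(n_exons)
  if (n_exons < 1L) stop("n_exons must be >= 1 for '", name, "'")
  if (!is.null(exons)) {
    exons <- matrix(as.integer(exons), ncol = 2L)
    if (nrow(exons) != n_exons)
      stop("feature '", name, "': ", nrow(exons),
           " exon intervals given but n_exons = ", n_exons)
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    if (any(exons[, 1L] > exons[, 2L]) ||
        any(exons[, 1L] < start) || any(exons[, 2L] > end))
      stop("exon sub-intervals outside [start, end] for '", name, "'")
    if (n_exons > 1L && any(exons[-1L, 1L] <= exons[-n_exons, 2L]))
      stop("exon sub-intervals overlap for '", name, "'")
  }
  df <- data.frame(name = name, type = type, start = start, end = end,
                   strand = strand, n_exons = n_exons,
                   nested_in_intron_of = nested_in_intron_of,
                   stringsAsFactors = FALSE)
  df$exons <- list(exons)
  df
}

normalize_strand <- function(s) {
  s <- tolower(as.character(s))
  out <- c("forward" = "forward", "+" = "forward", "1" = "forward",
           "reverse" = "reverse", "-" = "reverse", "-1" = "reverse")[s]
  if (any(is.na(out))) stop("malformed strand value(s): ",
                            paste(unique(s[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Assemble a feature table
#'
#' Sorts features by start and disambiguates duplicate names by appending
#' `#2`, `#3`, ... to second and later occurrences (fungal mitogenomes
#' routinely carry several identically named `LAGLIDADG endonuclease` or
#' `Hypothetical protein` ORFs).
#'
#' @param genome_id Identifier of the genome the features annotate.
#' @param features A `data.frame` of rows built by [gene_feature()] (or an
#'   `rbind` of them).
#' @return A `feature_table` (a `data.frame` subclass) with attribute
#'   `genome_id`.
#' @export
feature_table <- function(genome_id, features) {
  stopifnot(is.data.frame(features), nrow(features) >= 0L)
  features <- features[order(features$start, features$end), , drop = FALSE]
  nm <- features$name
  for (d in unique(nm[duplicated(nm)])) {
    idx <- which(nm == d)
    nm[idx[-1L]] <- paste0(d, " #", seq_along(idx)[-1L])
  }
  features$name <- nm
  rownames(features) <- NULL
  structure(features, genome_id = genome_id,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> genome %s: %d features (%s)\n",
              attr(x, "genome_id"), nrow(x),
              paste(names(summarize_annotation(x)), summarize_annotation(x),
                    sep = "=", collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x)[
    c("name", "type", "start", "end", "strand", "n_exons")], 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Count features by type
#'
#' @param ft A [feature_table()].
#' @return Named integer vector with counts for `CDS`, `tRNA` and `rRNA`.
#' @examples
#' ft <- feature_table("g", gene_feature("x", "CDS", 1, 90))
#' summarize_annotation(ft)
#' @export
summarize_annotation <- function(ft) {
  if (nrow(ft) == 0L) stop("empty feature table")
  types <- c("CDS", "tRNA", "rRNA")
  out <- vapply(types, function(t) sum(ft$type == t), 0L)
  names(out) <- types
  out
}

#' Read a feature table from GFF3 or TSV
#'
#' Two on-disk dialects are supported. GFF3 (1-based inclusive, read with
#' \pkg{rtracklayer}) represents each gene as one `CDS`/`tRNA`/`rRNA` row
#' carrying `ID`, `Name`, `n_exons` and optional `nested_in_intron_of`
#' attributes, with exon sub-intervals as `exon` rows whose `Parent` is
#' the gene `ID`. The TSV dialect mirrors the printed annotation tables:
#' header `name, type, start, end, strand, n_exons` plus optional `exons`
#' (`"s1-e1;s2-e2"`) and `nested_in_intron_of` columns.
#'
#' @param path Input file.
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"tsv"`.
#' @param genome_id Genome identifier to record; defaults to the GFF3
#'   seqid or the file name.
#' @param genome_length Optional; when given, coordinates beyond it are an
#'   error.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("auto", "gff3", "tsv"),
                               genome_id = NULL, genome_length = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  ft <- if (dialect == "gff3") read_features_gff3(path, genome_id)
        else read_features_tsv(path, genome_id)
  if (!is.null(genome_length) && nrow(ft) &&
      (any(ft$end > genome_length) || any(ft$start < 1L)))
    stop("feature coordinates outside 1..", genome_length, " in ", path)
  ft
}

read_features_tsv <- function(path, genome_id) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "type", "start", "end", "strand", "n_exons")
  if (!all(need %in% names(df)))
    stop("TSV feature dialect needs columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ex <- NULL
    if ("exons" %in% names(df) && nzchar(df$exons[i]) && !is.na(df$exons[i]))
      ex <- parse_exon_string(df$exons[i])
    nio <- if ("nested_in_intron_of" %in% names(df) &&
               !is.na(df$nested_in_intron_of[i]) &&
               nzchar(df$nested_in_intron_of[i]))
      df$nested_in_intron_of[i] else NA_character_
    gene_feature(df$name[i], df$type[i], df$start[i], df$end[i],
                 df$strand[i], df$n_exons[i], exons = ex,
                 nested_in_intron_of = nio)
  })
  feature_table(genome_id %||% basename(path), do.call(rbind, rows))
}

parse_exon_string <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
}

deparse_exon_string <- function(ex) {
  if (is.null(ex)) return("")
  paste(paste0(ex[, 1L], "-", ex[, 2L]), collapse = ";")
}

read_features_gff3 <- function(path, genome_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  is_exon <- as.character(meta$type) == "exon"
  genes <- gr[!is_exon]
  exons <- gr[is_exon]
  gm <- S4Vectors::mcols(genes)
  ids <- as.character(gm$ID)
  parent <- if (length(exons)) {
    p <- S4Vectors::mcols(exons)$Parent
    vapply(p, function(x) as.character(x)[1L], "")
  } else character(0)
  rows <- lapply(seq_along(genes), function(i) {
    kid <- exons[parent == ids[i]]
    ex <- if (length(kid))
      cbind(GenomicRanges::start(kid), GenomicRanges::end(kid)) else NULL
    nio <- if (!is.null(gm$nested_in_intron_of))
      as.character(gm$nested_in_intron_of[i]) else NA_character_
    n_ex <- if (!is.null(gm$n_exons) && !is.na(gm$n_exons[i]))
      as.integer(as.character(gm$n_exons[i]))
    else if (length(kid)) nrow(ex) else 1L
    gene_feature(as.character(gm$Name[i] %||% ids[i]),
                 as.character(gm$type[i]),
                 GenomicRanges::start(genes[i]), GenomicRanges::end(genes[i]),
                 as.character(GenomicRanges::strand(genes[i])),
                 n_ex, exons = ex, nested_in_intron_of = nio)
  })
  gid <- genome_id %||%
    (if (length(genes)) as.character(GenomicRanges::seqnames(genes[1L]))
     else basename(path))
  feature_table(gid, do.call(rbind, rows))
}

#' Write a feature table to GFF3 or TSV
#'
#' Inverse of [read_feature_table()]; `read(write(x))` is the identity on
#' valid tables.
#'
#' @param ft A [feature_table()].
#' @param path Output file.
#' @param dialect `"auto"`, `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (dialect == "tsv") {
    df <- as.data.frame(ft)[c("name", "type", "start", "end", "strand",
                              "n_exons")]
    df$exons <- vapply(ft$exons, deparse_exon_string, "")
    df$nested_in_intron_of <- ifelse(is.na(ft$nested_in_intron_of), "",
                                     ft$nested_in_intron_of)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write_features_gff3(ft, path)
  }
  invisible(path)
}

write_features_gff3 <- function(ft, path) {
  gid <- attr(ft, "genome_id")
  ids <- sprintf("feat%04d", seq_len(nrow(ft)))
  strands <- ifelse(ft$strand == "forward", "+", "-")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = gid,
    ranges = IRanges::IRanges(ft$start, ft$end),
    strand = strands,
    type = ft$type, ID = ids, Name = ft$name,
    n_exons = as.character(ft$n_exons),
    nested_in_intron_of = ft$nested_in_intron_of)
  ex_list <- lapply(seq_len(nrow(ft)), function(i) {
    ex <- ft$exons[[i]]
    if (is.null(ex)) return(NULL)
    GenomicRanges::GRanges(seqnames = gid,
                           ranges = IRanges::IRanges(ex[, 1L], ex[, 2L]),
                           strand = strands[i], type = "exon",
                           ID = paste0(ids[i], ".e", seq_len(nrow(ex))),
                           Name = NA_character_,
                           n_exons = NA_character_,
                           nested_in_intron_of = NA_character_,
                           Parent = ids[i])
  })
  ex_list <- ex_list[!vapply(ex_list, is.null, TRUE)]
  S4Vectors::mcols(gene_gr)$Parent <- NA_character_
  gr <- if (length(ex_list))
    c(gene_gr, do.call(c, ex_list)) else gene_gr
  withCallingHandlers(
    rtracklayer::export(gr, path, format = "gff3"),
    warning = function(w) {
      ## CDS phase is not modelled here; silence only that advisory
      if (grepl("phase information", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
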