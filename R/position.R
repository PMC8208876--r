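#' Classify a genomic interval against a feature table
#'
#' Any-overlap semantics with precedence `genic > intronic_orf >
#' intronic > intergenic`: sharing even a single base with an exon of a
#' top-level feature makes an interval genic; overlapping a CDS nested in
#' another gene's intron (a homing-endonuclease-style intronic ORF) makes
#' it intronic-ORF; overlapping only intron bases makes it intronic;
#' anything else is intergenic. tRNA and rRNA features count as genic.
#'
#' A feature is treated as nested when its `nested_in_intron_of` field is
#' set, or - when exon sub-intervals are available - when its span lies
#' within another feature's span without touching that feature's exons.
#' When any multi-exon feature lacks exon sub-intervals the classifier
#' degrades to a two-class genic/intergenic mode (gene spans act as
#' exonic) and flags the result `approximate`.
#'
#' @param start,end 1-based inclusive interval.
#' @param ft A [feature_table()].
#' @param genome_length Optional bound; an interval beyond it errors.
#' @return A list with `klass` (one of `"genic"`, `"intronic_orf"`,
#'   `"intronic"`, `"intergenic"`), `genes` (character vector, empty iff
#'   intergenic; intron hosts appear as `"(Intron)<gene>"`), and
#'   `approximate` (logical).
#' @export
classify_interval <- function(start, end, ft, genome_length = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid interval [", start, ", ", end, "]")
  if (!is.null(genome_length) && end > genome_length)
    stop("interval [", start, ", ", end, "] outside genome of length ",
         genome_length)
  if (nrow(ft) == 0L)
    return(list(klass = "intergenic", genes = character(0),
                approximate = FALSE))

  exact <- all(ft$n_exons == 1L |
                 !vapply(ft$exons, is.null, TRUE))
  span_hit <- ft$start <= end & ft$end >= start

  nested <- !is.na(ft$nested_in_intron_of)
  host_of <- ft$nested_in_intron_of
  if (exact) {
    exmat <- lapply(seq_len(nrow(ft)), function(i)
      feature_exons(as_feature_row(ft[i, ])))
    for (i in seq_len(nrow(ft))) {
      if (nested[i]) next
      for (j in seq_len(nrow(ft))) {
        if (i == j) next
        if (ft$start[i] >= ft$start[j] && ft$end[i] <= ft$end[j]) {
          ex <- exmat[[j]]
          touches_exon <- any(ex[, 1L] <= ft$end[i] & ex[, 2L] >= ft$start[i])
          if (!touches_exon) {
            nested[i] <- TRUE
            host_of[i] <- ft$name[j]
            break
          }
        }
      }
    }
    exon_hit <- vapply(seq_len(nrow(ft)), function(i) {
      ex <- exmat[[i]]
      any(ex[, 1L] <= end & ex[, 2L] >= start)
    }, TRUE)
  } else {
    exon_hit <- span_hit
  }

  if (!exact) {
    ## degraded two-class mode: spans act as exonic
    genes <- ft$name[span_hit]
    return(list(klass = if (length(genes)) "genic" else "intergenic",
                genes = genes, approximate = TRUE))
  }

  genic_genes <- ft$name[!nested & exon_hit & span_hit]
  orf_idx <- which(nested & exon_hit & span_hit)
  intron_idx <- which(!nested & span_hit & !exon_hit)

  genes <- character(0)
  genes <- c(genes, genic_genes)
  if (length(orf_idx))
    genes <- c(genes, ft$name[orf_idx],
               paste0("(Intron)", host_of[orf_idx]))
  if (length(intron_idx))
    genes <- c(genes, paste0("(Intron)", ft$name[intron_idx]))
  genes <- unique(genes)

  klass <- if (length(genic_genes)) "genic"
  else if (length(orf_idx)) "intronic_orf"
  else if (length(intron_idx)) "intronic"
  else "intergenic"
  list(klass = klass, genes = genes, approximate = FALSE)
}

#' Annotate an SSR catalog with positional classes
#'
#' Labels every record with [classify_interval()] and attaches summary
#' tables: per-class counts and per-gene counts of genic/intronic-ORF
#' records.
#'
#' @param catalog An `ssr_catalog` from [find_ssrs()].
#' @param ft A [feature_table()] for the same genome.
#' @param genome_length Optional genome length for bound checks.
#' @return The catalog with added columns `position_class` and `genes`
#'   (comma-joined, empty string for intergenic), plus attributes
#'   `class_counts` (named integer vector) and `gene_counts` (per-gene
#'   record counts) and `approximate` (logical).
#' @export
annotate_catalog <- function(catalog, ft, genome_length = NULL) {
  gid_c <- attr(catalog, "genome_id")
  gid_f <- attr(ft, "genome_id")
  if (!is.null(gid_c) && !is.null(gid_f) && !identical(gid_c, gid_f))
    stop("catalog genome '", gid_c, "' does not match feature table genome '",
         gid_f, "'")
  res <- lapply(seq_len(nrow(catalog)), function(i)
    classify_interval(catalog$start[i], catalog$end[i], ft, genome_length))
  catalog$position_class <- vapply(res, `[[`, "", "klass")
  catalog$genes <- vapply(res, function(r)
    paste(r$genes, collapse = ", "), "")
  classes <- c("genic", "intronic_orf", "intronic", "intergenic")
  class_counts <- vapply(classes,
                         function(k) sum(catalog$position_class == k), 0L)
  gene_lists <- lapply(res, function(r) sub("^\\(Intron\\)", "", r$genes))
  gene_counts <- sort(table(unlist(gene_lists)), decreasing = TRUE)
  structure(catalog, class_counts = class_counts,
            gene_counts = gene_counts,
            approximate = any(vapply(res, `[[`, TRUE, "approximate")))
}
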