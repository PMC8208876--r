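## category -> printed label and back
category_labels <- c(normal = "Normal SSR", extended = "Extended SSR",
                     potential = "Potential SSR")
type_labels <- stats::setNames(
  paste0(c("Mono", "Di", "Tri", "Tetra", "Penta", "Hexa", "Hepta",
           "Octa", "Nona", "Deca"), "SSR"),
  ssr_type_names)

#' Write an SSR catalog as a report TSV
#'
#' Columns mirror the published catalog layout: `No., Name, SSR type,
#' Type, Start, End, Unit sequence, Repeat number, Genes` (the `Genes`
#' column is filled when the catalog has been through
#' [annotate_catalog()], otherwise left empty).
#'
#' @param catalog An `ssr_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ssr_tsv <- function(catalog, path) {
  df <- data.frame(
    "No." = seq_len(nrow(catalog)),
    Name = catalog$ssr_id,
    "SSR type" = unname(category_labels[catalog$category]),
    Type = unname(type_labels[catalog$ssr_type]),
    Start = catalog$start, End = catalog$end,
    "Unit sequence" = catalog$unit,
    "Repeat number" = catalog$copy_number,
    Genes = if ("genes" %in% names(catalog)) catalog$genes else "",
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SSR catalog report TSV
#'
#' Inverse of [write_ssr_tsv()]; also reads published catalogs laid out
#' the same way.
#'
#' @param path TSV path.
#' @param genome_id Genome id to attach.
#' @return An `ssr_catalog` (with a `genes` column when present).
#' @export
read_ssr_tsv <- function(path, genome_id = basename(path)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cat_rev <- stats::setNames(names(category_labels), category_labels)
  type_rev <- stats::setNames(names(type_labels), type_labels)
  out <- data.frame(
    ssr_id = df$Name,
    category = unname(cat_rev[df$"SSR type"]),
    ssr_type = unname(type_rev[df$Type]),
    unit = df$"Unit sequence",
    copy_number = as.integer(df$"Repeat number"),
    start = as.integer(df$Start), end = as.integer(df$End),
    genome_id = genome_id, stringsAsFactors = FALSE)
  if ("Genes" %in% names(df))
    out$genes <- ifelse(is.na(df$Genes), "", df$Genes)
  structure(out, genome_id = genome_id,
            class = c("ssr_catalog", "data.frame"))
}

#' Write a variant table as a report TSV
#'
#' Columns: `No., Type, Coordination of multiple sequence alignments,
#' Strains, Base changes, Position`. Single-column events print one
#' coordinate, multi-column events `start-end`.
#'
#' @param events A `variant_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(events, path) {
  coord <- ifelse(events$msa_start == events$msa_end,
                  as.character(events$msa_start),
                  paste0(events$msa_start, "-", events$msa_end))
  vt <- c(SNP = "SNP", insertion = "Insertion", deletion = "Deletion")
  df <- data.frame(
    "No." = seq_len(nrow(events)),
    Type = unname(vt[events$vtype]),
    "Coordination of multiple sequence alignments" = coord,
    Strains = events$carriers,
    "Base changes" = events$base_changes,
    Position = if (is.null(events$position_note)) "" else
      events$position_note,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant report TSV
#'
#' @param path TSV path (layout of [write_variant_tsv()]).
#' @return A `variant_table`-shaped `data.frame`.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  coord <- strsplit(as.character(df$"Coordination of multiple sequence alignments"),
                    "-", fixed = TRUE)
  starts <- vapply(coord, function(x) as.integer(x[1L]), 0L)
  ends <- vapply(coord, function(x)
    as.integer(x[length(x)]), 0L)
  ch <- strsplit(df$"Base changes", " to ", fixed = TRUE)
  out <- data.frame(
    vtype = unname(c(SNP = "SNP", Insertion = "insertion",
                     Deletion = "deletion")[df$Type]),
    msa_start = starts, msa_end = ends,
    carriers = df$Strains,
    consensus_allele = vapply(ch, `[`, "", 1L),
    carrier_allele = vapply(ch, `[`, "", 2L),
    base_changes = df$"Base changes",
    position_note = df$Position,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("variant_table", "data.frame"))
}

#' Write variation summaries as a report TSV
#'
#' One row per panel, mirroring the published layout: `Species, No. of
#' mitogenomes, Aligned length (bp), No. of SNPs, SNP coverage (%),
#' No. of INDELs, INDEL coverage (%)`. Rounding is applied only here, at
#' the report boundary.
#'
#' @param summaries Named list of [variation_summary()] objects (names =
#'   panel/species labels).
#' @param path Output TSV path.
#' @param snp_digits,indel_digits Decimal places for the two coverage
#'   columns (defaults 3 and 2, the mixed precision used in print).
#' @return `path`, invisibly.
#' @export
write_variation_summary_tsv <- function(summaries, path, snp_digits = 3L,
                                        indel_digits = 2L) {
  df <- data.frame(
    Species = names(summaries),
    "No. of mitogenomes" = vapply(summaries, `[[`, 0L, "n_genomes"),
    "Aligned length (bp)" = vapply(summaries, `[[`, 0L, "aligned_length"),
    "No. of SNPs" = vapply(summaries, `[[`, 0L, "n_snps"),
    "SNP coverage (%)" = round(vapply(summaries, `[[`, 0, "snp_coverage_pct"),
                               snp_digits),
    "No. of INDELs" = vapply(summaries, `[[`, 0L, "n_indels"),
    "INDEL coverage (%)" = round(vapply(summaries, `[[`, 0,
                                        "indel_coverage_pct"), indel_digits),
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run log
#'
#' Records inputs, parameters, seed and package version alongside an
#' output artifact so every report can be re-derived from raw inputs
#' plus configuration.
#'
#' @param path Log path (JSON).
#' @param subcommand Name of the operation.
#' @param inputs Named list/vector of input paths.
#' @param params Named list of parameters (including any seed).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, subcommand, inputs = list(), params = list()) {
  log <- list(
    tool = "mitokit",
    version = as.character(utils::packageVersion("mitokit")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs, params = params)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
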