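# Independent brute-force oracles and shared fixture builders.

extdata <- function(f) system.file("extdata", f, package = "mitokit")

kr_features <- function() {
  read_feature_table(extdata("features_wbph_kr.tsv"), genome_id = "KR")
}

kr_ssr_catalog <- function() {
  read_ssr_tsv(extdata("ssr_catalog_wbph_kr.tsv"), genome_id = "KR")
}

kr_variation_rows <- function() {
  read.delim(extdata("variation_ophio.tsv"), check.names = FALSE)
}

kr_variant_rows <- function() {
  read_variant_tsv(extdata("variants_wbph.tsv"))
}

## brute-force maximal perfect tandem repeat enumerator: O(n^2 u),
## position-by-position, no run-length encoding
bf_primitive <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d != 0L) next
    if (paste(rep(substr(x, 1L, d), n / d), collapse = "") == x) return(FALSE)
  }
  TRUE
}

bf_tandem_repeats <- function(s, max_u = 10L) {
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  for (u in seq_len(max_u)) {
    if (n < 2L * u) next
    for (i in seq_len(n - 2L * u + 1L)) {
      unit <- substr(s, i, i + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      ## left-maximal: the periodic match must not extend to i-1
      if (i > 1L && chars[i - 1L] != "N" &&
          chars[i - 1L] == chars[i - 1L + u]) next
      k <- 1L
      while (i + (k + 1L) * u - 1L <= n &&
             substr(s, i + k * u, i + (k + 1L) * u - 1L) == unit)
        k <- k + 1L
      if (k < 2L) next
      if (!bf_primitive(unit)) next
      rows[[length(rows) + 1L]] <-
        data.frame(unit = unit, unit_length = u, copy_number = k,
                   start = i, end = i + k * u - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(unit = character(), unit_length = integer(),
                      copy_number = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## random primitive unit of a given length
random_primitive_unit <- function(u) {
  repeat {
    x <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE,
                      prob = c(.35, .15, .15, .35)), collapse = "")
    if (bf_primitive(x)) return(x)
  }
}

## planting spec from a published catalog: unit length is implied by the
## SSR type (span identity is authoritative); printed units that are
## truncated or non-primitive are replaced by synthesized units
planting_spec_from_catalog <- function(cat, seed = 1L) {
  set.seed(seed)
  u_target <- match(cat$ssr_type, c("mono", "di", "tri", "tetra", "penta",
                                    "hexa", "hepta", "octa", "nona", "deca"))
  unit <- cat$unit
  fix <- nchar(unit) != u_target | !vapply(unit, bf_primitive, TRUE)
  unit[fix] <- vapply(u_target[fix], random_primitive_unit, "")
  data.frame(unit = unit, copy_number = cat$copy_number,
             stringsAsFactors = FALSE)
}

## per-base extraction oracle for splicing: walk exon bases one by one
bf_splice <- function(genome, start, end, strand, exons = NULL) {
  if (is.null(exons)) exons <- matrix(c(start, end), 1L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (r in seq_len(nrow(exons)))
    for (p in exons[r, 1L]:exons[r, 2L]) out <- c(out, chars[p])
  if (strand == "reverse") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    out <- rev(unname(comp[out]))
  }
  paste(out, collapse = "")
}

## brute-force pairwise distance recount
bf_pdist <- function(r1, r2) {
  a <- strsplit(r1, "", fixed = TRUE)[[1]]
  b <- strsplit(r2, "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok]) / sum(ok)
}

random_dna <- function(n, gc = 0.3) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## feature fixture with a nested intronic ORF, exon detail present
nested_fixture <- function() {
  feature_table("toy", rbind(
    gene_feature("COX1", "CDS", 100, 1000, "reverse", n_exons = 2,
                 exons = rbind(c(100, 300), c(700, 1000))),
    gene_feature("HEG", "CDS", 350, 650, "reverse",
                 nested_in_intron_of = "COX1"),
    gene_feature("tRNA-Gly", "tRNA", 1200, 1270, "forward")))
}

## five-strain panel carrying the seven printed whole-mitogenome events:
## coordinates chosen so called events land at the printed alignment
## columns (insertion lengths 2, 10, 1; deletions 2, 3; two SNPs)
study_panel_spec <- function() {
  spec <- data.frame(
    vtype = c("insertion", "insertion", "SNP", "deletion", "SNP",
              "insertion", "deletion"),
    genome_pos = c(4208L, 27473L, 27475L, 32715L, 37562L, 38714L, 38715L),
    length = c(2L, 10L, 1L, 2L, 1L, 1L, 3L),
    alt = c("CC", "TGGGCCCCCC", "C", NA, "T", "G", NA),
    ref = c(NA, NA, "A", "CC", "A", NA, "GGG"),
    stringsAsFactors = FALSE)
  spec$carriers <- list(c("KR.1D", "KR.5D"), "KR.1D", "KR.1D", "KR.5D",
                        "KR.5D", "KR.1D", "KR.5D")
  spec
}

study_panel <- function(seed = 2024L) {
  anc <- generate_genome(55393L, 0.307, seed = seed, id = "KR")
  derive_strain_panel(anc, study_panel_spec(),
                      strains = c("KR", "KR.1D", "KR.5D", "KR.11D", "WGS"),
                      seed = seed)
}
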