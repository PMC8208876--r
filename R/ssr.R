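#' SSR detection and classification settings
#'
#' Defaults implement the three-tier scheme used for organellar genomes:
#' units of 1-6 bp whose total repeat length reaches at least 10 bp are
#' *normal* SSRs; units of 7-10 bp at two or more copies are *extended*
#' SSRs; and 5-6 bp units at exactly two copies are *potential* SSRs.
#' The length threshold is inclusive (>= 10 bp): published catalogs under
#' this scheme contain 10 bp records (a mononucleotide run of 10, a
#' dinucleotide at 5 copies), so "exceeds 10 bp" is read as reaching it.
#'
#' @param min_total_length_normal Minimum total span (bp) for a normal
#'   SSR; default 10.
#' @param normal_unit_range,extended_unit_range Inclusive unit-length
#'   ranges (bp) for the normal and extended tiers.
#' @param potential_unit_lengths Unit lengths eligible for the potential
#'   tier.
#' @param potential_copy_number Copy number defining the potential tier.
#' @param require_primitive_unit Re-express periodic units by their
#'   primitive unit (`"ATAT" x k` becomes `"AT" x 2k`); default `TRUE`.
#' @param scan_wraps_origin Reserved; origin-spanning scans are not
#'   performed (`FALSE`).
#' @return A list of class `ssr_config`.
#' @export
ssr_config <- function(min_total_length_normal = 10L,
                       normal_unit_range = c(1L, 6L),
                       extended_unit_range = c(7L, 10L),
                       potential_unit_lengths = c(5L, 6L),
                       potential_copy_number = 2L,
                       require_primitive_unit = TRUE,
                       scan_wraps_origin = FALSE) {
  stopifnot(min_total_length_normal >= 2L,
            length(normal_unit_range) == 2L,
            length(extended_unit_range) == 2L,
            normal_unit_range[1L] <= normal_unit_range[2L],
            extended_unit_range[1L] <= extended_unit_range[2L],
            normal_unit_range[2L] < extended_unit_range[1L])
  if (isTRUE(scan_wraps_origin))
    stop("origin-wrapping scans are not supported")
  structure(list(
    min_total_length_normal = as.integer(min_total_length_normal),
    normal_unit_range = as.integer(normal_unit_range),
    extended_unit_range = as.integer(extended_unit_range),
    potential_unit_lengths = as.integer(potential_unit_lengths),
    potential_copy_number = as.integer(potential_copy_number),
    require_primitive_unit = isTRUE(require_primitive_unit),
    scan_wraps_origin = FALSE), class = "ssr_config")
}

## TRUE if unit is not a whole-number repetition of a shorter string
is_primitive_unit <- function(unit) {
  vapply(unit, function(x) {
    n <- nchar(x)
    if (n <= 1L) return(TRUE)
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          identical(strrep(substr(x, 1L, d), n / d), x)) return(FALSE)
    }
    TRUE
  }, TRUE, USE.NAMES = FALSE)
}

#' Enumerate maximal perfect tandem repeats
#'
#' Scans a DNA string for perfect (exact-copy) tandem repeats of primitive
#' units of 1-10 bp. Every reported repeat is maximal (it cannot be
#' extended by a full unit on either side), left-anchored (`start` is the
#' first base of the first full copy) and carries the length of any
#' trailing partial copy. `N` bases never participate in a repeat.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param config An [ssr_config()].
#' @return A `data.frame` with columns `unit`, `unit_length`,
#'   `copy_number`, `start`, `end`, `trailing_partial_length`, sorted by
#'   `start` then `unit_length`. Candidates have >= 2 full copies.
#' @examples
#' find_tandem_repeats("GACACACACACG")
#' @export
find_tandem_repeats <- function(sequence, config = ssr_config()) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 1L) stop("empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  valid <- chars != "N"
  max_u <- config$extended_unit_range[2L]
  out <- vector("list", max_u)
  for (u in seq_len(max_u)) {
    if (n < 2L * u) break
    i <- seq_len(n - u)
    eq <- chars[i] == chars[i + u] & valid[i] & valid[i + u]
    r <- rle(eq)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    keep <- r$values & (r$lengths + u) >= 2L * u
    if (!any(keep)) next
    st <- starts_r[keep]
    L <- r$lengths[keep]
    copies <- (L + u) %/% u
    trailing <- (L + u) %% u
    unit <- substring(s, st, st + u - 1L)
    cand <- data.frame(unit = unit, unit_length = u, copy_number = copies,
                       start = st, end = st + copies * u - 1L,
                       trailing_partial_length = trailing,
                       stringsAsFactors = FALSE)
    if (config$require_primitive_unit && u > 1L)
      cand <- cand[is_primitive_unit(cand$unit), , drop = FALSE]
    out[[u]] <- cand
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(unit = character(), unit_length = integer(),
                      copy_number = integer(), start = integer(),
                      end = integer(), trailing_partial_length = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify tandem-repeat candidates into SSR tiers
#'
#' Applies the three-tier rule: units within the normal range whose total
#' length reaches the threshold are `"normal"`, unless the unit length is
#' in the potential set at exactly the potential copy number, which makes
#' them `"potential"`; units in the extended range at >= 2 copies are
#' `"extended"`; anything else is rejected (`NA`). With the defaults the
#' implied minimum copy numbers for normal SSRs are 10 (mono), 5 (di),
#' 4 (tri), 3 (tetra), 3 (penta) and 3 (hexa).
#'
#' @param unit_length Integer vector of unit lengths (bp).
#' @param copy_number Integer vector of full copy counts.
#' @param config An [ssr_config()].
#' @return Character vector: `"normal"`, `"extended"`, `"potential"` or
#'   `NA` (rejected).
#' @examples
#' classify_ssr(6, 2:3) # potential, normal
#' @export
classify_ssr <- function(unit_length, copy_number, config = ssr_config()) {
  u <- as.integer(unit_length); k <- as.integer(copy_number)
  total <- u * k
  out <- rep(NA_character_, length(u))
  pot <- u %in% config$potential_unit_lengths &
    k == config$potential_copy_number
  norm <- u >= config$normal_unit_range[1L] &
    u <= config$normal_unit_range[2L] &
    total >= config$min_total_length_normal & !pot
  ext <- u >= config$extended_unit_range[1L] &
    u <= config$extended_unit_range[2L] & k >= 2L
  out[pot] <- "potential"
  out[norm] <- "normal"
  out[ext] <- "extended"
  out
}

#' Detect and classify SSRs in a genome
#'
#' Composes [find_tandem_repeats()] and [classify_ssr()], resolves
#' overlaps among accepted records, and assigns catalog ids. Overlap
#' policy: records are ranked by total length (longer first), then unit
#' length (smaller first), then start (leftmost first); a record whose
#' span overlaps an already accepted record is suppressed, which in
#' particular suppresses records wholly contained in an accepted span.
#' Ids use per-type prefixes (`M`, `D`, `T`, `Te`, `P`, `H`, `cHp`, `O`,
#' `N`, `De`) with a zero-padded ordinal in start order; normal and
#' potential records of the same unit length share one id series.
#'
#' @param genome A [mitogenome()] or DNA string.
#' @param config An [ssr_config()].
#' @return An `ssr_catalog`: a `data.frame` with columns `ssr_id`,
#'   `category`, `ssr_type`, `unit`, `copy_number`, `start`, `end`,
#'   `genome_id`, sorted by `start`, plus a `genome_id` attribute.
#' @export
find_ssrs <- function(genome, config = ssr_config()) {
  if (is.character(genome)) genome <- mitogenome("seq", genome)
  cand <- find_tandem_repeats(genome$sequence, config)
  cand$category <- classify_ssr(cand$unit_length, cand$copy_number, config)
  acc <- cand[!is.na(cand$category), , drop = FALSE]
  ## overlap resolution: greedy by (total length desc, unit asc, start asc)
  if (nrow(acc) > 1L) {
    len <- acc$end - acc$start + 1L
    ord <- order(-len, acc$unit_length, acc$start)
    acc <- acc[ord, , drop = FALSE]
    keep <- logical(nrow(acc))
    occ_start <- integer(0); occ_end <- integer(0)
    for (i in seq_len(nrow(acc))) {
      if (!any(acc$start[i] <= occ_end & acc$end[i] >= occ_start)) {
        keep[i] <- TRUE
        occ_start <- c(occ_start, acc$start[i])
        occ_end <- c(occ_end, acc$end[i])
      }
    }
    acc <- acc[keep, , drop = FALSE]
  }
  acc <- acc[order(acc$start), , drop = FALSE]
  acc$ssr_type <- ssr_type_names[acc$unit_length]
  ids <- character(nrow(acc))
  for (tp in unique(acc$ssr_type)) {
    idx <- which(acc$ssr_type == tp)
    ids[idx] <- sprintf("%s%07d", ssr_id_prefixes[[tp]], seq_along(idx))
  }
  out <- data.frame(ssr_id = ids, category = acc$category,
                    ssr_type = acc$ssr_type, unit = acc$unit,
                    copy_number = acc$copy_number, start = acc$start,
                    end = acc$end, genome_id = rep(genome$id, nrow(acc)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, genome_id = genome$id, config = config,
            class = c("ssr_catalog", "data.frame"))
}

#' @export
print.ssr_catalog <- function(x, ...) {
  cat(sprintf("<ssr_catalog> genome %s: %d records (%d normal, %d extended, %d potential)\n",
              attr(x, "genome_id"), nrow(x), sum(x$category == "normal"),
              sum(x$category == "extended"), sum(x$category == "potential")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Tabulate an SSR catalog by unit-length type
#'
#' Mirrors the published per-genome count layout: one row per type from
#' mono to deca with normal+extended counts, and potential counts for the
#' 5-6 bp types.
#'
#' @param catalog An `ssr_catalog` from [find_ssrs()].
#' @return A `data.frame` with columns `ssr_type`, `normal_extended`,
#'   `potential`, with attribute `subtotals` (named vector
#'   `normal_extended`, `potential`).
#' @export
count_by_type <- function(catalog) {
  ne <- catalog[catalog$category %in% c("normal", "extended"), , drop = FALSE]
  po <- catalog[catalog$category == "potential", , drop = FALSE]
  cnt <- function(df) vapply(ssr_type_names,
                             function(t) sum(df$ssr_type == t), 0L)
  out <- data.frame(ssr_type = ssr_type_names,
                    normal_extended = cnt(ne), potential = cnt(po),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, subtotals = c(normal_extended = nrow(ne),
                               potential = nrow(po)))
}

#' Maximum SSR length in a catalog
#'
#' Longest total span among normal and extended records, in bp.
#'
#' @param catalog An `ssr_catalog`.
#' @return Integer length in bp.
#' @export
max_ssr_length <- function(catalog) {
  ne <- catalog[catalog$category %in% c("normal", "extended"), , drop = FALSE]
  if (nrow(ne) == 0L) stop("no normal or extended SSR records in catalog")
  max(ne$end - ne$start + 1L)
}
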