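#' Locus splice catalogs
#'
#' A `locus_catalog` is the curated splice model of one gene locus: its
#' exons (canonical, alternative-first, cryptic), the splice junctions
#' joining them, and the mapping from junction events to the candidate
#' splice-variant transcripts they diagnose. For the androgen receptor
#' the shipped example (`system.file("extdata", "ar_example.tsv",
#' package = "arvscan")`) encodes exons 1, 1a, 2-9 and cryptic exons
#' CE1/CE3/CE4/CE5, with the exon 3-CE3 junction (AR-V7) as the headline
#' target event and the first junctions 1-2 and 1a-2 as the
#' normalization references.
#'
#' Coordinates are 1-based inclusive in the TSV file (the common
#' annotation-interchange convention) and 0-based half-open internally.
#' Each junction's genomic gap is derived from its flanking exons:
#' `gap_start` is the upstream exon's end, `gap_end` the downstream
#' exon's start, so the gap abuts both exons exactly. Junction identity
#' is the exact gap interval; there is no fuzzy matching.
#'
#' @name locus_catalog
NULL

.exon_roles <- c("canonical", "alternative_first", "cryptic")
.junction_classes <- c("canonical", "cryptic_exon", "exon_skipping",
                       "alternative_first")

#' Construct and validate a locus catalog
#'
#' @param locus_name name of the locus (e.g. "AR").
#' @param chrom reference sequence name all exons live on.
#' @param strand "+" or "-" (metadata only; matching is coordinate-based).
#' @param exons data.frame with columns `id`, `start`, `end` (0-based
#'   half-open), `role` (one of canonical, alternative_first, cryptic).
#' @param junctions data.frame with columns `label` ("U-D"),
#'   `upstream_exon`, `downstream_exon`, `class`, `candidate_variants`
#'   (semicolon-separated, may be empty).
#' @param reference_junctions character vector of junction labels whose
#'   summed counts form the normalization denominator.
#' @param target_event junction label of the headline ratio numerator.
#' @return a validated object of class `locus_catalog` with junction gap
#'   intervals derived from the exon bounds.
#' @export
locus_catalog <- function(locus_name, chrom, strand, exons, junctions,
                          reference_junctions, target_event) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  junctions <- as.data.frame(junctions, stringsAsFactors = FALSE)
  if (anyDuplicated(exons$id))
    arv_stop("duplicate exon id(s) in catalog", "arvscan_catalog_error")
  if (anyDuplicated(junctions$label))
    arv_stop("duplicate junction label(s) in catalog", "arvscan_catalog_error")
  if (!all(exons$role %in% .exon_roles))
    arv_stop(sprintf("unknown exon role(s): %s",
                     paste(setdiff(exons$role, .exon_roles), collapse = ", ")),
             "arvscan_catalog_error")
  if (!all(junctions$class %in% .junction_classes))
    arv_stop(sprintf("unknown junction class(es): %s",
                     paste(setdiff(junctions$class, .junction_classes),
                           collapse = ", ")),
             "arvscan_catalog_error")
  if (any(exons$start >= exons$end))
    arv_stop("exon with start >= end", "arvscan_catalog_error")
  if (!strand %in% c("+", "-"))
    arv_stop("strand must be '+' or '-'", "arvscan_catalog_error")

  dangling <- setdiff(c(junctions$upstream_exon, junctions$downstream_exon),
                      exons$id)
  if (length(dangling))
    arv_stop(sprintf("junction references nonexistent exon(s): %s",
                     paste(unique(dangling), collapse = ", ")),
             "arvscan_catalog_error")

  up <- match(junctions$upstream_exon, exons$id)
  dn <- match(junctions$downstream_exon, exons$id)
  junctions$gap_start <- exons$end[up]
  junctions$gap_end <- exons$start[dn]
  if (any(junctions$gap_start >= junctions$gap_end))
    arv_stop("junction with gap_start >= gap_end (exons out of order?)",
             "arvscan_catalog_error")
  key <- paste(junctions$gap_start, junctions$gap_end)
  if (anyDuplicated(key))
    arv_stop("two junctions share an identical genomic gap",
             "arvscan_catalog_error")

  if (is.null(junctions$candidate_variants))
    junctions$candidate_variants <- ""
  junctions$candidate_variants[is.na(junctions$candidate_variants)] <- ""

  missing_lab <- setdiff(c(reference_junctions, target_event),
                         junctions$label)
  if (length(missing_lab))
    arv_stop(sprintf("reference/target label(s) not in catalog: %s",
                     paste(missing_lab, collapse = ", ")),
             "arvscan_catalog_error")

  structure(
    list(locus_name = locus_name, chrom = chrom, strand = strand,
         exons = exons[, c("id", "start", "end", "role")],
         junctions = junctions[, c("label", "upstream_exon",
                                   "downstream_exon", "gap_start", "gap_end",
                                   "class", "candidate_variants")],
         reference_junctions = reference_junctions,
         target_event = target_event),
    class = "locus_catalog"
  )
}

#' Load a locus catalog from TSV
#'
#' The file holds three record types distinguished by a `record` column:
#' `meta` (locus_name, strand, reference_junctions as a semicolon list,
#' target_event), `exon` (id, chrom, start_1based, end_1based, role) and
#' `junction` (label, upstream_exon, downstream_exon, class,
#' candidate_variants as a semicolon list). `#` comment lines are
#' ignored; a header row is required. Coordinates in the file are
#' 1-based inclusive and converted to 0-based half-open on load.
#'
#' @param path path to the catalog TSV.
#' @return a validated [locus_catalog].
#' @export
#' @examples
#' cat_path <- system.file("extdata", "ar_example.tsv", package = "arvscan")
#' ar <- load_catalog(cat_path)
#' ar$target_event
load_catalog <- function(path) {
  if (!file.exists(path))
    arv_stop(sprintf("catalog file not found: %s", path),
             "arvscan_input_error")
  tab <- read_tsv_plain(path, colClasses = "character")
  need <- c("record", "id", "chrom", "start_1based", "end_1based", "role",
            "label", "upstream_exon", "downstream_exon", "class",
            "candidate_variants", "locus_name", "strand",
            "reference_junctions", "target_event")
  if (!all(need %in% names(tab)))
    arv_stop(sprintf("catalog TSV missing column(s): %s",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "arvscan_catalog_error")

  meta <- tab[tab$record == "meta", , drop = FALSE]
  if (nrow(meta) != 1L)
    arv_stop("catalog must contain exactly one meta row",
             "arvscan_catalog_error")
  ex <- tab[tab$record == "exon", , drop = FALSE]
  jn <- tab[tab$record == "junction", , drop = FALSE]
  if (nrow(ex) == 0L || nrow(jn) == 0L)
    arv_stop("catalog needs at least one exon and one junction row",
             "arvscan_catalog_error")
  chroms <- unique(ex$chrom)
  if (length(chroms) != 1L)
    arv_stop("all catalog exons must be on one chromosome",
             "arvscan_catalog_error")

  start1 <- suppressWarnings(as.integer(ex$start_1based))
  end1 <- suppressWarnings(as.integer(ex$end_1based))
  if (anyNA(start1) || anyNA(end1))
    arv_stop("non-integer exon coordinates in catalog",
             "arvscan_catalog_error")

  locus_catalog(
    locus_name = meta$locus_name,
    chrom = chroms,
    strand = meta$strand,
    exons = data.frame(id = ex$id, start = start1 - 1L, end = end1,
                       role = ex$role, stringsAsFactors = FALSE),
    junctions = data.frame(label = jn$label,
                           upstream_exon = jn$upstream_exon,
                           downstream_exon = jn$downstream_exon,
                           class = jn$class,
                           candidate_variants = jn$candidate_variants,
                           stringsAsFactors = FALSE),
    reference_junctions = strsplit(meta$reference_junctions, ";",
                                   fixed = TRUE)[[1]],
    target_event = meta$target_event
  )
}

#' Write a locus catalog to TSV
#'
#' Inverse of [load_catalog()]: coordinates are converted back to
#' 1-based inclusive, so `load_catalog(write_catalog(x, f))` reproduces
#' `x` field for field.
#'
#' @param catalog a [locus_catalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "locus_catalog"))
  blank <- ""
  meta <- data.frame(record = "meta", id = blank, chrom = blank,
                     start_1based = blank, end_1based = blank, role = blank,
                     label = blank, upstream_exon = blank,
                     downstream_exon = blank, class = blank,
                     candidate_variants = blank,
                     locus_name = catalog$locus_name,
                     strand = catalog$strand,
                     reference_junctions = paste(catalog$reference_junctions,
                                                 collapse = ";"),
                     target_event = catalog$target_event,
                     stringsAsFactors = FALSE)
  ex <- catalog$exons
  exon_rows <- data.frame(record = "exon", id = ex$id, chrom = catalog$chrom,
                          start_1based = ex$start + 1L, end_1based = ex$end,
                          role = ex$role, label = blank,
                          upstream_exon = blank, downstream_exon = blank,
                          class = blank, candidate_variants = blank,
                          locus_name = blank, strand = blank,
                          reference_junctions = blank, target_event = blank,
                          stringsAsFactors = FALSE)
  jn <- catalog$junctions
  junc_rows <- data.frame(record = "junction", id = blank, chrom = blank,
                          start_1based = blank, end_1based = blank,
                          role = blank, label = jn$label,
                          upstream_exon = jn$upstream_exon,
                          downstream_exon = jn$downstream_exon,
                          class = jn$class,
                          candidate_variants = jn$candidate_variants,
                          locus_name = blank, strand = blank,
                          reference_junctions = blank, target_event = blank,
                          stringsAsFactors = FALSE)
  out <- rbind(meta, exon_rows, junc_rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Look up a catalog junction by its exact genomic gap
#'
#' @param catalog a [locus_catalog].
#' @param gap_start,gap_end 0-based half-open interval of a splice gap.
#' @return a one-row data.frame (the matching junction) or `NULL` when
#'   no catalog junction has exactly this gap.
#' @export
junction_for_gap_key <- function(catalog, gap_start, gap_end) {
  jn <- catalog$junctions
  hit <- which(jn$gap_start == gap_start & jn$gap_end == gap_end)
  if (length(hit) == 0L) return(NULL)
  jn[hit, , drop = FALSE]
}

#' Event-to-variant map of a catalog
#'
#' Junctions that carry candidate variant names, one row per event.
#'
#' @param catalog a [locus_catalog].
#' @return data.frame with `event_label` and `candidate_variants`
#'   (semicolon-separated).
#' @export
event_variant_map <- function(catalog) {
  jn <- catalog$junctions
  ev <- jn[nzchar(jn$candidate_variants), c("label", "candidate_variants")]
  names(ev) <- c("event_label", "candidate_variants")
  rownames(ev) <- NULL
  ev
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("locus_catalog '%s' (%s, strand %s)\n",
              x$locus_name, x$chrom, x$strand))
  cat(sprintf("  %d exons, %d junctions\n", nrow(x$exons), nrow(x$junctions)))
  cat(sprintf("  target event: %s; reference junctions: %s\n",
              x$target_event, paste(x$reference_junctions, collapse = " + ")))
  invisible(x)
}
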