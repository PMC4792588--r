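#' Junction-spanning read counting and event calling
#'
#' Each filtered splice gap that matches a catalog junction exactly (by
#' its genomic gap interval) adds one spanning read to that junction's
#' count for the read's sample. A read with two matching gaps increments
#' two junctions; gapless reads and non-matching gaps contribute
#' nothing. An event is called detected in a sample when its junction
#' accumulates at least `min_reads` spanning reads (default 1).
#'
#' @name detection
NULL

#' Count junction-spanning reads per sample
#'
#' @param reads data.frame of alignments as returned by
#'   [read_alignments()] (possibly concatenated over samples).
#' @param catalog a [locus_catalog].
#' @param cfg a [filter_config].
#' @return data.frame (long form) with one row per (sample_id, junction)
#'   for every catalog junction, columns `sample_id`, `junction_label`,
#'   `class`, `count`. Absent evidence is an explicit 0.
#' @export
count_junctions <- function(reads, catalog, cfg = filter_config()) {
  stopifnot(inherits(catalog, "locus_catalog"))
  jn <- catalog$junctions
  samples <- unique(reads$sample_id)
  if (nrow(reads)) {
    bad <- unique(reads$chrom[reads$chrom != catalog$chrom])
    if (length(bad))
      arv_stop(sprintf(
        "alignments on '%s' do not match catalog chromosome '%s'",
        paste(bad, collapse = ","), catalog$chrom), "arvscan_input_error")
  }

  counts <- matrix(0L, nrow = length(samples), ncol = nrow(jn),
                   dimnames = list(samples, jn$label))
  gap_key <- paste(jn$gap_start, jn$gap_end)

  # only gapped reads can contribute; skip the rest up front
  gapped <- grepl("N", reads$cigar, fixed = TRUE)
  if (cfg$drop_mapq0) gapped <- gapped & reads$mapq > 0L
  if (cfg$drop_secondary)
    gapped <- gapped & !reads$is_secondary & !reads$is_supplementary
  for (i in which(gapped)) {
    g <- extract_gaps(reads$pos[i], reads$cigar[i])
    ok <- pmin(g$left_overhang, g$right_overhang) >= cfg$min_overhang
    hit <- match(paste(g$gap_start, g$gap_end)[ok], gap_key)
    hit <- hit[!is.na(hit)]
    for (j in hit) counts[reads$sample_id[i], j] <- counts[reads$sample_id[i], j] + 1L
  }

  out <- data.frame(
    sample_id = rep(samples, each = nrow(jn)),
    junction_label = rep(jn$label, times = length(samples)),
    class = rep(jn$class, times = length(samples)),
    count = as.integer(t(counts)),
    stringsAsFactors = FALSE
  )
  if (length(samples) == 0L) out <- out[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call splice events from a junction count table
#'
#' An event is detected in a sample when at least `min_reads` reads span
#' its junction. Candidate variant transcripts (several variants may
#' share one junction, e.g. the 3-CE1 event) are carried along from the
#' catalog's event map and never resolved to a single variant.
#'
#' @param counts count table from [count_junctions()].
#' @param catalog a [locus_catalog].
#' @param min_reads detection threshold in spanning reads (default 1;
#'   must be >= 1).
#' @return data.frame with `sample_id`, `event_label`, `count`,
#'   `detected` (logical), `candidate_variants`.
#' @export
call_events <- function(counts, catalog, min_reads = 1L) {
  stopifnot(inherits(catalog, "locus_catalog"))
  min_reads <- as.integer(min_reads)
  if (is.na(min_reads) || min_reads < 1L)
    arv_stop("min_reads must be an integer >= 1", "arvscan_parameter_error")
  unknown <- setdiff(counts$junction_label, catalog$junctions$label)
  if (length(unknown))
    arv_stop(sprintf("count table has junction(s) not in catalog: %s",
                     paste(unknown, collapse = ", ")),
             "arvscan_input_error")
  idx <- match(counts$junction_label, catalog$junctions$label)
  data.frame(
    sample_id = counts$sample_id,
    event_label = counts$junction_label,
    count = counts$count,
    detected = counts$count >= min_reads,
    candidate_variants = catalog$junctions$candidate_variants[idx],
    stringsAsFactors = FALSE
  )
}
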