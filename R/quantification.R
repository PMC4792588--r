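#' Normalized variant ratios, cohort frequencies and correlations
#'
#' No splice junction is unique to the full-length transcript, so
#' target-event reads (e.g. exon 3-CE3, diagnostic of AR-V7) are scaled
#' by the summed reads over the locus's first splice junctions (exon 1-2
#' plus exon 1a-2), which every transcript isoform crosses. To avoid
#' inflated ratios in samples with little locus expression, a sample is
#' flagged `included` only when its reference junctions carry at least
#' `min_ref_reads` spanning reads (default 10). The inclusion filter
#' applies to ratio reporting only; event detection stays at the
#' >= 1-read rule.
#'
#' @name quantification
NULL

#' Normalized target-event ratio per sample
#'
#' @param counts count table from [count_junctions()].
#' @param catalog a [locus_catalog] defining `reference_junctions` and
#'   `target_event`.
#' @param min_ref_reads minimum summed reference-junction reads for a
#'   sample to be included in ratio reporting (default 10; must be >= 1).
#' @return data.frame with `sample_id`, `target_count`, `reference_sum`,
#'   `ratio` (NA when `reference_sum` is 0) and `included`.
#' @export
normalized_ratio <- function(counts, catalog, min_ref_reads = 10L) {
  stopifnot(inherits(catalog, "locus_catalog"))
  min_ref_reads <- as.integer(min_ref_reads)
  if (is.na(min_ref_reads) || min_ref_reads < 1L)
    arv_stop("min_ref_reads must be an integer >= 1",
             "arvscan_parameter_error")
  samples <- unique(counts$sample_id)
  is_ref <- counts$junction_label %in% catalog$reference_junctions
  is_tgt <- counts$junction_label == catalog$target_event
  ref_sum <- vapply(samples, function(s)
    sum(counts$count[is_ref & counts$sample_id == s]), 0L)
  tgt <- vapply(samples, function(s)
    sum(counts$count[is_tgt & counts$sample_id == s]), 0L)
  data.frame(
    sample_id = samples,
    target_count = tgt,
    reference_sum = ref_sum,
    ratio = ifelse(ref_sum > 0L, tgt / ref_sum, NA_real_),
    included = ref_sum >= min_ref_reads,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cohort positivity frequencies per group and event
#'
#' @param calls event calls from [call_events()] (or any data.frame with
#'   `sample_id`, `event_label`, `detected`).
#' @param groups data.frame with `sample_id` and `group` assigning every
#'   called sample to a cohort group (e.g. tumor/normal or subtype).
#' @return data.frame with `group`, `event_label`, `n_positive`,
#'   `n_total` and `percent` (half-up, one decimal).
#' @export
cohort_frequency <- function(calls, groups) {
  missing_g <- setdiff(unique(calls$sample_id), groups$sample_id)
  if (length(missing_g))
    arv_stop(sprintf("sample(s) without a group label: %s",
                     paste(missing_g, collapse = ", ")),
             "arvscan_input_error")
  grp <- groups$group[match(calls$sample_id, groups$sample_id)]
  df <- data.frame(group = grp, event_label = calls$event_label,
                   detected = calls$detected, stringsAsFactors = FALSE)
  pos <- stats::aggregate(detected ~ group + event_label, df, sum)
  tot <- stats::aggregate(detected ~ group + event_label, df, length)
  out <- data.frame(
    group = pos$group, event_label = pos$event_label,
    n_positive = as.integer(pos$detected), n_total = as.integer(tot$detected),
    percent = round_half_up(100 * pos$detected / tot$detected, 1),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$group, out$event_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between two junctions' counts across samples
#'
#' @param counts count table from [count_junctions()].
#' @param label_x,label_y junction labels to correlate.
#' @param method "spearman" (default; average ranks on ties) or
#'   "pearson".
#' @return correlation coefficient in `[-1, 1]`.
#' @export
count_correlation <- function(counts, label_x, label_y,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  samples <- unique(counts$sample_id)
  x <- vapply(samples, function(s)
    sum(counts$count[counts$sample_id == s &
                       counts$junction_label == label_x]), 0L)
  y <- vapply(samples, function(s)
    sum(counts$count[counts$sample_id == s &
                       counts$junction_label == label_y]), 0L)
  if (length(samples) < 3L)
    arv_stop("need at least 3 samples for a correlation",
             "arvscan_input_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    arv_stop("correlation undefined: constant count vector",
             "arvscan_input_error")
  stats::cor(x, y, method = method)
}
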