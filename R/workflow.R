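#' End-to-end workflow commands
#'
#' Thin composition layer over the catalog, detection, quantification
#' and qPCR modules: each command reads its inputs, runs the pipeline
#' stages, and writes sorted, diff-friendly TSVs with a deterministic
#' `#`-prefixed provenance header echoing the parameters actually
#' applied. On any error, partially written outputs are removed. A
#' command-line front end with the same commands ships at
#' `system.file("cli", "arvscan", package = "arvscan")`.
#'
#' @name workflow
NULL

# Run `writer` (which returns the paths it wrote); on error remove
# everything written so far and rethrow.
.with_cleanup <- function(paths, expr) {
  tryCatch(expr, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop(e)
  })
}

#' Scan SAM alignments against a catalog
#'
#' @param sam_paths character vector of SAM files (one sample each,
#'   sample id = file name stem) or a directory containing `*.sam`.
#' @param catalog_path path to a catalog TSV, or a [locus_catalog].
#' @param out_dir output directory for `counts.tsv`, `calls.tsv` and
#'   `ratios.tsv` (created if missing).
#' @param cfg a [filter_config].
#' @param min_reads detection threshold (default 1).
#' @param min_ref_reads ratio inclusion threshold (default 10).
#' @return invisibly, a list with `counts`, `calls` and `ratios`
#'   data.frames.
#' @export
scan_cohort <- function(sam_paths, catalog_path, out_dir,
                        cfg = filter_config(), min_reads = 1L,
                        min_ref_reads = 10L) {
  catalog <- if (inherits(catalog_path, "locus_catalog")) catalog_path
  else load_catalog(catalog_path)
  if (length(sam_paths) == 1L && dir.exists(sam_paths))
    sam_paths <- sort(list.files(sam_paths, pattern = "\\.sam$",
                                 full.names = TRUE))
  if (length(sam_paths) == 0L)
    arv_stop("no SAM files to scan", "arvscan_input_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- file.path(out_dir, c("counts.tsv", "calls.tsv", "ratios.tsv"))
  .with_cleanup(outs, {
    reads <- do.call(rbind, lapply(sam_paths, read_alignments))
    counts <- count_junctions(reads, catalog, cfg)
    counts <- counts[order(counts$sample_id, counts$junction_label), ]
    calls <- call_events(counts, catalog, min_reads = min_reads)
    ratios <- normalized_ratio(counts, catalog,
                               min_ref_reads = min_ref_reads)
    ratios <- ratios[order(ratios$sample_id), ]
    params <- list(catalog = catalog$locus_name,
                   min_overhang = cfg$min_overhang,
                   drop_mapq0 = cfg$drop_mapq0,
                   drop_secondary = cfg$drop_secondary,
                   min_reads = min_reads, min_ref_reads = min_ref_reads)
    calls_out <- calls
    calls_out$detected <- as.integer(calls_out$detected)
    ratios_out <- ratios
    ratios_out$included <- as.integer(ratios_out$included)
    write_tsv_provenance(counts, outs[1], params)
    write_tsv_provenance(calls_out, outs[2], params)
    write_tsv_provenance(ratios_out, outs[3], params)
    invisible(list(counts = counts, calls = calls, ratios = ratios))
  })
}

#' Summarize event calls into per-group positivity frequencies
#'
#' @param calls_path `calls.tsv` from [scan_cohort()] (or a calls
#'   data.frame).
#' @param groups_path TSV with columns `sample_id`, `group` (or a
#'   data.frame).
#' @param out_path output `summary.tsv` path, or NULL to skip writing.
#' @return invisibly, the summary data.frame.
#' @export
summarize_calls <- function(calls_path, groups_path, out_path = NULL) {
  calls <- if (is.data.frame(calls_path)) calls_path
  else read_tsv_plain(calls_path)
  groups <- if (is.data.frame(groups_path)) groups_path
  else read_tsv_plain(groups_path)
  if (!is.logical(calls$detected)) calls$detected <- calls$detected != 0
  extra <- setdiff(groups$sample_id, unique(calls$sample_id))
  if (length(extra))
    arv_stop(sprintf("groups file names unknown sample(s): %s",
                     paste(extra, collapse = ", ")),
             "arvscan_input_error")
  smry <- cohort_frequency(calls, groups)
  if (!is.null(out_path))
    .with_cleanup(out_path, write_tsv_provenance(smry, out_path))
  invisible(smry)
}

#' qPCR quantification command
#'
#' Fits one standard curve per target present in the standards table,
#' converts sample Cqs to absolute copies, calls Cq-cutoff positivity,
#' and (when the Cq table carries two conditions) computes
#' reference-normalized fold changes treated vs control.
#'
#' @param standards_path TSV with `target`, `copies`, `cq` (or a
#'   data.frame).
#' @param cq_path TSV with `sample_id`, `target`, `condition`,
#'   `replicate`, `cq`; empty cq = undetected (or a data.frame).
#' @param out_dir output directory for `copies.tsv`, `positivity.tsv`
#'   and (when applicable) `fold_change.tsv`.
#' @param cutoff strict Cq positivity cutoff (default 35).
#' @param reference reference gene for fold changes (default "GAPDH").
#' @param treated,control condition labels for the fold-change contrast
#'   (defaults "treated" / "vehicle").
#' @return invisibly, list with `curves`, `copies`, `positivity` and
#'   (possibly NULL) `fold_change`.
#' @export
run_qpcr <- function(standards_path, cq_path, out_dir, cutoff = 35,
                     reference = "GAPDH", treated = "treated",
                     control = "vehicle") {
  standards <- if (is.data.frame(standards_path)) standards_path
  else read_tsv_plain(standards_path)
  cq_tab <- if (is.data.frame(cq_path)) cq_path
  else read_tsv_plain(cq_path)
  if (is.null(cq_tab$condition)) cq_tab$condition <- "none"
  cq_tab$cq <- suppressWarnings(as.numeric(cq_tab$cq))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- file.path(out_dir,
                    c("copies.tsv", "positivity.tsv", "fold_change.tsv"))
  .with_cleanup(outs, {
    quant_targets <- setdiff(unique(cq_tab$target), reference)
    no_std <- setdiff(quant_targets, unique(standards$target))
    if (length(no_std))
      arv_stop(sprintf("no standards for target(s): %s",
                       paste(no_std, collapse = ", ")),
               "arvscan_input_error")
    curves <- lapply(stats::setNames(nm = quant_targets), function(tg) {
      s <- standards[standards$target == tg, ]
      fit_standard_curve(s$copies, s$cq)
    })
    m <- collapse_replicates(cq_tab)
    m <- m[m$target %in% quant_targets, ]
    m$copies <- vapply(seq_len(nrow(m)), function(i)
      cq_to_copies(curves[[m$target[i]]], m$cq[i]), 0)
    copies <- m[order(m$sample_id, m$target, m$condition),
                c("sample_id", "target", "condition", "cq", "copies")]
    rownames(copies) <- NULL

    posit <- cq_positivity(cq_tab[cq_tab$target %in% quant_targets, ],
                           cutoff = cutoff)
    posit <- posit[order(posit$sample_id, posit$event_label), ]
    posit_out <- posit
    posit_out$detected <- as.integer(posit_out$detected)
    rownames(posit_out) <- NULL

    fc <- NULL
    conds <- unique(cq_tab$condition)
    if (all(c(treated, control) %in% conds) &&
        reference %in% cq_tab$target) {
      fc <- do.call(rbind, lapply(quant_targets, function(tg)
        fold_change(cq_tab, tg, reference = reference,
                    treated = treated, control = control)))
      fc <- fc[order(fc$sample_id, fc$target), ]
      rownames(fc) <- NULL
    }
    params <- list(cutoff = cutoff, reference = reference)
    write_tsv_provenance(copies, outs[1], params)
    write_tsv_provenance(posit_out, outs[2], params)
    if (!is.null(fc)) write_tsv_provenance(fc, outs[3], params)
    invisible(list(curves = curves, copies = copies, positivity = posit,
                   fold_change = fc))
  })
}
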