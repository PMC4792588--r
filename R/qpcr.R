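#' qRT-PCR quantification
#'
#' Absolute quantification follows the classic standard-curve scheme:
#' Cq values measured on a plasmid dilution series are regressed on
#' log10 template copies, and unknowns are inverse-predicted from the
#' fitted line, copies = 10^((Cq - intercept)/slope). Amplification
#' efficiency is 10^(-1/slope): an ideal doubling chemistry gives a
#' slope of -1/log10(2) = -3.321928 and efficiency 2. Positivity uses a
#' strict Cq < 35 cutoff (Cq = 35 is negative; a missing Cq means
#' undetected). Relative expression uses 2^(-ddCq) against a reference
#' gene (GAPDH), with technical replicates collapsed by arithmetic mean
#' of Cq before any transform; efficiency is fixed at 2 for fold
#' changes even when a curve-derived efficiency is available.
#'
#' @name qpcr
NULL

#' Fit a Cq-versus-log10(copies) standard curve
#'
#' @param copies template copy numbers of the dilution series (> 0).
#' @param cq measured quantification cycles, same length.
#' @return object of class `standard_curve` with elements `slope`
#'   (Cq per log10 copies, negative), `intercept` (Cq at 1 copy),
#'   `r_squared` and `efficiency` = 10^(-1/slope).
#' @export
#' @examples
#' sc <- fit_standard_curve(c(1e6, 1e5, 1e4), c(15, 18.321928, 21.643856))
#' sc$efficiency  # 2
fit_standard_curve <- function(copies, cq) {
  if (any(!is.finite(copies)) || any(copies <= 0))
    arv_stop("standard-curve copies must be positive", "arvscan_input_error")
  if (length(copies) != length(cq))
    arv_stop("copies and cq must have equal length", "arvscan_input_error")
  if (length(unique(copies)) < 2L)
    arv_stop("need at least 2 distinct copy levels to fit a standard curve",
             "arvscan_fit_error")
  fit <- stats::lm(cq ~ log10(copies))
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         efficiency = 10^(-1 / slope), n = length(cq)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve (Cq ~ log10 copies)\n")
  cat(sprintf("  slope %.4f  intercept %.4f  R^2 %.4f  efficiency %.3f\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted Cq for given template copies
#'
#' @param object a `standard_curve`.
#' @param copies template copy numbers (> 0).
#' @param ... unused.
#' @return predicted Cq values.
#' @export
predict.standard_curve <- function(object, copies, ...) {
  if (any(copies <= 0))
    arv_stop("copies must be positive", "arvscan_input_error")
  object$intercept + object$slope * log10(copies)
}

#' Absolute copy number from a Cq value
#'
#' Inverse prediction on the standard curve. Missing Cq (NA) marks an
#' undetected target and yields NA copies.
#'
#' @param curve a fitted [fit_standard_curve()] object.
#' @param cq quantification cycle(s).
#' @return estimated copies, 10^((cq - intercept)/slope).
#' @export
cq_to_copies <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Cq-cutoff positivity call
#'
#' @param cq quantification cycle(s); NA means undetected.
#' @param cutoff strict upper Cq bound (default 35).
#' @return logical: TRUE iff Cq is present and strictly below the
#'   cutoff (Cq equal to the cutoff is negative).
#' @export
call_positive <- function(cq, cutoff = 35) {
  !is.na(cq) & cq < cutoff
}

#' Variant copies as a fraction of full-length copies
#'
#' @param v_copies variant transcript copies.
#' @param fl_copies full-length transcript copies (> 0).
#' @return `v_copies / fl_copies`.
#' @export
variant_fraction <- function(v_copies, fl_copies) {
  if (any(fl_copies == 0, na.rm = TRUE))
    arv_stop("variant fraction undefined: full-length copies are 0",
             "arvscan_input_error")
  v_copies / fl_copies
}

# Collapse technical replicates to the mean Cq per (sample, target,
# condition). A group where every replicate is NA stays NA (undetected).
collapse_replicates <- function(cq_tab) {
  agg <- stats::aggregate(
    cq ~ sample_id + target + condition, data = cq_tab,
    FUN = function(v) mean(v, na.rm = TRUE),
    na.action = stats::na.pass)
  agg$cq[is.nan(agg$cq)] <- NA_real_
  agg
}

#' GAPDH-normalized fold change, 2^(-ddCq)
#'
#' dCq = Cq(target) - Cq(reference) within each condition; ddCq =
#' dCq(treated) - dCq(control); fold = 2^(-ddCq). Technical replicates
#' are collapsed by mean Cq first.
#'
#' @param cq_tab long Cq table with columns `sample_id`, `target`,
#'   `condition`, `replicate`, `cq` (NA = undetected).
#' @param target target transcript name (e.g. "AR-V7").
#' @param reference reference gene name (default "GAPDH").
#' @param treated,control condition labels (defaults "treated" and
#'   "vehicle").
#' @return data.frame with `sample_id`, `target` and `fold` (NA when
#'   the target was undetected in either condition).
#' @export
fold_change <- function(cq_tab, target, reference = "GAPDH",
                        treated = "treated", control = "vehicle") {
  m <- collapse_replicates(cq_tab)
  samples <- unique(m$sample_id)
  get <- function(s, tg, cond) {
    v <- m$cq[m$sample_id == s & m$target == tg & m$condition == cond]
    if (length(v) == 0L) NA_real_ else v[1]
  }
  fold <- vapply(samples, function(s) {
    rt <- get(s, reference, treated); rc <- get(s, reference, control)
    if (is.na(rt) || is.na(rc))
      arv_stop(sprintf("missing reference (%s) Cq for sample %s",
                       reference, s), "arvscan_input_error")
    tt <- get(s, target, treated); tc <- get(s, target, control)
    if (is.na(tt) || is.na(tc)) return(NA_real_)
    ddcq <- (tt - rt) - (tc - rc)
    2^(-ddcq)
  }, 0)
  data.frame(sample_id = samples, target = target, fold = fold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample qPCR positivity calls
#'
#' Formats Cq-cutoff calls like detector event calls (`sample_id`,
#' `event_label`, `detected`) so cohort positivity percentages flow
#' through the same [cohort_frequency()] summary and rounding as the
#' RNA-seq arm.
#'
#' @param cq_tab long Cq table (see [fold_change()]); replicates are
#'   collapsed by mean Cq per sample and target.
#' @param cutoff strict Cq cutoff (default 35).
#' @return data.frame with `sample_id`, `event_label` (the target),
#'   `condition`, `cq` (collapsed) and `detected`.
#' @export
cq_positivity <- function(cq_tab, cutoff = 35) {
  if (is.null(cq_tab$condition)) cq_tab$condition <- "none"
  m <- collapse_replicates(cq_tab)
  data.frame(sample_id = m$sample_id, event_label = m$target,
             condition = m$condition, cq = m$cq,
             detected = call_positive(m$cq, cutoff),
             stringsAsFactors = FALSE)
}
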