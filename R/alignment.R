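#' Alignment ingest and splice-gap extraction
#'
#' Junction evidence is taken exclusively from gapped alignments: reads
#' whose CIGAR contains one or more `N` operations bridging a spliced-out
#' genomic interval. Reads mapping entirely within exons carry no splice
#' information here (they may originate from unprocessed transcripts or
#' DNA contamination) and are ignored by the detector.
#'
#' @name alignment_io
NULL

.cigar_ops <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
.ref_consuming <- c("M", "D", "N", "=", "X")
.aligned_ops <- c("M", "=", "X")

#' Alignment filter configuration
#'
#' @param min_overhang minimum number of reference-aligned bases required
#'   on each side of a splice gap (default 6 bp). The boundary is kept:
#'   an overhang of exactly `min_overhang` passes.
#' @param drop_mapq0 drop alignments with mapping quality 0 (default
#'   TRUE). Only mapq == 0 is excluded; there is no general threshold.
#' @param drop_secondary drop secondary and supplementary alignments
#'   (default TRUE).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_overhang = 6L, drop_mapq0 = TRUE,
                          drop_secondary = TRUE) {
  min_overhang <- as.integer(min_overhang)
  if (is.na(min_overhang) || min_overhang < 0L)
    arv_stop("min_overhang must be a non-negative integer",
             "arvscan_parameter_error")
  structure(list(min_overhang = min_overhang, drop_mapq0 = drop_mapq0,
                 drop_secondary = drop_secondary),
            class = "filter_config")
}

# Split a CIGAR string into integer lengths and operation codes.
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+|[A-Z=]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  if (length(tok) == 0L || length(tok) %% 2L != 0L)
    arv_stop(sprintf("malformed CIGAR: %s", cigar), "arvscan_parse_error")
  len <- suppressWarnings(as.integer(tok[c(TRUE, FALSE)]))
  op <- tok[c(FALSE, TRUE)]
  if (anyNA(len) || !all(op %in% .cigar_ops))
    arv_stop(sprintf("invalid CIGAR operation in: %s", cigar),
             "arvscan_parse_error")
  list(len = len, op = op)
}

#' Read alignments from a SAM file
#'
#' Parses a headered SAM text file into a data.frame of mapped reads.
#' Unmapped records (FLAG 0x4 or CIGAR `*`) are dropped. Optionally
#' restricts to records overlapping a region on one reference.
#'
#' @param path SAM file path.
#' @param region optional `list(chrom =, start =, end =)` with a 0-based
#'   half-open interval; only records whose reference span overlaps it
#'   are returned. The chromosome must appear in an `@SQ` header line.
#' @param sample_id sample identifier attached to every record; defaults
#'   to the file name stem. Use `sample_id = "RG"` to take it from each
#'   record's `RG:Z:` tag (falling back to the stem where absent).
#' @return data.frame with columns `read_name`, `sample_id`, `chrom`,
#'   `pos` (0-based leftmost mapped coordinate), `mapq`, `cigar`,
#'   `is_secondary`, `is_supplementary`.
#' @export
read_alignments <- function(path, region = NULL, sample_id = NULL) {
  if (!file.exists(path))
    arv_stop(sprintf("SAM file not found: %s", path), "arvscan_input_error")
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  sq <- lines[hdr & startsWith(lines, "@SQ")]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  if (!is.null(region) && !(region$chrom %in% sq_names))
    arv_stop(sprintf("region chromosome '%s' has no @SQ header line",
                     region$chrom), "arvscan_input_error")

  body_idx <- which(!hdr & nzchar(lines))
  stem <- sub("\\.[sb]am$", "", basename(path), ignore.case = TRUE)
  if (is.null(sample_id)) sample_id <- stem

  if (length(body_idx) == 0L) {
    return(data.frame(read_name = character(), sample_id = character(),
                      chrom = character(), pos = integer(), mapq = integer(),
                      cigar = character(), is_secondary = logical(),
                      is_supplementary = logical(),
                      stringsAsFactors = FALSE))
  }

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    arv_stop(sprintf("malformed SAM record at line %d (%d fields, need 11)",
                     body_idx[which(nf < 11L)[1]], min(nf)),
             "arvscan_input_error")

  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(flag) || anyNA(pos1) || anyNA(mapq))
    arv_stop(sprintf("malformed SAM record at line %d",
                     body_idx[which(is.na(flag) | is.na(pos1) |
                                      is.na(mapq))[1]]),
             "arvscan_input_error")
  cigar <- vapply(fields, `[[`, "", 6L)
  rname <- vapply(fields, `[[`, "", 3L)

  sid <- rep(if (identical(sample_id, "RG")) stem else sample_id,
             length(fields))
  if (identical(sample_id, "RG")) {
    rg <- vapply(fields, function(f) {
      tag <- grep("^RG:Z:", f[-(1:11)], value = TRUE)
      if (length(tag)) sub("^RG:Z:", "", tag[1]) else NA_character_
    }, "")
    sid[!is.na(rg)] <- rg[!is.na(rg)]
  }

  df <- data.frame(read_name = vapply(fields, `[[`, "", 1L),
                   sample_id = sid, chrom = rname, pos = pos1 - 1L,
                   mapq = mapq, cigar = cigar,
                   is_secondary = bitwAnd(flag, 256L) > 0L,
                   is_supplementary = bitwAnd(flag, 2048L) > 0L,
                   stringsAsFactors = FALSE)

  mapped <- bitwAnd(flag, 4L) == 0L & cigar != "*" & rname != "*"
  df <- df[mapped, , drop = FALSE]

  if (!is.null(region) && nrow(df)) {
    span <- vapply(df$cigar, function(cg) {
      p <- parse_cigar(cg)
      sum(p$len[p$op %in% .ref_consuming])
    }, 0L)
    keep <- df$chrom == region$chrom & df$pos < region$end &
      (df$pos + span) > region$start
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Extract splice gaps from one alignment
#'
#' Walks the CIGAR with a reference cursor advancing over
#' reference-consuming operations (M, D, N, =, X) and emits one gap per
#' `N` operation, in genomic order. The overhang on each side of a gap
#' is the number of reference-aligned bases (M/=/X only; D and I do not
#' count) between the gap and the nearest `N` operation or the read
#' terminus on that side.
#'
#' @param pos 0-based leftmost mapped coordinate.
#' @param cigar CIGAR string.
#' @return data.frame with columns `gap_start`, `gap_end` (0-based
#'   half-open), `left_overhang`, `right_overhang`; zero rows for a
#'   gapless alignment.
#' @export
#' @examples
#' extract_gaps(1000, "50M100N50M")  # one gap [1050, 1150), anchors 50/50
extract_gaps <- function(pos, cigar) {
  p <- parse_cigar(cigar)
  n_idx <- which(p$op == "N")
  empty <- data.frame(gap_start = integer(), gap_end = integer(),
                      left_overhang = integer(), right_overhang = integer())
  if (length(n_idx) == 0L) return(empty)

  ref_len <- ifelse(p$op %in% .ref_consuming, p$len, 0L)
  cum <- cumsum(ref_len)
  gap_start <- pos + c(0L, cum)[n_idx]
  gap_end <- pos + cum[n_idx]

  aligned <- ifelse(p$op %in% .aligned_ops, p$len, 0L)
  # segment id between consecutive N ops: 0 before the first gap, etc.
  seg <- cumsum(p$op == "N")
  seg_sum <- vapply(0:length(n_idx),
                    function(s) sum(aligned[seg == s]), 0L)
  data.frame(gap_start = gap_start, gap_end = gap_end,
             left_overhang = seg_sum[seq_along(n_idx)],
             right_overhang = seg_sum[seq_along(n_idx) + 1L])
}

#' Does a (read, gap) pair pass the alignment filters?
#'
#' @param mapq mapping quality of the read the gap came from.
#' @param gap one row of [extract_gaps()] output (or any list with
#'   `left_overhang` and `right_overhang`).
#' @param cfg a [filter_config].
#' @param is_secondary,is_supplementary alignment flags of the read.
#' @return TRUE iff the pair survives: mapq > 0 (when enabled), both
#'   overhangs at least `min_overhang`, and the read is neither
#'   secondary nor supplementary (when enabled).
#' @export
passes_filters <- function(mapq, gap, cfg = filter_config(),
                           is_secondary = FALSE, is_supplementary = FALSE) {
  if (cfg$drop_mapq0 && mapq == 0L) return(FALSE)
  if (cfg$drop_secondary && (is_secondary || is_supplementary)) return(FALSE)
  min(gap$left_overhang, gap$right_overhang) >= cfg$min_overhang
}
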