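#' Locus-restricted RNA-seq and qPCR simulation with ground truth
#'
#' Generates single-end, error-free-by-default alignments over a locus
#' catalog with known per-junction spanning-read counts, emulating the
#' statistical structure of locus expression in a tumor cohort:
#' per-sample locus expression varies log-normally, read counts are
#' Poisson at the sample's depth, fragment starts are uniform along each
#' transcript, and variant-transcript share can be tilted upward with
#' the locus factor so variant and full-length junction counts rise
#' concordantly. Each simulated read's POS/CIGAR is the exact genomic
#' projection of its transcript interval through the exon chain, so no
#' aligner is involved and detection can be validated read-for-read
#' against the recorded truth.
#'
#' @name synthetic_data
NULL

# Per-sample RNG stream: deterministic, 32-bit safe.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + index) %% 2147483647)
}

#' Build transcript models from exon chains
#'
#' @param catalog a [locus_catalog].
#' @param chains named list; each element is an ordered character vector
#'   of exon ids (e.g. `list("AR-V7" = c("1", "2", "3", "CE3"))`). Every
#'   consecutive exon pair must be a catalog junction.
#' @return named list of transcript models (class `transcript_model`):
#'   `name`, `exon_ids`, `junction_labels`, `length`, `segments`
#'   (per-exon genomic start/end and transcript offsets) and
#'   `is_variant` (TRUE when any junction in the chain is
#'   non-canonical).
#' @export
build_transcripts <- function(catalog, chains) {
  stopifnot(inherits(catalog, "locus_catalog"))
  ex <- catalog$exons
  jn <- catalog$junctions
  jkey <- paste(jn$upstream_exon, jn$downstream_exon, sep = "\r")
  lapply_named <- function(nms, f) stats::setNames(lapply(nms, f), nms)
  lapply_named(names(chains), function(nm) {
    chain <- chains[[nm]]
    idx <- match(chain, ex$id)
    if (anyNA(idx))
      arv_stop(sprintf("transcript %s uses unknown exon(s): %s", nm,
                       paste(chain[is.na(idx)], collapse = ", ")),
               "arvscan_model_error")
    jl <- character(0)
    if (length(chain) > 1L) {
      pair <- paste(chain[-length(chain)], chain[-1], sep = "\r")
      hit <- match(pair, jkey)
      if (anyNA(hit))
        arv_stop(sprintf(
          "transcript %s: no catalog junction between exons %s", nm,
          paste(gsub("\r", "-", pair[is.na(hit)]), collapse = ", ")),
          "arvscan_model_error")
      jl <- jn$label[hit]
    }
    len <- ex$end[idx] - ex$start[idx]
    segments <- data.frame(
      exon_id = chain,
      g_start = ex$start[idx], g_end = ex$end[idx],
      t_start = cumsum(c(0L, len[-length(len)])),  # 0-based transcript offset
      t_end = cumsum(len)
    )
    structure(list(name = nm, exon_ids = chain, junction_labels = jl,
                   length = sum(len), segments = segments,
                   is_variant = any(jn$class[match(jl, jn$label)] !=
                                      "canonical")),
              class = "transcript_model")
  })
}

#' Default AR transcript chains for the shipped example catalog
#'
#' Full-length AR (exons 1-8), AR-V7 (1/2/3/CE3), AR45 (1a/2-8),
#' AR-V1 (1/2/3/CE1), AR-V3 (1/2/CE4), AR-V9 (1/2/3/CE5) and
#' AR-V13 (1-6/9).
#'
#' @return named list of exon-id chains for [build_transcripts()].
#' @export
ar_default_chains <- function() {
  list(
    "AR-FL"  = c("1", "2", "3", "4", "5", "6", "7", "8"),
    "AR-V7"  = c("1", "2", "3", "CE3"),
    "AR45"   = c("1a", "2", "3", "4", "5", "6", "7", "8"),
    "AR-V1"  = c("1", "2", "3", "CE1"),
    "AR-V3"  = c("1", "2", "CE4"),
    "AR-V9"  = c("1", "2", "3", "CE5"),
    "AR-V13" = c("1", "2", "3", "4", "5", "6", "9")
  )
}

#' Simulation configuration
#'
#' @param seed integer master seed; every sample draws from its own
#'   stream derived from (seed, sample_index).
#' @param n_samples number of samples in the cohort.
#' @param read_length read length in bases (default 100).
#' @param mean_depth expected reads per sample over the locus at locus
#'   factor 1 (default 300).
#' @param mu_log,sigma_log meanlog/sdlog of the per-sample log-normal
#'   locus expression factor (defaults 0 and 0.5).
#' @param proportions named per-transcript mixture proportions (sum 1);
#'   default is a full-length-dominated AR mixture (AR-FL 0.85, AR-V7
#'   0.06, AR45 0.04, AR-V1/AR-V3 0.015, AR-V9/AR-V13 0.01).
#' @param coupling_beta logit-scale tilt of variant share with the
#'   standardized log locus factor (default 0.5): positive values make
#'   variant transcripts rise faster than full-length in high-expressing
#'   samples, so variant and reference junction counts increase
#'   concordantly. 0 disables the tilt (counts still correlate through
#'   the shared locus factor).
#' @param base_error_rate per-base substitution rate applied to the
#'   synthetic sequence fill (default 0). Alignments are positional, so
#'   errors never change POS/CIGAR or the recorded truth.
#' @param min_overhang anchor length used when recording ground-truth
#'   junction-spanning reads (default 6; must satisfy
#'   `read_length >= 2 * min_overhang`).
#' @param mapq mapping quality written to simulated records (default 50).
#' @param group_mixture optional named list of per-group proportion
#'   overrides used by [simulate_cohort()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_samples = 25L, read_length = 100L,
                              mean_depth = 300, mu_log = 0, sigma_log = 0.5,
                              proportions = c("AR-FL" = 0.85, "AR-V7" = 0.06,
                                              "AR45" = 0.04, "AR-V1" = 0.015,
                                              "AR-V3" = 0.015,
                                              "AR-V9" = 0.01,
                                              "AR-V13" = 0.01),
                              coupling_beta = 0.5, base_error_rate = 0,
                              min_overhang = 6L, mapq = 50L,
                              group_mixture = NULL) {
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    arv_stop("mixture proportions must be >= 0 and sum to 1",
             "arvscan_config_error")
  if (read_length < 2L * min_overhang)
    arv_stop("read_length must be >= 2 * min_overhang",
             "arvscan_config_error")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, mu_log = mu_log,
                 sigma_log = sigma_log, proportions = proportions,
                 coupling_beta = coupling_beta,
                 base_error_rate = base_error_rate,
                 min_overhang = as.integer(min_overhang),
                 mapq = as.integer(mapq), group_mixture = group_mixture),
            class = "simulation_config")
}

# Project a transcript interval [s, s+rl) (0-based transcript coords)
# through the exon chain: returns pos (0-based genomic) and CIGAR.
project_read <- function(tr, s, rl) {
  seg <- tr$segments
  t0 <- s; t1 <- s + rl
  hit <- which(seg$t_end > t0 & seg$t_start < t1)
  m_len <- pmin(seg$t_end[hit], t1) - pmax(seg$t_start[hit], t0)
  g_start <- seg$g_start[hit] + pmax(t0 - seg$t_start[hit], 0L)
  ops <- character(0)
  for (k in seq_along(hit)) {
    if (k > 1L) {
      n_len <- g_start[k] - (g_start[k - 1L] + m_len[k - 1L])
      ops <- c(ops, sprintf("%dN", n_len))
    }
    ops <- c(ops, sprintf("%dM", m_len[k]))
  }
  list(pos = g_start[1], cigar = paste(ops, collapse = ""))
}

#' Simulate one sample's alignments and ground truth
#'
#' @param catalog a [locus_catalog].
#' @param transcripts transcript models from [build_transcripts()].
#' @param cfg a [simulation_config].
#' @param sample_index 1-based sample index (selects the RNG stream).
#' @param proportions optional mixture override for this sample (e.g. a
#'   group-specific mixture); defaults to `cfg$proportions`.
#' @param sample_id sample name (default `sample_<index>` zero-padded).
#' @return list with `reads` (data.frame in [read_alignments()] layout
#'   plus `seq`), `truth` (named integer vector of ground-truth
#'   spanning-read counts per catalog junction, counting only reads
#'   anchored by at least `cfg$min_overhang` bases on both sides),
#'   `locus_factor`, `n_reads` and `proportions` (post-tilt).
#' @export
simulate_sample <- function(catalog, transcripts, cfg, sample_index,
                            proportions = NULL, sample_id = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  rl <- cfg$read_length
  if (is.null(proportions)) proportions <- cfg$proportions
  tr_names <- names(proportions)
  bad <- setdiff(tr_names, names(transcripts))
  if (length(bad))
    arv_stop(sprintf("mixture names unknown transcript(s): %s",
                     paste(bad, collapse = ", ")), "arvscan_config_error")
  too_short <- vapply(transcripts[tr_names],
                      function(t) t$length < rl, TRUE)
  if (any(too_short[proportions > 0]))
    arv_stop("read_length exceeds a mixed-in transcript's length",
             "arvscan_config_error")
  if (is.null(sample_id))
    sample_id <- sprintf("sample_%03d", sample_index)

  set.seed(derive_seed(cfg$seed, sample_index))
  L <- stats::rlnorm(1, cfg$mu_log, cfg$sigma_log)
  n_reads <- stats::rpois(1, cfg$mean_depth * L)

  # logit-linear tilt: variant share rises with the locus factor
  z <- (log(L) - cfg$mu_log) / cfg$sigma_log
  is_var <- vapply(transcripts[tr_names], `[[`, TRUE, "is_variant")
  w <- proportions * exp(cfg$coupling_beta * z * as.numeric(is_var))
  w <- w / sum(w)

  truth <- stats::setNames(integer(nrow(catalog$junctions)),
                           catalog$junctions$label)
  if (n_reads == 0L) {
    return(list(reads = data.frame(read_name = character(),
                                   sample_id = character(),
                                   chrom = character(), pos = integer(),
                                   mapq = integer(), cigar = character(),
                                   is_secondary = logical(),
                                   is_supplementary = logical(),
                                   seq = character(),
                                   stringsAsFactors = FALSE),
                truth = truth, locus_factor = L, n_reads = 0L,
                proportions = w))
  }

  pick <- sample.int(length(tr_names), n_reads, replace = TRUE, prob = w)
  pos <- integer(n_reads); cigar <- character(n_reads)
  fill <- strrep("A", rl)
  seqs <- rep(fill, n_reads)
  for (i in seq_len(n_reads)) {
    tr <- transcripts[[tr_names[pick[i]]]]
    s <- sample.int(tr$length - rl + 1L, 1L) - 1L  # 0-based start
    pr <- project_read(tr, s, rl)
    pos[i] <- pr$pos; cigar[i] <- pr$cigar
    # ground truth: junction k sits at transcript offset t_end[k]
    bounds <- tr$segments$t_end[-nrow(tr$segments)]
    span <- (bounds - s) >= cfg$min_overhang &
      (s + rl - bounds) >= cfg$min_overhang
    for (lab in tr$junction_labels[span])
      truth[lab] <- truth[lab] + 1L
  }
  if (cfg$base_error_rate > 0) {
    n_err <- stats::rbinom(n_reads, rl, cfg$base_error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(rl, n_err[i])
      sub <- strsplit(seqs[i], "")[[1]]
      sub[at] <- sample(c("C", "G", "T"), n_err[i], replace = TRUE)
      seqs[i] <- paste(sub, collapse = "")
    }
  }
  reads <- data.frame(
    read_name = sprintf("%s_r%06d", sample_id, seq_len(n_reads)),
    sample_id = sample_id, chrom = catalog$chrom, pos = pos,
    mapq = cfg$mapq, cigar = cigar, is_secondary = FALSE,
    is_supplementary = FALSE, seq = seqs, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, locus_factor = L,
       n_reads = n_reads, proportions = w)
}

#' Write alignments as a headered SAM file
#'
#' @param reads data.frame with at least `read_name`, `chrom`, `pos`
#'   (0-based), `mapq`, `cigar`; optional `seq`.
#' @param chrom_len reference length for the `@SQ` line (default: past
#'   the last aligned base).
#' @param path output path.
#' @return `path`, invisibly; `read_alignments(path)` reproduces the
#'   alignment fields.
#' @export
write_sam <- function(reads, path, chrom_len = NULL) {
  chrom <- unique(reads$chrom)
  if (nrow(reads) == 0L && is.null(chrom_len))
    arv_stop("empty read set needs an explicit chrom_len/chrom via reads",
             "arvscan_input_error")
  if (length(chrom) > 1L)
    arv_stop("write_sam expects reads on a single reference",
             "arvscan_input_error")
  if (is.null(chrom_len)) {
    span <- vapply(seq_len(nrow(reads)), function(i) {
      p <- parse_cigar(reads$cigar[i])
      reads$pos[i] + sum(p$len[p$op %in% .ref_consuming])
    }, 0L)
    chrom_len <- max(span) + 1000L
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (length(chrom))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len), con)
  if (nrow(reads)) {
    seq <- if (is.null(reads$seq)) {
      vapply(reads$cigar, function(cg) {
        p <- parse_cigar(cg)
        strrep("A", sum(p$len[p$op %in% c("M", "I", "S", "=", "X")]))
      }, "")
    } else reads$seq
    writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       reads$read_name, reads$chrom, reads$pos + 1L,
                       reads$mapq, reads$cigar, seq), con)
  }
  invisible(path)
}

#' Simulate a cohort of locus-restricted samples
#'
#' Deterministic for a fixed seed. When `out_dir` is given, one SAM per
#' sample plus `truth.tsv` and `groups.tsv` are written; otherwise
#' everything stays in memory.
#'
#' @param catalog a [locus_catalog].
#' @param transcripts models from [build_transcripts()].
#' @param cfg a [simulation_config].
#' @param groups optional character vector of length `n_samples`
#'   assigning each sample a group label; groups named in
#'   `cfg$group_mixture` use their own mixture proportions.
#' @param out_dir optional output directory (created if missing).
#' @return list with `reads` (one data.frame per sample), `truth`
#'   (long data.frame: sample_id, junction_label, truth_count),
#'   `samples` (per-sample locus factor, read count, group) and, when
#'   written, `sam_paths`.
#' @export
simulate_cohort <- function(catalog, transcripts, cfg, groups = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_samples
  if (!is.null(groups) && length(groups) != n)
    arv_stop("groups must have one label per sample",
             "arvscan_config_error")
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    prop <- cfg$proportions
    if (!is.null(groups) && !is.null(cfg$group_mixture[[groups[i]]]))
      prop <- cfg$group_mixture[[groups[i]]]
    sims[[i]] <- simulate_sample(catalog, transcripts, cfg, i,
                                 proportions = prop)
  }
  sample_ids <- vapply(sims, function(s)
    if (nrow(s$reads)) s$reads$sample_id[1] else "", "")
  sample_ids[!nzchar(sample_ids)] <-
    sprintf("sample_%03d", which(!nzchar(sample_ids)))
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(sample_id = sample_ids[i],
               junction_label = names(sims[[i]]$truth),
               truth_count = as.integer(sims[[i]]$truth),
               stringsAsFactors = FALSE)
  }))
  samples <- data.frame(
    sample_id = sample_ids,
    group = if (is.null(groups)) "cohort" else groups,
    locus_factor = vapply(sims, `[[`, 0, "locus_factor"),
    n_reads = vapply(sims, `[[`, 0L, "n_reads"),
    stringsAsFactors = FALSE)
  out <- list(reads = stats::setNames(lapply(sims, `[[`, "reads"),
                                      sample_ids),
              truth = truth, samples = samples)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(sample_ids, ".sam"))
    if (anyDuplicated(paths))
      arv_stop("sample file name collision in out_dir",
               "arvscan_io_error")
    chrom_len <- max(catalog$exons$end) + 1000L
    for (i in seq_len(n)) {
      r <- out$reads[[i]]
      if (nrow(r) == 0L) {
        # header-only SAM for empty samples
        con <- file(paths[i], "wt")
        writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                     sprintf("@SQ\tSN:%s\tLN:%d", catalog$chrom, chrom_len)),
                   con)
        close(con)
      } else {
        write_sam(r, paths[i], chrom_len = chrom_len)
      }
    }
    write_tsv_provenance(truth, file.path(out_dir, "truth.tsv"),
                         params = list(seed = cfg$seed))
    write_tsv_provenance(samples[, c("sample_id", "group")],
                         file.path(out_dir, "groups.tsv"),
                         params = list(seed = cfg$seed))
    out$sam_paths <- paths
  }
  out
}

#' Simulate a qPCR cohort (standards + sample Cq tables) with truth
#'
#' Standards follow an ideal-efficiency-2 line, Cq = intercept +
#' slope * log10(copies) with slope = -1/log10(2), plus Gaussian noise.
#' Sample Cqs are generated from per-sample true copies on the same
#' line; zero true copies yield a missing (undetected) Cq. An optional
#' treatment arm multiplies true copies by a per-target fold and emits
#' a second condition, with a constant-copy reference gene (GAPDH) for
#' delta-delta-Cq analysis.
#'
#' @param seed integer seed.
#' @param n_samples cohort size (default 54).
#' @param noise_sd Gaussian Cq noise, cycles (default 0.2).
#' @param intercept Cq at one template copy (default 34.931569, i.e.
#'   Cq 15 at 1e6 copies).
#' @param standard_levels copies of the dilution series (default
#'   10-fold, 1e6 down to 1e1).
#' @param standard_reps technical replicates per standard level
#'   (default 3).
#' @param fl_meanlog,fl_sdlog log-normal law of full-length (AR-FL)
#'   copies per reaction.
#' @param frac_meanlog,frac_sdlog log-normal law of the AR-V7:AR-FL
#'   copy fraction.
#' @param fl_dropout probability a sample has zero AR-FL (default 0.02).
#' @param treatment_fold optional named numeric of true fold changes
#'   (e.g. `c("AR-V7" = 2.29, "AR-FL" = 1.42)`); when given, conditions
#'   "vehicle" and "treated" are emitted with GAPDH reference rows.
#' @return list with `standards` (target, copies, cq), `cq` (sample_id,
#'   target, condition, replicate, cq) and `truth` (sample_id, target,
#'   condition, copies).
#' @export
simulate_cq_cohort <- function(seed = 1L, n_samples = 54L, noise_sd = 0.2,
                               intercept = 34.931569,
                               standard_levels = 10^(6:1),
                               standard_reps = 3L,
                               fl_meanlog = log(200), fl_sdlog = 1.2,
                               frac_meanlog = log(0.005), frac_sdlog = 1.0,
                               fl_dropout = 0.02,
                               treatment_fold = NULL) {
  slope <- -1 / log10(2)
  set.seed(derive_seed(seed, 0L))
  cq_of <- function(copies) {
    ifelse(copies > 0,
           intercept + slope * log10(pmax(copies, .Machine$double.xmin)) +
             stats::rnorm(length(copies), 0, noise_sd),
           NA_real_)
  }
  std <- expand.grid(target = c("AR-V7", "AR-FL"),
                     copies = standard_levels,
                     rep = seq_len(standard_reps),
                     stringsAsFactors = FALSE)
  if (any(standard_levels <= 0))
    arv_stop("standard copies must be positive", "arvscan_config_error")
  std$cq <- cq_of(std$copies)
  standards <- std[, c("target", "copies", "cq")]

  fl <- stats::rlnorm(n_samples, fl_meanlog, fl_sdlog)
  fl[stats::runif(n_samples) < fl_dropout] <- 0
  v7 <- fl * stats::rlnorm(n_samples, frac_meanlog, frac_sdlog)
  ids <- sprintf("q%03d", seq_len(n_samples))
  conditions <- if (is.null(treatment_fold)) "none" else
    c("vehicle", "treated")
  rows <- list()
  for (cond in conditions) {
    mult <- function(target) {
      if (cond == "treated" && !is.null(treatment_fold) &&
          target %in% names(treatment_fold)) treatment_fold[[target]] else 1
    }
    tab <- rbind(
      data.frame(sample_id = ids, target = "AR-V7", condition = cond,
                 copies = v7 * mult("AR-V7"), stringsAsFactors = FALSE),
      data.frame(sample_id = ids, target = "AR-FL", condition = cond,
                 copies = fl * mult("AR-FL"), stringsAsFactors = FALSE))
    if (!is.null(treatment_fold))
      tab <- rbind(tab, data.frame(sample_id = ids, target = "GAPDH",
                                   condition = cond, copies = 1e6,
                                   stringsAsFactors = FALSE))
    rows[[cond]] <- tab
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  cq <- do.call(rbind, lapply(1:2, function(rep_i) {
    out <- truth
    out$replicate <- rep_i
    out$cq <- cq_of(out$copies)
    out[, c("sample_id", "target", "condition", "replicate", "cq")]
  }))
  rownames(cq) <- NULL
  list(standards = standards, cq = cq, truth = truth)
}
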