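test_that("transcript chains resolve to catalog junctions", {
  ar <- ar_catalog()
  tr <- build_transcripts(ar, list(v7 = c("1", "2", "3", "CE3"),
                                   alt = c("1a", "2", "3")))
  expect_setequal(tr$v7$junction_labels, c("1-2", "2-3", "3-CE3"))
  expect_setequal(tr$alt$junction_labels, c("1a-2", "2-3"))
  expect_true(tr$v7$is_variant)
  expect_true(tr$alt$is_variant)   # alternative-first junction
  expect_false(build_transcripts(
    ar, list(fl = ar_default_chains()[["AR-FL"]]))$fl$is_variant)
  ex <- ar$exons
  expect_equal(tr$v7$length,
               sum((ex$end - ex$start)[ex$id %in% c("1", "2", "3", "CE3")]))
  expect_error(build_transcripts(ar, list(bad = c("1", "CE3"))),
               "no catalog junction", class = "arvscan_model_error")
  expect_error(build_transcripts(ar, list(bad = c("1", "ZZ"))),
               "unknown exon", class = "arvscan_model_error")
})

test_that("qualifying start positions per junction follow the anchor rule", {
  # enumeration oracle: at read length 12 and 6 bp anchors, exactly
  # L - 2*6 + 1 = 1 start position spans each junction
  ar <- ar_catalog()
  tr <- ar_transcripts()[["AR-V7"]]
  rl <- 12L; m <- 6L
  jn <- ar$junctions
  hits <- integer(length(tr$junction_labels))
  names(hits) <- tr$junction_labels
  for (s in 0:(tr$length - rl)) {
    pr <- arvscan:::project_read(tr, s, rl)
    g <- extract_gaps(pr$pos, pr$cigar)
    if (nrow(g)) {
      ok <- pmin(g$left_overhang, g$right_overhang) >= m
      lab <- jn$label[match(paste(g$gap_start[ok], g$gap_end[ok]),
                            paste(jn$gap_start, jn$gap_end))]
      hits[lab] <- hits[lab] + 1L
    }
  }
  expect_equal(unname(hits), rep(rl - 2L * m + 1L, length(hits)))
})

test_that("simulated reads project exactly through the exon chain", {
  ar <- ar_catalog()
  cfg <- simulation_config(seed = 13, n_samples = 2)
  sim <- simulate_sample(ar, ar_transcripts(), cfg, 1)
  expect_gt(nrow(sim$reads), 0)
  ex <- ar$exons
  for (i in seq_len(nrow(sim$reads))) {
    p <- arvscan:::parse_cigar(sim$reads$cigar[i])
    expect_equal(sum(p$len[p$op == "M"]), cfg$read_length)
    # every M block lies inside some catalog exon
    cum <- cumsum(ifelse(p$op %in% c("M", "N"), p$len, 0L))
    starts <- sim$reads$pos[i] + c(0L, cum)[seq_along(p$op)]
    for (k in which(p$op == "M")) {
      inside <- any(ex$start <= starts[k] &
                      ex$end >= starts[k] + p$len[k])
      expect_true(inside)
    }
  }
})

test_that("degenerate simulation configs behave per contract", {
  ar <- ar_catalog()
  tr <- ar_transcripts()
  cfg0 <- simulation_config(seed = 3, n_samples = 1, mean_depth = 0)
  s0 <- simulate_sample(ar, tr, cfg0, 1)
  expect_equal(nrow(s0$reads), 0L)
  expect_true(all(s0$truth == 0L))

  flonly <- simulation_config(seed = 3, n_samples = 1,
                              proportions = c("AR-FL" = 1))
  sfl <- simulate_sample(ar, tr, flonly, 1)
  noncanon <- ar$junctions$label[ar$junctions$class != "canonical"]
  expect_true(all(sfl$truth[noncanon] == 0L))

  expect_error(simulation_config(read_length = 10, min_overhang = 6),
               class = "arvscan_config_error")
  expect_error(simulation_config(proportions = c("AR-FL" = 0.6)),
               class = "arvscan_config_error")
  short <- simulation_config(seed = 1, n_samples = 1, read_length = 200,
                             min_overhang = 6,
                             proportions = c("AR-V3" = 1))
  expect_silent(simulate_sample(ar, tr, short, 1))
  toolong <- simulation_config(seed = 1, n_samples = 1, read_length = 2000,
                               proportions = c("AR-V7" = 1))
  expect_error(simulate_sample(ar, tr, toolong, 1),
               class = "arvscan_config_error")
})

test_that("SAM writing round-trips through read_alignments", {
  ar <- ar_catalog()
  f <- tempfile(fileext = ".sam")
  one <- make_read(1000L, "50M100N50M",
                   sample_id = sub("\\.sam$", "", basename(f)))
  write_sam(one, f)
  back <- read_alignments(f)
  expect_equal(back, one, ignore_attr = TRUE)

  # header-only file for an empty read set
  f2 <- tempfile(fileext = ".sam")
  empty <- one[0, ]
  write_sam(empty, f2, chrom_len = 50000L)
  expect_equal(nrow(read_alignments(f2)), 0L)

  # fuzzed seeded read sets round-trip exactly
  set.seed(37)
  cfg <- simulation_config(seed = 37, n_samples = 1)
  sim <- simulate_sample(ar, ar_transcripts(), cfg, 1)
  f3 <- tempfile(fileext = ".sam")
  sim$reads$sample_id <- sub("\\.sam$", "", basename(f3))
  write_sam(sim$reads, f3)
  back3 <- read_alignments(f3)
  expect_equal(back3, sim$reads[names(back3)], ignore_attr = TRUE)
})

test_that("simulated SAM parses identically through GenomicAlignments", {
  ar <- ar_catalog()
  cfg <- simulation_config(seed = 23, n_samples = 1)
  sim <- simulate_sample(ar, ar_transcripts(), cfg, 1)
  f <- tempfile(fileext = ".sam")
  write_sam(sim$reads, f)
  bam <- Rsamtools::asBam(f, tempfile(), overwrite = TRUE)
  ga <- GenomicAlignments::readGAlignments(bam)
  ours <- read_alignments(f)
  ord <- order(ours$pos)
  expect_equal(sort(BiocGenerics::start(ga)), sort(ours$pos + 1L))
  expect_equal(as.character(GenomicAlignments::cigar(ga))[order(BiocGenerics::start(ga))],
               ours$cigar[ord])
})

test_that("cohort simulation is seed-deterministic byte for byte", {
  ar <- ar_catalog()
  tr <- ar_transcripts()
  cfg <- simulation_config(seed = 101, n_samples = 3)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- simulate_cohort(ar, tr, cfg, out_dir = d1)
  c2 <- simulate_cohort(ar, tr, cfg, out_dir = d2)
  for (i in seq_along(c1$sam_paths)) {
    expect_identical(readLines(c1$sam_paths[i]), readLines(c2$sam_paths[i]))
  }
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  # distinct seeds give distinct cohorts
  c3 <- simulate_cohort(ar, tr,
                        simulation_config(seed = 102, n_samples = 3))
  expect_false(identical(c1$truth$truth_count, c3$truth$truth_count))
})

test_that("group mixtures shift cohort positivity through the full pipeline", {
  ar <- ar_catalog()
  tr <- ar_transcripts()
  cfg <- simulation_config(
    seed = 55, n_samples = 40, coupling_beta = 0,
    proportions = c("AR-FL" = 1),
    group_mixture = list(high = c("AR-FL" = 0.7, "AR-V7" = 0.3)))
  groups <- rep(c("none", "high"), each = 20)
  sim <- simulate_cohort(ar, tr, cfg, groups = groups)
  reads <- do.call(rbind, sim$reads)
  calls <- call_events(count_junctions(reads, ar), ar)
  fr <- cohort_frequency(calls[calls$event_label == "3-CE3", ],
                         sim$samples[, c("sample_id", "group")])
  expect_gt(fr$percent[fr$group == "high"], fr$percent[fr$group == "none"])
  expect_equal(fr$n_positive[fr$group == "none"], 0L)
})
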