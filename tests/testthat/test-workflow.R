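test_that("scan command produces sorted tables with detected AR-V7 events", {
  ar_path <- system.file("extdata", "ar_example.tsv", package = "arvscan")
  sam_dir <- tempfile(); dir.create(sam_dir)
  reads <- rbind(spanning_read("3-CE3", read_name = "a", sample_id = "s1"),
                 spanning_read("3-CE3", read_name = "b", sample_id = "s1"),
                 spanning_read("1-2", read_name = "c", sample_id = "s1"))
  write_sam(reads, file.path(sam_dir, "s1.sam"))
  out <- tempfile()
  res <- scan_cohort(sam_dir, ar_path, out)
  calls <- read_tsv <- utils::read.delim(file.path(out, "calls.tsv"),
                                         comment.char = "#")
  hit <- calls[calls$event_label == "3-CE3", ]
  expect_equal(hit$count, 2L)
  expect_equal(hit$detected, 1L)
  expect_equal(hit$candidate_variants, "AR-V7")
  counts <- utils::read.delim(file.path(out, "counts.tsv"),
                              comment.char = "#")
  expect_false(is.unsorted(counts$junction_label))
  # provenance header echoes applied thresholds
  hdr <- grep("^#", readLines(file.path(out, "counts.tsv")), value = TRUE)
  expect_true(any(grepl("min_overhang=6", hdr)))

  # re-running yields byte-identical outputs
  out2 <- tempfile()
  scan_cohort(sam_dir, ar_path, out2)
  for (f in c("counts.tsv", "calls.tsv", "ratios.tsv"))
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
})

test_that("scan failures leave no partial outputs", {
  sam_dir <- tempfile(); dir.create(sam_dir)
  write_sam(make_read(100L, "50M", sample_id = "s1"),
            file.path(sam_dir, "s1.sam"))
  bad_catalog <- tempfile(fileext = ".tsv")
  writeLines("record\tid", bad_catalog)
  out <- tempfile()
  expect_error(scan_cohort(sam_dir, bad_catalog, out),
               class = "arvscan_catalog_error")
  expect_equal(length(list.files(out, pattern = "tsv$")), 0L)
  expect_error(scan_cohort(tempfile(), bad_catalog, out),
               class = "arvscan_error")
})

test_that("an empty SAM yields all-zero counts and no detections", {
  ar_path <- system.file("extdata", "ar_example.tsv", package = "arvscan")
  sam_dir <- tempfile(); dir.create(sam_dir)
  con <- file(file.path(sam_dir, "empty.sam"), "wt")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrX\tLN:100000"), con); close(con)
  out <- tempfile()
  res <- scan_cohort(sam_dir, ar_path, out)
  expect_true(all(res$counts$count == 0L))
  expect_false(any(res$calls$detected))
})

test_that("summarize joins calls with groups and flags unknown samples", {
  calls <- data.frame(sample_id = c("a", "b"), event_label = "3-CE3",
                      count = c(3L, 1L), detected = c(1L, 1L))
  groups <- data.frame(sample_id = c("a", "b"), group = "tumor")
  out <- tempfile(fileext = ".tsv")
  smry <- summarize_calls(calls, groups, out_path = out)
  expect_equal(smry$percent, 100.0)
  expect_true(file.exists(out))
  bad <- rbind(groups, data.frame(sample_id = "ghost", group = "tumor"))
  expect_error(summarize_calls(calls, bad), "ghost",
               class = "arvscan_input_error")
})

test_that("qpcr command quantifies, calls positivity and computes fold changes", {
  q <- simulate_cq_cohort(seed = 6, n_samples = 10,
                          treatment_fold = c("AR-V7" = 2.29,
                                             "AR-FL" = 1.42))
  out <- tempfile()
  res <- run_qpcr(q$standards, q$cq, out, treated = "treated",
                  control = "vehicle")
  expect_true(all(file.exists(
    file.path(out, c("copies.tsv", "positivity.tsv", "fold_change.tsv")))))
  expect_lt(abs(res$curves[["AR-V7"]]$efficiency - 2), 0.05)
  fc <- res$fold_change[res$fold_change$target == "AR-FL", ]
  expect_equal(stats::median(fc$fold, na.rm = TRUE), 1.42, tolerance = 0.25)

  # a target with no standards fails up front
  q2 <- q; q2$standards <- q$standards[q$standards$target == "AR-FL", ]
  expect_error(run_qpcr(q2$standards, q2$cq, tempfile()),
               "standards", class = "arvscan_input_error")
  # single-level standards surface the fit error and leave nothing behind
  q3 <- q; q3$standards <- q$standards[q$standards$copies == 1e6, ]
  out3 <- tempfile()
  expect_error(run_qpcr(q3$standards, q3$cq, out3),
               class = "arvscan_fit_error")
  expect_equal(length(list.files(out3, pattern = "tsv$")), 0L)
})

test_that("the command-line front end runs scan end to end", {
  cli <- system.file("cli", "arvscan", package = "arvscan")
  expect_true(nzchar(cli))
  ar_path <- system.file("extdata", "ar_example.tsv", package = "arvscan")
  sam_dir <- tempfile(); dir.create(sam_dir)
  write_sam(rbind(spanning_read("3-CE3", sample_id = "s1")),
            file.path(sam_dir, "s1.sam"))
  out <- tempfile()
  status <- system2(file.path(R.home("bin"), "Rscript"),
                    c(cli, "scan", "--sam", sam_dir, "--catalog", ar_path,
                      "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "calls.tsv")))
  calls <- utils::read.delim(file.path(out, "calls.tsv"),
                             comment.char = "#")
  expect_equal(calls$detected[calls$event_label == "3-CE3"], 1L)

  # malformed catalog -> nonzero exit, message on stderr
  bad <- tempfile(); writeLines("nonsense", bad)
  res <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"),
            c(cli, "scan", "--sam", sam_dir, "--catalog", bad,
              "--out", tempfile()), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res, "status"), 1L)
})
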