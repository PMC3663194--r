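write_bundle <- function(study, dir) {
  write_study(study, dir)
  list(cq = file.path(dir, sprintf("cq_run%d.tsv",
                                   seq_along(study$cq_tables))),
       sheet = file.path(dir, "sample_sheet.tsv"))
}

test_that("the QC report bundle is complete and reflects the planted truth", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report")
  st <- generate_paired_study(n_mirs = 60, seed = 101)
  paths <- write_bundle(st, dir)
  res <- suppressMessages(qc_report(paths$cq, paths$sheet, out))
  expect_true(all(file.exists(file.path(out,
    c("fold_changes.tsv", "tiers.tsv", "log2_matrix.tsv", "subsets.json",
      "run_log.json")))))
  tr <- merge(res$report, st$truth, by = "mir_id")
  sus <- tr$truth_label == "susceptible"
  expect_gt(mean(tr$tier[sus] %in% c("elevated_all_pairs",
                                     "elevated_two_pairs",
                                     "elevated_one_pair")), 0.9)
  expect_setequal(res$specific,
                  st$truth$mir_id[st$truth$truth_label == "specific"])
  log <- jsonlite::read_json(file.path(out, "run_log.json"))
  expect_equal(log$thresholds$detect_cq, 35)
  expect_length(log$input_md5, 3)
})

test_that("re-running the report on identical inputs is byte-identical", {
  dir <- withr::local_tempdir()
  st <- generate_paired_study(n_mirs = 30, seed = 55)
  paths <- write_bundle(st, dir)
  out1 <- file.path(dir, "r1"); out2 <- file.path(dir, "r2")
  suppressMessages(qc_report(paths$cq, paths$sheet, out1))
  suppressMessages(qc_report(paths$cq, paths$sheet, out2))
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("a single-pair study only yields single-pair tiers", {
  dir <- withr::local_tempdir()
  st <- generate_paired_study(n_mirs = 40, n_pairs = 1,
                              hemolysis_pct = 0.25, seed = 23)
  paths <- write_bundle(st, dir)
  res <- suppressMessages(qc_report(paths$cq, paths$sheet,
                                    file.path(dir, "out")))
  expect_true(all(res$report$tier %in%
                    c("elevated_one_pair", "stable", "hemolysis_specific",
                      "indeterminate")))
})

test_that("hemolysis assessment runs from A414 tables and from spectra files", {
  dir <- withr::local_tempdir()
  a414 <- file.path(dir, "a414.tsv")
  utils::write.table(
    data.frame(sample_id = c("NH", "H"), a414 = c(0.143, 0.574),
               reference_a414 = c(0.143, 0.143)),
    a414, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- qc_assess(a414, output = file.path(dir, "assess.tsv"))
  expect_equal(res$label, c("non_hemolyzed", "hemolyzed"))
  expect_equal(res$degree_relative[2], 4.01, tolerance = 0.01)
  expect_true(file.exists(file.path(dir, "assess.tsv")))

  sp_file <- file.path(dir, "spectra.tsv")
  sp <- simulate_spectrum(2, sample_id = "S_heavy")
  write_spectrum(sp, sp_file)
  res2 <- qc_assess(sp_file)
  expect_equal(res2$label, "hemolyzed")
  expect_true(res2$severe)

  flat <- file.path(dir, "flat.tsv")
  write_spectrum(absorbance_spectrum(seq(350, 650, 2), rep(0.1, 151), "F"),
                 flat)
  expect_equal(qc_assess(flat)$label, "non_hemolyzed")
  expect_error(qc_assess(file.path(dir, "nope.tsv")), "not found")
})

test_that("the dilution command writes trajectories with correct calls", {
  dir <- withr::local_tempdir()
  sim <- generate_dilution_series(n_mirs = 15, noise_sd = 0.1, seed = 99)
  cqf <- file.path(dir, "cq.tsv")
  write_cq_table(sim$cq_table, cqf)
  shf <- file.path(dir, "sheet.tsv")
  write_sample_sheet(sim$sheet, shf)
  res <- qc_dilution(cqf, shf, file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "trajectories.tsv")))
  strong <- sim$truth$mir_id[sim$truth$truth_label == "susceptible" &
                               sim$truth$enrichment_k > 5000]
  expect_true(all(res$call[res$mir_id %in% strong] == "affected"))
})

test_that("simulate writes the full artifact bundle deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- scenario_config("paired", n_mirs = 10)
  f1 <- qc_simulate(d1, seed = 42, cfg = cfg)
  qc_simulate(d2, seed = 42, cfg = cfg)
  expect_true(all(file.exists(file.path(d1, c("cq_run1.tsv", "cq_run2.tsv",
                                              "sample_sheet.tsv",
                                              "spectra.tsv", "truth.tsv")))))
  for (f in basename(f1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  truth <- utils::read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(truth), 10)
})
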