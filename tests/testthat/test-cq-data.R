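write_lines_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("wide Cq tables parse with explicit undetected handling", {
  f <- write_lines_tsv(c("mir_id\tS1\tS2",
                         "miR-a\t24.5\tUndetermined",
                         "miR-b\t33.1\t30.2"))
  tab <- read_cq_table(f)
  expect_s3_class(tab, "cq_table")
  expect_equal(sum(is.na(tab$cq)), 1L)
  expect_equal(tab$cq[tab$mir_id == "miR-a" & tab$sample_id == "S1"], 24.5)

  # sample:replicate headers
  f2 <- write_lines_tsv(c("mir_id\tS1:1\tS1:2", "miR-a\t24.0\t25.0"))
  tab2 <- read_cq_table(f2)
  expect_equal(sort(tab2$replicate), c(1L, 2L))

  # out-of-range and duplicate assays are refused
  f3 <- write_lines_tsv(c("mir_id\tS1", "miR-a\t41.2"))
  expect_error(read_cq_table(f3), "\\(0, 40\\]")
  f4 <- write_lines_tsv(c("mir_id\tS1", "miR-a\t24", "miR-a\t25"))
  expect_error(read_cq_table(f4), "duplicate assay")
  f5 <- write_lines_tsv(c("mir_id\tS1", "miR-a\tnot_a_number"))
  expect_error(read_cq_table(f5), "non-numeric")
})

test_that("Cq tables round-trip through the wide dialect", {
  study <- generate_paired_study(n_mirs = 25, seed = 5)
  tab <- study$cq_tables[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(tab, f)
  back <- read_cq_table(f)
  ord <- function(t) {
    t <- as.data.frame(t)
    t[order(t$mir_id, t$sample_id, t$replicate), ]
  }
  a <- ord(tab); b <- ord(back)
  expect_equal(a$cq, b$cq, tolerance = 1e-12)
  expect_identical(is.na(a$cq), is.na(b$cq))
})

test_that("replicate collapsing follows the conservative duplicate rule", {
  m <- data.frame(mir_id = "miR-a", sample_id = "S1", replicate = 1:2,
                  cq = c(24, 25))
  expect_equal(collapse_replicates(cq_table(m))$cq, 24.5)
  m$cq <- c(NA, NA)
  expect_true(is.na(collapse_replicates(cq_table(m))$cq))
  m$cq <- c(33, NA)
  expect_true(is.na(collapse_replicates(cq_table(m))$cq))
  expect_equal(collapse_replicates(cq_table(m), "detected_only")$cq, 33)
  # one slot per (mir, sample); re-collapsing is identity
  study <- generate_paired_study(n_mirs = 15, seed = 9)
  col <- collapse_replicates(study$cq_tables[[1]])
  expect_equal(nrow(col), length(unique(col$mir_id)) *
                 length(unique(col$sample_id)))
  expect_equal(as.data.frame(collapse_replicates(col)), as.data.frame(col))
})

test_that("detection is strict at the Cq cutoff and mask counts match a loop oracle", {
  m <- matrix(c(34.99, 35.00, NA, 20), 2, 2,
              dimnames = list(c("a", "b"), c("S1", "S2")))
  mask <- detection_mask(cq_from_matrix(m), max_cq = 35)
  expect_identical(as.vector(mask), c(TRUE, FALSE, FALSE, TRUE))

  set.seed(3)
  m <- matrix(runif(120, 25, 40), 20, 6,
              dimnames = list(paste0("m", 1:20), paste0("S", 1:6)))
  m[sample(length(m), 15)] <- NA
  tab <- cq_from_matrix(m)
  mask <- detection_mask(tab, 35)
  for (j in 1:6) {
    manual <- 0L
    for (i in 1:20) if (!is.na(m[i, j]) && m[i, j] < 35) manual <- manual + 1L
    expect_equal(sum(mask[, j]), manual)
  }
  # monotone in the threshold
  expect_true(all(detection_mask(tab, 30) <= detection_mask(tab, 35)))
  expect_error(detection_mask(generate_paired_study(n_mirs = 4, seed = 1)$cq_tables[[1]]),
               "collapsed")
})

test_that("detectability filter matches enumeration and is idempotent", {
  set.seed(8)
  m <- matrix(runif(60, 28, 39), 10, 6,
              dimnames = list(paste0("m", 1:10), paste0("S", 1:6)))
  m[1, ] <- 36                     # beyond cutoff everywhere -> dropped
  m[2, ] <- c(30, 30, 30, 30, 36, 36)  # detected in 4/6 -> kept
  tab <- cq_from_matrix(m)
  kept <- filter_detectable(tab, colnames(m), min_detected_samples = 4)
  expected <- rownames(m)[vapply(seq_len(10), function(i)
    sum(!is.na(m[i, ]) & m[i, ] < 35) >= 4, logical(1))]
  expect_setequal(unique(kept$mir_id), expected)
  expect_true("m2" %in% kept$mir_id)
  expect_false("m1" %in% kept$mir_id)
  again <- filter_detectable(kept, colnames(m), min_detected_samples = 4)
  expect_equal(as.data.frame(again), as.data.frame(kept))
  expect_error(filter_detectable(tab, colnames(m), min_detected_samples = 7),
               "exceeds")
  expect_error(filter_detectable(tab, character(0)), "nonempty")
})

test_that("sample sheets enforce the pairing and dilution invariants", {
  ok <- pair_sheet(2)
  expect_s3_class(ok, "sample_sheet")
  bad <- as.data.frame(ok)
  bad$condition[2] <- "non_hemolyzed"   # two NH in one pair
  expect_error(validate_sample_sheet(bad), "pair")
  dil <- data.frame(sample_id = "d1", subject_id = "x",
                    condition = "dilution", pair_id = "", a414 = 0.14,
                    rbc_fraction = NA)
  expect_error(validate_sample_sheet(dil), "rbc_fraction")
  dil$rbc_fraction <- 0.125
  expect_s3_class(validate_sample_sheet(dil), "sample_sheet")
  dup <- rbind(as.data.frame(ok), as.data.frame(ok)[1, ])
  expect_error(validate_sample_sheet(dup), "duplicate")
})
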