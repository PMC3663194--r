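test_that("pair fold change is the un-normalized 2^-deltaCq", {
  expect_equal(pair_fold_change(25, 25), 1.0)
  expect_equal(pair_fold_change(24, 25), 2.0)
  expect_equal(pair_fold_change(22.68, 26.0), 2^3.32)
  expect_true(is.na(pair_fold_change(NA, 25)))
  # reciprocal symmetry
  set.seed(4)
  a <- runif(20, 20, 35); b <- runif(20, 20, 35)
  expect_equal(pair_fold_change(a, b) * pair_fold_change(b, a), rep(1, 20))
  expect_equal(fc_status(c(24, 24, NA, NA), c(25, NA, 25, NA)),
               c("ok", "hemolyzed_only", "nonhemolyzed_only",
                 "both_undetected"))
})

test_that("fold-change table summarizes runs and flags one-sided detection", {
  m <- matrix(c(25, 24,    # mir x (P1_NH, P1_H): detected both sides
                NA, 30,    # hemolyzed only
                30, NA,    # non-hemolyzed only
                NA, NA),   # neither
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("m", 1:4), c("P1_NH", "P1_H")))
  m <- cbind(m, RBC = c(20, 21, 22, 23))
  sheet <- pair_sheet(1, rbc = TRUE)
  fcs <- fold_change_matrix(cq_from_matrix(m), sheet)
  expect_equal(fcs$status,
               c("ok", "hemolyzed_only", "nonhemolyzed_only",
                 "both_undetected"))
  expect_equal(fcs$mean_fc[1], 2.0)
  expect_true(all(is.na(fcs$mean_fc[-1])))
  # species detected in hemolyzed plasma and RBC but never in NH plasma
  # feeds the hemolysis-specific call
  expect_equal(identify_specific(cq_from_matrix(m), sheet), "m2")

  # identical runs give sd 0
  fcs2 <- fold_change_matrix(list(cq_from_matrix(m), cq_from_matrix(m)),
                             sheet)
  expect_equal(fcs2$sd_fc[fcs2$status == "ok"], 0)
  expect_equal(fcs2$n_runs_ok[1], 2L)

  # missing pair member is a design error
  sheet2 <- pair_sheet(2)
  expect_error(fold_change_matrix(cq_from_matrix(m), sheet2), "P2")
})

test_that("noise-free paired study reproduces 1 + f*k exactly", {
  st <- generate_paired_study(n_mirs = 30, noise_sd = 0, seed = 21)
  fcs <- fold_change_matrix(st$cq_tables, st$sheet)
  f_of_pair <- c(pair1 = 0.05, pair2 = 0.125, pair3 = 0.25) / 100
  ok <- fcs$status == "ok"
  k <- st$truth$enrichment_k[match(fcs$mir_id, st$truth$mir_id)]
  expected <- 1 + f_of_pair[fcs$pair_id] * k
  expect_equal(fcs$mean_fc[ok], unname(expected[ok]), tolerance = 1e-12)
})

test_that("log2 clip matrix is monotone, bounded and NA for one-sided entries", {
  fcs <- data.frame(mir_id = c("a", "b", "c", "d"), pair_id = "pair1",
                    mean_fc = c(1.0, 14.06, 0.5, NA), sd_fc = NA,
                    n_runs_ok = 1L,
                    status = c("ok", "ok", "ok", "hemolyzed_only"))
  m <- log2_clip_matrix(fcs, limit = 3.3)
  expect_equal(m["a", 1], 0.0)
  expect_equal(m["b", 1], 3.3)   # 14.06-fold clips at the 10-fold limit
  expect_equal(m["c", 1], -1.0)
  expect_true(is.na(m["d", 1]))
  fc_grid <- sort(exp(runif(40, -4, 4)))
  vals <- log2_clip_matrix(
    data.frame(mir_id = paste0("m", seq_along(fc_grid)), pair_id = "p",
               mean_fc = fc_grid, sd_fc = NA, n_runs_ok = 1L,
               status = "ok"), 3.3)[, 1]
  expect_false(is.unsorted(vals))
  expect_true(all(abs(vals) <= 3.3))
})

test_that("collapsed-Cq fold change equals the geometric mean of per-replicate fold changes", {
  set.seed(6)
  for (i in 1:10) {
    h <- runif(3, 22, 30)
    nh <- runif(3, 22, 30)
    collapsed <- pair_fold_change(mean(h), mean(nh))
    geo <- exp(mean(log(pair_fold_change(h, nh))))
    expect_equal(collapsed, geo, tolerance = 1e-12)
  }
})

test_that("hemolysis indicator grows with RBC signal in the Cq table", {
  expect_equal(hemolysis_ratio(20, 27), 7)
  expect_equal(hemolysis_ratio(25, 25), 0)
  # noise-free dilution: indicator strictly increases with %RBC when the
  # affected species is far more RBC-enriched than the stable one
  mirs <- data.frame(mir_id = c("hsa-miR-451", "hsa-miR-23a"),
                     truth_label = c("susceptible", "stable"),
                     baseline_cq = c(26, 27), enrichment_k = c(15000, 10))
  params <- structure(list(mirs = mirs, noise_sd = 0, censor_cq = 40,
                           detect_cq = 35), class = "mixing_model_params")
  f <- c(0, 0.008, 0.016, 0.031, 0.0625, 0.125)
  df <- data.frame(
    mir_id = rep(mirs$mir_id, each = length(f)),
    sample_id = rep(paste0("d", seq_along(f)), 2),
    replicate = 1L,
    cq = c(simulate_cq(params, "hsa-miR-451", f),
           simulate_cq(params, "hsa-miR-23a", f)))
  rt <- hemolysis_ratio_table(cq_table(df, collapsed = TRUE))
  ind <- rt$indicator[match(paste0("d", seq_along(f)), rt$sample_id)]
  expect_true(all(diff(ind) > 0))
  expect_true(all(rt$status == "ok"))
})
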