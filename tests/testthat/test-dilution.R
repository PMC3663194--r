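# printed mean Cqs of four hemolysis-stable assays over the six-point series
stable_fixture <- function() {
  tab <- read_cq_table(extdata("stable_mir_dilution_cq.tsv"))
  sheet <- read_sample_sheet(extdata("stable_mir_dilution_sheet.tsv"))
  list(tab = tab, sheet = sheet)
}

test_that("trajectory statistics match hand-checked values on the printed series", {
  fx <- stable_fixture()
  series <- dilution_series(fx$tab, fx$sheet)
  expect_equal(series$fractions, c(0, 0.008, 0.016, 0.031, 0.0625, 0.125))

  s146 <- trajectory_stats(series, "miR-146a")
  expect_equal(s146$cq_range, 26.02 - 25.80, tolerance = 1e-12)

  s142 <- trajectory_stats(series, "miR-142-3p")
  expect_equal(s142$cq_range, 1.00, tolerance = 1e-12)
  # Spearman by hand: ranks of (24.33,24.55,24.34,23.86,23.65,23.55) are
  # (4,6,5,3,2,1) against fraction ranks (1..6): rho = 1 - 6*64/210
  expect_equal(s142$rank_correlation, 1 - 6 * 64 / 210, tolerance = 1e-12)
  expect_equal(s142$net_shift, 24.33 - 23.55, tolerance = 1e-12)
})

test_that("constant trajectories score zero range and zero rank correlation", {
  m <- matrix(26, 1, 6, dimnames = list("const", paste0("d", 1:6)))
  sheet <- read_sample_sheet(extdata("stable_mir_dilution_sheet.tsv"))
  st <- trajectory_stats(dilution_series(cq_from_matrix(m), sheet))
  expect_equal(st$cq_range, 0)
  expect_equal(st$rank_correlation, 0)
})

test_that("the affected call needs both magnitude and a monotone trend", {
  fx <- stable_fixture()
  res <- analyze_dilution(fx$tab, fx$sheet)
  # miR-142-3p trends strongly (rho ~ -0.83) but moves only 1.00 cycles
  expect_true(all(res$call == "unaffected"))

  # monotone in cq_range at fixed rho
  st <- data.frame(mir_id = "x", n_points = 6, cq_range = c(0.5, 1.0, 1.1, 2),
                   rank_correlation = -1, net_shift = 1, status = "ok")
  calls <- classify_trajectory(st)$call
  expect_equal(calls, c("unaffected", "unaffected", "affected", "affected"))

  # wide range without trend stays unaffected
  st2 <- data.frame(mir_id = "y", n_points = 6, cq_range = 3,
                    rank_correlation = 0.1, net_shift = 0, status = "ok")
  expect_equal(classify_trajectory(st2)$call, "unaffected")
})

test_that("a strongly RBC-enriched species is called affected in synthetic series", {
  sim <- generate_dilution_series(n_mirs = 20, noise_sd = 0, seed = 12)
  res <- analyze_dilution(sim$cq_table, sim$sheet)
  truth <- sim$truth
  sus <- truth$mir_id[truth$truth_label == "susceptible" &
                        truth$enrichment_k >= 2000]
  sta <- truth$mir_id[truth$truth_label == "stable"]
  expect_true(all(res$call[res$mir_id %in% sus] == "affected"))
  expect_true(all(res$call[res$mir_id %in% sta] == "unaffected"))
  # net shift of a k = 2000 species ~ log2(1 + 0.00125*2000) = 1.81 cycles,
  # inside the 1.5-2.4 band seen for validated susceptible microRNAs
  expect_equal(log2(1 + 0.00125 * 2000), 1.807, tolerance = 1e-3)
})

test_that("the affected boundary sits at the closed-form k* (bisection oracle)", {
  f_max <- 0.00125
  target <- function(k) log2(1 + f_max * k) - 1.1
  lo <- 1; hi <- 1e5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) hi <- mid else lo <- mid
  }
  k_star <- (lo + hi) / 2
  expect_equal(log2(1 + f_max * k_star), 1.1, tolerance = 1e-9)

  run_k <- function(k) {
    f <- c(0, 0.008, 0.016, 0.031, 0.0625, 0.125)
    cq <- 27 - log2(1 + (f / 100) * k)
    m <- matrix(cq, 1, 6, dimnames = list("x", paste0("d", 1:6)))
    sheet <- read_sample_sheet(extdata("stable_mir_dilution_sheet.tsv"))
    analyze_dilution(cq_from_matrix(m), sheet)$call
  }
  expect_equal(run_k(k_star * 0.98), "unaffected")
  expect_equal(run_k(k_star * 1.02), "affected")
})

test_that("averaging two independent series shrinks point scatter by about 1/sqrt(2)", {
  dev_for <- function(n_series, seed) {
    set.seed(seed + 1000L)
    p <- mixing_model_params(n_mirs = 4,
                             label_props = c(susceptible = 0, stable = 1,
                                             specific = 0),
                             stable_k_range = c(0, 0), noise_sd = 0.5)
    sim <- generate_dilution_series(n_series = n_series, n_duplicates = 1,
                                    seed = seed, params = p)
    series <- dilution_series(sim$cq_table, sim$sheet)
    truth <- sim$truth
    as.vector(series$mean_cq - truth$baseline_cq[match(rownames(series$mean_cq),
                                                       truth$mir_id)])
  }
  d1 <- unlist(lapply(1:40, function(s) dev_for(1, s)))
  d2 <- unlist(lapply(1:40, function(s) dev_for(2, s + 500)))
  ratio <- sd(d2) / sd(d1)
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.15)

  # missing 0% baseline is a configuration error
  sim <- generate_dilution_series(n_mirs = 3, seed = 2)
  sheet <- sim$sheet[sim$sheet$rbc_fraction > 0, ]
  expect_error(dilution_series(sim$cq_table, sheet), "baseline")
})
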