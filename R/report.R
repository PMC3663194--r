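#' QC run configuration
#'
#' Central container for every tunable threshold of the pipeline, with the
#' standard defaults: A414 hemolysis threshold 0.2 OD, detection cutoff Cq
#' 35, detectability in >= 4 samples, 2-fold elevation, +/-1.5-fold
#' stability band, hemolysis-degree cutoff 2 for subset selection, 1.1-cycle
#' dilution range threshold with Spearman rho <= -0.8, and a +/-3.3 log2
#' heatmap clip.
#'
#' @param a414_threshold OD threshold for the hemolyzed call.
#' @param detect_cq Detection cutoff in cycles.
#' @param min_detected_samples Detectability filter count.
#' @param up_threshold Fold-change threshold for "elevated".
#' @param stable_band Multiplicative stability band half-width.
#' @param degree_cutoff Minimum A414 ratio for subset-selection pairs.
#' @param range_threshold Dilution Cq-range threshold (cycles).
#' @param rho_threshold Dilution Spearman threshold.
#' @param clip_limit Heatmap clip in log2 units.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(a414_threshold = 0.2, detect_cq = 35,
                       min_detected_samples = 4, up_threshold = 2.0,
                       stable_band = 1.5, degree_cutoff = 2.0,
                       range_threshold = 1.1, rho_threshold = -0.8,
                       clip_limit = 3.3) {
  cfg <- list(a414_threshold = a414_threshold, detect_cq = detect_cq,
              min_detected_samples = min_detected_samples,
              up_threshold = up_threshold, stable_band = stable_band,
              degree_cutoff = degree_cutoff,
              range_threshold = range_threshold,
              rho_threshold = rho_threshold, clip_limit = clip_limit)
  pos <- c("a414_threshold", "detect_cq", "min_detected_samples",
           "up_threshold", "stable_band", "degree_cutoff",
           "range_threshold", "clip_limit")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  stopifnot(is.numeric(rho_threshold), length(rho_threshold) == 1L,
            rho_threshold >= -1, rho_threshold <= 1)
  structure(cfg, class = "run_config")
}

qc_log <- function(...) message("[hemoqc] ", ...)

run_log_entry <- function(inputs, config, seed = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "hemoqc",
       version = as.character(utils::packageVersion("hemoqc")),
       thresholds = unclass(config),
       seed = seed,
       input_md5 = digests)
}

#' Hemolysis assessment of a batch of samples
#'
#' Front end over the spectra module. The input is either a long-format
#' spectra file (columns `wavelength_nm`, `od`, optional `sample_id`) or a
#' table of direct A414 readings (columns `sample_id`, `a414`, optional
#' `reference_a414`); the format is sniffed from the header. Spectra inputs
#' additionally get the severe-hemolysis Q-band flag.
#'
#' @param input Path to the spectra or A414 file.
#' @param output Optional TSV path for the assessment table.
#' @param config A [run_config()].
#' @return Data frame `sample_id`, `a414`, `label`, `degree_relative`,
#'   `severe` (invisibly when `output` is written).
#' @export
qc_assess <- function(input, output = NULL, config = run_config()) {
  header <- names(read_delim_auto(input))
  if ("wavelength_nm" %in% header) {
    spectra <- read_spectra(input)
    a414 <- vapply(spectra, absorbance_at, numeric(1), wavelength = 414)
    res <- assess_hemolysis(a414, threshold = config$a414_threshold,
                            spectrum = spectra)
    res <- cbind(sample_id = names(spectra), res)
  } else {
    df <- read_delim_auto(input, colClasses = "character")
    if (!all(c("sample_id", "a414") %in% names(df))) {
      stop("A414 input must have columns sample_id and a414: ", input,
           call. = FALSE)
    }
    ref <- if ("reference_a414" %in% names(df))
      as.numeric(df$reference_a414) else NULL
    res <- assess_hemolysis(as.numeric(df$a414),
                            threshold = config$a414_threshold,
                            reference_a414 = ref)
    res <- cbind(sample_id = df$sample_id, res)
  }
  rownames(res) <- NULL
  if (!is.null(output)) {
    utils::write.table(res, output, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(res))
  }
  res
}

#' Consolidated matched-pair QC report
#'
#' Composes the full pipeline on matched-pair data: read the per-run Cq
#' tables and sample sheet, collapse replicates, apply the detectability
#' filter over the plasma samples, compute per-pair fold changes, identify
#' RBC/hemolysis-specific species (when an RBC sample is present), tier all
#' microRNAs, and select biomarker/endogenous-control subsets (when at
#' least two pairs qualify). Deterministic: identical inputs give
#' byte-identical outputs, and the run log records versions, thresholds and
#' input digests.
#'
#' @param cq_paths Character vector of wide Cq tables, one per independent
#'   run.
#' @param sheet_path Sample-sheet path.
#' @param output_dir Directory for the report bundle: `fold_changes.tsv`,
#'   `tiers.tsv`, `log2_matrix.tsv`, `subsets.json`, `run_log.json`.
#' @param config A [run_config()].
#' @return List with `fold_changes`, `report`, `specific`, `subsets`,
#'   `log2_matrix`, invisibly.
#' @export
qc_report <- function(cq_paths, sheet_path, output_dir,
                      config = run_config()) {
  sheet <- read_sample_sheet(sheet_path)
  tables <- lapply(cq_paths, read_cq_table)
  tables <- lapply(tables, function(t)
    if (is_collapsed(t)) t else collapse_replicates(t))
  plasma <- sheet$sample_id[sheet$condition %in%
                              c("non_hemolyzed", "hemolyzed")]
  if (length(plasma) == 0L) stop("no plasma samples in sample sheet",
                                 call. = FALSE)
  # specific species are sought among *all* assays: by definition they fail
  # the plasma detectability filter (absent from non-hemolyzed plasma)
  specific <- character(0)
  if (any(sheet$condition == "rbc")) {
    pooled <- cq_table(do.call(rbind, lapply(seq_along(tables), function(r) {
      t <- as.data.frame(tables[[r]])
      t$replicate <- r
      t
    })), collapsed = FALSE)
    specific <- identify_specific(collapse_replicates(pooled,
                                                      "detected_only"),
                                  sheet, detect_cq = config$detect_cq)
  }
  tables <- lapply(tables, function(t) {
    subset <- intersect(plasma, unique(t$sample_id))
    filter_detectable(t, sample_subset = subset,
                      min_detected_samples = min(config$min_detected_samples,
                                                 length(subset)),
                      max_cq = config$detect_cq)
  })
  # keep the assays that pass the filter in every run
  keep <- Reduce(intersect, lapply(tables, function(t) unique(t$mir_id)))
  tables <- lapply(tables, function(t)
    cq_table(t[t$mir_id %in% keep, ], collapsed = TRUE))
  qc_log(length(keep), " assays pass the detectability filter")

  fcs <- fold_change_matrix(tables, sheet, detect_cq = config$detect_cq)
  report <- tier_mirnas(fcs, up_threshold = config$up_threshold,
                        stable_band = config$stable_band,
                        specific_ids = specific)
  subsets <- tryCatch(
    select_subsets(fcs, sheet, degree_cutoff = config$degree_cutoff,
                   up_threshold = config$up_threshold,
                   stable_band = config$stable_band),
    error = function(e) {
      qc_log("subset selection skipped: ", conditionMessage(e))
      NULL
    })
  m <- log2_clip_matrix(fcs, limit = config$clip_limit)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_fold_changes(fcs, file.path(output_dir, "fold_changes.tsv"))
  write_susceptibility_report(report, fcs,
                              file.path(output_dir, "tiers.tsv"),
                              subsets = subsets)
  write_log2_matrix(m, file.path(output_dir, "log2_matrix.tsv"))
  summary <- list(tier_counts = as.list(tier_summary(report)$tier_counts),
                  specific = as.list(specific),
                  changing = as.list(subsets$changing %||% character(0)),
                  unaffected = as.list(subsets$unaffected %||% character(0)))
  jsonlite::write_json(summary, file.path(output_dir, "subsets.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(run_log_entry(c(cq_paths, sheet_path), config),
                       file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fold_changes = fcs, report = report, specific = specific,
                 subsets = subsets, log2_matrix = m))
}

#' Dilution-series trajectory report
#'
#' Reads the Cq table(s) and sample sheet of an RBC dilution experiment and
#' writes the per-microRNA trajectory statistics and affected/unaffected
#' calls.
#'
#' @param cq_paths Character vector of wide Cq tables (pooled; independent
#'   series are distinguished by the sample sheet).
#' @param sheet_path Sample-sheet path (condition `dilution`).
#' @param output_dir Directory for `trajectories.tsv` and `run_log.json`.
#' @param config A [run_config()].
#' @return The classified trajectory data frame, invisibly.
#' @export
qc_dilution <- function(cq_paths, sheet_path, output_dir,
                        config = run_config()) {
  sheet <- read_sample_sheet(sheet_path)
  tables <- lapply(cq_paths, read_cq_table)
  pooled <- do.call(rbind, lapply(seq_along(tables), function(r) {
    t <- as.data.frame(collapse_replicates(tables[[r]]))
    t$sample_id <- t$sample_id
    t$replicate <- r
    t
  }))
  # several input tables measure the same samples -> average across tables
  pooled <- collapse_replicates(cq_table(pooled), policy = "detected_only")
  res <- analyze_dilution(pooled, sheet, detect_cq = config$detect_cq,
                          range_threshold = config$range_threshold,
                          rho_threshold = config$rho_threshold)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(output_dir, "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(run_log_entry(c(cq_paths, sheet_path), config),
                       file.path(output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Simulate a synthetic study and write its bundle
#'
#' @param output_dir Directory for the artifact files (Cq tables, sample
#'   sheet, spectra, truth labels, scenario config).
#' @param seed Mandatory integer seed.
#' @param cfg A [scenario_config()] (default: the standard paired design).
#' @return Character vector of files written, invisibly.
#' @export
qc_simulate <- function(output_dir, seed, cfg = scenario_config("paired")) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  study <- simulate_from_config(cfg, seed = seed)
  files <- write_study(study, output_dir)
  cfg$seed <- as.integer(seed)
  cfgf <- file.path(output_dir, "scenario.yaml")
  write_scenario_config(cfg, cfgf)
  invisible(c(files, cfgf))
}
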