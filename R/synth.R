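#' Parameters of the RBC-contamination mixing model
#'
#' The generator's core model: each microRNA has a clean-plasma abundance
#' `2^-baseline_cq` (linear scale) and lysed RBC material adds `k` times
#' that baseline per unit lysed-RBC volume fraction `f`, so the measured
#' quantity is `2^-baseline_cq * (1 + f * k)` and
#'
#' `Cq(f) = baseline_cq - log2(1 + f * k) (+ Gaussian replicate noise).`
#'
#' This linear-abundance mixing is the minimal model consistent with a
#' volumetric spike-in design and 2^-deltaCq semantics. Truth labels:
#'
#' * `susceptible` — `k` log-uniform in `susceptible_k_range` (defaults
#'   produce 1.5-2.4+ cycle shifts at 0.125% RBC, the magnitude seen for
#'   RBC-enriched plasma microRNAs);
#' * `stable` — `k` uniform in `stable_k_range` (<= ~0.15-cycle shift);
#' * `specific` — absent from clean plasma: `baseline_cq` fixed at
#'   `specific_baseline_cq` (>= the censor limit, so undetected at `f = 0`)
#'   with very large `k`, giving pure-lysate Cqs near 21-23.
#'
#' Values beyond `censor_cq` are censored to the undetected state;
#' `detect_cq` is the downstream detection cutoff.
#'
#' Draws use the current RNG state; call [set.seed()] (or use the
#' `generate_*` wrappers, which seed for you) for reproducibility.
#'
#' @param n_mirs Number of microRNA assays.
#' @param label_props Named proportions for `susceptible`, `stable`,
#'   `specific`; must sum to 1.
#' @param susceptible_k_range,stable_k_range,specific_k_range Ranges for the
#'   enrichment factor `k` per truth label.
#' @param baseline_cq_range Clean-plasma baseline Cq range (cycles).
#' @param specific_baseline_cq Nominal baseline for specific species; must
#'   be >= `censor_cq`.
#' @param noise_sd Per-replicate Gaussian Cq noise (cycles).
#' @param censor_cq Censoring limit of the instrument (cycles).
#' @param detect_cq Detection cutoff used downstream (cycles).
#' @return Object of class `"mixing_model_params"`: list with per-microRNA
#'   data frame `mirs` (`mir_id`, `truth_label`, `baseline_cq`,
#'   `enrichment_k`) and the global settings.
#' @export
mixing_model_params <- function(n_mirs = 200,
                                label_props = c(susceptible = 0.45,
                                                stable = 0.45,
                                                specific = 0.10),
                                susceptible_k_range = c(800, 20000),
                                stable_k_range = c(0, 80),
                                specific_k_range = c(2^22, 2^24),
                                baseline_cq_range = c(24, 34),
                                specific_baseline_cq = 45,
                                noise_sd = 0.25,
                                censor_cq = 40,
                                detect_cq = 35) {
  need <- c("susceptible", "stable", "specific")
  if (!all(need %in% names(label_props))) {
    stop("`label_props` must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  label_props <- label_props[need]
  if (abs(sum(label_props) - 1) > 1e-8) {
    stop("`label_props` must sum to 1 (got ", format(sum(label_props)), ")",
         call. = FALSE)
  }
  stopifnot(n_mirs >= 1, noise_sd >= 0,
            specific_baseline_cq >= censor_cq,
            baseline_cq_range[1] > 15, baseline_cq_range[2] < 40)
  counts <- floor(label_props * n_mirs)
  rem <- n_mirs - sum(counts)
  if (rem > 0) {
    top <- order(label_props * n_mirs - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  labels <- rep(need, counts)
  k <- numeric(n_mirs)
  sus <- labels == "susceptible"
  sta <- labels == "stable"
  spe <- labels == "specific"
  loguni <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  k[sus] <- loguni(sum(sus), susceptible_k_range)
  k[sta] <- stats::runif(sum(sta), stable_k_range[1], stable_k_range[2])
  k[spe] <- loguni(sum(spe), specific_k_range)
  baseline <- stats::runif(n_mirs, baseline_cq_range[1], baseline_cq_range[2])
  baseline[spe] <- specific_baseline_cq
  mirs <- data.frame(
    mir_id = sprintf("syn-miR-%03d", seq_len(n_mirs)),
    truth_label = labels,
    baseline_cq = baseline,
    enrichment_k = k,
    stringsAsFactors = FALSE)
  structure(list(mirs = mirs, noise_sd = noise_sd, censor_cq = censor_cq,
                 detect_cq = detect_cq),
            class = "mixing_model_params")
}

#' Simulate a Cq reading under the mixing model
#'
#' @param params A [mixing_model_params()] object.
#' @param mir_id One microRNA id from `params$mirs`.
#' @param f_pct RBC contamination as %RBC by volume (vectorized; >= 0). The
#'   pure lysate corresponds to `f_pct = 100`.
#' @param noise_sd Per-draw Gaussian noise in cycles; defaults to the
#'   model's `noise_sd`. Uses the current RNG state.
#' @return Numeric Cq vector; `NA` where the draw exceeds the censor limit
#'   (undetected).
#' @export
simulate_cq <- function(params, mir_id, f_pct, noise_sd = NULL) {
  stopifnot(inherits(params, "mixing_model_params"))
  row <- match(mir_id, params$mirs$mir_id)
  if (is.na(row)) stop("unknown microRNA id: ", mir_id, call. = FALSE)
  f_pct <- as.numeric(f_pct)
  if (any(!is.finite(f_pct)) || any(f_pct < 0)) {
    stop("`f_pct` must be finite and >= 0", call. = FALSE)
  }
  noise_sd <- noise_sd %||% params$noise_sd
  sim_cq_core(params$mirs$baseline_cq[row], params$mirs$enrichment_k[row],
              pct_to_frac(f_pct), noise_sd, params$censor_cq)
}

# vectorized model core; f is the lysed-RBC volume *fraction*
sim_cq_core <- function(baseline_cq, k, f, noise_sd, censor_cq) {
  raw <- baseline_cq - log2(1 + f * k)
  if (any(raw <= 0)) {
    stop("mixing model produced Cq <= 0; parameterization invalid",
         call. = FALSE)
  }
  if (noise_sd > 0) raw <- raw + stats::rnorm(length(raw), 0, noise_sd)
  raw[raw > censor_cq] <- NA_real_
  raw
}

#' Parameters of the synthetic hemoglobin spectrum model
#'
#' The simulated spectrum is a gently sloping plasma background plus a
#' Soret-band Gaussian at 414 nm and two Q-band Gaussians at 541/576 nm
#' whose amplitude is a fixed fraction of the Soret amplitude. The Soret
#' amplitude is scaled so the spectrum's OD at 414 nm reproduces the linear
#' calibration `A414(f) = baseline_a414 + slope * f_pct` exactly; the
#' default slope is the line through a clean-plasma reading of 0.143 OD and
#' 0.626 OD at 0.125% RBC.
#'
#' @param baseline_a414 Clean-plasma OD at 414 nm.
#' @param slope OD per %RBC by volume.
#' @param soret_center,soret_width Soret band center and Gaussian sigma (nm).
#' @param q_band_centers,q_band_width Q-band centers and sigma (nm).
#' @param q_band_relative_amplitude Q-band amplitude as a fraction of the
#'   Soret amplitude.
#' @param background_slope OD per nm of the sloping plasma background.
#' @return List of class `"spectrum_model_params"`.
#' @export
spectrum_model_params <- function(baseline_a414 = 0.143,
                                  slope = (0.626 - 0.143) / 0.125,
                                  soret_center = 414, soret_width = 15,
                                  q_band_centers = c(541, 576),
                                  q_band_width = 8,
                                  q_band_relative_amplitude = 0.1,
                                  background_slope = -2e-4) {
  stopifnot(baseline_a414 >= 0, slope >= 0, soret_width > 0,
            q_band_width > 0, q_band_relative_amplitude >= 0)
  structure(list(baseline_a414 = baseline_a414, slope = slope,
                 soret_center = soret_center, soret_width = soret_width,
                 q_band_centers = q_band_centers, q_band_width = q_band_width,
                 q_band_relative_amplitude = q_band_relative_amplitude,
                 background_slope = background_slope),
            class = "spectrum_model_params")
}

# closed-form A414 of the spectrum model (the generator's calibration line)
a414_of <- function(params, f_pct) {
  params$baseline_a414 + params$slope * f_pct
}

#' Simulate a plasma absorbance spectrum
#'
#' @param f_pct RBC contamination as %RBC by volume (scalar, >= 0).
#' @param params A [spectrum_model_params()].
#' @param wavelengths Sampling grid in nm.
#' @param noise_sd Optional OD measurement noise (uses the current RNG).
#' @param sample_id Sample identifier.
#' @return An [absorbance_spectrum()]. Noise-free, its OD at 414 nm equals
#'   `baseline_a414 + slope * f_pct` to machine precision.
#' @export
simulate_spectrum <- function(f_pct, params = spectrum_model_params(),
                              wavelengths = seq(350, 650, by = 2),
                              noise_sd = 0, sample_id = NA_character_) {
  stopifnot(inherits(params, "spectrum_model_params"),
            length(f_pct) == 1L, f_pct >= 0)
  shape <- function(wl) {
    s <- exp(-(wl - params$soret_center)^2 / (2 * params$soret_width^2))
    for (c0 in params$q_band_centers) {
      s <- s + params$q_band_relative_amplitude *
        exp(-(wl - c0)^2 / (2 * params$q_band_width^2))
    }
    s
  }
  background <- function(wl) {
    params$baseline_a414 + params$background_slope * (wl - params$soret_center)
  }
  # scale so OD(414) hits the calibration line exactly
  amp <- params$slope * f_pct / shape(params$soret_center)
  od <- background(wavelengths) + amp * shape(wavelengths)
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  od <- pmax(od, -0.049)
  absorbance_spectrum(wavelengths, od, sample_id)
}

#' Generate a synthetic matched-pair hemolysis study
#'
#' Emulates the core study design: for each matched pair, a non-hemolyzed
#' plasma sample at 0% RBC and a hemolyzed counterpart at that pair's
#' contamination level; one pure RBC lysate sample (`f_pct = 100`); two
#' independent runs (RNA isolations), each measured in duplicate; matching
#' absorbance readings; and the truth labels needed for recovery tests.
#'
#' @param n_mirs Number of microRNA assays.
#' @param n_pairs Number of matched pairs.
#' @param hemolysis_pct %RBC contamination of each pair's hemolyzed member
#'   (length `n_pairs`). Defaults span mild to heavy hemolysis (A414 degree
#'   ratios ~2.4-7.8).
#' @param label_props,noise_sd Passed to [mixing_model_params()].
#' @param n_runs Independent runs (separate Cq tables).
#' @param n_duplicates qPCR duplicates within each run.
#' @param seed Mandatory integer seed; the generator has no hidden
#'   randomness.
#' @param params Optional pre-built [mixing_model_params()]; when supplied,
#'   `n_mirs`, `label_props` and `noise_sd` are ignored.
#' @param spectrum_params A [spectrum_model_params()].
#' @param include_rbc Include the pure-lysate RBC sample (needed by
#'   [identify_specific()]).
#' @return List with `cq_tables` (list of [cq_table()], one per run),
#'   `sheet` (sample sheet with per-sample A414 from the spectrum
#'   calibration), `spectra` (noise-free [absorbance_spectrum()] per plasma
#'   sample), `truth` (per-microRNA labels and model parameters) and
#'   `params`.
#' @export
generate_paired_study <- function(n_mirs = 200, n_pairs = 3,
                                  hemolysis_pct = c(0.05, 0.125, 0.25),
                                  label_props = c(susceptible = 0.45,
                                                  stable = 0.45,
                                                  specific = 0.10),
                                  noise_sd = 0.25, n_runs = 2,
                                  n_duplicates = 2, seed,
                                  params = NULL,
                                  spectrum_params = spectrum_model_params(),
                                  include_rbc = TRUE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_pairs >= 1, length(hemolysis_pct) == n_pairs,
            all(hemolysis_pct > 0), n_runs >= 1, n_duplicates >= 1)
  set.seed(as.integer(seed))
  if (is.null(params)) {
    params <- mixing_model_params(n_mirs = n_mirs, label_props = label_props,
                                  noise_sd = noise_sd)
  }
  pair_ids <- sprintf("pair%d", seq_len(n_pairs))
  sheet <- data.frame(
    sample_id = c(rbind(sprintf("P%d_NH", seq_len(n_pairs)),
                        sprintf("P%d_H", seq_len(n_pairs)))),
    subject_id = rep(sprintf("subj%d", seq_len(n_pairs)), each = 2L),
    condition = rep(c("non_hemolyzed", "hemolyzed"), n_pairs),
    pair_id = rep(pair_ids, each = 2L),
    a414 = c(rbind(a414_of(spectrum_params, 0),
                   a414_of(spectrum_params, hemolysis_pct))),
    rbc_fraction = NA_real_,
    stringsAsFactors = FALSE)
  f_pct_of <- c(rbind(rep(0, n_pairs), hemolysis_pct))
  names(f_pct_of) <- sheet$sample_id
  if (include_rbc) {
    sheet <- rbind(sheet, data.frame(
      sample_id = "RBC", subject_id = "donor", condition = "rbc",
      pair_id = "", a414 = NA_real_, rbc_fraction = NA_real_,
      stringsAsFactors = FALSE))
    f_pct_of <- c(f_pct_of, RBC = 100)
  }
  sheet <- validate_sample_sheet(sheet)

  cq_tables <- lapply(seq_len(n_runs), function(r) {
    grid <- expand.grid(mir = seq_len(nrow(params$mirs)),
                        sample = names(f_pct_of),
                        replicate = seq_len(n_duplicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cq <- sim_cq_core(params$mirs$baseline_cq[grid$mir],
                      params$mirs$enrichment_k[grid$mir],
                      pct_to_frac(f_pct_of[grid$sample]),
                      params$noise_sd, params$censor_cq)
    cq_table(data.frame(mir_id = params$mirs$mir_id[grid$mir],
                        sample_id = grid$sample,
                        replicate = grid$replicate,
                        cq = cq, stringsAsFactors = FALSE),
             collapsed = n_duplicates == 1L)
  })

  plasma <- sheet$sample_id[sheet$condition != "rbc"]
  spectra <- lapply(plasma, function(s)
    simulate_spectrum(f_pct_of[[s]], spectrum_params, sample_id = s))
  names(spectra) <- plasma

  list(cq_tables = cq_tables, sheet = sheet, spectra = spectra,
       truth = params$mirs, params = params)
}

#' Generate a synthetic RBC dilution series
#'
#' Emulates graded spikes of lysed RBCs into clean plasma: `n_series`
#' independent series over the same %RBC fractions (default the six-point
#' design 0-0.125%), measured in duplicate.
#'
#' @param fractions_pct %RBC points; must include 0.
#' @param n_series Independent dilution series (averaged per point
#'   downstream).
#' @param n_mirs,label_props,noise_sd,params As in
#'   [generate_paired_study()].
#' @param n_duplicates qPCR duplicates per measurement.
#' @param seed Mandatory integer seed.
#' @param spectrum_params A [spectrum_model_params()].
#' @return List with `cq_table`, `sheet`, `spectra`, `truth`, `params`.
#' @export
generate_dilution_series <- function(fractions_pct = c(0, 0.008, 0.016,
                                                       0.031, 0.0625, 0.125),
                                     n_series = 2, n_mirs = 200,
                                     label_props = c(susceptible = 0.45,
                                                     stable = 0.45,
                                                     specific = 0.10),
                                     noise_sd = 0.25, n_duplicates = 2, seed,
                                     params = NULL,
                                     spectrum_params = spectrum_model_params()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(any(fractions_pct == 0), all(fractions_pct >= 0),
            !anyDuplicated(fractions_pct), n_series >= 1)
  set.seed(as.integer(seed))
  if (is.null(params)) {
    params <- mixing_model_params(n_mirs = n_mirs, label_props = label_props,
                                  noise_sd = noise_sd)
  }
  grid_s <- expand.grid(point = seq_along(fractions_pct),
                        series = seq_len(n_series),
                        KEEP.OUT.ATTRS = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("D%d_%02d", grid_s$series, grid_s$point),
    subject_id = sprintf("series%d", grid_s$series),
    condition = "dilution",
    pair_id = "",
    a414 = a414_of(spectrum_params, fractions_pct[grid_s$point]),
    rbc_fraction = fractions_pct[grid_s$point],
    stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet)
  f_pct_of <- stats::setNames(sheet$rbc_fraction, sheet$sample_id)

  grid <- expand.grid(mir = seq_len(nrow(params$mirs)),
                      sample = sheet$sample_id,
                      replicate = seq_len(n_duplicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cq <- sim_cq_core(params$mirs$baseline_cq[grid$mir],
                    params$mirs$enrichment_k[grid$mir],
                    pct_to_frac(f_pct_of[grid$sample]),
                    params$noise_sd, params$censor_cq)
  table <- cq_table(data.frame(mir_id = params$mirs$mir_id[grid$mir],
                               sample_id = grid$sample,
                               replicate = grid$replicate,
                               cq = cq, stringsAsFactors = FALSE),
                    collapsed = n_duplicates == 1L)

  spectra <- lapply(sheet$sample_id, function(s)
    simulate_spectrum(f_pct_of[[s]], spectrum_params, sample_id = s))
  names(spectra) <- sheet$sample_id

  list(cq_table = table, sheet = sheet, spectra = spectra,
       truth = params$mirs, params = params)
}

#' Write a synthetic study bundle to disk
#'
#' Emits the exact text dialects the readers consume: one wide Cq TSV per
#' run, the sample sheet, a long-format spectra TSV and the truth-label
#' TSV.
#'
#' @param study Result of [generate_paired_study()] or
#'   [generate_dilution_series()].
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  tabs <- if (!is.null(study$cq_tables)) study$cq_tables else
    list(study$cq_table)
  for (r in seq_along(tabs)) {
    f <- file.path(dir, sprintf("cq_run%d.tsv", r))
    write_cq_table(tabs[[r]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(study$sheet, f)
  files <- c(files, f)
  spec_df <- do.call(rbind, lapply(study$spectra, function(sp)
    data.frame(sample_id = sp$sample_id, wavelength_nm = sp$wavelengths,
               od = sp$od, stringsAsFactors = FALSE)))
  f <- file.path(dir, "spectra.tsv")
  utils::write.table(spec_df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.tsv")
  utils::write.table(study$truth, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}

#' Scenario configuration for the generator
#'
#' A flat key-value description of a synthetic scenario, round-trippable
#' through YAML, so simulation settings can live next to the data they
#' produced.
#'
#' @param design `"paired"` or `"dilution"`.
#' @param ... Generator arguments overriding the defaults of
#'   [generate_paired_study()] / [generate_dilution_series()] (scalars and
#'   numeric vectors only).
#' @return Named list of class `"scenario_config"`.
#' @export
scenario_config <- function(design = c("paired", "dilution"), ...) {
  design <- match.arg(design)
  cfg <- c(list(design = design), list(...))
  structure(cfg, class = "scenario_config")
}

#' @rdname scenario_config
#' @param cfg A `"scenario_config"`.
#' @param path YAML file path.
#' @export
write_scenario_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "scenario_config")
}

#' Run the generator described by a scenario configuration
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed (overrides any seed stored in the config).
#' @return A study bundle (see [generate_paired_study()]).
#' @export
simulate_from_config <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config") || is.list(cfg))
  args <- cfg[setdiff(names(cfg), "design")]
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(args$label_props)) args$label_props <- unlist(args$label_props)
  if (identical(cfg$design, "dilution")) {
    do.call(generate_dilution_series, args)
  } else {
    do.call(generate_paired_study, args)
  }
}
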