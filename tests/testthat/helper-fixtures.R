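# Shared builders for in-code fixtures.

# cq_table from a mir x sample matrix (NA = undetected)
cq_from_matrix <- function(m, collapsed = TRUE) {
  df <- data.frame(mir_id = rep(rownames(m), ncol(m)),
                   sample_id = rep(colnames(m), each = nrow(m)),
                   replicate = 1L, cq = as.vector(m),
                   stringsAsFactors = FALSE)
  cq_table(df, collapsed = collapsed)
}

# minimal matched-pair sample sheet
pair_sheet <- function(n_pairs, a414_nh = rep(0.15, n_pairs),
                       a414_h = rep(0.45, n_pairs), rbc = FALSE) {
  df <- data.frame(
    sample_id = c(rbind(sprintf("P%d_NH", seq_len(n_pairs)),
                        sprintf("P%d_H", seq_len(n_pairs)))),
    subject_id = rep(sprintf("s%d", seq_len(n_pairs)), each = 2),
    condition = rep(c("non_hemolyzed", "hemolyzed"), n_pairs),
    pair_id = rep(sprintf("pair%d", seq_len(n_pairs)), each = 2),
    a414 = c(rbind(a414_nh, a414_h)),
    rbc_fraction = NA_real_, stringsAsFactors = FALSE)
  if (rbc) {
    df <- rbind(df, data.frame(sample_id = "RBC", subject_id = "donor",
                               condition = "rbc", pair_id = "",
                               a414 = NA_real_, rbc_fraction = NA_real_))
  }
  validate_sample_sheet(df)
}

# pool runs of a paired study and identify specific species, as qc_report does
study_specific <- function(study, detect_cq = 35) {
  pooled <- do.call(rbind, lapply(seq_along(study$cq_tables), function(r) {
    t <- as.data.frame(collapse_replicates(study$cq_tables[[r]]))
    t$replicate <- r
    t
  }))
  identify_specific(collapse_replicates(cq_table(pooled), "detected_only"),
                    study$sheet, detect_cq = detect_cq)
}

# tier a paired study end to end and join with truth labels
study_tiers <- function(study) {
  fcs <- fold_change_matrix(study$cq_tables, study$sheet)
  rep <- tier_mirnas(fcs, specific_ids = study_specific(study))
  merge(rep, study$truth, by = "mir_id")
}

# brute-force re-tiering of a fold-change table (independent oracle)
oracle_tiers <- function(fcs, up = 2, band = 1.5, n_design = NULL) {
  n_design <- if (is.null(n_design))
    length(unique(fcs$pair_id)) else n_design
  vapply(unique(fcs$mir_id), function(m) {
    rows <- fcs[fcs$mir_id == m, ]
    ok <- rows$status == "ok" & !is.na(rows$mean_fc)
    fc <- rows$mean_fc[ok]
    n_elev <- sum(fc >= up)
    if (n_elev == n_design && n_design >= 3) return("elevated_all_pairs")
    if (n_elev >= 2) return("elevated_two_pairs")
    if (n_elev == 1) return("elevated_one_pair")
    if (length(fc) > 0 && all(fc >= 1 / band & fc <= band)) return("stable")
    "indeterminate"
  }, character(1))
}

extdata <- function(name) system.file("extdata", name, package = "hemoqc")
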