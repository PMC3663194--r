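#' Tier microRNAs by hemolysis susceptibility
#'
#' Assigns every microRNA one of six mutually exclusive tiers from its
#' matched-pair fold changes:
#'
#' * `elevated_all_pairs` — mean fold change >= `up_threshold` in every pair
#'   of the design (designs of three or more pairs);
#' * `elevated_two_pairs` — in at least two pairs;
#' * `elevated_one_pair` — in exactly one pair;
#' * `stable` — no elevated pair and every evaluable fold change inside the
#'   symmetric band `[1/stable_band, stable_band]`;
#' * `hemolysis_specific` — detected only with RBC material present (see
#'   [identify_specific()]; supplied via `specific_ids`);
#' * `indeterminate` — everything else (e.g. decreased species, or variation
#'   outside the stable band short of the elevation threshold).
#'
#' Elevation is judged on the across-run mean fold change, inclusively
#' (`>=` 2-fold by default, reconciling ">2-fold" and "at least twofold"
#' conventions).
#'
#' @param fcs Fold-change table from [fold_change_matrix()].
#' @param up_threshold Fold-change threshold for "elevated" (default 2).
#' @param stable_band Half-width of the multiplicative stability band
#'   (default 1.5, i.e. fold changes within \[2/3, 1.5\]).
#' @param specific_ids Optional character vector of microRNAs detected only
#'   in RBC lysate and hemolyzed plasma; these are tiered
#'   `hemolysis_specific` regardless of fold changes.
#' @return Data frame of class `"susceptibility_report"`: `mir_id`, `tier`,
#'   `n_pairs_elevated`, `n_pairs_evaluable`, `min_fc`, `max_fc`.
#' @export
tier_mirnas <- function(fcs, up_threshold = 2.0, stable_band = 1.5,
                        specific_ids = NULL) {
  stopifnot(is.data.frame(fcs), up_threshold > 0, stable_band >= 1)
  n_design <- attr(fcs, "n_pairs_design") %||% length(unique(fcs$pair_id))
  mir <- factor(fcs$mir_id, levels = unique(fcs$mir_id))
  ok <- fcs$status == "ok" & !is.na(fcs$mean_fc)
  n_eval <- as.integer(tapply(ok, mir, sum))
  n_elev <- as.integer(tapply(ok & fcs$mean_fc >= up_threshold, mir, sum))
  in_band <- ok & fcs$mean_fc >= 1 / stable_band & fcs$mean_fc <= stable_band
  all_in_band <- as.logical(tapply(!ok | in_band, mir, all))
  min_fc <- as.numeric(tapply(ifelse(ok, fcs$mean_fc, NA_real_), mir,
                              function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)))
  max_fc <- as.numeric(tapply(ifelse(ok, fcs$mean_fc, NA_real_), mir,
                              function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)))

  tier <- rep("indeterminate", nlevels(mir))
  tier[n_elev == 1L] <- "elevated_one_pair"
  tier[n_elev >= 2L] <- "elevated_two_pairs"
  tier[n_elev == n_design & n_design >= 3L] <- "elevated_all_pairs"
  tier[n_elev == 0L & n_eval > 0L & all_in_band] <- "stable"
  if (!is.null(specific_ids)) {
    tier[levels(mir) %in% specific_ids] <- "hemolysis_specific"
  }

  out <- data.frame(mir_id = levels(mir), tier = tier,
                    n_pairs_elevated = n_elev, n_pairs_evaluable = n_eval,
                    min_fc = min_fc, max_fc = max_fc,
                    stringsAsFactors = FALSE)
  class(out) <- c("susceptibility_report", "data.frame")
  attr(out, "n_pairs_design") <- n_design
  attr(out, "up_threshold") <- up_threshold
  attr(out, "stable_band") <- stable_band
  out
}

#' Tier histogram and nested elevation counts
#'
#' @param report A `"susceptibility_report"` from [tier_mirnas()].
#' @return List with `tier_counts` (named vector) and the nested elevation
#'   counts `n_elevated_all`, `n_elevated_ge2`, `n_elevated_ge1` (each tier
#'   of elevation contains the next: all-pairs hits are a subset of
#'   >=2-pair hits, which are a subset of >=1-pair hits).
#' @export
tier_summary <- function(report) {
  tiers <- c("elevated_all_pairs", "elevated_two_pairs", "elevated_one_pair",
             "stable", "hemolysis_specific", "indeterminate")
  counts <- vapply(tiers, function(t) sum(report$tier == t), integer(1))
  list(
    tier_counts = counts,
    n_elevated_all = sum(report$n_pairs_elevated ==
                           (attr(report, "n_pairs_design") %||% max(report$n_pairs_evaluable))),
    n_elevated_ge2 = sum(report$n_pairs_elevated >= 2L),
    n_elevated_ge1 = sum(report$n_pairs_elevated >= 1L)
  )
}

#' Identify RBC/hemolysis-specific species
#'
#' Finds microRNAs present only when RBC material is present: detected
#' (Cq < `detect_cq`) in the pure RBC lysate and in at least one hemolyzed
#' plasma sample, but in no non-hemolyzed plasma sample. Species whose Cq
#' sits at or beyond the cutoff everywhere never qualify — they carry no
#' quantifiable signal.
#'
#' @param table A [cq_table()] (collapsed automatically if needed).
#' @param sheet A `"sample_sheet"`; must contain at least one sample with
#'   condition `rbc`.
#' @param detect_cq Detection cutoff in cycles (default 35).
#' @return Character vector of microRNA ids.
#' @export
identify_specific <- function(table, sheet, detect_cq = 35) {
  stopifnot(inherits(table, "cq_table"), is.data.frame(sheet))
  if (!is_collapsed(table)) table <- collapse_replicates(table)
  rbc <- sheet$sample_id[sheet$condition == "rbc"]
  if (length(rbc) == 0L) {
    stop("sample sheet contains no RBC-condition sample", call. = FALSE)
  }
  hem <- sheet$sample_id[sheet$condition == "hemolyzed"]
  nh <- sheet$sample_id[sheet$condition == "non_hemolyzed"]
  mask <- detection_mask(table, max_cq = detect_cq)
  pick <- function(ids) intersect(ids, colnames(mask))
  rbc_det <- rowSums(mask[, pick(rbc), drop = FALSE]) > 0
  hem_det <- rowSums(mask[, pick(hem), drop = FALSE]) > 0
  nh_det <- rowSums(mask[, pick(nh), drop = FALSE]) > 0
  rownames(mask)[rbc_det & hem_det & !nh_det]
}

#' Select matched biomarker / endogenous-control candidate subsets
#'
#' Restricts attention to the pairs with extensive hemolysis (relative
#' degree, i.e. A414 ratio hemolyzed/non-hemolyzed, at least
#' `degree_cutoff`) and partitions microRNAs into:
#'
#' * `changing` — fold change >= `up_threshold` in *every* selected pair,
#'   with fold changes ordered concordantly with the pairs' hemolysis
#'   degrees (abundance tracks contamination);
#' * `unaffected` — every selected-pair fold change inside
#'   `[1/stable_band, stable_band]` (endogenous-control candidates).
#'
#' The two subsets are disjoint by construction. MicroRNAs lacking a numeric
#' fold change in any selected pair join neither subset.
#'
#' @param fcs Fold-change table from [fold_change_matrix()].
#' @param sheet A `"sample_sheet"` carrying `a414` for both members of each
#'   pair.
#' @param degree_cutoff Minimum A414 ratio for a pair to count as
#'   extensively hemolyzed (default 2). At least two pairs must qualify.
#' @param up_threshold,stable_band As in [tier_mirnas()].
#' @return List with character vectors `changing` and `unaffected`, plus
#'   `pairs`: a data frame of the selected pairs and their degrees.
#' @export
select_subsets <- function(fcs, sheet, degree_cutoff = 2.0,
                           up_threshold = 2.0, stable_band = 1.5) {
  stopifnot(is.data.frame(fcs), is.data.frame(sheet))
  pairs <- setdiff(unique(sheet$pair_id), "")
  deg <- vapply(pairs, function(p) {
    a_h <- sheet$a414[sheet$pair_id == p & sheet$condition == "hemolyzed"]
    a_n <- sheet$a414[sheet$pair_id == p & sheet$condition == "non_hemolyzed"]
    if (anyNA(c(a_h, a_n))) return(NA_real_)
    relative_degree(a_h, a_n)
  }, numeric(1))
  sel <- pairs[!is.na(deg) & deg >= degree_cutoff]
  if (length(sel) < 2L) {
    stop("fewer than 2 pairs reach hemolysis degree >= ", degree_cutoff,
         "; lower `degree_cutoff` to select more pairs", call. = FALSE)
  }
  sel_deg <- deg[match(sel, pairs)]

  sub <- fcs[fcs$pair_id %in% sel, , drop = FALSE]
  changing <- character(0)
  unaffected <- character(0)
  for (m in unique(sub$mir_id)) {
    rows <- sub[sub$mir_id == m, , drop = FALSE]
    fc <- rows$mean_fc[match(sel, rows$pair_id)]
    okv <- rows$status[match(sel, rows$pair_id)] == "ok" & !is.na(fc)
    if (length(fc) != length(sel) || !all(okv)) next
    up <- all(fc >= up_threshold)
    # concordance: a strictly more hemolyzed pair may not show a smaller FC
    concordant <- TRUE
    for (i in seq_along(sel)) for (j in seq_along(sel)) {
      if (sel_deg[i] < sel_deg[j] && fc[i] > fc[j]) concordant <- FALSE
    }
    if (up && concordant) changing <- c(changing, m)
    else if (all(fc >= 1 / stable_band & fc <= stable_band)) {
      unaffected <- c(unaffected, m)
    }
  }
  list(changing = changing, unaffected = unaffected,
       pairs = data.frame(pair_id = sel, degree = sel_deg,
                          stringsAsFactors = FALSE))
}

#' Write a susceptibility report as TSV
#'
#' Emits the tier table with one fold-change column per pair and subset
#' membership flags when subsets are supplied.
#'
#' @param report A `"susceptibility_report"` from [tier_mirnas()].
#' @param fcs The fold-change table the report was built from.
#' @param path Output path.
#' @param subsets Optional result of [select_subsets()].
#' @return `path`, invisibly.
#' @export
write_susceptibility_report <- function(report, fcs, path, subsets = NULL) {
  pairs <- unique(fcs$pair_id)
  out <- as.data.frame(report)
  for (p in pairs) {
    v <- fcs$mean_fc[fcs$pair_id == p][match(out$mir_id,
                                             fcs$mir_id[fcs$pair_id == p])]
    out[[paste0("fc_", p)]] <- v
  }
  if (!is.null(subsets)) {
    out$subset_changing <- out$mir_id %in% subsets$changing
    out$subset_unaffected <- out$mir_id %in% subsets$unaffected
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
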