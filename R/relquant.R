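#' Un-normalized 2^-deltaCq fold change for a matched pair
#'
#' Relative abundance of a microRNA in a hemolyzed sample versus its matched
#' non-hemolyzed counterpart, `2^-(Cq_H - Cq_NH)`. Deliberately
#' un-normalized: no endogenous control is subtracted, because candidate
#' controls are themselves under evaluation for hemolysis susceptibility.
#'
#' @param cq_hemolyzed,cq_nonhemolyzed Cq values in cycles; `NA` means
#'   undetected. Vectorized.
#' @return Linear fold change (> 0); `NA` where either input is undetected
#'   (use [fc_status()] for the one-sided detection pattern).
#' @export
#' @examples
#' pair_fold_change(24, 25) # one cycle earlier = 2-fold more abundant
pair_fold_change <- function(cq_hemolyzed, cq_nonhemolyzed) {
  2^-(as.numeric(cq_hemolyzed) - as.numeric(cq_nonhemolyzed))
}

#' Detection status of a matched-pair measurement
#'
#' @param cq_hemolyzed,cq_nonhemolyzed Cq values (`NA` = undetected).
#' @return Character vector over `"ok"`, `"hemolyzed_only"`,
#'   `"nonhemolyzed_only"`, `"both_undetected"`.
#' @export
fc_status <- function(cq_hemolyzed, cq_nonhemolyzed) {
  h <- !is.na(cq_hemolyzed)
  n <- !is.na(cq_nonhemolyzed)
  out <- rep("both_undetected", length(h))
  out[h & n] <- "ok"
  out[h & !n] <- "hemolyzed_only"
  out[!h & n] <- "nonhemolyzed_only"
  out
}

# Combine per-run statuses for one (mir, pair).
combine_status <- function(statuses) {
  if (any(statuses == "ok")) return("ok")
  h <- any(statuses == "hemolyzed_only")
  n <- any(statuses == "nonhemolyzed_only")
  if (h && !n) return("hemolyzed_only")
  if (n && !h) return("nonhemolyzed_only")
  # conflicting one-sided detections across runs carry no usable signal
  "both_undetected"
}

#' Fold-change table for every microRNA and matched pair
#'
#' Computes the per-run 2^-deltaCq fold change of each microRNA in each
#' matched hemolyzed/non-hemolyzed pair, then summarizes across independent
#' runs as arithmetic mean +/- SD (the convention of validation tables
#' reporting "relative fold increase H vs. NH" over two isolations).
#' Detection is applied at `detect_cq` before forming ratios; measurements
#' detected on one side only are reported as statuses, never as
#' pseudo-count fold changes.
#'
#' @param tables A [cq_table()] or list of them, one per independent run.
#'   Uncollapsed tables are collapsed with [collapse_replicates()] first.
#' @param sheet A `"sample_sheet"` data frame; every `pair_id` must resolve
#'   to one hemolyzed and one non-hemolyzed sample present in the tables.
#' @param detect_cq Detection cutoff in cycles (default 35).
#' @param collapse_policy Replicate-collapsing policy, see
#'   [collapse_replicates()].
#' @param run_summary `"arithmetic"` (default) mean of per-run fold changes,
#'   or `"geometric"`.
#' @return Data frame with one row per microRNA x pair: `mir_id`, `pair_id`,
#'   `mean_fc`, `sd_fc`, `n_runs_ok`, `status`. Per-run fold changes are
#'   attached as attribute `"per_run"`.
#' @export
fold_change_matrix <- function(tables, sheet, detect_cq = 35,
                               collapse_policy = "conservative",
                               run_summary = c("arithmetic", "geometric")) {
  run_summary <- match.arg(run_summary)
  if (inherits(tables, "cq_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, inherits(sheet, "data.frame"))
  tables <- lapply(tables, function(t) {
    if (is_collapsed(t)) t else collapse_replicates(t, policy = collapse_policy)
  })
  pairs <- setdiff(unique(sheet$pair_id), "")
  if (length(pairs) == 0L) stop("sample sheet contains no matched pairs",
                                call. = FALSE)
  h_of <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$condition == "hemolyzed"],
    character(1))
  nh_of <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$condition == "non_hemolyzed"],
    character(1))
  mirs <- unique(unlist(lapply(tables, function(t) unique(t$mir_id))))

  per_run <- list()
  for (r in seq_along(tables)) {
    tab <- tables[[r]]
    have <- unique(tab$sample_id)
    miss <- setdiff(c(h_of, nh_of), have)
    if (length(miss)) {
      stop("run ", r, " lacks pair member sample(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    cq <- matrix(NA_real_, length(mirs), length(have),
                 dimnames = list(mirs, have))
    cq[cbind(match(tab$mir_id, mirs), match(tab$sample_id, have))] <- tab$cq
    cq[!is.na(cq) & cq >= detect_cq] <- NA_real_  # below detection
    for (p in seq_along(pairs)) {
      ch <- cq[, h_of[p]]
      cn <- cq[, nh_of[p]]
      per_run[[length(per_run) + 1L]] <- data.frame(
        mir_id = mirs, pair_id = pairs[p], run = r,
        fc = pair_fold_change(ch, cn),
        status = fc_status(ch, cn),
        stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, per_run)

  key <- paste(per_run$mir_id, per_run$pair_id, sep = "\r")
  first <- !duplicated(key)
  ord <- key[first]
  mean_fc <- tapply(seq_len(nrow(per_run)), key, function(i) {
    fcs <- per_run$fc[i][per_run$status[i] == "ok"]
    if (length(fcs) == 0L) return(NA_real_)
    if (run_summary == "arithmetic") mean(fcs) else exp(mean(log(fcs)))
  })
  sd_fc <- tapply(seq_len(nrow(per_run)), key, function(i) {
    fcs <- per_run$fc[i][per_run$status[i] == "ok"]
    if (length(fcs) < 2L) return(NA_real_)
    stats::sd(fcs)
  })
  n_ok <- tapply(per_run$status, key, function(s) sum(s == "ok"))
  status <- tapply(per_run$status, key, combine_status)

  out <- data.frame(
    mir_id = per_run$mir_id[first],
    pair_id = per_run$pair_id[first],
    mean_fc = as.numeric(mean_fc[ord]),
    sd_fc = as.numeric(sd_fc[ord]),
    n_runs_ok = as.integer(n_ok[ord]),
    status = as.character(status[ord]),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$mir_id, mirs), match(out$pair_id, pairs)), ]
  rownames(out) <- NULL
  attr(out, "per_run") <- per_run
  attr(out, "n_pairs_design") <- length(pairs)
  out
}

#' Clipped log2 fold-change matrix (heatmap export)
#'
#' Converts mean fold changes to log2 and clamps them to `+/- limit`
#' (default 3.3, roughly a 10-fold difference), the usual dynamic range for
#' relative-abundance heat maps. Entries without a numeric fold change
#' (one-sided or no detection) come out as `NA`.
#'
#' @param fcs Output of [fold_change_matrix()].
#' @param limit Clip limit in log2 units.
#' @return Numeric matrix, microRNAs x pairs.
#' @export
log2_clip_matrix <- function(fcs, limit = 3.3) {
  stopifnot(is.data.frame(fcs), limit > 0)
  mirs <- unique(fcs$mir_id)
  pairs <- unique(fcs$pair_id)
  m <- matrix(NA_real_, length(mirs), length(pairs),
              dimnames = list(mirs, pairs))
  ok <- fcs$status == "ok" & !is.na(fcs$mean_fc)
  m[cbind(match(fcs$mir_id[ok], mirs), match(fcs$pair_id[ok], pairs))] <-
    pmin(pmax(log2(fcs$mean_fc[ok]), -limit), limit)
  m
}

#' RBC-contamination indicator from a Cq ratio
#'
#' Difference between the Cq of a hemolysis-stable microRNA and that of a
#' strongly RBC-enriched one (by default miR-23a vs miR-451, the pairing in
#' common use). The more RBC material in the sample, the earlier the
#' RBC-enriched species amplifies relative to the stable one, so larger
#' values mean more hemolysis signal. No verdict threshold is applied; the
#' indicator is reported as cycles for downstream judgment.
#'
#' @param cq_affected Cq of the RBC-enriched (hemolysis-susceptible)
#'   species; `NA` = undetected.
#' @param cq_stable Cq of the hemolysis-stable species.
#' @return `cq_stable - cq_affected` in cycles; `NA` where either input is
#'   undetected.
#' @export
#' @examples
#' hemolysis_ratio(20, 27) # 7 cycles: strong RBC signal
hemolysis_ratio <- function(cq_affected, cq_stable) {
  as.numeric(cq_stable) - as.numeric(cq_affected)
}

#' Per-sample hemolysis indicator from a Cq table
#'
#' @param table A collapsed [cq_table()] containing both assays.
#' @param affected_id,stable_id Assay names of the RBC-enriched and stable
#'   species (defaults miR-451 / miR-23a; configurable because assay naming
#'   varies across platforms).
#' @param detect_cq Detection cutoff in cycles.
#' @return Data frame `sample_id`, `indicator` (cycles), `status`
#'   (`"ok"` or `"unavailable"` when either assay is undetected).
#' @export
hemolysis_ratio_table <- function(table, affected_id = "hsa-miR-451",
                                  stable_id = "hsa-miR-23a",
                                  detect_cq = 35) {
  stopifnot(inherits(table, "cq_table"))
  if (!is_collapsed(table)) table <- collapse_replicates(table)
  missing <- setdiff(c(affected_id, stable_id), unique(table$mir_id))
  if (length(missing)) {
    stop("assay(s) not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(table$sample_id)
  get <- function(id) {
    v <- rep(NA_real_, length(samples))
    rows <- table$mir_id == id
    v[match(table$sample_id[rows], samples)] <- table$cq[rows]
    v[!is.na(v) & v >= detect_cq] <- NA_real_
    v
  }
  aff <- get(affected_id)
  sta <- get(stable_id)
  data.frame(sample_id = samples,
             indicator = hemolysis_ratio(aff, sta),
             status = ifelse(!is.na(aff) & !is.na(sta), "ok", "unavailable"),
             stringsAsFactors = FALSE)
}

#' Write fold changes as long TSV
#'
#' @param fcs Output of [fold_change_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_changes <- function(fcs, path) {
  utils::write.table(fcs, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the clipped log2 matrix as wide TSV
#'
#' Missing cells (no numeric fold change) are left empty, ready for heatmap
#' tools.
#'
#' @param m Matrix from [log2_clip_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log2_matrix <- function(m, path) {
  df <- data.frame(mir_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
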