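#' Build an RBC dilution series from a Cq table and sample sheet
#'
#' Collects the samples with condition `dilution`, orders them by %RBC
#' spiked, and averages the Cq of each microRNA over the samples sharing a
#' fraction (independent dilution series contribute samples at the same
#' fractions, so per-point averaging pools them). Detection at `detect_cq`
#' is applied before averaging; a point with no detected sample is missing
#' for that microRNA.
#'
#' @param table A [cq_table()] (collapsed automatically if needed).
#' @param sheet A `"sample_sheet"` with dilution samples carrying
#'   `rbc_fraction` (%RBC by volume). The series must include a 0% baseline.
#' @param detect_cq Detection cutoff in cycles (default 35).
#' @return Object of class `"dilution_series"`: list with `fractions`
#'   (sorted %RBC values), `mean_cq` (microRNA x point matrix),
#'   `n_detected` (matrix of per-point detected sample counts) and
#'   `n_samples` per point.
#' @export
dilution_series <- function(table, sheet, detect_cq = 35) {
  stopifnot(inherits(table, "cq_table"), is.data.frame(sheet))
  if (!is_collapsed(table)) table <- collapse_replicates(table)
  dil <- sheet[sheet$condition == "dilution", , drop = FALSE]
  if (nrow(dil) == 0L) stop("sample sheet contains no dilution samples",
                            call. = FALSE)
  dil <- dil[dil$sample_id %in% unique(table$sample_id), , drop = FALSE]
  fractions <- sort(unique(dil$rbc_fraction))
  if (!any(fractions == 0)) {
    stop("dilution series must include a 0% RBC baseline", call. = FALSE)
  }
  mirs <- unique(table$mir_id)
  cq <- matrix(NA_real_, length(mirs), nrow(dil),
               dimnames = list(mirs, dil$sample_id))
  rows <- table$sample_id %in% dil$sample_id
  cq[cbind(match(table$mir_id[rows], mirs),
           match(table$sample_id[rows], dil$sample_id))] <- table$cq[rows]
  cq[!is.na(cq) & cq >= detect_cq] <- NA_real_
  mean_cq <- matrix(NA_real_, length(mirs), length(fractions),
                    dimnames = list(mirs, paste0(fractions, "%")))
  n_det <- matrix(0L, length(mirs), length(fractions),
                  dimnames = dimnames(mean_cq))
  for (k in seq_along(fractions)) {
    cols <- dil$sample_id[dil$rbc_fraction == fractions[k]]
    block <- cq[, cols, drop = FALSE]
    n <- rowSums(!is.na(block))
    m <- rowMeans(block, na.rm = TRUE)
    m[n == 0L] <- NA_real_
    mean_cq[, k] <- m
    n_det[, k] <- n
  }
  structure(list(fractions = fractions, mean_cq = mean_cq,
                 n_detected = n_det,
                 n_samples = as.integer(table(factor(dil$rbc_fraction,
                                                     levels = fractions)))),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("<dilution_series>", nrow(x$mean_cq), "assays over",
      length(x$fractions), "points:",
      paste0(x$fractions, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Cq trajectory statistics across the dilution series
#'
#' For each microRNA (or one selected microRNA) computes, over the
#' per-point mean Cq values:
#'
#' * `cq_range` — max minus min over all points (cycles);
#' * `rank_correlation` — Spearman correlation of Cq versus %RBC (midrank
#'   ties; a constant trajectory scores 0). Spearman is used because the 0%
#'   baseline rules out log-fraction regression and only the ordinal trend
#'   is claimed;
#' * `net_shift` — Cq at 0% minus Cq at the highest fraction (positive =
#'   abundance increase with contamination). Range and shift can disagree:
#'   the range uses extremes, the shift uses endpoints.
#'
#' MicroRNAs detected at fewer than `min_points` points get status
#' `"insufficient_data"` and `NA` statistics.
#'
#' @param series A [dilution_series()].
#' @param mir_id Optional single microRNA id; default all.
#' @param min_points Minimum detected points (default 4).
#' @return Data frame: `mir_id`, `n_points`, `cq_range`,
#'   `rank_correlation`, `net_shift`, `status`.
#' @export
trajectory_stats <- function(series, mir_id = NULL, min_points = 4) {
  stopifnot(inherits(series, "dilution_series"))
  mirs <- rownames(series$mean_cq)
  if (!is.null(mir_id)) {
    if (!all(mir_id %in% mirs)) {
      stop("microRNA(s) not in series: ",
           paste(setdiff(mir_id, mirs), collapse = ", "), call. = FALSE)
    }
    mirs <- mir_id
  }
  fr <- series$fractions
  out <- lapply(mirs, function(m) {
    cqs <- series$mean_cq[m, ]
    det <- !is.na(cqs)
    if (sum(det) < min_points) {
      return(data.frame(mir_id = m, n_points = sum(det), cq_range = NA_real_,
                        rank_correlation = NA_real_, net_shift = NA_real_,
                        status = "insufficient_data",
                        stringsAsFactors = FALSE))
    }
    v <- cqs[det]
    f <- fr[det]
    rho <- if (stats::sd(v) == 0) 0 else
      stats::cor(f, v, method = "spearman")
    net <- if (det[1] && fr[1] == 0) cqs[1] - v[length(v)] else NA_real_
    data.frame(mir_id = m, n_points = sum(det),
               cq_range = max(v) - min(v),
               rank_correlation = rho,
               net_shift = net,
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call microRNAs affected / unaffected by RBC contamination
#'
#' A microRNA is `affected` only when both conditions hold: the Cq range
#' across the series reaches `range_threshold` (default 1.1 cycles, the
#' empirical stability bound — validated susceptible species move 1.5-2.4
#' cycles, leaving a margin) *and* the Cq trend is strongly monotone
#' decreasing (Spearman rho <= `rho_threshold`, default -0.8; decreasing Cq
#' = increasing abundance). Requiring both prevents over-calling: a species
#' can trend down convincingly yet move too little to matter, and a noisy
#' species can span a wide range without any trend.
#'
#' @param stats Data frame from [trajectory_stats()].
#' @param range_threshold Minimum Cq range in cycles.
#' @param rho_threshold Maximum (most positive) Spearman rho that still
#'   counts as a contamination trend.
#' @return `stats` with an added `call` column (`"affected"`,
#'   `"unaffected"`, or `NA` for insufficient data).
#' @export
classify_trajectory <- function(stats, range_threshold = 1.1,
                                rho_threshold = -0.8) {
  stopifnot(is.data.frame(stats))
  call <- ifelse(stats$status != "ok", NA_character_,
                 ifelse(stats$cq_range >= range_threshold &
                          stats$rank_correlation <= rho_threshold,
                        "affected", "unaffected"))
  stats$call <- call
  stats
}

#' One-step dilution-series analysis
#'
#' Convenience wrapper: builds the series, computes trajectory statistics
#' for all microRNAs and classifies them.
#'
#' @param table,sheet As in [dilution_series()].
#' @param detect_cq,min_points,range_threshold,rho_threshold Passed through.
#' @return Classified trajectory data frame (see [classify_trajectory()]).
#' @export
analyze_dilution <- function(table, sheet, detect_cq = 35, min_points = 4,
                             range_threshold = 1.1, rho_threshold = -0.8) {
  series <- dilution_series(table, sheet, detect_cq = detect_cq)
  classify_trajectory(trajectory_stats(series, min_points = min_points),
                      range_threshold = range_threshold,
                      rho_threshold = rho_threshold)
}
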