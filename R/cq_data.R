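#' Quantification-cycle (Cq) table
#'
#' The central container for RT-qPCR readouts: one Cq value (or an explicit
#' undetected state, stored as `NA`) per microRNA assay, sample and
#' replicate. Internally a long data frame with columns `mir_id`,
#' `sample_id`, `replicate` and `cq`; the replicate dimension holds the
#' within-run qPCR duplicates. Independent runs (e.g. separate RNA
#' isolations) are kept as separate tables.
#'
#' @param df Data frame with columns `mir_id`, `sample_id`, `replicate`
#'   (integer) and `cq` (numeric; `NA` = undetected). Numeric Cq values must
#'   lie in (0, 40].
#' @param collapsed Logical: has the replicate dimension already been
#'   collapsed to one value per microRNA x sample?
#' @return An object of class `"cq_table"` (a data frame).
#' @seealso [read_cq_table()], [collapse_replicates()], [detection_mask()],
#'   [filter_detectable()]
#' @export
cq_table <- function(df, collapsed = FALSE) {
  need <- c("mir_id", "sample_id", "replicate", "cq")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("`df` must have columns mir_id, sample_id, replicate, cq",
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$mir_id <- as.character(df$mir_id)
  df$sample_id <- as.character(df$sample_id)
  df$replicate <- as.integer(df$replicate)
  df$cq <- as.numeric(df$cq)
  if (nrow(df) == 0L) stop("empty Cq table", call. = FALSE)
  bad <- !is.na(df$cq) & (df$cq <= 0 | df$cq > 40)
  if (any(bad)) {
    off <- utils::head(sprintf("%s/%s rep %d: %.3f", df$mir_id[bad],
                               df$sample_id[bad], df$replicate[bad],
                               df$cq[bad]), 5L)
    stop("Cq values outside (0, 40]: ", paste(off, collapse = "; "),
         if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L),
         call. = FALSE)
  }
  key <- paste(df$mir_id, df$sample_id, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (mir_id, sample_id, replicate) entries", call. = FALSE)
  }
  structure(df, class = c("cq_table", "data.frame"), collapsed = collapsed)
}

#' @export
print.cq_table <- function(x, ...) {
  cat("<cq_table> ", length(unique(x$mir_id)), " assays x ",
      length(unique(x$sample_id)), " samples",
      if (isTRUE(attr(x, "collapsed"))) " (collapsed)" else
        paste0(", max ", max(x$replicate), " replicates"),
      "; ", sum(is.na(x$cq)), " undetected entries\n", sep = "")
  invisible(x)
}

is_collapsed <- function(table) isTRUE(attr(table, "collapsed"))

#' Read a wide-format Cq table
#'
#' Parses the canonical wide dialect: first column the assay name, remaining
#' columns either `sample` or `sample:replicate`. The cell values
#' `"Undetermined"`, `"NA"` and empty strings map to the undetected state;
#' everything else must parse as a Cq in (0, 40].
#'
#' @param path CSV or TSV file (delimiter auto-detected).
#' @return A [cq_table()]. The table is flagged collapsed when every sample
#'   carries a single replicate.
#' @export
read_cq_table <- function(path) {
  df <- read_delim_auto(path, colClasses = "character")
  if (ncol(df) < 2L) stop("Cq table needs an assay column plus samples: ",
                          path, call. = FALSE)
  mirs <- df[[1]]
  if (anyDuplicated(mirs)) {
    stop("duplicate assay names in ", path, ": ",
         paste(unique(mirs[duplicated(mirs)]), collapse = ", "),
         call. = FALSE)
  }
  cols <- names(df)[-1]
  if (anyDuplicated(cols)) {
    stop("duplicate sample columns in ", path, call. = FALSE)
  }
  parts <- strsplit(cols, ":", fixed = TRUE)
  sample_ids <- vapply(parts, `[[`, character(1), 1L)
  reps <- vapply(parts, function(p) {
    if (length(p) > 1L) as.integer(p[2]) else 1L
  }, integer(1))
  long <- do.call(rbind, lapply(seq_along(cols), function(j) {
    raw <- trimws(df[[j + 1L]])
    und <- raw %in% c("", "NA") | tolower(raw) == "undetermined"
    cq <- suppressWarnings(as.numeric(raw))
    if (any(!und & is.na(cq))) {
      stop("non-numeric Cq entries in column '", cols[j], "' of ", path, ": ",
           paste(utils::head(unique(raw[!und & is.na(cq)]), 3L), collapse = ", "),
           call. = FALSE)
    }
    cq[und] <- NA_real_
    data.frame(mir_id = mirs, sample_id = sample_ids[j], replicate = reps[j],
               cq = cq, stringsAsFactors = FALSE)
  }))
  cq_table(long, collapsed = all(tapply(reps, sample_ids, max) == 1L))
}

#' Write a Cq table in the wide dialect
#'
#' Inverse of [read_cq_table()]: undetected values are serialized as
#' `"Undetermined"`, replicated samples as `sample:replicate` columns.
#'
#' @param table A [cq_table()].
#' @param path Output path; `.csv` writes CSV, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path) {
  stopifnot(inherits(table, "cq_table"))
  multi <- max(table$replicate) > 1L
  col <- if (multi) paste(table$sample_id, table$replicate, sep = ":") else
    table$sample_id
  mirs <- unique(table$mir_id)
  cols <- unique(col)
  wide <- matrix("Undetermined", nrow = length(mirs), ncol = length(cols),
                 dimnames = list(mirs, cols))
  det <- !is.na(table$cq)
  wide[cbind(match(table$mir_id[det], mirs), match(col[det], cols))] <-
    format(table$cq[det], trim = TRUE, digits = 15)
  out <- data.frame(mir_id = mirs, wide, stringsAsFactors = FALSE,
                    check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse qPCR replicates to one Cq per microRNA and sample
#'
#' Numeric replicates are averaged on the Cq scale (the conventional
#' "average of duplicates"). When every replicate is undetected the result
#' is undetected. Mixed detected/undetected replicates default to undetected
#' (`"conservative"`): a dropped-out duplicate near the detection limit
#' usually signals stochastic amplification, and trusting the surviving
#' replicate inflates low-abundance calls. Set `policy = "detected_only"` to
#' average the detected replicates instead.
#'
#' @param table A [cq_table()].
#' @param policy `"conservative"` (default) or `"detected_only"`.
#' @return A collapsed [cq_table()] with one slot per microRNA x sample.
#'   Collapsing an already-collapsed table is the identity.
#' @export
collapse_replicates <- function(table,
                                policy = c("conservative", "detected_only")) {
  stopifnot(inherits(table, "cq_table"))
  policy <- match.arg(policy)
  f <- paste(table$mir_id, table$sample_id, sep = "\r")
  idx <- !duplicated(f)
  cq <- if (policy == "conservative") {
    # any undetected replicate poisons the mean
    tapply(table$cq, f, function(v) if (anyNA(v)) NA_real_ else mean(v))
  } else {
    tapply(table$cq, f, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  out <- data.frame(mir_id = table$mir_id[idx],
                    sample_id = table$sample_id[idx],
                    replicate = 1L,
                    cq = as.numeric(cq[f[idx]]),
                    stringsAsFactors = FALSE)
  cq_table(out, collapsed = TRUE)
}

#' Detection mask at a Cq cutoff
#'
#' A microRNA counts as detected in a sample when its collapsed Cq is
#' numeric and strictly below `max_cq` (default 35 cycles); undetected
#' entries and Cq >= `max_cq` are not detected. The strict inequality makes
#' the detection rule and the "Cq > 35 excluded" convention consistent at
#' the boundary.
#'
#' @param table A collapsed [cq_table()] (see [collapse_replicates()]).
#' @param max_cq Detection cutoff in cycles.
#' @return Logical matrix, microRNAs x samples.
#' @export
detection_mask <- function(table, max_cq = 35) {
  stopifnot(inherits(table, "cq_table"))
  if (!is_collapsed(table)) {
    stop("detection_mask() expects a replicate-collapsed table; ",
         "run collapse_replicates() first", call. = FALSE)
  }
  mirs <- unique(table$mir_id)
  samples <- unique(table$sample_id)
  m <- matrix(FALSE, length(mirs), length(samples),
              dimnames = list(mirs, samples))
  det <- !is.na(table$cq) & table$cq < max_cq
  m[cbind(match(table$mir_id, mirs), match(table$sample_id, samples))] <- det
  m
}

#' Filter microRNAs by detectability
#'
#' Keeps microRNAs detected (Cq < `max_cq`) in at least
#' `min_detected_samples` of the samples in `sample_subset`, and drops any
#' microRNA with no detection in any sample of the whole table (the global
#' exclusion of assays undetermined or beyond the cutoff everywhere).
#' Idempotent.
#'
#' @param table A collapsed [cq_table()].
#' @param sample_subset Character vector of sample ids the detectability
#'   count runs over (e.g. the six plasma samples of a three-pair design).
#' @param min_detected_samples Minimum number of subset samples with
#'   detection (default 4).
#' @param max_cq Detection cutoff in cycles (default 35).
#' @return The filtered [cq_table()] (all samples retained, rows restricted
#'   to surviving microRNAs).
#' @export
filter_detectable <- function(table, sample_subset, min_detected_samples = 4,
                              max_cq = 35) {
  stopifnot(inherits(table, "cq_table"))
  if (length(sample_subset) == 0L) {
    stop("`sample_subset` must be nonempty", call. = FALSE)
  }
  missing <- setdiff(sample_subset, unique(table$sample_id))
  if (length(missing)) {
    stop("samples not in table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (min_detected_samples > length(sample_subset)) {
    stop("`min_detected_samples` (", min_detected_samples,
         ") exceeds the subset size (", length(sample_subset), ")",
         call. = FALSE)
  }
  mask <- detection_mask(table, max_cq = max_cq)
  n_subset <- rowSums(mask[, sample_subset, drop = FALSE])
  anywhere <- rowSums(mask) > 0
  keep <- rownames(mask)[n_subset >= min_detected_samples & anywhere]
  out <- table[table$mir_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no microRNA passes the detectability filter", call. = FALSE)
  }
  cq_table(out, collapsed = TRUE)
}

#' Read and validate a sample sheet
#'
#' The sample sheet ties measurements to the study design: which subject a
#' sample came from, whether it is the non-hemolyzed or hemolyzed member of
#' a matched pair, a pure RBC lysate, or a point of an RBC spike dilution
#' series; its A414 reading; and, for dilution points, the %RBC spiked.
#'
#' @param path TSV/CSV with columns `sample_id`, `subject_id`, `condition`
#'   (`non_hemolyzed`, `hemolyzed`, `rbc` or `dilution`), `pair_id` (shared
#'   by the two members of a matched pair, empty otherwise), `a414`
#'   (optional OD) and `rbc_fraction` (%RBC by volume, dilution rows only).
#' @return A validated data frame of class `"sample_sheet"`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path, colClasses = "character")
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' Checks the invariants of the study design: unique sample ids, known
#' conditions, each pair id owning exactly one non-hemolyzed and one
#' hemolyzed sample, and `rbc_fraction` present exactly for dilution
#' samples.
#'
#' @param df Data frame with the columns documented in
#'   [read_sample_sheet()].
#' @return The normalized data frame, classed `"sample_sheet"`.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "subject_id", "condition", "pair_id")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"a414" %in% names(df)) df$a414 <- NA
  if (!"rbc_fraction" %in% names(df)) df$rbc_fraction <- NA
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$condition <- as.character(df$condition)
  df$pair_id <- as.character(df$pair_id)
  df$pair_id[is.na(df$pair_id)] <- ""
  df$a414 <- suppressWarnings(as.numeric(df$a414))
  df$rbc_fraction <- suppressWarnings(as.numeric(df$rbc_fraction))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  known <- c("non_hemolyzed", "hemolyzed", "rbc", "dilution")
  if (!all(df$condition %in% known)) {
    stop("unknown condition(s): ",
         paste(setdiff(unique(df$condition), known), collapse = ", "),
         call. = FALSE)
  }
  for (p in setdiff(unique(df$pair_id), "")) {
    members <- df$condition[df$pair_id == p]
    if (!(sum(members == "non_hemolyzed") == 1L &&
          sum(members == "hemolyzed") == 1L && length(members) == 2L)) {
      stop("pair '", p, "' must contain exactly one non_hemolyzed and one ",
           "hemolyzed sample", call. = FALSE)
    }
  }
  dil <- df$condition == "dilution"
  if (any(dil & is.na(df$rbc_fraction))) {
    stop("dilution samples must carry `rbc_fraction` (%RBC)", call. = FALSE)
  }
  if (any(!dil & !is.na(df$rbc_fraction))) {
    stop("`rbc_fraction` is only meaningful for dilution samples",
         call. = FALSE)
  }
  if (any(df$rbc_fraction < 0, na.rm = TRUE)) {
    stop("`rbc_fraction` must be >= 0", call. = FALSE)
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet
#'
#' @param sheet A `"sample_sheet"` data frame.
#' @param path Output path; `.csv` writes CSV, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(sheet), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
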