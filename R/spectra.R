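#' Absorbance spectrum of a plasma sample
#'
#' Bundles a spectrophotometric scan (optical density versus wavelength) for
#' one plasma sample. Free hemoglobin absorbs strongly near 414 nm (the Soret
#' band), so the OD at 414 nm is the standard quantitative hemolysis readout;
#' secondary Q-bands at 541 and 576 nm emerge only at very high hemoglobin
#' levels and flag severe hemolysis.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing. Must bracket 414 nm; a full hemolysis scan typically spans
#'   350-650 nm.
#' @param od Optical densities (unitless), one per wavelength. A small
#'   negative instrument baseline down to -0.05 is tolerated; lower values
#'   are rejected as corrupt input rather than clamped.
#' @param sample_id Optional sample identifier.
#'
#' @return An object of class `"absorbance_spectrum"`: a list with elements
#'   `wavelengths`, `od` and `sample_id`.
#' @seealso [absorbance_at()], [assess_hemolysis()], [detect_q_bands()]
#' @export
#' @examples
#' sp <- absorbance_spectrum(seq(350, 650, by = 2), rep(0.15, 151), "S1")
#' absorbance_at(sp, 414)
absorbance_spectrum <- function(wavelengths, od, sample_id = NA_character_) {
  wavelengths <- as.numeric(wavelengths)
  od <- as.numeric(od)
  if (length(wavelengths) < 2L) {
    stop("an absorbance spectrum needs at least two points", call. = FALSE)
  }
  if (length(wavelengths) != length(od)) {
    stop("`wavelengths` and `od` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(wavelengths))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(od))) {
    stop("optical densities must be finite", call. = FALSE)
  }
  if (any(od < -0.05)) {
    stop("optical densities below -0.05 indicate corrupt input (offending minimum: ",
         format(min(od)), ")", call. = FALSE)
  }
  if (min(wavelengths) > 414 || max(wavelengths) < 414) {
    stop("spectrum must cover 414 nm (covered range: ",
         format(min(wavelengths)), "-", format(max(wavelengths)), " nm)",
         call. = FALSE)
  }
  structure(
    list(wavelengths = wavelengths, od = od,
         sample_id = as.character(sample_id)),
    class = "absorbance_spectrum"
  )
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat("<absorbance_spectrum> sample:", x$sample_id,
      "| range:", format(min(x$wavelengths)), "-", format(max(x$wavelengths)),
      "nm |", length(x$wavelengths), "points | A414:",
      format(round(absorbance_at(x, 414), 4)), "\n")
  invisible(x)
}

#' Optical density at a wavelength
#'
#' Reads the OD off a spectrum at an arbitrary wavelength, using linear
#' interpolation between the bracketing grid points. Grid points are
#' reproduced exactly. Linear interpolation (rather than nearest neighbor)
#' keeps 1-nm and 2-nm instrument grids consistent with each other.
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param wavelength Wavelength in nm; must lie within the covered range.
#' @return Optical density (unitless scalar, or vector if `wavelength` is a
#'   vector).
#' @export
absorbance_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  wavelength <- as.numeric(wavelength)
  lo <- min(spectrum$wavelengths)
  hi <- max(spectrum$wavelengths)
  if (any(wavelength < lo | wavelength > hi)) {
    stop("wavelength outside the covered range [", format(lo), ", ",
         format(hi), "] nm", call. = FALSE)
  }
  stats::approx(spectrum$wavelengths, spectrum$od, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Classify hemolysis from the A414 reading
#'
#' Applies the spectrophotometric hemolysis rule: a sample is called
#' `hemolyzed` when its OD at 414 nm strictly exceeds `threshold` (default
#' 0.2; readings of exactly 0.2 are non-hemolyzed). When a reference A414 is
#' supplied (typically the matched non-hemolyzed sample), the relative degree
#' of hemolysis `a414 / reference_a414` is reported. When a full spectrum is
#' supplied, the 541/576 nm Q-bands are scanned and severe hemolysis flagged.
#'
#' @param a414 Optical density at 414 nm (non-negative; vectorized).
#' @param threshold Classification threshold (OD, strictly positive).
#' @param reference_a414 Optional reference A414 (strictly positive) used to
#'   compute the relative degree of hemolysis; recycled against `a414`.
#' @param spectrum Optional [absorbance_spectrum()] (or list of spectra, one
#'   per element of `a414`) used for Q-band detection.
#'
#' @return A data frame with one row per reading and columns `a414`, `label`
#'   (`"hemolyzed"` / `"non_hemolyzed"`), `degree_relative` (NA when no
#'   reference was given) and `severe` (Q-band flag; FALSE when no spectrum
#'   was given).
#' @export
#' @examples
#' assess_hemolysis(c(0.574, 0.143, 0.2))
assess_hemolysis <- function(a414, threshold = 0.2, reference_a414 = NULL,
                             spectrum = NULL) {
  a414 <- as.numeric(a414)
  if (any(!is.finite(a414)) || any(a414 < 0)) {
    stop("`a414` must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive optical density", call. = FALSE)
  }
  degree <- rep(NA_real_, length(a414))
  if (!is.null(reference_a414)) {
    degree <- relative_degree(a414, reference_a414)
  }
  severe <- rep(FALSE, length(a414))
  if (!is.null(spectrum)) {
    spectra <- if (inherits(spectrum, "absorbance_spectrum")) list(spectrum) else spectrum
    if (length(spectra) == 1L) spectra <- rep(spectra, length(a414))
    if (length(spectra) != length(a414)) {
      stop("`spectrum` must be one spectrum or one per `a414` value", call. = FALSE)
    }
    severe <- vapply(spectra, detect_q_bands, logical(1))
  }
  data.frame(
    a414 = a414,
    label = ifelse(a414 > threshold, "hemolyzed", "non_hemolyzed"),
    degree_relative = degree,
    severe = severe,
    stringsAsFactors = FALSE
  )
}

#' Degree of hemolysis relative to a reference sample
#'
#' Ratio of a sample's A414 to a reference A414 (usually the matched
#' non-hemolyzed sample from the same collection). Values near 1 mean no
#' excess free hemoglobin; a heavily hemolyzed plasma typically scores 2-5x
#' its matched counterpart.
#'
#' @param a414_sample,a414_reference Optical densities at 414 nm, both
#'   strictly positive. Vectorized with recycling.
#' @return Unitless ratio `a414_sample / a414_reference`.
#' @export
#' @examples
#' relative_degree(0.574, 0.143) # ~4.01
relative_degree <- function(a414_sample, a414_reference) {
  a414_sample <- as.numeric(a414_sample)
  a414_reference <- as.numeric(a414_reference)
  if (any(!is.finite(a414_reference)) || any(a414_reference <= 0)) {
    stop("reference A414 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(a414_sample)) || any(a414_sample <= 0)) {
    stop("sample A414 must be finite and > 0", call. = FALSE)
  }
  a414_sample / a414_reference
}

#' Degree of hemolysis from replicate A414 readings
#'
#' Two conventions circulate for collapsing replicate spectrophotometer
#' readings into one relative degree: take the ratio of the replicate means
#' (`"ratio_of_means"`, the default), or form per-replicate ratios first and
#' average those (`"per_replicate"`). Differences are within instrument
#' rounding for typical replicate scatter; both are provided because
#' published tables do not always say which was used.
#'
#' @param sample_a414s Numeric vector of replicate A414 readings for the
#'   sample.
#' @param reference_a414s Replicate readings for the reference. For
#'   `"per_replicate"` both vectors must have equal length.
#' @param mode `"ratio_of_means"` or `"per_replicate"`.
#' @return A single relative-degree estimate.
#' @export
hemolysis_degree <- function(sample_a414s, reference_a414s,
                             mode = c("ratio_of_means", "per_replicate")) {
  mode <- match.arg(mode)
  if (mode == "ratio_of_means") {
    relative_degree(mean(as.numeric(sample_a414s)),
                    mean(as.numeric(reference_a414s)))
  } else {
    if (length(sample_a414s) != length(reference_a414s)) {
      stop("per-replicate averaging needs matched replicate vectors",
           call. = FALSE)
    }
    mean(relative_degree(sample_a414s, reference_a414s))
  }
}

#' Detect hemoglobin Q-bands (severe hemolysis)
#'
#' Scans the spectrum for the secondary hemoglobin absorbance peaks at 541
#' and 576 nm. Each window must contain a local maximum (on the sampling
#' grid) rising at least `prominence` OD above the straight line joining the
#' window endpoints. Both windows must fire for a `TRUE` call: the Q-bands
#' appear together, and requiring both rejects isolated noise bumps.
#'
#' @param spectrum An [absorbance_spectrum()] covering both windows.
#' @param windows List of `c(lo, hi)` wavelength windows in nm; defaults to
#'   541 +/- 5 and 576 +/- 5.
#' @param prominence Minimum height (OD) above the window's linear baseline.
#'   The default 0.02 ignores interpolation noise yet fires on visibly
#'   banded, heavily hemolyzed spectra.
#' @return Logical: `TRUE` if every window contains a qualifying peak.
#' @export
detect_q_bands <- function(spectrum,
                           windows = list(c(536, 546), c(571, 581)),
                           prominence = 0.02) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  wl <- spectrum$wavelengths
  od <- spectrum$od
  for (w in windows) {
    if (w[1] < min(wl) || w[2] > max(wl)) {
      stop("Q-band window [", w[1], ", ", w[2],
           "] nm outside covered range [", format(min(wl)), ", ",
           format(max(wl)), "] nm", call. = FALSE)
    }
    inside <- which(wl > w[1] & wl < w[2])
    if (length(inside) == 0L) return(FALSE)
    base_lo <- absorbance_at(spectrum, w[1])
    base_hi <- absorbance_at(spectrum, w[2])
    baseline <- base_lo + (base_hi - base_lo) * (wl[inside] - w[1]) / (w[2] - w[1])
    # local maximum on the sampling grid (weak inequality tolerates plateaus)
    left <- od[pmax(inside - 1L, 1L)]
    right <- od[pmin(inside + 1L, length(od))]
    is_max <- od[inside] >= left & od[inside] >= right &
      (od[inside] > left | od[inside] > right)
    hit <- any(is_max & (od[inside] - baseline >= prominence))
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Read absorbance spectra from a delimited text file
#'
#' Accepts CSV or TSV (auto-detected from the header line) with columns
#' `wavelength_nm` and `od`, plus an optional `sample_id` column for long
#' format holding several spectra in one file.
#'
#' @param path File path.
#' @param sample_id Identifier to use when the file has no `sample_id`
#'   column; defaults to the file name.
#' @return A list of [absorbance_spectrum()] objects, named by sample.
#' @export
read_spectra <- function(path, sample_id = NULL) {
  df <- read_delim_auto(path, colClasses = "character")
  need <- c("wavelength_nm", "od")
  if (!all(need %in% names(df))) {
    stop("spectrum file must have columns 'wavelength_nm' and 'od': ", path,
         call. = FALSE)
  }
  df$wavelength_nm <- as.numeric(df$wavelength_nm)
  df$od <- as.numeric(df$od)
  if (!"sample_id" %in% names(df)) {
    df$sample_id <- if (is.null(sample_id)) basename(path) else sample_id
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$wavelength_nm), , drop = FALSE]
    absorbance_spectrum(d$wavelength_nm, d$od, d$sample_id[1])
  })
  out[unique(df$sample_id)]
}

#' Write an absorbance spectrum to delimited text
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param path Output path; `.csv` extension writes CSV, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  df <- data.frame(sample_id = spectrum$sample_id,
                   wavelength_nm = spectrum$wavelengths,
                   od = spectrum$od)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
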