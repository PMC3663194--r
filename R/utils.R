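# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# All public interfaces express RBC contamination as %RBC by volume (the
# convention of spectrophotometric dilution tables); the mixing model works
# on the volume fraction. This is the single point of conversion.
pct_to_frac <- function(f_pct) f_pct / 100

# Delimiter sniffing for two-dialect (CSV/TSV) text inputs.
read_delim_auto <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses, na.strings = character(0),
                    comment.char = "", fill = TRUE)
}
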