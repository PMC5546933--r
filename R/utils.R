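# shared low-level helpers

norm_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("U", "T", toupper(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# percentage rounded (half-even, R default) to 1 decimal; NA on zero denominator
pct1 <- function(num, den) {
  ifelse(is.na(den) | den == 0, NA_real_, round(100 * num / den, 1))
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
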