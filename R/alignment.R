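# Global alignment of subcloned allele sequences against the reference
# amplicon, and extraction of left-normalised edit events.
#
# Scoring: match +1, mismatch -1, gap open -5, gap extend -1. Clones derived
# from Sanger subcloning are near-identical to the reference; the heavy gap
# opening penalty suppresses spurious indels. N scores 0 against everything
# and never produces an event.

.becall_submat <- local({
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
})

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("becall_input_error", "error")))
}

quality_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("becall_quality_error", "error")))
}

#' Align a subcloned allele sequence to its reference amplicon
#'
#' Performs a global (Needleman-Wunsch) alignment of a clone sequence against
#' the locus amplicon (match +1, mismatch -1, gap open -5, gap extend -1) and
#' extracts the differences as events in amplicon coordinates. Indels are
#' merged into single events and left-normalised (shifted to the smallest
#' amplicon offset producing an identical alternate sequence, the VCF
#' convention). Positions where either base is N are never called.
#'
#' @param locus A [target_locus()].
#' @param clone_seq Clone sequence (character; A/C/G/T/N, case-insensitive,
#'   U read as T). Length must be within 30% of the amplicon length.
#' @param min_identity Minimum fraction of identical alignment columns below
#'   which the clone is rejected with a quality error (default 0.6).
#' @return A data.frame of raw events with columns `kind`
#'   (`substitution`/`deletion`/`insertion`), `offset` (0-based amplicon
#'   offset; for insertions, the offset of the reference base immediately
#'   after the inserted sequence), `ref` and `alt` (reference/alternate
#'   strings in amplicon orientation), plus attribute `identity`.
#' @seealso [call_allele()] for category annotation.
#' @export
align_allele <- function(locus, clone_seq, min_identity = 0.6) {
  stopifnot(inherits(locus, "target_locus"))
  if (!is.character(clone_seq) || length(clone_seq) != 1L || !nzchar(clone_seq))
    input_error("clone sequence must be a non-empty character scalar")
  seq <- norm_seq(clone_seq)
  if (!grepl("^[ACGTN]+$", seq))
    input_error("clone sequence contains non-nucleotide characters")
  n_amp <- nchar(locus$amplicon)
  if (nchar(seq) < 0.7 * n_amp || nchar(seq) > 1.3 * n_amp)
    input_error(sprintf("clone length %d outside 30%% of amplicon length %d",
                        nchar(seq), n_amp))

  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = Biostrings::DNAString(locus$amplicon),
    type = "global", substitutionMatrix = .becall_submat,
    gapOpening = 5, gapExtension = 1)
  qry <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  ref <- seq_chars(as.character(Biostrings::alignedSubject(pa)))

  identity <- mean(qry == ref & ref != "-")
  if (identity < min_identity)
    quality_error(sprintf("alignment identity %.3f below floor %.3f",
                          identity, min_identity))

  ev <- extract_events(ref, qry, locus$amplicon)
  attr(ev, "identity") <- identity
  ev
}

# walk aligned columns -> raw events, then left-normalise indels
extract_events <- function(ref, qry, amplicon) {
  amp <- seq_chars(amplicon)
  events <- list()
  off <- 0L               # 0-based offset of the next reference base
  i <- 1L
  ncol_ <- length(ref)
  while (i <= ncol_) {
    r <- ref[i]; q <- qry[i]
    if (r != "-" && q != "-") {
      if (r != q && r != "N" && q != "N")
        events[[length(events) + 1L]] <-
          list(kind = "substitution", offset = off, ref = r, alt = q)
      off <- off + 1L
      i <- i + 1L
    } else if (q == "-") {           # deletion of reference bases
      j <- i
      while (j <= ncol_ && qry[j] == "-") j <- j + 1L
      len <- j - i
      norm <- normalize_deletion(amp, off, off + len - 1L)
      events[[length(events) + 1L]] <-
        list(kind = "deletion", offset = norm,
             ref = paste(amp[(norm + 1L):(norm + len)], collapse = ""),
             alt = "")
      off <- off + len
      i <- j
    } else {                          # insertion into the reference
      j <- i
      while (j <= ncol_ && ref[j] == "-") j <- j + 1L
      ins <- paste(qry[i:(j - 1L)], collapse = "")
      norm <- normalize_insertion(amp, off, ins)
      events[[length(events) + 1L]] <-
        list(kind = "insertion", offset = norm$offset, ref = "",
             alt = norm$ins)
      i <- j
    }
  }
  if (!length(events)) {
    return(data.frame(kind = character(), offset = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(events, function(e)
    data.frame(kind = e$kind, offset = as.integer(e$offset), ref = e$ref,
               alt = e$alt, stringsAsFactors = FALSE)))
  out[order(out$offset, out$kind), , drop = FALSE]
}

# deletion of amp[s..e] (0-based): shifting left by one is valid iff
# amp[s-1] == amp[e]
normalize_deletion <- function(amp, s, e) {
  while (s > 0L && amp[s] == amp[e + 1L]) {  # amp is 1-based here
    s <- s - 1L
    e <- e - 1L
  }
  s
}

# insertion of `ins` before 0-based offset p: shift left while the last
# inserted base equals the reference base just before the insertion point
normalize_insertion <- function(amp, p, ins) {
  k <- nchar(ins)
  while (p > 0L && substr(ins, k, k) == amp[p]) {
    ins <- paste0(amp[p], substr(ins, 1L, k - 1L))
    p <- p - 1L
  }
  list(offset = p, ins = ins)
}
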