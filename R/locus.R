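#' Define a guide RNA
#'
#' A guide is identified by its spacer, written 5'->3' and matching the
#' protospacer on the non-target strand. Full-length guides are 20 nt;
#' truncated variants of 16 or 17 nt are accepted (the 5' end stays position
#' 1, so the PAM starts at length + 1).
#'
#' @param name Guide name.
#' @param spacer Spacer sequence, A/C/G/T only, length 16-20.
#' @return An object of class `guide_rna` with elements `name`, `spacer`,
#'   `length`.
#' @examples
#' g <- guide_rna("gRNA-2", "GGGTGATGACTCTCTTGTCC")
#' g$length
#' @export
guide_rna <- function(name, spacer) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  spacer <- norm_seq(spacer)
  if (!grepl("^[ACGT]+$", spacer))
    stop("guide spacer must contain only A/C/G/T: ", name)
  if (nchar(spacer) < 16L || nchar(spacer) > 20L)
    stop("guide spacer length must be in [16, 20], got ", nchar(spacer))
  structure(list(name = name, spacer = spacer, length = nchar(spacer)),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat("<guide_rna> ", x$name, ": ", x$spacer, " (", x$length, " nt)\n", sep = "")
  invisible(x)
}

#' Define a target locus
#'
#' Binds a reference amplicon to a guide: where the protospacer sits in the
#' amplicon, on which strand, and the canonical deamination window. The PAM is
#' read from the amplicon immediately 3' of the protospacer (on the guide
#' orientation) and must match NGG. All downstream coordinates are expressed
#' relative to the protospacer: position 1 is the PAM-distal 5' base of the
#' spacer, positions `length+1 .. length+3` are the PAM, negative values are
#' upstream (there is no position 0).
#'
#' @param name Locus name.
#' @param amplicon Reference amplicon sequence (character).
#' @param protospacer_start 0-based offset of the leftmost protospacer base in
#'   the amplicon (amplicon coordinates, regardless of strand).
#' @param guide A [guide_rna()].
#' @param strand `"+"` if the protospacer reads 5'->3' on the amplicon as
#'   given, `"-"` if on its reverse complement.
#' @param window Inclusive protospacer-position range of the canonical
#'   deamination window; default `c(4, 8)`.
#' @return An object of class `target_locus`.
#' @examples
#' g <- guide_rna("g", "ACGTACGTACGTACGTACGT")
#' amp <- paste0("TTTTT", g$spacer, "AGG", "TTTTT")
#' loc <- target_locus("demo", amp, protospacer_start = 5, guide = g)
#' loc$pam
#' @export
target_locus <- function(name, amplicon, protospacer_start, guide,
                         strand = c("+", "-"), window = c(4L, 8L)) {
  strand <- match.arg(strand)
  stopifnot(inherits(guide, "guide_rna"))
  amplicon <- norm_seq(amplicon)
  if (!grepl("^[ACGTN]+$", amplicon))
    stop("amplicon must contain only A/C/G/T/N")
  L <- guide$length
  n <- nchar(amplicon)
  s <- as.integer(protospacer_start)
  if (s < 0L || s + L > n)
    stop("protospacer does not fit in amplicon")
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2] ||
      window[2] > L)
    stop("window must satisfy 1 <= lo <= hi <= guide length")

  proto <- substr(amplicon, s + 1L, s + L)
  if (strand == "-") proto <- revcomp(proto)
  if (proto != guide$spacer)
    stop("amplicon does not contain the guide spacer at protospacer_start ",
         s, " on strand ", strand)

  # PAM: 3 bases immediately 3' of the protospacer on the guide orientation
  if (strand == "+") {
    if (s + L + 3L > n) stop("amplicon too short to contain the PAM")
    pam <- substr(amplicon, s + L + 1L, s + L + 3L)
  } else {
    if (s - 3L < 0L) stop("amplicon too short to contain the PAM")
    pam <- revcomp(substr(amplicon, s - 2L, s))
  }
  if (!grepl("^[ACGT]GG$", pam))
    stop("PAM must match NGG, got ", pam)

  structure(list(name = name, amplicon = amplicon,
                 protospacer_start = s, strand = strand, guide = guide,
                 pam = pam, window = window),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat("<target_locus> ", x$name, "\n", sep = "")
  cat("  amplicon: ", nchar(x$amplicon), " bp; protospacer at offset ",
      x$protospacer_start, " (", x$strand, "), PAM ", x$pam, "\n", sep = "")
  cat("  guide: ", x$guide$name, " (", x$guide$length, " nt), window [",
      x$window[1], ", ", x$window[2], "]\n", sep = "")
  invisible(x)
}

#' Convert amplicon offsets to protospacer-relative positions
#'
#' Position 1 is the 5'-most (PAM-distal) protospacer base on the guide
#' orientation; the PAM occupies `length+1 .. length+3`. Bases 5' of the
#' protospacer get negative values counted as 1-based distances (-1 is the
#' base immediately upstream; there is no 0).
#'
#' @param locus A [target_locus()].
#' @param amplicon_offset Integer vector of 0-based amplicon offsets.
#' @return Integer vector of relative positions.
#' @examples
#' g <- guide_rna("g", "ACGTACGTACGTACGTACGT")
#' amp <- paste0("TTTTT", g$spacer, "AGGTTTTT")
#' loc <- target_locus("demo", amp, 5, g)
#' to_relative(loc, 5L)   # first protospacer base -> 1
#' @export
to_relative <- function(locus, amplicon_offset) {
  stopifnot(inherits(locus, "target_locus"))
  off <- as.integer(amplicon_offset)
  n <- nchar(locus$amplicon)
  if (any(off < 0L | off >= n))
    stop("amplicon offset out of bounds [0, ", n - 1L, "]")
  s <- locus$protospacer_start
  L <- locus$guide$length
  t <- if (locus$strand == "+") off - s else (s + L - 1L) - off
  ifelse(t >= 0L, t + 1L, t)
}

#' Convert protospacer-relative positions to amplicon offsets
#'
#' Inverse of [to_relative()].
#'
#' @param locus A [target_locus()].
#' @param rel Integer vector of relative positions (no 0).
#' @return Integer vector of 0-based amplicon offsets.
#' @export
from_relative <- function(locus, rel) {
  stopifnot(inherits(locus, "target_locus"))
  rel <- as.integer(rel)
  if (any(rel == 0L)) stop("relative position 0 does not exist")
  t <- ifelse(rel >= 1L, rel - 1L, rel)
  s <- locus$protospacer_start
  L <- locus$guide$length
  off <- if (locus$strand == "+") s + t else (s + L - 1L) - t
  n <- nchar(locus$amplicon)
  if (any(off < 0L | off >= n))
    stop("relative position maps outside the amplicon")
  off
}

#' Region of a protospacer-relative position
#'
#' Partitions coordinates into `upstream` (rel < 1), `protospacer`
#' (1..guide length; `window` inside the canonical window), `pam`
#' (length+1..length+3) and `downstream` (beyond the PAM).
#'
#' @param locus A [target_locus()].
#' @param rel Integer vector of relative positions.
#' @return Character vector of regions.
#' @export
rel_region <- function(locus, rel) {
  stopifnot(inherits(locus, "target_locus"))
  rel <- as.integer(rel)
  if (any(rel == 0L)) stop("relative position 0 does not exist")
  L <- locus$guide$length
  w <- locus$window
  ifelse(rel < 1L, "upstream",
    ifelse(rel <= L, ifelse(rel >= w[1] & rel <= w[2], "window", "protospacer"),
      ifelse(rel <= L + 3L, "pam", "downstream")))
}

#' Relative position with region annotation
#'
#' @param locus A [target_locus()].
#' @param amplicon_offset Integer vector of 0-based amplicon offsets.
#' @return A data.frame with columns `offset`, `value` (relative position)
#'   and `region`.
#' @export
rel_position <- function(locus, amplicon_offset) {
  v <- to_relative(locus, amplicon_offset)
  data.frame(offset = as.integer(amplicon_offset), value = v,
             region = rel_region(locus, v), stringsAsFactors = FALSE)
}

#' Protospacer sequence of a locus (guide orientation)
#' @param locus A [target_locus()].
#' @return Character scalar equal to the guide spacer.
#' @keywords internal
#' @noRd
locus_protospacer <- function(locus) locus$guide$spacer

#' The amplicon on the guide orientation
#'
#' Returns the amplicon as read 5'->3' along the guide (reverse complement of
#' the stored amplicon for minus-strand loci), together with the relative
#' position of each base. Internal helper for event sense conversion.
#' @noRd
guide_oriented_amplicon <- function(locus) {
  if (locus$strand == "+") locus$amplicon else revcomp(locus$amplicon)
}
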