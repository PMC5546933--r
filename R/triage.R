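# Off-target candidate triage for whole-genome-sequencing variant lists:
# quality and known-variant removal, low-complexity overlap, flank
# homopolymer filter, and guide-site matching (mismatch budget or perfect
# 3' seed, NGG PAM) in the +-flank around each surviving candidate.

#' Build a candidate table from chrom/pos/ref/alt vectors
#'
#' @param chrom,pos,ref,alt,qual Parallel vectors describing variant
#'   candidates (1-based positions; `qual` may be NA).
#' @return A data.frame with derived column `kind` (`snv` when ref and alt
#'   are both single bases, else `indel`).
#' @export
variant_candidates <- function(chrom, pos, ref, alt, qual = NA_real_) {
  ref <- toupper(ref); alt <- toupper(alt)
  kind <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
  qual <- rep(as.numeric(qual), length.out = length(pos))
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             ref = ref, alt = alt, kind = kind,
             qual = qual, stringsAsFactors = FALSE)
}

#' Quality filter
#'
#' Fails candidates whose QUAL is below the threshold; a candidate at the
#' threshold passes. Missing QUAL passes with a warning.
#'
#' @param candidates Candidate data.frame (see [variant_candidates()]).
#' @param min_qual Minimum QUAL (default 30).
#' @return Logical vector, TRUE = pass.
#' @export
filter_quality <- function(candidates, min_qual = 30) {
  q <- candidates$qual
  if (any(is.na(q)))
    warning(sum(is.na(q)), " candidate(s) with missing QUAL pass unfiltered")
  is.na(q) | q >= min_qual
}

#' Known-variant filter
#'
#' Fails candidates present in a known-variant set (dbSNP-style). In
#' `"exact"` mode chrom, pos, ref and alt must all match; in `"position"`
#' mode chrom and pos suffice.
#'
#' @param candidates Candidate data.frame.
#' @param known Known-variant data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt` (e.g. from [read_vcf()]).
#' @param mode `"exact"` (default) or `"position"`.
#' @return Logical vector, TRUE = pass (not known).
#' @export
filter_known <- function(candidates, known, mode = c("exact", "position")) {
  mode <- match.arg(mode)
  if (is.null(known) || !nrow(known)) return(rep(TRUE, nrow(candidates)))
  key <- function(df) {
    if (mode == "exact")
      paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    else paste(df$chrom, df$pos, sep = ":")
  }
  !(key(candidates) %in% key(known))
}

#' Low-complexity overlap filter
#'
#' Fails candidates whose reference span (POS .. POS + nchar(ref) - 1)
#' intersects a low-complexity interval. Intervals are 0-based half-open as
#' in BED; [read_bed()] returns them as a `GRanges` (1-based closed), which
#' is what this function expects.
#'
#' @param candidates Candidate data.frame.
#' @param intervals A `GRanges` of low-complexity regions.
#' @return Logical vector, TRUE = pass (no overlap).
#' @export
filter_low_complexity <- function(candidates, intervals) {
  if (is.null(intervals) || !length(intervals))
    return(rep(TRUE, nrow(candidates)))
  if (!nrow(candidates)) return(logical())
  spans <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(start = candidates$pos,
                     end = candidates$pos + nchar(candidates$ref) - 1L))
  hits <- GenomicRanges::countOverlaps(spans, intervals)
  hits == 0L
}

# longest single-base run in a character sequence window
max_homopolymer_run <- function(seq) {
  if (!nchar(seq)) return(0L)
  r <- rle(seq_chars(seq))
  max(r$lengths)
}

#' Flank homopolymer filter
#'
#' Fails candidates whose flanking window (variant position +- `radius`,
#' clipped at contig ends) contains a single-base run of at least `min_run`
#' bases. Runs are measured inside the window only: bases outside it do not
#' extend a run. The defaults implement "runs longer than 7 bp within
#' +-100 bp".
#'
#' @param candidates Candidate data.frame.
#' @param genome Named character vector or `DNAStringSet` of contigs.
#' @param radius Flank radius in bp (default 100).
#' @param min_run Minimal failing run length (default 8).
#' @return Logical vector, TRUE = pass.
#' @export
filter_flank_homopolymer <- function(candidates, genome, radius = 100,
                                     min_run = 8) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(candidates)), function(i) {
    chrom <- candidates$chrom[i]; pos <- candidates$pos[i]
    ctg <- genome[[chrom]]
    if (is.null(ctg)) stop("contig not in genome: ", chrom)
    n <- nchar(ctg)
    if (pos < 1L || pos > n)
      stop("variant position ", pos, " beyond contig ", chrom, " (", n, " bp)")
    win <- substr(ctg, max(1L, pos - radius), min(n, pos + radius))
    max_homopolymer_run(win) < min_run
  }, logical(1))
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (is.list(genome)) {
    stopifnot(!is.null(names(genome)),
              all(vapply(genome, is.character, logical(1))))
    return(genome)
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  as.list(genome)
}

#' Scan a sequence for guide-like sites
#'
#' Tests every protospacer-length window on both strands that is immediately
#' followed (3', same strand) by an NGG PAM. A window is reported when its
#' Hamming distance to the spacer is at most `max_mm`
#' (`rule = "full_mismatch_budget"`) or when its 3'-most `seed_len` bases
#' match the spacer exactly (`rule = "seed_10nt"`); when both hold the
#' mismatch-budget rule is recorded. N in the sequence never matches.
#'
#' @param flank_seq Sequence to scan (character).
#' @param flank_origin 0-based offset of `flank_seq` within its contig, used
#'   to report absolute coordinates.
#' @param guide A [guide_rna()].
#' @param max_mm Mismatch budget (default 5).
#' @param seed_len 3' seed length (default 10).
#' @param chrom Contig name for reporting.
#' @return A data.frame with one row per matched site: `chrom`, `start`
#'   (0-based offset of the protospacer-aligned window, leftmost base on the
#'   given contig), `strand`, `matched_seq` (guide orientation), `pam`,
#'   `mismatches`, `rule`.
#' @export
scan_guide_sites <- function(flank_seq, flank_origin = 0L, guide,
                             max_mm = 5L, seed_len = 10L, chrom = "seq") {
  stopifnot(inherits(guide, "guide_rna"))
  flank_seq <- norm_seq(flank_seq)
  L <- guide$length
  n <- nchar(flank_seq)
  empty <- data.frame(chrom = character(), start = integer(),
                      strand = character(), matched_seq = character(),
                      pam = character(), mismatches = integer(),
                      rule = character(), stringsAsFactors = FALSE)
  if (n < L + 3L) return(empty)

  scan_one <- function(seqv, strand) {
    m <- length(seqv)
    starts <- seq_len(m - L - 2L)           # 1-based window starts
    g <- seq_chars(guide$spacer)
    mm <- integer(length(starts))
    seed_mm <- integer(length(starts))
    for (p in seq_len(L)) {
      diffp <- seqv[starts + p - 1L] != g[p] | seqv[starts + p - 1L] == "N"
      mm <- mm + diffp
      if (p > L - seed_len) seed_mm <- seed_mm + diffp
    }
    pam1 <- seqv[starts + L]
    pam2 <- seqv[starts + L + 1L]
    pam3 <- seqv[starts + L + 2L]
    ok <- (pam2 == "G" & pam3 == "G") & (mm <= max_mm | seed_mm == 0L)
    idx <- which(ok)
    if (!length(idx)) return(empty)
    data.frame(chrom = chrom,
               start = idx - 1L,            # 0-based within scanned strand
               strand = strand,
               matched_seq = vapply(idx, function(i)
                 paste(seqv[i:(i + L - 1L)], collapse = ""), character(1)),
               pam = paste0(pam1[idx], pam2[idx], pam3[idx]),
               mismatches = mm[idx],
               rule = ifelse(mm[idx] <= max_mm, "full_mismatch_budget",
                             "seed_10nt"),
               stringsAsFactors = FALSE)
  }

  fwd <- scan_one(seq_chars(flank_seq), "+")
  rev_ <- scan_one(seq_chars(revcomp(flank_seq)), "-")
  # map reverse-strand window starts back to forward coordinates: a window
  # at 0-based position j on the reverse complement covers forward offsets
  # [n - j - L, n - j - 1]
  if (nrow(rev_)) rev_$start <- n - rev_$start - L
  out <- rbind(fwd, rev_)
  if (nrow(out)) {
    out$start <- out$start + as.integer(flank_origin)
    out <- out[order(out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Triage a candidate list against a genome and guide
#'
#' Runs the four per-candidate filters (quality, known variant,
#' low-complexity overlap, flank homopolymer) independently, then scans the
#' +-`flank` window around every filter-surviving candidate for guide-like
#' sites. A surviving candidate with at least one site hit is a potential
#' off-target-associated variant; survivors without hits are background.
#'
#' @param candidates Candidate data.frame (see [variant_candidates()] or
#'   [read_vcf()]).
#' @param genome Named character vector or `DNAStringSet` of contigs.
#' @param guide A [guide_rna()].
#' @param known Known-variant data.frame, or NULL.
#' @param intervals Low-complexity `GRanges`, or NULL.
#' @param flank Flank radius for the guide-site scan (default 100 bp).
#' @param max_mm Guide mismatch budget (default 5).
#' @param seed_len 3' seed length (default 10).
#' @param min_run Homopolymer run threshold (default 8; runs of `min_run` or
#'   more fail).
#' @param min_qual Quality threshold (default 30).
#' @param known_mode Known-variant matching mode, see [filter_known()].
#' @return An object of class `triage_report`: list with `candidates` (the
#'   input plus verdict columns and `status`), `site_hits` (data.frame of
#'   guide-site matches with `candidate` index and `distance_to_variant`),
#'   `summary` (named counts) and `outcome` (text).
#' @export
triage <- function(candidates, genome, guide, known = NULL, intervals = NULL,
                   flank = 100L, max_mm = 5L, seed_len = 10L, min_run = 8L,
                   min_qual = 30, known_mode = "exact") {
  genome <- as_genome(genome)
  bad <- setdiff(unique(candidates$chrom), names(genome))
  if (length(bad))
    stop("candidate contigs absent from genome: ", paste(bad, collapse = ", "))

  n <- nrow(candidates)
  cand <- candidates
  cand$pass_quality <- filter_quality(cand, min_qual)
  cand$pass_known <- filter_known(cand, known, mode = known_mode)
  cand$pass_low_complexity <- filter_low_complexity(cand, intervals)
  cand$pass_homopolymer <-
    if (n) filter_flank_homopolymer(cand, genome, radius = flank,
                                    min_run = min_run) else logical()
  surviving <- cand$pass_quality & cand$pass_known &
    cand$pass_low_complexity & cand$pass_homopolymer

  hit_rows <- list()
  L <- guide$length
  for (i in which(surviving)) {
    ctg <- genome[[cand$chrom[i]]]
    len <- nchar(ctg)
    lo <- max(1L, cand$pos[i] - flank)
    hi <- min(len, cand$pos[i] + flank)
    hits <- scan_guide_sites(substr(ctg, lo, hi), flank_origin = lo - 1L,
                             guide = guide, max_mm = max_mm,
                             seed_len = seed_len, chrom = cand$chrom[i])
    if (nrow(hits)) {
      ws <- hits$start + 1L               # 1-based window span
      we <- hits$start + L
      hits$distance_to_variant <- ifelse(
        cand$pos[i] < ws, ws - cand$pos[i],
        ifelse(cand$pos[i] > we, cand$pos[i] - we, 0L))
      hits$candidate <- i
      hit_rows[[length(hit_rows) + 1L]] <- hits
    }
  }
  site_hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
    else data.frame(chrom = character(), start = integer(),
                    strand = character(), matched_seq = character(),
                    pam = character(), mismatches = integer(),
                    rule = character(), distance_to_variant = integer(),
                    candidate = integer(), stringsAsFactors = FALSE)

  has_hit <- seq_len(n) %in% site_hits$candidate
  cand$status <- ifelse(!surviving, "removed",
                        ifelse(has_hit, "potential_off_target", "background"))
  n_pot <- sum(cand$status == "potential_off_target")
  summary <- c(n_candidates = n,
               fail_quality = sum(!cand$pass_quality),
               fail_known = sum(!cand$pass_known),
               fail_low_complexity = sum(!cand$pass_low_complexity),
               fail_homopolymer = sum(!cand$pass_homopolymer),
               surviving = sum(surviving),
               potential_off_target = n_pot)
  outcome <- if (n_pot == 0L)
    "no potential off-target site indel or SNV"
  else sprintf("%d potential off-target-associated variant(s)", n_pot)
  structure(list(candidates = cand, site_hits = site_hits,
                 summary = summary, outcome = outcome),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("<triage_report>\n")
  s <- x$summary
  cat("  candidates:", s[["n_candidates"]],
      " surviving:", s[["surviving"]],
      " potential off-target:", s[["potential_off_target"]], "\n")
  cat("  fails - quality:", s[["fail_quality"]],
      " known:", s[["fail_known"]],
      " low-complexity:", s[["fail_low_complexity"]],
      " homopolymer:", s[["fail_homopolymer"]], "\n")
  cat("  outcome:", x$outcome, "\n")
  invisible(x)
}
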