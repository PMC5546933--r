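# Deamination category assignment and per-clone allele calls.

#' Event categories used by the classifier
#'
#' `window_deamination`: deamination-consistent substitution inside the
#' canonical window; `on_target_deamination`: inside the protospacer but
#' outside the window; `proximal_site_deamination`: outside the protospacer
#' (upstream, PAM or downstream); `other_substitution`: not
#' deamination-consistent; `indel`: insertion or deletion.
#' @keywords internal
#' @name event-categories
NULL

EVENT_CATEGORIES <- c("window_deamination", "on_target_deamination",
                      "proximal_site_deamination", "other_substitution",
                      "indel")

#' Categorise a raw edit event
#'
#' Assigns the deamination category and strand call to raw events expressed
#' in non-target-strand (protospacer) sense. A C with any alternate base is a
#' deaminated cytidine on the non-target strand (C>T canonical, C>G/A
#' non-canonical); a G is a deaminated cytidine on the target strand (G>A
#' canonical, G>T/C non-canonical). Deamination-consistent events are then
#' placed by region: canonical window, elsewhere in the protospacer, or
#' proximal (upstream/PAM/downstream of the protospacer). All other
#' substitutions are `other_substitution`; indels are `indel`.
#'
#' @param events A data.frame with columns `kind`, `ref`, `alt`, `rel`
#'   (protospacer-relative position).
#' @param locus A [target_locus()].
#' @return The data.frame with added columns `region`, `category`,
#'   `strand_call` (`non_target`/`target`/`n/a`) and `canonical` (logical;
#'   NA for non-deamination events).
#' @export
categorize_event <- function(events, locus) {
  stopifnot(inherits(locus, "target_locus"),
            all(c("kind", "ref", "alt", "rel") %in% names(events)))
  n <- nrow(events)
  region <- if (n) rel_region(locus, events$rel) else character()
  category <- character(n)
  strand_call <- rep("n/a", n)
  canonical <- rep(NA, n)
  for (i in seq_len(n)) {
    if (events$kind[i] != "substitution") {
      category[i] <- "indel"
      next
    }
    ref <- events$ref[i]; alt <- events$alt[i]
    deam <- FALSE
    if (ref == "C" && alt %in% c("T", "G", "A")) {
      deam <- TRUE
      strand_call[i] <- "non_target"
      canonical[i] <- alt == "T"
    } else if (ref == "G" && alt %in% c("A", "T", "C")) {
      deam <- TRUE
      strand_call[i] <- "target"
      canonical[i] <- alt == "A"
    }
    if (!deam) {
      category[i] <- "other_substitution"
    } else if (region[i] == "window") {
      category[i] <- "window_deamination"
    } else if (region[i] == "protospacer") {
      category[i] <- "on_target_deamination"
    } else {
      category[i] <- "proximal_site_deamination"
    }
  }
  events$region <- region
  events$category <- factor(category, levels = EVENT_CATEGORIES)
  events$strand_call <- strand_call
  events$canonical <- canonical
  events
}

#' Call one allele from a subcloned sequence
#'
#' Aligns a clone to the locus amplicon ([align_allele()]), annotates every
#' event with its protospacer-relative position and deamination category, and
#' classifies the allele: `wild_type` (no events), `indel_allele` (at least
#' one insertion/deletion), `edited` otherwise. For minus-strand loci,
#' substitution ref/alt bases are complemented so events are always reported
#' in non-target-strand sense; indel ref/alt strings stay in amplicon
#' orientation (positions are left-normalised amplicon offsets).
#'
#' @param locus A [target_locus()].
#' @param clone_id Clone identifier.
#' @param clone_seq Clone sequence.
#' @param min_identity Alignment identity floor, see [align_allele()].
#' @return An object of class `allele_call`: list with `clone_id`, `events`
#'   (annotated data.frame), `allele_class`, `pattern_key`, `identity`.
#' @examples
#' g <- guide_rna("g", "ACGTACGTACGTACGTACGT")
#' amp <- paste0("TTATT", g$spacer, "AGGTTATT")
#' loc <- target_locus("demo", amp, 5, g)
#' call_allele(loc, "c1", amp)$allele_class   # wild_type
#' @export
call_allele <- function(locus, clone_id, clone_seq, min_identity = 0.6) {
  raw <- align_allele(locus, clone_seq, min_identity = min_identity)
  ev <- annotate_events(raw, locus)
  allele_class <- if (!nrow(ev)) "wild_type"
    else if (any(ev$kind != "substitution")) "indel_allele"
    else "edited"
  structure(list(clone_id = clone_id, events = ev,
                 allele_class = allele_class,
                 pattern_key = pattern_key(ev),
                 identity = attr(raw, "identity")),
            class = "allele_call")
}

# raw amplicon-space events -> guide-sense annotated events
annotate_events <- function(raw, locus) {
  ev <- raw
  if (nrow(ev) && locus$strand == "-") {
    subs <- ev$kind == "substitution"
    ev$ref[subs] <- complement_base(ev$ref[subs])
    ev$alt[subs] <- complement_base(ev$alt[subs])
  }
  ev$rel <- if (nrow(ev)) to_relative(locus, ev$offset) else integer()
  categorize_event(ev, locus)
}

#' Canonical text encoding of an event list
#'
#' Identical event lists yield identical keys, used to tally clones per
#' sequence pattern. Wild type encodes as `"WT"`.
#'
#' @param events Annotated event data.frame (from [call_allele()]).
#' @return Character scalar.
#' @export
pattern_key <- function(events) {
  if (!nrow(events)) return("WT")
  events <- events[order(events$offset, events$kind), , drop = FALSE]
  parts <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    switch(e$kind,
      substitution = sprintf("S%d:%s>%s", e$rel, e$ref, e$alt),
      deletion     = sprintf("D%d:%d", e$offset, nchar(e$ref)),
      insertion    = sprintf("I%d:%s", e$offset, e$alt))
  }, character(1))
  paste(parts, collapse = "|")
}

#' @export
print.allele_call <- function(x, ...) {
  cat("<allele_call> ", x$clone_id, ": ", x$allele_class,
      " [", x$pattern_key, "]\n", sep = "")
  invisible(x)
}

#' Call every clone in a pool
#'
#' Applies [call_allele()] to a named set of clone sequences. Identical
#' sequences are aligned once and the call reused. Clones failing the
#' alignment identity floor are excluded with a warning and reported in the
#' `excluded` attribute.
#'
#' @param locus A [target_locus()].
#' @param seqs Named character vector or `DNAStringSet` of clone sequences.
#' @param min_identity Alignment identity floor.
#' @return A list of `allele_call` objects (one per surviving clone), with
#'   attribute `excluded` naming rejected clones.
#' @export
classify_pool <- function(locus, seqs, min_identity = 0.6) {
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  cache <- new.env(parent = emptyenv())
  excluded <- character()
  calls <- list()
  for (id in names(seqs)) {
    s <- norm_seq(seqs[[id]])
    hit <- cache[[s]]
    if (is.null(hit)) {
      hit <- tryCatch(call_allele(locus, id, s, min_identity = min_identity),
                      becall_quality_error = function(e) e)
      cache[[s]] <- hit
    }
    if (inherits(hit, "becall_quality_error")) {
      warning("clone ", id, " excluded: ", conditionMessage(hit))
      excluded <- c(excluded, id)
    } else {
      hit$clone_id <- id
      calls[[id]] <- hit
    }
  }
  attr(calls, "excluded") <- excluded
  calls
}

#' Per-clone event table
#'
#' Flattens a list of allele calls into one row per event (wild-type clones
#' contribute one row with empty event fields), suitable for writing as TSV.
#'
#' @param calls List of `allele_call` objects.
#' @return A data.frame.
#' @export
events_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    if (!nrow(cl$events)) {
      data.frame(clone_id = cl$clone_id, allele_class = cl$allele_class,
                 pattern_key = cl$pattern_key, kind = NA_character_,
                 offset = NA_integer_, rel = NA_integer_,
                 region = NA_character_, ref = NA_character_,
                 alt = NA_character_, category = NA_character_,
                 strand_call = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(clone_id = cl$clone_id, allele_class = cl$allele_class,
                 pattern_key = cl$pattern_key, kind = cl$events$kind,
                 offset = cl$events$offset, rel = cl$events$rel,
                 region = cl$events$region, ref = cl$events$ref,
                 alt = cl$events$alt,
                 category = as.character(cl$events$category),
                 strand_call = cl$events$strand_call,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
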