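# Synthetic data: clone pools from a per-position deamination model, and toy
# genomes with planted guide-like sites, homopolymer runs, low-complexity
# intervals and variant candidates.

#' Stochastic editing model for simulated embryos
#'
#' Editing acts per allele lineage: every cytidine (non-target strand, i.e.
#' amplicon C on the guide orientation) is deaminated independently with a
#' probability set by its position -- `p_window` inside the canonical window,
#' `p_protospacer_out` elsewhere in the protospacer, and for bases outside
#' the protospacer an exponentially decaying proximal rate
#' `p_proximal_max * exp(-d / proximal_scale)` truncated beyond
#' `proximal_range` bp, with distance d counted from the protospacer edge
#' (the PAM is downstream distance 1-3). Target-strand cytidines (amplicon
#' Gs) use the same positional rate times `p_target_strand_factor`. A
#' deaminated C becomes T, G or A with probabilities `outcome_probs`
#' (complement-mapped for target-strand events). Each allele independently
#' acquires a 1-3 bp indel near the window with probability `p_indel`.
#'
#' @param p_window Per-position deamination probability in the window
#'   (default 0.2).
#' @param p_protospacer_out Rate in the protospacer outside the window
#'   (default 0.02).
#' @param p_proximal_max,proximal_scale,proximal_range Proximal-rate decay:
#'   peak rate at distance 1 (default 0.01), e-folding scale in bp (default
#'   20), truncation distance (default 100).
#' @param outcome_probs Probabilities of alt T/G/A given deamination
#'   (default 0.8, 0.1, 0.1).
#' @param p_target_strand_factor Multiplier for target-strand cytidines
#'   (default 0.5).
#' @param p_indel Per-allele indel probability (default 0.02).
#' @param n_lineages Allele lineages per embryo: 2 (editing at the zygote
#'   stage, no mosaicism) or 4 (post-division editing).
#' @param clones_per_embryo Subclones sequenced per embryo (default 15).
#' @param noise_rate Per-base clone-level sequencing error rate (default 0).
#' @return An object of class `editing_model` (validated list).
#' @export
editing_model <- function(p_window = 0.2, p_protospacer_out = 0.02,
                          p_proximal_max = 0.01, proximal_scale = 20,
                          proximal_range = 100,
                          outcome_probs = c(T = 0.8, G = 0.1, A = 0.1),
                          p_target_strand_factor = 0.5, p_indel = 0.02,
                          n_lineages = 2L, clones_per_embryo = 15L,
                          noise_rate = 0) {
  probs <- c(p_window, p_protospacer_out, p_proximal_max, outcome_probs,
             p_target_strand_factor, p_indel, noise_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            abs(sum(outcome_probs) - 1) < 1e-9,
            n_lineages %in% c(2L, 4L), clones_per_embryo >= 1L,
            proximal_scale > 0, proximal_range >= 0)
  structure(list(p_window = p_window, p_protospacer_out = p_protospacer_out,
                 p_proximal_max = p_proximal_max,
                 proximal_scale = proximal_scale,
                 proximal_range = proximal_range,
                 outcome_probs = outcome_probs,
                 p_target_strand_factor = p_target_strand_factor,
                 p_indel = p_indel, n_lineages = as.integer(n_lineages),
                 clones_per_embryo = as.integer(clones_per_embryo),
                 noise_rate = noise_rate),
            class = "editing_model")
}

# per-offset deamination rate for one locus under a model; returns a
# data.frame of editable positions: offset, base (amplicon), rate, is C on
# the non-target (guide) sense?
position_rates <- function(locus, model) {
  amp <- seq_chars(locus$amplicon)
  offs <- seq_along(amp) - 1L
  rel <- to_relative(locus, offs)
  region <- rel_region(locus, rel)
  L <- locus$guide$length
  # distance outside the protospacer (PAM = downstream 1..3)
  dist_out <- ifelse(rel < 1L, -rel, ifelse(rel > L, rel - L, 0L))
  base_rate <- ifelse(region == "window", model$p_window,
    ifelse(region == "protospacer", model$p_protospacer_out,
      ifelse(dist_out <= model$proximal_range,
             model$p_proximal_max * exp(-dist_out / model$proximal_scale),
             0)))
  # guide-sense C: amplicon C on + loci, amplicon G on - loci (and vice versa)
  sense_base <- if (locus$strand == "+") amp else complement_base(amp)
  is_c <- sense_base == "C"
  is_g <- sense_base == "G"
  rate <- ifelse(is_c, base_rate,
                 ifelse(is_g, base_rate * model$p_target_strand_factor, 0))
  data.frame(offset = offs, base = amp, sense_base = sense_base,
             rate = rate, stringsAsFactors = FALSE)
}

# analytic per-allele probability of acquiring at least one edit
allele_edit_probability <- function(locus, model, include_indel = FALSE) {
  r <- position_rates(locus, model)
  p <- 1 - prod(1 - r$rate)
  if (include_indel) p <- 1 - (1 - p) * (1 - model$p_indel)
  p
}

# mutate one allele lineage; returns list(seq, events) with events as a raw
# amplicon-space data.frame (kind, offset, ref, alt)
simulate_allele <- function(locus, model, rates) {
  amp <- seq_chars(locus$amplicon)
  hit <- which(stats::runif(nrow(rates)) < rates$rate)
  events <- list()
  for (i in hit) {
    # draw outcome in guide sense, then express in amplicon orientation
    alt_sense <- sample(names(model$outcome_probs), 1L,
                        prob = model$outcome_probs)
    sense_ref <- rates$sense_base[i]
    if (sense_ref == "C") {
      amp_alt <- if (locus$strand == "+") alt_sense else
        complement_base(alt_sense)
    } else {                      # target-strand C = guide-sense G
      amp_alt <- if (locus$strand == "+") complement_base(alt_sense) else
        alt_sense
    }
    if (amp_alt == rates$base[i]) next   # G>G impossible by construction, guard
    events[[length(events) + 1L]] <-
      data.frame(kind = "substitution", offset = rates$offset[i],
                 ref = rates$base[i], alt = amp_alt, stringsAsFactors = FALSE)
  }
  if (stats::runif(1) < model$p_indel) {
    w_off <- from_relative(locus, locus$window[1]:locus$window[2])
    anchor <- sample(rep(w_off, 2L), 1L) + sample(-2L:2L, 1L)
    anchor <- max(1L, min(length(amp) - 4L, anchor))
    len <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {
      # deletion of amplicon bases anchor..anchor+len-1 (0-based);
      # left-normalised so truth matches the caller's VCF-style placement
      norm <- normalize_deletion(amp, anchor, anchor + len - 1L)
      # right extent of the equivalent placements (repeat context): a block
      # [s,e] shifts right while amp0[s] == amp0[e+1]
      s <- anchor; e <- anchor + len - 1L
      while (e + 2L <= length(amp) && amp[s + 1L] == amp[e + 2L]) {
        s <- s + 1L; e <- e + 1L
      }
      drop_span <- c(norm - 1L, e + 1L)
      events[[length(events) + 1L]] <-
        data.frame(kind = "deletion", offset = norm,
                   ref = paste(amp[(norm + 1L):(norm + len)], collapse = ""),
                   alt = "", stringsAsFactors = FALSE)
    } else {                       # insertion before 0-based offset anchor
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      norm <- normalize_insertion(amp, anchor, ins)
      rp <- anchor; ri <- ins; k <- nchar(ins)
      while (rp + 1L <= length(amp) && substr(ri, 1L, 1L) == amp[rp + 1L]) {
        ri <- paste0(substr(ri, 2L, k), amp[rp + 1L]); rp <- rp + 1L
      }
      drop_span <- c(norm$offset - 1L, rp)
      events[[length(events) + 1L]] <-
        data.frame(kind = "insertion", offset = norm$offset, ref = "",
                   alt = norm$ins, stringsAsFactors = FALSE)
    }
    # substitutions deleted by, or adjacent to, the indel would make the
    # optimal alignment ambiguous: drop them from the truth and the allele
    keep <- vapply(events, function(e)
      e$kind != "substitution" ||
        e$offset < drop_span[1] || e$offset > drop_span[2], logical(1))
    events <- events[keep]
  }

  # rebuild the allele sequence from the reference and the event list
  seq <- amp
  for (e in events)
    if (e$kind == "substitution") seq[e$offset + 1L] <- e$alt
  for (e in events) {
    if (e$kind == "deletion")
      seq <- seq[-((e$offset + 1L):(e$offset + nchar(e$ref)))]
    else if (e$kind == "insertion")
      seq <- append(seq, seq_chars(e$alt), after = e$offset)
  }
  ev <- if (length(events)) do.call(rbind, events)
    else data.frame(kind = character(), offset = integer(), ref = character(),
                    alt = character(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$offset), , drop = FALSE]
  rownames(ev) <- NULL
  list(seq = paste(seq, collapse = ""), events = ev)
}

#' Simulate a cohort of edited embryos
#'
#' For each embryo, `n_lineages` allele lineages are edited independently
#' under the model, and `clones_per_embryo` subclones are drawn uniformly
#' with replacement from the lineages (optionally with per-base sequencing
#' noise). The returned truth records each lineage's sequence and true event
#' list, which lineages each clone came from, and the expected genotype class
#' derived from the lineages actually sampled -- by the same pattern rules
#' the genotyper applies.
#'
#' @param locus A [target_locus()].
#' @param model An [editing_model()].
#' @param n_embryos Number of embryos.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An object of class `sim_cohort`: list with `clones` (named
#'   character vector, names `"embryoNN/cloneNN"`), `truth` (per-embryo
#'   list: `lineage_seqs`, `lineage_events`, `clone_lineage`,
#'   `expected_class`, `expected_mutant`, `expected_proximal`,
#'   `expected_indel`), and `locus`.
#' @export
simulate_cohort <- function(locus, model, n_embryos, seed) {
  stopifnot(inherits(locus, "target_locus"), inherits(model, "editing_model"))
  set.seed(as.integer(seed))
  rates <- position_rates(locus, model)
  clones <- character()
  truth <- vector("list", n_embryos)
  for (e in seq_len(n_embryos)) {
    eid <- sprintf("embryo%03d", e)
    lin <- lapply(seq_len(model$n_lineages), function(j)
      simulate_allele(locus, model, rates))
    assign_ <- sample(model$n_lineages, model$clones_per_embryo,
                      replace = TRUE)
    cl <- vapply(assign_, function(j) lin[[j]]$seq, character(1))
    if (model$noise_rate > 0) cl <- vapply(cl, add_noise,
                                           character(1), model$noise_rate)
    names(cl) <- sprintf("%s/clone%02d", eid, seq_along(cl))
    clones <- c(clones, cl)

    lineage_keys <- vapply(lin, function(l)
      pattern_key(annotate_events(l$events, locus)), character(1))
    sampled <- sort(unique(assign_))
    keys <- unique(lineage_keys[sampled])
    edited_keys <- setdiff(keys, "WT")
    expected_class <- genotype_from_patterns("WT" %in% keys,
                                             length(edited_keys))
    sampled_ev <- lapply(sampled, function(j)
      annotate_events(lin[[j]]$events, locus))
    truth[[e]] <- list(
      embryo_id = eid,
      lineage_seqs = vapply(lin, `[[`, character(1), "seq"),
      lineage_events = lapply(lin, function(l)
        annotate_events(l$events, locus)),
      lineage_keys = lineage_keys,
      clone_lineage = assign_,
      expected_class = expected_class,
      expected_mutant = length(edited_keys) > 0L,
      expected_proximal = any(vapply(sampled_ev, function(ev)
        any(ev$category == "proximal_site_deamination"), logical(1))),
      expected_indel = any(vapply(sampled_ev, function(ev)
        any(ev$kind != "substitution"), logical(1))))
  }
  names(truth) <- vapply(truth, `[[`, character(1), "embryo_id")
  structure(list(clones = clones, truth = truth, locus = locus,
                 model = model, seed = as.integer(seed)),
            class = "sim_cohort")
}

add_noise <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$truth), " embryos, ",
      length(x$clones), " clones (locus ", x$locus$name, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

# --- toy genome simulation ---------------------------------------------------

# random background with homopolymer runs capped at 4 bp
random_background <- function(n, cap = 4L) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  run <- 0L
  prev <- ""
  draws <- sample(bases, n, replace = TRUE)
  for (i in seq_len(n)) {
    b <- draws[i]
    if (b == prev && run >= cap) b <- sample(setdiff(bases, prev), 1L)
    if (b == prev) run <- run + 1L else run <- 1L
    prev <- b
    out[i] <- b
  }
  out
}

# construct a guide-like site sequence (protospacer+PAM, forward sense) with
# a prescribed mismatch count / seed status / PAM validity
make_site_seq <- function(guide, mismatches, seed_intact, pam_ok,
                          seed_len = 10L) {
  g <- seq_chars(guide$spacer)
  L <- length(g)
  non_seed <- seq_len(L - seed_len)
  seedpos <- (L - seed_len + 1L):L
  if (mismatches > 0L) {
    if (seed_intact) {
      if (mismatches > length(non_seed))
        stop("cannot keep the seed intact with ", mismatches, " mismatches")
      pos <- sample(non_seed, mismatches)
    } else {
      n_seed_mm <- min(mismatches, max(1L, mismatches - length(non_seed)))
      pos <- c(sample(seedpos, n_seed_mm),
               if (mismatches - n_seed_mm > 0L)
                 sample(non_seed, mismatches - n_seed_mm))
    }
    for (p in pos) g[p] <- sample(setdiff(c("A", "C", "G", "T"), g[p]), 1L)
  } else if (!seed_intact) {
    stop("a 0-mismatch site always has an intact seed")
  }
  pam <- if (pam_ok) paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
    else paste0(sample(c("A", "C", "G", "T"), 1L),
                sample(c("A", "C", "T"), 1L), sample(c("A", "C", "T"), 1L))
  paste0(paste(g, collapse = ""), pam)
}

#' Simulate a toy genome with planted features
#'
#' Builds one contig of random sequence (background homopolymer runs capped
#' at 4 bp) and plants, at the stated 1-based positions: guide-like sites
#' (with a prescribed mismatch count, seed status, PAM validity and strand),
#' homopolymer runs (flanked by guard bases so the run length is exact),
#' low-complexity intervals, and variant candidates. Planted features must
#' not overlap. The truth table records, for each variant, which filters it
#' should survive by construction and whether it lies within `flank` bp of a
#' planted qualifying site.
#'
#' @param length Contig length in bp.
#' @param guide A [guide_rna()].
#' @param planted_sites NULL or data.frame with columns `pos` (1-based start
#'   of the protospacer+PAM block), `mismatches`, `seed_intact`, `pam_ok`
#'   (logicals), `strand` (`"+"`/`"-"`).
#' @param homopolymers NULL or data.frame with columns `base`, `run`, `pos`
#'   (1-based start).
#' @param lc_intervals NULL or data.frame with columns `start`, `end`
#'   (0-based half-open, BED convention).
#' @param variants NULL or data.frame with columns `pos` (1-based), `kind`
#'   (`"snv"`/`"del"`/`"ins"`), optional `len` (indel length, default 1),
#'   optional `qual` (default 100), optional `known` (logical; emitted in
#'   the known set instead of marking, default FALSE).
#' @param seed Integer seed.
#' @param chrom Contig name (default `"chrS"`).
#' @param flank Association radius used for the truth table (default 100).
#' @return An object of class `sim_genome`: list with `genome` (named
#'   character), `candidates` and `known` (candidate data.frames),
#'   `intervals` (`GRanges`), `sites` (planted-site table with final
#'   coordinates), `truth` (per-variant expectations) and `chrom`.
#' @export
simulate_genome <- function(length, guide, planted_sites = NULL,
                            homopolymers = NULL, lc_intervals = NULL,
                            variants = NULL, seed, chrom = "chrS",
                            flank = 100L) {
  stopifnot(inherits(guide, "guide_rna"))
  set.seed(as.integer(seed))
  n <- as.integer(length)
  g <- random_background(n)
  L <- guide$length

  occupied <- integer()
  claim <- function(from, to, what) {
    if (from < 1L || to > n) stop("planted ", what, " outside contig")
    span <- from:to
    if (any(span %in% occupied)) stop("planted features overlap at ", what)
    occupied <<- c(occupied, span)
    span
  }

  sites <- NULL
  if (!is.null(planted_sites) && nrow(planted_sites)) {
    sites <- planted_sites
    sites$site_seq <- NA_character_
    for (i in seq_len(nrow(sites))) {
      s <- make_site_seq(guide, sites$mismatches[i], sites$seed_intact[i],
                         sites$pam_ok[i])
      if (sites$strand[i] == "-") s <- revcomp(s)
      span <- claim(sites$pos[i], sites$pos[i] + L + 2L, "guide site")
      g[span] <- seq_chars(s)
      sites$site_seq[i] <- s
    }
    # protospacer window span in forward coordinates (PAM excluded)
    sites$proto_start <- ifelse(sites$strand == "+", sites$pos,
                                sites$pos + 3L)
    sites$proto_end <- sites$proto_start + L - 1L
    sites$qualifies <- sites$pam_ok &
      (sites$mismatches <= 5L | sites$seed_intact)
  }

  if (!is.null(homopolymers) && nrow(homopolymers)) {
    for (i in seq_len(nrow(homopolymers))) {
      b <- homopolymers$base[i]; run <- homopolymers$run[i]
      pos <- homopolymers$pos[i]
      span <- claim(pos - 1L, pos + run, "homopolymer")  # with guard bases
      other <- setdiff(c("A", "C", "G", "T"), b)
      g[pos - 1L] <- sample(other, 1L)
      g[pos:(pos + run - 1L)] <- b
      g[pos + run] <- sample(other, 1L)
    }
  }

  intervals <- NULL
  if (!is.null(lc_intervals) && nrow(lc_intervals)) {
    intervals <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = lc_intervals$start + 1L,
                              end = lc_intervals$end))
  }

  candidates <- variant_candidates(character(), integer(), character(),
                                   character())
  known <- candidates
  truth <- NULL
  if (!is.null(variants) && nrow(variants)) {
    v <- variants
    if (is.null(v$len)) v$len <- 1L
    if (is.null(v$qual)) v$qual <- 100
    if (is.null(v$known)) v$known <- FALSE
    rows <- lapply(seq_len(nrow(v)), function(i) {
      pos <- v$pos[i]
      if (v$kind[i] == "snv") {
        ref <- g[pos]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      } else if (v$kind[i] == "del") {
        ref <- paste(g[pos:(pos + v$len[i])], collapse = "")
        alt <- g[pos]
      } else {
        ref <- g[pos]
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), v$len[i],
                                        replace = TRUE), collapse = ""))
      }
      variant_candidates(chrom, pos, ref, alt, v$qual[i])
    })
    all_rows <- do.call(rbind, rows)
    known <- all_rows[v$known, , drop = FALSE]
    candidates <- all_rows

    ref_end <- all_rows$pos + nchar(all_rows$ref) - 1L
    lc_fail <- if (is.null(intervals)) rep(FALSE, nrow(v)) else
      !filter_low_complexity(all_rows, intervals)
    near_site <- rep(FALSE, nrow(v))
    if (!is.null(sites) && any(sites$qualifies)) {
      qs <- sites[sites$qualifies, , drop = FALSE]
      # the whole protospacer+PAM block must fit in the variant's +-flank
      # window for the scanner to see it
      for (i in seq_len(nrow(v)))
        near_site[i] <- any(qs$pos >= all_rows$pos[i] - flank &
                            qs$pos + L + 2L <= all_rows$pos[i] + flank)
    }
    hp_fail <- rep(FALSE, nrow(v))
    if (!is.null(homopolymers) && nrow(homopolymers)) {
      for (i in seq_len(nrow(v))) {
        hs <- homopolymers$pos; he <- homopolymers$pos + homopolymers$run - 1L
        # the run must lie entirely inside the variant's +-flank window to
        # reach its full planted length there
        inside <- pmax(hs, all_rows$pos[i] - flank)
        outside <- pmin(he, all_rows$pos[i] + flank)
        hp_fail[i] <- any(outside - inside + 1L >= 8L &
                          homopolymers$run >= 8L)
      }
    }
    truth <- data.frame(pos = all_rows$pos, kind = all_rows$kind,
                        expect_pass_quality = v$qual >= 30,
                        expect_pass_known = !v$known,
                        expect_pass_low_complexity = !lc_fail,
                        expect_pass_homopolymer = !hp_fail,
                        expect_site_hit = near_site,
                        stringsAsFactors = FALSE)
    truth$expect_potential_off_target <- truth$expect_pass_quality &
      truth$expect_pass_known & truth$expect_pass_low_complexity &
      truth$expect_pass_homopolymer & truth$expect_site_hit
  }

  genome <- stats::setNames(paste(g, collapse = ""), chrom)
  structure(list(genome = genome, candidates = candidates, known = known,
                 intervals = intervals, sites = sites, truth = truth,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", x$chrom, ": ", nchar(x$genome), " bp, ",
      if (is.null(x$sites)) 0L else nrow(x$sites), " planted sites, ",
      nrow(x$candidates), " variants (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
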