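# Shared fixtures: loci built in code, plus independent oracles used by the
# property tests (a brute-force affine-gap aligner, a Hamming site scanner,
# and the closed-form 2x2 chi-square).

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a 203-bp amplicon with the guide protospacer at offset 60 and an AGG PAM
make_test_locus <- function(spacer = "GGGTGATGACTCTCTTGTCC",
                            guide_name = "guide20", seed = 7,
                            amp_len = 203, proto_at = 60, window = c(4, 8)) {
  g <- becall::guide_rna(guide_name, spacer)
  set.seed(seed)
  bg <- rand_seq(amp_len)
  amp <- paste0(substr(bg, 1, proto_at), g$spacer, "AGG",
                substr(bg, proto_at + g$length + 4, amp_len))
  becall::target_locus("test-locus", amp, proto_at, g, window = window)
}

# mirror locus: same physical molecule given as its reverse complement with
# the protospacer on the minus strand
mirror_locus <- function(locus) {
  amp2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(locus$amplicon)))
  s2 <- nchar(amp2) - locus$protospacer_start - locus$guide$length
  becall::target_locus(paste0(locus$name, "-rc"), amp2, s2, locus$guide,
                       strand = "-", window = locus$window)
}

# amplicon offsets whose guide-sense base is `base` and whose region matches
offsets_with_base <- function(locus, base, region) {
  offs <- seq_len(nchar(locus$amplicon)) - 1L
  rp <- becall::rel_position(locus, offs)
  amp <- strsplit(locus$amplicon, "")[[1]]
  sense <- if (locus$strand == "+") amp else chartr("ACGT", "TGCA", amp)
  offs[sense == base & rp$region %in% region]
}

# apply guide-sense substitutions to the amplicon: df(offset, alt_sense)
mutate_amplicon <- function(locus, offset, alt_sense) {
  ch <- strsplit(locus$amplicon, "")[[1]]
  alt_amp <- if (locus$strand == "+") alt_sense else
    chartr("ACGT", "TGCA", alt_sense)
  ch[offset + 1L] <- alt_amp
  paste(ch, collapse = "")
}

# ---- independent affine-gap alignment oracle --------------------------------
# Exhaustive dynamic programming with the same scoring as the classifier
# (match +1, mismatch -1, a length-k gap costs 5 + k). Enumerates every
# optimal global alignment and returns the set of event lists, each
# left-normalised by an independent re-implementation.

oracle_score <- function(a, b) if (a == b) 1 else -1

oracle_alignments <- function(query, ref, max_paths = 200L) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -5 - i        # gap in ref (insertion)
  for (j in seq_len(m)) Y[1, j + 1] <- -5 - j        # gap in query (deletion)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- oracle_score(q[i], r[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - 6, X[i, j + 1] - 1)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 6, Y[i + 1, j] - 1)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  paths <- list()
  # walk backwards; state in {M, X, Y}; collect (op, i, j) ops
  walk <- function(i, j, state, acc) {
    if (length(paths) >= max_paths) return()
    if (i == 0 && j == 0 && state == "M") {
      paths[[length(paths) + 1L]] <<- rev(acc)
      return()
    }
    if (state == "M") {
      if (i > 0 && j > 0) {
        s <- oracle_score(q[i], r[j])
        target <- M[i + 1, j + 1] - s
        for (prev in c("M", "X", "Y")) {
          val <- switch(prev, M = M[i, j], X = X[i, j], Y = Y[i, j])
          if (val == target)
            walk(i - 1, j - 1, prev,
                 c(acc, list(list(op = if (q[i] == r[j]) "=" else "S",
                                  i = i, j = j))))
        }
      }
    } else if (state == "X") {     # q[i] aligned to a gap: insertion
      if (i > 0) {
        if (j >= 0 && M[i, j + 1] - 6 == X[i + 1, j + 1])
          walk(i - 1, j, "M", c(acc, list(list(op = "I", i = i, j = j))))
        if (X[i, j + 1] - 1 == X[i + 1, j + 1])
          walk(i - 1, j, "X", c(acc, list(list(op = "I", i = i, j = j))))
      }
    } else {                       # Y: r[j] deleted
      if (j > 0) {
        if (M[i + 1, j] - 6 == Y[i + 1, j + 1])
          walk(i, j - 1, "M", c(acc, list(list(op = "D", i = i, j = j))))
        if (Y[i + 1, j] - 1 == Y[i + 1, j + 1])
          walk(i, j - 1, "Y", c(acc, list(list(op = "D", i = i, j = j))))
      }
    }
  }
  for (st in c("M", "X", "Y")) {
    val <- switch(st, M = M[n + 1, m + 1], X = X[n + 1, m + 1],
                  Y = Y[n + 1, m + 1])
    if (val == best) walk(n, m, st, list())
  }
  list(score = best, paths = paths, q = q, r = r)
}

# ops -> raw event data.frame in the package's representation
oracle_events <- function(ops, q, r) {
  ev <- list()
  k <- 1L
  nops <- length(ops)
  while (k <= nops) {
    o <- ops[[k]]
    if (o$op == "=") { k <- k + 1L; next }
    if (o$op == "S") {
      ev[[length(ev) + 1L]] <- data.frame(kind = "substitution",
                                          offset = o$j - 1L, ref = r[o$j],
                                          alt = q[o$i])
      k <- k + 1L
    } else if (o$op == "D") {
      j0 <- o$j
      while (k + 1L <= nops && ops[[k + 1L]]$op == "D") { k <- k + 1L }
      j1 <- ops[[k]]$j
      s <- j0 - 1L; e <- j1 - 1L
      while (s > 0 && r[s] == r[e + 1L]) { s <- s - 1L; e <- e - 1L }
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "deletion", offset = s,
        ref = paste(r[(s + 1L):(s + 1L + j1 - j0)], collapse = ""), alt = "")
      k <- k + 1L
    } else {                       # insertion run
      i0 <- o$i
      while (k + 1L <= nops && ops[[k + 1L]]$op == "I") { k <- k + 1L }
      i1 <- ops[[k]]$i
      ins <- paste(q[i0:i1], collapse = "")
      p <- o$j                    # 0-based ref offset before which inserted
      kk <- nchar(ins)
      while (p > 0 && substr(ins, kk, kk) == r[p]) {
        ins <- paste0(r[p], substr(ins, 1, kk - 1L))
        p <- p - 1L
      }
      ev[[length(ev) + 1L]] <- data.frame(kind = "insertion", offset = p,
                                          ref = "", alt = ins)
      k <- k + 1L
    }
  }
  if (!length(ev))
    return(data.frame(kind = character(), offset = integer(),
                      ref = character(), alt = character()))
  out <- do.call(rbind, ev)
  out <- out[order(out$offset, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

event_sig <- function(ev) paste(ev$kind, ev$offset, ev$ref, ev$alt,
                                sep = ":", collapse = "|")

# ---- independent guide-site scanner oracle ----------------------------------
brute_scan <- function(seq, guide, max_mm = 5, seed_len = 10) {
  L <- nchar(guide$spacer)
  g <- strsplit(guide$spacer, "")[[1]]
  hits <- list()
  test_strand <- function(s, strand, n) {
    ch <- strsplit(s, "")[[1]]
    for (j in seq_len(length(ch) - L - 2L)) {
      win <- ch[j:(j + L - 1L)]
      pam <- ch[(j + L):(j + L + 2L)]
      if (!(pam[2] == "G" && pam[3] == "G")) next
      mm <- sum(win != g)
      seed_ok <- all(win[(L - seed_len + 1L):L] == g[(L - seed_len + 1L):L])
      if (mm <= max_mm || seed_ok) {
        start0 <- if (strand == "+") j - 1L else n - (j - 1L) - L
        hits[[length(hits) + 1L]] <<- data.frame(
          start = start0, strand = strand, mismatches = mm,
          rule = if (mm <= max_mm) "full_mismatch_budget" else "seed_10nt")
      }
    }
  }
  n <- nchar(seq)
  test_strand(seq, "+", n)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  test_strand(rc, "-", n)
  if (!length(hits))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer(), rule = character()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- closed-form chi-square oracle ------------------------------------------
chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# ---- lightweight fake allele calls for genotype-rule tests ------------------
fake_call <- function(key, class = if (key == "WT") "wild_type" else "edited",
                      categories = character(), kinds = NULL) {
  if (is.null(kinds))
    kinds <- ifelse(categories == "indel", "deletion", "substitution")
  k <- length(categories)
  ev <- data.frame(kind = as.character(kinds), offset = seq_len(k),
                   ref = rep("C", k), alt = rep("T", k), rel = seq_len(k),
                   region = rep("window", k),
                   category = factor(categories,
                                     levels = becall:::EVENT_CATEGORIES),
                   strand_call = rep("non_target", k),
                   canonical = rep(TRUE, k),
                   stringsAsFactors = FALSE)
  structure(list(clone_id = "x", events = ev, allele_class = class,
                 pattern_key = key, identity = 1),
            class = "allele_call")
}

# embryo built from pattern spec: list of (key, count, categories)
fake_embryo <- function(spec, id = "e") {
  calls <- list()
  for (s in spec) {
    for (i in seq_len(s$count)) {
      calls[[length(calls) + 1L]] <-
        fake_call(s$key, class = s$class %||% if (s$key == "WT")
          "wild_type" else "edited",
          categories = s$categories %||% if (s$key == "WT")
            character() else "window_deamination")
    }
  }
  becall::genotype_embryo(calls, embryo_id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
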