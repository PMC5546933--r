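test_that("quality, known and low-complexity filters apply their boundary rules", {
  cand <- variant_candidates(rep("c1", 4), c(100L, 150L, 200L, 250L),
                             c("A", "C", "G", "T"), c("G", "T", "A", "C"),
                             qual = c(50, 10, 30, NA))
  expect_warning(pass <- filter_quality(cand), "missing QUAL")
  expect_identical(pass, c(TRUE, FALSE, TRUE, TRUE))   # boundary qual==min passes

  known <- variant_candidates("c1", c(100L, 150L), c("A", "C"), c("G", "A"))
  expect_identical(filter_known(cand, known),
                   c(FALSE, TRUE, TRUE, TRUE))          # same pos, other alt passes
  expect_identical(filter_known(cand, known, mode = "position"),
                   c(FALSE, FALSE, TRUE, TRUE))

  # interval [100, 200) in BED coordinates = 1-based positions 101..200
  iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))
  expect_identical(filter_low_complexity(cand, iv),
                   c(TRUE, FALSE, FALSE, TRUE))
  # half-open boundary: the first base past the interval passes
  expect_true(filter_low_complexity(
    variant_candidates("c1", 201L, "A", "G"), iv))
  # a deletion straddling the interval edge fails
  expect_false(filter_low_complexity(
    variant_candidates("c1", 198L, "AAAAA", "A"), iv))
})

test_that("the flank homopolymer filter counts runs inside the window only", {
  mk_genome <- function(core) c(c1 = paste0(
    paste(rep(c("A", "C", "G", "T"), 30), collapse = ""), core,
    paste(rep(c("T", "G", "C", "A"), 30), collapse = "")))
  # 8-bp run 50 bp from the variant fails; 7-bp passes
  g8 <- mk_genome(paste0(strrep("A", 8), strrep("CT", 40)))
  g7 <- mk_genome(paste0(strrep("A", 7), strrep("CT", 40)))
  v <- variant_candidates("c1", 170L, "C", "G")
  expect_false(filter_flank_homopolymer(v, g8))
  expect_true(filter_flank_homopolymer(v, g7))
  # a run of 8 with only 6 bases inside the +-radius window passes
  ge <- c(c1 = paste0(strrep("A", 8), strrep("CT", 100)))
  v_edge <- variant_candidates("c1", 103L, "C", "T")  # window starts at base 3
  expect_true(filter_flank_homopolymer(v_edge, ge))
  expect_false(filter_flank_homopolymer(
    variant_candidates("c1", 100L, "C", "T"), ge))    # all 8 bases inside
  expect_error(filter_flank_homopolymer(
    variant_candidates("c1", 10000L, "A", "C"), g8), "beyond contig")
})

test_that("guide-site scanning applies the mismatch, seed and PAM rules", {
  g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
  pad <- strrep("T", 30)
  exact <- paste0(pad, g$spacer, "AGG", pad)
  hit <- scan_guide_sites(exact, 0L, g)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 30L)
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$rule, "full_mismatch_budget")
  expect_identical(hit$pam, "AGG")

  # 6 mismatches confined to the 5' half, perfect 3' seed, TGG PAM
  sp <- strsplit(g$spacer, "")[[1]]
  sp[1:6] <- c("T", "A", "T", "C", "A", "T")
  stopifnot(sum(sp != strsplit(g$spacer, "")[[1]]) == 6)
  seed_only <- paste0(pad, paste(sp, collapse = ""), "TGG", pad)
  hit2 <- scan_guide_sites(seed_only, 0L, g)
  expect_identical(hit2$rule, "seed_10nt")
  expect_identical(hit2$mismatches, 6L)

  # 5 mismatches but no NGG PAM: rejected
  sp5 <- strsplit(g$spacer, "")[[1]]
  sp5[2:6] <- c("A", "T", "C", "A", "T")
  no_pam <- paste0(pad, paste(sp5, collapse = ""), "ATT", pad)
  expect_identical(nrow(scan_guide_sites(no_pam, 0L, g)), 0L)

  # flank shorter than guide + PAM: empty result
  expect_identical(nrow(scan_guide_sites("ACGT", 0L, g)), 0L)

  # when both rules fire the mismatch-budget rule is recorded
  one_mm <- sp5 <- strsplit(g$spacer, "")[[1]]
  one_mm[3] <- "T"
  hit3 <- scan_guide_sites(paste0(pad, paste(one_mm, collapse = ""), "CGG"),
                           0L, g)
  expect_identical(hit3$rule, "full_mismatch_budget")
  expect_identical(hit3$mismatches, 1L)
})

test_that("the scanner agrees with a brute-force Hamming oracle on planted genomes", {
  g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
  sites <- data.frame(
    pos = seq(200, 4400, by = 300),
    mismatches = c(0, 1, 2, 3, 4, 5, 6, 7, 6, 5, 3, 0, 2, 7, 4),
    seed_intact = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                    FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    pam_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    strand = rep(c("+", "-", "+"), 5))
  sim <- simulate_genome(5000, g, planted_sites = sites, seed = 99)
  seq <- sim$genome[[1]]
  got <- scan_guide_sites(seq, 0L, g)
  want <- brute_scan(seq, g)
  expect_identical(got$start, want$start)
  expect_identical(got$strand, want$strand)
  expect_identical(got$mismatches, as.integer(want$mismatches))
  expect_identical(got$rule, want$rule)
  # planted-truth recovery: every qualifying planted site is found,
  # no decoy (PAM-violating or >5 mm with broken seed) is reported
  found_at <- got$start
  qs <- sim$sites
  proto0 <- ifelse(qs$strand == "+", qs$pos - 1L, qs$pos + 2L)
  expect_true(all(proto0[qs$qualifies] %in% found_at))
  expect_false(any(proto0[!qs$qualifies] %in% found_at))
})

test_that("scanning is symmetric under reverse complement", {
  g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
  sim <- simulate_genome(2000, g, planted_sites = data.frame(
    pos = c(300, 900, 1500), mismatches = c(0, 2, 4),
    seed_intact = TRUE, pam_ok = TRUE, strand = c("+", "-", "+")),
    seed = 12)
  seq <- sim$genome[[1]]
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  a <- scan_guide_sites(seq, 0L, g)
  b <- scan_guide_sites(rc, 0L, g)
  # mirrored coordinates and flipped strands
  b$mirror_start <- n - b$start - g$length
  b <- b[order(b$mirror_start), ]
  a <- a[order(a$start), ]
  expect_identical(a$start, b$mirror_start)
  expect_identical(a$mismatches, b$mismatches)
  expect_setequal(paste(a$start, chartr("+-", "-+", a$strand)),
                  paste(b$mirror_start, b$strand))
})

test_that("triage combines independent filters and associates sites", {
  g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
  sim <- simulate_genome(6000, g,
    planted_sites = data.frame(pos = 1000, mismatches = 3,
                               seed_intact = FALSE, pam_ok = TRUE,
                               strand = "+"),
    homopolymers = data.frame(base = "A", run = 9, pos = 2500),
    lc_intervals = data.frame(start = 3500, end = 3700),
    variants = data.frame(
      pos = c(1020, 2520, 3600, 4500, 5000, 5200),
      kind = c("snv", "snv", "del", "snv", "snv", "snv"),
      len = c(1, 1, 3, 1, 1, 1),
      qual = c(100, 100, 100, 10, 100, 100),
      known = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    seed = 7)
  rep <- triage(sim$candidates, sim$genome, g, known = sim$known,
                intervals = sim$intervals)
  cand <- rep$candidates
  expect_identical(cand$status,
                   c("potential_off_target",  # near the planted site
                     "removed",               # homopolymer flank
                     "removed",               # low-complexity overlap
                     "removed",               # low quality
                     "removed",               # known variant
                     "background"))           # survives, no site
  expect_identical(unname(rep$summary["potential_off_target"]), 1L)
  expect_identical(sim$truth$expect_potential_off_target,
                   cand$status == "potential_off_target")
  # verdicts match the generator's truth per filter
  expect_identical(cand$pass_quality, sim$truth$expect_pass_quality)
  expect_identical(cand$pass_known, sim$truth$expect_pass_known)
  expect_identical(cand$pass_low_complexity,
                   sim$truth$expect_pass_low_complexity)
  expect_identical(cand$pass_homopolymer, sim$truth$expect_pass_homopolymer)
  expect_identical(rep$site_hits$candidate, 1L)
  expect_lte(rep$site_hits$distance_to_variant, 100L)
  expect_error(triage(variant_candidates("chrZ", 5L, "A", "C"),
                      sim$genome, g), "absent from genome")
})

test_that("an empty or fully filtered candidate list reports the clean outcome", {
  g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
  sim <- simulate_genome(2000, g, seed = 3)
  rep0 <- triage(sim$candidates, sim$genome, g)
  expect_identical(unname(rep0$summary["n_candidates"]), 0L)
  expect_identical(rep0$outcome, "no potential off-target site indel or SNV")
})
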