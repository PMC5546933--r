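---
title: "Classifying cytidine base-editing outcomes and triaging off-target variants"
author: "becall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cytidine base-editing outcomes and triaging off-target variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(becall)
```

## The analysis problem

Cytidine base editors (a cytidine deaminase fused to a dead or nicking Cas9
plus a uracil-glycosylase inhibitor) convert C to U at guide-RNA-directed
sites; after replication the edit reads as C-to-T. In zygote-injection
experiments the read-out is Sanger sequencing of subcloned PCR amplicons:
each bacterial subclone is one allele molecule, and a pool of 10-15
subclones per embryo samples the embryo's allele population. `becall`
implements the downstream computation for such experiments:

1. **Allele calling** -- align each subclone to the reference amplicon and
   extract substitution/indel events;
2. **Event classification** -- place every deamination-consistent event in
   the editing geometry (canonical window, elsewhere in the protospacer,
   or *proximal*: upstream, PAM, downstream) and call the edited strand;
3. **Embryo genotyping** -- aggregate clone patterns into wild-type /
   heterozygous / biallelic / homozygous / mosaic classes;
4. **Cohort statistics** -- per-group mutant and proximal-deamination
   percentages and pairwise Pearson chi-square comparisons;
5. **Off-target variant triage** -- filter a whole-genome-sequencing
   variant list (quality, known variants, low-complexity overlap, flank
   homopolymers) and associate survivors with nearby guide-like sites;
6. **Synthetic data** -- generators for clone pools and toy genomes, so
   every stage is testable without external data.

## Coordinate model

All positions are protospacer-relative: position 1 is the 5'-most
(PAM-distal) base of the protospacer on the non-target strand, the PAM
occupies positions `L+1 .. L+3` for a guide of length `L`, upstream bases
are negative (no position 0, so "-38" means 38 bp upstream, matching how
such distances are usually quoted). The canonical deamination window
defaults to positions 4-8, where cytidine deaminase activity concentrates.
For truncated guides (16 or 17 nt) position 1 stays at the guide's 5' end,
the PAM starts at `length+1`, and the window default is unchanged -- the
truncation removes PAM-distal bases, not window bases. Internally all
file-facing coordinates are 0-based half-open; VCF I/O is 1-based.

```{r}
g <- guide_rna("demo-guide", "GGGTGATGACTCTCTTGTCC")
set.seed(101)
bg <- paste(sample(c("A", "C", "G", "T"), 203, TRUE), collapse = "")
amp <- paste0(substr(bg, 1, 60), g$spacer, "AGG", substr(bg, 84, 203))
loc <- target_locus("demo-locus", amp, protospacer_start = 60, guide = g)
rel_position(loc, c(60L, 64L, 80L, 22L))
```

## Allele calling and event classification

Clones are aligned globally (Needleman-Wunsch via Biostrings) with match
+1, mismatch -1, gap open -5, gap extend -1. Subclones are near-identical
to the reference, so the heavy gap-opening penalty suppresses spurious
indels; indel events are merged and left-normalised to the smallest
amplicon offset (the VCF convention), which also fixes placement inside
repeats. Ns (Sanger ambiguity) are masked and never called. Clones whose
alignment identity falls below 60% (configurable) are excluded with a
warning rather than force-fit.

Classification rules, applied to events expressed in non-target-strand
sense:

* `C>T` is canonical deamination on the non-target strand; `G>A` is
  canonical deamination of the target-strand cytidine (`strand_call =
  "target"`); `C>G/A` and `G>T/C` are the rarer non-canonical outcomes of
  the same deaminations (`canonical = FALSE`).
* Deamination-consistent events are then categorised **by position**:
  `window_deamination` inside the canonical window, `on_target_deamination`
  elsewhere in the protospacer, `proximal_site_deamination` outside it
  (upstream, PAM, or downstream -- proximal edits have been observed ~40 bp
  from the site, so the scan covers the whole amplicon with no distance
  cutoff).
* Everything else is `other_substitution`; insertions/deletions are
  `indel`.

An allele is `wild_type` with no events, `indel_allele` with any indel,
else `edited`. Identical event lists share a `pattern_key`, the unit in
which clones are tallied.

```{r}
clone <- amp
substr(clone, 65, 65) <- "A"            # G>A at protospacer position 5
call_allele(loc, "clone1", clone)$events[, c("rel", "region", "ref", "alt",
                                             "category", "strand_call")]
```

## Genotyping and cohort statistics

Patterns with clone support below `min_support` (default 1 clone) are
dropped; the remaining patterns determine the genotype: all wild type ->
`wild_type`; wild type + one edited pattern -> `heterozygous`; wild type +
several -> `mosaic`; no wild type and one / two / more edited patterns ->
`homozygous` / `biallelic` / `mosaic`. An embryo is *mutant* with at least
one supported edited pattern; by default an embryo whose only edit is an
indel still counts as mutant (`indel_only_is_mutant` switches this off; in
practice indel alleles carry substitutions too, so the switch rarely
matters). An embryo is counted as proximally deaminated when a supported
pattern carries a proximal event -- since a proximal edit is an edit, every
proximally deaminated embryo is mutant, which keeps the two reported ratios
(proximal/mutant and proximal/total) consistent by construction.

Group summaries report percentages rounded half-even to one decimal
(`round()`'s behaviour), which reproduces published cohort tables of this
design exactly from their integer counts. The proximal/mutant ratio is
undefined (NA) for groups without mutants. Group comparisons use Pearson's
chi-square on 2x2 tables, **without** continuity correction, df = 1. The
uncorrected statistic reproduces the expected significance pattern
(non-significant proximal-ratio differences, strongly significant
mutant-rate differences); published work of this kind rarely states which
variant was used, so the choice is documented here and the statistic is
cross-checked in the tests against both the closed form
$n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))$ and `chisq.test(correct = FALSE)`.

Founder-pup summaries follow the same genotype rules; coat colour is input
metadata, never inferred. Percentages over pups use the *genotyped*
denominator (litters can lose pups before genotyping), survival uses the
injected denominator, and birth rate the transferred denominator.

## Off-target variant triage

The triage stage starts from a called variant list (VCF) -- alignment,
deduplication and variant calling are upstream tools' business. Four
per-candidate filters are evaluated independently (so verdicts are
order-free and all are reported):

* **quality**: QUAL below `min_qual` (default 30; thresholds of this kind
  are typically unstated, so it is explicit configuration here). Boundary
  passes; missing QUAL passes with a warning.
* **known variant**: exact chrom/pos/ref/alt match against a dbSNP-style
  VCF (position-only mode available).
* **low complexity**: the variant's reference span intersects a
  RepeatMasker-style BED interval. BED is 0-based half-open on disk and
  1-based closed in memory (GRanges); touching intervals are merged, which
  only affects reporting granularity, never overlap verdicts.
* **flank homopolymer**: a single-base run of 8 or more (">7 bp") within
  +-100 bp of the variant position. The window is clipped at contig ends
  and runs are counted inside the window only -- bases outside it do not
  extend a run.

Survivors' +-100 bp flanks are then scanned exhaustively on both strands
for guide-like sites: every protospacer-length window immediately followed
(3', same strand) by an NGG PAM is accepted with at most 5 mismatches
against the spacer **or** a perfect match of the guide's 3'-most 10 nt (the
seed, PAM-proximal). The published procedure used a short-read aligner for
this search; at +-100 bp per candidate an exhaustive scan is feasible and
has no heuristic misses, so that is what is implemented -- the acceptance
rules are identical. When both rules fire, the mismatch-budget rule is
recorded; the mismatch count is always reported. A filter-surviving
candidate with at least one site hit is a *potential off-target-associated
variant*; with none, background. A clean run reports the outcome string
"no potential off-target site indel or SNV".

Design notes: PAM N is any base and must be immediately adjacent (no gap);
for truncated guides the seed stays the 3' 10 nt; the variant anchor for
flank extraction is the VCF POS base, and indels use the full reference
span for overlap tests.

## The synthetic-data generator

`simulate_cohort()` emulates the experiment that produced the clone pools.
Editing acts per **allele lineage** (2 lineages = editing at the one-cell
stage; 4 emulates post-division editing, the interpretation of coat-colour
mosaics), never per clone; clones then sample lineages uniformly with
replacement. Each guide-sense C is deaminated independently with a
positional probability; each amplicon G is a target-strand C and uses the
same rate times `p_target_strand_factor`. Defaults, chosen once as a
realistic study condition and not tuned afterwards:

| parameter | default | rationale |
|---|---|---|
| `p_window` | 0.2 per C per allele | gives per-embryo mutant fractions ~1-(1-q)^2 in the range reported for efficient full-length guides (~40%) |
| `p_protospacer_out` | 0.02 | on-target but out-of-window edits are rare |
| `p_proximal_max`, scale, range | 0.01, 20 bp, 100 bp | exponential decay is an invention for test realism; no analysis stage depends on its form. The peak keeps proximally deaminated embryos a minority of mutants, as observed |
| `outcome_probs` | T/G/A = 0.8/0.1/0.1 | C>T dominates; C>G/A are the rarer outcomes |
| `p_target_strand_factor` | 0.5 | target-strand conversion is seen "to a lesser extent" |
| `p_indel` | 0.02 per allele | indels appeared in 2 of 44 edited embryos |
| `clones_per_embryo` | 15 | typical subclone count per pool |

Planted indels are left-normalised with the same convention the caller
uses, and substitutions falling inside an indel's placement-ambiguity
corridor (the repeat context across which an equal-scoring alignment could
shift) are dropped from the allele, so that noise-free simulations admit
exactly one optimal interpretation and truth comparison can demand
equality, not similarity. What the generator deliberately does **not**
model: chromatogram noise, PCR/cloning bias between alleles, large
rearrangements, and real-genome base composition. Passing round-trip tests
therefore demonstrates the correctness of the calling logic, not robustness
to real Sanger artefacts; clone-level uniform base noise is available
(`noise_rate`) for exercising the `min_support` path.

`simulate_genome()` builds one contig of random background whose
homopolymer runs are capped at 4 bp, then plants guide-like sites with a
prescribed mismatch count/seed status/PAM validity/strand, homopolymer runs
of exact length (guard bases prevent accidental extension), low-complexity
intervals and variant candidates, and emits a per-variant truth table of
expected filter verdicts and site associations. The truth table demands
that the whole protospacer+PAM block fit inside a variant's +-flank window,
matching what the scanner can see.

## Numerical choices and degenerate inputs

* Rounding of reported percentages: half-even to 1 decimal; zero
  denominators give NA (printed blank).
* Chi-square requires positive margins; degenerate tables raise an error
  (pairwise tables involving empty groups propagate NA).
* Alignment ties: substitutions are preferred over gaps by the gap-open
  penalty; equal-scoring gap placements are resolved leftmost.
* `min_support` may be a count or a fraction of the pool; if it would
  eliminate every pattern, the modal pattern is kept so a genotype is
  always produced.
* Empty candidate lists, empty groups and empty FASTA records are
  explicit, tested cases.
* Fixed seeds make both generators byte-deterministic.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on synthetic
data: cohorts of 12-67 embryos (6-15 clones each), 5-8 kb planted genomes,
exhaustive chi-square verification over all 2x2 tables with cells at most
30, and 20 replicates of 400 embryos for the mutant-fraction recovery
check. These sizes give exact or tight stochastic checks with the whole
suite completing in a few minutes on one core.

## Known limitations

* Direct Sanger traces (double peaks) and `.ab1` files are out of scope;
  the input is one sequence per subclone.
* The triage stage associates variants with guide-like sites in their
  flanks; it does not enumerate genome-wide off-target sites, and it
  starts from a VCF -- variant calling quality is inherited, not assessed.
* Whether a "gRNA target site" distance quoted in the literature includes
  the PAM is ambiguous; both conventions are representable through
  `rel_position()` (PAM positions are distinct from downstream ones) and
  none is hard-coded.
* The per-position editing model is independent across positions; real
  deamination may be processive, so simulated pattern diversity is an
  approximation.
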