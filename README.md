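# becall

Base-editing allele classification, embryo genotyping, and off-target
variant triage.

## What it is for

Cytidine base editors (rAPOBEC1 fused to a dead or nicking Cas9, plus a
uracil-glycosylase inhibitor) convert C→T inside a deamination window
(protospacer positions 4–8) at guide-RNA-directed sites. In zygote editing
experiments the read-out is Sanger sequencing of subcloned PCR amplicons —
each subclone is one allele molecule — and, for specificity, whole-genome
sequencing of edited embryos. `becall` implements the computational side of
such studies for R users:

* **Allele calling**: global alignment of each subclone against the
  reference amplicon; substitutions and left-normalised indels as events in
  protospacer-relative coordinates (position 1 = PAM-distal 5′ end, PAM at
  `L+1..L+3`, negative = upstream).
* **Event classification**: canonical window deamination, on-target
  (in-protospacer) deamination, **proximal-site deamination** (deamination-
  consistent edits outside the protospacer — upstream, PAM or downstream),
  non-canonical outcomes (C→G/A), target-strand calls (G→A in protospacer
  sense), other substitutions, indels.
* **Genotyping and cohort statistics**: wild-type / heterozygous /
  biallelic / homozygous / mosaic embryos from clone-pattern tallies; group
  summaries (mutant %, proximal/mutant %, proximal/total %, half-even
  rounding to 1 decimal); founder-pup summaries; pairwise Pearson χ²
  (no continuity correction), `X² = n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`.
* **WGS off-target triage**: quality, known-variant, low-complexity (BED)
  and flank-homopolymer (run > 7 bp within ±100 bp) filters, then an
  exhaustive both-strand scan of each survivor's ±100 bp flank for
  guide-like sites with ≤5 mismatches **or** a perfect 3′ 10-nt seed,
  requiring an adjacent NGG PAM.
* **Synthetic data**: a per-position stochastic editing model generating
  clone pools with known truth, and toy genomes with planted guide sites,
  homopolymers, low-complexity intervals and variant candidates.

## Worked example

A small simulated cohort (8 embryos, 15 subclones each) ships with the
package:

```r
library(becall)
demo <- system.file("extdata/demo/config.yaml", package = "becall")
rep <- run_pipeline(demo)
print(rep$groups, row.names = FALSE)
#>       group n_total n_mutant n_proximal pct_mutant ratio_proximal_mutant
#>  demo-group       8        7          3       87.5                  42.9
#>  ratio_proximal_total
#>                  37.5
```

Seven of the eight embryos carry at least one supported edited pattern
(87.5% mutant); three of those seven also carry a deamination-consistent
edit outside the protospacer (42.9% of mutants, 37.5% of all embryos).
Per-embryo calls show the genotype classes:

```r
rep$embryos[, c("embryo_id", "genotype_class", "has_proximal")]
#>  embryo_id genotype_class has_proximal
#>  embryo001   heterozygous        FALSE
#>  embryo002      biallelic         TRUE
#>  ...
```

Off-target triage on a toy genome with one planted near-match site (3
mismatches, NGG PAM), one 9-bp homopolymer, and three candidate variants:

```r
g <- guide_rna("g", "ACGTTGCAGGATCCATTGCA")
sim <- simulate_genome(6000, g,
  planted_sites = data.frame(pos = 1000, mismatches = 3,
                             seed_intact = FALSE, pam_ok = TRUE,
                             strand = "+"),
  homopolymers = data.frame(base = "A", run = 9, pos = 2500),
  variants = data.frame(pos = c(1020, 2520, 4000), kind = "snv"),
  seed = 7)
triage(sim$candidates, sim$genome, g)
#> <triage_report>
#>   candidates: 3  surviving: 2  potential off-target: 1
#>   fails - quality: 0  known: 0  low-complexity: 0  homopolymer: 1
#>   outcome: 1 potential off-target-associated variant(s)
```

The variant 20 bp from the planted site is flagged as a potential
off-target-associated variant; the one next to the homopolymer run is
removed; the background variant survives but is unassociated. A run with
every candidate removed or unassociated reports
`no potential off-target site indel or SNV`.

A thin CLI wraps the same functions
(`Rscript inst/cli/becall.R summarize --config <yaml>`, plus `classify`,
`triage` and `simulate` subcommands).

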