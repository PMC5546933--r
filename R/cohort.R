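# Embryo genotyping from clone pools and experimental-group summaries.

GENOTYPE_CLASSES <- c("wild_type", "heterozygous", "biallelic", "homozygous",
                      "mosaic")

# shared rule: genotype class from supported pattern keys
# n_wt: wild-type pattern supported? n_edited: number of distinct supported
# non-wild-type patterns.
genotype_from_patterns <- function(wt_supported, n_edited) {
  if (n_edited == 0L) return("wild_type")
  if (wt_supported) {
    if (n_edited == 1L) "heterozygous" else "mosaic"
  } else {
    if (n_edited == 1L) "homozygous"
    else if (n_edited == 2L) "biallelic"
    else "mosaic"
  }
}

#' Genotype one embryo from its clone calls
#'
#' Tallies clones per sequence pattern, drops patterns below the support
#' threshold, and assigns the genotype class: all wild type -> `wild_type`;
#' wild type plus one edited pattern -> `heterozygous`; wild type plus two or
#' more -> `mosaic`; no wild type and exactly one edited pattern ->
#' `homozygous`; no wild type and two edited patterns -> `biallelic`; more
#' than two -> `mosaic`.
#'
#' @param clone_calls List of `allele_call` objects for one embryo (from
#'   [classify_pool()]).
#' @param embryo_id Embryo identifier.
#' @param min_support Minimum clone support for a pattern to count; an
#'   integer count, or a fraction (< 1) of the number of clones. Default 1.
#' @param indel_only_is_mutant Should an embryo whose only edited patterns
#'   are pure indel alleles count as mutant? Default TRUE.
#' @return An object of class `embryo_genotype`: embryo id, pattern tallies,
#'   genotype class, and flags `is_mutant`, `is_biallelic`, `has_proximal`
#'   (some supported pattern carries a proximal-site deamination event) and
#'   `has_indel`.
#' @export
genotype_embryo <- function(clone_calls, embryo_id = "embryo",
                            min_support = 1, indel_only_is_mutant = TRUE) {
  if (!length(clone_calls))
    input_error("no clone calls supplied for embryo ", embryo_id)
  keys <- vapply(clone_calls, function(x) x$pattern_key, character(1))
  tab <- table(keys)
  thr <- if (min_support < 1) min_support * length(clone_calls) else min_support
  supported <- names(tab)[tab >= thr]
  if (!length(supported))
    supported <- names(tab)[tab == max(tab)]   # degenerate threshold: keep modal

  rep_call <- function(key) clone_calls[[match(key, keys)]]
  edited_keys <- setdiff(supported, "WT")
  wt_supported <- "WT" %in% supported

  has_indel <- any(vapply(edited_keys, function(k)
    rep_call(k)$allele_class == "indel_allele", logical(1)))
  has_sub <- function(k) any(rep_call(k)$events$kind == "substitution")
  mutant_keys <- if (indel_only_is_mutant) edited_keys
    else Filter(has_sub, edited_keys)
  has_proximal <- any(vapply(edited_keys, function(k)
    any(rep_call(k)$events$category == "proximal_site_deamination"),
    logical(1)))

  gclass <- genotype_from_patterns(wt_supported, length(edited_keys))
  structure(list(embryo_id = embryo_id,
                 clone_calls = clone_calls,
                 distinct_patterns = tab,
                 supported_patterns = supported,
                 genotype_class = gclass,
                 is_mutant = length(mutant_keys) > 0L,
                 is_biallelic = !wt_supported && length(edited_keys) > 0L,
                 has_proximal = has_proximal,
                 has_indel = has_indel),
            class = "embryo_genotype")
}

#' @export
print.embryo_genotype <- function(x, ...) {
  cat("<embryo_genotype> ", x$embryo_id, ": ", x$genotype_class,
      if (x$is_mutant) " (mutant)" else "",
      if (x$has_proximal) " +proximal" else "",
      if (x$has_indel) " +indel" else "", "\n", sep = "")
  np <- length(x$distinct_patterns)
  cat("  ", sum(x$distinct_patterns), " clones, ", np, " pattern",
      if (np != 1) "s", "\n", sep = "")
  invisible(x)
}

#' Summarise an experimental group of embryos
#'
#' Computes the group counts and the three reported percentages: mutant
#' embryos over total, proximally deaminated embryos over mutant embryos, and
#' proximally deaminated over total. Percentages are rounded (half-even) to
#' one decimal; the proximal/mutant ratio is NA when there are no mutants.
#'
#' @param group_name Group label.
#' @param genotypes List of `embryo_genotype` objects (may be empty).
#' @return A one-row data.frame of class `group_summary` with columns
#'   `group`, `n_total`, `n_mutant`, `n_proximal`, `pct_mutant`,
#'   `ratio_proximal_mutant`, `ratio_proximal_total`.
#' @examples
#' # 67 embryos of which 26 mutant, 15 proximally deaminated
#' # -> 38.8 / 57.7 / 22.4
#' @export
summarize_group <- function(group_name, genotypes) {
  stopifnot(all(vapply(genotypes, inherits, logical(1), "embryo_genotype")))
  n_total <- length(genotypes)
  n_mutant <- sum(vapply(genotypes, function(g) g$is_mutant, logical(1)))
  n_proximal <- sum(vapply(genotypes, function(g)
    g$is_mutant && g$has_proximal, logical(1)))
  out <- data.frame(group = group_name, n_total = n_total,
                    n_mutant = n_mutant, n_proximal = n_proximal,
                    pct_mutant = pct1(n_mutant, n_total),
                    ratio_proximal_mutant = pct1(n_proximal, n_mutant),
                    ratio_proximal_total = pct1(n_proximal, n_total),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", class(out))
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square statistic without continuity correction, df = 1,
#' with the p-value from the upper tail of the chi-square distribution.
#' The table is
#' \preformatted{  a  b
#'   c  d}
#' All arguments are vectorised.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return A data.frame with columns `statistic` and `p_value`.
#' @examples
#' chi2_2x2(10, 10, 10, 10)  # statistic 0, p 1
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0))
    stop("degenerate margin: every row and column total must be positive")
  # Pearson X^2 = sum (O - E)^2 / E with E from the margins
  e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  stat <- rowSums((counts - e)^2 / e)
  data.frame(statistic = unname(stat),
             p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

#' Pairwise chi-square comparisons between group summaries
#'
#' For every pair of groups, tests either the mutant/non-mutant composition
#' (`what = "mutant"`) or the proximal/non-proximal composition among mutant
#' embryos (`what = "proximal_of_mutant"`).
#'
#' @param summaries A data.frame of group summaries (rows from
#'   [summarize_group()], rbind-ed).
#' @param what Which composition to compare.
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `p_value`.
#' @export
chi2_pairwise <- function(summaries,
                          what = c("mutant", "proximal_of_mutant")) {
  what <- match.arg(what)
  k <- nrow(summaries)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    s1 <- summaries[ij[1], ]; s2 <- summaries[ij[2], ]
    if (what == "mutant") {
      t1 <- c(s1$n_mutant, s1$n_total - s1$n_mutant)
      t2 <- c(s2$n_mutant, s2$n_total - s2$n_mutant)
    } else {
      t1 <- c(s1$n_proximal, s1$n_mutant - s1$n_proximal)
      t2 <- c(s2$n_proximal, s2$n_mutant - s2$n_proximal)
    }
    res <- tryCatch(chi2_2x2(t1[1], t1[2], t2[1], t2[2]),
                    error = function(e)
                      data.frame(statistic = NA_real_, p_value = NA_real_))
    data.frame(group1 = s1$group, group2 = s2$group,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a founder-pup group
#'
#' Computes litter-level percentages: embryo survival (survived/injected),
#' birth rate (pups born/transferred), and the genotype percentages over
#' genotyped pups (albino, coat mosaic, mutant black, mutant, biallelic
#' mutant). Pups lost before genotyping (e.g. cannibalised) are counted in
#' `n_born` but not in the genotype denominators. Percentages are rounded to
#' one decimal and NA on zero denominators.
#'
#' @param group_name Group label.
#' @param n_injected,n_survived,n_transferred,n_born Embryo/litter counts.
#' @param pups A data.frame of genotyped pups with columns `is_mutant`,
#'   `is_biallelic` (logical) and `coat`
#'   (`"black"`/`"albino"`/`"mosaic"`), or NULL when no pups were genotyped.
#' @return A one-row data.frame of class `pup_summary`.
#' @examples
#' # 7/11 mutants (63.6%), 3/11 biallelic (27.3%)
#' @export
summarize_pups <- function(group_name, n_injected, n_survived, n_transferred,
                           n_born = NULL, pups = NULL) {
  n_geno <- if (is.null(pups)) 0L else nrow(pups)
  if (is.null(n_born)) n_born <- n_geno
  if (n_geno) {
    stopifnot(all(c("is_mutant", "is_biallelic", "coat") %in% names(pups)))
    n_mutant <- sum(pups$is_mutant)
    n_biallelic <- sum(pups$is_biallelic)
    n_albino <- sum(pups$coat == "albino")
    n_mosaic <- sum(pups$coat == "mosaic")
    n_mutant_black <- sum(pups$is_mutant & pups$coat == "black")
  } else {
    n_mutant <- n_biallelic <- n_albino <- n_mosaic <- n_mutant_black <- 0L
  }
  out <- data.frame(group = group_name,
                    n_injected = n_injected, n_survived = n_survived,
                    n_transferred = n_transferred, n_born = n_born,
                    n_genotyped = n_geno,
                    n_albino = n_albino, n_mosaic_coat = n_mosaic,
                    n_mutant_black = n_mutant_black,
                    n_mutant = n_mutant, n_biallelic = n_biallelic,
                    pct_survived = pct1(n_survived, n_injected),
                    pct_born = pct1(n_born, n_transferred),
                    pct_albino = pct1(n_albino, n_geno),
                    pct_mosaic_coat = pct1(n_mosaic, n_geno),
                    pct_mutant_black = pct1(n_mutant_black, n_geno),
                    pct_mutant = pct1(n_mutant, n_geno),
                    pct_biallelic = pct1(n_biallelic, n_geno),
                    stringsAsFactors = FALSE)
  class(out) <- c("pup_summary", class(out))
  out
}
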