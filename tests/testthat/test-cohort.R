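test_that("genotype classes follow the pattern-support rules", {
  wt <- list(key = "WT", count = 15)
  p1 <- list(key = "S5:C>T", count = 8)
  p2 <- list(key = "S6:C>T", count = 4)
  p3 <- list(key = "S7:C>T", count = 3)

  expect_identical(fake_embryo(list(wt))$genotype_class, "wild_type")
  expect_identical(fake_embryo(list(list(key = "WT", count = 7), p1))$genotype_class,
                   "heterozygous")
  expect_identical(fake_embryo(list(wt, p1, p2))$genotype_class, "mosaic")
  hom <- fake_embryo(list(p1))
  expect_identical(hom$genotype_class, "homozygous")
  expect_true(hom$is_mutant && hom$is_biallelic)
  expect_identical(fake_embryo(list(p1, p2))$genotype_class, "biallelic")
  expect_identical(fake_embryo(list(p1, p2, p3))$genotype_class, "mosaic")
  expect_error(genotype_embryo(list()), class = "becall_input_error")
})

test_that("genotype rules agree with a brute-force truth table over support configurations", {
  # enumerate all (wt clones, pattern1 clones, pattern2 clones) with a total
  # of <= 8 clones and compare against a direct restatement of the rules
  for (n_wt in 0:4) for (n_p1 in 0:4) for (n_p2 in 0:4) {
    if (n_wt + n_p1 + n_p2 == 0) next
    spec <- list()
    if (n_wt) spec <- c(spec, list(list(key = "WT", count = n_wt)))
    if (n_p1) spec <- c(spec, list(list(key = "S5:C>T", count = n_p1)))
    if (n_p2) spec <- c(spec, list(list(key = "S6:C>T", count = n_p2)))
    g <- fake_embryo(spec)
    n_edited <- (n_p1 > 0) + (n_p2 > 0)
    expected <- if (n_edited == 0) "wild_type"
      else if (n_wt > 0 && n_edited == 1) "heterozygous"
      else if (n_wt > 0) "mosaic"
      else if (n_edited == 1) "homozygous"
      else "biallelic"
    expect_identical(g$genotype_class, expected,
                     info = sprintf("wt=%d p1=%d p2=%d", n_wt, n_p1, n_p2))
    expect_identical(g$is_mutant, n_edited > 0)
  }
})

test_that("min_support drops singleton patterns", {
  g <- genotype_embryo(c(replicate(7, fake_call("WT"), simplify = FALSE),
                         replicate(8, fake_call("S5:C>T",
                           categories = "window_deamination"),
                           simplify = FALSE),
                         list(fake_call("S9:C>T",
                           categories = "proximal_site_deamination"))),
                       min_support = 2)
  expect_identical(g$genotype_class, "heterozygous")
  expect_false(g$has_proximal)    # the proximal pattern had 1 clone only
})

test_that("proximal and indel flags propagate from supported patterns", {
  g <- fake_embryo(list(list(key = "WT", count = 7),
                        list(key = "S5:C>T|S-20:C>T", count = 8,
                             categories = c("window_deamination",
                                            "proximal_site_deamination"))))
  expect_true(g$has_proximal)
  expect_false(g$has_indel)
  gi <- fake_embryo(list(list(key = "D10:2", count = 5, class = "indel_allele",
                              categories = "indel")))
  expect_true(gi$has_indel && gi$is_mutant)
  # with the switch off, an indel-only embryo is not counted as mutant
  calls <- replicate(5, fake_call("D10:2", class = "indel_allele",
                                  categories = "indel"), simplify = FALSE)
  expect_false(genotype_embryo(calls, indel_only_is_mutant = FALSE)$is_mutant)
})

test_that("group summaries reproduce printed percentages from counts", {
  mk <- function(n_total, n_mutant, n_proximal) {
    gts <- c(
      replicate(n_proximal, fake_embryo(list(list(key = "S5:C>T|S-20:C>T",
        count = 5, categories = c("window_deamination",
                                  "proximal_site_deamination")))),
        simplify = FALSE),
      replicate(n_mutant - n_proximal, fake_embryo(list(list(key = "S5:C>T",
        count = 5, categories = "window_deamination"))), simplify = FALSE),
      replicate(n_total - n_mutant, fake_embryo(list(list(key = "WT",
        count = 5))), simplify = FALSE))
    summarize_group("grp", gts)
  }
  s2 <- mk(67, 26, 15)
  expect_equal(c(s2$pct_mutant, s2$ratio_proximal_mutant,
                 s2$ratio_proximal_total), c(38.8, 57.7, 22.4))
  s4 <- mk(59, 9, 3)
  expect_equal(c(s4$pct_mutant, s4$ratio_proximal_mutant,
                 s4$ratio_proximal_total), c(15.3, 33.3, 5.1))
  # empty group: all counts zero, percentages undefined
  s0 <- summarize_group("empty", list())
  expect_identical(s0$n_total, 0L)
  expect_true(is.na(s0$pct_mutant) && is.na(s0$ratio_proximal_mutant))
  # no mutants: proximal/mutant ratio undefined
  s_wt <- mk(5, 0, 0)
  expect_true(is.na(s_wt$ratio_proximal_mutant))
  expect_identical(s_wt$pct_mutant, 0)
})

test_that("percentages recompute exactly from emitted counts and are monotone", {
  mk_gt <- function(mutant) fake_embryo(list(list(
    key = if (mutant) "S5:C>T" else "WT", count = 3,
    categories = if (mutant) "window_deamination" else NULL)))
  set.seed(42)
  gts <- lapply(runif(30) < 0.4, mk_gt)
  s <- summarize_group("g", gts)
  expect_identical(s$n_mutant + sum(!vapply(gts, `[[`, logical(1),
                                            "is_mutant")), s$n_total)
  expect_equal(s$pct_mutant, round(100 * s$n_mutant / s$n_total, 1))
  # adding a mutant embryo never decreases pct_mutant
  s2 <- summarize_group("g", c(gts, list(mk_gt(TRUE))))
  expect_gte(s2$pct_mutant, s$pct_mutant)
})

test_that("the 2x2 chi-square matches its closed form and chisq.test", {
  expect_equal(chi2_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi2_2x2(10, 10, 10, 10)$p_value, 1)
  # exhaustive small-table agreement with the closed form
  grid <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  grid <- grid[(grid$a + grid$b) > 0 & (grid$c + grid$d) > 0 &
               (grid$a + grid$c) > 0 & (grid$b + grid$d) > 0, ]
  res <- chi2_2x2(grid$a, grid$b, grid$c, grid$d)
  expect_equal(res$statistic,
               chi2_closed_form(grid$a, grid$b, grid$c, grid$d),
               tolerance = 1e-12)
  # independent cross-check against stats::chisq.test without correction
  set.seed(1)
  idx <- sample(nrow(grid), 200)
  for (i in idx) {
    m <- matrix(unlist(grid[i, ]), 2, 2, byrow = TRUE)
    if (any(m == 0)) next    # chisq.test warns; expected values still fine
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    r <- chi2_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    expect_equal(r$statistic, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-9)
  }
  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
})

test_that("pup summaries use the genotyped denominator", {
  pups2 <- data.frame(
    is_mutant = c(rep(TRUE, 7), rep(FALSE, 4)),
    is_biallelic = c(rep(TRUE, 3), rep(FALSE, 8)),
    coat = c("albino", "mosaic", "mosaic", "mosaic", "mosaic", "black",
             "black", rep("black", 4)))
  s <- summarize_pups("guide2", n_injected = 145, n_survived = 106,
                      n_transferred = 106, n_born = 11, pups = pups2)
  expect_equal(s$pct_mutant, 63.6)
  expect_equal(s$pct_biallelic, 27.3)
  expect_equal(s$pct_mosaic_coat, 36.4)
  expect_equal(s$pct_born, 10.4)
  s1 <- summarize_pups("guide1", 162, 120, 120, n_born = 13,
                       pups = data.frame(is_mutant = c(TRUE, TRUE,
                                                       rep(FALSE, 9)),
                                         is_biallelic = FALSE,
                                         coat = "black"))
  expect_equal(s1$pct_survived, 74.1)
  expect_equal(s1$pct_mutant, 18.2)     # 2 of 11 genotyped, 13 born
  s0 <- summarize_pups("none", 10, 8, 8)
  expect_true(is.na(s0$pct_mutant) && is.na(s0$pct_biallelic))
})
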