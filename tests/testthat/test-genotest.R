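# The multi-breed cohort shape used for layout tests: 24 affected and 520
# control German Shorthaired Pointers, plus the related-breed control strata
# and the affected Vizsla.
cohort_fixture <- function() {
  strata <- list(
    list(breed = "German Shorthaired Pointer", phen = "case",    g = c(1, 0, 23)),
    list(breed = "German Shorthaired Pointer", phen = "control", g = c(457, 63, 0)),
    list(breed = "German Longhaired Pointer",  phen = "control", g = c(50, 2, 0)),
    list(breed = "German Wirehaired Pointer",  phen = "control", g = c(210, 0, 0)),
    list(breed = "Braque du Bourbonnais",      phen = "control", g = c(7, 0, 0)),
    list(breed = "Vizsla",                     phen = "case",    g = c(0, 0, 1)),
    list(breed = "Vizsla",                     phen = "control", g = c(51, 5, 0)))
  calls <- integer(0); breed <- character(0); phen <- character(0)
  for (s in strata) {
    k <- sum(s$g)
    calls <- c(calls, rep(c(0L, 1L, 2L), s$g))
    breed <- c(breed, rep(s$breed, k))
    phen <- c(phen, rep(s$phen, k))
  }
  ids <- sprintf("d%04d", seq_along(calls))
  list(calls = stats::setNames(calls, ids),
       samples = sample_table(ids, breed, phen))
}

test_that("genotype tabulation aggregates and is order-invariant", {
  st <- sample_table(c("a", "b", "c"), "B", rep("case", 3))
  calls <- stats::setNames(c(0L, 1L, 2L), c("a", "b", "c"))
  tab <- tabulate_genotypes(calls, st)
  expect_equal(nrow(tab), 1L)
  expect_equal(unlist(tab[1, c("n_hom_ref", "n_het", "n_hom_alt")], use.names = FALSE),
               c(1L, 1L, 1L))
  withr::with_seed(2, perm <- sample(3))
  expect_equal(tabulate_genotypes(calls[perm], st), tab)
  # a call without metadata is an error, and missing calls are tallied apart
  expect_error(tabulate_genotypes(stats::setNames(1L, "zz"), st), "no metadata")
  calls2 <- stats::setNames(c(0L, NA, 2L), c("a", "b", "c"))
  tab2 <- tabulate_genotypes(calls2, st)
  expect_equal(tab2$n_missing, 1L)
  expect_equal(tab2$n, 2L)
})

test_that("a cohort-shaped fixture tabulates into the standard multi-breed report layout", {
  fx <- cohort_fixture()
  tab <- tabulate_genotypes(fx$calls, fx$samples)
  expect_equal(nrow(tab), 7L)  # one row per breed x phenotype stratum
  gsp_case <- tab[tab$breed == "German Shorthaired Pointer" & tab$phenotype == "case", ]
  expect_equal(unlist(gsp_case[c("n_hom_ref", "n_het", "n_hom_alt", "n")], use.names = FALSE),
               c(1L, 0L, 23L, 24L))
  gsp_ctrl <- tab[tab$breed == "German Shorthaired Pointer" & tab$phenotype == "control", ]
  expect_equal(gsp_ctrl$n, 520L)
  expect_equal(gsp_ctrl$n_hom_alt, 0L)
  expect_equal(sum(tab$n), 870L)  # all genotyped dogs across strata
  # row totals always equal the declared n
  expect_true(all(tab$n_hom_ref + tab$n_het + tab$n_hom_alt == tab$n))
  # written report round-trips the counts
  dir <- withr::local_tempdir()
  write_report(tab, file.path(dir, "tab.tsv"))
  back <- read_report(file.path(dir, "tab.tsv"))
  expect_equal(back$n_hom_alt, tab$n_hom_alt)
})

test_that("the log-space Fisher test matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(0, 7, 0, 11), 1.0)  # degenerate margin
  expect_equal(fisher_exact_2x2(2, 3, 1, 4), fisher_oracle(2, 3, 1, 4), tolerance = 1e-12)
  withr::with_seed(13, {
    for (i in 1:40) {
      t4 <- as.integer(sample(0:12, 4, TRUE))
      if (sum(t4) == 0) next
      mine <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])
      ft <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
      expect_equal(mine, ft, tolerance = 1e-9)
    }
  })
  # one-sided variants sum the correct tail
  expect_equal(fisher_exact_2x2(5, 1, 1, 5, "greater"),
               sum(stats::dhyper(5:6, 6, 6, 6)), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("the recessive collapse of the pointer cohort reproduces the headline p-value", {
  p <- fisher_exact_2x2(23, 1, 0, 520)
  expect_equal(signif(p, 2), 1.2e-39)
  # log-space: finite, positive, stable under row reordering
  expect_gt(p, 0)
  p_swapped <- fisher_exact_2x2(0, 520, 23, 1)
  expect_equal(p_swapped, p, tolerance = 1e-9)
  # and via the table interface
  fx <- cohort_fixture()
  tab <- tabulate_genotypes(fx$calls, fx$samples)
  res <- test_variant(tab, "recessive", breeds = "German Shorthaired Pointer")
  expect_equal(res$p_value, p, tolerance = 1e-12)
  expect_true(res$or_corrected)  # zero cell -> Haldane-corrected OR
  expect_gt(res$odds_ratio, 1)
})

test_that("balanced tables are null under every coding", {
  st <- sample_table(sprintf("s%02d", 1:12), "B",
                     rep(c("case", "control"), each = 6))
  calls <- stats::setNames(rep(c(0L, 1L, 2L), 4), st$sample_id)
  tab <- tabulate_genotypes(calls, st)
  for (cod in c("recessive", "dominant", "allelic", "genotypic"))
    expect_equal(test_variant(tab, cod, min_margin = 0)$p_value, 1.0)
})

test_that("the genotypic exact test agrees with full enumeration on small tables", {
  withr::with_seed(19, {
    for (i in 1:12) {
      m <- matrix(as.integer(sample(0:6, 6, TRUE)), 2, 3)
      if (any(rowSums(m) == 0) || sum(m) == 0) next
      mine <- exact_test_2x3(m)
      orac <- stats::fisher.test(m)$p.value
      expect_equal(mine, orac, tolerance = 1e-7)
    }
  })
  # p is invariant under simultaneous row and column swaps
  m <- matrix(c(5L, 1L, 2L, 0L, 3L, 4L), 2, 3)
  expect_equal(exact_test_2x3(m[2:1, 3:1]), exact_test_2x3(m), tolerance = 1e-12)
  # the Monte Carlo fallback is seeded and reproducible
  big <- matrix(c(200L, 150L, 120L, 180L, 140L, 160L), 2, 3)
  p1 <- exact_test_2x3(big, max_enumeration = 10, seed = 5)
  p2 <- exact_test_2x3(big, max_enumeration = 10, seed = 5)
  expect_identical(p1, p2)
})

test_that("single-individual strata are guarded from lone testing", {
  fx <- cohort_fixture()
  tab <- tabulate_genotypes(fx$calls, fx$samples)
  expect_error(test_variant(tab, "recessive", breeds = "Vizsla"), "guard")
  # but the guard is configurable
  res <- test_variant(tab, "recessive", breeds = "Vizsla", min_margin = 0)
  expect_lt(res$p_value, 0.05)
  expect_error(test_variant(tab, "recessive", breeds = "NoSuchBreed"), "not present")
})
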