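test_that("haplotype diversity hits its closed-form anchors", {
  expect_equal(haplotype_diversity(c(5))$H, 0) # monomorphic
  expect_equal(haplotype_diversity(rep(1, 8))$H, 1) # all distinct: correction cancels
  expect_equal(haplotype_diversity(c(2, 1, 1))$H, (4 / 3) * (1 - (0.25 + 0.0625 + 0.0625)))
  expect_error(haplotype_diversity(c(1)), class = "haplodiv_sample_error")
})

test_that("haplotype diversity and its SD match independent estimators on random spectra", {
  set.seed(101)
  for (i in 1:1000) {
    nh <- sample(2:12, 1)
    freqs <- sample(1:20, nh, replace = TRUE)
    res <- haplotype_diversity(freqs)
    expect_equal(res$H, oracle_gene_diversity(freqs), tolerance = 1e-12)
    expect_equal(res$sd, sqrt(oracle_gene_diversity_var(freqs)), tolerance = 1e-12)
  }
})

test_that("haplotype diversity is permutation-invariant and increases when a singleton splits off", {
  spectra <- list(c(5, 3, 2), c(10, 1), c(4, 4, 4), c(7, 2, 2, 1))
  for (f in spectra) {
    expect_equal(
      haplotype_diversity(f)$H,
      haplotype_diversity(rev(f))$H
    )
    split <- c(f[1] - 1, f[-1], 1) # peel a singleton off the largest class
    expect_gt(haplotype_diversity(split)$H, haplotype_diversity(f)$H)
  }
})

test_that("nucleotide diversity equals the brute-force mean pairwise difference", {
  # single segregating site between two sequences of length 582
  a <- strrep("A", 582)
  b <- paste0("C", strrep("A", 581))
  expect_equal(nucleotide_diversity(c(a, b), c(1, 1)), 1 / 582)
  expect_equal(nucleotide_diversity(a, 5), 0) # monomorphic

  set.seed(7)
  L <- 40
  seqs <- vapply(
    1:6,
    function(i) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)
  )
  freqs <- c(3, 2, 1, 1, 1, 2)
  expanded <- rep(seqs, freqs)
  expect_equal(
    nucleotide_diversity(seqs, freqs),
    oracle_pi(expanded, L),
    tolerance = 1e-12
  )
})

test_that("rarefaction is exact at the boundaries and matches exhaustive enumeration", {
  # k = n returns the observed haplotype count with zero spread
  res <- rarefy_haplotypes(c(3, 2, 1), k = 6, replications = 50, seed = 1)
  expect_equal(res$mean_nht, 3)
  expect_equal(res$sd_nht, 0)
  expect_equal(res$expected_nht, 3)
  # k = 1: expectation is exactly 1
  expect_equal(rarefy_haplotypes(c(3, 2, 1), k = 1, replications = 10, seed = 1)$expected_nht, 1)
  # closed form vs exhaustive enumeration of all C(6,3) = 20 subsets
  enum <- oracle_rarefaction_enum(c(3, 2, 1), 3)
  res3 <- rarefy_haplotypes(c(3, 2, 1), k = 3, replications = 2000, seed = 4)
  expect_equal(res3$expected_nht, enum, tolerance = 1e-12)
  expect_lt(
    abs(res3$mean_nht - enum),
    3 * res3$sd_nht / sqrt(res3$replications)
  )
  expect_error(rarefy_haplotypes(c(3, 2, 1), k = 7), class = "haplodiv_rarefaction_error")
})

test_that("rarefaction is reproducible under a seed and leaves the RNG alone", {
  f <- c(8, 5, 3, 2, 1, 1)
  a <- rarefy_haplotypes(f, k = 10, replications = 100, seed = 99)
  b <- rarefy_haplotypes(f, k = 10, replications = 100, seed = 99)
  expect_equal(a, b)
  set.seed(1)
  x <- stats::runif(1)
  set.seed(1)
  invisible(rarefy_haplotypes(f, k = 10, replications = 10, seed = 5))
  expect_equal(stats::runif(1), x)
})

test_that("haplogroup percentages are computed on the full regional sample", {
  sc <- tibble::tibble(
    region = "Thailand",
    haplogroup = rep(c("A", "B", "C", "E"), c(220, 26, 13, 6))
  )
  hs <- haplogroup_summary(sc)
  expect_equal(hs$n_total, 265L)
  expect_equal(hs$n_ABC, 259L)
  expect_equal(hs$n_DEF, 6L)
  expect_equal(round(hs$pctA, 1), 83.0)
  expect_equal(round(hs$pctB, 1), 9.8)
  expect_equal(round(hs$pctC, 1), 4.9)
  expect_equal(round(hs$pctDEF, 1), 2.3)

  all_a <- haplogroup_summary(tibble::tibble(region = "X", haplogroup = rep("A", 10)))
  expect_equal(all_a$pctA, 100)
  expect_equal(all_a$pctB, 0)
  expect_error(
    haplogroup_summary(tibble::tibble(region = character(), haplogroup = character())),
    class = "haplodiv_empty_region_error"
  )
})

test_that("the region table satisfies its structural invariants on synthetic data", {
  cfg <- synth_preset("thailand_like", seed = 13)
  rules <- make_rules(cfg)
  sim <- simulate_dataset(cfg, rules)
  haps <- collapse_haplotypes(sim$alignment)
  calls <- call_haplotypes(haps, rules)
  sc <- call_samples(sim$alignment, haps, calls)
  rt <- region_table(sc, haps, k = 32, replications = 200, seed = 8)

  per_region <- rt |> dplyr::filter(region != "Total")
  expect_equal(sum(per_region$n_total), nrow(sim$alignment))
  expect_true(all(rt$n_ABC + rt$n_DEF == rt$n_total))
  expect_true(all(rt$nA + rt$nB + rt$nC == rt$n_ABC))
  expect_true(all(rt$pctUT <= rt$pctUTd + 1e-12)) # every UT is also a UTd
  expect_true(all(rt$HT_div >= 0 & rt$HT_div <= 1))
  expect_true(all(is.na(rt$nHT_res) | rt$nHT_res <= rt$nHT))
  expect_lte(sum(per_region$HTuq), nrow(haps))
  # rarefied mean stays near its hypergeometric expectation
  ok <- !is.na(rt$nHT_res)
  expect_true(all(abs(rt$nHT_res[ok] - rt$nHT_res_expected[ok]) <
    4 * pmax(rt$nHT_res_sd[ok], 1e-9) / sqrt(200) + 1e-9))

  # a single-region run owns all its haplotypes
  solo <- region_table(sc |> dplyr::mutate(region = "All"), haps,
    k = 32, replications = 50, seed = 1
  )
  expect_equal(solo$HTuq, solo$nHT)

  # empty input gives an empty table
  empty <- region_table(sc[0, ], haps, k = 10)
  expect_equal(nrow(empty), 0L)
})

test_that("regions smaller than k get NA rarefaction instead of an error", {
  sc <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    region = rep(c("big", "small"), c(6, 2)),
    haplotype = c("h1", "h1", "h2", "h3", "h3", "h4", "h5", "h5"),
    haplogroup = "A", subhaplogroup = "a1",
    ut_status = factor("other", levels = c("UT", "UTd", "other"))
  )
  haps <- tibble::tibble(
    haplotype = paste0("h", 1:5),
    seq = c("AAAA", "AAAC", "AACC", "ACCC", "CCCC")
  )
  rt <- region_table(sc, haps, k = 4, replications = 50, seed = 2, pooled = FALSE)
  expect_true(is.na(rt$nHT_res[rt$region == "small"]))
  expect_false(is.na(rt$nHT_res[rt$region == "big"]))
})
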