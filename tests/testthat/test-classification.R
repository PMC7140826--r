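test_that("haplogroup assignment is first-match-wins over diagnostic sites", {
  rules <- tiny_rules()
  expect_equal(assign_haplogroup(tiny_seq("C"), rules), "C")
  expect_equal(
    assign_haplogroup(c(tiny_seq("A"), tiny_seq("B"), tiny_seq("E")), rules),
    c("A", "B", "E")
  )
  # no rule matches: error names the nearest rule and mismatching site
  expect_error(
    assign_haplogroup(tiny_base(), rules),
    regexp = "no haplogroup rule",
    class = "haplodiv_unclassified_error"
  )
})

test_that("sub-haplogroups resolve within A/B/C with a1/b1 as the unmarked fallback", {
  rules <- tiny_rules()
  s_a2 <- tiny_seq("A", c(`105` = "C"))
  s_a1 <- tiny_seq("A")
  s_c1 <- tiny_seq("C", c(`107` = "C"))
  s_c2 <- tiny_seq("C", c(`107` = "G"))
  s_e <- tiny_seq("E")
  seqs <- c(s_a2, s_a1, s_c1, s_c2, s_e)
  hg <- assign_haplogroup(seqs, rules)
  expect_equal(
    assign_subhaplogroup(seqs, hg, rules),
    c("a2", "a1", "c1", "c2", NA)
  )
  # haplogroup C sequence matching neither c1 nor c2, with no fallback
  s_c_none <- tiny_seq("C")
  expect_error(
    assign_subhaplogroup(s_c_none, "C", rules),
    class = "haplodiv_unclassified_error"
  )
})

test_that("UT classification thresholds: 0 = UT, 1 = UTd, >= 2 = other", {
  rules <- tiny_rules()
  ut <- rules$ut$seq[1]
  one_off <- tiny_seq("A", c(`115` = "C"))
  two_off <- tiny_seq("A", c(`115` = "C", `116` = "C"))
  res <- classify_ut(c(ut, one_off, two_off), rules)
  expect_equal(as.character(res$ut_status), c("UT", "UTd", "other"))
  expect_equal(res$min_dist_to_ut, c(0L, 1L, 2L))
  # brute-force confirmation of the two-step case against all UTs
  expect_equal(unname(oracle_nearest_ut(two_off, rules$ut$seq)[1]), 2)
  # empty UT set is a configuration error
  bad <- tiny_rules()
  bad$ut <- bad$ut[0, ]
  expect_error(classify_ut(ut, bad), class = "haplodiv_config_error")
})

test_that("UT/UTd classifier agrees exactly with a brute-force nearest-UT scan", {
  cfg <- synth_config(seed = 5, L = 120, regions = c(R1 = 10L))
  rules <- make_rules(cfg)
  gens <- attr(rules, "generator")
  set.seed(42)
  seqs <- vapply(1:400, function(i) {
    base <- sample(rules$ut$seq, 1)
    chars <- strsplit(base, "")[[1]]
    nmut <- sample(0:5, 1)
    pos <- sample(length(chars), nmut)
    chars[pos] <- vapply(
      chars[pos],
      function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
      character(1)
    )
    paste(chars, collapse = "")
  }, character(1))
  res <- classify_ut(seqs, rules)
  expected <- t(vapply(seqs, oracle_nearest_ut,
    numeric(2),
    ut_seqs = rules$ut$seq
  ))
  mind <- unname(expected[, 1])
  expect_equal(res$min_dist_to_ut, as.integer(mind))
  expect_equal(
    as.character(res$ut_status),
    ifelse(mind == 0, "UT", ifelse(mind == 1, "UTd", "other"))
  )
})

test_that("calls are deterministic, complete, and local to each haplotype", {
  rules <- tiny_rules()
  aln <- make_aln(c(
    rules$ut$seq[1], rules$ut$seq[1],
    tiny_seq("A", c(`105` = "C")),
    tiny_seq("B", c(`106` = "C", `115` = "G"))
  ))
  haps <- collapse_haplotypes(aln)
  calls <- call_haplotypes(haps, rules)
  expect_equal(nrow(calls), nrow(haps))
  expect_false(any(is.na(calls$haplogroup)))
  expect_true(all(c("matched_sites", "min_dist_to_ut") %in% names(calls)))
  # invariant: status thresholds tie to distances
  expect_true(all((calls$ut_status == "UT") == (calls$min_dist_to_ut == 0)))
  expect_true(all((calls$ut_status == "UTd") == (calls$min_dist_to_ut == 1)))
  expect_true(all((calls$ut_status == "other") == (calls$min_dist_to_ut >= 2)))

  # locality: adding an unrelated non-UT haplotype changes no existing call
  aln2 <- dplyr::bind_rows(aln, make_aln(tiny_seq("E", c(`118` = "G")), ids = "extra"))
  calls2 <- call_haplotypes(collapse_haplotypes(aln2), rules)
  joined <- dplyr::inner_join(
    calls |> dplyr::left_join(haps[, c("haplotype", "seq")], by = "haplotype"),
    calls2 |> dplyr::left_join(collapse_haplotypes(aln2)[, c("haplotype", "seq")],
      by = "haplotype"
    ),
    by = "seq"
  )
  expect_equal(joined$haplogroup.x, joined$haplogroup.y)
  expect_equal(joined$subhaplogroup.x, joined$subhaplogroup.y)
  expect_equal(as.character(joined$ut_status.x), as.character(joined$ut_status.y))

  # empty input gives an empty call table
  expect_equal(nrow(call_haplotypes(collapse_haplotypes(make_aln(character(0), ids = character(0))), rules)), 0L)

  # a dataset of only UT sequences is called all-UT
  all_ut <- collapse_haplotypes(make_aln(rules$ut$seq))
  expect_true(all(call_haplotypes(all_ut, rules)$ut_status == "UT"))
})

test_that("planted sub-haplogroup labels are recovered perfectly on synthetic data", {
  cfg <- synth_config(
    seed = 9, L = 200,
    regions = c(R1 = 60L, R2 = 40L),
    haplogroup_freqs = c(A = 0.7, B = 0.18, C = 0.1, D = 0, E = 0.02, F = 0)
  )
  rules <- make_rules(cfg)
  sim <- simulate_dataset(cfg, rules)
  haps <- collapse_haplotypes(sim$alignment)
  calls <- call_haplotypes(haps, rules)
  truth <- sim$truth_haplotypes
  m <- match(haps$seq, truth$seq)
  expect_equal(calls$haplogroup, truth$haplogroup[m])
  expect_equal(calls$subhaplogroup, truth$subhaplogroup[m])
  expect_equal(as.character(calls$ut_status), as.character(truth$ut_status[m]))
})

test_that("haplogroup sample proportions track a planted composition at n = 1000", {
  planted <- c(A = 0.83, B = 0.10, C = 0.05, D = 0, E = 0.02, F = 0)
  cfg <- synth_config(
    seed = 21, L = 200, regions = c(R1 = 1000L),
    haplogroup_freqs = planted
  )
  sim <- simulate_dataset(cfg, make_rules(cfg))
  haps <- collapse_haplotypes(sim$alignment)
  calls <- call_haplotypes(haps, make_rules(cfg))
  sc <- call_samples(sim$alignment, haps, calls)
  obs <- prop.table(table(factor(sc$haplogroup, levels = names(planted))))
  for (hg in c("A", "B", "C", "E")) {
    se <- sqrt(planted[hg] * (1 - planted[hg]) / 1000)
    expect_lt(abs(obs[[hg]] - planted[[hg]]), 3 * se + 1e-12)
  }
})

test_that("rule sets round-trip through the YAML schema", {
  cfg <- synth_config(seed = 2, L = 150, regions = c(R1 = 5L))
  rules <- make_rules(cfg)
  path <- tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back$haplogroups, rules$haplogroups)
  expect_equal(back$subhaplogroups, rules$subhaplogroups)
  expect_equal(back$fallbacks, rules$fallbacks)
  expect_equal(back$ut, rules$ut)
  expect_equal(back$map$ref_start, rules$map$ref_start)
})
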