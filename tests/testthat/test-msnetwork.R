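test_that("substitution distances match a per-column brute-force scan", {
  expect_equal(distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0L)
  expect_equal(distance_matrix(c(a = "ACGT", b = "TGCA"))["a", "b"], 4L)
  expect_equal(distance_matrix(c(a = "ACGTA", b = "AGGTC"))["a", "b"], 2L)
  # gap/ambiguity columns are skipped under the default policy
  expect_equal(distance_matrix(c(a = "AC-TN", b = "ACGTA"))["a", "b"], 0L)
  expect_equal(distance_matrix(c(a = "AC-TN", b = "TCGTA"), policy = "skip")["a", "b"], 1L)

  set.seed(31)
  seqs <- vapply(
    1:20,
    function(i) paste(sample(c("A", "C", "G", "T", "N", "-"), 60,
      replace = TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)
    ), collapse = ""),
    character(1)
  )
  names(seqs) <- sprintf("h%02d", 1:20)
  d <- distance_matrix(seqs)
  expect_true(isSymmetric(unclass(d)[, ]))
  expect_equal(unname(diag(d)), rep(0L, 20))
  for (i in 1:19) {
    for (j in (i + 1):20) {
      expect_equal(d[i, j], oracle_hamming(seqs[i], seqs[j]))
    }
  }
  expect_error(distance_matrix(c("ACGT", "ACG")), class = "haplodiv_geometry_error")
})

test_that("small networks take their forced shapes", {
  # two haplotypes: the single connecting edge
  d2 <- distance_matrix(c(a = "AAAA", b = "AATT"))
  net2 <- build_msn(d2)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 2L)
  expect_true(net2$edges$in_all_msts)

  # distances (1, 1, 2): unique MST, heavy edge excluded
  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  net3 <- build_msn(d3)
  expect_equal(nrow(net3$edges), 2L)
  expect_equal(sort(net3$edges$weight), c(1L, 1L))
  expect_true(all(net3$edges$in_all_msts))
  expect_equal(net3$mst_weight, 2L)

  # equilateral triangle: all three tied edges kept as alternatives
  deq <- matrix(1, 3, 3) - diag(3)
  dimnames(deq) <- list(c("a", "b", "c"), c("a", "b", "c"))
  neteq <- build_msn(deq)
  expect_equal(nrow(neteq$edges), 3L)
  expect_false(any(neteq$edges$in_all_msts))
  expect_equal(neteq$mst_weight, 2)

  # degenerate inputs
  expect_equal(nrow(build_msn(distance_matrix(c(only = "ACGT")))$edges), 0L)
  expect_equal(nrow(build_msn(matrix(integer(0), 0, 0))$nodes), 0L)
})

test_that("the network is the union of all minimum spanning trees (exhaustive oracle)", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    d <- random_distance_matrix(n)
    net <- build_msn(d)
    oracle <- oracle_mst_exhaustive(d)
    expect_equal(net$mst_weight, oracle$min_weight)
    # edge sets must coincide exactly
    got <- sort(paste(pmin(net$edges$from, net$edges$to),
      pmax(net$edges$from, net$edges$to),
      sep = "|"
    ))
    labs <- rownames(d)
    want <- sort(apply(
      oracle$pairs[oracle$in_some_mst, , drop = FALSE], 1,
      function(p) paste(sort(labs[p]), collapse = "|")
    ))
    expect_equal(got, want)
    # forced-backbone edges are exactly those present in every MST:
    # dropping one must make the minimum weight unreachable
    for (e in which(net$edges$in_all_msts)) {
      u <- match(net$edges$from[e], labs)
      v <- match(net$edges$to[e], labs)
      d_cut <- d
      d_cut[u, v] <- d_cut[v, u] <- max(d) * n + 1L # effectively remove
      expect_gt(oracle_mst_exhaustive(d_cut)$min_weight, oracle$min_weight)
    }
  }
})

test_that("network construction is invariant under node relabeling order", {
  set.seed(77)
  d <- random_distance_matrix(7)
  net <- build_msn(d)
  perm <- sample(7)
  dp <- d[perm, perm]
  netp <- build_msn(dp)
  canon <- function(net) {
    dplyr::arrange(
      dplyr::mutate(net$edges,
        a = pmin(from, to), b = pmax(from, to)
      )[, c("a", "b", "weight", "in_all_msts")],
      a, b
    )
  }
  expect_equal(canon(net), canon(netp))
  expect_equal(net$mst_weight, netp$mst_weight)
})

test_that("node annotations carry frequency, regions and private/shared status", {
  rules <- tiny_rules()
  aln <- make_aln(
    c(
      rules$ut$seq[1], rules$ut$seq[1], rules$ut$seq[1],
      tiny_seq("A", c(`115` = "C")),
      tiny_seq("B", c(`116` = "G"))
    ),
    regions = c("N", "S", "N", "N", "S")
  )
  haps <- collapse_haplotypes(aln)
  calls <- call_haplotypes(haps, rules)
  sc <- call_samples(aln, haps, calls)
  net <- annotate_msn(build_msn(distance_matrix(haps)), sc)
  nodes <- net$nodes
  shared <- nodes[nodes$n == 3, ]
  expect_equal(shared$status, "shared")
  expect_equal(shared$n_regions, 2L)
  expect_true(shared$ut)
  expect_true(all(nodes$status[nodes$n == 1] == "unique"))
  # a node without a sample call is an annotation error
  bad_net <- build_msn(distance_matrix(c(ghost = tiny_seq("A"))))
  expect_error(annotate_msn(bad_net, sc), class = "haplodiv_annotation_error")
})

test_that("unique-flagged node counts equal the generator's private plants", {
  cfg <- synth_preset("thailand_like", seed = 19)
  rules <- make_rules(cfg)
  sim <- simulate_dataset(cfg, rules)
  haps <- collapse_haplotypes(sim$alignment)
  calls <- call_haplotypes(haps, rules)
  sc <- call_samples(sim$alignment, haps, calls)
  net <- annotate_msn(build_msn(distance_matrix(haps)), sc)
  # truth: haplotypes observed in exactly one region
  truth_unique <- sim$truth_samples |>
    dplyr::distinct(hap_id, region) |>
    dplyr::count(hap_id) |>
    dplyr::filter(n == 1L) |>
    nrow()
  expect_equal(sum(net$nodes$status == "unique"), truth_unique)
})

test_that("multi-step edges expand into unit chains through hypothetical nodes", {
  d <- distance_matrix(c(a = "AAAA", b = "AATT", c = "AATA"))
  net <- build_msn(d)
  ex <- expand_msn(net)
  expect_true(all(ex$edges$weight == 1L))
  real <- ex$nodes$name[!ex$nodes$hypothetical]
  expect_setequal(real, c("a", "b", "c"))
  # weight-w edge contributes w-1 intermediaries
  expect_equal(
    sum(ex$nodes$hypothetical),
    sum(pmax(net$edges$weight - 1L, 0L))
  )
  # every real-real unit edge is exactly one substitution apart
  seqs <- c(a = "AAAA", b = "AATT", c = "AATA")
  rr <- ex$edges[ex$edges$from %in% real & ex$edges$to %in% real, ]
  for (i in seq_len(nrow(rr))) {
    expect_equal(oracle_hamming(seqs[[rr$from[i]]], seqs[[rr$to[i]]]), 1)
  }
})

test_that("network export writes edge list, node table and GraphML", {
  cfg <- synth_config(seed = 4, L = 100, regions = c(R1 = 30L))
  rules <- make_rules(cfg)
  sim <- simulate_dataset(cfg, rules)
  haps <- collapse_haplotypes(sim$alignment)
  sc <- call_samples(sim$alignment, haps, call_haplotypes(haps, rules))
  net <- annotate_msn(build_msn(distance_matrix(haps)), sc)
  edges <- tempfile(fileext = ".tsv")
  nodes <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  export_msn(net, edges, nodes, gml)
  etab <- readr::read_tsv(edges, show_col_types = FALSE)
  expect_equal(names(etab), c("u", "v", "weight", "in_all_msts"))
  expect_equal(nrow(etab), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
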