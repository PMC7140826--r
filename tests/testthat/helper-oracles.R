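# Independent oracles. Each reimplements a quantity from first principles
# (per-character scans, exhaustive enumeration, closed forms written with
# different algebra) and must never call the implementation it checks.

# Substitution distance by per-character scan; gap/ambiguity columns skipped.
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  bases <- c("A", "C", "G", "T")
  ok <- ca %in% bases & cb %in% bases
  sum(ca[ok] != cb[ok])
}

# Nearest-UT scan: returns c(min_dist, index).
oracle_nearest_ut <- function(seq, ut_seqs) {
  d <- vapply(ut_seqs, oracle_hamming, numeric(1), a = seq, USE.NAMES = FALSE)
  c(min(d), which.min(d))
}

# Gene diversity as a matching probability: 1 - P(two draws without
# replacement are identical). Algebraically equivalent to the corrected
# closed form but computed from ordered pair counts.
oracle_gene_diversity <- function(freqs) {
  n <- sum(freqs)
  same_pairs <- sum(freqs * (freqs - 1))
  1 - same_pairs / (n * (n - 1))
}

# Nei (1987) gene-diversity variance, coded independently term by term.
oracle_gene_diversity_var <- function(freqs) {
  n <- sum(freqs)
  p <- freqs / n
  a <- sum(p^2)
  b <- sum(p^3)
  (2 / (n * (n - 1))) * (2 * (n - 2) * (b - a^2) + a - a^2)
}

# Mean pairwise difference per site over all C(n,2) expanded sequence
# pairs. The n/(n-1) frequency correction in the haplotype-form estimator
# cancels against the ordered/unordered pair count, leaving the plain
# pairwise mean.
oracle_pi <- function(seqs_expanded, L) {
  n <- length(seqs_expanded)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + oracle_hamming(seqs_expanded[i], seqs_expanded[j])
    }
  }
  tot / choose(n, 2) / L
}

# Expected distinct haplotypes in a subsample of size k, by exhaustive
# enumeration of all C(n, k) subsets (tiny n only).
oracle_rarefaction_enum <- function(freqs, k) {
  ids <- rep(seq_along(freqs), freqs)
  subsets <- combn(length(ids), k)
  mean(apply(subsets, 2, function(ix) length(unique(ids[ix]))))
}

# --- spanning-tree oracles -------------------------------------------------

# Exhaustive: enumerate all (n-1)-edge subsets, keep spanning trees, return
# list(min_weight, edges) where edges is a logical matrix marking, for each
# candidate pair, membership in at least one minimum spanning tree.
oracle_mst_exhaustive <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  combos <- combn(ne, n - 1)
  best <- Inf
  member <- rep(FALSE, ne)
  for (ci in seq_len(ncol(combos))) {
    sel <- combos[, ci]
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    acyclic <- TRUE
    for (e in sel) {
      ru <- find(pairs[e, 1])
      rv <- find(pairs[e, 2])
      if (ru == rv) {
        acyclic <- FALSE
        break
      }
      parent[ru] <- rv
    }
    if (!acyclic) next
    w <- sum(d[pairs[sel, , drop = FALSE]])
    if (w < best - 1e-9) {
      best <- w
      member <- rep(FALSE, ne)
      member[sel] <- TRUE
    } else if (abs(w - best) < 1e-9) {
      member[sel] <- TRUE
    }
  }
  list(min_weight = best, pairs = pairs, in_some_mst = member)
}

# igraph-based route: total MST weight of a weighted complete graph.
oracle_mst_weight_igraph <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# Minimum spanning weight with edge (u, v) forced into the tree: contract v
# into u (parallel edges collapse to their minimum) and add w(u, v).
oracle_mst_weight_forced <- function(d, u, v) {
  n <- nrow(d)
  keep <- setdiff(seq_len(n), v)
  d2 <- d[keep, keep, drop = FALSE]
  upos <- match(u, keep)
  others <- setdiff(seq_along(keep), upos)
  for (x in others) {
    orig <- keep[x]
    d2[upos, x] <- d2[x, upos] <- min(d[u, orig], d[v, orig])
  }
  w_rest <- if (length(keep) > 1) oracle_mst_weight_igraph(d2) else 0
  d[u, v] + w_rest
}

random_distance_matrix <- function(n, max_w = 5L) {
  d <- matrix(0L, n, n)
  w <- sample.int(max_w, n * (n - 1) / 2, replace = TRUE)
  d[upper.tri(d)] <- w
  d <- d + t(d)
  dimnames(d) <- list(paste0("h", seq_len(n)), paste0("h", seq_len(n)))
  d
}
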