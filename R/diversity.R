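#' Haplotype (gene) diversity with standard deviation
#'
#' The probability that two samples drawn at random carry different
#' haplotypes, with the usual small-sample correction:
#' \deqn{H = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big)}
#' where \eqn{p_i} are haplotype relative frequencies. The standard
#' deviation comes from Nei's (1987) variance of gene diversity,
#' \deqn{V(H) = \frac{2}{n(n-1)}\Big[2(n-2)\big(\sum p_i^3 - (\sum p_i^2)^2\big)
#'   + \sum p_i^2 - (\sum p_i^2)^2\Big],}
#' the estimator implemented by Arlequin's standard-diversity routines.
#'
#' @param freqs Integer vector of haplotype member counts.
#' @return A tibble with columns `n`, `n_haplotypes`, `H`, `sd`.
#' @examples
#' haplotype_diversity(c(2, 1, 1)) # H = 5/6
#' @export
haplotype_diversity <- function(freqs) {
  freqs <- freqs[freqs > 0]
  n <- sum(freqs)
  if (n < 2) {
    abort("haplotype diversity needs at least 2 samples",
      class = "haplodiv_sample_error"
    )
  }
  p <- freqs / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  tibble(
    n = n, n_haplotypes = length(freqs),
    H = H, sd = sqrt(max(V, 0))
  )
}

#' Nucleotide diversity per site
#'
#' Mean pairwise substitution difference per comparable site,
#' \deqn{\pi = \frac{n}{n-1} \sum_{i<j} 2 p_i p_j \frac{d_{ij}}{L},}
#' over distinct haplotypes with relative frequencies \eqn{p_i} and
#' substitution distances \eqn{d_{ij}}. Columns with a gap or ambiguity in
#' either sequence are excluded from `d`; `L` defaults to the alignment
#' width.
#'
#' @param seqs Aligned haplotype sequences (distinct).
#' @param freqs Member counts, parallel to `seqs`.
#' @param L Number of comparable sites (default: alignment width).
#' @return Nucleotide diversity, a single non-negative number.
#' @export
nucleotide_diversity <- function(seqs, freqs, L = NULL) {
  stopifnot(length(seqs) == length(freqs))
  keep <- freqs > 0
  seqs <- seqs[keep]
  freqs <- freqs[keep]
  n <- sum(freqs)
  if (n < 2) {
    abort("nucleotide diversity needs at least 2 samples",
      class = "haplodiv_sample_error"
    )
  }
  L <- L %||% nchar(seqs[[1]])
  if (L == 0) {
    abort("no comparable columns (L = 0)", class = "haplodiv_geometry_error")
  }
  if (length(seqs) == 1L) {
    return(0)
  }
  d <- pairwise_subst(seq_matrix(seqs), policy = "skip")
  p <- freqs / n
  pi_hat <- 0
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      pi_hat <- pi_hat + 2 * p[i] * p[j] * d[i, j]
    }
  }
  n / (n - 1) * pi_hat / L
}

#' Rarefied haplotype counts by resampling without replacement
#'
#' Adjusts haplotype counts for unequal sample sizes: draws `replications`
#' subsamples of size `k` without replacement and reports the mean and sd
#' of the number of distinct haplotypes, together with the closed-form
#' hypergeometric expectation
#' \deqn{E[K] = \sum_i \Big[1 - \binom{n-f_i}{k} \big/ \binom{n}{k}\Big].}
#' Both are always returned so the Monte-Carlo estimate can be checked
#' against the analytic value.
#'
#' @param freqs Haplotype member counts (sums to `n`).
#' @param k Resample size; must satisfy `k <= n`.
#' @param replications Number of Monte-Carlo draws (classically 1000).
#' @param seed Optional integer seed; the draw is reproducible and leaves
#'   the global RNG state untouched.
#' @return A tibble with columns `k`, `replications`, `mean_nht`, `sd_nht`,
#'   `expected_nht`.
#' @examples
#' rarefy_haplotypes(c(3, 2, 1), k = 3, replications = 200, seed = 1)
#' @export
rarefy_haplotypes <- function(freqs, k, replications = 1000L, seed = NULL) {
  freqs <- as.integer(freqs[freqs > 0])
  n <- sum(freqs)
  k <- as.integer(k)
  if (k > n) {
    abort(sprintf("resample size k = %d exceeds sample size n = %d", k, n),
      class = "haplodiv_rarefaction_error"
    )
  }
  if (k < 1L || replications < 1L) {
    abort("k and replications must be at least 1", class = "haplodiv_rarefaction_error")
  }
  expected <- sum(1 - exp(lchoose(n - freqs, k) - lchoose(n, k)))
  pool <- rep.int(seq_along(freqs), freqs)
  draw <- function() {
    counts <- vapply(
      seq_len(replications),
      function(i) length(unique(pool[sample.int(n, k)])),
      integer(1)
    )
    counts
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(
    k = k, replications = as.integer(replications),
    mean_nht = mean(counts),
    sd_nht = if (replications > 1L) sd(counts) else 0,
    expected_nht = expected
  )
}

#' Per-region haplogroup counts and percentages
#'
#' Counts samples per haplogroup within each region and expresses A, B, C
#' and the pooled rare groups (D, E, F) as percentages of the region total,
#' the layout of classical control-region survey tables. Percentages are
#' kept at full precision; rounding belongs to the report layer
#' ([render_table1()]).
#'
#' @param sample_calls Per-sample call table from [call_samples()] (columns
#'   `region`, `haplogroup`).
#' @return A tibble with one row per region: `region`, `n_total`, `n_ABC`,
#'   `n_DEF`, `nA`, `nB`, `nC`, `pctA`, `pctB`, `pctC`, `pctDEF`.
#' @export
haplogroup_summary <- function(sample_calls) {
  if (nrow(sample_calls) == 0L) {
    abort("no samples in region", class = "haplodiv_empty_region_error")
  }
  sample_calls |>
    group_by(.data$region) |>
    summarise(
      n_total = dplyr::n(),
      nA = sum(.data$haplogroup == "A"),
      nB = sum(.data$haplogroup == "B"),
      nC = sum(.data$haplogroup == "C"),
      n_DEF = sum(.data$haplogroup %in% c("D", "E", "F")),
      .groups = "drop"
    ) |>
    mutate(
      n_ABC = .data$nA + .data$nB + .data$nC,
      pctA = 100 * .data$nA / .data$n_total,
      pctB = 100 * .data$nB / .data$n_total,
      pctC = 100 * .data$nC / .data$n_total,
      pctDEF = 100 * .data$n_DEF / .data$n_total
    ) |>
    select(
      "region", "n_total", "n_ABC", "n_DEF", "nA", "nB", "nC",
      "pctA", "pctB", "pctC", "pctDEF"
    )
}

#' Per-region diversity table
#'
#' Computes, for every region (plus an optional pooled row), the classical
#' control-region survey statistics: haplogroup counts and percentages,
#' number of haplotypes (`nHT`), haplotypes unique to the region (`HTuq`,
#' relative to the other regions of the same run), percentages of samples
#' carrying a UT or a UTd haplotype (UTd includes UTs by definition, so
#' `pctUT <= pctUTd`), number of distinct sub-haplogroups among A/B/C
#' samples, rarefied haplotype count at resample size `k` (`NA` where
#' `n_total < k`; rendered as a dash), and haplotype and nucleotide
#' diversity. Full precision throughout; see [render_table1()] for display
#' rounding.
#'
#' @param sample_calls Per-sample call table from [call_samples()].
#' @param haplotypes Haplotype tibble (`seq` + name column used in
#'   `sample_calls`) for nucleotide diversity.
#' @param k Rarefaction resample size. Required: the choice of `k` (often
#'   the smallest region size) materially affects comparability and is
#'   recorded in the output attributes.
#' @param replications Monte-Carlo replications for rarefaction.
#' @param seed Integer seed making rarefaction reproducible.
#' @param pooled Add a pooled all-samples row labelled `pooled_label`?
#' @param pooled_label Label for the pooled row.
#' @return A tibble of class `region_table`, one row per region, with
#'   attributes `k`, `replications`, `seed`.
#' @export
region_table <- function(sample_calls, haplotypes, k,
                         replications = 1000L, seed = NULL,
                         pooled = TRUE, pooled_label = "Total") {
  if (nrow(sample_calls) == 0L || length(unique(sample_calls$region)) == 0L) {
    out <- region_table_empty()
    return(out)
  }
  hap_name <- if ("name" %in% names(haplotypes)) haplotypes$name else haplotypes$haplotype
  hap_seq <- setNames(haplotypes$seq, hap_name)
  regions <- unique(sample_calls$region)
  # haplotypes private to a single region of this run
  region_sets <- sample_calls |>
    distinct(.data$haplotype, .data$region) |>
    count(.data$haplotype, name = "n_regions")
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(regions) + 1L)
  } else {
    as.list(seed + seq_len(length(regions) + 1L) - 1L)
  }
  one_region <- function(df, this_region, sd_seed, unique_known = TRUE) {
    hs <- haplogroup_summary(df |> mutate(region = this_region))
    freqs <- df |> count(.data$haplotype, name = "f")
    nht <- nrow(freqs)
    htuq <- if (unique_known) {
      sum(region_sets$n_regions[match(freqs$haplotype, region_sets$haplotype)] == 1L)
    } else {
      NA_integer_
    }
    hd <- haplotype_diversity(freqs$f)
    ntd <- nucleotide_diversity(unname(hap_seq[freqs$haplotype]), freqs$f)
    rar <- if (nrow(df) >= k) {
      rarefy_haplotypes(freqs$f, k,
        replications = replications,
        seed = sd_seed
      )
    } else {
      tibble(
        k = as.integer(k), replications = as.integer(replications),
        mean_nht = NA_real_, sd_nht = NA_real_, expected_nht = NA_real_
      )
    }
    hs |>
      mutate(
        region = this_region,
        nHT = nht,
        HTuq = htuq,
        pctUT = 100 * mean(df$ut_status == "UT"),
        pctUTd = 100 * mean(df$ut_status %in% c("UT", "UTd")),
        n_subHG = dplyr::n_distinct(na.omit(df$subhaplogroup)),
        nHT_res = rar$mean_nht,
        nHT_res_sd = rar$sd_nht,
        nHT_res_expected = rar$expected_nht,
        HT_div = hd$H,
        HT_div_sd = hd$sd,
        nt_div = ntd
      )
  }
  rows <- map(seq_along(regions), function(i) {
    one_region(
      sample_calls |> filter(.data$region == regions[[i]]),
      regions[[i]], seeds[[i]]
    )
  })
  if (pooled && length(regions) > 1L) {
    rows <- c(rows, list(
      one_region(sample_calls, pooled_label,
        seeds[[length(seeds)]],
        unique_known = FALSE
      )
    ))
  }
  out <- bind_rows(rows)
  attr(out, "k") <- as.integer(k)
  attr(out, "replications") <- as.integer(replications)
  attr(out, "seed") <- seed
  class(out) <- c("region_table", class(out))
  out
}

region_table_empty <- function() {
  out <- tibble(
    region = character(), n_total = integer(), n_ABC = integer(),
    n_DEF = integer(), nA = integer(), nB = integer(), nC = integer(),
    pctA = double(), pctB = double(), pctC = double(), pctDEF = double(),
    nHT = integer(), HTuq = integer(), pctUT = double(), pctUTd = double(),
    n_subHG = integer(), nHT_res = double(), nHT_res_sd = double(),
    nHT_res_expected = double(), HT_div = double(), HT_div_sd = double(),
    nt_div = double()
  )
  class(out) <- c("region_table", class(out))
  out
}

#' @export
glance.region_table <- function(x, ...) {
  per_region <- x[!is.na(x$HTuq), , drop = FALSE]
  if (nrow(per_region) == 0L) per_region <- x
  tibble(
    n_regions = nrow(per_region),
    n_samples = sum(per_region$n_total),
    n_haplotypes = max(c(x$nHT, 0L)),
    k = attr(x, "k"),
    replications = attr(x, "replications")
  )
}
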