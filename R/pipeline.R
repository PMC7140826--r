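#' Run the full analysis pipeline
#'
#' End-to-end orchestration: read the alignment and metadata, validate
#' geometry, collapse haplotypes, (optionally) match them against a named
#' catalog and name novel ones, classify haplogroups / sub-haplogroups /
#' UT status, compute the per-region diversity table, build and annotate
#' the minimum spanning network, and write the report bundle. All outputs
#' are a pure function of the inputs and `seed`: rerunning with identical
#' inputs yields byte-identical files. Results are computed in full before
#' anything is written, so a failing stage leaves no partial bundle.
#'
#' Files written to `out_dir`: `haplotypes.tsv`, `calls.tsv`,
#' `sample_calls.tsv`, `table1.tsv` (display-rounded),
#' `region_table.json` (full precision + run metadata), `msn_edges.tsv`,
#' `msn_nodes.tsv`, `msn.graphml`, `run_log.json` (parameters, seed and
#' rule-set checksum for provenance).
#'
#' @param alignment_path,metadata_path Aligned FASTA and metadata TSV.
#' @param rules_path Classification rule YAML ([read_rules()] schema).
#' @param catalog_path Optional haplotype catalog (FASTA or TSV).
#' @param k Rarefaction resample size (required; record of the smallest
#'   comparable sample size is a per-study choice).
#' @param replications Rarefaction replications.
#' @param seed Integer seed controlling rarefaction resampling.
#' @param out_dir Output directory, created if needed.
#' @param strict Haplotype identity policy (see [collapse_haplotypes()]).
#' @return Invisibly, a list with `haplotypes`, `calls`, `sample_calls`,
#'   `region_table`, `network` and the output paths.
#' @export
run_pipeline <- function(alignment_path, metadata_path, rules_path,
                         catalog_path = NULL, k, replications = 1000L,
                         seed = 1L, out_dir, strict = TRUE) {
  for (p in c(alignment_path, metadata_path, rules_path, catalog_path)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p),
        class = "haplodiv_config_error"
      )
    }
  }
  rules <- read_rules(rules_path)
  aln <- read_alignment(alignment_path, metadata_path)
  validate_window(aln, rules$map)
  haps <- collapse_haplotypes(aln, strict = strict)
  calls <- call_haplotypes(haps, rules)
  if (!is.null(catalog_path)) {
    catalog <- read_catalog(catalog_path)
    haps <- match_catalog(haps, catalog)
    haps <- name_novel_haplotypes(haps, calls, catalog)
  }
  sc <- call_samples(aln, haps, calls)
  rt <- region_table(sc, haps,
    k = k, replications = replications,
    seed = seed, pooled = TRUE
  )
  hap_names <- if ("name" %in% names(haps)) haps$name else haps$haplotype
  d <- distance_matrix(haps |> mutate(name = hap_names))
  net <- build_msn(d) |> annotate_msn(sc)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    haplotypes = file.path(out_dir, "haplotypes.tsv"),
    calls = file.path(out_dir, "calls.tsv"),
    sample_calls = file.path(out_dir, "sample_calls.tsv"),
    table1 = file.path(out_dir, "table1.tsv"),
    region_json = file.path(out_dir, "region_table.json"),
    edges = file.path(out_dir, "msn_edges.tsv"),
    nodes = file.path(out_dir, "msn_nodes.tsv"),
    graphml = file.path(out_dir, "msn.graphml"),
    log = file.path(out_dir, "run_log.json")
  )
  write_haplotypes(haps, paths$haplotypes)
  readr::write_tsv(calls, paths$calls, progress = FALSE)
  readr::write_tsv(sc, paths$sample_calls, progress = FALSE)
  readr::write_tsv(render_table1(rt), paths$table1, progress = FALSE)
  write_region_json(rt, paths$region_json)
  export_msn(net,
    edges_path = paths$edges, nodes_path = paths$nodes,
    graphml_path = paths$graphml
  )
  log <- list(
    package = "haplodiv",
    version = as.character(utils::packageVersion("haplodiv")),
    seed = seed, k = as.integer(k), replications = as.integer(replications),
    strict_identity = strict,
    rules_checksum = unname(tools::md5sum(rules_path)),
    ut_names = rules$ut$name,
    n_samples = nrow(aln), n_haplotypes = nrow(haps)
  )
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    haplotypes = haps, calls = calls, sample_calls = sc,
    region_table = rt, network = net, paths = paths
  ))
}

#' Render the diversity table at report precision
#'
#' Formats a [region_table()] the way survey tables print it: combined
#' `ABC (DEF)` counts, `count (percent)` columns at one decimal, haplotype
#' diversity at three decimals with its SD, and a dash wherever
#' rarefaction was not computable (`n_total < k`). Rounding happens here
#' only; the underlying table keeps full precision.
#'
#' @param rt A [region_table()].
#' @param digits_pct Decimals for percentages.
#' @param digits_H Decimals for haplotype diversity.
#' @return A character tibble, one row per region.
#' @export
render_table1 <- function(rt, digits_pct = 1L, digits_H = 3L) {
  fmt_pct <- function(x) formatC(round(x, digits_pct), format = "f", digits = digits_pct)
  fmt_H <- function(x) formatC(round(x, digits_H), format = "f", digits = digits_H)
  dash <- function(x, f) ifelse(is.na(x), "-", f(x))
  tibble(
    Region = rt$region,
    `ABC (DEF)` = sprintf("%d (%d)", rt$n_ABC, rt$n_DEF),
    `nA (%)` = sprintf("%d (%s)", rt$nA, fmt_pct(rt$pctA)),
    `nB (%)` = sprintf("%d (%s)", rt$nB, fmt_pct(rt$pctB)),
    `nC (%)` = sprintf("%d (%s)", rt$nC, fmt_pct(rt$pctC)),
    nHT = rt$nHT,
    HTuq = ifelse(is.na(rt$HTuq), "-", as.character(rt$HTuq)),
    `UT (%)` = fmt_pct(rt$pctUT),
    `UTd (%)` = fmt_pct(rt$pctUTd),
    NsubHG = rt$n_subHG,
    nHTres = dash(rt$nHT_res, function(x) formatC(x, format = "f", digits = 2)),
    `HT Diversity (SD)` = sprintf("%s (%s)", fmt_H(rt$HT_div), fmt_H(rt$HT_div_sd))
  )
}

write_region_json <- function(rt, path) {
  payload <- list(
    k = attr(rt, "k"),
    replications = attr(rt, "replications"),
    seed = attr(rt, "seed"),
    regions = as.data.frame(rt)
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null"
  )
  invisible(path)
}

#' @export
autoplot.region_table <- function(object, metric = c(
                                    "HT_div", "pctUTd", "pctUT",
                                    "n_subHG", "nHT_res"
                                  ), ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object) |>
    mutate(region = factor(.data$region, levels = .data$region))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data[[metric]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (metric == "HT_div") {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$HT_div - .data$HT_div_sd,
        ymax = .data$HT_div + .data$HT_div_sd
      ),
      width = 0.2
    )
  }
  p
}
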