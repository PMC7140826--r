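#' Pairwise substitution distance matrix between haplotypes
#'
#' Counts substitutions between every pair of aligned haplotype sequences.
#' Under the default `"skip"` policy, columns carrying a gap or an IUPAC
#' ambiguity code in either sequence are excluded from the count; under
#' `"literal"` every state (including gaps) is compared as-is.
#'
#' @param haps Haplotype tibble (`seq` plus a name column) or a character
#'   vector of sequences.
#' @param policy `"skip"` (default) or `"literal"`.
#' @return A symmetric integer matrix with haplotype names as dimnames and
#'   the policy attached as attribute `policy`.
#' @export
distance_matrix <- function(haps, policy = c("skip", "literal")) {
  policy <- match.arg(policy)
  if (is.character(haps)) {
    seqs <- haps
    labels <- names(haps) %||% sprintf("H%03d", seq_along(haps))
  } else {
    seqs <- haps$seq
    labels <- if ("name" %in% names(haps)) haps$name else haps$haplotype
  }
  d <- pairwise_subst(seq_matrix(seqs), policy = policy)
  dimnames(d) <- list(labels, labels)
  attr(d, "policy") <- policy
  d
}

#' Build the minimum spanning network over haplotype distances
#'
#' Constructs the union of all minimum spanning trees (the Excoffier--Smouse
#' minimum spanning network): a Kruskal-style pass over ascending distance
#' classes in which, within each class, *every* edge joining two components
#' that were distinct at the start of that class is kept. Ties between
#' equally short connections are therefore represented, not broken. Edges
#' present in every MST (the forced backbone) are flagged via
#' `in_all_msts`; the remaining edges are alternative minimum-length
#' connections.
#'
#' @param d Symmetric distance matrix from [distance_matrix()].
#' @return An object of class `haplo_network`: a list with `nodes`
#'   (tibble `name`), `edges` (tibble `from`, `to`, `weight`,
#'   `in_all_msts`) and `mst_weight` (total weight of any single MST).
#' @examples
#' d <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
#'   dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
#' )
#' net <- build_msn(d)
#' net$edges # all three tied edges kept, none forced
#' @export
build_msn <- function(d) {
  n <- nrow(d) %||% 0L
  labels <- rownames(d) %||% character(0)
  empty_edges <- tibble(
    from = character(), to = character(),
    weight = integer(), in_all_msts = logical()
  )
  if (is.null(dim(d)) || n == 0L) {
    return(new_haplo_network(tibble(name = character()), empty_edges, 0L))
  }
  if (n == 1L) {
    return(new_haplo_network(tibble(name = labels), empty_edges, 0L))
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[pairs]
  # union-find over node indices
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- list()
  mst_weight <- 0L
  for (w in sort(unique(ew))) {
    cls <- which(ew == w)
    comp_start <- vapply(seq_len(n), find, integer(1))
    keep <- cls[comp_start[pairs[cls, 1]] != comp_start[pairs[cls, 2]]]
    if (length(keep) == 0L) next
    ku <- comp_start[pairs[keep, 1]]
    kv <- comp_start[pairs[keep, 2]]
    # an edge is in every MST iff it is a bridge of the multigraph of kept
    # class edges over the start-of-class components
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ku), to = as.character(kv)),
      directed = FALSE
    )
    br <- igraph::bridges(g)
    in_all <- seq_along(keep) %in% as.integer(br)
    merged <- 0L
    for (e in seq_along(keep)) {
      ru <- find(pairs[keep[e], 1])
      rv <- find(pairs[keep[e], 2])
      if (ru != rv) {
        parent[ru] <- rv
        merged <- merged + 1L
      }
    }
    mst_weight <- mst_weight + merged * w
    edges[[length(edges) + 1L]] <- tibble(
      from = labels[pairs[keep, 1]],
      to = labels[pairs[keep, 2]],
      weight = as.integer(w),
      in_all_msts = in_all
    )
  }
  edges <- if (length(edges) > 0L) bind_rows(edges) else empty_edges
  new_haplo_network(tibble(name = labels), edges, mst_weight)
}

new_haplo_network <- function(nodes, edges, mst_weight) {
  structure(
    list(nodes = nodes, edges = edges, mst_weight = mst_weight),
    class = "haplo_network"
  )
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "<haplo_network> %d node(s), %d edge(s) (%d alternative), MST weight %d\n",
    nrow(x$nodes), nrow(x$edges), sum(!x$edges$in_all_msts), x$mst_weight
  ))
  invisible(x)
}

#' @export
tidy.haplo_network <- function(x, ...) {
  x$edges
}

#' @export
glance.haplo_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_alternative_edges = sum(!x$edges$in_all_msts),
    mst_weight = x$mst_weight
  )
}

#' Annotate network nodes with frequencies, regions and classification
#'
#' Adds to every node its sample frequency, the regions it occurs in,
#' whether it is shared between regions or unique (private) to one, its
#' haplogroup/sub-haplogroup and UT flag — the annotations carried by
#' published MS-network figures.
#'
#' @param net A [build_msn()] network.
#' @param sample_calls Per-sample call table from [call_samples()].
#' @return The network with an extended `nodes` tibble (`name`, `n`,
#'   `regions` list-column, `n_regions`, `status` shared/unique,
#'   `haplogroup`, `subhaplogroup`, `ut`).
#' @export
annotate_msn <- function(net, sample_calls) {
  missing <- setdiff(net$nodes$name, sample_calls$haplotype)
  if (length(missing) > 0L) {
    abort(
      sprintf("network node '%s' has no sample call", missing[1]),
      class = "haplodiv_annotation_error"
    )
  }
  ann <- sample_calls |>
    group_by(.data$haplotype) |>
    summarise(
      n = dplyr::n(),
      regions = list(sort(unique(.data$region))),
      haplogroup = .data$haplogroup[1],
      subhaplogroup = .data$subhaplogroup[1],
      ut = .data$ut_status[1] == "UT",
      .groups = "drop"
    ) |>
    mutate(
      n_regions = map_int(.data$regions, length),
      status = ifelse(.data$n_regions > 1L, "shared", "unique")
    )
  net$nodes <- net$nodes |>
    left_join(ann, by = c(name = "haplotype")) |>
    select(
      "name", "n", "regions", "n_regions", "status",
      "haplogroup", "subhaplogroup", "ut"
    )
  net
}

#' Expand multi-step edges through hypothetical intermediaries
#'
#' Rendering convention for MS-network figures: an edge of weight `w > 1`
#' becomes a chain of `w` unit steps through `w - 1` hypothetical
#' intermediary nodes (the "black dots"). A display-layer transform only;
#' the analytic network keeps weighted edges.
#'
#' @param net A `haplo_network`.
#' @return A `haplo_network` whose edges all have weight 1; hypothetical
#'   nodes are named `med_<from>_<to>_<i>` and marked by
#'   `hypothetical = TRUE` in `nodes`.
#' @export
expand_msn <- function(net) {
  nodes <- net$nodes |> mutate(hypothetical = FALSE)
  if (nrow(net$edges) == 0L) {
    net$nodes <- nodes
    return(net)
  }
  pieces <- pmap(
    net$edges[, c("from", "to", "weight", "in_all_msts")],
    function(from, to, weight, in_all_msts) {
      if (weight == 1L) {
        return(list(
          edges = tibble(
            from = from, to = to, weight = 1L,
            in_all_msts = in_all_msts
          ),
          meds = character(0)
        ))
      }
      meds <- sprintf("med_%s_%s_%d", from, to, seq_len(weight - 1L))
      chain <- c(from, meds, to)
      list(
        edges = tibble(
          from = chain[-length(chain)], to = chain[-1],
          weight = 1L, in_all_msts = in_all_msts
        ),
        meds = meds
      )
    }
  )
  med_names <- unlist(map(pieces, "meds"))
  if (length(med_names) > 0L) {
    med_nodes <- tibble(name = med_names)
    for (col in setdiff(names(nodes), "name")) {
      med_nodes[[col]] <- NA
    }
    med_nodes$hypothetical <- TRUE
    nodes <- bind_rows(nodes, med_nodes)
  }
  new_net <- new_haplo_network(nodes, bind_rows(map(pieces, "edges")), net$mst_weight)
  new_net
}

#' Export a haplotype network
#'
#' Writes the edge list (`u`, `v`, `weight`, `in_all_msts`) and node table
#' as TSV and the full graph as GraphML. No layout is computed (published
#' MS networks are drawn manually).
#'
#' @param net A (preferably annotated) `haplo_network`.
#' @param edges_path,nodes_path,graphml_path Output paths; `NULL` skips
#'   that file.
#' @return `net`, invisibly.
#' @export
export_msn <- function(net, edges_path = NULL, nodes_path = NULL,
                       graphml_path = NULL) {
  flat_nodes <- net$nodes
  if ("regions" %in% names(flat_nodes)) {
    flat_nodes <- flat_nodes |>
      mutate(regions = map_chr(.data$regions, function(r) {
        if (length(r) == 0L || all(is.na(r))) NA_character_ else paste(r, collapse = ",")
      }))
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(
      net$edges |> dplyr::rename(u = "from", v = "to"),
      edges_path,
      progress = FALSE
    )
  }
  if (!is.null(nodes_path)) {
    readr::write_tsv(flat_nodes, nodes_path, progress = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges,
      directed = FALSE,
      vertices = as.data.frame(flat_nodes)
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' @export
autoplot.haplo_network <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot())
  }
  g <- igraph::graph_from_data_frame(
    object$edges,
    directed = FALSE,
    vertices = object$nodes$name
  )
  lay <- withr::with_seed(
    seed,
    igraph::layout_with_fr(g, weights = object$edges$weight)
  )
  pos <- tibble(
    name = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2]
  ) |>
    left_join(object$nodes, by = "name")
  seg <- object$edges |>
    left_join(pos |> select("name", "x", "y"), by = c(from = "name")) |>
    left_join(pos |> select("name", xend = "x", yend = "y"), by = c(to = "name"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linetype = .data$in_all_msts
      ),
      colour = "grey40"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      name = "in all MSTs"
    ) +
    ggplot2::theme_void()
  if ("haplogroup" %in% names(pos) && "n" %in% names(pos)) {
    p <- p + ggplot2::geom_point(
      data = pos,
      ggplot2::aes(
        x = .data$x, y = .data$y, size = .data$n,
        colour = .data$haplogroup
      )
    )
  } else {
    p <- p + ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y),
      size = 3
    )
  }
  p
}
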