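#' Collapse aligned samples into distinct haplotypes
#'
#' Groups samples carrying identical sequences into haplotypes, the step
#' performed with DnaSP-style haplotype calling in classical control-region
#' studies. Under the default strict identity policy two sequences belong to
#' the same haplotype iff they match at every column, with gaps and IUPAC
#' ambiguity codes compared literally. With `strict = FALSE`, ambiguity
#' codes (including `N`) act as wildcards that match any base; samples are
#' then greedily merged, in sequence-lexicographic order, into the first
#' compatible haplotype (wildcard matching is not transitive, so a
#' deterministic processing order is part of the policy).
#'
#' Output order is deterministic: descending member count, then
#' lexicographic sequence. Haplotypes receive provisional ids `H001`,
#' `H002`, ... until matched against a catalog.
#'
#' @param aln Alignment tibble from [read_alignment()].
#' @param strict Logical; literal comparison of ambiguity codes (default).
#' @return A tibble with columns `haplotype`, `seq`, `n`, `samples`
#'   (list-column of sample ids) and `regions` (list-column of region
#'   labels, one per member).
#' @examples
#' aln <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s3", "s4"),
#'   region = "R1",
#'   seq = c("ACGT", "ACGT", "ACGA", "TCGA")
#' )
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(aln, strict = TRUE) {
  if (nrow(aln) == 0L) {
    return(tibble(
      haplotype = character(), seq = character(), n = integer(),
      samples = list(), regions = list()
    ))
  }
  seq_matrix(aln$seq) # geometry check
  if (strict) {
    key <- aln$seq
  } else {
    key <- wildcard_group_keys(aln)
  }
  out <- aln |>
    mutate(.key = key) |>
    group_by(.data$.key) |>
    summarise(
      seq = .data$seq[1],
      n = dplyr::n(),
      samples = list(.data$sample_id),
      regions = list(.data$region),
      .groups = "drop"
    ) |>
    select(-".key") |>
    arrange(dplyr::desc(.data$n), .data$seq) |>
    mutate(haplotype = sprintf("H%03d", row_number())) |>
    select("haplotype", "seq", "n", "samples", "regions")
  out
}

# Greedy wildcard grouping: ambiguity codes/N match any base. Samples are
# processed in (seq, sample_id) order; each joins the first existing group
# whose representative is compatible, and the representative is refined to
# the member with fewest ambiguous characters.
wildcard_group_keys <- function(aln) {
  ord <- order(aln$seq, aln$sample_id)
  m <- seq_matrix(aln$seq)
  base <- is_base_code(m)
  gapc <- utf8ToInt("-")
  reps <- integer(0) # column indices of group representatives
  key <- integer(nrow(aln))
  compatible <- function(i, j) {
    # gaps literal; ambiguity wildcards
    gi <- m[, i] == gapc
    gj <- m[, j] == gapc
    if (any(gi != gj)) {
      return(FALSE)
    }
    both <- base[, i] & base[, j]
    all(m[both, i] == m[both, j])
  }
  n_ambig <- colSums(!base & m != gapc)
  for (i in ord) {
    hit <- 0L
    for (g in seq_along(reps)) {
      if (compatible(i, reps[g])) {
        hit <- g
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    } else if (n_ambig[i] < n_ambig[reps[hit]]) {
      reps[hit] <- i
    }
    key[i] <- hit
  }
  aln$seq[reps][key]
}

#' Read a haplotype catalog
#'
#' A catalog names known haplotypes (e.g. `A17`, `B050`, `E005`) and their
#' aligned sequences. Accepted formats: FASTA (record id = haplotype name)
#' or a two-column TSV with header `name`, `seq`.
#'
#' @param path Path to the catalog file.
#' @return A tibble with columns `name`, `seq`.
#' @export
read_catalog <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    recs <- Biostrings::readBStringSet(path)
    cat <- tibble(
      name = sub("\\s.*$", "", names(recs)),
      seq = toupper(unname(as.character(recs)))
    )
  } else {
    cat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
      mutate(seq = toupper(.data$seq))
  }
  validate_catalog(cat)
}

validate_catalog <- function(catalog) {
  if (!all(c("name", "seq") %in% names(catalog))) {
    abort("catalog needs columns 'name' and 'seq'", class = "haplodiv_catalog_error")
  }
  if (anyDuplicated(catalog$name)) {
    abort(sprintf(
      "catalog name '%s' is duplicated",
      catalog$name[duplicated(catalog$name)][1]
    ), class = "haplodiv_catalog_error")
  }
  if (anyDuplicated(catalog$seq)) {
    dup <- catalog$seq[duplicated(catalog$seq)][1]
    nms <- catalog$name[catalog$seq == dup]
    abort(
      sprintf(
        "catalog entries %s share an identical sequence",
        paste(sQuote(nms), collapse = ", ")
      ),
      class = "haplodiv_catalog_error"
    )
  }
  as_tibble(catalog)
}

#' Match observed haplotypes against a named catalog
#'
#' Each observed haplotype either takes its catalog name (exact sequence
#' identity) or is flagged novel with a provisional `NOVEL-k` name; use
#' [name_novel_haplotypes()] after classification to assign final
#' letter+integer names in the catalog's scheme.
#'
#' @param haps Haplotype tibble from [collapse_haplotypes()].
#' @param catalog Catalog tibble (`name`, `seq`), see [read_catalog()].
#' @return `haps` with columns `name` (catalog or provisional) and `novel`
#'   (logical).
#' @export
match_catalog <- function(haps, catalog) {
  catalog <- validate_catalog(catalog)
  idx <- match(haps$seq, catalog$seq)
  novel <- is.na(idx)
  name <- catalog$name[idx]
  name[novel] <- sprintf("NOVEL-%d", seq_len(sum(novel)))
  haps |> mutate(name = name, novel = novel)
}

#' Assign final names to novel haplotypes
#'
#' Novel haplotypes are named `<haplogroup letter><next free integer>` in
#' the catalog's numbering, e.g. a catalog topping out at `A227` yields new
#' names `A228`, `A229`, ...; zero-padding follows the widest suffix already
#' used for that letter (`B049` begets `B050`).
#'
#' @param haps Output of [match_catalog()].
#' @param calls Classification tibble from [call_haplotypes()] (column
#'   `haplogroup`), keyed by `haplotype`.
#' @param catalog The catalog used for matching.
#' @return `haps` with provisional `NOVEL-k` names replaced.
#' @export
name_novel_haplotypes <- function(haps, calls, catalog) {
  if (!any(haps$novel)) {
    return(haps)
  }
  hg <- calls$haplogroup[match(haps$haplotype, calls$haplotype)]
  cat_letter <- sub("^([A-Za-z]+).*$", "\\1", catalog$name)
  cat_num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", catalog$name)))
  new_names <- haps$name
  for (letter in unique(hg[haps$novel])) {
    sel <- which(haps$novel & hg == letter)
    nums <- cat_num[cat_letter == letter & !is.na(cat_num)]
    width <- if (length(nums) > 0L) {
      max(nchar(sub("^[A-Za-z]+", "", catalog$name[cat_letter == letter])))
    } else {
      1L
    }
    start <- if (length(nums) > 0L) max(nums) + 1L else 1L
    new_names[sel] <- sprintf(paste0("%s%0", width, "d"), letter, start + seq_along(sel) - 1L)
  }
  haps |> mutate(name = new_names)
}

#' Write the haplotype table
#'
#' @param haps Haplotype tibble (optionally named/matched).
#' @param path Output TSV path.
#' @return `haps`, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  flat <- haps |>
    mutate(
      samples = map_chr(.data$samples, paste, collapse = ","),
      regions = map_chr(.data$regions, function(r) {
        paste(names(sort(table(r), decreasing = TRUE)), collapse = ",")
      })
    )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(haps)
}
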