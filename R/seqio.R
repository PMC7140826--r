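#' Coordinate map between reference positions and alignment columns
#'
#' The analysed fragment is addressed in two coordinate systems: 1-based
#' inclusive positions on the mitochondrial reference (the numbering used in
#' diagnostic-mutation tables) and alignment columns. A `coord_map` is the
#' single conversion point between the two. The default spans reference
#' positions 15,458--16,039, the 582-column control-region window commonly
#' analysed for domestic dogs.
#'
#' @param ref_start First reference position covered by the alignment
#'   (1-based, inclusive).
#' @param ref_end Last reference position covered (1-based, inclusive).
#' @return A `coord_map` object with fields `ref_start`, `ref_end` and
#'   `columns`.
#' @examples
#' cm <- coord_map()
#' cm$columns # 582
#' ref_to_col(cm, 15458) # 1
#' @export
coord_map <- function(ref_start = 15458L, ref_end = 16039L) {
  ref_start <- as.integer(ref_start)
  ref_end <- as.integer(ref_end)
  if (ref_start >= ref_end) {
    abort("ref_start must be strictly less than ref_end",
      class = "haplodiv_coordinate_error"
    )
  }
  structure(
    list(
      ref_start = ref_start,
      ref_end = ref_end,
      columns = ref_end - ref_start + 1L
    ),
    class = "coord_map"
  )
}

#' @export
print.coord_map <- function(x, ...) {
  cat(sprintf(
    "<coord_map> reference %d..%d (1-based, inclusive), %d alignment columns\n",
    x$ref_start, x$ref_end, x$columns
  ))
  invisible(x)
}

#' Convert reference positions to alignment columns
#'
#' @param map A [coord_map()].
#' @param pos Integer vector of 1-based reference positions.
#' @return Integer vector of 1-based alignment columns.
#' @export
ref_to_col <- function(map, pos) {
  pos <- as.integer(pos)
  out <- pos - map$ref_start + 1L
  if (any(out < 1L | out > map$columns)) {
    bad <- pos[out < 1L | out > map$columns][1]
    abort(
      sprintf(
        "reference position %d falls outside the mapped window %d..%d",
        bad, map$ref_start, map$ref_end
      ),
      class = "haplodiv_coordinate_error"
    )
  }
  out
}

#' Read an aligned FASTA together with its sample metadata
#'
#' Reads a multi-record (wrapped or unwrapped) FASTA of pre-aligned
#' control-region sequences and a tab-separated metadata table with columns
#' `sample_id` and `region` (extra columns such as `breed` or `country` are
#' carried along). Sequences are uppercased; the alignment must be
#' rectangular; every FASTA identifier must appear in the metadata.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the metadata TSV.
#' @param regions Optional character vector declaring the allowed region
#'   labels; labels outside this set raise an error.
#' @return A tibble with one row per sample and columns `sample_id`,
#'   `region`, `seq` (plus any extra metadata columns). The alignment width
#'   is attached as attribute `L`.
#' @seealso [write_alignment()], [validate_window()]
#' @export
read_alignment <- function(fasta_path, metadata_path, regions = NULL) {
  recs <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(as.character(recs))
  ids <- sub("\\s.*$", "", names(recs))
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "region") %in% names(meta))) {
    abort("metadata TSV must have columns 'sample_id' and 'region'",
      class = "haplodiv_metadata_error"
    )
  }
  alignment_from_parts(ids, seqs, meta, regions = regions)
}

# Shared assembly/validation used by read_alignment() and tests that build
# datasets in memory.
alignment_from_parts <- function(ids, seqs, meta, regions = NULL) {
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate sample id '%s' in FASTA",
      ids[duplicated(ids)][1]
    ), class = "haplodiv_metadata_error")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref_len <- lens[[1]]
    off <- ids[lens != ref_len][1]
    abort(
      sprintf(
        "alignment is not rectangular: sequence '%s' has length %d, expected %d",
        off, lens[ids == off][1], ref_len
      ),
      class = "haplodiv_geometry_error"
    )
  }
  check_alphabet(seqs, ids)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf(
      "FASTA id '%s' not present in metadata",
      missing[1]
    ), class = "haplodiv_metadata_error")
  }
  out <- tibble(sample_id = ids, seq = unname(seqs)) |>
    left_join(meta, by = "sample_id") |>
    select("sample_id", "region", "seq", dplyr::everything())
  if (!is.null(regions) && !all(out$region %in% regions)) {
    bad <- setdiff(out$region, regions)[1]
    abort(sprintf(
      "region label '%s' is not in the declared region set",
      bad
    ), class = "haplodiv_metadata_error")
  }
  attr(out, "L") <- unname(nchar(out$seq[1] %||% character(0))[1])
  out
}

#' Write an alignment back to FASTA + metadata TSV
#'
#' Inverse of [read_alignment()]: round-tripping preserves `sample_id`,
#' `region` and `seq` exactly.
#'
#' @param aln Alignment tibble as returned by [read_alignment()].
#' @param fasta_path,metadata_path Output paths.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path) {
  set <- Biostrings::BStringSet(setNames(aln$seq, aln$sample_id))
  Biostrings::writeXStringSet(set, fasta_path)
  meta <- aln |> select(-"seq")
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  invisible(aln)
}

#' Validate alignment geometry against a coordinate map
#'
#' Confirms the alignment width equals the mapped window and profiles each
#' column's gap and ambiguity fractions. Columns where half or more of the
#' samples carry a gap or an ambiguity code are flagged for inspection.
#'
#' @param aln Alignment tibble.
#' @param map A [coord_map()]; the expected window.
#' @return An object of class `alignment_validation`: a list with `ok`,
#'   a per-column `columns` tibble (`column`, `ref_pos`, `gap_frac`,
#'   `ambig_frac`, `flagged`) and a `region_counts` tibble.
#' @export
validate_window <- function(aln, map = coord_map()) {
  L <- nchar(aln$seq[1] %||% "")
  if (nrow(aln) == 0L) {
    abort("empty alignment", class = "haplodiv_geometry_error")
  }
  if (L != map$columns) {
    abort(
      sprintf(
        "column count mismatch: coordinate map %d..%d expects %d columns, alignment has %d",
        map$ref_start, map$ref_end, map$columns, L
      ),
      class = "haplodiv_coordinate_error"
    )
  }
  m <- seq_matrix(aln$seq)
  gap <- rowMeans(m == utf8ToInt("-"))
  ambig <- rowMeans(!is_base_code(m) & m != utf8ToInt("-"))
  cols <- tibble(
    column = seq_len(L),
    ref_pos = map$ref_start + seq_len(L) - 1L,
    gap_frac = gap,
    ambig_frac = ambig,
    flagged = gap >= 0.5 | ambig >= 0.5
  )
  structure(
    list(
      ok = TRUE,
      n_samples = nrow(aln),
      columns = cols,
      region_counts = aln |> count(.data$region, name = "n")
    ),
    class = "alignment_validation"
  )
}

#' @export
print.alignment_validation <- function(x, ...) {
  cat(sprintf(
    "<alignment_validation> %d samples x %d columns; %d flagged column(s)\n",
    x$n_samples, nrow(x$columns), sum(x$columns$flagged)
  ))
  print(x$region_counts)
  invisible(x)
}
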