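# Shared fixtures: a tiny hand-built rule set over a 20-column window, and
# in-memory alignment builders. Everything is constructed in code; no data
# files.

tiny_map <- function() coord_map(101L, 120L)

# Base sequence of 20 A's; haplogroups are diagnosed at positions 101-104,
# marked sub-haplogroups at 105-107 (c1/c2 share position 107 with
# different required bases).
tiny_base <- function() strrep("A", 20)

tiny_rules <- function(ut_seqs = NULL) {
  site <- function(pos, base) tibble::tibble(pos = pos, base = base)
  nosite <- tibble::tibble(pos = integer(), base = character())
  uts <- ut_seqs %||% tibble::tibble(
    name = c("A1", "B1", "C1"),
    seq = c(
      tiny_seq(hg = "A"),
      tiny_seq(hg = "B"),
      tiny_seq(hg = "C", extra = c(`107` = "C"))
    )
  )
  haplo_rules(
    haplogroups = tibble::tibble(
      name = c("A", "B", "C", "E"),
      sites = list(site(101L, "G"), site(102L, "C"), site(103L, "T"), site(104L, "C"))
    ),
    subhaplogroups = tibble::tibble(
      label = c("a2", "a1", "b2", "b1", "c1", "c2"),
      parent = c("A", "A", "B", "B", "C", "C"),
      sites = list(
        site(105L, "C"), nosite,
        site(106L, "C"), nosite,
        site(107L, "C"), site(107L, "G")
      )
    ),
    fallbacks = c(A = "a1", B = "b1"),
    universal_types = uts,
    map = tiny_map()
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a 20-column sequence carrying a haplogroup's diagnostic base plus
# arbitrary extra substitutions given as c(`ref_pos` = "BASE").
tiny_seq <- function(hg = "A", extra = character(0)) {
  chars <- strsplit(tiny_base(), "")[[1]]
  hg_site <- c(A = 101L, B = 102L, C = 103L, E = 104L)
  hg_base <- c(A = "G", B = "C", C = "T", E = "C")
  chars[hg_site[[hg]] - 100L] <- hg_base[[hg]]
  for (p in names(extra)) chars[as.integer(p) - 100L] <- extra[[p]]
  paste(chars, collapse = "")
}

make_aln <- function(seqs, regions = "R1", ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  regions <- rep_len(regions, length(seqs))
  out <- tibble::tibble(sample_id = ids, region = regions, seq = seqs)
  attr(out, "L") <- nchar(seqs[1])
  out
}

write_tmp_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

write_tmp_meta <- function(ids, regions, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tibble::tibble(sample_id = ids, region = regions), path)
  path
}
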