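# Internal sequence helpers shared by the classification, diversity and
# network modules. Sequences are handled as integer code matrices (one
# column per sequence) so pairwise comparisons vectorise.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
ALLOWED_CHARS <- c(DNA_BASES, IUPAC_AMBIG, "-")

BASE_CODES <- vapply(DNA_BASES, utf8ToInt, integer(1))

# L x n integer matrix of character codes; errors if lengths are ragged.
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort("sequences have unequal lengths; an aligned rectangular set is required",
      class = "haplodiv_geometry_error"
    )
  }
  m <- vapply(seqs, utf8ToInt, integer(lens[[1]]), USE.NAMES = FALSE)
  if (is.null(dim(m))) m <- matrix(m, nrow = lens[[1]])
  m
}

is_base_code <- function(m) {
  m == BASE_CODES[["A"]] | m == BASE_CODES[["C"]] |
    m == BASE_CODES[["G"]] | m == BASE_CODES[["T"]]
}

# Substitution distance between columns i and j of a code matrix.
# Columns where either sequence is a gap or an ambiguity code are skipped
# ("skip" policy) or counted as ordinary states ("literal").
pairwise_subst <- function(m, policy = c("skip", "literal")) {
  policy <- match.arg(policy)
  n <- ncol(m)
  d <- matrix(0L, n, n)
  if (n < 2L) {
    return(d)
  }
  base <- is_base_code(m)
  for (i in seq_len(n - 1L)) {
    xi <- m[, i]
    rest <- (i + 1L):n
    neq <- m[, rest, drop = FALSE] != xi
    if (policy == "skip") {
      neq <- neq & base[, rest, drop = FALSE] & base[, i]
    }
    d[i, rest] <- d[rest, i] <- colSums(neq)
  }
  d
}

# Distances from each column of m (queries) to each column of u (refs).
cross_subst <- function(m, u, policy = c("skip", "literal")) {
  policy <- match.arg(policy)
  out <- matrix(0L, ncol(m), ncol(u))
  base_m <- is_base_code(m)
  base_u <- is_base_code(u)
  for (j in seq_len(ncol(u))) {
    neq <- m != u[, j]
    if (policy == "skip") neq <- neq & base_m & base_u[, j]
    out[, j] <- colSums(neq)
  }
  out
}

check_alphabet <- function(seqs, ids = NULL) {
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% ALLOWED_CHARS)
    if (length(bad) > 0L) {
      id <- if (is.null(ids)) i else ids[[i]]
      abort(
        sprintf(
          "illegal character '%s' at alignment column %d of sequence '%s' (allowed: A C G T, IUPAC ambiguity codes, '-')",
          chars[bad[1]], bad[1], id
        ),
        class = "haplodiv_alphabet_error"
      )
    }
  }
  invisible(seqs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
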