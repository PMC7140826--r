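#' Build a classification rule set
#'
#' A rule set carries the diagnostic-mutation definitions used to assign
#' haplogroups (A--F) and sub-haplogroups (a1--a6, b1, b2, c1, c2), plus
#' the set of universal-type (UT) haplotypes. Diagnostic sites are
#' `(reference position, required base)` pairs on the 1-based reference
#' numbering; the [coord_map()] inside the rule set converts them to
#' alignment columns. Rule order is significant: the first rule whose
#' diagnostic sites all match wins. A rule with zero sites matches
#' everything and so acts as a catch-all when ordered last (the
#' conventional reading of a1/b1 as "the unmarked part" of their
#' haplogroup); explicit fallbacks may be configured as well.
#'
#' Diagnostic-mutation tables are study-specific configuration, not part of
#' the package: supply them from the literature or generate a synthetic set
#' with [make_rules()].
#'
#' @param haplogroups Tibble `name`, `sites` (list-column of tibbles with
#'   `pos`, `base`), in match order.
#' @param subhaplogroups Tibble `label`, `parent`, `sites`, in match order.
#' @param fallbacks Named character vector, e.g. `c(A = "a1", B = "b1")`.
#' @param universal_types Tibble `name`, `seq` of UT haplotypes.
#' @param map A [coord_map()] giving the reference window.
#' @return An object of class `haplo_rules`.
#' @export
haplo_rules <- function(haplogroups, subhaplogroups, fallbacks,
                        universal_types, map = coord_map()) {
  stopifnot(all(c("name", "sites") %in% names(haplogroups)))
  stopifnot(all(c("label", "parent", "sites") %in% names(subhaplogroups)))
  if (!all(subhaplogroups$parent %in% c("A", "B", "C"))) {
    abort("sub-haplogroup parents must be A, B or C", class = "haplodiv_rules_error")
  }
  if (!all(c("name", "seq") %in% names(universal_types))) {
    abort("universal_types needs columns 'name' and 'seq'", class = "haplodiv_rules_error")
  }
  structure(
    list(
      haplogroups = as_tibble(haplogroups),
      subhaplogroups = as_tibble(subhaplogroups),
      fallbacks = fallbacks,
      ut = as_tibble(universal_types),
      map = map
    ),
    class = "haplo_rules"
  )
}

#' @export
print.haplo_rules <- function(x, ...) {
  cat(sprintf(
    "<haplo_rules> %d haplogroup rule(s), %d sub-haplogroup rule(s), %d universal type(s)\n",
    nrow(x$haplogroups), nrow(x$subhaplogroups), nrow(x$ut)
  ))
  cat(sprintf(
    "  reference window %d..%d\n",
    x$map$ref_start, x$map$ref_end
  ))
  invisible(x)
}

#' Read / write a rule set as YAML
#'
#' The on-disk schema has blocks `coordinates` (`ref_start`, `ref_end`),
#' `haplogroups` (list of `{name, sites: [{pos, base}, ...]}`),
#' `subhaplogroups` (`{label, parent, sites}`), `fallbacks` (map) and
#' `universal_types` (list of `{name, seq}`).
#'
#' @param path YAML file path.
#' @return For `read_rules()`, a `haplo_rules` object.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  sites_tbl <- function(sites) {
    if (length(sites) == 0L) {
      return(tibble(pos = integer(), base = character()))
    }
    tibble(
      pos = map_int(sites, function(s) as.integer(s$pos)),
      base = map_chr(sites, function(s) toupper(s$base))
    )
  }
  haplo_rules(
    haplogroups = tibble(
      name = map_chr(y$haplogroups, "name"),
      sites = map(y$haplogroups, function(h) sites_tbl(h$sites))
    ),
    subhaplogroups = tibble(
      label = map_chr(y$subhaplogroups, "label"),
      parent = map_chr(y$subhaplogroups, "parent"),
      sites = map(y$subhaplogroups, function(h) sites_tbl(h$sites))
    ),
    fallbacks = unlist(y$fallbacks %||% list()),
    universal_types = tibble(
      name = map_chr(y$universal_types, "name"),
      seq = toupper(map_chr(y$universal_types, "seq"))
    ),
    map = coord_map(y$coordinates$ref_start, y$coordinates$ref_end)
  )
}

#' @rdname read_rules
#' @param rules A `haplo_rules` object.
#' @return For `write_rules()`, `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  sites_list <- function(sites) {
    pmap(sites, function(pos, base) list(pos = as.integer(pos), base = base))
  }
  y <- list(
    coordinates = list(
      ref_start = rules$map$ref_start,
      ref_end = rules$map$ref_end
    ),
    haplogroups = pmap(rules$haplogroups, function(name, sites) {
      list(name = name, sites = sites_list(sites))
    }),
    subhaplogroups = pmap(rules$subhaplogroups, function(label, parent, sites) {
      list(label = label, parent = parent, sites = sites_list(sites))
    }),
    fallbacks = as.list(rules$fallbacks),
    universal_types = pmap(rules$ut, function(name, seq) {
      list(name = name, seq = seq)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# TRUE where every diagnostic site of `sites` matches; chars is the split
# sequence, map the coord_map.
sites_match <- function(chars, sites, map) {
  if (nrow(sites) == 0L) {
    return(TRUE)
  }
  cols <- ref_to_col(map, sites$pos)
  all(chars[cols] == sites$base)
}

site_audit <- function(chars, sites, map) {
  if (nrow(sites) == 0L) {
    return("catch-all")
  }
  cols <- ref_to_col(map, sites$pos)
  paste(sprintf("%d=%s", sites$pos, chars[cols]), collapse = ",")
}

#' Assign haplogroups from diagnostic mutations
#'
#' First-match-wins over the configured haplogroup rules: a sequence is
#' assigned to the first haplogroup whose diagnostic sites all carry the
#' required base. A sequence matching no rule raises an error naming the
#' nearest rule and its mismatching sites.
#'
#' @param seqs Character vector of aligned sequences (or a haplotype tibble
#'   column).
#' @param rules A [haplo_rules()] rule set.
#' @return Character vector of haplogroup letters.
#' @export
assign_haplogroup <- function(seqs, rules) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(rules$haplogroups))) {
      if (sites_match(chars, rules$haplogroups$sites[[i]], rules$map)) {
        return(rules$haplogroups$name[[i]])
      }
    }
    # no rule matched: report the rule with fewest mismatching sites
    mism <- map_int(rules$haplogroups$sites, function(st) {
      cols <- ref_to_col(rules$map, st$pos)
      sum(chars[cols] != st$base)
    })
    best <- which.min(mism)
    st <- rules$haplogroups$sites[[best]]
    cols <- ref_to_col(rules$map, st$pos)
    bad <- which(chars[cols] != st$base)
    abort(
      sprintf(
        "sequence matches no haplogroup rule; nearest is '%s' (mismatch at %s)",
        rules$haplogroups$name[[best]],
        paste(sprintf(
          "%d: found %s, need %s", st$pos[bad], chars[cols][bad],
          st$base[bad]
        ), collapse = "; ")
      ),
      class = "haplodiv_unclassified_error"
    )
  }, character(1), USE.NAMES = FALSE)
}

#' Assign sub-haplogroups within haplogroups A, B and C
#'
#' For haplogroups A--C the first matching sub-rule of that parent wins;
#' when none matches, the configured fallback label (conventionally `a1`
#' for A and `b1` for B, the "unmarked" parts of those haplogroups)
#' applies. Haplogroups D--F carry no sub-haplogroup (`NA`). Haplogroup C
#' with no matching rule and no fallback is an error.
#'
#' @inheritParams assign_haplogroup
#' @param haplogroups Character vector of previously assigned letters.
#' @return Character vector of sub-haplogroup labels (`NA` outside A--C).
#' @export
assign_subhaplogroup <- function(seqs, haplogroups, rules) {
  stopifnot(length(seqs) == length(haplogroups))
  out <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    hg <- haplogroups[[i]]
    if (!hg %in% c("A", "B", "C")) next
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    sub <- rules$subhaplogroups |> filter(.data$parent == hg)
    hit <- NA_character_
    for (j in seq_len(nrow(sub))) {
      if (sites_match(chars, sub$sites[[j]], rules$map)) {
        hit <- sub$label[[j]]
        break
      }
    }
    if (is.na(hit)) hit <- unname(rules$fallbacks[hg])
    if (is.na(hit) || is.null(hit)) {
      abort(
        sprintf(
          "haplogroup %s sequence matches no sub-haplogroup rule and no fallback is configured",
          hg
        ),
        class = "haplodiv_unclassified_error"
      )
    }
    out[[i]] <- hit
  }
  out
}

#' Classify haplotypes as universal type (UT), UT-derived (UTd) or other
#'
#' Computes each sequence's minimum substitution distance to the rule set's
#' UT haplotypes (columns with a gap or ambiguity code in either sequence
#' are excluded, matching the network distance policy) and classifies:
#' distance 0 is a UT, exactly 1 a UTd, 2 or more "other". In summary
#' statistics the UTd proportion conventionally includes UTs ("a UT or one
#' mutation from a UT").
#'
#' @inheritParams assign_haplogroup
#' @return A tibble with columns `ut_status` (factor UT/UTd/other),
#'   `min_dist_to_ut` and `nearest_ut`.
#' @export
classify_ut <- function(seqs, rules) {
  if (nrow(rules$ut) == 0L) {
    abort("rule set contains no universal-type haplotypes",
      class = "haplodiv_config_error"
    )
  }
  if (length(seqs) == 0L) {
    return(tibble(
      ut_status = factor(character(), levels = c("UT", "UTd", "other")),
      min_dist_to_ut = integer(), nearest_ut = character()
    ))
  }
  m <- seq_matrix(seqs)
  u <- seq_matrix(rules$ut$seq)
  if (nrow(m) != nrow(u)) {
    abort("universal-type sequences are not aligned to the same columns as the input",
      class = "haplodiv_geometry_error"
    )
  }
  d <- cross_subst(m, u, policy = "skip")
  mind <- apply(d, 1L, min)
  nearest <- rules$ut$name[apply(d, 1L, which.min)]
  status <- ifelse(mind == 0L, "UT", ifelse(mind == 1L, "UTd", "other"))
  tibble(
    ut_status = factor(status, levels = c("UT", "UTd", "other")),
    min_dist_to_ut = as.integer(mind),
    nearest_ut = nearest
  )
}

#' Classify every haplotype: haplogroup, sub-haplogroup and UT status
#'
#' One call per haplotype, deterministic, with an audit column recording the
#' diagnostic sites that matched.
#'
#' @param haps Haplotype tibble (from [collapse_haplotypes()]; any tibble
#'   with columns `haplotype` and `seq` works).
#' @param rules A [haplo_rules()] rule set.
#' @return A tibble with columns `haplotype`, `haplogroup`,
#'   `subhaplogroup`, `ut_status`, `min_dist_to_ut`, `nearest_ut`,
#'   `matched_sites`.
#' @export
call_haplotypes <- function(haps, rules) {
  if (nrow(haps) == 0L) {
    return(tibble(
      haplotype = character(), haplogroup = character(),
      subhaplogroup = character(),
      ut_status = factor(character(), levels = c("UT", "UTd", "other")),
      min_dist_to_ut = integer(), nearest_ut = character(),
      matched_sites = character()
    ))
  }
  hg <- tryCatch(assign_haplogroup(haps$seq, rules),
    error = function(e) {
      # re-raise with the haplotype name attached
      per <- map(haps$seq, function(s) {
        tryCatch(assign_haplogroup(s, rules), error = function(e2) e2)
      })
      bad <- which(map_lgl(per, inherits, "error"))[1]
      abort(
        sprintf(
          "haplotype '%s': %s", haps$haplotype[[bad]],
          conditionMessage(per[[bad]])
        ),
        class = "haplodiv_unclassified_error"
      )
    }
  )
  sub <- assign_subhaplogroup(haps$seq, hg, rules)
  ut <- classify_ut(haps$seq, rules)
  audit <- map_chr(seq_along(haps$seq), function(i) {
    chars <- strsplit(haps$seq[[i]], "", fixed = TRUE)[[1]]
    hrule <- rules$haplogroups |> filter(.data$name == hg[[i]])
    parts <- sprintf("%s:%s", hg[[i]], site_audit(chars, hrule$sites[[1]], rules$map))
    if (!is.na(sub[[i]])) {
      srule <- rules$subhaplogroups |> filter(.data$label == sub[[i]])
      if (nrow(srule) == 1L) {
        parts <- c(parts, sprintf(
          "%s:%s", sub[[i]],
          site_audit(chars, srule$sites[[1]], rules$map)
        ))
      } else {
        parts <- c(parts, sprintf("%s:fallback", sub[[i]]))
      }
    }
    paste(parts, collapse = "|")
  })
  tibble(
    haplotype = haps$haplotype,
    haplogroup = hg,
    subhaplogroup = sub,
    matched_sites = audit
  ) |>
    dplyr::bind_cols(ut) |>
    select(
      "haplotype", "haplogroup", "subhaplogroup", "ut_status",
      "min_dist_to_ut", "nearest_ut", "matched_sites"
    )
}

#' @importFrom purrr map_lgl
NULL

#' Join per-sample records with their haplotype calls
#'
#' Expands haplotype-level calls back to one row per sample, the table the
#' per-region diversity statistics are computed from.
#'
#' @param aln Alignment tibble.
#' @param haps Haplotype tibble with `samples` list-column (and `name` if
#'   catalog-matched; falls back to the provisional `haplotype` id).
#' @param calls Output of [call_haplotypes()].
#' @return Tibble with one row per sample: `sample_id`, `region`,
#'   `haplotype`, `haplogroup`, `subhaplogroup`, `ut_status`.
#' @export
call_samples <- function(aln, haps, calls) {
  hap_name <- if ("name" %in% names(haps)) haps$name else haps$haplotype
  member_map <- haps |>
    mutate(.name = hap_name) |>
    select(".name", "haplotype", "samples") |>
    tidyr::unnest("samples") |>
    dplyr::rename(sample_id = "samples")
  aln |>
    select("sample_id", "region") |>
    left_join(member_map, by = "sample_id") |>
    left_join(
      calls |> select("haplotype", "haplogroup", "subhaplogroup", "ut_status"),
      by = "haplotype"
    ) |>
    select(-"haplotype") |>
    dplyr::rename(haplotype = ".name")
}
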