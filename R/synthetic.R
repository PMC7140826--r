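#' Configuration for the synthetic population generator
#'
#' Describes a set of regional mtDNA control-region populations with known
#' ground truth: haplogroup composition, sub-haplogroup inventories,
#' star-like clusters of derived haplotypes around universal-type (UT)
#' founders, and region-private derived haplotypes. The generator's
#' defaults emulate a Southern-East-Asia-like population: haplogroup
#' frequencies inside the ranges typical of Old-World surveys (60--80% A,
#' 10--30% B, 5--15% C) and a UT/UTd cline around 40%/52% of samples.
#'
#' @param seed Integer seed; with the config it fully determines the
#'   output.
#' @param L Alignment length in columns (default 582, the classical
#'   control-region window).
#' @param regions Named integer vector of region sample sizes.
#' @param haplogroup_freqs Probability vector over haplogroups
#'   `c(A,B,C,D,E,F)` (named), or a named list of such vectors keyed by
#'   region.
#' @param subhaplogroup_mix Named list, per haplogroup letter, of
#'   probability vectors over its sub-haplogroup labels; default uniform.
#' @param ut_count Number of universal-type founder haplotypes (default
#'   18).
#' @param step_probs Probability vector `c(q0, q1, q2)` that a sampled
#'   lineage carries its founder haplotype, a 1-step derivative, or a
#'   2-step derivative; or a named list per region.
#' @param private_haplotype_rate Probability that a newly minted derived
#'   haplotype is private to the region minting it.
#' @param derived_reuse_prob Probability that a lineage re-uses an already
#'   minted compatible derivative instead of minting a new one (controls
#'   how star-like the clusters are).
#' @param region_subhaplogroups Optional named list, per region, of the
#'   sub-haplogroup labels allowed (and guaranteed present) there; default:
#'   all ten in every region.
#' @param ref_start First reference position of the window (default
#'   15,458).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         L = 582L,
                         regions = c(R1 = 100L),
                         haplogroup_freqs = c(
                           A = 0.72, B = 0.18, C = 0.08,
                           D = 0, E = 0.02, F = 0
                         ),
                         subhaplogroup_mix = NULL,
                         ut_count = 18L,
                         step_probs = c(0.407, 0.113, 0.48),
                         private_haplotype_rate = 0.5,
                         derived_reuse_prob = 0.5,
                         region_subhaplogroups = NULL,
                         ref_start = 15458L) {
  if (is.null(names(regions)) || any(regions < 1L)) {
    abort("regions must be a named vector of sizes >= 1", class = "haplodiv_config_error")
  }
  check_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(sprintf("%s must be a probability vector summing to 1", what),
        class = "haplodiv_config_error"
      )
    }
  }
  if (is.list(haplogroup_freqs)) {
    walk(haplogroup_freqs, check_probs, what = "haplogroup_freqs")
  } else {
    check_probs(haplogroup_freqs, "haplogroup_freqs")
  }
  if (is.list(step_probs)) {
    walk(step_probs, check_probs, what = "step_probs")
  } else {
    check_probs(step_probs, "step_probs")
  }
  subs_all <- sub_labels()
  if (!is.null(region_subhaplogroups)) {
    walk(region_subhaplogroups, function(s) {
      if (!all(s %in% subs_all)) {
        abort("unknown sub-haplogroup label in region_subhaplogroups",
          class = "haplodiv_config_error"
        )
      }
    })
  }
  structure(
    list(
      seed = as.integer(seed), L = as.integer(L), regions = regions,
      haplogroup_freqs = haplogroup_freqs,
      subhaplogroup_mix = subhaplogroup_mix,
      ut_count = as.integer(ut_count), step_probs = step_probs,
      private_haplotype_rate = private_haplotype_rate,
      derived_reuse_prob = derived_reuse_prob,
      region_subhaplogroups = region_subhaplogroups,
      ref_start = as.integer(ref_start)
    ),
    class = "synth_config"
  )
}

sub_labels <- function() {
  c(paste0("a", 1:6), "b1", "b2", "c1", "c2")
}

sub_parent <- function(labels) {
  toupper(substr(labels, 1, 1))
}

#' Generate a synthetic classification rule set
#'
#' Builds a mutually consistent set of diagnostic mutations and founder
#' haplotypes from a random reference sequence: two diagnostic sites per
#' haplogroup (A--F), one site per marked sub-haplogroup (a2--a6, b2, c1,
#' c2), catch-all entries for a1 and b1 (the "unmarked parts" of A and B),
#' and `ut_count` universal-type founders spread across all ten
#' sub-haplogroups. All diagnostic sites occupy disjoint alignment columns
#' and founders differ from each other at two or more private columns.
#' Deterministic per `(config, seed)`.
#'
#' @param config A [synth_config()].
#' @return A [haplo_rules()] object. Generator internals (founder table
#'   including the rare D/E/F founders, protected diagnostic columns,
#'   reference sequence) are attached as attribute `"generator"` and
#'   consumed by [simulate_dataset()].
#' @export
make_rules <- function(config) {
  L <- config$L
  need <- 12L + 8L + 2L * config$ut_count + 3L
  if (L < need + 5L) {
    abort(
      sprintf(
        "alignment length %d too small to host %d diagnostic/founder sites",
        L, need
      ),
      class = "haplodiv_capacity_error"
    )
  }
  withr::with_seed(config$seed, make_rules_impl(config))
}

make_rules_impl <- function(config) {
  L <- config$L
  ref <- sample(DNA_BASES, L, replace = TRUE)
  hg_letters <- c("A", "B", "C", "D", "E", "F")
  marked_subs <- c("a2", "a3", "a4", "a5", "a6", "b2", "c1", "c2")
  n_site <- 2L * length(hg_letters) + length(marked_subs)
  pos_pool <- sample.int(L, n_site + 2L * config$ut_count + 3L)
  take <- function(k) {
    out <- pos_pool[seq_len(k)]
    pos_pool <<- pos_pool[-seq_len(k)]
    out
  }
  other_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)
  mk_sites <- function(cols) {
    tibble(
      pos = as.integer(cols + config$ref_start - 1L),
      base = vapply(ref[cols], other_base, character(1), USE.NAMES = FALSE)
    )
  }
  hg_rules <- tibble(
    name = hg_letters,
    sites = map(hg_letters, function(h) mk_sites(take(2L)))
  )
  sub_marked <- tibble(
    label = marked_subs,
    parent = sub_parent(marked_subs),
    sites = map(marked_subs, function(s) mk_sites(take(1L)))
  )
  sub_rules <- bind_rows(
    sub_marked |> filter(.data$parent == "A"),
    tibble(
      label = "a1", parent = "A",
      sites = list(tibble(pos = integer(), base = character()))
    ),
    sub_marked |> filter(.data$parent == "B"),
    tibble(
      label = "b1", parent = "B",
      sites = list(tibble(pos = integer(), base = character()))
    ),
    sub_marked |> filter(.data$parent == "C")
  )
  protected <- sort(unique(unlist(map(
    c(hg_rules$sites, sub_rules$sites),
    function(s) s$pos - config$ref_start + 1L
  ))))
  apply_sites <- function(seq_chars, sites) {
    cols <- sites$pos - config$ref_start + 1L
    seq_chars[cols] <- sites$base
    seq_chars
  }
  founder_seq <- function(hg, sub) {
    s <- apply_sites(ref, hg_rules$sites[[match(hg, hg_rules$name)]])
    if (!is.na(sub)) {
      s <- apply_sites(s, sub_rules$sites[[match(sub, sub_rules$label)]])
    }
    s
  }
  # UT founders: cycle the ten sub-haplogroups, two private columns each
  ut_subs <- rep(sub_labels(), length.out = config$ut_count)
  ut_rows <- vector("list", config$ut_count)
  letter_counter <- c(A = 0L, B = 0L, C = 0L, D = 0L, E = 0L, F = 0L)
  for (i in seq_len(config$ut_count)) {
    sub <- ut_subs[[i]]
    hg <- sub_parent(sub)
    s <- founder_seq(hg, sub)
    priv <- take(2L)
    s[priv] <- vapply(s[priv], other_base, character(1))
    letter_counter[hg] <- letter_counter[hg] + 1L
    ut_rows[[i]] <- tibble(
      name = sprintf("%s%d", hg, letter_counter[hg]),
      seq = paste(s, collapse = ""),
      haplogroup = hg, subhaplogroup = sub, is_ut = TRUE
    )
  }
  def_rows <- map(c("D", "E", "F"), function(hg) {
    s <- founder_seq(hg, NA)
    priv <- take(1L)
    s[priv] <- other_base(s[priv])
    tibble(
      name = paste0(hg, "1"), seq = paste(s, collapse = ""),
      haplogroup = hg, subhaplogroup = NA_character_, is_ut = FALSE
    )
  })
  founders <- bind_rows(c(ut_rows, def_rows))
  rules <- haplo_rules(
    haplogroups = hg_rules,
    subhaplogroups = sub_rules,
    fallbacks = c(A = "a1", B = "b1"),
    universal_types = founders |>
      filter(.data$is_ut) |>
      select("name", "seq"),
    map = coord_map(config$ref_start, config$ref_start + L - 1L)
  )
  attr(rules, "generator") <- list(
    founders = founders,
    protected = protected,
    ref = paste(ref, collapse = "")
  )
  rules
}

resolve_per_region <- function(x, region) {
  if (is.list(x)) x[[region]] else x
}

#' Simulate a regional dataset with exact ground truth
#'
#' Draws `n` lineages per region. Each lineage picks a haplogroup from the
#' configured frequencies, a sub-haplogroup from the region's allowed
#' inventory (every allowed label is guaranteed to occur at least once, so
#' the planted inventory is recovered exactly), a founder haplotype of that
#' sub-haplogroup, and a mutation-step class: the founder itself, a 1-step
#' derivative, or a 2-step derivative. Derivatives mutate only
#' non-diagnostic columns, never collide with existing haplotypes, and
#' 2-step derivatives are rejected while within one substitution of any UT
#' -- so the planted haplogroup, sub-haplogroup and UT-status labels are
#' exact, not probabilistic. Derivatives may be re-used by later lineages
#' (star-like clusters) and may be private to the region that minted them.
#'
#' @param config A [synth_config()].
#' @param rules Rule set from [make_rules()] (must carry its generator
#'   attribute).
#' @return A list of class `synth_dataset`: `alignment` (sample tibble as
#'   from [read_alignment()]), `truth_samples` (per-sample truth:
#'   `sample_id`, `region`, `hap_id`, `haplogroup`, `subhaplogroup`,
#'   `ut_status`, `steps`), and `truth_haplotypes` (per-haplotype truth
#'   with sequences and `private_region`).
#' @export
simulate_dataset <- function(config, rules) {
  gen <- attr(rules, "generator")
  if (is.null(gen)) {
    abort("rules must come from make_rules() (generator attribute missing)",
      class = "haplodiv_config_error"
    )
  }
  withr::with_seed(config$seed + 1L, simulate_impl(config, rules, gen))
}

simulate_impl <- function(config, rules, gen) {
  L <- config$L
  founders <- gen$founders
  free_cols <- setdiff(seq_len(L), gen$protected)
  ut_m <- seq_matrix(founders$seq[founders$is_ut])
  # mutable haplotype pool: founders first, derivatives appended
  pool <- founders |>
    mutate(steps = 0L, founder = .data$name, private_region = NA_character_)
  pool_seqs <- new.env(parent = emptyenv())
  walk(pool$seq, function(s) assign(s, TRUE, envir = pool_seqs))
  mint <- function(founder_row, steps, region) {
    base_chars <- strsplit(pool$seq[[founder_row]], "", fixed = TRUE)[[1]]
    for (try in 1:200) {
      cand <- base_chars
      cols <- sample(free_cols, steps)
      for (cc in cols) {
        cand[cc] <- sample(setdiff(DNA_BASES, cand[cc]), 1L)
      }
      cand_s <- paste(cand, collapse = "")
      if (exists(cand_s, envir = pool_seqs, inherits = FALSE)) next
      if (steps >= 2L) {
        d <- cross_subst(seq_matrix(cand_s), ut_m, policy = "skip")
        if (min(d) <= 1L) next
      }
      return(cand_s)
    }
    abort("failed to mint a collision-free derivative haplotype",
      class = "haplodiv_capacity_error"
    )
  }
  draw_hap <- function(founder_name, steps, region) {
    if (steps == 0L) {
      return(which(pool$name == founder_name))
    }
    compat <- which(
      pool$founder == founder_name & pool$steps == steps &
        (is.na(pool$private_region) | pool$private_region == region)
    )
    if (length(compat) > 0L && stats::runif(1) < config$derived_reuse_prob) {
      return(if (length(compat) == 1L) compat else sample(compat, 1L))
    }
    frow <- which(pool$name == founder_name)
    s <- mint(frow, steps, region)
    priv <- if (stats::runif(1) < config$private_haplotype_rate) region else NA_character_
    k <- sum(pool$founder == founder_name) # derivative index
    new_row <- tibble(
      name = sprintf("%s.d%02d", founder_name, k),
      seq = s,
      haplogroup = pool$haplogroup[[frow]],
      subhaplogroup = pool$subhaplogroup[[frow]],
      is_ut = FALSE,
      steps = steps,
      founder = founder_name,
      private_region = priv
    )
    pool <<- bind_rows(pool, new_row)
    assign(s, TRUE, envir = pool_seqs)
    nrow(pool)
  }
  subs_all <- sub_labels()
  uniform_mix <- function(labels) setNames(rep(1 / length(labels), length(labels)), labels)
  records <- list()
  for (region in names(config$regions)) {
    n_r <- config$regions[[region]]
    inv <- config$region_subhaplogroups[[region]] %||% subs_all
    hgf <- resolve_per_region(config$haplogroup_freqs, region)
    sp <- resolve_per_region(config$step_probs, region)
    # zero haplogroups whose allowed sub set is empty, renormalise
    for (hg in c("A", "B", "C")) {
      if (!any(sub_parent(inv) == hg)) hgf[hg] <- 0
    }
    hgf <- hgf[hgf > 0] / sum(hgf[hgf > 0])
    if (length(inv) > n_r) {
      abort(sprintf(
        "region '%s': %d samples cannot cover %d planted sub-haplogroups",
        region, n_r, length(inv)
      ), class = "haplodiv_config_error")
    }
    # forced coverage of the planted inventory, then free multinomial draws
    plan_sub <- c(inv, rep(NA_character_, n_r - length(inv)))
    plan_hg <- sub_parent(plan_sub)
    free <- which(is.na(plan_sub))
    if (length(free) > 0L) {
      plan_hg[free] <- sample(names(hgf), length(free), replace = TRUE, prob = hgf)
      for (i in free) {
        hg <- plan_hg[[i]]
        if (hg %in% c("A", "B", "C")) {
          mix <- config$subhaplogroup_mix[[hg]] %||%
            uniform_mix(subs_all[sub_parent(subs_all) == hg])
          mix <- mix[names(mix) %in% inv]
          mix <- mix / sum(mix)
          plan_sub[[i]] <- sample(names(mix), 1L, prob = mix)
        }
      }
    }
    for (i in seq_len(n_r)) {
      hg <- plan_hg[[i]]
      sub <- plan_sub[[i]]
      cand <- if (is.na(sub)) {
        which(founders$haplogroup == hg & !founders$is_ut)
      } else {
        which(founders$subhaplogroup == sub & founders$is_ut)
      }
      fidx <- if (length(cand) == 1L) cand else sample(cand, 1L)
      founder_name <- founders$name[[fidx]]
      steps <- sample(0:2, 1L, prob = sp)
      row <- draw_hap(founder_name, steps, region)
      records[[length(records) + 1L]] <- tibble(
        sample_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", region), i),
        region = region,
        hap_row = row
      )
    }
  }
  samples <- bind_rows(records)
  hap_status <- ifelse(
    pool$founder %in% founders$name[founders$is_ut],
    ifelse(pool$steps == 0L & pool$is_ut, "UT",
      ifelse(pool$steps == 1L, "UTd", "other")
    ),
    "other"
  )
  pool$ut_status <- factor(hap_status, levels = c("UT", "UTd", "other"))
  truth_samples <- samples |>
    mutate(
      hap_id = pool$name[.data$hap_row],
      haplogroup = pool$haplogroup[.data$hap_row],
      subhaplogroup = pool$subhaplogroup[.data$hap_row],
      ut_status = pool$ut_status[.data$hap_row],
      steps = pool$steps[.data$hap_row]
    ) |>
    select(-"hap_row")
  realized <- sort(unique(samples$hap_row))
  alignment <- truth_samples |>
    mutate(seq = pool$seq[match(.data$hap_id, pool$name)]) |>
    select("sample_id", "region", "seq")
  attr(alignment, "L") <- L
  structure(
    list(
      alignment = alignment,
      truth_samples = truth_samples,
      truth_haplotypes = pool[realized, ] |>
        select(
          hap_id = "name", "seq", "haplogroup", "subhaplogroup",
          "ut_status", "steps", "founder", "private_region"
        )
    ),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %d samples, %d regions, %d distinct haplotypes\n",
    nrow(x$truth_samples), length(unique(x$truth_samples$region)),
    nrow(x$truth_haplotypes)
  ))
  invisible(x)
}

#' Write a synthetic dataset to standard files
#'
#' Emits the alignment FASTA, metadata TSV, per-sample and per-haplotype
#' truth TSVs, and the rule set YAML -- the exact inputs the analysis
#' pipeline consumes.
#'
#' @param sim A [simulate_dataset()] result.
#' @param rules The matching rule set.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, rules, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(
    sim$alignment,
    file.path(dir, "alignment.fasta"),
    file.path(dir, "metadata.tsv")
  )
  readr::write_tsv(sim$truth_samples, file.path(dir, "truth_samples.tsv"),
    progress = FALSE
  )
  readr::write_tsv(sim$truth_haplotypes, file.path(dir, "truth_haplotypes.tsv"),
    progress = FALSE
  )
  write_rules(rules, file.path(dir, "rules.yaml"))
  invisible(dir)
}

#' Ready-made synthetic study designs
#'
#' Three presets mirroring the structure of published Old-World
#' control-region surveys:
#' * `"thailand_like"`: four regions sized 80/60/32/61 (n = 233) with
#'   planted sub-haplogroup inventories of sizes 10/7/5/8, per-region
#'   haplogroup frequencies and UT/UTd step mixes on the Southern-East-Asia
#'   side of the diversity cline. `include_ridgeback = TRUE` adds a
#'   28-sample breed-like group with reduced diversity.
#' * `"europe_like"`: one region, 4 sub-haplogroups, UTd around 92% -- the
#'   low-diversity western end of the cline.
#' * `"southeast_asia_like"`: one region, all 10 sub-haplogroups, UTd
#'   around 52%.
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config.
#' @param include_ridgeback Add the breed-like group (thailand_like only).
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("thailand_like", "europe_like", "southeast_asia_like"),
                         seed = 1L, include_ridgeback = FALSE) {
  name <- match.arg(name)
  if (name == "thailand_like") {
    regions <- c(N.Thai = 80L, C.Thai = 32L, NE.Thai = 60L, S.Thai = 61L)
    freqs <- list(
      N.Thai = c(A = 0.838, B = 0.100, C = 0.050, D = 0, E = 0.012, F = 0),
      C.Thai = c(A = 0.781, B = 0.094, C = 0.094, D = 0, E = 0.031, F = 0),
      NE.Thai = c(A = 0.817, B = 0.150, C = 0.033, D = 0, E = 0, F = 0),
      S.Thai = c(A = 0.852, B = 0.033, C = 0.066, D = 0, E = 0.049, F = 0)
    )
    steps <- list(
      N.Thai = c(0.275, 0.063, 0.662),
      C.Thai = c(0.406, 0.094, 0.500),
      NE.Thai = c(0.500, 0.033, 0.467),
      S.Thai = c(0.443, 0.114, 0.443)
    )
    inventories <- list(
      N.Thai = sub_labels(),
      C.Thai = c("a1", "a2", "a3", "b1", "b2", "c1", "c2"),
      NE.Thai = c("a1", "a2", "b1", "b2", "c1"),
      S.Thai = c("a1", "a2", "a3", "a4", "b1", "b2", "c1", "c2")
    )
    if (include_ridgeback) {
      regions <- c(regions, Ridgeback = 28L)
      freqs$Ridgeback <- c(A = 0.857, B = 0.143, C = 0, D = 0, E = 0, F = 0)
      steps$Ridgeback <- c(0.179, 0.357, 0.464)
      inventories$Ridgeback <- c("a1", "a2", "b1")
    }
    return(synth_config(
      seed = seed, regions = regions, haplogroup_freqs = freqs,
      step_probs = steps, region_subhaplogroups = inventories
    ))
  }
  if (name == "europe_like") {
    return(synth_config(
      seed = seed, regions = c(Europe = 450L),
      haplogroup_freqs = c(A = 0.649, B = 0.211, C = 0.080, D = 0.060, E = 0, F = 0),
      step_probs = c(0.778, 0.144, 0.078),
      region_subhaplogroups = list(Europe = c("a1", "b1", "c1", "c2"))
    ))
  }
  synth_config(
    seed = seed, regions = c(SEAsia = 587L),
    haplogroup_freqs = c(A = 0.799, B = 0.133, C = 0.056, D = 0, E = 0.012, F = 0),
    step_probs = c(0.407, 0.113, 0.480),
    region_subhaplogroups = list(SEAsia = sub_labels())
  )
}
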