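---
title: "Methods: haplotype diversity, classification and networks for mtDNA control-region data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, classification and networks for mtDNA control-region data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiv)
library(dplyr)
```

## The problem

Intraspecific phylogeography of domestic dogs (and many other mammals)
leans heavily on a short, fast-evolving fragment of the mitochondrial
control region. A typical survey aligns a few hundred samples over a
fixed window — here 582 columns corresponding to reference positions
15,458–16,039 — collapses identical sequences into haplotypes, assigns
each haplotype to a haplogroup (A–F) and, within the three universal
haplogroups A–C, to one of ten sub-haplogroups (a1–a6, b1, b2, c1, c2)
using published diagnostic mutations, and then summarises each sampling
region with a battery of diversity statistics. `haplodiv` implements that
pipeline as composable tidy functions, with a synthetic-population
generator that provides exact ground truth for every stage.

## Coordinates and alignment assumptions

Sequences are assumed pre-aligned; the package validates geometry, it
does not align. Reference positions are 1-based inclusive; a single
`coord_map()` object converts them to alignment columns, so diagnostic
rules can be written in the literature's coordinates. The default window
is 582 columns: the stated positions 15,458–16,039 imply 582, and that is
the default `L`, configurable for other fragments. Lowercase input is
uppercased; `U` is rejected (DNA only); gaps and IUPAC ambiguity codes
are permitted and tracked per column by `validate_window()`.

## Haplotype identity

Two samples share a haplotype iff their sequences match at every column.
By default this comparison is strict: `N` and other ambiguity codes are
ordinary states, and gaps compare literally. This is the reproducible
choice — wildcard matching is not transitive, so any merging policy must
also fix a processing order. A relaxed mode (`strict = FALSE`) is
provided for DnaSP-like behaviour: ambiguity codes match any base, and
samples are merged greedily in sequence-lexicographic order, the group
representative being the member with fewest ambiguous characters.
Haplotype output order is deterministic (member count descending, then
sequence), so runs are byte-stable.

## Classification by diagnostic mutations

The diagnostic-mutation tables for dog mtDNA sub-haplogroups are
study-specific literature content, so they are run-time configuration
(YAML), never hard-coded. A rule is an ordered list of
`(position, required base)` sites; the first rule whose sites all match
wins, which resolves overlapping rules deterministically, and every call
carries an audit string of the sites it matched. Within haplogroups A and
B the labels a1 and b1 conventionally denote the *unmarked* remainder of
the haplogroup, which the schema expresses either as a catch-all rule
(zero sites, ordered last) or as an explicit fallback; both are
supported. Haplogroup C has no unmarked part: c1 and c2 must be
rule-defined, and a C haplotype matching neither is an error rather than
a silent guess.

Universal types (UTs) — the small set of haplotypes shared across distant
regions, 18 in the classical dog data — are part of the configuration. A
haplotype's UT status comes from its minimum substitution distance to the
UT set: 0 is a UT, exactly 1 a UT-derived haplotype (UTd), 2 or more
"other". Distances count substitutions only; columns with a gap or
ambiguity in either sequence are excluded, matching the network distance
policy. Whether the original studies counted indels is not stated
anywhere we could verify, so the substitution-only rule is declared
explicitly and applied uniformly. In regional summaries the UTd
percentage includes UTs ("a UT or one step from a UT"), so
`pctUT <= pctUTd` always holds.

## Diversity statistics

*Haplotype (gene) diversity* uses the corrected estimator
$H = \frac{n}{n-1}(1 - \sum_i p_i^2)$, and its standard deviation comes
from Nei's (1987) variance of gene diversity,
$V(H) = \frac{2}{n(n-1)}\left[2(n-2)\left(\sum p_i^3 - (\sum p_i^2)^2\right) + \sum p_i^2 - (\sum p_i^2)^2\right]$,
the estimator documented for Arlequin's standard indices. *Nucleotide
diversity* is the mean pairwise substitution difference per comparable
site with the same $n/(n-1)$ correction; the tests verify it against a
brute-force mean over all sequence pairs.

*Rarefaction* adjusts haplotype counts for unequal region sizes by
resampling without replacement. `rarefy_haplotypes()` always returns
both the Monte-Carlo mean/sd over the requested replications (1000 in the
classical design) and the closed-form hypergeometric expectation
$E[K] = \sum_i \left[1 - \binom{n-f_i}{k}\middle/\binom{n}{k}\right]$,
computed with `lchoose()` for stability at large $n$. Reporting both is
deliberate: the historical computations used unpublished in-house
programs, and the closed form anchors correctness. The resample size `k`
is a **required** argument with no default — published tables have used
both "the smallest sample" and other values for the same data, so a
silent default would invite incomparable numbers; `k` is recorded in the
output attributes and the JSON sidecar. Regions with `n < k` yield `NA`,
rendered as a dash. The summary reported is the mean (with sd); whether
historical tables used mean or median is unknowable, and the mean is what
the closed form predicts.

All computations keep full precision; rounding (one decimal for
percentages, three for diversities) happens only in `render_table1()`.

## The minimum spanning network

Distances are substitution counts between haplotype sequences. The
network is the union of all minimum spanning trees (the
Excoffier–Smouse construction): a Kruskal-style sweep over ascending
weight classes in which every edge joining two components that were
distinct at the start of its class is kept. Ties are therefore
*represented*, not broken by arbitrary order — published networks are
drawn from such tied alternatives. Edges present in every MST are
flagged (`in_all_msts`): within a weight class these are exactly the
bridges of the kept-edge multigraph over start-of-class components.
Hypothetical intermediary haplotypes (the "black dots" of published
figures) are a rendering concern: `expand_msn()` turns a weight-$w$ edge
into $w$ unit steps at display/export time, leaving the analytic graph
clean. Exports are edge-list TSV, node-table TSV and GraphML; no layout
is computed.

## What the synthetic generator emulates — and what it does not

`make_rules()` draws a random reference sequence and plants disjoint
diagnostic sites: two per haplogroup, one per marked sub-haplogroup
(c1/c2 each get their own), catch-alls for a1/b1, and founder haplotypes:
UTs cycled across all ten sub-haplogroups with two private columns each,
plus one founder for each rare haplogroup D/E/F. `simulate_dataset()`
then draws lineages per region: haplogroup from the configured
frequencies, sub-haplogroup from the region's allowed inventory (each
allowed label is seeded with one guaranteed sample, so the planted
inventory is recovered exactly), a founder of that sub-haplogroup, and a
step class — the founder itself ($q_0$), a one-step derivative ($q_1$),
or a two-step derivative ($q_{2+}$, realised as exactly two steps).
Derivatives mutate only non-diagnostic columns, never collide with
existing haplotypes, and two-step derivatives are re-drawn while within
one substitution of any UT. Truth labels are therefore exact by
construction, not probabilistic. Derivatives are re-used by later
lineages with probability `derived_reuse_prob` (0.5 by default), which
produces the star-like clusters around founder haplotypes, and a newly
minted derivative is region-private with probability
`private_haplotype_rate` (0.5).

Defaults place the population on the Southern-East-Asia side of the
published diversity cline: haplogroup frequencies around 72/18/8 % for
A/B/C with 2 % rare groups, and $q = (0.407, 0.113, 0.480)$. The
`thailand_like` preset uses four regions sized 80/60/32/61 (n = 233)
with per-region haplogroup frequencies, step mixes and sub-haplogroup
inventories of sizes 10/7/5/8; `europe_like` and `southeast_asia_like`
provide the two ends of the cline (4 sub-haplogroups and UTd ≈ 92 %
versus 10 and ≈ 52 %).

The generator is *not* a coalescent simulator: no genealogy, no mutation
rate or dating, no recombination (appropriate for mtDNA), no homoplasy
(each derivative is minted fresh rather than evolving along a tree), and
no sequencing artefacts (no gaps or ambiguity codes unless you add
them). Passing the recovery tests therefore demonstrates that the
pipeline's bookkeeping, rule logic and distance computations are exact —
it does not demonstrate robustness to alignment error, heteroplasmy or
ambiguous base calls in real chromatogram-derived data.

## Numerical and design choices

- Fragment length: positions 15,458–16,039 imply 582 columns, used as
  the default everywhere; `L` is configurable.
- Distances, UT status and nucleotide diversity skip gap/ambiguity
  columns; haplotype identity does not (strict by default).
- Rarefaction uses `exp(lchoose(...))`; Monte-Carlo draws are seeded via
  `withr::with_seed`, leaving the caller's RNG untouched. Within
  `region_table()` each region gets `seed + i` so row order does not
  leak between regions.
- The MSN keeps all tied minimum connections; single-MST consumers can
  filter on `in_all_msts` plus any completion.
- `run_pipeline()` computes everything before writing anything, so a
  failing stage leaves no partial bundle, and writes no timestamps, so
  identical inputs and seed give byte-identical outputs (the run log
  carries the rule-set checksum, UT list, seed and parameters instead).
- Problem sizes in the test-suite: property checks use 1000 random
  frequency spectra, 10,000 random haplotypes for the UT classifier
  oracle, 100 random distance matrices of 3–8 nodes for the network
  oracle (exhaustive spanning-tree enumeration up to 5 nodes, an
  independent reference MST plus edge-forcing by contraction above
  that), and the 233-sample preset for end-to-end recovery.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_preset("thailand_like", seed = 1)
rules <- make_rules(cfg)
sim <- simulate_dataset(cfg, rules)

haps <- collapse_haplotypes(sim$alignment)
calls <- call_haplotypes(haps, rules)
sc <- call_samples(sim$alignment, haps, calls)

rt <- region_table(sc, haps, k = 32, replications = 1000, seed = 1)
render_table1(rt)
autoplot(rt, metric = "HT_div")

net <- build_msn(distance_matrix(haps)) |> annotate_msn(sc)
glance(net)
```

## Known limitations

- The wildcard (non-strict) identity mode is order-dependent by design;
  documents should state which mode produced a table.
- `HTuq` (region-private haplotypes) is defined relative to the regions
  in the same run, so pooled rows carry `NA` there.
- Classification is only as good as the supplied rule file; the package
  ships no biological diagnostic tables.
- Between-population distance matrices, AMOVA/Φst, neutrality tests and
  tree building are out of scope; use Arlequin/`pegas`/`ape` downstream.
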