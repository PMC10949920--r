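---
title: "The evidence architecture behind regulatory interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evidence architecture behind regulatory interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riconf)
```

## The problem

A transcriptional regulatory interaction (RI) in a curated bacterial
network database is the triplet of a transcription factor (TF), its effect
(activation or repression) and a regulated target — a promoter, a
transcription unit (TU) or, when less is known, just a gene. Each RI is
supported by evidence of two distinct kinds: *binding* evidence (the TF
physically occupies a site) and *function* evidence (its presence changes
transcription of the target). Methods producing that evidence range from
classical molecular biology (EMSA and footprinting with purified protein,
site mutagenesis, cellular-extract binding) through genome-wide
high-throughput (HT) binding assays — ChIP-chip/ChIP-seq/ChIP-exo in vivo,
gSELEX and DAP-seq in vitro — to purely computational motif predictions.

Because HT-derived collections are routinely benchmarked *against* such
databases, the evidence behind every RI must be dissectable: a user
validating a new ChIP-seq pipeline needs a gold standard that provably does
not already contain ChIP-seq evidence. riconf implements that machinery:
a declarative evidence catalog, the additive-evidence confidence calculus,
peak-to-site mapping, recovery benchmarking, and gold-standard extraction
with arbitrary method exclusion.

## The confidence calculus

Every evidence type carries a *base level* — strong when the method gives
direct physical proof with the precise site (binding of purified protein;
site mutation), weak otherwise (HT methods involve variable bioinformatic
processing; cellular extracts admit indirect effects; predictions are
predictions). Methods are partitioned into seven *independence groups*:
methods within a group share failure modes and never corroborate each
other, methods from different groups do. Groups 1–2 are the strong
classical methods, group 3 cellular-extract binding, group 4 the ChIP
family, group 5 gSELEX, group 6 DAP-seq, group 7 computational analysis.
Author statements and curator inferences carry no group and never touch
confidence.

The RI level is then the maximum of the base level and of the consequents
of four upgrade rules counted over *distinct groups* of the binding
evidence (two ChIP-family codes count once):

| rule | antecedent (distinct groups)        | consequent |
|------|-------------------------------------|-----------|
| 1    | 2 weak groups (4–7)                 | strong    |
| 2    | 2 strong groups (1 and 2)           | confirmed |
| 3    | 2 weak groups + 1 strong group      | confirmed |
| 4    | 4 weak groups (4–7)                 | confirmed |

All four rules are gated on function evidence: corroborating binding
without any evidence of a regulatory effect upgrades nothing (the base
level still applies). No single evidence type reaches `confirmed`.

Worked pattern (the one the Cra–*fru* interaction exhibits): computational
binding evidence plus expression function evidence is weak; once peaks from
ChIP-exo, gSELEX and DAP-seq all cover the site, the binding evidence spans
four distinct weak groups (7, 4, 5, 6) and rule 4 lifts the RI to
confirmed.

```{r}
catalog <- default_catalog()
assign_confidence("COMP-ANALYSIS", "EXP-GENE-EXPRESSION-ANALYSIS", catalog)
assign_confidence(c("COMP-ANALYSIS", "HT-IDA-CHIP-EXO", "HT-IDA-GSELEX",
                    "HT-IDA-DAP-SEQ"),
                  "EXP-GENE-EXPRESSION-ANALYSIS", catalog)
```

### Design choices in the engine

* **Rule 3 needs three groups.** "Two weak plus a strong" is read
  literally: two distinct weak groups *and* at least one strong group.
* **The gate applies to every rule**, including strong+strong→confirmed:
  the proviso on function evidence is stated for upgrades generally, and a
  uniform gate is also the only order-independent reading.
* **Any function-aspect code opens the gate** — the gate tests
  non-emptiness of the (post-exclusion) function evidence resolved to
  function-aspect catalog codes, not specific methods.
* **Group 3 never counts toward antecedents.** The printed rules name
  groups 1/2 and 4–7 only; cellular-extract binding therefore contributes
  its weak base level and nothing else. Whether the production calculator
  ever combined group 3 is unknowable from the text; the literal reading
  is implemented and is the conservative one (it never upgrades more).
* **Rules are data.** `default_ruleset()` is a four-row data frame;
  alternative rule sets (JSON) let users define their own confidence
  vocabulary over the same group algebra, which is what makes the gold
  standards "flexible".

Exclusion (`recompute_with_exclusions()`) removes a selected code set —
named codes, whole categories, or whole groups — from both evidence sides
of every RI and recomputes from scratch. It is a pure function; the
engine's only invariants worth stating are monotonicity (more evidence
never lowers a level, exclusion never raises one) and group-distinctness,
and both are enforced property-style in the test suite against a
brute-force oracle that enumerates code tuples instead of counting groups.

## Peak mapping

HT datasets report peaks either as start/end pairs or as a center alone.
Coordinates are 1-based inclusive end to end. Two normalization policies
exist: `as_reported` keeps author-reported ends and expands centers to a
fixed window; `uniform_200` recenters everything on the peak midpoint. A
center `c` expands to `[c − 100, c + 99]` — exactly 200 nt, the figure the
analyses quote; the 201-nt "100 bp on each side inclusive" variant is one
`uniform_width = 201` away. An RI site matches a peak when *both* site
coordinates lie inside the peak (strict containment, strand ignored); each
matching method contributes its evidence code once, then confidence is
recomputed. Containment is deliberately strict even though ChIP-exo peaks
(mean width ≈ 34 nt) can be narrower than a site — that asymmetry is a
property of the data worth seeing, not papering over.

Genome-version lifting applies a user-supplied ordered offset table (each
coordinate shifts by the last threshold at or below it); intervals spanning
a breakpoint are flagged for manual review rather than silently stretched.
Deriving the offsets between genome builds is out of scope.

## Recovery benchmarking

`filter_classical()` keeps RIs with at least one classical binding code and
a site; `filter_classical_confirmed()` first strips the whole HT category,
recomputes, and keeps the still-confirmed classical RIs — the
anti-circularity set. Recovery is counted over *distinct sites* (RIs
sharing a coordinate pair count once): per TF, the percentage of sites
contained in ≥ 1 same-TF peak of a method; per method, the unweighted mean
± sample (n−1) sd across eligible TFs and the count-weighted pooled
percentage. Methods with no eligible TF are absent, not 0 %. Methods are
compared with a tie-corrected Kruskal–Wallis test on the per-TF fractions
plus pairwise two-sided Mann–Whitney U tests under Bonferroni correction
(the number of pairs); Dunn's test was considered and not used — with only
a "Bonferroni correction" named, pairwise Mann–Whitney is the commonest
reading and the one implemented.

## The synthetic world

`generate_corpus()` emulates the three inputs with planted truth: a 4.64-Mb
genome, 50 TFs × 20 sites of 16–30 nt (typical TF-box widths), an evidence
mixture shaped like a mature curated collection (classical-confirmed,
classical-strong, HT-only, computational-only and mixed strata), and one
peak collection per method in which each site is covered with a planted
probability — defaults 0.8 (ChIP-seq), 0.65 (gSELEX), 0.5 (DAP-seq), 0.3
(ChIP-exo), i.e. the recovery ordering the field reports — plus uniformly
placed decoy peaks. Peak widths sit at the published collection averages
(≈ 582, 55 and 34 nt; gSELEX center-only with the 200-nt convention).
`expected_confidence_distribution()` enumerates the mixture support exactly
and serves as the closed-form oracle for the engine on generated corpora.

What the generator does **not** emulate: peak-caller noise profiles,
correlated failures between methods, condition-dependent binding,
power-law-correlated evidence depth, or sequence content. A green recovery
test therefore establishes that the bookkeeping — containment, set
semantics, aggregation, test statistics — is right, not that any real
method performs at the planted rate.

## Numerical conventions and degenerate inputs

* Coordinates: 1-based inclusive everywhere a user sees them; widths are
  `right − left + 1`.
* Center expansion of even widths puts the extra base on the left of the
  center (`[c − w/2, c + w/2 − 1]`); normalized windows are clamped at
  coordinate 1 with a warning.
* Empty binding evidence is weak; an empty RI set summarizes to zeros; a
  gold-standard filter with no survivors writes a header-only file.
* Unknown evidence codes are retained and flagged (curation vocabularies
  evolve); `strict = TRUE` promotes the flag to an error. Unknown codes are
  inert in the calculus.
* Percentages are reported to one decimal; per-type percentages are
  relative to the RI-type total.
* All randomness is seed-scoped: `generate_corpus()` restores the caller's
  RNG state, and equal seeds give byte-identical corpora.

## Known limitations

* Promoter- and TU-level confidence is out of scope (no published rules).
* The stored-vs-derived confidence column: the reader trusts a stored
  level (it may legitimately encode an exclusion recomputation) and derives
  only when the cell is absent or invalid; mismatches are counted in an
  attribute, not resolved.
* Offset tables are applied, never derived.
* The recovery comparison inherits every confounder of the underlying
  data — heterogeneous TF panels per method, single-lab collections,
  peak-width differences — and the package makes no attempt to correct for
  them beyond offering the uniform-width policy.
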