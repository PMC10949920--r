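# riconf

Evidence architecture and confidence calculus for transcription-factor
regulatory interactions (RIs).

Curated bacterial regulatory-network databases annotate each RI — a
transcription factor, its effect, and a regulated promoter, transcription
unit or gene — with evidence codes for *binding* (the TF occupies a site)
and *function* (it changes transcription). Because new high-throughput
(HT) binding methods are benchmarked against these databases, users need
to dissect the evidence behind every interaction and build gold standards
that exclude the method under evaluation. riconf provides the machinery:

* an **evidence catalog** with independence groups — methods within a
  group share failure modes; methods from different groups corroborate;
* the **additive-evidence confidence calculus** assigning each RI a level
  in `weak < strong < confirmed`. With `W` = number of distinct weak
  groups (ChIP family, gSELEX, DAP-seq, computational) and `S` = number of
  distinct strong groups (purified-protein binding, site mutation) among
  the binding evidence, and function evidence present:

  | antecedent        | consequent |
  |-------------------|-----------|
  | W ≥ 2             | strong    |
  | S ≥ 2             | confirmed |
  | W ≥ 2 and S ≥ 1   | confirmed |
  | W ≥ 4             | confirmed |

  floored at the base level (strong iff S ≥ 1); no upgrade fires without
  function evidence, and no single evidence type is confirmed;
* **peak-to-site mapping**: HT peaks (reported ends, or centers expanded
  to 200 nt) enrich an RI's evidence when they fully contain its site,
  same TF, strict containment;
* **recovery benchmarking**: per-TF percentage of classically supported
  sites recovered by each HT method, mean ± sd and pooled, compared by
  Kruskal–Wallis with Bonferroni-corrected pairwise Mann–Whitney tests;
* **gold-standard extraction** with exclusion of arbitrary codes,
  categories or groups, and a provenance sidecar;
* a **synthetic-corpus generator** with planted per-method recovery, so
  everything above is testable without downloading anything.

## Worked example

```r
library(riconf)
catalog <- default_catalog()

# ChIP-seq (group 4) + gSELEX (group 5) + expression evidence:
# two distinct weak groups through the function gate -> strong
assign_confidence(c("HT-IDA-CHIP-SEQ", "HT-IDA-GSELEX"),
                  "EXP-GENE-EXPRESSION-ANALYSIS", catalog)
#> [1] "strong"

# A synthetic corpus with planted recovery 0.8/0.65/0.5/0.3
corpus <- generate_corpus(corpus_config(seed = 42))
enriched <- map_riset(corpus$riset, corpus$peaks, peak_policy("as_reported"))
summarize_architecture(enriched)
#> Architecture summary: 1000 RIs
#>   confidence: weak 118 (11.8%), strong 297 (29.7%), confirmed 585 (58.5%)
#>   category:   classical 21 (2.1%), ht 135 (13.5%), classical_and_ht 844 (84.4%), nonexperimental 0 (0.0%)

classical <- filter_classical(corpus$riset)
report <- recovery(classical, corpus$peaks, peak_policy("as_reported"))
report
#> Recovery report (policy: as_reported )
#>   chip_exo  50 TFs  mean  29.6% +/- 12.8  pooled  29.7% (174/586 sites)
#>   chip_seq  50 TFs  mean  79.8% +/- 10.3  pooled  79.9% (468/586 sites)
#>   dap_seq   50 TFs  mean  48.0% +/- 16.7  pooled  48.1% (282/586 sites)
#>   gselex    50 TFs  mean  65.9% +/- 15.6  pooled  65.7% (385/586 sites)

compare_methods(report)$kruskal
#> $statistic
#> [1] 130.0386
#> $df
#> [1] 3
#> $p_value
#> [1] 5.305843e-28
```

The per-method pooled recoveries land on the planted probabilities (29.7 %
vs 0.3, 79.9 % vs 0.8, …), confirming the containment bookkeeping; the
Kruskal–Wallis test rejects homogeneity across the four methods, as it
must when the planted rates differ.

The mapping step enriched evidence levels: confirming interactions rose
because sites covered by several independent HT methods cross the
four-weak-groups rule (see the vignette for the calculus and its gates).

## Command line

```sh
RICONF=$(Rscript -e 'cat(system.file("exec/riconf", package = "riconf"))')
Rscript $RICONF simulate --out corpus/ --seed 5
Rscript $RICONF map-peaks --riset corpus/riset.tsv --peaks corpus/peaks.tsv \
        --policy uniform_200 --out enriched.tsv --matches matches.tsv
Rscript $RICONF recover --riset corpus/riset.tsv --peaks corpus/peaks.tsv \
        --set classical --out report.tsv --stats stats.tsv
Rscript $RICONF assign-confidence --riset enriched.tsv --out no-ht.tsv \
        --exclude-category ht
```

Exit codes: 0 success, 1 validation error, 2 I/O error. Logs go to
stderr; data only to the declared outputs.

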