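# cernet

Post-quantification analysis of long non-coding RNA (lncRNA) expression
studies, culminating in competing endogenous RNA (ceRNA) network
construction. The package is aimed at transcriptomics analysts who have
transcript annotations, count/FPKM matrices, coding-potential verdict
tables and miRNA-target predictions in hand, and who want the
downstream statistics — lncRNA identification, differential expression,
target assignment, enrichment, and the lncRNA–miRNA–mRNA triad screen —
as tested, composable R functions rather than a one-off script chain.
A built-in simulator with planted ceRNA triads provides ground truth
for validating every stage.

## The statistics at the core

* **lncRNA identification.** Structural filter (exon count ≥ 2, mature
  length > 200 bp) followed by the intersection of four
  coding-potential verdicts (CNCI, CPC2, CPAT, PFAM): a transcript
  survives only if every tool calls it non-coding.
* **Differential expression.** A self-contained conditional
  negative-binomial exact test: counts are total-count normalized to
  the geometric-mean library size, a common dispersion φ
  (Var = μ + φμ²) is estimated by method of moments, and for each
  feature the conditional distribution of the group-A sum given the
  total is enumerated, with a two-sided *minlike* p-value. Calls use
  p < 0.05 and |log₂FC| ≥ 0.26. At φ = 0 the test reduces exactly to
  the conditional binomial test.
* **Target assignment.** Cis: protein-coding genes within 100 kb of a
  DE lncRNA's span (inclusive; distance 0 on overlap). Trans: genes
  with |Pearson r| > 0.95 and p < 0.05 across shared samples, with the
  p-value from the t-transform `t = r·√((n−2)/(1−r²))`.
* **Enrichment.** Hypergeometric over-representation of target genes
  against a supplied term→gene map, with significance tiers p < 0.05
  and p < 0.01.
* **ceRNA screen.** A triple (lncRNA, miRNA, mRNA) is accepted iff the
  miRNA targets both (from interaction tables), all three are DE,
  Spearman(miRNA, lncRNA) ≤ −0.7 and Spearman(miRNA, mRNA) ≤ −0.7,
  Pearson(lncRNA, mRNA) > 0.9, and the shared-miRNA hypergeometric
  p < 0.05. Accepted triads assemble into a typed network (edges are
  the two targeting links) exportable for Cytoscape.

See `vignettes/cerna-screening.Rmd` for the model, the design
decisions, and known limitations.

## Worked example

```r
library(cernet)
library(dplyr)

cfg <- sim_config(seed = 1, n_replicates_per_condition = 15)
ds  <- simulate_dataset(cfg)   # annotation, counts, votes, interactions
ex  <- ds$expression

# lncRNA identification (structural + 4-tool consensus)
lnc <- identify_lncrnas(ds$annotation$transcripts, ds$coding_calls)

# differential expression, ovary: laying vs broodiness
de_lnc  <- de_test(ex$lncrna, ex$samples, "laying", "broodiness",
                   tissue = "ovary") |> call_de()
glance(de_lnc)
#> # A tibble: 1 × 7
#>   n_features n_significant  n_up n_down   phi lfc_threshold p_threshold
#>        <int>         <int> <int>  <int> <dbl>         <dbl>       <dbl>
#> 1        150            53    30     23 0.166          0.26        0.05

# ceRNA screen on the ovary samples
sig <- function(d) d$feature_id[d$significant]
de_mir  <- de_test(ex$mirna, ex$samples, "laying", "broodiness",
                   tissue = "ovary") |> call_de()
de_mrna <- de_test(ex$mrna,  ex$samples, "laying", "broodiness",
                   tissue = "ovary") |> call_de()
triads <- build_triads(sig(de_lnc), sig(de_mir), sig(de_mrna),
                       ds$interactions, ex,
                       sample_ids = ex$samples$sample_id[
                         ex$samples$tissue == "ovary"])
head(as_tibble(triads), 3)
#> # A tibble: 3 × 8
#>   lncrna_id mirna_id mrna_id  scc_lnc_mirna scc_mrna_mirna pcc_lnc_mrna
#>   <chr>     <chr>    <chr>            <dbl>          <dbl>        <dbl>
#> 1 LNC0006   mir-0009 MRNA0070        -0.958         -0.957        0.947
#> 2 LNC0018   mir-0077 MRNA0191        -0.970         -0.944        0.965
#> 3 LNC0034   mir-0060 MRNA0020        -0.931         -0.931        0.959
#> # ℹ 2 more variables: shared_mirna_count <int>, hypergeom_p <dbl>

dirs <- bind_rows(as_tibble(de_lnc), as_tibble(de_mrna),
                  as_tibble(de_mir))[, c("feature_id", "direction")]
net <- assemble_network(triads, dirs, comparison = "ovary")
network_stats(net)
#> <cerna_network_stats> 33 nodes, 22 edges
#> # A tibble: 3 × 4
#>   class      n  n_up n_down
#>   <chr>  <int> <int>  <int>
#> 1 lncRNA    11     7      4
#> 2 mRNA      11     7      4
#> 3 miRNA     11     4      7
```

Every accepted triad satisfies the screen's thresholds (the recorded
Spearman values are ≤ −0.7, the Pearson values > 0.9), and the network
counts each triad's two targeting edges after deduplication. The miRNA
regulation directions run opposite to their targets, as the ceRNA
mechanism predicts. `autoplot(de_lnc)` draws the volcano plot,
`autoplot(net)` the network; `export_network(net, dir, "sif")` writes
Cytoscape files.

The whole chain — simulate → identify → de → targets → enrich →
cerna — also runs as a deterministic pipeline with on-disk artifacts
and a manifest:

```r
run_pipeline(pipeline_config(outdir = "run1", seed = 1))
```

or from a shell via `inst/scripts/cernet-pipeline.R`.

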