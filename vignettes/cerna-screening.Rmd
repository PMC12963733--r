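---
title: "Identifying lncRNAs and screening ceRNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lncRNAs and screening ceRNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
library(dplyr)
```

## The analysis in one paragraph

Long non-coding RNAs (lncRNAs) can act as competing endogenous RNAs
(ceRNAs): an lncRNA that shares miRNA binding with an mRNA sponges those
miRNAs away and thereby de-represses the mRNA. The observable signature
in expression data is a triangle — the miRNA anti-correlated with both
the lncRNA and the mRNA, the lncRNA and mRNA positively co-expressed,
and the two targets sharing more miRNAs than chance. `cernet`
implements the post-quantification stages of such a study as composable
tibble-in/tibble-out functions: lncRNA identification from assembled
transcripts, differential expression (DE) with a conditional
negative-binomial (NB) exact test, cis/trans target assignment, term
enrichment, and the triad screen, plus a simulator that plants ceRNA
triads so every stage can be validated against known truth.

## The screening model and its thresholds

A candidate (lncRNA, miRNA, mRNA) triple is accepted when all of the
following hold, with every threshold exposed as an argument and
defaulting to the values customary in these studies:

| filter | rule | default |
|---|---|---|
| structural lncRNA | exon count $\ge 2$ and mature length $> 200$ bp | fixed |
| coding potential | all of CNCI, CPC2, CPAT, PFAM call non-coding | intersection |
| differential expression | $p < 0.05$ and $|\log_2 FC| \ge 0.26$, all three members | both |
| targeting | miRNA→lncRNA and miRNA→mRNA links present | — |
| miRNA vs targets | Spearman $\rho \le -0.7$ for both pairs | $-0.7$ |
| lncRNA vs mRNA | Pearson $r > 0.9$ (strict) | $0.9$ |
| shared miRNAs | hypergeometric upper tail $p < 0.05$ | $0.05$ |

Cis targets are protein-coding genes whose genomic span lies within
100 kb of a DE lncRNA's span (inclusive boundary, distance 0 on
overlap, strand ignored); trans targets are genes with $|r| > 0.95$ and
$p < 0.05$ across the shared samples.

Several of these rules required a choice where common usage varies;
the choices here are:

* **Mature length for the 200 bp rule.** "Length" is the sum of exon
  lengths, not the genomic span — this is how assemblers report
  transcript length, and it is the quantity the 200 nt definition of an
  lncRNA refers to. Users with span-based annotations should be aware
  the two differ for spliced transcripts.
* **Span-to-span distance for the cis window.** The 100 kb window is
  measured between the nearer ends of the two spans (`start2 - end1`
  for disjoint spans), inclusively: a gap of exactly 100,000 bp is
  retained, 100,001 bp is not. TSS-based definitions would be an
  alternative; span distance is the more conservative, symmetric
  reading of "within 100 kb upstream and downstream".
* **Counts are the tested unit.** The NB exact test runs on normalized
  counts; FPKM is computed for description and for the expression
  summaries, not for testing.
* **Both miRNA pairs face the SCC filter.** The negative-correlation
  requirement is applied to miRNA–lncRNA *and* miRNA–mRNA, the stricter
  and more standard ceRNA reading.
* **Raw p-values throughout.** DE, trans, the shared-miRNA test and
  enrichment all use unadjusted p-values by default, matching the
  stated criteria of the studies this pipeline follows;
  `enrich_terms(correction = ...)` offers any `p.adjust` method.
* **The 0.26 boundary.** The DE fold-change rule is $\ge 0.26$ by
  default (`lfc_boundary = "ge"`); the strict variant is one argument
  away, since published wording is inconsistent on this point.
* **Correlations on the log scale.** `trans_targets()` and
  `build_triads()` correlate `log1p`-transformed expression by default.
  Spearman statistics are unchanged by the transform; Pearson on raw NB
  counts is dominated by the heavy lognormal tail (for a latent
  log-scale coupling of strength $\beta$ the raw-scale correlation is
  bounded near $(e^{\beta^2}-1)/(e^{\beta^2}(1+\phi)-1)$, which sits
  below 0.91 at $\beta = 1.5, \phi = 0.1$ no matter how strong the
  biological coupling), so log-scale correlation is the scale on which
  the PCC > 0.9 rule is meaningful. Set `log_transform = FALSE` to
  correlate raw values.

## The NB exact test

edgeR-style machinery is deliberately not called; DE is a
self-contained, documented approximation with three parts:

1. **Normalization.** Total-count scaling of every sample to the
   geometric mean of the library sizes (`normalize_counts()`).
2. **Dispersion.** One common $\phi$ with variance model
   $\mathrm{Var} = \mu + \phi\mu^2$, estimated by method of moments:
   per feature, the pooled within-group variance $s^2$ and grand mean
   $m$ give $(s^2 - m)/m^2$, averaged over features and floored at 0
   (`estimate_common_dispersion()`). `de_test()` uses the robust
   variant (median over features) because a minority of genuinely
   hyper-variable features — exactly what planted ceRNA triads are,
   with latent multiplicative variance $e^{\beta^2} \approx 9.5$ at
   $\beta = 1.5$ — otherwise inflates the common value several-fold and
   destroys power for every feature. This mirrors the motivation for
   the robust dispersion options in the established empirical-Bayes DE
   tools.
3. **The conditional test.** Given group sums $s_A, s_B$ with
   $t = s_A + s_B$, the null common mean is $\hat\mu = t/(n_A+n_B)$
   per sample, group sums are modelled as
   $\mathrm{NB}(n_A\hat\mu, \phi/n_A)$ and
   $\mathrm{NB}(n_B\hat\mu, \phi/n_B)$, the conditional distribution of
   $s_A$ given $t$ is enumerated over $0..t$ in log space, and the
   two-sided p-value sums all outcomes no more probable than the
   observed split (the *minlike* rule — stated explicitly because
   doubling-the-smaller-tail gives different numbers). At $\phi = 0$
   the construction collapses to the conditional binomial exact test,
   which the test suite verifies to $10^{-10}$; for general parameters
   it is verified against brute-force enumeration to $10^{-12}$.
   $t = 0$ returns $p = 1$ by convention, so p-values live in $(0,1]$.

Two behaviours of this stand-in are worth knowing. Exact conditional
tests are conservative at small totals, so the null rejection rate at
$p<0.05$ sits slightly below 0.05 for 3-vs-3 designs (the suite asserts
the 0.02–0.08 band). And total-count normalization carries composition
bias: when a large fraction of the library shifts in one direction,
fold changes of unchanged features are dragged the other way. The
pipeline inherits this deliberately — it is the documented
normalization — and the simulator's default condition effect
(`de_fraction = 0.1` of background features, balanced signs) keeps it
small; at `de_fraction = 0.3` with strong shifts the bias is clearly
visible in the null features' fold changes.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a 3-tissue × 2-condition (laying vs
broodiness) design with a configurable number of replicates (default 3,
the scale of the motivating study; recovery benchmarks use 15). Counts
are NB with $\mathrm{Var} = \mu + \phi\mu^2$ ($\phi = 0$ handled as
Poisson). Each planted triad loads one per-sample standard-normal
latent factor $z_s$ on the natural-log mean: $+\beta$ for the lncRNA
and mRNA, $-\beta$ for the miRNA, which forces exactly the correlation
signs the screen tests. The condition effect is $\pm\delta/2$ log2
units on a feature's log-mean (so the true between-condition
$\log_2 FC$ is $\pm\delta$), applied to every triad member with
coherent signs (lncRNA and mRNA together, miRNA opposite — the
ceRNA-consistent direction) and to a random `de_fraction` of other
features; it acts on the log-mean, not on $z$, so DE truth and coupling
truth are independent knobs. Coding-potential verdicts flip the true
biotype independently per tool with probability `coding_call_flip_rate`
(default 0.1), and interaction tables contain every planted link plus
independent background links at `background_interaction_rate` (default
0.02). All randomness flows from one root seed through fixed per-stage
child seeds, so any stage reproduces independently.

Defaults were fixed once, from the study design and from what is
typical for this kind of data: 300 mRNAs / 150 lncRNAs / 150 miRNAs
(desk-scale catalogs; miRNA count also keeps coupled features a
minority of each class, which any common-dispersion estimate needs),
baseline means log-uniform on 20–500 counts, $\beta = 1.5$,
$\phi = 0.1$, $\delta = 2$, 50 planted triads, mature lengths 300–5000
bp (lncRNA) and 500–9000 bp (mRNA) with 2–5 and 4–16 exons. The mRNA
exon-count range is deliberately compressed relative to real
vertebrate mRNAs so simulated gene spans stay small.

The simulator does **not** emulate: sequence (no reads, no miRNA seed
sites — targeting is injected directly as tables), assembly artefacts,
batch effects, library-composition shifts beyond the planted condition
effect, tissue-specific baselines, or correlated tool errors in the
coding-potential votes. Passing the recovery benchmarks therefore
demonstrates the screen's statistical machinery, not robustness to
those real-data complications.

## What recovery benchmarks show — a known structural limit

With 15 replicates per condition, the correlation and targeting arms of
the screen recover planted triads essentially whenever all three
members pass DE (the suite asserts conditional sensitivity $\ge 0.9$
and precision $\ge 0.9$), and each member passes DE at roughly 0.92, so
the three-way conjunction reaches about 0.8 sensitivity before the
shared-miRNA filter.

The shared-miRNA hypergeometric arm, however, imposes a structural
ceiling on this benchmark. Each planted pair shares exactly **one**
miRNA ($k = 1$), because features belong to at most one triad. With
target sets of size $K$ and $n$ in a universe of $N$ miRNAs,
$P(X \ge 1) \approx Kn/N$, and under background linking at rate $b$ the
sets grow as $1 + b(N-1)$; at $b = 0.02$ the inequality
$(1 + 0.02N)^2 < 0.05\,N$ has no solution in $N$ (negative
discriminant), so a singleton-overlap pair can clear $p < 0.05$ only
when both sets happen to stay near-singletons — at best ~40% of triads
at the optimal universe size. Full-screen sensitivity on this benchmark
is therefore ~0.2–0.3 (precision stays 1.0), and that is a property of
the benchmark's one-shared-miRNA construction, not of the screen: real
ceRNA pairs share many miRNAs, giving $k \gg 1$ and tiny p-values. The
package reports both numbers (`triad_recovery_sensitivity` and
`triad_recovery_sensitivity_correlation_arms` in the acceptance
output) so the two effects stay visible, and the corresponding
full-screen recovery test is left failing rather than weakened.

At study scale (3 replicates, 6 samples per comparison) correlation
estimates at thresholds as extreme as 0.9–0.95 are too noisy for
reliable recovery; there the tests assert only that reported triads
satisfy their own recorded thresholds.

## Numerical and degenerate-input conventions

* Correlations use the direct product-moment formula, which returns
  exactly $\pm 1$ on perfectly monotone input; p-values come from the
  $t = r\sqrt{(n-2)/(1-r^2)}$ transform (two-sided), with $p = 0$ at
  $|r| = 1$ and an error for $n < 3$ or constant vectors. Inside the
  screen, constant rows yield `NaN` correlations and are rejected by
  the thresholds rather than erroring.
* The hypergeometric upper tail is `phyper(k-1, K, N-K, n, lower =
  FALSE)` — exact and stable; $k = 0$ gives $p = 1$.
* The minlike outcome comparison uses a relative tolerance of $10^{-7}$
  when deciding "no more probable than observed", the standard guard
  against ties lost to floating point.
* Normalized group sums are rounded to integers before the conditional
  enumeration; an all-zero feature ($t=0$) gets $p = 1$.
* `nb_exact_test` enumerates $0..t$, so runtime is linear in the total
  count of a feature across the compared samples.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on simulated data at
desk scale: identification benchmarks at 2,000 lncRNAs, the null-size
simulation at 2,000 features × 6 samples, recovery at 600 features × 90
samples with 50 planted triads, and the exhaustive hypergeometric
comparison over every parameter combination with $N \le 25$ (~44,000
cases). These sizes were chosen so the full validation completes in a
few minutes while the binomial/LLN tolerances they assert (3 standard
errors, 5% relative) remain tight.

## A worked example

```{r example, eval = FALSE}
library(cernet)

cfg <- sim_config(seed = 1, n_replicates_per_condition = 15)
ds  <- simulate_dataset(cfg)
ex  <- ds$expression

# identification: structural + 4-tool consensus
lnc <- identify_lncrnas(ds$annotation$transcripts, ds$coding_calls)

# differential expression, ovary comparison
de_lnc <- de_test(ex$lncrna, ex$samples, "laying", "broodiness",
                  tissue = "ovary") |> call_de()
glance(de_lnc)
autoplot(de_lnc)

# ceRNA screen and network
sig <- function(d) d$feature_id[d$significant]
de_mir  <- de_test(ex$mirna, ex$samples, "laying", "broodiness",
                   tissue = "ovary") |> call_de()
de_mrna <- de_test(ex$mrna,  ex$samples, "laying", "broodiness",
                   tissue = "ovary") |> call_de()
triads <- build_triads(sig(de_lnc), sig(de_mir), sig(de_mrna),
                       ds$interactions, ex,
                       sample_ids = ex$samples$sample_id[
                         ex$samples$tissue == "ovary"])
net <- assemble_network(triads, comparison = "ovary")
glance(net)
network_stats(net)
```

Or, end to end with artifacts on disk:

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(outdir = "run1", seed = 1)
run_pipeline(cfg)
```

## Limitations

Beyond the simulator's scope listed above: the DE stand-in has no
tagwise dispersion or TMM normalization, so strongly compositional
libraries bias fold changes; enrichment is a plain hypergeometric
over-representation test with no term topology; known-vs-novel lncRNA
status is decided purely by id membership in a reference list; and the
cis rule knows nothing about regulatory elements — it is a distance
cutoff.
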