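---
title: "Promoter regression modelling of TF binding-site activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter regression modelling of TF binding-site activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promreg)
```

## The model

promreg infers which transcription factors (TFs) drive the expression of a set
of up-regulated genes from two ingredients: their promoter sequences and a
library of position weight matrices (PWMs). The central assumption is a linear
model on the log2 scale,

$$
\log_2(\mathrm{expr}_g + 1) \;=\; \beta_0 + \sum_m \beta_m\, x_{gm} + \varepsilon_g,
\qquad \varepsilon_g \sim N(0, \sigma^2),
$$

where $x_{gm}$ counts the occurrences of binding sites for PWM $m$ in the
promoter of gene $g$ (both strands), and the regression coefficient (RC)
$\beta_m$ measures the activating (positive) or repressing (negative)
contribution of that TFBS. The pipeline has four stages, each usable on its
own:

1. **Motif scanning** (`scan_promoters()`, `tfbs_features()`): every window of
   each promoter is scored on both strands with the information-weighted
   matrix similarity score
   $\mathrm{MSS} = (\mathrm{Current}-\mathrm{Min})/(\mathrm{Max}-\mathrm{Min})$,
   where $\mathrm{Current} = \sum_i I(i) f(i, b_i)$,
   $I(i) = \sum_b f(i,b)\ln(4 f(i,b))$, and Min/Max are the worst and best
   windows the matrix admits; the core similarity score (CSS) is the same
   quantity restricted to the five consecutive positions of maximal summed
   information. Windows passing both cutoffs become hits; hit counts per gene
   and PWM form the feature matrix.
2. **Differential up-regulation** (`call_upregulated()`,
   `partition_upregulated()`): genes up-regulated against control
   (fold change $> 2$, BH-adjusted $q < 0.05$) are split into shared and
   condition-unique sets, and *differentially up-regulated genes* (DUGs) are
   those whose between-treatment mean ratio exceeds 2 in favour of a treatment
   where they are up-regulated.
3. **Model search and RC distributions** (`promoter_lm()`): the best TFBS
   subset (by BIC) is found by exhaustive enumeration up to `max_model_size`;
   a gene-level bootstrap repeats the search `B` times and records each
   TFBS's coefficient (zero when it is not selected), giving a length-`B` RC
   distribution per TFBS tested against zero by a one-sample t-test with
   Bonferroni control. Comparing two conditions classifies each TFBS as
   `identical`, `opposite`, `unique_to_*` or `not_significant`
   (`classify_tfbs()`).
4. **Network assembly** (`candidate_tfs()`, `build_network()`): TFs bound to
   significant TFBSs whose own coding genes are up-regulated are linked to
   every DUG whose promoter carries at least one of their sites; networks
   from separate analyses merge by node/edge union and export to SIF,
   GraphML or edge lists for graph viewers.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mss_cutoff`, `css_cutoff` | 0.85, 0.90 | minimum matrix / core similarity for a hit; `[0, 1]`, dimensionless. Per-matrix tuned profiles (minimizing false positives or negatives) are the usual practice when available; fixed conservative values are used here and can be overridden per scan. |
| `fc_threshold`, `fdr_threshold` | 2, 0.05 | up-regulation calls: abundance-scale fold change and BH q-value. |
| `pseudocount` | 1 | added to both condition means in every fold-change ratio; guards division by zero on FPKM-scale data. |
| `min_abundance` | 1 | a gene is "expressed" when some condition's mean exceeds this (FPKM-like units); conventional, configurable. |
| `max_model_size` | 10 | largest TFBS subset fitted; exhaustive enumeration is guarded by a `budget` of $10^6$ subsets, beyond which `mode = "forward"` (greedy stepwise, same criterion) is required. |
| `B` | 1000 | RC replicates per TFBS. |
| `alpha` | 0.01 | Bonferroni-adjusted significance level for RC tests. |

## Design choices where the design was open

* **Fit criterion.** "Well-fitted" admits several readings; BIC is the
  default because it penalizes model size and so makes "best combination"
  well-defined with a deterministic tie-break (smaller subset, then
  lexicographic TFBS order). Adjusted $R^2$ is available via
  `criterion = "adjr2"`.
* **Where the B coefficients come from.** The RC-replication scheme is a
  declared choice: the default is a seeded gene-level bootstrap of the whole
  model search, the standard way to obtain coefficient replicates; an
  alternative (`scheme = "subsets"`: B random feature subsets fitted on the
  full data) sits behind the same interface. A TFBS absent from a replicate's
  winning model contributes RC 0, keeping every distribution exactly length
  `B`; conditioning on inclusion instead is a one-line change in `test_rcs()`
  inputs.
* **DE engine.** Up-regulation is called with Welch's t-test on
  `log2(x + 1)` replicate values plus BH correction — deliberately a plain,
  transparent engine. The thresholding logic around it (the fold-change and
  FDR gates, the partition, the DUG rule) is the part the package fixes; the
  test behind the p-value is pluggable.
* **DUG direction.** A DUG is assigned to the treatment with the larger
  condition mean (ratio $> 2$ with the pseudocount) *and* must be
  up-regulated versus control in that treatment, matching the two-branch
  partition diagram the analysis follows.
* **Coordinates.** Hits are reported 0-based, half-open, on the plus strand
  (BED convention); `core_start` on a PWM object is 1-based, as R indexing
  makes natural.

## Numerical choices

* Window scores and their Min/Max normalizers are accumulated position by
  position in the same order, so a consensus window scores exactly
  `mss = 1` and an anticonsensus exactly 0 — cutoff-1.0 scans are exact, not
  tolerance-based.
* In the subset search, RSS is floored at `1e-12 * TSS` before the criterion
  is evaluated, so numerically perfect fits share one criterion value and the
  smallest such subset wins; collinear subsets (Cholesky failure on the
  normal equations) are treated as worse than any valid fit.
* `N` bases contribute the row-minimum score, so ambiguity can never create
  a hit; all-uniform matrices have zero score range and score 0 with a
  warning.
* Count matrices read from TRANSFAC- or JASPAR-style files get a pseudocount
  of 0.01 per cell before row normalization, keeping information weights
  finite.
* Degenerate bootstrap resamples (constant response) are redrawn, up to
  `10 * B` attempts, and the redraw count is recorded.

## What the synthetic generator emulates — and what it does not

`simulate_study()` builds the ground-truth scenario used throughout the test
suite: uniform-background promoters (0.25 per base) with planted *consensus*
occurrences of simulated PWMs, and replicate expression generated from the
linear model above with the link $2^x - 1$ (the exact inverse of the
`log2(x + 1)` transform applied downstream). Plants are consensus strings
rather than probabilistic PWM draws so that a scan at cutoff 1.0 recovers
them exactly, making recovery testable without tolerance judgement calls.
Default study conditions mirror a desk-scale version of the analysis the
package implements: 300 genes, 10 PWMs of width 6–10, 500-bp promoters,
plants drawn Binomial(2, 0.25) per gene and PWM, two treatments plus control
with 4 replicates each, replicate noise 0.5 on the log2 scale, and B = 200
bootstrap replicates in the heavier experiments (B = 1000 remains the
user-facing default). Each generator operation draws from its own seeded RNG
stream, so adding one never perturbs another's output.

Real data differ in ways the generator deliberately ignores: non-uniform and
GC-biased backgrounds, degenerate (non-consensus) binding sites, correlated
TFBS occurrences, isoform structure, and library-level count noise. Passing
the synthetic suite therefore demonstrates that the machinery is correct
under its own assumptions, not that those assumptions hold for any given
RNA-seq experiment.

## A known limitation: the RC t-test is anti-conservative

The one-sample t-test on a bootstrap RC distribution tests the *set of
replicates*, not the underlying coefficient. For a TFBS with no true effect
that enters the winning model in $k$ of $B$ resamples — almost always with a
sign fixed by the realized sample correlation, which every resample shares —
the distribution is $k$ similar values and $B-k$ zeros, and its t-statistic
is approximately $\sqrt{k}$ regardless of the coefficient's size. Any TFBS
selected in more than roughly a dozen replicates therefore reaches Bonferroni
significance, whatever `B` is. In the package's own 20-seed recovery
experiment the two planted TFBSs are recovered with correct signs in every
repetition, but 35–45% of null TFBSs are also flagged. Selection frequency
(reported in every `promoter_lm()` summary) and the RC magnitude are the
practical guards: a "significant" TFBS selected in 7% of replicates with a
mean RC of 0.01 is a different object from one selected in 100% of replicates
with a mean RC of 2. Interpreting significance flags without those two
columns is not recommended.

## Problem sizes

The test suite and the acceptance script run the recovery experiment at 300
genes x 10 PWMs x 200 bootstrap replicates x 20 seeds, scan oracle checks on
promoters up to 60 bp, exhaustive-search oracle checks up to 12 TFBSs at
subset size 3, and hypergeometric enumeration over all universes up to 12
genes — sizes chosen so every oracle can be brute-forced exactly while the
regression stage still operates in its intended regime (many more genes than
selected features).
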