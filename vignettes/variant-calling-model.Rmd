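---
title: "Calling amplicon sequence variants against a depth-calibrated error background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling amplicon sequence variants against a depth-calibrated error background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hashsv)
```

## The problem

Deep 16S rRNA amplicon sequencing resolves community members down to single
nucleotide differences, but the same depth that makes this possible also
guarantees that sequencing errors are observed many times over. For a parent
sequence of length $L$ there are $3L$ possible single-substitution variants,
and with enough reads essentially *all* of them will appear in the data.
The task of a sequence-variant caller is to decide which observed variants
are biological and which are the error cloud of a more abundant neighbor.

`hashsv` takes a deliberately simple and conservative route. It ignores
quality scores entirely, pools all samples into one analysis, and asks a
single statistical question per variant: *is this sequence more abundant
than sequencing error of its parent can explain, given how deeply the
parent was sequenced?*

## The procedure

1. **Dereplication.** All reads are trimmed to one constant length and
   counted per sample in a hash map — linear time in the number of reads.
   Within each sample, sequences seen exactly once (singletons) are
   zeroed out, so every retained variant has total count $\ge 2$.
2. **One-mismatch clustering.** Variants are sorted by total abundance.
   The most abundant unassigned variant becomes a cluster *parent*; all
   unassigned variants at Hamming distance exactly 1 (found by probing the
   hash with the parent's $3L$ neighbors, never by pairwise comparison)
   become its *children*, and the procedure repeats on the remaining pool.
   Every variant ends up in exactly one cluster. Ties in abundance are
   broken lexicographically so the partition is deterministic.
3. **Error-rate fit (diagnostic).** If each base mutates independently with
   probability $P$, a specific one-mismatch child of a parent with depth
   $P_i$ is seen at least once with probability
   $$1 - e^{-P_i P / 3},$$
   the zero term of a Poisson with rate $P_i P/3$ (the factor 3 because
   each position can mutate to three alternative bases). Fitting this
   one-parameter curve to the observed fraction of possible children per
   cluster, by least squares on the fraction scale, yields a single
   per-base error rate for the whole run.
4. **Abundance inference.** The Poisson distribution badly underestimates
   the spread of child abundances (counts are overdispersed), so the
   final test instead models $\log_{10}$ child abundance as normal. The
   background mean $M_i$ and standard deviation $S_i$ for cluster $i$ are
   each the **maximum** of the cluster's own statistics and a LOESS
   regression of those statistics on $\log_{10}$ parent abundance across
   all clusters. Each child with abundance $C_{ji}$ receives the one-sided
   upper tail
   $$p_{ji} = \Pr\!\left\{ \mathcal{N}(M_i, S_i) \ge \log_{10} C_{ji} \right\},$$
   p-values are Benjamini–Hochberg adjusted over all tested children, and
   a child is called a true variant when its q-value falls below the FDR
   threshold (default 0.05). Parents of retained clusters are called true
   unconditionally.

The max rule is what makes the caller conservative: wherever the local
regression and the cluster disagree, the wider background wins, so sparse
clusters cannot manufacture significance out of a tiny sample SD.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `trim_length` | — | constant read length (nt); shorter reads are discarded, longer ones 3'-truncated |
| `min_parent_abundance` | 1000 reads | clusters with shallower parents are filtered, untested. Below roughly 1,000 reads the mean/SD-vs-depth relationship becomes too noisy to calibrate; very deep runs may warrant 10,000 |
| `fdr` | 0.05 | BH false-discovery-rate threshold for calling children |
| `loess_span` | 0.75 | span of the degree-2 local regression for both background curves |
| `sd_floor` | 1e-3 | lower bound on the background SD (log10 scale), keeps the normal tail defined when fitted SDs collapse |
| `error_handling` | `"collapse"` | counts of children called `error` are added back to their parent (preserves read depth); `"drop"` discards them |

The abundance filter applies to *clusters through their parent's total
abundance*: a significant child below the threshold is still reported,
because the threshold exists to avoid testing in the sparse regime, not to
censor discoveries.

## What the simulator emulates — and what it does not

`simulate_reads()` models a polymerase/sequencer that copies each template
with an independent per-base substitution probability, choosing uniformly
among the three alternative bases. Per read, the number of substituted
positions is drawn from Binomial($L$, $P$) and positions are placed without
replacement — identical in distribution to per-base Bernoulli sampling but
much faster at realistic rates. Reads are dealt round-robin across samples,
and a truth table records every biological sequence, so calls can be scored
exactly.

The simulator does **not** model: quality-score structure (the caller never
uses it), PCR chimeras, indels (the caller treats an indel variant as a
separate parent), nucleotide- or position-specific error rates, sample-wise
abundance heterogeneity, or PCR-amplification overdispersion. That last
omission matters for interpretation: on simulated data child counts really
are Poisson, so the Poisson abundance test is roughly calibrated there,
whereas on real data it is grossly anticonservative. The package's test
suite therefore demonstrates the Poisson test's anticonservativeness
through the one bias the pipeline does induce — presence/absence fractions
computed after singleton removal are truncated, the fitted rate drops, and
the Poisson test inflates — which reproduces the qualitative contrast
(Poisson calls many children, the normal background calls almost none)
without claiming to reproduce any real data set's numbers. Passing tests
show the machinery is correct and conservative under its own model; they
do not certify sensitivity or FDR on real amplicon chemistry.

## Numerical choices

* **Error-rate fit.** Unweighted least squares of the observed against the
  expected child fraction, minimized over $P \in [10^{-7}, 10^{-1}]$ with a
  bounded scalar search carried out on the $\log_{10} P$ scale (uniform
  relative precision across five decades). Degenerate inputs — no children
  anywhere — are an error rather than a boundary estimate. Fits from fewer
  than 10 clusters or less than two decades of parent depth warn.
* **LOESS.** Degree 2, tricube weights, span 0.75, exact (`"direct"`)
  surface so predictions are defined everywhere; predictions are clamped to
  the fitted depth range, because polynomial extrapolation beyond the
  deepest fitted parent is wild exactly where the deepest clusters live.
  Fitted SDs are floored at `sd_floor`.
* **Small runs.** The LOESS needs at least 10 clusters with defined
  statistics for each curve. Below that, `run_pipeline()` falls back (with
  a warning) to a constant background — the pooled mean and SD of all
  log10 child abundances. This keeps desk-scale data (e.g. an eight-member
  mock community, which yields eight clusters) runnable; the max rule then
  compares each cluster against the pooled spread.
* **Singletons and trimming.** Reads are trimmed first; singletons are
  defined on trimmed sequences, per sample. Primer matching is an exact
  anchored IUPAC prefix match with no mismatch tolerance — deterministic,
  at the cost of discarding reads with a sequencing error inside the
  primer.
* **Ties.** Equal-abundance candidates are ordered lexicographically by
  sequence everywhere (parent selection, output ordering), which makes
  reruns byte-identical.
* **Count conservation.** With `error_handling = "collapse"`, reads of
  error children return to their parent, so the final table conserves the
  dereplicated read count *within retained clusters*. Clusters removed by
  `min_parent_abundance` leave the table entirely; global conservation
  holds exactly when nothing is filtered.

## Design choices that were genuinely open

* The BH family is *all tested children in one run*, not per cluster or
  per sample — the run is the unit of inference here, since all samples
  are pooled anyway.
* The cluster's own mean and SD include the tested child itself. This is
  the conservative reading (an abundant true child inflates its own
  background), and it is what the max-rule formulas operate on.
* Non-significant children default to collapsing into their parents
  because discarding them would silently shrink library sizes; `"drop"`
  is available for users who want an errors-removed table.
* The Poisson abundance test is exported for diagnostics and comparison
  but is never used for final calls.

## Problem sizes used in the validation suite

The packaged tests run entirely on simulated data: one million 250-nt
reads for the multi-mismatch-rarity check, 100 simulated clusters spanning
depths $10$–$10^5$ for error-rate recovery, 50 random instances of up to
300 variants for brute-force clustering equivalence, three replicate
error-only communities of 25 parents (depths $3\times10^3$–$6\times10^4$)
for FDR behavior, and an eight-parent mock community at depths
$10^4$–$5\times10^4$ for end-to-end recovery. These sizes make the whole
suite run in a couple of minutes while leaving each statistical check
well-powered.

## Known limitations

* Insensitive to true low-abundance variants by design; a variant whose
  parent cluster is filtered is never tested.
* One-mismatch only: a true variant two substitutions from its nearest
  abundant neighbor forms its own parent and is called (if deep enough),
  but the error model never links it to that neighbor. Long-read data
  violate the multi-mismatch-rarity assumption underlying this.
* Indels are not modeled; an indel variant of length different from
  `trim_length` is discarded at trimming.
* No compositional correction of the resulting count table.
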