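---
title: "Replicon copy number, polyploidy and plasmid stability from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicon copy number, polyploidy and plasmid stability from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bacteria with multipartite genomes — a chromosome plus several plasmids, as
in *Aminobacter* sp. MSH1 with its seven plasmids (pBAM1, pBAM2,
pUSP1–pUSP5) — routinely show plasmid sequencing depth well below the
chromosome's. Two very different biological explanations produce the same
depth signal:

* **unstable inheritance**: only a fraction *c* of cells carry the plasmid,
  so the bulk culture contributes fewer plasmid reads per cell;
* **chromosome polyploidy**: every cell carries the plasmid once, but the
  chromosome is present in *P* > 1 copies per cell, inflating the
  denominator.

The depth statistic used throughout is **NormCov**: the mean read depth in a
window divided by the mean depth of the chromosome,

$$\mathrm{NormCov}_w \;=\; \frac{\bar d_w}{\mu_{chr}},\qquad
  \mu_{chr} \;=\; \frac{\text{aligned bases on the chromosome}}{L_{chr}}.$$

NormCov of 1 means one replicon copy per chromosome copy. Under a population
model with ploidy $P$, per-carrying-cell copy number $CN$ and carriage $c$,
the expected replicon-level NormCov is $c \cdot CN / P$ — so a bulk value of
0.5 is equally consistent with $(c = 0.5, P = 1)$ and $(c = 1, P = 2)$.

The ambiguity is resolved by a **colony panel**: pick $n$ clonal colonies
(each founded by a single cell) and score each plasmid present/absent. Under
instability with carriage $c$, the number of colonies lacking the plasmid is
$X \sim \mathrm{Binomial}(n, 1 - c)$; with $c \approx 0.5$ and $n = 14$,
about half the colonies should have lost it. Under polyploidy, losses occur
only at a small background rate $\varepsilon$. Observing $k$ losses, the
package reports the exact lower tail

$$p = P(X \le k \mid X \sim \mathrm{Binomial}(n, 1-\hat c)),
  \qquad \hat c = \min(\mathrm{NormCov}, 1),$$

computed by direct summation of binomial point masses, together with the
log-likelihood ratio
$\log_{10} \mathrm{Binom}(k; n, \varepsilon)/\mathrm{Binom}(k; n, 1-\hat c)$.
The verdict is `polyploidy_supported` when $p < \alpha$ **and** the ratio
favours the background model, `instability_supported` when $p \ge \alpha$
and the ratio favours the instability model, and `inconclusive` otherwise.
Note the direction: $p$ is non-*decreasing* in $\hat c$ — higher carriage
means fewer expected losses under the instability null, making a small $k$
less surprising.

## The pipeline

```{r}
library(normcov)

cfg <- experiment_config(seed = 1, out_dir = "run",
                         ploidy = 2, plasmid_copy = 1, carriage = 1)
res <- run_experiment(cfg)
res$estimates          # per-replicon NormCov with bootstrap intervals
res$report$tests       # per-plasmid stability verdicts
```

`run_experiment()` chains the stages: simulate a genome for the registry (if
no sequenced genome is supplied), simulate a bulk paired-end library, compute
windowed depth and NormCov, estimate per-replicon copy number, sequence `n`
simulated clonal colonies, score plasmid presence from each colony's own
NormCov, and run the binomial test per plasmid. Every output file carries a
provenance header (package version, seed, configuration hash) and reruns with
the same seed are byte-identical.

## The synthetic-data generator

The generator emulates the study conditions:

* **Genome**: the eight MSH1 replicons at their published lengths and GC
  (chromosome 5,301,518 bp; pBAM1 40,559; pBAM2 53,893; pUSP1 367,423;
  pUSP2 365,485; pUSP3 97,029; pUSP4 64,122; pUSP5 31,577; total
  6,321,606 bp), with i.i.d. random sequence at the target GC.
* **Population**: ploidy is a population constant (the contrast of interest
  is medium-dependent ploidy, not cell-to-cell variance); plasmid presence
  events are independent across plasmids (independence is the null — a
  shared-loss hook exists for sensitivity work but defaults off); fractional
  copy numbers such as 2.5 are abundance weights over carrying cells, not
  per-cell integers.
* **Reads**: 2 × 151 bp pairs, insert 400 ± 40 bp, 100,000 pairs for a bulk
  library and 5,000 per colony; replicons are drawn per fragment with
  probability proportional to `effective copies × length` (i.i.d. across
  fragments — equivalent in expectation to per-cell draws and simpler);
  substitution errors default to 0; qualities are constant Q40 and unused.

What it does **not** emulate: mapping ambiguity and repeats (truth
alignments replace a mapper), GC-dependent coverage bias, indel and
quality-pattern errors, mate merging of overlapping pairs, and origin-biased
replication gradients. Passing tests therefore demonstrate correctness of
the statistics given correct alignments, not robustness to mapping artefacts
in real libraries.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; SAM POS (1-based) and VCF POS
  are converted at the file boundary. Circular topology is recorded but
  windows and fragments never wrap the origin; at these replicon sizes the
  edge deficit is negligible and replicon-level means are unaffected (the
  total of aligned bases does not depend on placement).
* Fragment starts are uniform over **all** placements `0 … L − fragment`
  inclusive, so the last base of a replicon is coverable; fragment lengths
  are normal, truncated to `[read length, L)`. Replicons no longer than one
  read are excluded with a warning.
* The trailing partial window keeps its actual width and all replicon-level
  summaries weight windows by width, so partial windows introduce no bias;
  the replicon-level NormCov is then exactly the total-depth ratio and is
  invariant to window size (verified to 1e-9 across 1/1000/10000 bp).
* `mu_chr` is the per-base mean over the whole chromosome (total aligned
  bases / length), not the mean of window means; the two coincide except for
  the partial-window effect, and the per-base form is well-defined always.
* Overlapping mates double-count by default, matching standard depth
  tooling; `windowed_depth(..., double_count = FALSE)` subtracts the mate
  overlap instead.
* Default analysis window: 1000 bp. Bootstrap: percentile over windows,
  1000 replicates, seeded.
* `N` bases count toward replicon length but never toward GC or pileup
  depth. GC skew is `(G − C)/(G + C)` with 0 reported for GC-free windows.
* The variant screen interprets the 35% consensus cutoff as
  alternate-allele fraction ≥ 0.35 (inclusive boundary); minimum depth 10.
  Two-sample site classes use 0.05/0.95 as absent/fixed bounds. Indels are
  out of the caller's scope: the alignment dialect is M-only and the
  simulator produces no indels.
* $\varepsilon$ (background loss under polyploidy) defaults to 0.02 — small
  but nonzero, consistent with a single observed loss among 14 colonies —
  and every report includes a sensitivity sweep over
  {0.005, 0.01, 0.02, 0.05, 0.1}. No multiple-testing correction across
  plasmids by default.
* Colony presence is scored from the colony library's own NormCov with a
  floor of 0.05; with ≥ 1,500 error-free pairs a present plasmid is
  essentially never missed and an absent one yields zero reads.

## Problem sizes in the test suite

Unit and property tests run on scaled-down genomes (tens of kb) chosen so
each statistical check retains ≥ 3-sigma headroom: multinomial
goodness-of-fit at 50,000 pairs, copy-number recovery over the
ploidy {1,2,3} × CN {0.5,1,2.5} grid at 100,000 pairs (relative error
< 5%), colony-panel calibration and power on 10,000 panels of 14. The
mixture heterogeneity check engineers 30 SNVs at 60/40 haplotype fractions
and sequences to ~2000× mean depth; at the 35% cutoff the per-site miss
probability is then ~1e-5, so "every site called, none invented" is a sound
assertion (at the 50× floor a 40% allele would drop below 35% in a quarter
of sites by sampling alone). Full-registry simulations (6.32 Mb, 100,000
pairs) back the band-recovery checks.

## Limitations

* The package quantifies *consistency* with polyploidy; it does not estimate
  the ploidy value beyond the descriptive `1/NormCov`, and it cannot
  distinguish sub-unit average copy numbers from mixtures of integer copy
  numbers — both render as abundance weights.
* The instability null treats carriage as equal to bulk NormCov capped at 1;
  bulk NormCov > 1 is itself evidence against instability and is flagged.
* Truth alignments sidestep mapping; applying the coverage and pileup stages
  to real BAM-derived SAM requires the upstream mapper to emit M/=/X-only
  CIGARs or a conversion step.
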