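# normcov

Replicon copy number, chromosome polyploidy and plasmid stability from
sequencing read depth, for bacteria with multipartite genomes.

## The problem

In a multi-replicon bacterium such as *Aminobacter* sp. MSH1 (a chromosome
plus seven plasmids, 6.32 Mb in total), several plasmids sequence at a depth
well below the chromosome's. Two hypotheses explain a depth ratio of, say,
0.5: only half the cells carry the plasmid (unstable inheritance), or every
cell carries it once but the chromosome is diploid (polyploidy). `normcov`
implements the complete analysis that separates them, plus the synthetic
data generators needed to validate it:

* **NormCov** — windowed read depth divided by the chromosome mean depth
  `mu_chr = aligned chromosome bases / L_chr`. NormCov 1 ⇒ one replicon copy
  per chromosome copy; under ploidy *P*, carriage *c* and copy number *CN*
  the expectation is *c·CN/P*.
* **Colony-panel test** — among *n* clonal colonies the instability
  hypothesis predicts `X ~ Binomial(n, 1 − ĉ)` colonies losing the plasmid
  (ĉ = min(NormCov, 1)). The package reports the exact tail
  `p = P(X ≤ k)` by direct summation and the log₁₀ likelihood ratio against
  a small background loss rate ε, and issues a verdict
  (`polyploidy_supported` / `instability_supported` / `inconclusive`).
  With NormCov ≈ 0.5 and n = 14, instability predicts ~7 losses; observing
  k = 1 gives p = 15/16384 ≈ 9.2e−4.
* **Heterogeneity screen** — pileup base counts with variants called at an
  alternate-allele fraction ≥ 0.35 (depth ≥ 10), and a two-sample
  classification into fixed differences vs shared/private heterogeneity.
* **Simulators** — random replicons at target GC (including the full MSH1
  registry: chromosome 5,301,518 bp; pBAM1 40,559; pBAM2 53,893; pUSP1
  367,423; pUSP2 365,485; pUSP3 97,029; pUSP4 64,122; pUSP5 31,577),
  populations with ploidy/copy-number/carriage, clonal colony founders,
  paired-end 2×151 bp reads with truth alignments (minimal SAM), FASTQ/VCF
  writers, GC and GC-skew tracks.

## Worked example

Simulate the registry genome with a diploid chromosome and single-copy
plasmids, sequence 100,000 pairs, and estimate copy numbers:

```r
library(normcov)

g   <- simulate_genome(msh1_registry(), seed = 1)
m   <- population_model(g, ploidy = 2, plasmid_copy = 1, carriage = 1)
sim <- simulate_reads(m, read_pair_spec(100000, seed = 11))
nct <- normcov(windowed_depth(sim$alignments, 1000), chromosome = "chromosome")
copy_number_summary(nct, seed = 5)
#>     replicon normcov_mean normcov_median    ci_low   ci_high n_windows
#> 1 chromosome    1.0000000      0.9897969 0.9939027 1.0060231      5302
#> 2      pBAM1    0.5275529      0.5296501 0.4820770 0.5719968        41
#> 3      pBAM2    0.5383610      0.5362924 0.4961210 0.5821844        54
#> 4      pUSP1    0.4848728      0.4718911 0.4677060 0.4998278       368
#> 5      pUSP2    0.5095570      0.4973051 0.4930120 0.5274206       366
#> 6      pUSP3    0.5159493      0.4973051 0.4850023 0.5441417        98
#> 7      pUSP4    0.4860301      0.5046212 0.4446745 0.5320012        65
#> 8      pUSP5    0.5339893      0.5555454 0.4760334 0.5941227        32
```

Every plasmid sits near NormCov 0.5 — one copy per *cell*, two chromosomes
per cell. The chromosome is exactly 1 by construction (self-normalization).
A colony panel then separates the hypotheses:

```r
test_stability(0.5, n = 14, k = 1, epsilon = 0.02)
#> <stability_test> NA: c_hat=0.500, k=1/14, p=0.000916, log10 LR=2.40 -> polyploidy_supported
```

The full pipeline (bulk library → NormCov → 14 simulated colonies →
per-plasmid verdicts, all written as TSV/JSON with provenance headers) is
`run_experiment(experiment_config(...))`; see the vignette in
`vignettes/replicon-stability.Rmd` for the model, the generator's scope and
all numerical choices.

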