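# pileupcall

Bayesian consensus base calling and cross-platform read-quality
benchmarking on synthetic bacterial genomes.

## What it does, and for whom

`pileupcall` is for people studying how short-read platform characteristics
— read length, per-base accuracy, position-dependent error, and the
fraction of unmappable "junk" reads — propagate into single-base
substitution (SNP) detection. It re-implements, as a tested R pipeline, a
classic three-platform comparison workflow (FLX-style long reads, GA-style
36 bp reads with a rising 3' error ramp, SOLiD-style short reads with ~50%
junk):

1. **Simulate** a reference genome (default 50.8% GC) with near-identical
   repeat units emulating rRNA operons, a sample genome with planted
   substitutions, and platform-styled read sets with known ground truth.
2. **Preprocess** — trim bases with quality value (QV) below 0, drop reads
   shorter than 32 bases, strip adapters.
3. **Map** reads ungapped with at most 3 mismatches, with the two
   multi-mapping policies the analysis needs: *best_all* (tied reads placed
   everywhere, for quality statistics) and *unique_only* (tied reads
   excluded, for calling).
4. **Estimate** the empirical read-probability matrix
   `p(b'|b) = (m(b'|b) + c) / Σ(m(b'|b) + c)` from aligned (reference base,
   read base) pairs.
5. **Call** the consensus base per position from the multinomial pileup
   likelihood under a uniform prior,

   ```
   P(N_i | b) = n_i! / Π N_i(b')!  ×  Π p(b'|b)^N_i(b')
   P(b | N_i) ∝ P(N_i | b)
   ```

   reporting a significant substitution where the consensus differs from
   the reference with posterior above 1e-8.
6. **Evaluate** TP/FP/FN against the planted truth (with uncovered false
   negatives split out), subsample reads over the twofold ladder 1/32 … 1/2,
   and fit the saturation model `TP(n) = T (1 − A n^−B)` to detection
   counts versus mean coverage `n`.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

```r
library(pileupcall)

cfg <- pipeline_config(genome_length = 20000, n_substitutions = 100,
                       repeat_unit_length = 1000, profiles = c("flx", "ga"),
                       mean_coverage = 15, seed = 7)
bundle <- run_pipeline(cfg, quiet = TRUE)

bundle$mapping_summary
#>   profile reads_total mapped_ratio_pct accuracy_pct mean_coverage uncovered_bases
#> 1     FLX        1250          82.8000     99.69750      34.14925             215
#> 2      GA        8268          63.5462     96.15543      28.73275              12

bundle$evaluation
#>   profile mean_coverage TP FP FN FN_uncovered
#> 1     FLX       8.78365 87  3 13           13
#> 2      GA       6.21175 95  9  5            5
```

Reading the numbers: the GA-like set maps worse (63.5% of reads) and is
less accurate per base (96.2%) because of its junk fraction and 3' error
ramp — yet after trimming it still detects most planted substitutions,
at the price of more false positives under the permissive 1e-8 posterior
threshold. The FLX-like run's false negatives are all *uncovered*
positions: sites inside the identical repeat units (and their
low-unique-coverage shadows), where unique-only mapping excludes every
read — the synthetic analogue of substitutions hidden in rRNA operons.
`mapping_summary$mean_coverage` uses best_all mapping, where reads tied
across the 7 repeat copies are counted at every copy; the evaluation
rows show the lower unique-only coverage used for calling.

```r
ga <- subset(bundle$saturation, profile == "GA")
fit <- fit_saturation(data.frame(n = ga$mean_coverage, TP = ga$TP))
fit
#> <saturation_fit> TP(n) = T (1 - A n^-B)
#>   T = 159.6, A = 0.5862, B = 0.2611, SSE = 331.8
autoplot(fit)
```

A shallow exponent and an asymptote far above the observed counts are the
signature of an unsaturated data set: at these coverages the GA-like run
has not yet reached its detection plateau.

A thin command-line wrapper with subcommands
(`simulate trim map stats errmatrix call evaluate saturate run`) is
installed as `exec/pileupcall`.

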