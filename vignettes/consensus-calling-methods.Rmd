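---
title: "Bayesian consensus base calling and platform read-quality benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian consensus base calling and platform read-quality benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pileupcall)
```

## The problem

Early short-read sequencing platforms differed sharply in read length,
per-base accuracy, the position-dependence of their errors, and the fraction
of reads that cannot be placed on the genome at all ("junk": adapter
artifacts, polyclonal beads, optical noise). `pileupcall` implements, as a
reusable and fully tested pipeline, the analysis used to compare such
platforms on a common bacterial DNA sample and to detect single-base
substitutions between two strains: ungapped mapping under a mismatch budget,
empirical error-matrix estimation, multinomial-likelihood Bayesian consensus
calling, and a coverage-subsampling saturation analysis. Because the original
raw read sets are not openly deposited, the package ships a synthetic-data
module that emulates the three platform styles with known ground truth;
every downstream stage is exercised against planted truth rather than
against irreproducible external data.

## The model

### Mapping

Reads are aligned ungapped to both strands of the reference at every fully
contained offset with Hamming distance at most `max_mismatch` (default 3);
quality values are ignored during mapping. Among a read's candidate
placements the minimum-mismatch stratum is kept. Two multi-mapping policies
mirror the two analysis stages:

* **best_all** — a read tied at several positions is placed at all of them,
  as if multiplied. Used for the read-quality comparison (mapped ratio,
  per-base accuracy, mismatch-by-cycle profile, uncovered bases).
* **unique_only** — reads with tied best placements are excluded entirely.
  Used for substitution calling, where a misplaced read would corrupt the
  pileup.

The implementation is a pigeonhole seed-and-extend search in C++ (any
placement with at most *m* mismatches must contain at least one exact 8-mer
among *m*+1 disjoint seed windows), but correctness is *defined* by exact
equivalence to an exhaustive every-offset scan, which the test suite and
acceptance script verify on random genomes, including tie multiplication and
unique-only exclusion. Gapped alignment is deliberately out of model: the
method counts mismatches only, so homopolymer indel errors typical of
flowgram chemistry appear as unmapped reads rather than as shifted
alignments (a known limitation).

### Error matrix (read probability)

From a unique-only alignment set the package tallies every aligned pair
(reference base $b$, read base $b'$), complementing minus-strand reads into
reference orientation, and row-normalises with additive smoothing:

$$p(b' \mid b) = \frac{m(b'\mid b) + c}{\sum_{b'} \left( m(b'\mid b) + c \right)}$$

The matrix is pooled over all genome positions. The pseudocount defaults to
$c = 1$ (add-one smoothing): the calling likelihood raises these
probabilities to per-position depth powers, so a structural zero would let a
single stray read assign zero posterior to a base regardless of all other
evidence. With genome-scale counts (millions of aligned bases) the smoothing
is numerically negligible; it matters only as a guard.

### Consensus calling

Let $N_i(b')$ be the pileup count of base $b'$ at position $i$ and
$n_i = \sum_{b'} N_i(b')$. Under the hypothesis that the sample genome's
base is $b$, the observation probability is multinomial:

$$P(N_i \mid b) = \frac{n_i!}{\prod_{b'} N_i(b')!} \prod_{b'} p(b' \mid b)^{N_i(b')}$$

With a uniform prior of 1/4 per base, Bayes' theorem gives the posterior
$P(b \mid N_i) \propto P(N_i \mid b)$, normalised over the four bases. The
consensus is the posterior argmax; a position is reported as a significant
substitution when the consensus differs from the reference base and its
posterior exceeds the threshold (default $1\times10^{-8}$, applied as
strictly greater-than). Depth-0 positions are uncovered and never called.

Numerical choices:

* All likelihoods are evaluated in log space and normalised with
  log-sum-exp: observed depths in this kind of data reach several hundred
  fold, and a direct product of hundreds of probabilities underflows double
  precision.
* The multinomial coefficient cancels in the posterior normalisation; the
  package computes it in `observation_log_probability()` (whose contract is
  the full multinomial) but omits it in the vectorised whole-genome path.
  A dedicated test asserts the two give identical posteriors.
* Posterior ties are broken towards the lexicographically smallest base and
  flagged `ambiguous` (the underlying method statement never discusses
  ties; with empirical diagonal-dominant matrices they essentially never
  occur at positive depth).
* The $10^{-8}$ threshold is strikingly permissive — at any realistic depth
  the winning posterior is near 1 — and the package applies it literally,
  with no hidden extra filter such as a minimum depth. It is configurable.
  The practical consequence is visible in the synthetic experiments: with an
  elevated error rate and shallow subsampled coverage, false positives rise,
  which is exactly the behaviour the coverage-saturation analysis is meant
  to expose.

The posterior path is verified against an exact-arithmetic oracle: with
matrix entries expressed as integer numerators over a power-of-ten
denominator, every intermediate for depths up to 5 is an exactly
representable integer, so the oracle posterior is exact and the log-space
implementation must agree to within $10^{-12}$ relative error on all 126
count vectors.

### Evaluation and saturation

Calls are scored against the planted truth: a true positive must match both
position and alternative base (a wrong-alt call is a detection failure —
one false positive plus one false negative); false negatives at depth-0
positions are reported separately as uncovered. The coverage experiment
resamples fractions 1/32 to 1/2 (twofold ladder, 3 seeds per fraction by
default — the original analysis does not state a replicate count) and reruns
the *identical* chain per subsample, including re-estimating the error
matrix within the subsample. Mean coverage is recomputed from each
subsample's own depth track. Detected true positives versus coverage $n$
are then fitted with the power-law saturation model

$$\mathrm{TP}(n) = T \left( 1 - A\, n^{-B} \right)$$

by bounded Levenberg–Marquardt least squares (`minpack.lm`), multi-started
over $B \in \{0.5, 1, 2\}$ with the best residual kept. Bounds
$T \ge \max(\mathrm{TP})$, $A \ge 0$, $B \ge 0$ keep the fitted curve
non-decreasing. Degenerate input (all TP equal with $T$ free) pins $A = 0$
and reports $B$ as undefined rather than fitting an unidentifiable
exponent. On noiseless curves the fit recovers generating parameters to
machine precision (the tests require $10^{-4}$ relative error over a
parameter grid, and $10^{-6}$ on a reference case).

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once and
are not tuned against test outcomes.

* **Reference genome** — i.i.d. bases at 50.8% GC, the GC content of the
  *E. coli* strain the method was developed on. The default experiment uses
  a 50 kb genome: large enough that 36-mers are effectively unique outside
  planted repeats, small enough that the full pipeline runs in seconds.
* **Repeats** — 7 copies of a repeat unit emulate the rRNA operons whose
  near-identity defeats unique mapping in the real genome. At the 50 kb
  scale the unit length is 2 kb (realistic 5 kb operons would occupy 70% of
  the genome). Divergence 0 (identical copies) is the default condition:
  each copy receives exactly `floor(unit_length * divergence / 2)` private
  substitutions, so pairwise identity is guaranteed to be at least
  1 − divergence rather than only in expectation.
* **Planted substitutions** — 259 by default, of which 12/259 are directed
  into repeat interiors, mirroring the observed failure mode in which 12 of
  15 undetectable strain differences lay in rRNA operons. In-repeat sites
  are placed at least 100 bp inside unit boundaries so that, for short
  reads, every read covering them lies wholly within the repeat and is
  excluded by unique-only mapping — this is what makes them *uncovered*
  false negatives rather than borderline-detectable ones.
* **Platform profiles** — FLX-like (240 ± 40 bp plus 10 bp adapters at both
  ends, 0.1% flat error, 10% junk), GA-like (36 bp, error ramp 0.2% → 8%
  across cycles, 25% junk, 15% of reads with tail signal decay), SOLiD-like
  (25/50 bp, 0.2% flat error, 50% junk). The upstream documents describe
  these behaviours only qualitatively (mapped-read ratios, accuracy, a
  rising 3' mismatch curve), so the numbers are qualitative calibrations,
  chosen once.
* **Quality values** are reported on the Solexa odds scale
  $QV = -10\log_{10}(e/(1-e))$ with Gaussian reporting noise (sd 2). A
  "trim bases with QV < 0" policy only has bite if negative QVs exist, and
  on this scale QV < 0 requires an error probability above 0.5; that is why
  the GA-like profile includes the tail-decay component (error 0.55 from a
  random late cycle in a fraction of reads), emulating reads whose
  fluorescent signal is lost. Junk reads are uniform random sequence — the
  neutral unmappable composition, since no junk composition is documented.
* **What the generator does not emulate** — flowgram homopolymer indels,
  color-space encoding, mate-pair structure (the method ignores mate pairs),
  GC-dependent coverage bias, and position-correlated error bursts. Passing
  tests therefore demonstrate correctness of the *algorithms* under the
  stated error model, not calling performance on real instrument data.

## Preprocessing

`trim_policy()` defaults to the literal published rule: trim at QV < 0,
drop reads shorter than 32 bases. Two readings of "trim the bases" are
provided: the default `three_prime_run` removes the maximal 3'-terminal run
of sub-threshold bases (low quality accumulates at the 3' end; deleting
internal bases would create chimeric reads that no longer align ungapped),
while `per_base_mask` is the literal per-base reading — sub-threshold bases
become `N`, which never matches during mapping and contributes no pileup or
error-matrix count. Whether the original analysis meant a higher positive
cutoff is unknowable; the threshold is therefore configurable with the
literal default. Adapter stripping is exact end-anchored matching only — no
published adapter algorithm exists to reproduce, and the FLX-style profile
attaches adapters verbatim.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `max_mismatch` | 3 | mismatches/read | the published mapping budget |
| `qv_threshold` | 0 | Solexa QV | literal published trim rule |
| `min_length` | 32 | bases | literal published length filter |
| `pseudocount` | 1 | counts | guards Eq-2 structural zeros |
| `threshold` | 1e-8 | posterior | literal published significance rule |
| `fractions` | 1/32 … 1/2 | — | published twofold resampling ladder |
| `in_repeats_fraction` | 12/259 | — | observed rRNA-operon failure share |

## Problem sizes

The default experiment sizes are the package's own choice of a desk-scale
study: 50 kb genome / 259 substitutions / 30× for planted-truth recovery,
20 kb / 15–20× for the error-matrix, junk-fraction and ramp round trips,
50 random 1 kb genomes × 100 reads for the mapper-oracle equivalence, and a
15 kb genome for the saturation experiment. The full test suite runs in
about a minute; `scripts/acceptance.R` in well under a minute.

## Known limitations

* Ungapped, substitution-only throughout: indels are neither simulated by
  default nor called.
* The error matrix is genome-wide, not position- or quality-stratified
  (the pooled form is what the method defines; stratified matrices are an
  extension point).
* Haploid consensus only — no heterozygous genotype model.
* `import_sam()` accepts only fully-matched ungapped records; anything with
  indels or clipping is dropped (and counted), so external gapped aligners
  are usable only for their ungapped records.
* The uncovered-region GC analysis computes GC over the uncovered positions
  themselves, not over windows containing them (the original definition is
  ambiguous; positions are the more direct reading).

## A worked miniature

```{r mini, eval = FALSE}
cfg <- pipeline_config(genome_length = 20000, n_substitutions = 100,
                       repeat_unit_length = 1000, profiles = c("flx", "ga"),
                       mean_coverage = 15, seed = 7)
bundle <- run_pipeline(cfg, quiet = TRUE)
bundle$mapping_summary
bundle$evaluation
autoplot(fit_saturation(data.frame(
  n = bundle$saturation$mean_coverage[bundle$saturation$profile == "GA"],
  TP = bundle$saturation$TP[bundle$saturation$profile == "GA"])))
```
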