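---
title: "Joint multisample somatic SNV calling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multisample somatic SNV calling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointsnv)
```

## The problem

Multiregion and longitudinal tumour sequencing yields several samples from
the same patient. The scientific object of interest is not only *where*
somatic SNVs occur but *which samples carry them* — the regional
distribution that phylogenetic reconstruction of the tumour depends on.
Pairwise tumour–normal callers analyse each tumour against the normal
independently, discarding the strongest signal available for rare shared
variants: their recurrence across related samples. `jointsnv` infers all
samples jointly, per locus, in a single Bayesian model.

## The model

### Allelic compositions, not genotypes

Tumour samples are impure mixtures of cell populations with unknown copy
number, so a diploid genotype is the wrong latent variable. Each sample
`k` instead carries an **allelic composition** `S^k`, the set of distinct
alleles present at the locus. The normal sample, assumed pure and diploid,
takes one of the 10 one- or two-allele subsets of {A,C,G,T}; each tumour
takes one of the 14 subsets of size one to three. Sets of all four alleles
are excluded from both universes. An important consequence of working with
sets is that the caller naturally handles sites that are germline
heterozygous and sites where no allele matches the reference — cases many
pairwise somatic callers skip.

### Likelihood

A read that reports base τ with miscall probability `e` (decoded from its
Phred quality, `e = 10^(-Q/10)`) has likelihood

$$P(r=\tau \mid S, f) = (1-e)\,f_\tau + \frac{e}{3}(1-f_\tau),$$

treating the three possible miscalls as equally likely. Reads are
conditionally independent, so the column likelihood is a product. The
allele-fraction vector `f` lives on the simplex restricted to the alleles
of `S` and is **plugged in at its MAP estimate** rather than sampled: under
a symmetric Dirichlet(a) prior on the member alleles and the error-free
limit of the likelihood, the posterior is Dirichlet with parameters
`a + v_τ` (`v_τ` = reads supporting τ), whose mode is the closed form
implemented in `map_allele_fractions()`. The error-free limit is used
*only* for estimating `f`; the likelihood itself always uses the full
per-read error probabilities. This split is cheap, accurate once
low-quality bases are filtered, and keeps the state space discrete.

Free allele fractions are what give the model its sensitivity at low
variant allele frequency: a variant at VAF 0.05 does not fight a
heterozygous-diploid assumption, it simply shifts `f`.

### Prior strengths `a`

The Dirichlet strength acts as a pseudo-coverage. For the normal we want
to *bias* fractions towards 1 (homozygous) or 0.5 (heterozygous), so the
default is five times the median normal coverage; for tumours we want only
gentle regularisation, so the default is 20% of the median tumour
coverage. Both are clamped to ≥ 1 so the MAP mode stays inside the simplex
(`a < 1` could push the closed form negative at `v_τ = 0`). Median
coverages are computed from the input loci (or supplied via
`med_cov`/`--median-cov` when the input is a small region of a larger
experiment).

### Coupling priors across samples

The tumour compositions are modelled as draws from a multinomial over the
14 states whose probabilities carry a Dirichlet prior with pseudocounts
`δ_z`; integrating the multinomial probabilities out gives the
Dirichlet–multinomial conditional implemented in
`tumor_conditional_prior()`:

$$P(S^{T_i}=z \mid S^N, S^{-T_i}) = \frac{c_z + \delta_z}{\sum_z (c_z + \delta_z)},$$

with `c_z` the number of *other* tumours currently in state `z`. Observed
states add directly to the numerator — this is the borrowing mechanism
that raises the prior of a mutation already seen in other samples. The
pseudocounts encode distance from the normal state: `δ_z = wμ` when `z`
has exactly one extra allele relative to `S^N` (a somatic SNV;
`μ = 3×10⁻⁷`, near the per-base somatic mutation rate), `δ_z = wμ²` for
every other transition, and the remainder at `z = S^N` so that
`Σ_z δ_z = w` exactly. "One mutation away" is read strictly as *gaining*
one allele; allele-loss (LOH-like) transitions get the `wμ²` branch. The
weight `w = 10(n+1)` grows with the sample count so that the fixed prior
mass keeps pace with the at-most-`n−1` observational counts and shared
events are not overcalled.

The normal prior has the same form over the 10-state universe, with
pseudocounts `wα, wβ, wγ, wδ` for heterozygous-reference,
heterozygous-variant, homozygous-variant and homozygous-reference states
(`α = 3.34×10⁻⁴`, `β = 8.33×10⁻⁸`, `γ = 1.665×10⁻⁴`, `δ = 0.9985`,
standard diploid genotype-prior constants). Two deliberate literalisms:
the four constants sum to slightly more than 1 (`δ+3α+3β+3γ ≈ 1.0000017`)
and are used exactly as stated, since the conditional normalises anyway;
and the tumour-state counts `n_z` entering the normal conditional ignore
tri-allelic tumour states, which have no counterpart in the normal
universe.

## Inference

Each locus is analysed independently (the model has no linkage), by Gibbs
sampling on the joint state `(S^N, S^{T_1}, …, S^{T_n})`:

1. initialise every sample's state uniformly at random;
2. sweep in a fixed systematic order — normal first, then tumours in input
   order — redrawing each state from its full conditional
   (likelihood × Dirichlet–multinomial prior, normalised by log-sum-exp),
   each new draw immediately visible to the next conditional;
3. after a 100-sweep burn-in, tally draws; every 300 sweeps compare the
   per-sample modal states of the last two windows and declare convergence
   when they agree and each within-window modal frequency is ≥ 0.5;
4. stop at convergence or at 3000 sweeps (the cap); non-converged loci are
   reported and flagged, not dropped.

The point estimate per sample is its most frequently drawn state, ties
broken by canonical state order (size, then lexicographic) so results are
deterministic. The per-candidate log-likelihoods do not depend on other
samples' states, so they are computed once per locus and cached; a sweep
then costs only prior updates and 14-way draws, which is what makes
100 000-locus benchmarks practical. The sweep loop is compiled (Rcpp), but
a pure-R reference implementation of the same conditional and sweep
(`conditional_distribution()`, `gibbs_sweep()`) is part of the API, and
the test suite verifies that the compiled chain replays the R reference
draw-for-draw from the same seed, and that its long-run distribution for
`n = 1` matches the exact stationary distribution of the explicitly
constructed 140×140 scan-transition matrix.

Two caveats are worth stating. The systematic scan order and the windowed
convergence rule (100/300/3000, threshold 0.5) are implementation choices
— the model itself only caps the chain at 3000 sweeps — and all four knobs
are exposed in `gibbs_config()`. And because `f` is plugged in rather than
integrated, the per-sample conditionals are not guaranteed to cohere into
a single joint distribution; the implementation therefore targets, and the
oracle test verifies, the stationary law of the fixed-scan kernel.

Reproducibility contract: each locus's chain is seeded by
`derive_locus_seed(seed, chrom, pos)`, so calls are invariant to locus
order and to any parallel partitioning of the input.

## Calling, strand bias, filters

With point estimates in hand, each tumour is compared with the normal by
set difference: gained alleles (`S^T \ S^N`) are somatic SNVs, lost
alleles at a heterozygous normal are LOH, both together are
`SOMATIC_SNV_AND_LOH`. A site is somatic if any tumour gains or loses;
`S^T = S^N ≠ {ref}` is germline-only and deliberately *not* emitted as
somatic.

Strand bias is tested by **pooling** forward/reverse counts of the gained
allele versus the normal's alleles across all tumours whose call gains
that allele, then applying a two-sided Fisher exact test — pooling first
gives more reads and hence more power than per-sample testing. Membership
of the pool ("samples whose call gains the allele") and the handling of
multiallelic sites (one 2×2 test per gained allele, minimum p reported
with its allele) are implementation choices, documented here because a
2×k exact alternative would also be defensible.

The high-confidence filter set (`filter_config()`) is intentionally simple
and fully configurable: strand-bias p < 0.01, pooled variant reads < 2,
normal depth < 10, or a non-converged chain each raise a flag; a call with
no flags is high confidence. Flags annotate the VCF FILTER column; nothing
is silently removed.

## The simulator

`simulate_pileup()` generates the benchmarking conditions: uniform depth,
perfectly aligned reads, constant base quality, independent error. Per
locus, reference and variant alleles are drawn uniformly (distinct);
tumour reads support the variant with probability `vaf`; normal reads with
probability `contamination × vaf` (contaminating tumour cells carry the
variant at rate `vaf` — the simplest consistent reading of "x%
contamination", exposed as a formula in the documentation); every read is
then miscalled with probability `10^(-base_q/10)` uniformly to another
base; strands are fair coin flips. Defaults are the benchmark design: four
tumours, Q30 for sensitivity runs, Q15/Q20/Q30 for noise runs.

What the simulator deliberately omits: alignment and mapping error, indel
artefacts, context-dependent (correlated) errors, GC and strand biases,
variable depth, and real contamination structure. Passing the benchmarks
therefore demonstrates correctness of the *inference machinery* under the
stated error model, not robustness to correlated artefacts of real data —
the latter is exactly where the strand-bias and high-confidence filters,
and consensus approaches with haplotype-aware callers, earn their keep.
The likelihood also has no explicit term for tumour-in-normal
contamination; variant reads in the normal are attributed to sequencing
error, which makes contaminated-normal false positives *more* likely at
*higher* base quality.

The sensitivity benchmark plants the same SNV in all tumours and counts a
true positive only when the site is called somatic with the planted allele
gained in **every** tumour (a per-site any-tumour variant is available via
`per_site = TRUE`). The false-positive benchmark reports loci called
somatic per million simulated loci; one locus is one base, so this is a
rate per megabase.

## Numerical and degenerate-input choices

- Conditionals are normalised in log space (log-sum-exp); draws are
  inverse-CDF over the canonical state order, one uniform per draw, which
  is what makes the R/C++ draw-for-draw equivalence testable.
- Empty sample columns have log-likelihood 0, so their conditional reduces
  exactly to the prior.
- A base-quality filter threshold keeps reads with `e ≤ 10^(-q/10)`
  (default q = 20); any sample left below `min_depth` (default 1) skips
  the locus — only sites with nonzero depth everywhere are analysed.
- mpileup structural symbols (`^x`, `$`, indel descriptors, `*`, `>`, `<`,
  `N`) are consumed without emitting reads; ambiguity codes are never
  stored. The raw depth field is kept for diagnostics only.
- Exact modal ties break to the earlier state in canonical order.
- `a` strengths below 1 are clamped to 1 (see above); the pseudocount
  remainder at `z = S^N` is positive for any realistic `μ`.

## Problem sizes used in the checks

The test suite runs the noise benchmark at 20 000 loci (Q15, depth 10,
four tumours) and the sensitivity grid at 300 loci per cell over depths
15/30/60 and VAFs 0.1–0.5 — sizes chosen to give binomial standard errors
comfortably inside the margins being asserted. The standalone benchmark
script (`scripts/acceptance.R`) runs the noise arm at the full 100 000
loci. The exact-oracle comparison uses one tumour (140 joint states,
100 000 recorded sweeps); the clamped-conditional check uses 50 000 draws
per locus on five random loci; the MAP check compares 200 random instances
against a coarse-to-fine grid search (final step 1e-4).

## Known limitations

- No indel calling, no realignment, no BAM/CRAM input; the caller consumes
  mpileup text and trusts upstream mapping-quality filtering.
- Samples are modelled as exchangeable given the normal; known phylogenetic
  structure between regions is not exploited.
- `f` is a plug-in MAP, not marginalised; very low-depth loci can fail the
  convergence rule (such loci are flagged, and in practice are the ones
  with extremely low VAF and/or depth).
- Correlated artefacts (homopolymer context errors, misalignment around
  indels) will recur across samples and can imitate shared somatic
  variants; the borrowing prior then works against specificity. Filters
  mitigate but do not remove this.
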