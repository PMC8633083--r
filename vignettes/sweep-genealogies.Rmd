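---
title: "Genealogies linked to hard sweeps of arbitrary age: model, observables, inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogies linked to hard sweeps of arbitrary age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepGF)
```

## The model

`sweepGF` describes the genealogy of a sample of `n` lineages at a neutral
locus linked to a hard selective sweep: a single de novo beneficial,
codominant mutation with heterozygous advantage `s` that swept to fixation
in a panmictic Wright–Fisher population of `Ne` diploids, completing `Ta`
units of `2*Ne` generations before sampling. Pastward from the sample, the
ancestry is the Kingman coalescent until the sweep is reached; the sweep
itself is fast on the coalescent time scale and is modelled as an
*instantaneous partition* of the lineages extant at `Ta`:

* **star-like**: each lineage escapes the sweep independently by
  recombination, with probability `Pe = 1 - exp(-alpha)`, where
  `alpha = (r*d/s) * log(2*Ne*s)` is the recombination distance `r*d`
  scaled by the sweep duration (`alpha = r*d*t_fix/2`,
  `t_fix = 2*log(2*Ne*s)/s` generations). All non-escapees merge in a
  single multiple-merger event at the origin of the beneficial mutation.
* **marked Yule** (`yule_model()`): the beneficial ancestry during the
  sweep is a pure-birth tree with split rate `2*Ne*s`, stopped at
  `ceiling(4*Ne*s)` lineages, marked by recombination at rate `2*Ne*r*d`
  per lineage. Tracing sampled lineages through the marked tree partitions
  them into late recombinant singletons, early-recombinant families (a
  group that first coalesces, then recombines out as a unit), and one
  nonrecombinant family identical by descent to the sweep founder. The
  partition tables are estimated by Monte Carlo; the sampler draws only
  the induced genealogy of the sample through the backward jump chain of
  the Yule tree (uniform pair mergers with hazard `C(m,2)/C(j,2)` at the
  level-`j` boundary) with segment durations drawn as exponential order
  statistics, so no full tree is ever built. Outcomes with more than one
  early family — which the instantaneous approximation formally excludes —
  are retained with their exact shape and reported through
  `multi_family_freq` as a diagnostic.

Before and after the sweep the coalescent is neutral, so the whole history
is: Kingman on `[0, Ta)`, one partition event, Kingman to the root.

## The generating function

All analytic results flow from the joint Laplace transform of the branch
lengths (the *generating function*, GF). Each extant branch `x` carries a
dummy variable `omega_x`; the GF is built by a recursion over states
`Omega` (partitions of the sample): in a state with `k` lineages the next
event is one of the `C(k,2)` coalescences, contributing a factor
`1/(C(k,2) + sum omega_x)` and recursing on the merged state. A sweep is
embedded as a competing exponential event with rate `delta`; because the
partition is instantaneous it adds no branch length, and `delta` never
appears after it, so each path contains the sweep at most once. The
transform in `delta` is converted to a fixed sweep age by an inverse
Laplace transform of `GF/delta` (`invert_sweep_time()`), performed
term-by-term through partial fractions — repeated poles are supported and
produce polynomial-in-`Ta` coefficients.

The package represents the GF explicitly as a canonical sum of terms

```
coef * Ta^p * exp(-Ta*(b + sum(c*omega))) * prod_j (b_j + sum(c_j*omega))^(-m_j)
```

rather than through a computer-algebra system: every operation the theory
needs — evaluation, differentiation (`gf_deriv()`), truncated Taylor
expansion (`gf_taylor()`), limits, variable merging, and the inverse
transforms — is closed on this family and exact up to floating point.
Normalisation (`GF = 1` at `omega = 0`) holds to `1e-12` for every
constructed expression and is asserted in the tests.

The full joint GF is built for samples of up to 6 lineages (the number of
event histories grows super-exponentially; construction fails fast above
the cap). Expected i-Ton branch lengths for larger samples (`n` up to 12)
use a separate marginal-moments path (`expected_iton_lengths()`): because
the Kingman jump chain is independent of its holding times, the expected
number of size-`i` blocks at each lineage count is a fixed combinatorial
quantity, and expected times decompose over lineage-count levels
(Tavaré's formula for the level occupancy before the sweep, an escape
partition step, and a jump-chain recursion after it). For `n = 4` the two
routes agree to `1e-10`, which is one of the package's standing tests.

## Observables

* `expected_tmrca(alpha, Ta)`: `1 - exp(-Ta - 2*alpha)` for a pair, also
  recomputable by GF differentiation (`method = "gf"`); the dual-path
  agreement is tested on a 10 x 10 parameter grid.
* `tmrca_distribution()`: density `exp(-t)` before the sweep epoch, an
  atom of `exp(-Ta - 2*alpha)` at `t = Ta` (the burst of coalescence), and
  the neutral density thinned by the pair-escape probability beyond.
* `expected_sfs(n, alpha, Ta)`: normalised expected i-Ton lengths. At the
  sweep center the singleton class is strongly inflated; away from the
  center a recent sweep inflates the high-frequency classes (the merged
  lineage subtends most of the sample), and as the sweep ages the
  intermediate classes recover first, leaving a U-shaped ratio to the
  neutral spectrum. `alpha = 0` with `Ta = 0` is a zero-length tree and is
  an error, not `NaN`.
* `topology_probs_n4()`: probabilities of the three root classes for
  `n = 4`. The package classifies by tripleton branches: *asymmetric* if a
  branch with three descendants ever exists, *star* if neither a
  doubleton nor a tripleton ever exists (the single four-way merger,
  probability `exp(-6*Ta) * P04`), *symmetric* otherwise — which places
  trifurcating roots (a `{2,1,1}` three-way merger) in the symmetric
  class. This convention is the unique one under which the closed forms
  constitute a probability partition; it was confirmed against
  Monte-Carlo classification of simulated genealogies. Neutrality gives
  the classic `(1/3, 2/3, 0)`.
* `iton_marginal_distribution(i, alpha, Ta)`: the full marginal law of the
  total length of `i`-descendant branches for `n = 4`, obtained by
  inverting the GF in the corresponding variable. The results are
  piecewise sums of exponentials with atoms at multiples of `Ta`;
  `pwe_discontinuities()` counts the points where the analytic form
  changes (including atoms): `n - 1` of them for singletons, at
  `{Ta, 2*Ta, 4*Ta}`, and `floor(n/i) + 1` for `i > 1`. Note that at some
  of these points the density is continuous — the left and right pieces
  take different forms but equal limits — so the count is about the
  representation, not jump sizes. Under neutrality the tripleton law
  carries an atom of `1/3` at zero (the asymmetric-topology probability).
  Growing exponential modes appear legitimately on interior intervals of
  these densities and must cancel on the final interval; the inversion
  pools coefficients and verifies the cancellation.
* `bsfs_probabilities(alpha, Ta, mut)`: the probability of every blockwise
  mutation configuration `(k1, k2, k3)` for subsamples of 4, counts capped
  at `k_max` (so `(k_max + 2)^3 = 64` configurations at the default
  `k_max = 2`). Mutations fall on a branch class at rate `theta/2` per
  unit length with `theta = 4*Ne*mu*l` for a block of `l` bases; interior
  probabilities are mixed Taylor coefficients of the GF at
  `omega = theta/2`, and the capped bins follow by inclusion–exclusion
  over partially marginalised evaluations (`omega = 0` for the free
  classes). The convention is pinned by the pairwise check
  `P[k] = theta^k/(1+theta)^(k+1)`.

## Simulators

`simulate_hybrid_genealogy()` samples exactly from the model above
(Kingman, partition, Kingman) with full branch information;
`simulate_iton_batch()` is a vectorised case-analysis sampler for `n = 2`
and `n = 4` under the star-like model, cross-checked in the tests against
the generic sampler and against an independently written brute-force
oracle. `simulate_blocks()` draws an independent genealogy per block at
that block's `alpha` — matching the composite-likelihood assumption of
independent, internally non-recombining blocks — and Poisson mutation
counts per class.

`simulate_pair_trajectory()` is the full-model reference: a structured
coalescent along the beneficial-allele frequency trajectory, with
pairwise coalescence at rate `1/(2*Ne*X)` per generation on the
beneficial background, escape with probability `r*d*(1-X)` per
generation, and coalescence at rate `1/(2*Ne*(1-X))` between escaped
lineages while the sweep segregates. The default trajectory is a
deterministic logistic with effective starting frequency `1/(1+2*Ne*s)`
— the standard deterministic stand-in for conditioning on fixation — whose
natural duration equals `t_fix` and whose escape integral equals `alpha`
exactly; back-migration onto the beneficial background is neglected. Two
properties of this reference matter for interpretation:

1. the burst of coalescence sits near the sweep's *origin*, i.e. around
   `Ta + t_fix/(2*Ne)` rather than `Ta`. The instantaneous models place it
   at `Ta`, which biases age estimates downward; all observables and fits
   accept `correct_duration = TRUE` to substitute `Ta + t_fix/(2*Ne)`
   (off by default, matching the plain closed forms).
2. the probability that a pair fails to escape exceeds `exp(-2*alpha)` by
   a few parts in a thousand to a few percent (0.013 at `alpha = 0.069`,
   `s = 0.05`, `Ne = 1e4`): coalescence concentrated near the origin
   truncates recombination exposure, a competing-risk effect that all
   instantaneous-partition approximations drop and that vanishes only as
   `2*Ne*s` grows. This is a property of the approximations, not a
   numerical artefact (a deterministic competing-risk integration along
   the trajectory reproduces it), and it bounds how closely the
   structured-coalescent reference can agree with the star-like closed
   forms at these parameter values.

## Composite-likelihood inference

Data are blockwise configurations, either simulated or extracted from a
phased, ancestral-polarized VCF (`extract_blocks()` + `tabulate_bsfs()`;
all `choose(n, x)` subsamples of `x = 4` haplotypes contribute). The
composite log-likelihood adds `log P[k]` over blocks and subsamples —
terms are summed as they stand, with no variance correction for their
dependence. Fitting is a two-step grid procedure (`fit_grid()`): `theta`
is first estimated from blocks whose scaled distance exceeds
`alpha_threshold` under *every* candidate `s` on the grid (default
threshold 0.5 — at `Ne = 1e4`, `r = 1e-7`, `s = 0.05` this keeps blocks
beyond roughly 36 kb), then `(Ta, s)` maximise the sweep likelihood
conditional on `theta_hat`, and the sweep support is
`delta_lnCL = lnCL_sweep - lnCL_neutral`. Grid ties break toward the
neutral-most cell (largest `Ta`, then smallest `s`), a deliberately
conservative choice.

The computational device that makes grid fits over thousands of blocks
cheap is exact in this model: every configuration probability is a
polynomial of degree at most 4 in `Pe` (each event history contains
exactly one partition event over at most four lineages), so evaluating
the table at five `Pe` nodes reconstructs it exactly at every block
distance by solving a 5-point Vandermonde system. This is an exact
evaluation path, not an approximation, and it reproduces the directly
constructed tables to `1e-15`. Configurations with vanishing model
probability floor the log at `log(1e-300)` with a warning.

Power is summarised by ROC curves (`roc_curve()`): sweep and neutral
`delta_lnCL` scores are jointly ranked in descending order (ties pooled),
and the AUC is the Mann–Whitney statistic.

## Study conditions and what the tests show

The validation suite runs at the conditions the analysis targets:
`Ne = 1e4`, `r = 1e-7`, blocks of `l = 100` bases with `theta = 0.5`,
`B = 2000` blocks split evenly around the target, subsamples of `x = 4`,
`k_max = 2`, and a grid of `theta` in `{0.3..0.7}`, `Ta` in
`{0, 0.1, 0.5, 1, 2}`, `s` in `{0.005, 0.01, 0.05}`. Distributional
checks use 1e5 Monte-Carlo replicates at
`alpha` in `{0.069, 0.14}` x `Ta` in `{0.1, 0.25}`; parameter-recovery and
power experiments use 200 sweep and 2000 neutral replicates per
condition. With these sizes the strong recent sweep (`s = 0.05`,
`Ta = 0.1`) is recovered in the true grid cell in over 90% of
replicates, detection power is essentially perfect (AUC 1.00), old strong
sweeps remain detectable (AUC around 0.99, dropping to about 0.91 when
`Ta` is forced to 0 in the fit), and weak old sweeps (`s = 0.005`,
`Ta = 1`) show dispersed, partially non-identifiable estimates with
AUC around 0.93.

The generator draws blocks as *independent* genealogies with no
recombination inside blocks and no correlation along the chromosome, a
constant-size panmictic population, and a single completed hard sweep.
Passing tests therefore validate the analytic machinery and the
estimator under the model's own assumptions; they say nothing about
robustness to along-sequence linkage of block genealogies, intra-block
recombination, demography, background selection, or mutation-rate
heterogeneity — the last two being the dominant practical complications
for real scans, since the blockwise likelihood is highly sensitive to the
assumed `theta`.

## Numerical choices

* Algebraic-identity tests run at `1e-10` relative tolerance; GF
  normalisation at `1e-12`; density masses and integrals at `1e-8`.
* Partial-fraction residues are computed symbolically (poles are linear
  forms with exact small-integer data), so coinciding poles are detected
  structurally, merged before expansion, and repeated poles of any degree
  are supported. Coinciding poles with zero constant difference raise an
  error rather than returning garbage.
* Pole grouping during density inversion uses a `1e-9` tolerance on pole
  locations; pooled coefficients below `1e-8` of their group scale are
  zeroed (these are the exactly-cancelling growing modes).
* The marked-Yule sampler's level boundaries use precomputed cumulative
  log-survival tables with binary search, and segment times use
  single-beta-draw exponential order statistics; both are exact, not
  discretised.
* The trajectory simulator steps one generation at a time with
  coalescence applied before escape within a step; halving the step does
  not change its results beyond Monte-Carlo noise.

## Limitations

Joint GFs are limited to `n <= 6` (marginal moments to `n = 12`); the
topology classes and blockwise tables are provided for subsamples of 4;
recurrent and soft sweeps, standing variation, demography and migration
are out of scope; the scan loop is minimal (no genome-wide
orchestration), and significance of `delta_lnCL` is assessed by simulated
ROC, not asymptotic theory.
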