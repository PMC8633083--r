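# sweepGF

Analytic description and composite-likelihood inference of **hard
selective sweeps of arbitrary age** from linked neutral variation.

Most sweep scans assume the population was sampled at the moment the
beneficial allele fixed, and compare models to the data only through the
site frequency spectrum. `sweepGF` targets both limitations. It models
the genealogy of a sample at a neutral locus a recombination distance
`d` from a beneficial mutation (selection coefficient `s`, diploid
population size `Ne`) that fixed `Ta` units of `2Ne` generations before
sampling, and it leverages the *joint* distribution of linked variants
within short blocks — the blockwise site frequency spectrum (bSFS) —
rather than averages. It is aimed at population geneticists who want
analytic expectations near sweeps, exact simulators for them, and a
likelihood framework that jointly estimates the sweep's age and strength.

## The model in brief

The joint distribution of genealogical branch lengths is represented by
its generating function (GF): associating a dummy variable ω with each
branch, the neutral coalescent satisfies the recursion

    Φ[Ω] = 1/(C(|Ω|,2) + Σ_x ω_x) · Σ_{i<j} Φ[Ω_ij],

and a sweep enters as a competing exponential event at rate δ that
instantaneously partitions the extant lineages — each lineage escapes the
sweep with probability `Pe = 1 − exp(−α)`, `α = (r·d/s)·log(2Ne·s)`, and
non-escapees merge at once (the star-like approximation; a marked-Yule
partition is also provided). An inverse Laplace transform in δ conditions
on the sweep completing exactly at `Ta`. From the resulting expression
the package derives, in closed form: the distribution of the pairwise
coalescence time (with its atom `exp(−Ta − 2α)` at `t = Ta`), the
expected SFS, the probabilities of the three root-topology classes for
samples of four, the full marginal distributions of singleton, doubleton
and tripleton branch lengths, and the probabilities of all `(k_max+2)³`
blockwise mutation configurations. These feed a composite likelihood

    lnCL(θ, Ta, s) = Σ_blocks Σ_subsamples ln P[k_ij],

maximised on a grid after estimating θ from distant blocks, with the
sweep support measured by `ΔlnCL = lnCL_sweep − lnCL_neutral`.

Everything is validated against internal coalescent simulators: an exact
sampler of the analytic model and a structured coalescent along the
beneficial-allele frequency trajectory.

## Worked example

A sweep with `s = 0.05` in a population of `Ne = 10⁴` diploids completed
`Ta = 0.1` coalescent units before sampling; we look at a locus 10 kb
away (`r = 10⁻⁷` per base per generation):

```r
library(sweepGF)

pp <- sweep_params(Ne = 10000, s = 0.05, r = 1e-7, Ta = 0.1)
al <- sweep_alpha(pp$r, d = 10000, s = pp$s, Ne = pp$Ne)
round(al, 4)
#> [1] 0.1382
expected_tmrca(al, pp$Ta)
#> [1] 0.3136
tmrca_distribution(al, pp$Ta)
#> <pwe_density> intervals: 0, 0.1 ... Inf
#>   point masses: 0.6864 @ t=0.1
```

So 10 kb from this sweep the expected pairwise coalescence time is 0.31
instead of the neutral 1, and 69% of pairs coalesce in the burst at
`t = Ta` — the atom that carries the information about the sweep's age.

Simulate a blockwise dataset around the target (2000 blocks of 100 bp,
`θ = 0.5` per block) and re-estimate the parameters:

```r
set.seed(1)
geom <- block_geometry(B = 2000, l = 100)
ds   <- simulate_blocks(pp, geom, n = 4, mut = mutation_model(0.5, 2),
                        mode = "sweep")
grid <- grid_spec(theta = c(0.3, 0.4, 0.5, 0.6, 0.7),
                  Ta = c(0, 0.1, 0.5, 1, 2), s = c(0.005, 0.01, 0.05))
fit_grid(ds, grid, pp)
#> cl_result: theta=0.4, Ta=0.1, s=0.05, DlnCL=79.954 (sweep -3102.47 vs neutral -3182.43)
```

The fit recovers the generating sweep age and strength exactly (θ is
biased slightly low because even "distant" blocks retain a trace of the
sweep), and a `ΔlnCL` of 80 log-units is overwhelming support for a sweep
— neutral datasets of this size have median `ΔlnCL` below 0.

A thin command-line layer wraps the same functions
(`inst/cli/sweepgf.R`): `expect`, `simulate`, `infer`, `power`,
`extract` (phased + polarized VCF → blockwise configurations) and `scan`.

```sh
Rscript inst/cli/sweepgf.R expect --stat tmrca --alpha 0.25 --Ta 0.5 --out tmrca.tsv
```

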