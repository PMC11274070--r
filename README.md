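# cleftsim

Paired first-passage-time simulation of neurotransmitter transport across
synaptic clefts.

## The problem

A synapse communicates by releasing neurotransmitters (most commonly
glutamate, carrying charge −e) that diffuse across a ~20 nm cleft to the
post-synaptic membrane.  If two pre-synaptic neurons fire *simultaneously*,
is the arrival at the two post-synaptic membranes also (nearly)
simultaneous — or does the stochastic transit wash the timing correlation
out?  The question matters for any mechanism that relies on correlated
neuron triggering, and it is quantitative: transit is a drift–diffusion
first-passage problem, and at physiological parameters it is
diffusion-dominated (Péclet number `v·d/D ≈ 0.15`), so the answer depends
on the details of what confines the walk.

`cleftsim` is a tool for that question.  It simulates pairs of
simultaneously released molecules, one per cleft, each following the
overdamped Langevin equation

    ζ dx/dt = F + ξ(t),     ⟨ξ(t) ξ(t′)⟩ = 2 ζ T δ(t − t′),   D = T/ζ,

with a constant electrostatic drift `F = −eV/d` and a localized soft-wall
force near the pre-synaptic membrane that keeps the molecule in the cleft
without hard reflection.  Each trajectory is integrated with
Euler–Maruyama until absorption at `x = d`; the observable is the
first-passage-time difference `ΔT = t₁ − t₂` over many pairs, summarized
as a histogram with width (std), mean and skewness.

For the wall-free case the first-passage law is inverse-Gaussian
(`γ(t) = d/√(4πDt³) · exp(−(d − vt)²/4Dt)` with `v = e|V|D/(Td)`), and
the std of `ΔT` has the closed form

    δ = 2 (T/e|V|)^(3/2) d²/D  ≈ 41.8 µs at defaults,

both of which the package implements as benchmarks (density, CDF, exact
sampler, quadrature cross-checks) to validate the simulator.

## Worked example

```r
library(cleftsim)

p <- cleft_params()       # d = 20 nm, D = 0.33 µm²/ms, V = −4 mV, kB·310 K
print(p)
#> Synaptic cleft parameters (SI internally):
#>   d        = 20 nm
#>   D        = 0.33 um2/ms
#>   V        = -4 mV
#>   T        = 4.28e-21 J (kB * 310.0 K)
#>   zeta     = 1.297e-11 kg/s   (T/D)
#>   v_drift  = 0.002471 m/s    (-eV/d / zeta)

w  <- wall_params()                            # soft anti-return wall
ex <- run_experiment(p, p, w, w, sim_config(n_runs = 50000L, seed = 1))
print(ex)
#> Paired first-passage result: 50000 pairs (0 censored)
#>   dT = t1 - t2: mean = 0.005259 us, sd = 1.218 us, skewness = 22.313
#> Histogram: 101 bins on [-209.2, 209.2] us; n = 50000 (0 out of range); modal bin at -2.711e-14 us
#>   wall-free analytic delta std = 41.84 us

summarize_core(ex$result$delta_times)$sd * 1e6
#> [1] 0.4751715
```

Reading the output: the two molecules arrive within a fraction of a
microsecond of each other in the vast majority of pairs — the histogram
is a sharp peak whose modal bin sits at zero.  The *core* width of the
difference distribution is 0.48 µs (the plain sd, 1.22 µs, is inflated by
a handful of rare pairs in which one molecule briefly slipped behind the
soft wall).  Both are far below the 41.8 µs wall-free benchmark: the wall
speeds transit up ~19× because the free walk wastes most of its time on
the pre-synaptic side.  Correlated release therefore survives transit as
correlated arrival at physiological parameters.

Sweeps reproduce the perturbation analyses: `sweep_symmetric_D()` (the
histogram broadens as exactly 1/D as diffusion slows; correlations are
lost around 0.03 µm²/ms), `sweep_asymmetric_D()` (slowing *one* cleft
broadens and skews the histogram; speeding one up does not), and
`sweep_voltage()` (physiological voltage changes barely matter).  A thin
CLI wraps these: `exec/cleftsim run|sweep-d|sweep-d-asym|sweep-v|validate|analytic`,
configured by an INI-style file (see `inst/extdata/physiological.ini`)
with `--seed`, `--runs`, `--dt-ns`, `--out` overrides.

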