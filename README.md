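# fibermix

Modeling and demixing of fluorescence recorded through bundles of splayed
optical microfibers.

Implanted bundles of hundreds to thousands of 8-um microfibers extend fiber
photometry into a many-channel deep-brain interface: each fiber splays along
a path of least resistance and collects bulk calcium fluorescence from the
tissue at its aperture. Whether such recordings can be unmixed into
individual neural traces depends on how the fibers' sensitivity profiles
overlap the neuron population. `fibermix` is a simulation framework for
exactly that question, aimed at researchers designing microfiber interfaces
or source-separation pipelines for them.

The model chain:

1. **Photon transport** — weighted-packet Monte Carlo in voxelized tissue
   (exponential free paths with `mu_t = mu_a + mu_s`, fractional absorption
   `mu_a/mu_t` per interaction, Henyey–Greenstein scattering with g = 0.9,
   Russian roulette, track-length fluence estimator) gives a fiber's 3-D
   sensitivity profile on a 1-mm cube of 5-um voxels.
2. **Bundle interface** — fiber tips sampled from the observed bivariate
   normal splay (σ = 150 um) over a uniform neuron population
   (250,000 /mm³) yield the non-negative mixing matrix
   `M[i,j] = h[i,j] * Σ_k g[j,k]`, with excitation `g` (490 nm) and
   collection `h` (512 nm, by reciprocity) normalized to the brightest
   possible cell.
3. **Neural simulation** — Bernoulli spiking (0.4 Hz) convolved with a
   unit-peak GCaMP6f kernel (0.14-s rise, 0.32-s decay half-life), mixed
   through `M`: `y_i = Σ_j M[i,j] x_j`.
4. **Source separation** — inverse filtering of the indicator waveform
   (`z = w⁻¹ * y`), whitening, and non-negative ICA by orthonormal
   rotations minimizing the rectification error
   `J(W) = mean ‖min(W z, 0)‖²`, then refiltering into fluorescence traces.
5. **Evaluation** — r²-based matching to the simulated truth (accurate at
   r² ≥ 0.6), paired comparison against the raw-fiber baseline, and a
   threshold-crossing spike-detection ROC/AUC with a random-trace negative
   control.

## Worked example

A desk-scale run of the full pipeline (one iteration for brevity; the
profile stage simulates 10^6 photon packets and takes ~10 s, the ICA a
minute or two):

```r
library(fibermix)

cfg <- scenario_config(n_iterations = 1, seed = 42)
res <- run_scenario(cfg)
res
#> <scenario_result> 1 iteration(s)
#>   accuracy raw  : 73.0% +/- NA
#>   accuracy sep  : 72.0% +/- NA
#>   control AUC   : 0.497
```

73% of the 100 raw fiber signals already match an individual simulated
neuron at r² ≥ 0.6 — at this geometry most fibers are dominated by one or
two cells, so the raw recordings are close to single-neuron traces and
non-negative ICA has little headroom (here it lands at 72%; over repeated
realizations the two methods are within a few points of each other, with
the separation benefit growing as bundles get denser and profiles
overlap more). The control AUC near 0.5 confirms that matches against
freshly generated traces carry no spike-detection information. Interface
statistics come from the same machinery:

```r
exc <- cached_profile("tissue490", 1e6, seed = 101)
col <- cached_profile("tissue512", 1e6, seed = 102)
lay <- sample_fiber_positions(100, seed = 1)
pop <- sample_neuron_positions(250000, seed = 2)
mm  <- build_mixing_matrix(lay, pop, exc, col)
visibility_stats(mm, thresholds = 0.01)
#>   threshold visible_ge1 visible_ge2 mean_per_fiber
#> 1      0.01         415          48           4.72
brightness_dominance(mm)
#> [1] 126.8949
```

At the 1% brightness threshold ~400 of 300,000 neurons are visible to at
least one of the 100 fibers, ~50 to two or more, and (reading the
fiber-averaged contribution curve) the brightest neuron per fiber
contributes about 127% more signal than the runner-up.

A thin CLI over the same functions lives at `inst/cli/fibermix.R`
(`profile`, `bundle`, `simulate`, `separate`, `evaluate`, `run`, `sweep`,
`toy` subcommands).

## Method vignette

`vignettes/modeling-microfiber-interfaces.Rmd` documents the model
assumptions, parameter choices, numerical decisions (deconvolution
stability, ROC conventions, background aggregation) and known limitations.
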