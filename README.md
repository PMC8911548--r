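# phasorseg

Unsupervised segmentation of time-resolved fluorescence lifetime maps by
phasor analysis and Gaussian-mixture clustering.

Portable time-correlated single photon counting (TCSPC) probes record one
fluorescence decay histogram per measurement point as they scan a surface —
for example the boundary between two paint mixtures on a heritage object,
where the binder (rabbit-skin glue, egg yolk, acrylic PVA, linseed oil)
dominates the decay kinetics. `phasorseg` turns such decay maps into
segmented lifetime images without any decay-curve fitting:

1. **Phasor transform.** Each decay histogram `c_k` is projected onto the
   first harmonic of the laser repetition rate `f` (20 MHz by default),
   using bin-centre times `t_k` and `ω = 2πf`:

   `g = Σ c_k cos(ω t_k) / Σ c_k`, `s = Σ c_k sin(ω t_k) / Σ c_k`

   Mono-exponential decays fall on the universal semicircle
   `(g − ½)² + s² = ¼`; mixtures fall inside it. The phase lifetime is
   `τ_phase = s / (2πf·g)`.
2. **Quality filter.** Only decays with peak counts strictly above 100 are
   analysed.
3. **GMM segmentation.** The (g, s) cloud is modelled as
   `p(x) = Σ_i f_i N(x; µ_i, Σ_i)` and fitted by expectation–maximization
   (K = 2 by default); each phasor is hard-assigned to its most probable
   component, and reciprocity maps every phasor back to its source pixel,
   yielding a segmented image plus per-cluster mean ± SD phase lifetimes.

A seeded simulator (mono/bi-exponential decays under periodic excitation,
Poisson counting noise, two-population interface maps with ground truth)
supports validation end to end.

## Worked example

```r
library(phasorseg)

# interface between a long-lived (3.7 ns) and short-lived (1.7 ns) mixture
map <- simulate_interface_map(
  population_spec(3.7, target_peak = 500, label = 1),
  population_spec(1.7, target_peak = 500, label = 2),
  shape = c(50, 60), boundary_col = 30, seed = 0
)
res <- segment_decay_map(map, seed = 0)
res$summary
#> # A tibble: 2 × 7
#>   cluster     n fraction mean_tau_ns sd_tau_ns mean_g mean_s
#>     <int> <int>    <dbl>       <dbl>     <dbl>  <dbl>  <dbl>
#> 1       1  1500      0.5        3.70    0.0402  0.822  0.382
#> 2       2  1500      0.5        1.70    0.0247  0.956  0.205

segmentation_accuracy(res$seg, matrix(map$truth, 50, 60, byrow = TRUE))
#> [1] 1
```

All 3000 pixels pass the peak-count filter; the two clusters recover the
simulated lifetimes (cluster 1 is canonically the longer-lived population)
with sub-0.05 ns spread, and every pixel lands on the correct side of the
interface. `autoplot(res)` draws the segmented map, `autoplot(res$cloud)`
the phasor plot, and `tidy()`/`glance()` give broom-style views of the fit.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/phasorseg simulate --out run1 --tau-a 3.7 --tau-b 1.7 --seed 0
Rscript inst/cli/phasorseg segment --in run1/decaymap.csv --out run1/analysis
Rscript inst/cli/phasorseg report --out table.csv run1/analysis/cluster_summary.csv
```

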