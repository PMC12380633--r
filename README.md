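# spatdecay

Estimating how functional connectivity between cortical neurons decays
with intersomatic distance, directly from a spike raster and somatic
coordinates — without reconstructing pairwise connections.

## The problem and the method

Neuronal wiring is spatially embedded: the probability that neuron *j*
connects to neuron *i* falls with their distance, summarised by the
exponential distance rule

> P(J<sub>ij</sub> = 1) = exp(−λ d<sub>ij</sub>),

with d<sub>ij</sub> in mm and λ in 1/mm (1/λ is the characteristic length
scale of interaction). For populations of thousands of neurons,
estimators built from all pairwise interaction measures are expensive
and noisy. `spatdecay` instead fits the single global decay parameter by
maximum likelihood on the raster itself:

* **raster-only likelihood** — the per-bin spike probability is
  approximated by the population-normalised interaction sum
  P<sub>i</sub>(t) = I<sub>i</sub>(t)/N with
  I<sub>i</sub>(t) = Σ<sub>j≠i</sub> S<sub>j</sub>(t) e^(−λ d<sub>ij</sub>),
  and the Bernoulli log-likelihood is profiled over λ (no baseline or
  coupling needed);
* **known-parameter likelihood** — for simulated data the full logistic
  generative likelihood with
  h<sub>i</sub>(t) = r₀ + α Σ<sub>j≠i</sub> S<sub>j</sub>(t−1) e^(−λ d<sub>ij</sub>)
  is profiled over λ;
* **spatial GLM** — the three-parameter fit (r₀, α, λ) with analytic
  gradients, also used to identify the generating kernel family among
  exponential, half-Gaussian, linear, inverse-square and lognormal
  candidates by maximized log-likelihood.

Around the estimators sit the generative models used to validate them (a
linear Poisson network and a spatially embedded Izhikevich network),
mean-field theory linking decay to pairwise correlations
(C(d) ≈ J²/(J²+σ²) · e^(−2λd) — correlations decay at *twice* the wiring
rate), and comparator estimators (transfer entropy, point-process
Granger causality, spike-count correlations, each reduced to a decay
estimate by least squares against distance).

## Worked example

Simulate a 250-neuron network for 30 s with decay 5/mm and recover the
decay from the raster with the matched likelihood:

```r
library(spatdecay)

cfg <- poisson_net_config(n_neurons = 250, T_ms = 3e4, r0 = -6, alpha = 0.4,
                          link = "logistic",
                          kernel = decay_kernel("exponential", lambda = 5),
                          seed = 8)
sim <- simulate_poisson_network(cfg)
sim$raster
#> spike_raster: 250 neurons x 30000 bins (1 ms/bin, 30 s)
#>   19150 spikes, population rate 2.55 Hz

fit <- estimate_decay(sim$raster, sim$geom, grid_size = 12,
                      likelihood = "poisson_model", r0 = -6, alpha = 0.4)
fit
#> decay_fit (exponential kernel): lambda = 4.708  [logLik -133389]
#>   250 neurons x 30000 bins, lag 0, bounds [0.1, 20]
```

The estimate (λ̂ = 4.71/mm, i.e. a characteristic interaction scale of
about 0.21 mm) recovers the generating value 5/mm to within 6% from 30 s
of data at this small population size; the `decay_fit` object also
carries the full log-likelihood profile for plotting. Raster diagnostics
summarise how Poisson-like the data are:

```r
raster_diagnostics(sim$raster)
#> raster diagnostics (counting bin 10 ms)
#>   population rate : 2.55 Hz (0 silent neurons)
#>   mean Fano factor: 0.998
#>   mean pairwise correlation: 0.0002458 (31125 pairs)
```

A command-line front end wraps the same functions
(`inst/cli/spatdecay`): `simulate-poisson`, `simulate-izhikevich`,
`estimate`, `fit-glm`, `baselines`, `select-model`, `sweep`,
`stability`.

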