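# mdinfer

Statistical inference for molecular-simulation observables.

Molecular dynamics (MD) output is stochastic: whether a conformational
transition happens in a 1-μs trajectory, what a non-equilibrium work value
comes out as, how fast water appears to diffuse in a finite periodic box —
all of these vary from repeat to repeat. Conclusions drawn from single
simulations ("the transition only occurs in the small box") are anecdotes
unless the uncertainty is quantified. mdinfer is a toolbox for doing that
quantification properly, aimed at simulators analysing trajectory-derived
tables rather than raw trajectories.

## What it computes

**Transition kinetics, Bayesian.** For $n$ observed transitions in total
exposure time $\Theta$ (event times plus full lengths of censored
trajectories), the rate posterior is $\mathrm{Gamma}(n{+}1,\Theta)$ under a
uniform prior (defined even for $n=0$) or $\mathrm{Gamma}(n,\Theta)$ under
the Jeffreys prior, with closed-form means $(n{+}1)/\Theta$ and $n/\Theta$.
Two conditions are compared by the odds ratio favouring two distinct rate
processes,

$$\frac{2}{\pi}\,\frac{n/\Theta}{n_1^2/\Theta_1^2+n_2^2/\Theta_2^2}\,
\frac{n_1!\,n_2!}{n!}\,
\frac{\Theta^{n+1}}{\Theta_1^{n_1+1}\Theta_2^{n_2+1}},$$

interpreted on Jeffreys' scale (1/3 and 3 as thresholds).

**Transition kinetics, frequentist.** Survival curves with exponential
fits ($t_{1/2}=\tau\ln 2$), bootstrap standard errors, the $N^{-1/2}$
scaling of the uncertainty with the number of trajectories, and the
enumeration of all conclusions a one-simulation-per-condition design could
have produced, with their probabilities.

**Free energies.** $\Delta G$ from forward/reverse non-equilibrium work by
the Crooks/Bennett maximum-likelihood estimator with bootstrap errors;
potentials of mean force from umbrella-sampling windows by multistate
(MBAR-style) reweighting with convergence-vs-data-fraction diagnostics;
autocorrelation times and statistical inefficiency $g=1+2\sum\rho$;
replicate means with t-based confidence intervals and trend tests.

**Solvent observables.** Diffusion coefficients from mean squared
displacements with the Yeh–Hummer finite-size correction
$\xi k_BT/(6\pi\eta L)$, bulk-water extrapolation for protein boxes, and
radial distribution functions with spherical / excluded-volume
normalization (the $V_\mathrm{box}/(V_\mathrm{box}-V_\mathrm{protein})$
artifact).

**Synthetic data.** Generators for censored exponential transitions,
Crooks-consistent Gaussian work, Boltzmann-sampled umbrella windows over a
double well, AR(1) series, Brownian particles in a periodic box, and
excluded-sphere point configurations — so every estimator is testable by
parameter recovery without running simulations.

## Worked example

One hemoglobin-style comparison: in the small box a transition is seen
after 0.466 μs; in the large box nothing happens within 1 μs. Is that
evidence for a box-size effect?

```r
library(mdinfer)
a <- transition_data(TRUE, 0.466, 1, unit = "us")   # transition at 0.466 us
b <- transition_data(FALSE, NA, 1, unit = "us")     # censored at 1 us
bayes_factor(a, b)
#> Odds favouring two processes: 0.933 (barely worth mentioning)
#>   A: n = 1, theta = 0.466; B: n = 0, theta = 1 us
```

Odds of 0.93 mean the data cannot distinguish one shared rate process from
two — a single pair of simulations supports no conclusion either way. The
rate itself is still estimable, with honest width:

```r
rate_posterior(a, "uniform")
#> Rate posterior (uniform prior): Gamma(shape = 2, rate = 0.466 us)
#>   mean 4.292 1/us, sd 3.035, 95% CI [0.5198, 11.96]
```

Free energy from 500+500 synthetic Gaussian work values with true
ΔG = 5 kJ/mol, and an AR(1) autocorrelation check with theoretical
inefficiency 19:

```r
ws <- gen_gaussian_work(5, 2, 500, 500, temperature = 298, seed = 3)
crooks_mle_dg(ws, n_boot = 300, seed = 1)
#> Crooks-MLE dG = 5.075 +/- 0.0666 kJ/mol (nf = 500, nr = 500, T = 298 K)

acf_analysis(gen_ar1(0.9, 1, 1e5, seed = 4), max_lag = 200)
#> ACF over 200 lags: integrated time 9.111, statistical inefficiency g = 19.22
```

Finite-size correction of a water diffusion coefficient measured in a
9-nm periodic box (water-model viscosity 3.08e-4 kg m⁻¹ s⁻¹):

```r
yeh_hummer_correct(0.0021, 9)
#>    d_pbc l_box correction d_corrected d_corrected_cm2_s
#> 1 0.0021     9   0.000223     0.00232              2.32
```

Each result object has `tidy()`/`glance()` methods and an `autoplot()`
view; `run_pipeline()` executes configured stages on CSV/TSV inputs and
writes deterministic JSON reports. See the vignette
(`vignettes/statistics-for-md-observables.Rmd`) for the models,
assumptions and numerical choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates all synthetic inputs under the given seed and re-runs the main
analyses end to end — the Bayes-factor comparisons, the posterior and
credible interval, the sample-size scaling of the standard error, the
Crooks-MLE recovery, the umbrella-sampling PMF recovery, the AR(1)
inefficiency, the diffusion correction and the RDF normalization —
printing a progress log and writing the results JSON to `--out`.
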