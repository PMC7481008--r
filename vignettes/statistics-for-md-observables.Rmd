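---
title: "Statistical inference for molecular-simulation observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical inference for molecular-simulation observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdinfer)
```

mdinfer quantifies the uncertainty of observables derived from molecular
dynamics (MD) simulations: transition rates estimated from a handful of
trajectories, free energies from non-equilibrium work or umbrella
sampling, and solvent properties that carry finite-size artifacts. The
recurring theme is that a single simulation is an anecdote; every
estimator here either propagates uncertainty from replicates or supplies
a posterior distribution, so that "no evidence of a difference" and
"evidence of no difference" can be told apart.

Nothing in the package runs MD. Instead, a synthetic-data module generates
inputs with exactly the statistical structure each estimator assumes, so
every stage is validated by parameter recovery against a known ground
truth.

## Rate inference from censored trajectories

### The model

A set of $N$ equal-length trajectories is started in state A; $n$ of them
reach state B, the $i$-th after time $t_{fi}$, while the rest run to their
full length without transitioning (type-I right-censoring at the fixed
trajectory length). Under single-exponential kinetics with rate $k$, the
likelihood is

$$ \ell(k) = k^{\,n} e^{-k\Theta}, \qquad
   \Theta = \sum_{i=1}^{n} t_{fi} + \sum_{i=1}^{N-n} t_i , $$

where $\Theta$ is the total exposure time: event times of transitioning
trajectories plus full lengths of censored ones. $(n, \Theta)$ are
sufficient; `transition_stats()` computes them.

### Posteriors

Two priors are supported. The uniform prior gives the Gamma posterior
$\mathrm{Gamma}(n+1, \Theta)$ with mean $(n+1)/\Theta$ and variance
$(n+1)/\Theta^2$; it is proper even with $n = 0$, which is what makes
rate statements possible for simulations in which nothing happened. The
scale-invariant Jeffreys prior ($\propto 1/k$) gives
$\mathrm{Gamma}(n, \Theta)$ with mean $n/\Theta$; it requires at least
one observed event and `rate_posterior()` refuses it otherwise. With
growing $n$ the two posteriors converge (the package tests this as a
monotone decrease of their total-variation distance).

Credible intervals are central equal-tailed Gamma quantiles by default.
The source material does not specify the interval construction;
highest-posterior-density intervals are available via `type = "hpd"`.

```{r}
d <- transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1), unit = "us")
tidy(rate_posterior(d, "uniform"))
```

### Comparing two conditions: the Bayes factor

Whether two sets of trajectories (say, two simulation-box sizes) are
governed by one rate process or two is decided by the odds ratio

$$ \frac{P(D \mid H_2)}{P(D \mid H_1)} =
   \frac{2}{\pi}\,
   \frac{n/\Theta}{n_1^2/\Theta_1^2 + n_2^2/\Theta_2^2}\;
   \frac{n_1!\, n_2!}{n!}\;
   \frac{\Theta^{\,n+1}}{\Theta_1^{\,n_1+1}\,\Theta_2^{\,n_2+1}} $$

with pooled $n = n_1 + n_2$, $\Theta = \Theta_1 + \Theta_2$. The published
rendering of this expression is typographically ambiguous; the form above
was fixed by validating against three independent printed anchors (the
single-repeat comparison giving 0.93, its tripled variant exceeding 3,
and the requirement that identical large samples favour one process).
`bayes_factor()` evaluates it in log space with `lfactorial`, supports
$n_i = 0$ on one side, and is exactly symmetric in its arguments. The
verbal scale of `interpret_bayes_factor()` is Jeffreys': below 1/3
substantial evidence for one process, above 3 for two, in between
"barely worth mentioning".

```{r}
bayes_factor(transition_data(TRUE, 0.466, 1),
             transition_data(FALSE, NA, 1))
```

### Frequentist route

`survival_curve()` computes the fraction of trajectories that have not
yet transitioned (product-limit estimate, so censored trajectories stay
at risk until their end time) and fits $S(t) = e^{-t/\tau}$ by nonlinear
least squares; the half-life is $t_{1/2} = \tau \ln 2$. The censored-data
maximum-likelihood estimate $\hat\tau = \Theta/n$ is always reported
alongside and the object is flagged when the two disagree by more than
two rough standard errors. With zero observed transitions the function
errors and points at the Bayesian route, which remains well defined.

`bootstrap_half_life()` (default 1000 resamples) resamples trajectories
with replacement; zero-transition resamples are redrawn and counted. For
any dataset with at least one event the probability of such a resample is
at most $1/e$, so the documented refusal at a 50% redraw rate can only
trigger on pathological inputs — the redraw counter is the informative
output.

`rate_vs_sample_size()` subsamples a trajectory pool without replacement
at increasing sizes and reports the estimate spread per size together
with the fitted log–log slope of SE versus $N$. For i.i.d. transition
data the statistically forced scaling is $N^{-1/2}$, and that is what the
package asserts on synthetic data; the narrative text accompanying the
original figures calls the same curve "1/N", a discrepancy we flag here
rather than resolve. (A finite pool adds a small finite-population
correction, steepening the fitted slope by about 0.01 at the default
sizes.)

`conclusion_probabilities()` quantifies the risk of single-repeat
designs: given per-condition transition counts, it enumerates all $2^B$
transition/no-transition patterns a one-trajectory-per-condition design
could produce and their probabilities under independent Bernoulli draws,
either with per-condition empirical frequencies or with a pooled common
probability. Whether the original analysis computed these probabilities
exactly as products of empirical frequencies is not stated; the product
model is what is implemented and documented.

## Free energies

### Crooks maximum likelihood (Bennett acceptance ratio)

`crooks_mle_dg()` estimates $\Delta G$ from forward and reverse
non-equilibrium work samples via the two-sided acceptance-ratio
maximum-likelihood equation, solved with a bracketing root finder (the
equation is monotone in $\Delta G$). Sign convention, stated explicitly
because upstream tools differ: forward work drives A→B and fluctuates
about $+\Delta G$, reverse work drives B→A and fluctuates about
$-\Delta G$. The estimator is exactly antisymmetric under swapping the
two lists. Standard errors come from a bootstrap over work values
(default 1000 resamples); a gap of more than 50 kT between the forward
and negated-reverse distributions sets an overlap warning flag.

The synthetic generator draws Crooks-consistent Gaussians: forward from
$\mathcal N(\Delta G + \beta\sigma^2/2, \sigma^2)$, reverse from
$\mathcal N(-\Delta G + \beta\sigma^2/2, \sigma^2)$, which satisfies the
fluctuation relation exactly and gives a closed-form dissipated work for
moment tests.

### Umbrella sampling and the PMF

`mbar_pmf()` combines restrained windows into a potential of mean force
by binless multistate reweighting: the window free energies $f_k$ solve

$$ e^{-f_k} = \sum_n \frac{e^{-u_k(x_n)}}
   {\sum_l N_l\, e^{\,f_l - u_l(x_n)}} $$

with $u_k$ the reduced restraint bias. The solver is plain damped
self-consistent iteration to a relative tolerance of $10^{-8}$ (default
damping 1; umbrella ladders converge in a few hundred iterations, so the
contemplated Newton fallback proved unnecessary — non-convergence raises
an error carrying the residual). Because the $u_k$ are bias energies
bounded below by zero, $e^{-u_k}$ is precomputed once and each iteration
is two matrix–vector products. Adjacent windows (ordered by center) must
have overlapping sampled ranges; a gap is reported by position. Periodic
coordinates (dihedrals) are supported through a minimum-image bias via
`periodic = TRUE`.

The unbiased weights are histogrammed (default 50 uniform bins over the
sampled range) and converted to $-k_BT\ln$ densities; the profile is
aligned so its minimum is exactly zero, matching the convention of
setting the profile minimum to $\Delta G = 0$. Temperature enters as the
thermal energy `kt` in the same units as the force constants (1 for
reduced units; `kT_kJ_per_mol()` converts kelvin for kJ/mol data).

Per-bin standard errors are a deliberate approximation: the Kish
effective sample size of the importance weights, deflated by the mean
statistical inefficiency of the window chains, feeds a multinomial error
on the bin mass, $\mathrm{se}_i = k_BT\sqrt{(1-p_i)/(p_i N_\mathrm{eff})}$.
This is cheap, conservative in the well-restrained interior, and honest
about MCMC correlation; it is not the full asymptotic covariance of the
reweighting estimator. Bins beyond the outermost restraint centers are
reached only by rare excursions — their estimates are noisy and should
not be over-read, which is why flatness checks in the test-suite are
restricted to the restrained interior.

`profile_convergence()` re-estimates the profile from leading sub-slices
of each window (e.g. 1%, 10%, 100% of the data) on a common bin grid, so
the full-fraction entry reproduces `mbar_pmf()` exactly; per-fraction
standard errors come from independent replicate blocks of the chains,
following the replicate-based philosophy used throughout. Equilibration
is discarded as a leading fraction per window (`discard_fraction`),
mirroring the practice of dropping the first nanoseconds of each window.

### Diagnostics and replicate statistics

`acf_analysis()` returns the normalised autocovariance, the integrated
autocorrelation time, and the statistical inefficiency
$g = 1 + 2\sum_\tau \rho(\tau)$ with the sum truncated at the first
non-positive $\rho$ (initial-positive-sequence style; `truncate = "none"`
gives the fixed-window alternative). $g$ is the subsampling interval that
renders a chain approximately independent; note that for an AR(1) chain
with $\phi = 0.9$ the residual correlation after subsampling every
$g$-th point is $\phi^g \approx 0.135$, small but not zero.

`replicate_statistics()` is the workhorse for "average over independent
repeats with a 95% confidence interval": SE $= s/\sqrt{n}$ and a
Student-t interval ($n-1$ degrees of freedom). A normal-quantile variant
is provided because some published intervals at very small $n$ assume a
normal quantile; the t interval is the default and the wider, safer
choice at $n = 3$. A single value is refused with an explicit "N = 1"
error. `trend_significance()` extends this across ordered conditions: a
trend is called supported only when the regression slope's confidence
interval excludes zero, guarding against reading a monotone-looking
sequence of anecdotes as an effect.

## Solvent observables and finite-size effects

`msd_diffusion()` fits $\mathrm{MSD}(t) = 6Dt$ over a configurable lag
window (default 10–50% of the trajectory, avoiding poorly averaged long
lags) and reports chunked estimates whose spread serves as the
uncertainty. Wrapped coordinates are refused outright — if any
single-step displacement exceeds half the box edge the input was almost
certainly wrapped; no unwrapping heuristic is applied, since heuristic
unwrapping under a barostat is itself a documented artifact source.
Whether to fit whole trajectories or chunks is left to the caller; both
numbers are returned.

`yeh_hummer_correct()` applies the additive hydrodynamic finite-size
correction $\xi k_BT / (6\pi\eta L)$ with the cubic-lattice constant
$\xi = 2.837297$ (taken from the underlying hydrodynamic derivation; the
source text does not print it) and reports results in nm²/ps and
$10^{-5}$ cm²/s. `extrapolate_diffusion()` implements the deliberately
simple water-count-weighted average used to renormalize protein-box
diffusion coefficients to a larger box; it is an approximation and
documented as such.

`rdf_spherical()` computes a distance-resolved pair density around a
reference point and normalises by the reference density over either the
box volume or a sphere of given radius (default 4.25 nm, the protein-box
convention), minus an excluded volume. This addresses the normalization
artifact whereby ignoring the solvent-inaccessible protein volume
inflates the RDF by exactly $V_\mathrm{box}/(V_\mathrm{box} -
V_\mathrm{protein})$ — the package tests this factor exactly. The
reference is a point (the box/protein center); averaging over a reference
point set is out of scope here.

## The synthetic-data world

Each generator states the closed form it draws from, and its defaults
are the conditions of the study the package models: 1 μs trajectories
with type-I censoring, 6000-sub-trajectory pools for sample-size scaling,
20 replicates for free-energy repeat statistics, 1000 bootstrap
resamples, umbrella ladders over the unit double well
$U(x) = a(x^2-1)^2$ (barrier $a$ in kT, wells at $\pm 1$). Umbrella
chains use Metropolis Monte Carlo with the step tuned to roughly 40%
acceptance during a discarded 10% burn-in — the source names no sampler,
and Metropolis is sufficient for Boltzmann-correct samples. Window
chains use deterministic per-window sub-seeds so output is invariant to
generation order; generators restore the caller's RNG state.

What a green parameter-recovery test establishes is that the estimator
is correct *for data satisfying its model*: exponential waiting times,
Gaussian work, AR(1) observables, ideal Brownian motion. Real MD output
violates these in known ways (multi-exponential kinetics, anharmonic
work tails, long-memory observables), so recovery tests validate the
inference machinery, not the physics of any particular system.

## Numerical choices and degenerate inputs

* Bayes factors and factorials are always evaluated in log space.
* Endstate ties (equidistant from both reference states) count as *no
  transition* — the conservative choice.
* `rate_vs_sample_size()` with the subset size equal to the pool size is
  degenerate (one possible subset); it is flagged and its SE reported as
  zero rather than `NA` noise.
* Empty PMF bins yield `NA` free energies; alignment ignores them.
* Constant series are rejected by `acf_analysis()` (zero variance), and
  zero-rate transition data by the frequentist fitters.
* All tabular I/O is plain CSV/TSV with mandatory units for times;
  `time value` series accept `#`/`@` comment lines as produced by common
  xvg exports.

## Known limitations

* Single-exponential kinetics only; no multi-exponential or
  hidden-Markov models.
* The PMF standard error is the approximation described above, not the
  full MBAR covariance.
* The alchemical multi-λ ladder with per-state energies is not
  implemented; the reweighting core is exercised on umbrella-style data.
* No rotational or membrane hydrodynamic corrections; the finite-size
  correction applies to translational diffusion in cubic boxes.
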