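# Shared fixtures, built in code. The two-trajectory "anchor" dataset is
# the single-repeat comparison used throughout: one trajectory
# transitioning at 0.466 us versus one 1-us trajectory with no transition.

anchor_a <- function() transition_data(TRUE, 0.466, 1, unit = "us")
anchor_b <- function() transition_data(FALSE, NA_real_, 1, unit = "us")

# n replications of the anchor observations
anchor_rep <- function(n) {
  transition_data(rep(TRUE, n), rep(0.466, n), rep(1, n), unit = "us")
}
anchor_rep_censored <- function(n) {
  transition_data(rep(FALSE, n), rep(NA_real_, n), rep(1, n), unit = "us")
}

# total posterior mass by quadrature over the quantile-bounded support
# (integrate() misses narrow Gamma peaks on (0, Inf))
posterior_mass <- function(post) {
  lo <- qgamma(1e-13, post$shape, rate = post$theta)
  hi <- qgamma(1 - 1e-13, post$shape, rate = post$theta)
  integrate(function(k) posterior_density(post, k), lo, hi,
            rel.tol = 1e-10)$value
}

# small umbrella ladder over a double well, shared across tests
small_double_well_windows <- function(barrier = 5, n_windows = 9,
                                      n_samples = 8000, seed = 42) {
  gen_umbrella_samples(double_well(barrier),
                       seq(-1.4, 1.4, length.out = n_windows),
                       force_constant = 14, n_samples = n_samples,
                       seed = seed)
}
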