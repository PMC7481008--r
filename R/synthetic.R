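# Synthetic-data generators.
#
# Every generator draws from a closed-form model of the statistical structure
# that the downstream estimators assume, so parameter-recovery tests have an
# exact ground truth. All generators are deterministic given `seed` and leave
# the caller's RNG state untouched.

#' Censored transition-time data
#'
#' Construct or validate a tibble of per-trajectory transition outcomes:
#' each trajectory either shows a barrier-crossing event at `event_time`
#' (observed) or runs to `total_time` without one (censored). This is the
#' input of both the Bayesian and the frequentist rate estimators.
#'
#' @param observed Logical vector: did the trajectory transition?
#' @param event_time Numeric vector of event times; `NA` where censored.
#' @param total_time Numeric vector of trajectory lengths.
#' @param unit Declared time unit (free-form string, e.g. `"us"`, `"ns"`).
#'   Rates inherit this unit; no conversion is ever performed silently.
#' @return A `transition_data` tibble with columns `trajectory_id`,
#'   `observed`, `event_time`, `total_time` and attribute `time_unit`.
#' @export
#' @examples
#' transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1), unit = "us")
transition_data <- function(observed, event_time, total_time, unit = "us") {
  n <- length(observed)
  if (n < 1L) {
    abort("transition data must contain at least one trajectory.",
          class = "mdinfer_input_error")
  }
  stopifnot(is.logical(observed), length(event_time) == n,
            length(total_time) == n)
  if (any(is.na(total_time)) || any(total_time <= 0)) {
    abort("`total_time` must be positive for every trajectory.",
          class = "mdinfer_input_error")
  }
  if (any(observed & is.na(event_time))) {
    abort("observed trajectories must carry an `event_time`.",
          class = "mdinfer_input_error")
  }
  if (any(!observed & !is.na(event_time))) {
    abort("censored trajectories must have `event_time = NA`.",
          class = "mdinfer_input_error")
  }
  bad <- observed & (event_time <= 0 | event_time > total_time)
  if (any(bad)) {
    abort(sprintf(
      "event times must lie in (0, total_time]; offending rows: %s",
      paste(which(bad), collapse = ", ")), class = "mdinfer_input_error")
  }
  out <- tibble(
    trajectory_id = seq_len(n),
    observed = observed,
    event_time = as.numeric(event_time),
    total_time = as.numeric(total_time)
  )
  attr(out, "time_unit") <- unit
  class(out) <- c("transition_data", class(out))
  out
}

#' Time unit of a transition dataset
#' @param data A `transition_data` tibble.
#' @return The declared unit string (defaults to `"us"` if absent).
#' @export
time_unit <- function(data) attr(data, "time_unit") %||% "us"

#' Simulate censored first-passage times
#'
#' Draws exponential waiting times with the given rate and censors them at
#' the fixed trajectory length `t_max` (type-I censoring), emulating a set
#' of equal-length simulations of which only some show the transition.
#'
#' @param rate True transition rate (1/time unit); `rate = 0` never
#'   transitions.
#' @param n_traj Number of trajectories.
#' @param t_max Trajectory length (censoring time).
#' @param seed Integer seed.
#' @param unit Declared time unit.
#' @return A [transition_data()] tibble.
#' @export
#' @examples
#' gen_transition_data(rate = 2, n_traj = 10, t_max = 1, seed = 1)
gen_transition_data <- function(rate, n_traj, t_max, seed, unit = "us") {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    abort("`rate` must be a single non-negative number.",
          class = "mdinfer_input_error")
  }
  n_traj <- check_count(n_traj, "n_traj")
  check_positive_scalar(t_max, "t_max")
  local_rng(seed)
  t_event <- if (rate == 0) rep(Inf, n_traj) else rexp(n_traj, rate)
  observed <- t_event <= t_max
  transition_data(
    observed = observed,
    event_time = ifelse(observed, t_event, NA_real_),
    total_time = rep(t_max, n_traj),
    unit = unit
  )
}

#' Forward/reverse non-equilibrium work values
#'
#' Construct a work set for the Crooks maximum-likelihood free-energy
#' estimator. Sign convention: `forward` work drives A to B and fluctuates
#' around `dg + dissipation`; `reverse` work drives B to A and fluctuates
#' around `-dg + dissipation`.
#'
#' @param forward,reverse Numeric work values, kJ/mol.
#' @param temperature Temperature in kelvin.
#' @return A `work_set` tibble with columns `direction`, `work` and
#'   attribute `temperature`.
#' @export
work_set <- function(forward, reverse, temperature = 298) {
  if (length(forward) < 1L || length(reverse) < 1L) {
    abort("both forward and reverse work lists must be non-empty.",
          class = "mdinfer_input_error")
  }
  check_positive_scalar(temperature, "temperature")
  stopifnot(all(is.finite(forward)), all(is.finite(reverse)))
  out <- dplyr::bind_rows(
    tibble(direction = "forward", work = as.numeric(forward)),
    tibble(direction = "reverse", work = as.numeric(reverse))
  )
  attr(out, "temperature") <- temperature
  class(out) <- c("work_set", class(out))
  out
}

#' Crooks-consistent Gaussian work distributions
#'
#' Forward works are drawn from Normal(dg_true + beta*sigma^2/2, sigma^2)
#' and reverse works from Normal(-dg_true + beta*sigma^2/2, sigma^2); this
#' Gaussian pair satisfies the Crooks fluctuation relation exactly, with
#' dissipated work beta*sigma^2/2 on each side.
#'
#' @param dg_true True free-energy difference, kJ/mol.
#' @param sigma Work standard deviation, kJ/mol (0 gives delta functions).
#' @param n_fwd,n_rev Sample counts.
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @return A [work_set()].
#' @export
gen_gaussian_work <- function(dg_true, sigma, n_fwd, n_rev,
                              temperature = 298, seed = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort("`sigma` must be a single non-negative number.",
          class = "mdinfer_input_error")
  }
  n_fwd <- check_count(n_fwd, "n_fwd")
  n_rev <- check_count(n_rev, "n_rev")
  kt <- kT_kJ_per_mol(temperature)
  diss <- sigma^2 / (2 * kt)
  local_rng(seed)
  work_set(
    forward = rnorm(n_fwd, mean = dg_true + diss, sd = sigma),
    reverse = rnorm(n_rev, mean = -dg_true + diss, sd = sigma),
    temperature = temperature
  )
}

#' Symmetric double-well model potential
#'
#' Minimal two-state model standing in for systems with two major
#' conformations. The potential is `U(x) = a * ((x/x0)^2 - 1)^2` in units
#' of kT, with wells at `x = -x0, +x0` and barrier height `a` at `x = 0`
#' (for the default `x0 = 1` this is `a * (x^2 - 1)^2`).
#'
#' @param barrier_height Barrier height `a` in kT units; must be >= 0.
#' @param well_separation Half-distance `x0` between the wells (reduced
#'   units); wells sit at -x0 and +x0.
#' @return A `double_well` object with a `$potential(x)` function.
#' @export
#' @examples
#' dw <- double_well(5)
#' dw$potential(c(-1, 0, 1))
double_well <- function(barrier_height, well_separation = 1) {
  if (!is.numeric(barrier_height) || length(barrier_height) != 1L ||
      barrier_height < 0) {
    abort("`barrier_height` must be a single non-negative number (kT).",
          class = "mdinfer_input_error")
  }
  check_positive_scalar(well_separation, "well_separation")
  a <- barrier_height
  x0 <- well_separation
  structure(
    list(
      barrier_height = a,
      well_separation = x0,
      potential = function(x) a * ((x / x0)^2 - 1)^2
    ),
    class = "double_well"
  )
}

#' A single umbrella-sampling window
#'
#' @param samples Numeric reaction-coordinate samples.
#' @param center Restraint center.
#' @param force_constant Harmonic restraint force constant, kT per
#'   coordinate unit squared.
#' @param discard_fraction Leading fraction to discard as equilibration
#'   before any estimation.
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(samples, center, force_constant,
                            discard_fraction = 0) {
  check_positive_scalar(force_constant, "force_constant")
  if (discard_fraction < 0 || discard_fraction >= 1) {
    abort("`discard_fraction` must lie in [0, 1).",
          class = "mdinfer_input_error")
  }
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  structure(
    list(samples = as.numeric(samples), center = center,
         force_constant = force_constant,
         discard_fraction = discard_fraction),
    class = "umbrella_window"
  )
}

# window samples after equilibration discard
window_production <- function(w) {
  n <- length(w$samples)
  drop <- floor(n * w$discard_fraction)
  w$samples[(drop + 1L):n]
}

#' Boltzmann sampling of restrained umbrella windows
#'
#' Runs an independent Metropolis Monte Carlo chain per window, sampling
#' `exp(-[U(x) + K/2 (x - c)^2])` (energies in kT). The proposal step is
#' tuned to roughly 40% acceptance during a burn-in of 10% of the chain,
#' which is then discarded. Each window uses a deterministic sub-seed so
#' the output does not depend on generation order.
#'
#' @param model A [double_well()] (or any object with `$potential`).
#' @param centers Numeric vector of at least two restraint centers (a single
#'   center is allowed only via [gen_single_window()]-style direct calls with
#'   `allow_single = TRUE`).
#' @param force_constant Restraint force constant, kT per unit^2.
#' @param n_samples Retained samples per window (after burn-in).
#' @param seed Integer seed.
#' @param allow_single Permit a single window (used for null checks).
#' @return A list of [umbrella_window()] objects.
#' @export
gen_umbrella_samples <- function(model, centers, force_constant, n_samples,
                                 seed, allow_single = FALSE) {
  if (length(centers) < 2L && !allow_single) {
    abort("at least two umbrella centers are required.",
          class = "mdinfer_input_error")
  }
  if (length(centers) < 1L) {
    abort("`centers` must not be empty.", class = "mdinfer_input_error")
  }
  check_positive_scalar(force_constant, "force_constant")
  n_samples <- check_count(n_samples, "n_samples")
  stopifnot(is.function(model$potential))

  n_burn <- max(100L, ceiling(0.1 * n_samples))
  purrr::imap(as.list(centers), function(cc, i) {
    local_rng(substream_seed(seed, i))
    u_bias <- function(x) model$potential(x) +
      0.5 * force_constant * (x - cc)^2
    # start at the restraint center; initial step ~ restrained width
    step <- 2 * sqrt(1 / force_constant)
    x <- cc
    ux <- u_bias(x)
    burn_acc <- 0L
    chain <- numeric(n_samples)
    total <- n_burn + n_samples
    prop <- rnorm(total)
    unif <- runif(total)
    for (t in seq_len(total)) {
      xn <- x + step * prop[t]
      un <- u_bias(xn)
      if (log(unif[t]) < ux - un) {
        x <- xn; ux <- un
        if (t <= n_burn) burn_acc <- burn_acc + 1L
      }
      if (t <= n_burn && t %% 50L == 0L) {
        # tune toward ~40% acceptance
        rate <- burn_acc / t
        step <- step * exp(rate - 0.4)
      }
      if (t > n_burn) chain[t - n_burn] <- x
    }
    umbrella_window(chain, center = cc, force_constant = force_constant)
  })
}

#' Stationary AR(1) series
#'
#' `x_t = phi * x_{t-1} + eps_t`, `eps ~ Normal(0, sigma^2)`, initialised
#' from the stationary distribution so the whole series is stationary.
#' Fixture for autocorrelation/statistical-inefficiency diagnostics.
#'
#' @param phi AR coefficient, `|phi| < 1`.
#' @param sigma Innovation standard deviation.
#' @param n Series length.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_ar1 <- function(phi, sigma, n, seed) {
  if (!is.numeric(phi) || length(phi) != 1L || abs(phi) >= 1) {
    abort("`phi` must satisfy |phi| < 1 (stationarity).",
          class = "mdinfer_input_error")
  }
  if (sigma < 0) abort("`sigma` must be non-negative.",
                       class = "mdinfer_input_error")
  n <- check_count(n, "n")
  local_rng(seed)
  eps <- rnorm(n, 0, sigma)
  x0 <- rnorm(1, 0, sigma / sqrt(1 - phi^2))
  as.numeric(stats::filter(eps, phi, method = "recursive", init = x0))
}

#' Brownian particles in a periodic box
#'
#' Independent 3-D Gaussian random walks with per-step displacement variance
#' `2 * d_true * dt` per dimension. Both unwrapped and wrapped (into
#' `[0, l_box)`) coordinates are returned.
#'
#' @param d_true Diffusion coefficient, length^2/time (e.g. nm^2/ps).
#' @param l_box Box edge length.
#' @param n_particles,n_steps Counts.
#' @param dt Time step.
#' @param seed Integer seed.
#' @return Tibble with columns `frame`, `particle`, wrapped `x, y, z` and
#'   unwrapped `xu, yu, zu`; attributes `l_box`, `dt`.
#' @export
gen_brownian_box <- function(d_true, l_box, n_particles, n_steps, dt, seed) {
  if (!is.numeric(d_true) || length(d_true) != 1L || d_true < 0) {
    abort("`d_true` must be a single non-negative number.",
          class = "mdinfer_input_error")
  }
  check_positive_scalar(l_box, "l_box")
  check_positive_scalar(dt, "dt")
  n_particles <- check_count(n_particles, "n_particles")
  n_steps <- check_count(n_steps, "n_steps")
  local_rng(seed)
  sd_step <- sqrt(2 * d_true * dt)
  coords <- purrr::map(c("xu", "yu", "zu"), function(dim) {
    start <- runif(n_particles, 0, l_box)
    steps <- matrix(rnorm(n_particles * n_steps, 0, sd_step),
                    nrow = n_steps, ncol = n_particles)
    # rows: frames 0..n_steps; columns: particles
    rbind(start, apply(steps, 2, cumsum) + rep(start, each = n_steps))
  })
  names(coords) <- c("xu", "yu", "zu")
  out <- tibble(
    frame = rep(0:n_steps, times = n_particles),
    particle = rep(seq_len(n_particles), each = n_steps + 1L),
    xu = as.vector(coords$xu), yu = as.vector(coords$yu),
    zu = as.vector(coords$zu)
  )
  out$x <- out$xu %% l_box
  out$y <- out$yu %% l_box
  out$z <- out$zu %% l_box
  out <- out[, c("frame", "particle", "x", "y", "z", "xu", "yu", "zu")]
  attr(out, "l_box") <- l_box
  attr(out, "dt") <- dt
  out
}

#' Uniform point configurations with a central excluded sphere
#'
#' Points are laid down as an ideal gas over the box and rejected inside a
#' sphere of radius `r_excl` around the box center, mimicking solvent
#' excluded from the volume occupied by a protein. Per-frame counts are
#' Poisson with mean `density * l_box^3`, so the achieved density over the
#' accessible volume matches `density`.
#'
#' @param density Target number density (count/length^3).
#' @param l_box Box edge.
#' @param r_excl Excluded-sphere radius (0 for pure ideal gas); requires
#'   `2 * r_excl < l_box`.
#' @param n_frames Number of independent configurations.
#' @param seed Integer seed.
#' @return Tibble `frame, x, y, z` with attributes `l_box`, `r_excl`.
#' @export
gen_excluded_config <- function(density, l_box, r_excl, n_frames, seed) {
  check_positive_scalar(density, "density")
  check_positive_scalar(l_box, "l_box")
  n_frames <- check_count(n_frames, "n_frames")
  if (!is.numeric(r_excl) || r_excl < 0 || 2 * r_excl >= l_box) {
    abort("`r_excl` must satisfy 0 <= 2*r_excl < l_box.",
          class = "mdinfer_input_error")
  }
  local_rng(seed)
  ctr <- l_box / 2
  frames <- purrr::map(seq_len(n_frames), function(f) {
    n0 <- stats::rpois(1, density * l_box^3)
    if (n0 == 0L) return(tibble(frame = integer(), x = numeric(),
                                y = numeric(), z = numeric()))
    x <- runif(n0, 0, l_box); y <- runif(n0, 0, l_box)
    z <- runif(n0, 0, l_box)
    keep <- (x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 >= r_excl^2
    tibble(frame = f, x = x[keep], y = y[keep], z = z[keep])
  })
  out <- dplyr::bind_rows(frames)
  attr(out, "l_box") <- l_box
  attr(out, "r_excl") <- r_excl
  attr(out, "n_frames") <- n_frames
  out
}

#' Independent replicate free-energy estimates
#'
#' i.i.d. Normal(mu, sigma^2) draws, emulating repeated free-energy
#' calculations whose spread yields the replicate-based standard error.
#'
#' @param mu True mean, kJ/mol.
#' @param sigma Between-replicate standard deviation, kJ/mol.
#' @param n_rep Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_rep`.
#' @export
gen_replicate_dg <- function(mu, sigma, n_rep, seed) {
  n_rep <- check_count(n_rep, "n_rep", min = 2L)
  if (sigma < 0) abort("`sigma` must be non-negative.",
                       class = "mdinfer_input_error")
  local_rng(seed)
  rnorm(n_rep, mu, sigma)
}
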