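# Free-energy estimation layer: Crooks/Bennett maximum-likelihood dG from
# non-equilibrium work, multistate reweighting of umbrella windows into a
# PMF, data-fraction convergence, autocorrelation diagnostics and replicate
# statistics.

#' Crooks maximum-likelihood free-energy difference
#'
#' Solves the two-sided acceptance-ratio (Bennett) maximum-likelihood
#' equation for the free-energy difference implied by forward and reverse
#' non-equilibrium work distributions related by the Crooks fluctuation
#' theorem. Sign convention: forward work drives A to B (fluctuates about
#' `+dG`), reverse work drives B to A (about `-dG`). The standard error is
#' obtained by bootstrap over the work values.
#'
#' @param works A [work_set()] (tibble `direction`, `work` in kJ/mol with a
#'   `temperature` attribute) or anything coercible via [work_set()].
#' @param n_boot Bootstrap resamples for the SE (default 1000; 0 skips).
#' @param seed Integer seed for the bootstrap.
#' @return A `crooks_dg` object: `dg`, `se` (kJ/mol), `temperature`,
#'   sample sizes, and `overlap_warning` when the forward and negated
#'   reverse work distributions are separated by more than 50 kT.
#' @export
#' @examples
#' ws <- gen_gaussian_work(5, 2, 200, 200, seed = 1)
#' crooks_mle_dg(ws, n_boot = 100)
crooks_mle_dg <- function(works, n_boot = 1000, seed = 1) {
  stopifnot(is.data.frame(works), all(c("direction", "work") %in% names(works)))
  wf <- works$work[works$direction == "forward"]
  wr <- works$work[works$direction == "reverse"]
  if (length(wf) < 1L || length(wr) < 1L) {
    abort("need at least one work value on each side.",
          class = "mdinfer_input_error")
  }
  stopifnot(all(is.finite(wf)), all(is.finite(wr)))
  temperature <- attr(works, "temperature") %||% 298
  kt <- kT_kJ_per_mol(temperature)

  overlap_warning <- (min(wf) - max(-wr)) > 50 * kt
  if (overlap_warning) {
    warn("forward and reverse work distributions barely overlap (> 50 kT gap); the estimate is unreliable.")
  }
  dg <- bar_solve(wf, wr, kt)
  se <- NA_real_
  if (n_boot >= 2) {
    local_rng(seed)
    boots <- purrr::map_dbl(seq_len(n_boot), function(b) {
      bar_solve(sample(wf, replace = TRUE), sample(wr, replace = TRUE), kt)
    })
    se <- sd(boots)
  }
  structure(
    list(dg = dg, se = se, temperature = temperature,
         n_fwd = length(wf), n_rev = length(wr),
         overlap_warning = overlap_warning, n_boot = n_boot),
    class = "crooks_dg"
  )
}

# root of the Bennett self-consistency equation; monotone in dg
bar_solve <- function(wf, wr, kt) {
  m <- log(length(wf) / length(wr))
  g <- function(dg) {
    sum(stats::plogis(-(m + (wf - dg) / kt))) -
      sum(stats::plogis(-(-m + (wr + dg) / kt)))
  }
  lo <- min(c(wf, -wr)) - 1
  hi <- max(c(wf, -wr)) + 1
  # widen until the root is bracketed (g is increasing in dg)
  while (g(lo) > 0) lo <- lo - (hi - lo)
  while (g(hi) < 0) hi <- hi + (hi - lo)
  uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.crooks_dg <- function(x, ...) {
  cat(sprintf("Crooks-MLE dG = %.4g +/- %.3g kJ/mol (nf = %d, nr = %d, T = %g K)\n",
              x$dg, x$se, x$n_fwd, x$n_rev, x$temperature))
  if (isTRUE(x$overlap_warning)) cat("  warning: poor work-distribution overlap\n")
  invisible(x)
}

#' @export
tidy.crooks_dg <- function(x, ...) {
  tibble(dg = x$dg, se = x$se, temperature = x$temperature,
         n_fwd = x$n_fwd, n_rev = x$n_rev,
         overlap_warning = x$overlap_warning)
}

#' @export
glance.crooks_dg <- function(x, ...) tidy(x)

#' Potential of mean force by multistate reweighting
#'
#' Combines samples from harmonically restrained umbrella windows into an
#' unbiased free-energy profile. The per-window free energies solve the
#' standard multistate (MBAR/binless-WHAM) self-consistency equations,
#' iterated to a relative tolerance of `tol`; the unbiased importance
#' weights are then histogrammed on a uniform grid and converted to
#' \eqn{-k_B T \ln} densities. The returned profile is aligned so its
#' minimum is exactly zero.
#'
#' Per-bin standard errors use the Kish effective sample size of the
#' importance weights, deflated by the mean statistical inefficiency of the
#' window chains (see the package vignette for the construction).
#'
#' @param windows List of [umbrella_window()] objects (>= 2; a single
#'   window is permitted and reduces to a plain Boltzmann histogram). Each
#'   window's `discard_fraction` is applied before estimation.
#' @param kt Thermal energy in the units of the window force constants
#'   (1 for reduced/kT units; use [kT_kJ_per_mol()] for kelvin inputs).
#' @param bins Number of uniform bins over the sampled range (default 50),
#'   or a numeric vector of explicit breaks.
#' @param periodic Treat the coordinate as periodic with period `period`
#'   when evaluating restraint biases (e.g. dihedrals)?
#' @param period Coordinate period when `periodic = TRUE`.
#' @param tol Relative convergence tolerance on the window free energies.
#' @param max_iter Maximum self-consistent iterations.
#' @return A `fe_profile` tibble: `x` (bin centers), `dg`, `se`,
#'   `n_samples`; attributes `kt`, `window_f` (converged window free
#'   energies), `iterations`, `residual`, `alignment`.
#' @export
mbar_pmf <- function(windows, kt = 1, bins = 50, periodic = FALSE,
                     period = 2 * pi, tol = 1e-8, max_iter = 1e4) {
  stopifnot(is.list(windows), length(windows) >= 1L)
  check_positive_scalar(kt, "kt")
  ok <- purrr::map_lgl(windows, inherits, "umbrella_window")
  if (!all(ok)) {
    abort("`windows` must be a list of umbrella_window objects.",
          class = "mdinfer_input_error")
  }
  samples <- purrr::map(windows, window_production)
  check_window_overlap(windows, samples)

  n_k <- lengths(samples)
  x <- unlist(samples, use.names = FALSE)
  centers <- purrr::map_dbl(windows, "center")
  kconst <- purrr::map_dbl(windows, "force_constant")

  dx_fun <- if (periodic) {
    function(d) d - period * round(d / period)
  } else identity
  # reduced bias energies, samples x windows
  u_kn <- vapply(seq_along(windows), function(k) {
    0.5 * kconst[k] * dx_fun(x - centers[k])^2 / kt
  }, numeric(length(x)))

  sol <- mbar_solve(u_kn, n_k, tol = tol, max_iter = max_iter)
  log_w <- -sol$log_denom # unnormalised unbiased log-weights
  log_w <- log_w - logsumexp(log_w)
  w <- exp(log_w)

  breaks <- if (length(bins) > 1L) as.numeric(bins) else {
    seq(min(x), max(x), length.out = bins + 1L)
  }
  bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = FALSE)
  inside <- bin >= 1L & bin <= length(breaks) - 1L
  nb <- length(breaks) - 1L
  wsum <- vapply(seq_len(nb), function(i) sum(w[inside & bin == i]),
                 numeric(1))
  counts <- tabulate(bin[inside], nbins = nb)
  width <- diff(breaks)
  dg <- ifelse(wsum > 0, -kt * (log(wsum) - log(width)), NA_real_)
  dg <- dg - min(dg, na.rm = TRUE)

  # effective sample size, deflated by chain autocorrelation
  ess <- sum(w)^2 / sum(w^2)
  g_mean <- mean(purrr::map_dbl(samples, function(s) {
    if (length(s) < 10L || sd(s) == 0) return(1)
    acf_analysis(s, max_lag = min(length(s) %/% 3L, 500L))$inefficiency
  }))
  ess_adj <- ess / g_mean
  p <- wsum
  se <- ifelse(p > 0, kt * sqrt((1 - p) / (p * ess_adj)), NA_real_)

  out <- tibble(x = (head(breaks, -1) + tail(breaks, -1)) / 2,
                dg = dg, se = se, n_samples = counts)
  structure(out,
            kt = kt, window_f = sol$f * kt, iterations = sol$iterations,
            residual = sol$residual, alignment = "min_zero",
            ess = ess_adj,
            class = c("fe_profile", class(out)))
}

# Self-consistent multistate reweighting on reduced bias energies.
# Because the u_kn are bias energies bounded below by 0, exp(-u_kn) can be
# precomputed once and each iteration reduces to two matrix-vector
# products; the window free energies are kept shifted so the exponentials
# stay in range.
mbar_solve <- function(u_kn, n_k, tol = 1e-8, max_iter = 1e4,
                       damping = 1) {
  K <- ncol(u_kn)
  f <- numeric(K)
  E <- exp(-u_kn) # samples x windows, entries in [0, 1]
  resid <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    fmax <- max(f)
    # denom_n = sum_l N_l exp(f_l - u_ln), carried as exp(fmax) * d_n
    d <- drop(E %*% (n_k * exp(f - fmax)))
    f_new <- fmax - log(drop(crossprod(E, 1 / d)))
    f_new <- f_new - f_new[1L]
    f_new <- (1 - damping) * f + damping * f_new
    resid <- max(abs(f_new - f) / pmax(abs(f_new), 1))
    f <- f_new
    if (resid < tol || it >= max_iter) break
  }
  if (resid >= tol) {
    abort(sprintf(
      "multistate reweighting did not converge in %d iterations (residual %.3g).",
      it, resid), class = "mdinfer_convergence_error")
  }
  fmax <- max(f)
  log_denom <- fmax + log(drop(E %*% (n_k * exp(f - fmax))))
  list(f = f, log_denom = log_denom, iterations = it, residual = resid)
}

# adjacent windows (by center) must have overlapping sampled ranges
check_window_overlap <- function(windows, samples) {
  if (length(windows) < 2L) return(invisible(TRUE))
  ord <- order(purrr::map_dbl(windows, "center"))
  rng <- purrr::map(samples[ord], range)
  ctr <- purrr::map_dbl(windows, "center")[ord]
  for (i in seq_len(length(rng) - 1L)) {
    if (rng[[i]][2] < rng[[i + 1L]][1]) {
      abort(sprintf(
        "no sample overlap between adjacent windows centered at %g and %g (gap [%g, %g]).",
        ctr[i], ctr[i + 1L], rng[[i]][2], rng[[i + 1L]][1]),
        class = "mdinfer_overlap_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "Free-energy profile: %d bins, kt = %g, converged in %d iterations\n",
    nrow(x), attr(x, "kt"), attr(x, "iterations")))
  NextMethod()
}

#' Convergence of the PMF with increasing data
#'
#' Re-estimates the profile from leading sub-slices of each window (the
#' first `fraction` of its production samples), emulating how a profile
#' built from 0.1%, 1%, 10%, 100% of the data converges. Standard errors
#' per fraction come from `n_rep` independent replicate estimates, obtained
#' by splitting each window chain into `n_rep` contiguous blocks and
#' profiling each block's leading sub-slice; the per-bin SE is the SD
#' across replicates divided by `sqrt(n_rep)`.
#'
#' All profiles share the bin grid of the full-data estimate, so the
#' `fractions = 1` entry reproduces [mbar_pmf()] exactly.
#'
#' @inheritParams mbar_pmf
#' @param fractions Numeric vector in (0, 1]; each must leave >= 10
#'   samples per window.
#' @param n_rep Number of replicate blocks (default 10).
#' @return Named list of `fe_profile` objects (names = fractions), each
#'   with attribute `fraction`.
#' @export
profile_convergence <- function(windows, fractions = c(0.01, 0.1, 1),
                                n_rep = 10, kt = 1, bins = 50,
                                periodic = FALSE, period = 2 * pi) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1L)
  if (any(fractions <= 0) || any(fractions > 1)) {
    abort("`fractions` must lie in (0, 1].", class = "mdinfer_input_error")
  }
  n_rep <- check_count(n_rep, "n_rep", min = 2L)
  prod_lens <- purrr::map_int(windows, function(w)
    length(window_production(w)))
  min_take <- floor(min(fractions) * min(prod_lens))
  if (min_take < 10L) {
    abort(sprintf(
      "smallest fraction %g leaves only %d samples in the shortest window (>= 10 required).",
      min(fractions), min_take), class = "mdinfer_input_error")
  }
  full_x <- unlist(purrr::map(windows, window_production))
  breaks <- seq(min(full_x), max(full_x), length.out = bins + 1L)

  slice_window <- function(w, from, to, frac) {
    s <- window_production(w)[from:to]
    take <- max(1L, floor(frac * length(s)))
    umbrella_window(s[seq_len(take)], w$center, w$force_constant)
  }

  out <- purrr::map(fractions, function(frac) {
    prof <- mbar_pmf(
      purrr::map(windows, function(w)
        slice_window(w, 1L, length(window_production(w)), frac)),
      kt = kt, bins = breaks, periodic = periodic, period = period)
    reps <- purrr::map(seq_len(n_rep), function(r) {
      wins_r <- purrr::map(windows, function(w) {
        n <- length(window_production(w))
        from <- floor((r - 1L) * n / n_rep) + 1L
        to <- floor(r * n / n_rep)
        slice_window(w, from, to, frac)
      })
      tryCatch(mbar_pmf(wins_r, kt = kt, bins = breaks,
                        periodic = periodic, period = period)$dg,
               error = function(e) rep(NA_real_, length(breaks) - 1L))
    })
    rep_mat <- do.call(cbind, reps)
    prof$se <- apply(rep_mat, 1L, sd, na.rm = TRUE) / sqrt(n_rep)
    attr(prof, "fraction") <- frac
    attr(prof, "replicates") <- rep_mat
    prof
  })
  names(out) <- as.character(fractions)
  out
}

#' Autocorrelation analysis of an observable series
#'
#' Normalised autocovariance function, integrated autocorrelation time and
#' statistical inefficiency \eqn{g = 1 + 2 \sum_\tau \rho(\tau)}, with the
#' sum truncated at the first non-positive autocorrelation
#' (initial-positive-sequence truncation; a fixed-window alternative is
#' available via `truncate = "none"`, which sums all computed lags).
#' `g` is the factor by which autocorrelation reduces the number of
#' effectively independent samples: subsampling every `g`-th point yields
#' approximately uncorrelated data.
#'
#' @param series Numeric observable time series (non-constant).
#' @param max_lag Largest lag to compute; must satisfy
#'   `length(series) > 2 * max_lag`. Default `min(n %/% 3, 1000)`.
#' @param dt Time per step (scales `integrated_time`); default 1.
#' @param truncate `"first_nonpositive"` (default) or `"none"`.
#' @return An `acf_result`: tibble `lag`, `acf` with attributes and fields
#'   `integrated_time`, `inefficiency`, `cutoff_lag`.
#' @export
#' @examples
#' x <- gen_ar1(0.9, 1, 5e3, seed = 2)
#' acf_analysis(x)$inefficiency # ~ (1 + 0.9)/(1 - 0.9) = 19
acf_analysis <- function(series, max_lag = NULL, dt = 1,
                         truncate = c("first_nonpositive", "none")) {
  truncate <- rlang::arg_match(truncate)
  stopifnot(is.numeric(series))
  n <- length(series)
  if (is.null(max_lag)) max_lag <- min(n %/% 3L, 1000L)
  max_lag <- check_count(max_lag, "max_lag")
  if (n <= 2L * max_lag) {
    abort("series length must exceed 2 * max_lag.",
          class = "mdinfer_input_error")
  }
  if (sd(series) == 0) {
    abort("series is constant: autocorrelation is undefined (zero variance).",
          class = "mdinfer_input_error")
  }
  rho <- as.numeric(acf(series, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
  lags <- 0:max_lag
  if (truncate == "first_nonpositive") {
    neg <- which(rho[-1L] <= 0)
    cutoff <- if (length(neg)) neg[1L] - 1L else max_lag
  } else {
    cutoff <- max_lag
  }
  tau_int <- if (cutoff >= 1L) sum(rho[2:(cutoff + 1L)]) * dt else 0
  g <- max(1, 1 + 2 * tau_int / dt)
  structure(
    list(table = tibble(lag = lags * dt, acf = rho),
         integrated_time = tau_int,
         inefficiency = g,
         cutoff_lag = cutoff,
         n = n, dt = dt),
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf(
    "ACF over %d lags: integrated time %.4g, statistical inefficiency g = %.4g\n",
    nrow(x$table) - 1L, x$integrated_time, x$inefficiency))
  invisible(x)
}

#' @export
tidy.acf_result <- function(x, ...) x$table

#' @export
glance.acf_result <- function(x, ...) {
  tibble(integrated_time = x$integrated_time,
         inefficiency = x$inefficiency,
         cutoff_lag = x$cutoff_lag, n = x$n)
}

#' Mean and confidence interval over replicate estimates
#'
#' Replicate-based uncertainty: the standard error is the standard
#' deviation of the replicate values divided by `sqrt(n_rep)`, and the
#' confidence interval uses the Student-t quantile with `n_rep - 1`
#' degrees of freedom (`quantile = "normal"` switches to the normal
#' quantile, as sometimes used with very few repeats).
#'
#' @param values Numeric replicate estimates (>= 2; a single value is an
#'   N = 1 anecdote and is refused).
#' @param level Confidence level, default 0.95.
#' @param quantile `"t"` (default) or `"normal"`.
#' @return One-row tibble: `n_rep`, `mean`, `se`, `low`, `high`, `level`.
#' @export
#' @examples
#' replicate_statistics(gen_replicate_dg(-10, 1, 20, seed = 3))
replicate_statistics <- function(values, level = 0.95,
                                 quantile = c("t", "normal")) {
  quantile <- rlang::arg_match(quantile)
  stopifnot(is.numeric(values))
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    abort(paste(
      "N = 1 statistics: a single replicate provides no uncertainty",
      "estimate; at least two independent replicates are required."),
      class = "mdinfer_n1_error")
  }
  if (level <= 0 || level >= 1) {
    abort("`level` must lie strictly between 0 and 1.",
          class = "mdinfer_input_error")
  }
  n <- length(values)
  m <- mean(values)
  se <- sd(values) / sqrt(n)
  q <- if (quantile == "t") qt(1 - (1 - level) / 2, df = n - 1L)
       else qnorm(1 - (1 - level) / 2)
  tibble(n_rep = n, mean = m, se = se,
         low = m - q * se, high = m + q * se, level = level)
}

#' Is an apparent trend across conditions statistically supported?
#'
#' Guards against over-interpreting anecdotal differences between
#' conditions (e.g. free energies across box sizes). Reports per-condition
#' confidence intervals, a one-way ANOVA location test, and a linear trend
#' fit across the ordered conditions; a monotone trend is called supported
#' only when the slope's confidence interval excludes zero. Refuses any
#' condition with a single replicate.
#'
#' @param condition_values Data frame with columns `condition` and `value`,
#'   or a named list of numeric vectors. Conditions are ordered by their
#'   order of appearance (factors keep their level order).
#' @param level Confidence level for intervals, default 0.95.
#' @return A `trend_report`: `per_condition` tibble, `anova_p`, `slope`,
#'   `slope_low`, `slope_high`, `trend_significant`.
#' @export
trend_significance <- function(condition_values, level = 0.95) {
  if (is.list(condition_values) && !is.data.frame(condition_values)) {
    condition_values <- purrr::imap_dfr(
      condition_values, function(v, nm) tibble(condition = nm, value = v))
  }
  stopifnot(is.data.frame(condition_values),
            all(c("condition", "value") %in% names(condition_values)))
  df <- as_tibble(condition_values)
  df$condition <- factor(df$condition, levels = unique(df$condition))
  counts <- table(df$condition)
  if (length(counts) < 2L) {
    abort("at least two conditions are required.",
          class = "mdinfer_input_error")
  }
  if (any(counts < 2L)) {
    abort(paste(
      "N = 1 statistics: every condition needs at least two replicates",
      "before a trend can be assessed."), class = "mdinfer_n1_error")
  }
  per <- df |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key)
      replicate_statistics(d$value, level = level)) |>
    dplyr::ungroup()
  aov_p <- summary(aov(value ~ condition, data = df))[[1]][["Pr(>F)"]][1]
  df$cond_index <- as.numeric(df$condition)
  fit <- lm(value ~ cond_index, data = df)
  ci <- confint(fit, "cond_index", level = level)
  structure(
    list(per_condition = per,
         anova_p = aov_p,
         slope = unname(coef(fit)["cond_index"]),
         slope_low = ci[1], slope_high = ci[2],
         trend_significant = ci[1] > 0 || ci[2] < 0,
         level = level),
    class = "trend_report"
  )
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf(
    "Trend across %d conditions: slope %.4g [%.4g, %.4g], ANOVA p = %.3g\n",
    nrow(x$per_condition), x$slope, x$slope_low, x$slope_high, x$anova_p))
  cat(if (x$trend_significant) "  trend supported (slope CI excludes 0)\n"
      else "  no statistically supported trend\n")
  invisible(x)
}

#' @export
tidy.trend_report <- function(x, ...) x$per_condition

#' @export
glance.trend_report <- function(x, ...) {
  tibble(slope = x$slope, slope_low = x$slope_low,
         slope_high = x$slope_high, anova_p = x$anova_p,
         trend_significant = x$trend_significant, level = x$level)
}
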