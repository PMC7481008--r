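# Frequentist rate and half-life estimation from censored trajectories:
# survival curves, exponential fits, bootstrap errors, sample-size scaling
# and the enumeration of conclusions reachable from single-repeat designs.

#' Classify a trajectory endstate by proximity
#'
#' A trajectory counts as transitioned when its endpoint is strictly closer
#' to the target (R) state than to the starting (T) state. Ties are
#' assigned to T, i.e. no transition -- the conservative convention.
#'
#' @param dist_to_R,dist_to_T Non-negative distances (e.g. RMSD) of the
#'   final frame to the two reference states; vectorised.
#' @return Character vector of `"R"` / `"T"`.
#' @export
#' @examples
#' classify_endstate(c(0.2, 0.5, 0.3), c(0.5, 0.2, 0.3))
classify_endstate <- function(dist_to_R, dist_to_T) {
  if (any(dist_to_R < 0, na.rm = TRUE) || any(dist_to_T < 0, na.rm = TRUE)) {
    abort("distances must be non-negative.", class = "mdinfer_input_error")
  }
  stopifnot(length(dist_to_R) == length(dist_to_T))
  ifelse(dist_to_R < dist_to_T, "R", "T")
}

#' Survival curve and exponential half-life fit
#'
#' Computes the fraction of trajectories that have not yet transitioned as
#' a function of time (censored trajectories remain at risk until their end
#' time; the product-limit estimate via the survival package) and fits
#' \eqn{S(t) = \exp(-t/\tau)} to it by nonlinear least squares. The
#' censored-data maximum-likelihood estimate \eqn{\hat\tau = \Theta/n} is
#' reported alongside; when the two disagree by more than 2 bootstrap-free
#' standard errors (\eqn{\hat\tau/\sqrt n}) the object is flagged. The
#' half-life is \eqn{t_{1/2} = \tau \ln 2}.
#'
#' @param data A [transition_data()] tibble with at least one observed
#'   transition.
#' @return A `survival_estimate` object: `curve` tibble (`time`,
#'   `survival`), `tau`, `half_life` (curve fit), `tau_mle`,
#'   `half_life_mle`, `estimators_disagree` flag.
#' @export
#' @examples
#' d <- gen_transition_data(2, 200, 1, seed = 4)
#' s <- survival_curve(d)
#' s$half_life
survival_curve <- function(data) {
  data <- validate_transitions(data)
  s <- transition_stats(data)
  if (s$n_observed < 1L) {
    abort(paste(
      "no transitions observed: the survival-curve fit is undefined;",
      "use the Bayesian rate estimator (rate_posterior) for such data."),
      class = "mdinfer_no_transition_error")
  }
  time <- ifelse(data$observed, data$event_time, data$total_time)
  status <- as.integer(data$observed)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  curve <- tibble(time = fit$time, survival = fit$surv,
                  n_risk = fit$n.risk, n_event = fit$n.event)
  tau_mle <- s$theta / s$n_observed
  ev <- curve[curve$n_event > 0, ]
  tau_fit <- tryCatch({
    f <- nls(survival ~ exp(-time / tau), data = ev,
             start = list(tau = tau_mle))
    coef(f)[["tau"]]
  }, error = function(e) tau_mle)
  se_rough <- tau_mle / sqrt(s$n_observed)
  structure(
    list(curve = curve,
         tau = tau_fit, half_life = tau_fit * log(2),
         tau_mle = tau_mle, half_life_mle = tau_mle * log(2),
         estimators_disagree = abs(tau_fit - tau_mle) > 2 * se_rough,
         n_observed = s$n_observed, theta = s$theta,
         time_unit = s$time_unit),
    class = "survival_estimate"
  )
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf(
    "Survival fit: tau = %.4g %s, t1/2 = %.4g %s (MLE tau = %.4g)\n",
    x$tau, x$time_unit, x$half_life, x$time_unit, x$tau_mle))
  if (isTRUE(x$estimators_disagree)) {
    cat("  note: curve fit and censored MLE disagree by > 2 SE\n")
  }
  invisible(x)
}

#' @export
tidy.survival_estimate <- function(x, ...) {
  tibble(estimator = c("curve_fit", "mle"),
         tau = c(x$tau, x$tau_mle),
         half_life = c(x$half_life, x$half_life_mle),
         time_unit = x$time_unit)
}

#' Evaluate a survival estimate at arbitrary times
#' @param est A `survival_estimate`.
#' @param t Times.
#' @return Empirical survival fractions (right-continuous step function).
#' @export
survival_at <- function(est, t) {
  sf <- stats::stepfun(est$curve$time, c(1, est$curve$survival),
                       right = FALSE)
  sf(t)
}

#' Bootstrap standard error of the half-life
#'
#' Resamples trajectories with replacement, refits the survival curve per
#' resample and takes the standard deviation of the bootstrap half-life
#' distribution as the standard error. Resamples containing no transition
#' cannot be fitted and are redrawn (their number is reported); if they
#' outnumber the valid ones the data are too sparse for the frequentist
#' route and an error recommends the Bayesian estimator.
#'
#' @param data A [transition_data()] tibble.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param estimator `"curve"` (nonlinear fit of the survival curve,
#'   default) or `"mle"` (censored maximum likelihood, theta/n).
#' @return One-row tibble: `half_life`, `se`, `tau`, `se_tau`, `n_boot`,
#'   `n_redrawn`.
#' @export
bootstrap_half_life <- function(data, n_boot = 1000, seed = 1,
                                estimator = c("curve", "mle")) {
  estimator <- rlang::arg_match(estimator)
  data <- validate_transitions(data)
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  est <- survival_curve(data) # also validates >= 1 transition
  n <- nrow(data)
  local_rng(seed)
  taus <- numeric(n_boot)
  redrawn <- 0L
  max_attempts <- 2L * n_boot
  attempts <- 0L
  filled <- 0L
  while (filled < n_boot && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, ]
    if (!any(boot$observed)) {
      redrawn <- redrawn + 1L
      next
    }
    s <- transition_stats(boot)
    tau <- s$theta / s$n_observed
    if (estimator == "curve") {
      tau <- tryCatch(survival_curve(boot)$tau, error = function(e) tau)
    }
    filled <- filled + 1L
    taus[filled] <- tau
  }
  if (filled < n_boot) {
    abort(paste(
      "more than half of the bootstrap resamples contained no transition;",
      "too few events for frequentist estimation -- use rate_posterior()."),
      class = "mdinfer_no_transition_error")
  }
  tibble(
    half_life = est$half_life, se = sd(taus * log(2)),
    tau = est$tau, se_tau = sd(taus),
    n_boot = n_boot, n_redrawn = redrawn,
    time_unit = est$time_unit
  )
}

#' Estimate versus sample size, with scaling exponent
#'
#' Draws, for each requested size, random subsets of the pooled trajectories
#' (without replacement within a subset, independently across resamples),
#' estimates the half-life per subset, and reports the mean and the spread
#' (SD across subsets) per size. A least-squares fit of log SE against log N
#' yields the scaling exponent; for i.i.d. transition data it is -1/2.
#'
#' @param pool A [transition_data()] tibble to subsample from.
#' @param sizes Strictly increasing subset sizes, each `<= nrow(pool)`.
#' @param n_resample Resamples per size (default 200).
#' @param seed Integer seed.
#' @param estimator Passed to the per-subset fit: `"mle"` (default, fast)
#'   or `"curve"`.
#' @return A `sample_size_curve` object: tibble `size`, `estimate`
#'   (half-life), `se`, `degenerate` plus attributes `scaling_exponent`
#'   and `scaling_exponent_se`.
#' @export
rate_vs_sample_size <- function(pool, sizes, n_resample = 200, seed = 1,
                                estimator = c("mle", "curve")) {
  estimator <- rlang::arg_match(estimator)
  pool <- validate_transitions(pool)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L) || any(sizes > nrow(pool))) {
    abort("every size must lie in [1, nrow(pool)].",
          class = "mdinfer_input_error")
  }
  n_resample <- check_count(n_resample, "n_resample")
  local_rng(seed)
  rows <- purrr::map(sizes, function(sz) {
    ests <- purrr::map_dbl(seq_len(n_resample), function(r) {
      idx <- sample.int(nrow(pool), sz, replace = FALSE)
      sub <- pool[idx, ]
      s <- transition_stats(sub)
      if (s$n_observed == 0L) return(NA_real_)
      tau <- s$theta / s$n_observed
      if (estimator == "curve") {
        tau <- tryCatch(survival_curve(sub)$tau, error = function(e) tau)
      }
      tau * log(2)
    })
    ests <- ests[!is.na(ests)]
    degenerate <- sz == nrow(pool) || length(ests) < 2L
    tibble(size = sz,
           estimate = mean(ests),
           se = if (degenerate && sz == nrow(pool)) 0 else sd(ests),
           n_valid = length(ests),
           degenerate = degenerate)
  })
  curve <- dplyr::bind_rows(rows)
  ok <- !curve$degenerate & curve$se > 0
  expo <- expo_se <- NA_real_
  if (sum(ok) >= 2L) {
    fit <- lm(log(se) ~ log(size), data = curve[ok, ])
    expo <- unname(coef(fit)[2])
    expo_se <- summary(fit)$coefficients[2, 2]
  }
  structure(curve,
            scaling_exponent = expo,
            scaling_exponent_se = expo_se,
            estimand = "half_life",
            class = c("sample_size_curve", class(curve)))
}

#' Scaling exponent of a sample-size curve
#' @param curve A `sample_size_curve`.
#' @return The fitted log-log slope of SE versus N.
#' @export
scaling_exponent <- function(curve) attr(curve, "scaling_exponent")

#' Probabilities of single-repeat conclusions
#'
#' Given, per condition (e.g. simulation box size), the number of
#' trajectories that transitioned out of the total, enumerates every
#' transition/no-transition pattern that a design with a single trajectory
#' per condition could produce, and its probability under independent
#' per-condition Bernoulli draws. With `pooled = TRUE` every condition uses
#' the common pooled frequency `sum(n) / sum(N)` (the "same probability in
#' every box" null); otherwise each uses its empirical `n_b / N_b`.
#'
#' @param counts Tibble/data frame with columns `condition`,
#'   `n_transitioned`, `n_total`.
#' @param pooled Use the pooled transition probability for every condition?
#' @return Tibble with one logical column per condition, a `pattern`
#'   string, and `probability` (summing to 1).
#' @export
#' @examples
#' cnt <- tibble::tibble(condition = c("9nm", "12nm", "15nm"),
#'                       n_transitioned = c(12, 5, 9),
#'                       n_total = c(21, 11, 21))
#' conclusion_probabilities(cnt)
conclusion_probabilities <- function(counts, pooled = FALSE) {
  req <- c("condition", "n_transitioned", "n_total")
  if (!is.data.frame(counts) || !all(req %in% names(counts)) ||
      nrow(counts) < 1L) {
    abort("`counts` needs columns condition, n_transitioned, n_total.",
          class = "mdinfer_input_error")
  }
  if (any(counts$n_total < 1L)) {
    abort("every condition needs n_total >= 1.",
          class = "mdinfer_input_error")
  }
  if (any(counts$n_transitioned < 0) ||
      any(counts$n_transitioned > counts$n_total)) {
    abort("n_transitioned must lie in [0, n_total].",
          class = "mdinfer_input_error")
  }
  p <- if (pooled) {
    rep(sum(counts$n_transitioned) / sum(counts$n_total), nrow(counts))
  } else {
    counts$n_transitioned / counts$n_total
  }
  b <- nrow(counts)
  grid <- do.call(expand.grid, c(rep(list(c(FALSE, TRUE)), b),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- as.character(counts$condition)
  prob <- apply(grid, 1L, function(pat) {
    prod(ifelse(as.logical(pat), p, 1 - p))
  })
  out <- as_tibble(grid)
  out$pattern <- apply(grid, 1L, function(pat) {
    paste(ifelse(as.logical(pat), "transition", "no-transition"),
          collapse = "/")
  })
  out$probability <- prob
  dplyr::arrange(out, dplyr::desc(.data$probability))
}
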