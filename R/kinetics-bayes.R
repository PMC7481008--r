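# Bayesian single-exponential rate inference and model comparison.
#
# For n observed transitions in total exposure time Theta (event times of
# transitioning trajectories plus full lengths of censored ones), the
# likelihood is l(k) = k^n exp(-k Theta). Under a uniform prior the
# posterior is Gamma(n + 1, Theta); under the scale-invariant Jeffreys
# prior (propto 1/k) it is Gamma(n, Theta), proper only for n >= 1.

#' Sufficient statistics of censored transition data
#'
#' Reduces a set of per-trajectory outcomes to the pair that fully
#' determines the single-exponential likelihood: the number of observed
#' transitions `n` and the total exposure time `theta` (sum of event times
#' of transitioning trajectories plus full lengths of the censored ones).
#'
#' @param data A [transition_data()] tibble.
#' @return One-row tibble: `n_observed`, `n_total`, `theta`, `time_unit`.
#' @export
#' @examples
#' d <- transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1))
#' transition_stats(d) # n = 1, theta = 1.466
transition_stats <- function(data) {
  data <- validate_transitions(data)
  theta <- sum(data$event_time[data$observed]) +
    sum(data$total_time[!data$observed])
  tibble(
    n_observed = sum(data$observed),
    n_total = nrow(data),
    theta = theta,
    time_unit = time_unit(data)
  )
}

# accept either a transition_data tibble or a plain data frame with the
# required columns
validate_transitions <- function(data) {
  if (inherits(data, "transition_data")) return(data)
  req <- c("observed", "total_time")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort("expected a transition_data tibble (columns observed, event_time, total_time).",
          class = "mdinfer_input_error")
  }
  et <- if ("event_time" %in% names(data)) data$event_time else
    rep(NA_real_, nrow(data))
  transition_data(as.logical(data$observed), et, data$total_time,
                  unit = attr(data, "time_unit") %||% "us")
}

#' Posterior distribution of a transition rate
#'
#' Closed-form Gamma posterior for the rate of a single-exponential process
#' observed through censored trajectories. `prior = "uniform"` yields
#' Gamma(n + 1, theta) with mean (n+1)/theta and variance (n+1)/theta^2; it
#' is proper even when no transition was observed. `prior = "jeffreys"`
#' yields Gamma(n, theta) with mean n/theta and variance n/theta^2 and
#' requires at least one observed transition.
#'
#' @param data A [transition_data()] tibble.
#' @param prior `"uniform"` (default) or `"jeffreys"`.
#' @return A `rate_posterior` object.
#' @export
#' @examples
#' d <- transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1))
#' p <- rate_posterior(d, "uniform")
#' tidy(p)
rate_posterior <- function(data, prior = c("uniform", "jeffreys")) {
  prior <- rlang::arg_match(prior)
  s <- transition_stats(data)
  if (prior == "jeffreys" && s$n_observed < 1L) {
    abort(paste(
      "the Jeffreys prior is only applicable when at least one barrier",
      "crossing event is observed; use the uniform prior for n = 0."),
      class = "mdinfer_jeffreys_error")
  }
  structure(
    list(prior = prior,
         n = s$n_observed,
         theta = s$theta,
         shape = if (prior == "uniform") s$n_observed + 1 else s$n_observed,
         time_unit = s$time_unit),
    class = "rate_posterior"
  )
}

#' @export
print.rate_posterior <- function(x, ...) {
  ci <- credible_interval(x)
  cat(sprintf(
    "Rate posterior (%s prior): Gamma(shape = %g, rate = %g %s)\n",
    x$prior, x$shape, x$theta, x$time_unit))
  cat(sprintf("  mean %.4g 1/%s, sd %.4g, 95%% CI [%.4g, %.4g]\n",
              posterior_mean(x), x$time_unit, sqrt(posterior_var(x)),
              ci$low, ci$high))
  invisible(x)
}

#' Posterior mean and variance of the rate
#' @param post A `rate_posterior`.
#' @return Numeric scalar (1/time unit, or its square).
#' @export
posterior_mean <- function(post) post$shape / post$theta

#' @rdname posterior_mean
#' @export
posterior_var <- function(post) post$shape / post$theta^2

#' Posterior density over a rate grid
#' @param post A `rate_posterior`.
#' @param k Numeric vector of rates.
#' @return Density values.
#' @export
posterior_density <- function(post, k) dgamma(k, post$shape, rate = post$theta)

#' Credible interval for the transition rate
#'
#' Central equal-tailed interval of the Gamma posterior (the
#' highest-posterior-density alternative is available via
#' `type = "hpd"`, computed by numerical optimisation of the interval
#' endpoints).
#'
#' @param post A `rate_posterior`.
#' @param level Credibility level in (0, 1); default 0.95.
#' @param type `"central"` (default) or `"hpd"`.
#' @return One-row tibble `level`, `low`, `high`.
#' @export
credible_interval <- function(post, level = 0.95,
                              type = c("central", "hpd")) {
  type <- rlang::arg_match(type)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must lie strictly between 0 and 1.",
          class = "mdinfer_input_error")
  }
  if (type == "central") {
    a <- (1 - level) / 2
    lo <- qgamma(a, post$shape, rate = post$theta)
    hi <- qgamma(1 - a, post$shape, rate = post$theta)
  } else {
    # shortest interval containing `level` mass
    f <- function(a) {
      qgamma(a + level, post$shape, rate = post$theta) -
        qgamma(a, post$shape, rate = post$theta)
    }
    a <- optimize(f, c(0, 1 - level))$minimum
    lo <- qgamma(a, post$shape, rate = post$theta)
    hi <- qgamma(a + level, post$shape, rate = post$theta)
  }
  tibble(level = level, low = lo, high = hi)
}

#' @export
tidy.rate_posterior <- function(x, level = 0.95, ...) {
  ci <- credible_interval(x, level)
  tibble(
    prior = x$prior,
    n_observed = x$n,
    theta = x$theta,
    mean = posterior_mean(x),
    variance = posterior_var(x),
    low = ci$low, high = ci$high, level = level,
    time_unit = x$time_unit
  )
}

#' @export
glance.rate_posterior <- function(x, ...) {
  tibble(prior = x$prior, shape = x$shape, rate = x$theta,
         mean = posterior_mean(x), sd = sqrt(posterior_var(x)))
}

#' Bayes factor: one rate process versus two
#'
#' Odds ratio comparing the hypothesis that two transition datasets were
#' generated by two distinct single-exponential processes against a single
#' common process. With per-dataset sufficient statistics (n1, theta1),
#' (n2, theta2) and pooled n = n1 + n2, theta = theta1 + theta2, the odds
#' favouring two processes are
#' \deqn{\frac{2}{\pi}\,\frac{n/\Theta}{n_1^2/\Theta_1^2 + n_2^2/\Theta_2^2}
#'   \,\frac{n_1!\,n_2!}{n!}\,
#'   \frac{\Theta^{n+1}}{\Theta_1^{n_1+1}\Theta_2^{n_2+1}}}
#' evaluated in log space (log-Gamma for the factorials). The expression is
#' symmetric in the two datasets; datasets with zero observed transitions on
#' one side are supported (uniform-prior branch), but at least one
#' transition must be observed overall.
#'
#' @param data_a,data_b [transition_data()] tibbles in the same time unit.
#' @return A `bayes_factor` object with elements `odds`, `log_odds`,
#'   `label` and the per-dataset and pooled sufficient statistics.
#' @export
#' @examples
#' a <- transition_data(TRUE, 0.466, 1)
#' b <- transition_data(FALSE, NA, 1)
#' bayes_factor(a, b) # odds ~ 0.93, "barely worth mentioning"
bayes_factor <- function(data_a, data_b) {
  sa <- transition_stats(data_a)
  sb <- transition_stats(data_b)
  if (!identical(sa$time_unit, sb$time_unit)) {
    abort("the two datasets declare different time units; convert first.",
          class = "mdinfer_input_error")
  }
  n1 <- sa$n_observed; t1 <- sa$theta
  n2 <- sb$n_observed; t2 <- sb$theta
  n <- n1 + n2; tt <- t1 + t2
  if (n < 1L) {
    abort("at least one observed transition is required across the two datasets.",
          class = "mdinfer_input_error")
  }
  # log of n1^2/t1^2 + n2^2/t2^2 via logsumexp (terms with n_i = 0 drop out)
  terms <- c(if (n1 > 0) 2 * (log(n1) - log(t1)),
             if (n2 > 0) 2 * (log(n2) - log(t2)))
  log_odds <- log(2 / pi) + log(n) - log(tt) - logsumexp(terms) +
    lfactorial(n1) + lfactorial(n2) - lfactorial(n) +
    (n + 1) * log(tt) - (n1 + 1) * log(t1) - (n2 + 1) * log(t2)
  odds <- exp(log_odds)
  structure(
    list(odds = odds, log_odds = log_odds,
         label = interpret_bayes_factor(odds),
         data_a = sa, data_b = sb,
         pooled = tibble(n_observed = n, theta = tt)),
    class = "bayes_factor"
  )
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Odds favouring two processes: %.3g (%s)\n", x$odds, x$label))
  cat(sprintf("  A: n = %d, theta = %g; B: n = %d, theta = %g %s\n",
              x$data_a$n_observed, x$data_a$theta,
              x$data_b$n_observed, x$data_b$theta, x$data_a$time_unit))
  invisible(x)
}

#' @export
tidy.bayes_factor <- function(x, ...) {
  tibble(
    odds = x$odds, log_odds = x$log_odds, label = x$label,
    n1 = x$data_a$n_observed, theta1 = x$data_a$theta,
    n2 = x$data_b$n_observed, theta2 = x$data_b$theta,
    n_pooled = x$pooled$n_observed, theta_pooled = x$pooled$theta
  )
}

#' Jeffreys-style interpretation of a Bayes factor
#'
#' Verbal scale for the odds favouring two distinct rate processes:
#' below 1/3 is substantial evidence that one process generated both
#' datasets, above 3 is substantial evidence for two processes, and the
#' band between is "barely worth mentioning".
#'
#' @param odds Positive odds ratio.
#' @return Character label.
#' @export
#' @examples
#' interpret_bayes_factor(0.26)
interpret_bayes_factor <- function(odds) {
  if (!is.numeric(odds) || length(odds) != 1L || is.na(odds) || odds <= 0) {
    abort("`odds` must be a single positive number.",
          class = "mdinfer_input_error")
  }
  if (odds < 1 / 3) "substantial evidence for one process"
  else if (odds <= 3) "barely worth mentioning"
  else "substantial evidence for two processes"
}
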