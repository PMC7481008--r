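# Free energies: Crooks/Bennett MLE, multistate reweighting, convergence
# with data fraction, autocorrelation, replicate statistics.

test_that("Crooks MLE solves the consistent-delta and midpoint cases", {
  # all forward = 2, all reverse = -2: dG = 2 exactly
  ws <- work_set(rep(2, 10), rep(-2, 10))
  expect_equal(crooks_mle_dg(ws, n_boot = 0)$dg, 2, tolerance = 1e-8)

  # equal-width equal-n Gaussians: dG at the midpoint of the two means
  # (brute-force check of the Crooks crossing symmetry)
  withr::with_seed(41, {
    wf <- rnorm(4000, 6, 1.5)
    wr <- rnorm(4000, -4, 1.5)
  })
  # impose exact sample symmetry: negated reverse = mirror of forward
  mid <- (mean(wf) - mean(wr)) / 2
  ws2 <- work_set(wf, -(2 * mid - wf))
  expect_equal(crooks_mle_dg(ws2, n_boot = 0)$dg, mid, tolerance = 1e-6)

  # parameter recovery on Crooks-consistent Gaussians
  ws3 <- gen_gaussian_work(5, 2, 500, 500, seed = 42)
  est <- crooks_mle_dg(ws3, n_boot = 200, seed = 1)
  expect_lt(abs(est$dg - 5), 3 * est$se)

  # antisymmetry under direction swap
  swapped <- work_set(ws3$work[ws3$direction == "reverse"],
                      ws3$work[ws3$direction == "forward"])
  expect_equal(crooks_mle_dg(swapped, n_boot = 0)$dg,
               -crooks_mle_dg(ws3, n_boot = 0)$dg, tolerance = 1e-8)

  # non-overlapping work distributions are flagged
  expect_warning(
    far <- crooks_mle_dg(work_set(rep(200, 5), rep(200, 5)), n_boot = 0),
    "overlap")
  expect_true(far$overlap_warning)

  expect_error(crooks_mle_dg(work_set(numeric(0), 1)),
               class = "mdinfer_input_error")
})

test_that("multistate reweighting recovers the generating potential", {
  wins <- small_double_well_windows()
  prof <- mbar_pmf(wins)
  expect_lt(attr(prof, "residual"), 1e-8)
  expect_equal(min(prof$dg, na.rm = TRUE), 0)

  truth <- double_well(5)$potential(prof$x)
  sel <- prof$n_samples > 100 & abs(prof$x) <= 1.4
  rmsd <- sqrt(mean((prof$dg[sel] - (truth[sel] - min(truth[sel])))^2))
  expect_lt(rmsd, 0.3)

  # flat potential: restrained interior flat within per-bin uncertainties
  flat_wins <- gen_umbrella_samples(double_well(0),
                                    seq(-1, 1, length.out = 6), 10, 6000,
                                    seed = 43)
  pf <- mbar_pmf(flat_wins, bins = seq(-1, 1, length.out = 11))
  wm <- sum(pf$dg / pf$se^2) / sum(1 / pf$se^2)
  expect_true(all(abs(pf$dg - wm) < 2 * pf$se))

  # single unrestrained window reduces to -kt ln(histogram)
  withr::with_seed(44, x <- rnorm(20000))
  w1 <- list(umbrella_window(x, 0, 1e-9))
  p1 <- mbar_pmf(w1, bins = 20)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 21), plot = FALSE)
  ref <- -log(h$counts / sum(h$counts))
  ref <- ref - min(ref[is.finite(ref)])
  ok <- h$counts > 0
  expect_equal(p1$dg[ok], ref[ok], tolerance = 1e-6)

  # periodic coordinates: bias wraps across the boundary, so samples at
  # +pi and a window centered at -pi are treated as adjacent
  withr::with_seed(52, xp <- c(rnorm(4000, pi - 0.05, 0.15),
                               rnorm(4000, -pi + 0.05, 0.15)))
  xp <- (xp + pi) %% (2 * pi) - pi
  wp <- list(umbrella_window(xp[1:4000], pi - 0.05, 20),
             umbrella_window(xp[4001:8000], -pi + 0.05, 20))
  pp <- mbar_pmf(wp, periodic = TRUE, period = 2 * pi, bins = 20)
  fgap <- abs(diff(attr(pp, "window_f")))
  expect_lt(fgap, 0.5) # symmetric windows across the seam agree

  # non-overlapping adjacent windows raise an error naming the gap
  wa <- umbrella_window(rnorm(100, -2, 0.05), -2, 50)
  wb <- umbrella_window(rnorm(100, 2, 0.05), 2, 50)
  expect_error(mbar_pmf(list(wa, wb)), "overlap",
               class = "mdinfer_overlap_error")

  # discard_fraction removes leading equilibration samples
  w_burn <- umbrella_window(c(rep(100, 500), rnorm(4500)), 0, 1e-9,
                            discard_fraction = 0.1)
  p_burn <- mbar_pmf(list(w_burn), bins = 10)
  expect_lt(max(abs(p_burn$x)), 10) # the burn-in spike never enters
})

test_that("profile convergence tightens with data fraction", {
  wins <- small_double_well_windows(n_samples = 10000, seed = 45)
  profs <- profile_convergence(wins, fractions = c(0.05, 1), n_rep = 5)

  # fraction 1 reproduces the full estimate exactly
  full <- mbar_pmf(wins)
  expect_equal(profs[["1"]]$dg, full$dg, tolerance = 1e-10)

  # SE at the small fraction exceeds SE at the full fraction
  ok <- is.finite(profs[["0.05"]]$se) & is.finite(profs[["1"]]$se) &
    profs[["1"]]$n_samples > 100
  expect_gt(mean(profs[["0.05"]]$se[ok]), mean(profs[["1"]]$se[ok]))
  expect_true(mean(profs[["0.05"]]$se[ok] >= profs[["1"]]$se[ok]) > 0.8)

  # replicate disagreement shrinks with fraction
  spread <- vapply(profs, function(p) {
    reps <- attr(p, "replicates")
    mean(apply(reps, 1, sd), na.rm = TRUE)
  }, numeric(1))
  expect_lt(spread[["1"]], spread[["0.05"]])

  expect_error(profile_convergence(wins, fractions = 1e-5),
               class = "mdinfer_input_error")
})

test_that("ACF analysis matches AR(1) theory", {
  x <- gen_ar1(0.9, 1, 1e5, seed = 46)
  res <- acf_analysis(x, max_lag = 200)
  rho <- res$table$acf[res$table$lag %in% 1:20]
  expect_equal(rho, 0.9^(1:20), tolerance = 0.08)
  expect_equal(res$inefficiency, 19, tolerance = 0.15 * 19)

  # subsampling every g-th point nearly decorrelates the series: the
  # residual lag-1 correlation is phi^g = 0.9^19 ~ 0.135
  g <- ceiling(res$inefficiency)
  sub <- x[seq(1, length(x), by = g)]
  r1 <- acf(sub, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.9^g + 4 / sqrt(length(sub)))
  expect_lt(abs(r1), 0.25) # vastly below the unsubsampled rho(1) = 0.9

  # white noise: all rho(tau >= 1) ~ 0
  wn <- gen_ar1(0, 1, 1e5, seed = 47)
  rw <- acf_analysis(wn, max_lag = 50)
  expect_true(all(abs(rw$table$acf[-1]) < 3 / sqrt(1e5) * 1.5))
  expect_equal(rw$table$acf[1], 1)

  expect_error(acf_analysis(rep(1, 1000)), "constant",
               class = "mdinfer_input_error")
  expect_error(acf_analysis(rnorm(10), max_lag = 5),
               class = "mdinfer_input_error")
})

test_that("replicate statistics give t-based CIs with nominal behaviour", {
  r <- replicate_statistics(c(1, 1, 1, 1))
  expect_equal(r$mean, 1)
  expect_equal(r$se, 0)
  expect_equal(c(r$low, r$high), c(1, 1))

  expect_error(replicate_statistics(3.2), "N = 1",
               class = "mdinfer_n1_error")

  # coverage ~ 95% over 1000 simulations of 20 Normal(-10, 1) draws
  withr::with_seed(48, {
    hits <- vapply(1:1000, function(i) {
      v <- rnorm(20, -10, 1)
      ci <- replicate_statistics(v)
      ci$low <= -10 && -10 <= ci$high
    }, logical(1))
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)

  # halving n_rep widens the CI by ~ sqrt(2) (large n)
  v <- gen_replicate_dg(0, 1, 400, seed = 49)
  w_full <- as.numeric(diff(unlist(replicate_statistics(v)[c("low", "high")])))
  w_half <- as.numeric(diff(unlist(replicate_statistics(v[1:200])[c("low", "high")])))
  expect_equal(w_half / w_full, sqrt(2), tolerance = 0.25)

  # normal-quantile variant is narrower at small n
  v3 <- c(-1, 0, 1)
  wt <- replicate_statistics(v3, quantile = "t")
  wn <- replicate_statistics(v3, quantile = "normal")
  expect_lt(wn$high - wn$low, wt$high - wt$low)
})

test_that("trend significance guards against anecdotal conclusions", {
  expect_error(trend_significance(
    data.frame(condition = c("a", "b"), value = c(1, 2))),
    "N = 1", class = "mdinfer_n1_error")

  # null: identical distributions across 6 conditions rarely flag a trend
  withr::with_seed(50, {
    flags <- vapply(1:200, function(i) {
      df <- data.frame(condition = rep(paste0("c", 1:6), each = 20),
                       value = rnorm(120))
      trend_significance(df)$trend_significant
    }, logical(1))
  })
  expect_lt(mean(flags), 0.10)

  # power: slope of 3 SE per condition is detected most of the time
  withr::with_seed(51, {
    hits <- vapply(1:100, function(i) {
      se_cond <- 1 / sqrt(20)
      df <- data.frame(
        condition = rep(paste0("c", 1:6), each = 20),
        value = rnorm(120) + rep(3 * se_cond * (1:6), each = 20))
      trend_significance(df)$trend_significant
    }, logical(1))
  })
  expect_gt(mean(hits), 0.8)
})
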