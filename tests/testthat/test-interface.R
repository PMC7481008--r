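# File formats and pipeline orchestration: lossless round-trips, row-level
# validation with informative errors, deterministic reports.

test_that("transitions CSV round-trips losslessly and computes Eq-style sums", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  d <- transition_data(c(TRUE, FALSE), c(0.466, NA), c(1, 1), unit = "us")
  write_transitions(d, tmp)
  back <- read_transitions(tmp)
  s <- transition_stats(back)
  expect_equal(s$n_observed, 1)
  expect_equal(s$theta, 1.466)
  expect_equal(time_unit(back), "us")
  expect_equal(back$event_time, d$event_time)

  big <- gen_transition_data(2, 200, 1, seed = 71)
  write_transitions(big, tmp)
  back <- read_transitions(tmp)
  expect_equal(back$observed, big$observed)
  expect_equal(back$event_time, big$event_time)
  expect_equal(back$total_time, big$total_time)
})

test_that("transitions reader rejects malformed rows with row numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("trajectory_id,observed,event_time,total_time,unit"), tmp)
  expect_error(read_transitions(tmp), class = "mdinfer_input_error")

  writeLines(c("trajectory_id,observed,event_time,total_time,unit",
               "1,TRUE,,1,us"), tmp)
  expect_error(read_transitions(tmp), "rows 1",
               class = "mdinfer_input_error")

  writeLines(c("trajectory_id,observed,event_time,total_time,unit",
               "1,TRUE,2.5,1,us"), tmp)
  expect_error(read_transitions(tmp), "exceeds",
               class = "mdinfer_input_error")

  writeLines(c("trajectory_id,observed,event_time,total_time,unit",
               "1,TRUE,0.5,1,us", "1,FALSE,,1,us"), tmp)
  expect_warning(dd <- read_transitions(tmp), "duplicated")
  expect_equal(nrow(dd), 2)
})

test_that("work, series, window and position formats round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ws <- gen_gaussian_work(5, 2, 20, 15, seed = 72)
  write_works(ws, tmp)
  back <- read_works(tmp, temperature = 298)
  expect_equal(back$work, ws$work)
  expect_equal(sum(back$direction == "reverse"), 15)

  # xvg-style series with comment lines
  stmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "@ xaxis label", "0 1.5", "1 2.5"), stmp)
  s <- read_series(stmp)
  expect_equal(s$value, c(1.5, 2.5))
  write_series(s, stmp, comment = "round trip")
  expect_equal(read_series(stmp)$value, c(1.5, 2.5))

  wdir <- withr::local_tempdir()
  wins <- gen_umbrella_samples(double_well(1), c(-0.5, 0.5), 5, 200,
                               seed = 73)
  man <- write_windows(wins, wdir)
  back <- read_windows(man)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$samples, wins[[1]]$samples)
  expect_equal(back[[2]]$center, 0.5)
  expect_equal(back[[1]]$force_constant, 5)

  ptmp <- withr::local_tempfile(fileext = ".csv")
  pos <- gen_brownian_box(0.1, 10, 3, 20, 1, seed = 74)
  write_positions(pos, ptmp)
  pback <- read_positions(ptmp, l_box = 10, dt = 1)
  expect_equal(pback$xu, pos$xu)
})

test_that("pipeline validates configs before computing", {
  expect_error(validate_config(list(stages = "rates_bayes", typo = 1)),
               "unknown configuration keys", class = "mdinfer_input_error")
  expect_error(validate_config(list(stages = "nonsense")),
               "unknown stages", class = "mdinfer_input_error")
  expect_error(validate_config(list()), class = "mdinfer_input_error")
  cfg <- validate_config(list(rates_bayes = list(prior = "uniform")))
  expect_equal(cfg$stages, "rates_bayes")
  expect_equal(cfg$seed, 1)
})

test_that("pipeline produces a deterministic machine-readable report", {
  dir <- withr::local_tempdir()
  # the single-repeat anchor comparison: one transition at 0.466 us vs one
  # censored 1-us trajectory
  tfile <- file.path(dir, "transitions.csv")
  write_transitions(transition_data(TRUE, 0.466, 1), tfile)
  cfile <- file.path(dir, "compare.csv")
  write_transitions(transition_data(FALSE, NA, 1), cfile)

  cfg <- list(
    stages = "rates_bayes",
    seed = 5,
    rates_bayes = list(transitions = tfile, prior = "both",
                       compare = cfile)
  )
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  b <- run_pipeline(cfg, out_dir = out1)
  run_pipeline(cfg, out_dir = out2)

  rep1 <- jsonlite::read_json(file.path(out1, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(rep1$seed, 5)
  post <- rep1$stages$rates_bayes$posterior
  expect_equal(post$n_observed, c(1, 1))
  expect_equal(post$theta, c(0.466, 0.466))
  expect_equal(post$mean[post$prior == "uniform"], 2 / 0.466)
  expect_equal(post$mean[post$prior == "jeffreys"], 1 / 0.466)
  expect_true(all(c("low", "high") %in% names(post)))
  expect_equal(rep1$stages$rates_bayes$bayes_factor$odds, 0.93,
               tolerance = 0.01)

  # byte-identical across runs with the same config and seed
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))

  # a failing stage names itself
  bad <- list(stages = "dg_neq", dg_neq = list(works = "/no/such.csv"))
  expect_error(run_pipeline(bad), "dg_neq",
               class = "mdinfer_stage_error")
})

test_that("pipeline runs the frequentist, work and diagnostic stages", {
  dir <- withr::local_tempdir()
  tfile <- file.path(dir, "transitions.csv")
  write_transitions(gen_transition_data(2, 100, 1, seed = 75), tfile)
  wfile <- file.path(dir, "works.csv")
  write_works(gen_gaussian_work(5, 2, 100, 100, seed = 76), wfile)

  cfg <- list(
    stages = c("rates_freq", "dg_neq", "acf", "replicates"),
    seed = 7,
    rates_freq = list(transitions = tfile, n_boot = 50),
    dg_neq = list(works = wfile, n_boot = 50, temperature = 298),
    acf = list(series = gen_ar1(0.8, 1, 5000, seed = 77)),
    replicates = list(values = gen_replicate_dg(-10, 1, 20, seed = 78))
  )
  b <- run_pipeline(cfg)
  expect_equal(b$stages$dg_neq$dg, 5, tolerance = 0.5)
  expect_gt(b$stages$acf$inefficiency, 4)
  expect_lt(abs(b$stages$replicates$mean + 10), 1)
  expect_gt(b$stages$rates_freq$half_life$half_life, 0)
})
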