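test_that("all presets load, validate, and are listed", {
  tab <- list_scenarios()
  expect_equal(nrow(tab), 9)
  for (nm in tab$name) {
    sc <- load_scenario(nm)
    expect_s3_class(sc, "ws_scenario")
    expect_identical(sc$name, nm)
  }
  # regime aliases resolve to their presets
  expect_identical(load_scenario("long_lived_high_Fc")$name, "fig5C")
  expect_identical(load_scenario("low_Fc_elastic")$name, "fig5G")
  expect_error(load_scenario("fig9Z"), class = "wallsense_unknown_scenario")
})

test_that("scenario validation rejects unknown and missing keys", {
  sc <- unclass(load_scenario("fig4D"))
  bad <- c(sc, list(mystery = 1))
  expect_error(as_scenario(bad), class = "wallsense_bad_scenario")
  sc$wall <- NULL
  expect_error(as_scenario(sc), class = "wallsense_bad_scenario")
})

test_that("scenarios round-trip through YAML and JSON configs", {
  for (nm in c("fig4E", "fig5C", "fig5E")) { # includes an F_c = Inf preset
    sc <- load_scenario(nm)
    for (ext in c(".yaml", ".json")) {
      path <- withr::local_tempfile(fileext = ext)
      write_scenario(sc, path)
      back <- load_scenario(path)
      expect_equal(unclass(back), unclass(sc), tolerance = 1e-12)
    }
  }
})

test_that("running the matched-time preset reproduces the overlap law", {
  tr <- run_scenario("fig4D")
  s <- summarize_trace(tr)
  expect_lt(max(abs(tr$output - tr$input)[tr$time > 5]), 0.02)
  expect_equal(s$steady_pre, 1, tolerance = 0.01)
})

test_that("trace summaries count extrema by prominence", {
  g <- make_grid(0, 10, 500)
  flat <- tibble::tibble(time = g$time, output = rep(2, 501))
  s <- summarize_trace(flat)
  expect_equal(s$n_peaks, 0)
  expect_equal(s$n_dips, 0)
  expect_equal(s$steady_pre, s$steady_post)

  bump <- tibble::tibble(
    time = g$time,
    output = 1 + exp(-((g$time - 5) / 0.8)^2)
  )
  s2 <- summarize_trace(bump)
  expect_equal(s2$n_peaks, 1)
  expect_equal(s2$peak_times[[1]], 5, tolerance = 0.05)
  expect_error(
    summarize_trace(tibble::tibble(time = 1:10, output = 1:10)),
    class = "wallsense_short_trace"
  )
})

test_that("peak finding reports topographic prominence", {
  # two bumps of known prominence on a shared shoulder
  x <- c(0, 1, 2, 3, 2.5, 2.8, 1, 0)
  p <- find_peaks(x)
  expect_equal(p$index, c(4, 6))
  expect_equal(p$value, c(3, 2.8))
  expect_equal(p$prominence, c(3, 0.3)) # second peak rises 0.3 above the saddle
  # threshold filters the minor peak
  expect_equal(find_peaks(x, min_prominence = 0.5)$index, 4)
  # plateau peaks are counted once
  expect_equal(nrow(find_peaks(c(0, 1, 1, 1, 0))), 1)
  expect_equal(nrow(find_peaks(c(1, 1, 1))), 0)
})

test_that("response FWHM recovers the width of a known pulse", {
  g <- make_grid(0, 20, 2000)
  y <- 0.5 + exp(-4 * log(2) * ((g$time - 10) / 1.5)^2)
  expect_equal(response_fwhm(g$time, y), 1.5, tolerance = 0.02)
})

test_that("outputs serialize with a checksummed manifest and round-trip", {
  out_dir <- withr::local_tempdir()
  tr <- run_scenario("fig4E")
  s <- summarize_trace(tr)
  man <- write_outputs(
    list(trace = tr, summary = s), out_dir,
    manifest_extra = list(scenario = "fig4E")
  )
  expect_true(file.exists(file.path(out_dir, "trace.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_equal(length(man$files), 2)
  back <- read_trace_csv(file.path(out_dir, "trace.csv"))
  expect_equal(back$output_normalized, tr$output, tolerance = 1e-15)
  expect_equal(back$input_normalized, tr$input, tolerance = 1e-15)
  # an empty result set still yields a valid manifest
  empty_dir <- withr::local_tempdir()
  man0 <- write_outputs(list(), empty_dir)
  expect_equal(length(man0$files), 0)
  expect_true(file.exists(file.path(empty_dir, "manifest.json")))
})

test_that("identical scenario and seed give byte-identical trace files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sc <- load_scenario("fig5F")
  sc$grid$n_steps <- 1000 # keep the reproducibility check quick
  sc <- as_scenario(unclass(sc))
  for (d in c(d1, d2)) {
    tr <- run_scenario(sc, seed = 3, with_ensemble = TRUE, n_sensors = 100)
    write_outputs(
      list(
        trace = tr,
        ensemble = attr(tr, "ensemble")
      ),
      d
    )
  }
  for (f in c("trace.csv", "ensemble_events.jsonl")) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f)))
    )
  }
})

test_that("population traces export the normalized column dialect", {
  sc <- load_scenario("fig5D")
  sc$grid$n_steps <- 1500
  tr <- run_scenario(as_scenario(unclass(sc)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_true(all(c(
    "time_over_tauc", "input_norm", "detach_force_over_F0",
    "rate_times_tauc"
  ) %in% names(back)))
  expect_equal(back$rate_times_tauc, tr$rate_norm, tolerance = 1e-15)
  meta <- attr(back, "metadata")
  expect_equal(meta$F_0, 0.01)
})

test_that("tidy and glance methods expose traces and ensembles", {
  tr <- run_scenario("fig4E")
  td <- generics::tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "input", "output") %in% names(td)))
  gl <- generics::glance(tr)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_peaks, 1)

  wall <- default_wall()
  input <- constant_signal(0, "strain_rate", t1 = 5, n = 500)
  ens <- simulate_ensemble(input, wall, default_seg(wall), default_law(),
    n_sensors = 100, seed = 2
  )
  expect_equal(nrow(generics::glance(ens)), 1)
  expect_identical(generics::tidy(ens), ens$events)
})

test_that("autoplot methods return ggplot objects", {
  tr <- run_scenario("fig4E")
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
  g <- make_grid(0, 5, 100)
  sig <- ws_signal(g$time, sin(g$time), "stress")
  expect_s3_class(ggplot2::autoplot(sig), "ggplot")
})

test_that("the command-line entry point parses cleanly", {
  cli <- system.file("scripts", "wallsense-cli.R", package = "wallsense")
  expect_true(nzchar(cli))
  expect_silent(parse(cli))
})
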