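test_that("mini end-to-end run produces sane metrics quickly", {
  sim <- cached("mini_run", {
    cryo_simulate(probes = probe_spec(Dp = 5, Lp = 22, tip_center = c(2.5, 0, -47.5)),
                  h = 5, V = 0.2, end_time = 60, dt_scale = 10,
                  metric_interval = 5)
  })
  m <- sim$metrics
  expect_equal(m$time[1], 0)
  expect_equal(m$iceball_volume[1], 0)          # end time 0: no ice yet
  expect_equal(m$min_wall_temperature[1], 37)
  expect_true(all(diff(m$time) > 0))
  expect_true(all(m$lethal_volume <= m$iceball_volume + 1e-12))
  # iceball volume is non-decreasing while the probe is active
  expect_true(all(diff(m$iceball_volume) > -1e-9))
  expect_gt(m$iceball_volume[nrow(m)], 0)
  # metric CSV rerun is bit-identical (no randomness anywhere)
  sim2 <- cryo_simulate(probes = probe_spec(Dp = 5, Lp = 22, tip_center = c(2.5, 0, -47.5)),
                        h = 5, V = 0.2, end_time = 60, dt_scale = 10,
                        metric_interval = 5)
  expect_identical(sim$metrics, sim2$metrics)
})

test_that("run_case writes provenance outputs", {
  dir <- withr::local_tempdir()
  cfg <- cryo_config(probes = probe_spec(Dp = 5, Lp = 22, tip_center = c(2.5, 0, -47.5)), h = 5,
                     end_time = 10, dt_scale = 10, metric_interval = 5)
  sim <- run_case(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$config$h, 5)
  expect_equal(js$config$params$D0, 10)
  got <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_equal(got$iceball_volume, sim$metrics$iceball_volume)
})

test_that("a zero freezing horizon yields only the initial metrics", {
  sim <- cryo_simulate(probes = probe_spec(Dp = 5, Lp = 22,
                                           tip_center = c(2.5, 0, -47.5)),
                       h = 5, end_time = 0)
  expect_equal(nrow(sim$metrics), 1)
  expect_equal(sim$metrics$iceball_volume, 0)
  expect_equal(sim$metrics$min_wall_temperature, 37)
  expect_true(is.infinite(sim$treatment_time))
})

test_that("halving the time-step scale barely moves the frozen volumes", {
  base <- cached("mini_run", stop("populated above"))
  fine <- cryo_simulate(probes = probe_spec(Dp = 5, Lp = 22,
                                            tip_center = c(2.5, 0, -47.5)),
                        h = 5, V = 0.2, end_time = 60, dt_scale = 5,
                        metric_interval = 60)
  v1 <- base$metrics$iceball_volume[nrow(base$metrics)]
  v2 <- fine$metrics$iceball_volume[nrow(fine$metrics)]
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("degenerate one-value sweep equals a single run", {
  sw <- run_sweep("Ld", values = 30, end_time = 10, fidelity = "desk",
                  metric_interval = 5)
  expect_equal(nrow(sw), 1)
  single <- cryo_simulate(probes = probe_spec(Ld = 30), h = 2,
                          dt_scale = 10, end_time = 10, metric_interval = 5)
  expect_equal(sw$iceball_volume,
               single$metrics$iceball_volume[nrow(single$metrics)],
               tolerance = 1e-12)
})

test_that("treatment-time table handles the degenerate horizon", {
  tt <- run_table3(Ld_values = c(10, 20), V_values = 0.2, horizon = 0)
  expect_true(all(is.infinite(tt)))
  expect_equal(dim(tt), c(1, 2))
  expect_error(run_table3(Ld_values = numeric(0)), "length")
})

test_that("iceball component counting finds separated and merged regions", {
  lab <- array(cryovessel:::LBL[["TISSUE"]], c(10, 10, 10))
  grid <- cryovessel:::make_grid_raw(lab, 1)
  Tarr <- array(37, c(10, 10, 10))
  Tarr[2:3, 2:3, 2:3] <- -5
  Tarr[7:8, 7:8, 7:8] <- -5
  expect_equal(iceball_components(Tarr, grid), 2L)
  Tarr[3:7, 3, 3] <- -5   # bridge the two
  Tarr[7, 3:7, 3] <- -5
  Tarr[7, 7, 3:7] <- -5
  expect_equal(iceball_components(Tarr, grid), 1L)
  expect_equal(iceball_components(array(37, c(10, 10, 10)), grid), 0L)
})

test_that("configs round-trip through JSON", {
  cfg <- cryo_config(probes = list(probe_spec(Ld = 25),
                                   probe_spec(Dp = 2, Lp = 20,
                                              tip_center = c(0, 0, -70))),
                     h = 2, V = 0.05, end_time = 300, dt_scale = 5,
                     advection_order = 2, fine_until = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$V, 0.05)
  expect_equal(back$h, 2)
  expect_equal(back$fine_until, 60)
  expect_equal(back$params$D1, cfg$params$D1)
  expect_equal(length(back$probes), 2)
  expect_equal(back$probes[[1]]$Ld, 25)
  expect_equal(back$probes[[2]]$tip_center, c(0, 0, -70))
  expect_equal(back$props$Qf, cfg$props$Qf)
})

test_that("the shipped example configuration loads and resolves", {
  path <- system.file("extdata", "single-probe-Ld30.json",
                      package = "cryovessel")
  cfg <- read_config(path)
  expect_s3_class(cfg, "cryo_config")
  expect_equal(cfg$V, 0.2)
  expect_equal(cfg$probes[[1]]$Ld, 30)
  expect_null(cfg$probes[[1]]$tip_center)  # resolved from Ld at build time
  expect_equal(cfg$checkpoint_times, numeric(0))
  geom <- build_geometry(cfg$params, cfg$probes)
  expect_equal(geom$probes[[1]]$tip_center, c(0, 0, -50))
})

test_that("VTK export writes a readable structured-points file", {
  fx <- make_fixture("straight_tube", h = 2)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_grid(fx$grid, path,
                 fields = list(temperature = array(37, fx$grid$dims)))
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_true(any(grepl("^SCALARS label int", lines)))
  expect_true(any(grepl("^SCALARS temperature float", lines)))
  d <- fx$grid$dims
  expect_equal(sum(grepl("DIMENSIONS", lines)), 1)
})

test_that("cryosim methods print and plot", {
  sim <- cached("mini_run", stop("populated above"))
  expect_output(print(sim), "iceball volume")
  expect_output(summary(sim), "Picard")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(sim))
})
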