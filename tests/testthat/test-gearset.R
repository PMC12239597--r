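# Gearset simulator: motor ensemble, belt state machine, event log.

test_that("motor ensemble honours the stationary two-state chain", {
  # absorbing limit: bias = 1 keeps every motor in the dominant direction
  ms <- simulate_motor_ensemble(gearset_params(n_motors = 3, bias = 1,
                                               duration_s = 5, seed = 11))
  expect_true(all(ms$directions == 1))
  ms_cw <- simulate_motor_ensemble(gearset_params(n_motors = 2, bias = 1,
                                                  dominant_direction = -1,
                                                  duration_s = 5, seed = 11))
  expect_true(all(ms_cw$directions == -1))

  # closed form: stationary P(dominant) = tau_d / (tau_d + tau_m) = bias;
  # averaged over 10 independent chains to tame the frozen-seed draw
  ms9 <- simulate_motor_ensemble(gearset_params(
    n_motors = 10, bias = 0.9, mean_dwell_dominant_s = 10,
    duration_s = 10000, dt_s = 0.1, seed = 5))
  expect_equal(mean(ms9$directions == 1), 0.9, tolerance = 0.01 / 0.9)

  ms5 <- simulate_motor_ensemble(gearset_params(
    n_motors = 10, bias = 0.5, mean_dwell_dominant_s = 10,
    duration_s = 10000, dt_s = 0.1, seed = 6))
  expect_equal(mean(ms5$directions == 1), 0.5, tolerance = 0.02 / 0.5)
})

test_that("direction census estimates the population split", {
  ms <- simulate_motor_ensemble(gearset_params(
    n_motors = 500, bias = 0.9, mean_dwell_dominant_s = 10,
    duration_s = 30, seed = 21))
  cen <- direction_census(ms)
  expect_equal(cen$pct_ccw, 90, tolerance = 0.02)
  expect_equal(cen$pct_ccw + cen$pct_cw, 100)
  expect_length(cen$per_motor_frac_ccw, 500)
})

test_that("opposite_fraction computes the dissent percentage", {
  expect_identical(opposite_fraction(8, 1), 12.5)
  expect_equal(opposite_fraction(12, 1), 100 / 12)
  expect_identical(opposite_fraction(10, 0), 0)
  expect_error(opposite_fraction(0, 0), class = "gearbelt_param_error")
  expect_error(opposite_fraction(8, 9), class = "gearbelt_param_error")
  expect_error(opposite_fraction(8, -1), class = "gearbelt_param_error")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(gearset_params(bias = 0), class = "gearbelt_param_error")
  expect_error(gearset_params(bias = 1.2), class = "gearbelt_param_error")
  expect_error(gearset_params(n_motors = 0), class = "gearbelt_param_error")
  expect_error(gearset_params(reversal_prob = 2), class = "gearbelt_param_error")
  expect_error(gearset_params(dt_s = 0), class = "gearbelt_param_error")
  expect_error(gearset_params(dominant_direction = 2),
               class = "gearbelt_param_error")
})

test_that("noise-free belt glides straight with no slip events", {
  p <- gearset_params(bias = 1, duration_s = 20, seed = 3)
  res <- simulate_gliding_cell(p)
  expect_identical(nrow(res$events), 0L)
  disp <- farthest_displacement(res$track)
  expect_equal(disp, p$run_speed_um_s * p$duration_s, tolerance = 1e-9)
  expect_equal(path_length(res$track), disp, tolerance = 1e-9)
})

test_that("slip rate and run durations follow the ensemble flip process", {
  # per-motor flip rate 2*bias/tau_d; mean run ~ 1/(n * flip rate)
  p <- gearset_params(n_motors = 10, bias = 0.9, mean_dwell_dominant_s = 10,
                      duration_s = 400, slip_mean_s = 0.5, seed = 42)
  res <- simulate_gliding_cell(p)
  n_slip <- sum(res$events$kind == "slip")
  expect_gte(n_slip, 1)
  expect_lte(n_slip, p$duration_s * p$n_motors / p$mean_dwell_dominant_s * 2)
  slips <- res$events$time_s[res$events$kind == "slip"]
  res_t <- res$events$time_s[res$events$kind == "re_engage"]
  runs <- c(slips[1], slips[-1] - res_t[seq_len(n_slip - 1)])
  flip_rate <- 2 * p$bias / p$mean_dwell_dominant_s
  expect_equal(mean(runs), 1 / (p$n_motors * flip_rate), tolerance = 0.2)
})

test_that("every slip has a matching later re-engagement", {
  for (seed in 1:5) {
    res <- simulate_gliding_cell(gearset_params(duration_s = 60, seed = seed))
    ev <- res$events
    slips <- ev$time_s[ev$kind == "slip"]
    rees <- ev$time_s[ev$kind == "re_engage"]
    expect_length(rees, length(slips))
    expect_true(all(rees >= slips))
  }
})

test_that("displacement respects the speed bound and the time range", {
  for (seed in 1:8) {
    p <- gearset_params(duration_s = 30, run_speed_um_s = 2, seed = seed)
    res <- simulate_gliding_cell(p)
    expect_lte(path_length(res$track),
               p$run_speed_um_s * p$duration_s + 1e-9)
    expect_equal(range(res$track$t_s), c(0, p$duration_s))
  }
})

test_that("simulations are reproducible under a fixed seed", {
  p <- gearset_params(duration_s = 25, seed = 99)
  a <- simulate_gliding_cell(p)
  b <- simulate_gliding_cell(p)
  expect_identical(a$track$x_um, b$track$x_um)
  expect_identical(a$events, b$events)
  expect_identical(a$motor_series$directions, b$motor_series$directions)
  c <- simulate_gliding_cell(gearset_params(duration_s = 25, seed = 100))
  expect_false(identical(a$track$x_um, c$track$x_um))
})

test_that("forced reversals alternate the run heading by pi", {
  p <- gearset_params(reversal_prob = 1, duration_s = 120,
                      mean_dwell_dominant_s = 30, seed = 12)
  res <- simulate_gliding_cell(p)
  ev <- res$events
  # heading of each engaged segment from the truth track
  slips <- ev$time_s[ev$kind == "slip"]
  rees <- c(0, ev$time_s[ev$kind == "re_engage"])
  h <- rep(NA_real_, length(slips))
  for (k in seq_along(slips)) {
    t0 <- rees[k]; t1 <- slips[k]
    if (t1 - t0 < 0.2) next       # too short to resolve on the grid
    i0 <- which.min(abs(res$track$t_s - t0))
    i1 <- which.min(abs(res$track$t_s - t1))
    h[k] <- atan2(res$track$y_um[i1] - res$track$y_um[i0],
                  res$track$x_um[i1] - res$track$x_um[i0])
  }
  # exactly one reversal between adjacent runs: headings differ by pi
  adj <- which(!is.na(h[-length(h)]) & !is.na(h[-1]))
  expect_gte(length(adj), 2)
  dh <- abs(vapply(h[adj + 1L] - h[adj], gearbelt:::wrap_to_pi, numeric(1)))
  expect_true(all(abs(dh - pi) < 0.05))
})

test_that("run lengths are exponential when bias approaches 1", {
  p <- gearset_params(n_motors = 10, bias = 0.999, mean_dwell_dominant_s = 10,
                      duration_s = 2500, dt_s = 0.1, slip_mean_s = 0.5,
                      seed = 77)
  res <- simulate_gliding_cell(p)
  ev <- res$events
  slips <- ev$time_s[ev$kind == "slip"]
  rees <- ev$time_s[ev$kind == "re_engage"]
  runs <- (slips[-1] - rees[seq_len(length(slips) - 1)])
  runs <- runs[runs > 0]
  expect_gte(length(runs), 700)
  ks <- suppressWarnings(
    stats::ks.test(runs, "pexp", rate = p$n_motors / p$mean_dwell_dominant_s))
  expect_gt(ks$p.value, 0.01)
})

test_that("gear ratio constant matches the observed speed/frequency pair", {
  expect_equal(belt_um_per_rev(), 2 / 1.3)
})

test_that("events serialize as JSON lines", {
  res <- simulate_gliding_cell(gearset_params(duration_s = 40, seed = 2))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_events_jsonl(res, f)
  lines <- readLines(f)
  expect_length(lines, nrow(res$events))
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("time_s", "kind"))
})
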