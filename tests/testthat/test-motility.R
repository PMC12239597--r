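# Trajectory linking and gliding kinematics.

test_that("parallel cells link into separate tracks without identity swap", {
  t <- 0:49 / 15
  det <- data.frame(
    frame = rep(0:49, each = 2), t_s = rep(t, each = 2),
    x_um = c(rbind(0.2 * t * 15 / 15, 0.2 * t * 15 / 15)),
    y_um = c(rbind(rep(0, 50), rep(10, 50))))
  trs <- link_tracks(det, max_jump_um = 2)
  expect_length(trs, 2L)
  expect_true(all(vapply(trs, function(tr) diff(range(tr$y_um)) == 0,
                         logical(1))))
})

test_that("a single detection per frame yields one track equal to input", {
  t <- 0:19 / 15
  det <- data.frame(frame = 0:19, t_s = t, x_um = sin(t), y_um = cos(t))
  trs <- link_tracks(det, max_jump_um = 2)
  expect_length(trs, 1L)
  expect_equal(trs[[1]]$x_um, det$x_um)
})

test_that("gaps within the tolerance keep a track; larger gaps split it", {
  t <- 0:19 / 15
  det <- data.frame(frame = 0:19, t_s = t, x_um = 0.1 * (0:19), y_um = 0)
  with_gap <- det[!det$frame %in% c(8, 9), ]
  trs <- link_tracks(with_gap, max_jump_um = 2, max_gap_frames = 2L)
  expect_length(trs, 1L)
  trs2 <- link_tracks(with_gap, max_jump_um = 2, max_gap_frames = 1L)
  expect_length(trs2, 2L)
})

test_that("greedy linking matches brute-force assignment in tracking regimes", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    heads <- cbind(runif(n, 0, 20), runif(n, 0, 20))
    # enforce tracking regime: separations >> steps
    while (n > 1 && min(dist(heads)) < 2) {
      heads <- cbind(runif(n, 0, 20), runif(n, 0, 20))
    }
    steps <- matrix(rnorm(2 * n, 0, 0.15), n)
    dets <- heads + steps
    det_df <- data.frame(
      frame = rep(0:1, each = n), t_s = rep(c(0, 1 / 15), each = n),
      x_um = c(heads[, 1], dets[, 1]), y_um = c(heads[, 2], dets[, 2]))
    trs <- link_tracks(det_df, max_jump_um = 1)
    linked <- sum(vapply(trs, nrow, integer(1)) == 2L)
    greedy_cost <- sum(vapply(trs[vapply(trs, nrow, integer(1)) == 2L],
                              path_length, numeric(1)))
    oracle <- brute_assignment_cost(heads, dets, max_jump = 1)
    expect_identical(linked, oracle$links)
    expect_equal(greedy_cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(32)
  t <- 0:9 / 15
  base <- do.call(rbind, lapply(0:9, function(f) {
    data.frame(frame = f, t_s = f / 15,
               x_um = c(0.2 * f, 5 + 0.2 * f, 10 - 0.2 * f),
               y_um = c(0, 3, 6))
  }))
  shuf <- do.call(rbind, lapply(split(base, base$frame),
                                function(d) d[sample(nrow(d)), ]))
  key <- function(trs) sort(vapply(trs, function(tr)
    paste(round(tr$x_um, 9), round(tr$y_um, 9), collapse = ";"),
    character(1)))
  expect_identical(key(link_tracks(base, 2)), key(link_tracks(shuf, 2)))
})

test_that("track_speed recovers constant, circular, and noisy motion", {
  t <- 0:299 / 15
  straight <- track(t, 2 * t, rep(0, 300))
  expect_equal(track_speed(straight), 2, tolerance = 1e-9)

  R <- 5; Tper <- 10
  circ <- track(t, R * cos(2 * pi * t / Tper), R * sin(2 * pi * t / Tper))
  expect_equal(track_speed(circ), 2 * pi * R / Tper, tolerance = 0.01)

  # documented noise floor: stationary track, sd 0.05 um, 15 fps, window 5
  set.seed(33)
  floors <- vapply(1:20, function(i)
    track_speed(track(t, rnorm(300, 0, 0.05), rnorm(300, 0, 0.05))),
    numeric(1))
  expect_lt(mean(floors), 0.15)

  expect_warning(track_speed(track(0:2 / 15, c(0, 1, 2), c(0, 0, 0))),
                 "shorter than smoothing window")
})

test_that("farthest_displacement follows the definition", {
  t <- 0:99 / 15
  straight <- track(t, 40 * t / max(t), rep(0, 100))
  expect_equal(farthest_displacement(straight), 40)
  # full circle starting on the circle: farthest point is the antipode
  circ <- track(t, 3 * cos(2 * pi * t / max(t)) - 3,
                3 * sin(2 * pi * t / max(t)))
  expect_equal(farthest_displacement(circ), 6, tolerance = 1e-3)
  # gearset truth: equals an independent recomputation over samples
  res <- simulate_gliding_cell(gearset_params(duration_s = 30, seed = 5))
  manual <- max(sqrt((res$track$x_um - res$track$x_um[1])^2 +
                       (res$track$y_um - res$track$y_um[1])^2))
  expect_identical(farthest_displacement(res$track), manual)
})

test_that("turn and reversal events are detected", {
  t <- 0:149 / 15
  straight <- track(t, t, rep(0, 150))
  expect_identical(detect_turn_events(straight),
                   list(n_turn_events = 0L, n_reversals = 0L))

  # one 180-degree flip halfway
  x <- c(seq(0, 5, length.out = 75), seq(5, 0, length.out = 75))
  flip <- track(t, x, rep(0, 150))
  ev <- detect_turn_events(flip)
  expect_identical(ev$n_turn_events, 1L)
  expect_identical(ev$n_reversals, 1L)

  # a right-angle turn is a turn but not a reversal
  xy <- cbind(c(seq(0, 5, length.out = 75), rep(5, 75)),
              c(rep(0, 75), seq(0, 5, length.out = 75)))
  ell <- track(t, xy[, 1], xy[, 2])
  ev2 <- detect_turn_events(ell, angle_threshold_rad = pi / 3)
  expect_identical(ev2$n_turn_events, 1L)
  expect_identical(ev2$n_reversals, 0L)
})

test_that("forced-reversal gearset tracks yield one reversal per slip", {
  p <- gearset_params(reversal_prob = 1, duration_s = 90,
                      mean_dwell_dominant_s = 60, slip_mean_s = 0.5, seed = 8)
  res <- simulate_gliding_cell(p)
  k <- sum(res$events$kind == "reversal")
  # two flips closer than the smoothing window cancel each other and are
  # unresolvable at the sampling rate: count resolvable truth events
  # (separated by more than a window from their neighbours)
  rev_t <- res$events$time_s[res$events$kind == "reversal"]
  gaps <- diff(c(0, rev_t, p$duration_s))
  resolvable <- sum(gaps[-length(gaps)] > 0.5 & gaps[-1] > 0.5)
  ev <- detect_turn_events(res$track)
  expect_gte(k, 2)
  expect_gte(ev$n_reversals, resolvable - 1L)
  expect_lte(ev$n_reversals, k)
})

test_that("farthest displacement never exceeds path length", {
  for (seed in 1:6) {
    res <- simulate_gliding_cell(gearset_params(duration_s = 40, seed = seed))
    det <- noisy_detections(res$track, seed = 100 + seed)
    tr <- longest_track(link_tracks(det, 2))
    expect_lte(farthest_displacement(tr), path_length(tr) + 1e-9)
  }
})

test_that("population_summary averages per-track statistics", {
  t <- 0:149 / 15
  tr1 <- track(t, t, rep(0, 150))            # fd 149/15
  tr2 <- track(t, 2 * t, rep(0, 150))        # fd 2*149/15
  pop <- population_summary(list(tr1, tr2))
  expect_identical(pop$n, 2L)
  expect_equal(pop$farthest_displacement_um, 1.5 * 149 / 15)
  expect_equal(pop$mean_speed_um_s, 1.5, tolerance = 1e-9)
  one <- population_summary(list(tr1))
  expect_equal(one$mean_speed_um_s, track_speed(tr1))
  expect_error(population_summary(list()), class = "gearbelt_param_error")
})

test_that("track CSV round trips through the documented schema", {
  t <- 0:20 / 15
  trs <- list(track(t, sin(t), cos(t), intensity = rep(7, 21), track_id = "a"),
              track(t, t, t, track_id = "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(trs, f)
  expect_identical(readLines(f, n = 1L), "# gearbelt track csv v1")
  back <- read_tracks_csv(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$x_um, trs[[1]]$x_um, tolerance = 1e-12)
  expect_equal(back[[2]]$t_s, trs[[2]]$t_s, tolerance = 1e-12)
})
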