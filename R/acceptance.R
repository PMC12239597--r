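# Parameter-recovery experiments: the raw assay videos behind the study are
# not deposited, so the printed population values are reproduced as
# recovery experiments on synthetic data generated with those values as
# ground truth. Each function runs the full pipeline (generate -> analyze)
# and returns the recovered summaries.

#' Tethered-cell rotation recovery experiment
#'
#' Renders `n_videos` tethered-cell videos at a signed ground-truth
#' frequency (10 s, 15 fps, default noise) and runs the rotation pipeline
#' (angle extraction, frequency, population distribution).
#'
#' @param signed_freq_hz ground-truth signed frequency (+ = CCW).
#' @param n_videos number of videos.
#' @param seed base seed; per-video seeds are derived from it.
#' @param duration_s video duration (default 10 s).
#' @param noise_sd pixel noise (fraction of dynamic range).
#' @return list with `records` (rotation records) and `dist`
#'   (a [speed_distribution()]).
#' @export
run_rotation_recovery <- function(signed_freq_hz, n_videos, seed = 1L,
                                  duration_s = 10, noise_sd = 0.05) {
  fps <- 15
  meta <- video_meta(n_frames = as.integer(duration_s * fps),
                     shape_px = c(128L, 128L))
  records <- lapply(seq_len(n_videos), function(i) {
    s <- derive_seed(seed, paste0("tethered-", i))
    set.seed(s)
    theta0 <- runif(1, -pi, pi)
    rv <- render_tethered_video(signed_freq_hz = signed_freq_hz,
                                meta = meta, noise_sd = noise_sd,
                                theta0 = theta0, seed = s)
    rotation_frequency(extract_angle_trace(rv$video))
  })
  list(records = records, dist = speed_distribution(records))
}

#' Gliding-speed recovery experiment
#'
#' Simulates `n_tracks` gearset trajectories at a ground-truth run speed,
#' adds localization noise to the per-frame positions, links the
#' detections, and returns the per-track mean speeds.
#'
#' @param run_speed_um_s ground-truth run speed (um/s).
#' @param n_tracks population size.
#' @param seed base seed.
#' @param reversal_prob heading-reversal probability at re-engagement
#'   (1 = back-and-forth mode).
#' @param duration_s track duration.
#' @param noise_sd_um localization noise (um).
#' @param mean_dwell_dominant_s dominant dwell; `NULL` uses the default.
#' @return numeric vector of recovered per-track mean speeds.
#' @export
run_gliding_recovery <- function(run_speed_um_s, n_tracks = 30L, seed = 1L,
                                 reversal_prob = 0.5, duration_s = 60,
                                 noise_sd_um = 0.05,
                                 mean_dwell_dominant_s = NULL) {
  vapply(seq_len(n_tracks), function(i) {
    s <- derive_seed(seed, paste0("glide-", i))
    args <- list(run_speed_um_s = run_speed_um_s, bias = 0.9,
                 reversal_prob = reversal_prob, duration_s = duration_s,
                 seed = s)
    if (!is.null(mean_dwell_dominant_s))
      args$mean_dwell_dominant_s <- mean_dwell_dominant_s
    res <- simulate_gliding_cell(do.call(gearset_params, args))
    set.seed(derive_seed(seed, paste0("glide-noise-", i)))
    det <- data.frame(frame = seq_len(nrow(res$track)) - 1L,
                      t_s = res$track$t_s,
                      x_um = res$track$x_um + rnorm(nrow(res$track), 0, noise_sd_um),
                      y_um = res$track$y_um + rnorm(nrow(res$track), 0, noise_sd_um))
    trs <- link_tracks(det, max_jump_um = 2)
    track_speed(trs[[which.max(vapply(trs, nrow, integer(1)))]])
  }, numeric(1))
}

#' Straight-run speed recovery experiment
#'
#' `n_tracks` straight constant-speed tracks with localization noise, the
#' regime behind the per-strain mean gliding speeds.
#'
#' @inheritParams run_gliding_recovery
#' @return numeric vector of recovered per-track mean speeds.
#' @export
run_straight_recovery <- function(run_speed_um_s, n_tracks = 30L, seed = 1L,
                                  duration_s = 60, noise_sd_um = 0.05) {
  t <- seq(0, duration_s, by = 1 / 15)
  vapply(seq_len(n_tracks), function(i) {
    set.seed(derive_seed(seed, paste0("straight-", i)))
    th <- runif(1, -pi, pi)
    tr <- track(t,
                run_speed_um_s * t * cos(th) + rnorm(length(t), 0, noise_sd_um),
                run_speed_um_s * t * sin(th) + rnorm(length(t), 0, noise_sd_um))
    track_speed(tr)
  }, numeric(1))
}

#' Farthest-displacement recovery experiment
#'
#' Calibrates the gearset run-length parameter (dominant dwell) by
#' bisection so the ground-truth per-track farthest displacement averages
#' `target_um` over the population of noiseless truth tracks, then adds
#' localization noise and recovers the population mean through the
#' pipeline.
#'
#' @param target_um target ground-truth mean farthest displacement (um).
#' @param n_tracks population size.
#' @param seed base seed.
#' @param duration_s track duration.
#' @param noise_sd_um localization noise (um).
#' @return list with `truth_mean_um`, `recovered_mean_um`,
#'   `mean_dwell_dominant_s` (calibrated value).
#' @export
run_farthest_recovery <- function(target_um = 27, n_tracks = 30L, seed = 1L,
                                  duration_s = 60, noise_sd_um = 0.05) {
  truth_tracks <- function(dwell) {
    lapply(seq_len(n_tracks), function(i) {
      p <- gearset_params(run_speed_um_s = 2, bias = 0.9,
                          mean_dwell_dominant_s = dwell,
                          duration_s = duration_s,
                          seed = derive_seed(seed, paste0("fd-", i)))
      simulate_gliding_cell(p)$track
    })
  }
  mean_fd <- function(tracks)
    mean(vapply(tracks, farthest_displacement, numeric(1)))
  lo <- 2; hi <- 2000
  for (iter in 1:24) {
    mid <- sqrt(lo * hi)
    m <- mean_fd(truth_tracks(mid))
    if (abs(m - target_um) < 0.05) break
    if (m < target_um) lo <- mid else hi <- mid
  }
  tracks <- truth_tracks(mid)
  recovered <- vapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    set.seed(derive_seed(seed, paste0("fd-noise-", i)))
    det <- data.frame(frame = seq_len(nrow(tr)) - 1L, t_s = tr$t_s,
                      x_um = tr$x_um + rnorm(nrow(tr), 0, noise_sd_um),
                      y_um = tr$y_um + rnorm(nrow(tr), 0, noise_sd_um))
    trs <- link_tracks(det, max_jump_um = 2)
    farthest_displacement(trs[[which.max(vapply(trs, nrow, integer(1)))]])
  }, numeric(1))
  list(truth_mean_um = mean_fd(tracks),
       recovered_mean_um = mean(recovered),
       mean_dwell_dominant_s = mid)
}

#' Motor-population direction census experiment
#'
#' Simulates `n_motors` independent motors at the stationary wild-type
#' bias and reports the percentage of motor-time spent rotating CCW —
#' the simulated analogue of the published population split (90% of units
#' CCW at any instant). Classifying each motor by its net rotation over an
#' ergodically long window would instead converge to 100% CCW, which is
#' not the quantity the census reports (see the methods vignette).
#'
#' @param n_motors number of independent motors.
#' @param bias stationary CCW probability.
#' @param mean_dwell_dominant_s dominant dwell (s).
#' @param duration_s observation window (s).
#' @param seed RNG seed.
#' @return percentage of motor-time in the CCW direction.
#' @export
run_motor_census <- function(n_motors = 1000L, bias = 0.9,
                             mean_dwell_dominant_s = 10, duration_s = 30,
                             seed = 1L) {
  ms <- simulate_motor_ensemble(gearset_params(
    n_motors = n_motors, bias = bias,
    mean_dwell_dominant_s = mean_dwell_dominant_s,
    duration_s = duration_s, seed = seed))
  direction_census(ms)$pct_ccw
}

#' Conveyor-belt spot speed recovery experiment
#'
#' Renders `n_videos` belt-loop TIRF videos of an elongated cell at a
#' ground-truth belt speed and recovers the mean spot speed through
#' detection, linking, and the shared speed estimator.
#'
#' @param belt_speed_um_s ground-truth belt speed (um/s).
#' @param n_videos number of videos (the study tracked at least six spots
#'   per strain).
#' @param seed base seed.
#' @param duration_s video duration (s).
#' @return numeric vector of recovered per-video spot speeds.
#' @export
run_spot_recovery <- function(belt_speed_um_s = 2, n_videos = 6L, seed = 1L,
                              duration_s = 20) {
  meta <- video_meta(n_frames = as.integer(duration_s * 15),
                     shape_px = c(64L, 128L), bit_depth = 16L)
  vapply(seq_len(n_videos), function(i) {
    s <- derive_seed(seed, paste0("spot-", i))
    set.seed(s)
    sv <- render_spot_video(cell_length_um = 10, cell_width_um = 0.5,
                            belt_speed_um_s = belt_speed_um_s, meta = meta,
                            s0 = runif(1, 0, 20), seed = s)
    trs <- link_tracks(detect_spots_stack(sv$video), max_jump_um = 0.5)
    spot_speed(trs[[which.max(vapply(trs, nrow, integer(1)))]])
  }, numeric(1))
}
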