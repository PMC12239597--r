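# Gliding-motility trajectory analysis: detection linking, gliding speed,
# farthest displacement, and turn/reversal events.

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor assignment: within each frame, candidate links
#' between open track heads and detections are taken in ascending distance
#' order; links longer than `max_jump_um` are rejected. Tracks survive up
#' to `max_gap_frames` consecutive missed frames (positions are not
#' imputed); unmatched detections seed new tracks. Equidistant candidate
#' links break ties by track age (older track first), which makes the
#' result invariant to detection order within a frame.
#'
#' @param detections data.frame with columns `frame` (integer), `t_s`,
#'   `x_um`, `y_um` and optionally `intensity`, time-ordered.
#' @param max_jump_um maximum link distance (um).
#' @param max_gap_frames tolerated missing frames within a track.
#' @return list of tracks (see [track()]), ordered by creation.
#' @export
#' @examples
#' det <- data.frame(frame = rep(0:4, each = 2), t_s = rep(0:4 / 15, each = 2),
#'                   x_um = c(rbind(0:4 * 0.2, 10 + 0:4 * 0.2)),
#'                   y_um = rep(c(0, 0), 5))
#' length(link_tracks(det, max_jump_um = 2))  # 2
link_tracks <- function(detections, max_jump_um = 2, max_gap_frames = 2L) {
  need <- c("frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(detections)))
    abort_param("detections need columns ", paste(need, collapse = ", "))
  has_int <- "intensity" %in% names(detections)
  tracks <- list()     # each: list(rows = list of det rows, last_frame)
  open <- integer(0)   # indices into `tracks`
  for (fr in sort(unique(detections$frame))) {
    det <- detections[detections$frame == fr, , drop = FALSE]
    # close stale tracks
    if (length(open)) {
      stale <- vapply(tracks[open], function(tr) fr - tr$last_frame,
                      numeric(1)) > max_gap_frames + 1L
      open <- open[!stale]
    }
    assigned_det <- rep(FALSE, nrow(det))
    assigned_trk <- rep(FALSE, length(open))
    if (length(open) && nrow(det)) {
      heads <- t(vapply(tracks[open], function(tr) {
        last <- tr$rows[[length(tr$rows)]]
        c(last$x_um, last$y_um)
      }, numeric(2)))
      d <- sqrt(outer(heads[, 1], det$x_um, "-")^2 +
                outer(heads[, 2], det$y_um, "-")^2)
      cand <- which(d <= max_jump_um, arr.ind = TRUE)
      if (nrow(cand)) {
        # ascending distance; ties by track age, then detection coordinates
        # (content-based, so linking is invariant to detection order)
        ord <- order(d[cand], cand[, 1],
                     det$x_um[cand[, 2]], det$y_um[cand[, 2]])
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (assigned_trk[ti] || assigned_det[di]) next
          assigned_trk[ti] <- TRUE; assigned_det[di] <- TRUE
          tr <- tracks[[open[ti]]]
          tr$rows[[length(tr$rows) + 1L]] <- det[di, , drop = FALSE]
          tr$last_frame <- fr
          tracks[[open[ti]]] <- tr
        }
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <-
        list(rows = list(det[di, , drop = FALSE]), last_frame = fr)
      open <- c(open, length(tracks))
    }
    open <- open[order(open)]
  }
  lapply(seq_along(tracks), function(i) {
    d <- do.call(rbind, tracks[[i]]$rows)
    track(d$t_s, d$x_um, d$y_um,
          intensity = if (has_int) d$intensity,
          track_id = i, source = "cell")
  })
}

#' Mean gliding speed of a track
#'
#' Positions are smoothed with a centered moving average
#' (`smooth_window_frames` samples, default 5 — about 0.33 s at 15 fps,
#' enough to suppress localization noise without erasing reversals); the
#' speed is the mean of `|dr| / dt` with the displacement evaluated at the
#' window timescale (smoothed positions one window apart, so successive
#' endpoints share no raw samples). At the defaults this puts the noise
#' floor of a stationary track with 0.05 um localization noise below
#' 0.15 um/s. Steps across detection gaps (dt larger than 1.5x the nominal
#' span) are excluded from the average. Tracks shorter than the window
#' fall back to raw consecutive-frame differences with a warning.
#'
#' @param track a track with at least 2 samples.
#' @param smooth_window_frames moving-average window (frames).
#' @return mean speed in um/s.
#' @export
track_speed <- function(track, smooth_window_frames = 5L) {
  n <- nrow(track)
  if (n < 2L) abort_param("track needs at least 2 samples")
  if (n < smooth_window_frames + 1L) {
    warning("track shorter than smoothing window; using raw positions")
    dt <- diff(track$t_s)
    steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
    return(mean((steps / dt)[dt <= 1.5 * median(dt)]))
  }
  w <- as.integer(smooth_window_frames)
  xs <- moving_average(track$x_um, w)
  ys <- moving_average(track$y_um, w)
  lag <- max(1L, w)
  i <- seq_len(n - lag)
  dt <- track$t_s[i + lag] - track$t_s[i]
  keep <- dt <= 1.5 * lag * median(diff(track$t_s))
  steps <- sqrt((xs[i + lag] - xs[i])^2 + (ys[i + lag] - ys[i])^2)
  mean((steps / dt)[keep])
}

#' Farthest displacement of a track
#'
#' Maximum Euclidean distance of any trajectory point from the first
#' sample, in micrometers.
#'
#' @param track a track with at least 2 samples.
#' @return micrometers.
#' @export
farthest_displacement <- function(track) {
  if (nrow(track) < 2L) abort_param("track needs at least 2 samples")
  max(sqrt((track$x_um - track$x_um[1])^2 + (track$y_um - track$y_um[1])^2))
}

#' Detect turn and reversal events along a track
#'
#' Headings come from the smoothed per-frame velocity. A turn event is a
#' change larger than `angle_threshold_rad` between the circular mean
#' heading of the `window_frames` preceding and following a frame, with
#' successive events separated by at least `window_frames`. A reversal is
#' a turn whose heading change lies within pi +/- pi/6.
#'
#' @param track a track with at least `2 * window_frames` samples.
#' @param angle_threshold_rad turn threshold (default pi/2).
#' @param window_frames heading-averaging window (frames).
#' @return list with `n_turn_events` and `n_reversals`.
#' @export
detect_turn_events <- function(track, angle_threshold_rad = pi / 2,
                               window_frames = 5L) {
  n <- nrow(track)
  if (n < 2L * window_frames) abort_param("track too short for turn detection")
  xs <- moving_average(track$x_um, window_frames)
  ys <- moving_average(track$y_um, window_frames)
  vx <- diff(xs); vy <- diff(ys)
  sp <- sqrt(vx^2 + vy^2)
  # headings are defined on moving frames only, so a pause (slip) does not
  # mask the heading change across it
  moving <- sp > max(1e-9, 0.05 * median(sp))
  h <- atan2(vy, vx)[moving]
  m <- length(h)
  w <- window_frames
  events <- integer(0); reversals <- 0L
  last_event <- -Inf
  i <- w + 1L
  while (i <= m - w + 1L) {
    dh <- abs(wrap_to_pi(circ_mean(h[i:(i + w - 1L)]) -
                           circ_mean(h[(i - w):(i - 1L)])))
    if (dh > angle_threshold_rad && i - last_event >= w) {
      events <- c(events, i)
      if (abs(dh - pi) <= pi / 6) reversals <- reversals + 1L
      last_event <- i
      i <- i + w            # skip past this event
      next
    }
    i <- i + 1L
  }
  list(n_turn_events = length(events), n_reversals = reversals)
}

#' Per-track kinematic statistics
#'
#' @param track a track.
#' @param smooth_window_frames window for [track_speed()] and
#'   [detect_turn_events()].
#' @return a `track_stats` list: `mean_speed_um_s`,
#'   `farthest_displacement_um`, `path_length_um`, `n_turn_events`,
#'   `n_reversals`, `duration_s`.
#' @export
track_stats <- function(track, smooth_window_frames = 5L) {
  turns <- if (nrow(track) >= 2L * smooth_window_frames)
    detect_turn_events(track, window_frames = smooth_window_frames)
  else list(n_turn_events = NA_integer_, n_reversals = NA_integer_)
  structure(list(
    mean_speed_um_s = track_speed(track, smooth_window_frames),
    farthest_displacement_um = farthest_displacement(track),
    path_length_um = path_length(track),
    n_turn_events = turns$n_turn_events,
    n_reversals = turns$n_reversals,
    duration_s = diff(range(track$t_s))
  ), class = "track_stats")
}

#' Population summary of track statistics
#'
#' Arithmetic means of each [track_stats()] field across tracks, with the
#' population size `n`.
#'
#' @param tracks non-empty list of tracks.
#' @param smooth_window_frames passed to [track_stats()].
#' @return data.frame with one row of means plus `n`.
#' @export
population_summary <- function(tracks, smooth_window_frames = 5L) {
  if (!length(tracks)) abort_param("population_summary needs at least 1 track")
  st <- lapply(tracks, track_stats, smooth_window_frames = smooth_window_frames)
  fields <- c("mean_speed_um_s", "farthest_displacement_um", "path_length_um",
              "n_turn_events", "n_reversals", "duration_s")
  out <- lapply(fields, function(f) {
    v <- vapply(st, function(s) as.numeric(s[[f]]), numeric(1))
    mean(v, na.rm = TRUE)
  })
  names(out) <- fields
  cbind(as.data.frame(out), n = length(tracks))
}

#' Write per-track statistics to CSV
#'
#' @param tracks list of tracks.
#' @param path output file.
#' @param smooth_window_frames passed to [track_stats()].
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(tracks, path, smooth_window_frames = 5L) {
  st <- lapply(tracks, track_stats, smooth_window_frames = smooth_window_frames)
  df <- data.frame(
    track_id = vapply(tracks, function(tr) as.character(attr(tr, "track_id")),
                      character(1)),
    mean_speed_um_s = vapply(st, `[[`, numeric(1), "mean_speed_um_s"),
    farthest_displacement_um = vapply(st, `[[`, numeric(1),
                                      "farthest_displacement_um"),
    path_length_um = vapply(st, `[[`, numeric(1), "path_length_um"),
    n_turn_events = vapply(st, function(s) as.numeric(s$n_turn_events), numeric(1)),
    n_reversals = vapply(st, function(s) as.numeric(s$n_reversals), numeric(1)),
    duration_s = vapply(st, `[[`, numeric(1), "duration_s"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gearbelt track stats v1", con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
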