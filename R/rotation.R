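# Tethered-cell rotation analysis: signed rotational frequency (CCW
# positive) with the full-revolution inclusion filter.

#' Angular trace of a rotating tethered cell
#'
#' @param times_s sample times (s), strictly increasing.
#' @param theta_rad unwrapped angle (radians, CCW positive); consecutive
#'   differences must stay below pi in magnitude.
#' @param center_xy_um estimated rotation center (um).
#' @param radius_um mean orbit radius (um).
#' @param flagged_frames indices of frames whose centroid was interpolated.
#' @return an `angular_trace` list.
#' @export
angular_trace <- function(times_s, theta_rad, center_xy_um = c(NA, NA),
                          radius_um = NA_real_, flagged_frames = integer(0)) {
  if (length(times_s) != length(theta_rad))
    abort_param("times and angles must have equal length")
  if (length(times_s) >= 2L && any(diff(times_s) <= 0))
    abort_param("times must be strictly increasing")
  structure(list(times_s = times_s, theta_rad = theta_rad,
                 center_xy_um = center_xy_um, radius_um = radius_um,
                 flagged_frames = flagged_frames),
            class = "angular_trace")
}

# Otsu threshold on an integer image; returns the gray level maximizing
# between-class variance (foreground = darker class, values <= threshold).
otsu_threshold <- function(img, maxval) {
  counts <- tabulate(as.vector(img) + 1L, nbins = maxval + 1L)
  p <- counts / sum(counts)
  levels <- 0:maxval
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  levels[which.max(between)]
}

# Algebraic (Kasa) circle fit; falls back to the centroid of the cloud
# when the design matrix is ill-conditioned (static or near-static cell).
kasa_center <- function(x, y) {
  B <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch({
    q <- qr(B)
    if (q$rank < 3L) NULL else qr.coef(q, b)
  }, error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit[1:2])) ||
      sqrt((fit[1] - mean(x))^2 + (fit[2] - mean(y))^2) >
        10 * (diff(range(x)) + diff(range(y)) + 1e-12))
    return(c(mean(x), mean(y)))
  fit[1:2]
}

# Largest 4-connected foreground component. `fg` is a logical matrix.
# Ties in size break toward the component containing the lowest row index.
# Returns linear pixel indices, or integer(0).
largest_component <- function(fg, min_area_px) {
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  if (!length(idx)) return(integer(0))
  labels <- integer(nr * nc)
  best <- integer(0); best_n <- 0L; best_row <- nr + 1L
  queue <- integer(length(idx))
  for (seed in idx) {
    if (labels[seed]) next
    labels[seed] <- 1L
    queue[1L] <- seed; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- (p - 1L) %% nr + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (p > nr) p - nr, if (p <= nr * (nc - 1L)) p + nr)
      nb <- nb[fg[nb] & !labels[nb]]
      for (q in nb) {
        labels[q] <- 1L
        qt <- qt + 1L
        if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
        queue[qt] <- q
      }
    }
    comp <- queue[seq_len(qt)]
    if (length(comp) >= min_area_px) {
      row_min <- min((comp - 1L) %% nr + 1L)
      if (length(comp) > best_n ||
          (length(comp) == best_n && row_min < best_row)) {
        best <- comp; best_n <- length(comp); best_row <- row_min
      }
    }
  }
  best
}

#' Extract the unwrapped tether angle from a rotation video
#'
#' Per frame: global Otsu threshold (dark object), largest 4-connected
#' component above `min_area_px`, intensity-weighted centroid (weight =
#' darkness below threshold). The rotation center is estimated by an
#' algebraic (Kasa) circle fit to the centroid cloud — unbiased also for
#' trajectories covering a non-integer number of revolutions, where the
#' time-mean centroid is systematically offset; the fit falls back to the
#' time-mean centroid when the cloud is degenerate (e.g. a static cell).
#' Raw angles `atan2(y - yc, x - xc)` are unwrapped with
#' [unwrap_angles()]. Frames with no usable component are linearly
#' interpolated when they make up at most 10% of the video, otherwise an
#' error is raised.
#'
#' @param video a `video_stack`.
#' @param threshold_method currently only `"otsu"`.
#' @param min_area_px minimum component area in pixels.
#' @param center_xy_um optional known rotation center (um); when supplied
#'   (e.g. the tether position of a generator), no center is estimated.
#' @return an [angular_trace()].
#' @export
extract_angle_trace <- function(video, threshold_method = "otsu",
                                min_area_px = 20L, center_xy_um = NULL) {
  stopifnot(inherits(video, "video_stack"))
  threshold_method <- match.arg(threshold_method, "otsu")
  meta <- video$meta
  axes <- px_axes(meta)
  maxval <- 2^meta$bit_depth - 1
  nfr <- meta$n_frames
  cx <- rep(NA_real_, nfr); cy <- rep(NA_real_, nfr)
  nr <- meta$shape_px[1]
  for (f in seq_len(nfr)) {
    img <- video$frames[, , f]
    thr <- otsu_threshold(img, maxval)
    comp <- largest_component(img <= thr, min_area_px)
    if (!length(comp)) next
    w <- thr - img[comp] + 1
    r <- (comp - 1L) %% nr + 1L
    cc <- (comp - 1L) %/% nr + 1L
    cx[f] <- sum(w * axes$x[cc]) / sum(w)
    cy[f] <- sum(w * axes$y[r]) / sum(w)
  }
  bad <- which(is.na(cx))
  if (length(bad) > 0.1 * nfr)
    abort_param("more than 10% of frames lack a usable component (",
                length(bad), " of ", nfr, ")")
  times <- (seq_len(nfr) - 1L) * meta$frame_interval_s
  if (length(bad)) {
    ok <- setdiff(seq_len(nfr), bad)
    cx <- approx(times[ok], cx[ok], xout = times, rule = 2)$y
    cy <- approx(times[ok], cy[ok], xout = times, rule = 2)$y
  }
  center <- if (!is.null(center_xy_um)) center_xy_um else kasa_center(cx, cy)
  raw <- atan2(cy - center[2], cx - center[1])
  angular_trace(times, unwrap_angles(raw), center_xy_um = center,
                radius_um = mean(sqrt((cx - center[1])^2 + (cy - center[2])^2)),
                flagged_frames = bad)
}

#' Unwrap a sequence of raw angles
#'
#' Maps each successive difference into `(-pi, pi]` (an exact difference of
#' pi resolves toward +pi) and accumulates from the first angle. Valid when
#' the true motion advances less than half a turn per sample, which the
#' synthetic generator guarantees through its Nyquist margin.
#'
#' @param raw_theta raw angles in radians (any branch).
#' @return unwrapped angles, same length, starting at `raw_theta[1]`.
#' @export
#' @examples
#' unwrap_angles(c(0, 3 * pi / 4, -pi / 2))  # 0, 3pi/4, 3pi/2
unwrap_angles <- function(raw_theta) {
  if (length(raw_theta) < 2L) return(raw_theta)
  raw_theta[1] + c(0, cumsum(wrap_to_pi(diff(raw_theta))))
}

#' Signed rotation frequency and direction of an angular trace
#'
#' Frequency is computed from the net unwrapped excursion,
#' `(theta_end - theta_start) / (2*pi*duration)` — robust to centroid
#' jitter and aligned with the full-revolution inclusion filter: a record
#' passes when the net excursion reaches at least one full turn
#' (`n_revolutions >= 1`), the criterion used to exclude Brownian
#' dithering. Direction is CCW for positive passing records, CW for
#' negative, otherwise indeterminate.
#'
#' @param trace an [angular_trace()] spanning at least 1 s.
#' @return a `rotation_record` list: `frequency_hz`, `direction`,
#'   `n_revolutions`, `passes_filter`, `duration_s`.
#' @export
rotation_frequency <- function(trace) {
  stopifnot(inherits(trace, "angular_trace"))
  if (any(diff(trace$times_s) <= 0)) abort_param("non-monotone times")
  duration <- trace$times_s[length(trace$times_s)] - trace$times_s[1]
  if (duration < 1 - 1e-12) abort_param("trace must span at least 1 s")
  net <- trace$theta_rad[length(trace$theta_rad)] - trace$theta_rad[1]
  freq <- net / (2 * pi * duration)
  n_rev <- abs(net) / (2 * pi)
  passes <- n_rev >= 1
  direction <- if (!passes) "indeterminate" else if (freq > 0) "CCW" else "CW"
  structure(list(frequency_hz = freq, direction = direction,
                 n_revolutions = n_rev, passes_filter = passes,
                 duration_s = duration),
            class = "rotation_record")
}

#' Speed distribution over a population of rotation records
#'
#' Histograms the signed frequencies of records passing the
#' full-revolution filter. The dominant direction is the sign of the
#' majority (a tie resolves to CCW, the wild-type bias);
#' `fraction_dominant` is the majority share and `mean_dominant_hz` the
#' mean unsigned speed of the dominant-direction subpopulation.
#'
#' @param records list of `rotation_record`s.
#' @param bin_width_hz histogram bin width (Hz).
#' @return a `speed_distribution` list; when no record passes the filter, a
#'   sentinel with `n_passing = 0` and NA summaries.
#' @export
speed_distribution <- function(records, bin_width_hz = 0.1) {
  if (inherits(records, "rotation_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "rotation_record")))
  f <- vapply(records, `[[`, numeric(1), "frequency_hz")
  pass <- vapply(records, `[[`, logical(1), "passes_filter")
  fp <- f[pass]
  if (!length(fp)) {
    return(structure(list(signed_speeds_hz = numeric(0), bin_edges = numeric(0),
                          counts = integer(0), mean_dominant_hz = NA_real_,
                          dominant_direction = NA_character_,
                          fraction_dominant = NA_real_, n_passing = 0L,
                          n_total = length(records)),
                     class = "speed_distribution"))
  }
  lo <- floor(min(fp) / bin_width_hz) * bin_width_hz
  hi <- ceiling(max(fp) / bin_width_hz) * bin_width_hz
  if (hi <= lo) hi <- lo + bin_width_hz
  edges <- seq(lo, hi, by = bin_width_hz)
  counts <- tabulate(pmin(findInterval(fp, edges, rightmost.closed = TRUE),
                          length(edges) - 1L), nbins = length(edges) - 1L)
  n_ccw <- sum(fp > 0)
  dominant <- if (n_ccw >= length(fp) / 2) "CCW" else "CW"
  dom_set <- if (dominant == "CCW") fp[fp > 0] else fp[fp < 0]
  structure(list(signed_speeds_hz = fp, bin_edges = edges, counts = counts,
                 mean_dominant_hz = mean(abs(dom_set)),
                 dominant_direction = dominant,
                 fraction_dominant = length(dom_set) / length(fp),
                 n_passing = length(fp), n_total = length(records)),
            class = "speed_distribution")
}

#' Write rotation records to CSV
#'
#' Columns: `motor_id, frequency_hz, direction, n_revolutions,
#' passes_filter, duration_s`, with a schema-version header comment.
#'
#' @param records list of `rotation_record`s.
#' @param path output file.
#' @param motor_ids identifiers (defaults to 1..n).
#' @return `path`, invisibly.
#' @export
write_rotation_csv <- function(records, path, motor_ids = seq_along(records)) {
  df <- data.frame(
    motor_id = motor_ids,
    frequency_hz = vapply(records, `[[`, numeric(1), "frequency_hz"),
    direction = vapply(records, `[[`, character(1), "direction"),
    n_revolutions = vapply(records, `[[`, numeric(1), "n_revolutions"),
    passes_filter = vapply(records, `[[`, logical(1), "passes_filter"),
    duration_s = vapply(records, `[[`, numeric(1), "duration_s"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gearbelt rotation records v1", con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
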