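# Synthetic microscopy renderer: seeded, ground-truth-annotated videos for
# the tethered-cell, gliding, and TIRF spot assays.
#
# Conventions: the analysis frame has y increasing upward,
#   x_um = (col - 0.5) * pixel_size,  y_um = (n_rows - row + 0.5) * pixel_size,
# so CCW in the mathematical sense equals CCW in a conventionally displayed
# image after the flip. Phase contrast is approximated as a dark rod on a
# bright background with Gaussian noise; TIRF as a Gaussian spot with
# Poisson photon noise.

#' Video metadata
#'
#' @param pixel_size_um micrometers per pixel (default 0.1, cell of ~5 um
#'   spans ~50 px).
#' @param frame_interval_s seconds per frame (default 1/15: 15 fps).
#' @param n_frames number of frames.
#' @param shape_px integer `(rows, cols)`.
#' @param bit_depth 8 or 16.
#' @return a `video_meta` list.
#' @export
video_meta <- function(pixel_size_um = 0.1, frame_interval_s = 1 / 15,
                       n_frames = 150L, shape_px = c(512L, 512L),
                       bit_depth = 8L) {
  check_scalar(pixel_size_um, "pixel_size_um", lower = 0)
  check_scalar(frame_interval_s, "frame_interval_s", lower = 0)
  if (!bit_depth %in% c(8L, 16L)) abort_param("bit_depth must be 8 or 16")
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 shape_px = as.integer(shape_px),
                 bit_depth = as.integer(bit_depth)),
            class = "video_meta")
}

#' @rdname video_meta
#' @param meta a `video_meta`.
#' @param frames integer array `rows x cols x n_frames`.
#' @export
video_stack <- function(meta, frames) {
  stopifnot(inherits(meta, "video_meta"),
            length(dim(frames)) == 3L,
            all(dim(frames)[1:2] == meta$shape_px))
  meta$n_frames <- dim(frames)[3]
  structure(list(meta = meta, frames = frames), class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  cat(sprintf("<video_stack> %d frames %dx%d px, %g um/px, %.1f fps, %d-bit\n",
              x$meta$n_frames, x$meta$shape_px[1], x$meta$shape_px[2],
              x$meta$pixel_size_um, 1 / x$meta$frame_interval_s,
              x$meta$bit_depth))
  invisible(x)
}

# pixel-center coordinate axes in micrometers (y flipped to point up)
px_axes <- function(meta) {
  px <- meta$pixel_size_um
  list(x = (seq_len(meta$shape_px[2]) - 0.5) * px,
       y = (meta$shape_px[1] - seq_len(meta$shape_px[1]) + 0.5) * px)
}

# Paint a dark capsule (rod) into a normalized [0,1] intensity matrix.
# center in um (analysis frame), theta = axis orientation, length_um is the
# tip-to-tip length. Soft one-pixel edge; overlapping rods keep the darker
# value. Returns the modified matrix, or signals an out-of-field error.
paint_capsule <- function(img, axes, center, theta, length_um, width_um,
                          fg, frame_idx) {
  px <- axes$x[2] - axes$x[1]
  half <- (length_um - width_um) / 2
  u <- c(cos(theta), sin(theta))
  reach <- half + width_um / 2 + px
  lims <- c(min(axes$x) - px / 2, max(axes$x) + px / 2,
            min(axes$y) - px / 2, max(axes$y) + px / 2)
  if (center[1] - reach < lims[1] || center[1] + reach > lims[2] ||
      center[2] - reach < lims[3] || center[2] + reach > lims[4])
    abort_param("rendered cell leaves the field of view at frame ", frame_idx)
  ci <- which(axes$x >= center[1] - reach & axes$x <= center[1] + reach)
  ri <- which(axes$y >= center[2] - reach & axes$y <= center[2] + reach)
  if (!length(ci) || !length(ri)) return(img)
  dx <- outer(axes$y[ri] - center[2], axes$x[ci] - center[1],
              function(yy, xx) xx)          # col offsets
  dy <- outer(axes$y[ri] - center[2], axes$x[ci] - center[1],
              function(yy, xx) yy)
  tpar <- pmin(pmax(dx * u[1] + dy * u[2], -half), half)  # nearest axis point
  d <- sqrt((dx - tpar * u[1])^2 + (dy - tpar * u[2])^2)
  cov <- pmin(pmax(0.5 - (d - width_um / 2) / px, 0), 1)
  sub <- img[ri, ci, drop = FALSE]
  img[ri, ci] <- pmin(sub, sub - (sub - fg) * cov)
  img
}

quantize_stack <- function(norm_frames, meta) {
  maxval <- 2^meta$bit_depth - 1
  arr <- array(0L, dim = dim(norm_frames))
  arr[] <- as.integer(pmin(pmax(round(norm_frames * maxval), 0), maxval))
  video_stack(meta, arr)
}

#' Render a synthetic tethered-cell rotation video
#'
#' A dark rod rotates rigidly about a fixed tether point at the field
#' center, with its long axis through the tether and its centroid offset by
#' `tether_offset_um`. Frame `t` has rod orientation
#' `theta0 + 2*pi*signed_freq_hz*t` (positive = CCW in the analysis frame).
#'
#' @param cell_length_um,cell_width_um rod geometry (tip-to-tip length).
#' @param signed_freq_hz signed rotation frequency; must satisfy the
#'   Nyquist margin `|f| <= 0.25 / frame_interval_s`.
#' @param tether_offset_um distance from rod centroid to tether point.
#' @param meta a [video_meta()].
#' @param noise_sd Gaussian pixel noise, as a fraction of the dynamic range
#'   (default 0.05).
#' @param theta0 initial orientation (radians).
#' @param seed RNG seed.
#' @return list with `video` (a `video_stack`) and `truth` (a
#'   `ground_truth` holding the exact [angular_trace()]).
#' @export
#' @examples
#' vt <- render_tethered_video(signed_freq_hz = 1,
#'   meta = video_meta(n_frames = 15, shape_px = c(96, 96)), seed = 1)
#' vt$truth$angle_trace$theta_rad[1:3]
render_tethered_video <- function(cell_length_um = 5, cell_width_um = 0.7,
                                  signed_freq_hz = 1.3, tether_offset_um = 1,
                                  meta = video_meta(n_frames = 150L,
                                                    shape_px = c(128L, 128L)),
                                  noise_sd = 0.05, theta0 = 0, seed = 1L) {
  if (abs(signed_freq_hz) > 0.25 / meta$frame_interval_s)
    abort_param("signed_freq_hz beyond the Nyquist margin of ",
                format(0.25 / meta$frame_interval_s), " Hz")
  axes <- px_axes(meta)
  tether <- c(mean(range(axes$x)), mean(range(axes$y)))
  times <- (seq_len(meta$n_frames) - 1L) * meta$frame_interval_s
  theta <- theta0 + 2 * pi * signed_freq_hz * times
  set.seed(seed)
  frames <- array(0, dim = c(meta$shape_px, meta$n_frames))
  for (f in seq_len(meta$n_frames)) {
    img <- matrix(0.85, meta$shape_px[1], meta$shape_px[2])
    center <- tether + tether_offset_um * c(cos(theta[f]), sin(theta[f]))
    img <- paint_capsule(img, axes, center, theta[f], cell_length_um,
                         cell_width_um, fg = 0.2, frame_idx = f)
    frames[, , f] <- img + rnorm(length(img), 0, noise_sd)
  }
  truth <- structure(list(
    kind = "tethered",
    angle_trace = angular_trace(times, theta, center_xy_um = tether,
                                radius_um = tether_offset_um),
    tracks = NULL,
    params = list(cell_length_um = cell_length_um,
                  cell_width_um = cell_width_um,
                  signed_freq_hz = signed_freq_hz,
                  tether_offset_um = tether_offset_um,
                  noise_sd = noise_sd, theta0 = theta0, seed = seed)
  ), class = "ground_truth")
  list(video = quantize_stack(frames, meta), truth = truth)
}

#' Render a synthetic gliding-motility video
#'
#' Each input track is rendered as a moving dark rod oriented along its
#' instantaneous velocity; the ground truth echoes the input tracks.
#'
#' @param tracks list of tracks (positions in micrometers, analysis frame).
#' @param cell_length_um,cell_width_um rod geometry.
#' @param meta a [video_meta()].
#' @param noise_sd Gaussian noise (fraction of dynamic range).
#' @param seed RNG seed.
#' @return list with `video` and `truth`.
#' @export
render_gliding_video <- function(tracks, cell_length_um = 5,
                                 cell_width_um = 0.7,
                                 meta = video_meta(n_frames = 150L,
                                                   shape_px = c(256L, 256L)),
                                 noise_sd = 0.05, seed = 1L) {
  times <- (seq_len(meta$n_frames) - 1L) * meta$frame_interval_s
  axes <- px_axes(meta)
  pos <- lapply(tracks, function(tr) {
    list(x = approx(tr$t_s, tr$x_um, xout = times, rule = 2)$y,
         y = approx(tr$t_s, tr$y_um, xout = times, rule = 2)$y)
  })
  set.seed(seed)
  frames <- array(0, dim = c(meta$shape_px, meta$n_frames))
  thetas <- lapply(pos, function(p) {
    vx <- c(diff(p$x), 0); vy <- c(diff(p$y), 0)
    th <- atan2(vy, vx)
    sp <- sqrt(vx^2 + vy^2)
    for (k in seq_along(th)[-1]) if (sp[k] < 1e-9) th[k] <- th[k - 1]
    if (length(th) > 1 && sp[1] < 1e-9) th[1] <- th[2]
    th
  })
  for (f in seq_len(meta$n_frames)) {
    img <- matrix(0.85, meta$shape_px[1], meta$shape_px[2])
    for (k in seq_along(pos)) {
      img <- paint_capsule(img, axes, c(pos[[k]]$x[f], pos[[k]]$y[f]),
                           thetas[[k]][f], cell_length_um, cell_width_um,
                           fg = 0.2, frame_idx = f)
    }
    frames[, , f] <- img + rnorm(length(img), 0, noise_sd)
  }
  truth <- structure(list(kind = "gliding", angle_trace = NULL,
                          tracks = tracks,
                          params = list(cell_length_um = cell_length_um,
                                        cell_width_um = cell_width_um,
                                        noise_sd = noise_sd, seed = seed)),
                     class = "ground_truth")
  list(video = quantize_stack(frames, meta), truth = truth)
}

# Closed stadium path (capsule midline perimeter) as an arc-length
# parameterized polyline, vertex spacing <= 0.05 um. Returns interpolation
# tables x(s), y(s) with s in [0, perimeter].
stadium_path <- function(cell_length_um, cell_width_um, center, ds = 0.05) {
  a <- (cell_length_um - cell_width_um) / 2
  r <- cell_width_um / 2
  perim <- 4 * a + 2 * pi * r
  s <- seq(0, perim, by = ds)
  if (tail(s, 1) < perim) s <- c(s, perim)
  seg <- function(si) {
    if (si <= 2 * a) c(-a + si, r)                        # top edge ->
    else if (si <= 2 * a + pi * r) {
      phi <- pi / 2 - (si - 2 * a) / r                    # right cap
      c(a + r * cos(phi), r * sin(phi))
    } else if (si <= 4 * a + pi * r) c(a - (si - 2 * a - pi * r), -r)
    else {
      phi <- -pi / 2 - (si - 4 * a - pi * r) / r          # left cap
      c(-a + r * cos(phi), r * sin(phi))
    }
  }
  xy <- vapply(s, seg, numeric(2))
  list(s = s, x = xy[1, ] + center[1], y = xy[2, ] + center[2],
       perimeter = perim)
}

#' Render a synthetic conveyor-belt spot video
#'
#' A diffraction-limited fluorescent spot (2D Gaussian, sd `psf_sigma_um`)
#' travels along the closed stadium path of an elongated cell at constant
#' speed, wrapping at the path end (`mode = "loop"`), or bounces back and
#' forth within a short segment of the path (`mode = "oscillate"`,
#' mimicking trajectories of a disrupted belt). Poisson photon noise.
#'
#' @param cell_length_um,cell_width_um capsule geometry of the elongated
#'   (cephalexin-like) cell.
#' @param belt_speed_um_s spot speed along the path.
#' @param meta a [video_meta()] (16-bit recommended).
#' @param psf_sigma_um PSF standard deviation; a warning is logged when
#'   below half the pixel size (undersampled PSF).
#' @param photon_level expected total photons in the spot per frame.
#' @param bg_photons expected background photons per pixel.
#' @param mode `"loop"` or `"oscillate"`.
#' @param osc_segment_um length of the bounce segment in oscillate mode.
#' @param s0 starting arc-length position (um).
#' @param seed RNG seed.
#' @return list with `video` and `truth` (ground-truth spot track).
#' @export
render_spot_video <- function(cell_length_um = 10, cell_width_um = 0.5,
                              belt_speed_um_s = 2,
                              meta = video_meta(n_frames = 300L,
                                                shape_px = c(64L, 128L),
                                                bit_depth = 16L),
                              psf_sigma_um = 0.15, photon_level = 2000,
                              bg_photons = 10, mode = c("loop", "oscillate"),
                              osc_segment_um = 1, s0 = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (psf_sigma_um < meta$pixel_size_um / 2)
    warning("undersampled PSF: psf_sigma_um < pixel_size_um / 2")
  axes <- px_axes(meta)
  center <- c(mean(range(axes$x)), mean(range(axes$y)))
  path <- stadium_path(cell_length_um, cell_width_um, center)
  reach <- cell_length_um / 2 + 3 * psf_sigma_um
  if (center[1] - reach < min(axes$x) || center[1] + reach > max(axes$x) ||
      center[2] - cell_width_um / 2 - 3 * psf_sigma_um < min(axes$y))
    abort_param("belt path does not fit the field of view")
  times <- (seq_len(meta$n_frames) - 1L) * meta$frame_interval_s
  s <- if (mode == "loop") {
    (s0 + belt_speed_um_s * times) %% path$perimeter
  } else {
    tri <- abs(((s0 + belt_speed_um_s * times) %% (2 * osc_segment_um)) -
                 osc_segment_um)
    (s0 + tri) %% path$perimeter
  }
  sx <- approx(path$s, path$x, xout = s)$y
  sy <- approx(path$s, path$y, xout = s)$y
  set.seed(seed)
  px <- meta$pixel_size_um
  amp <- photon_level * px^2 / (2 * pi * psf_sigma_um^2)
  frames <- array(0L, dim = c(meta$shape_px, meta$n_frames))
  maxval <- 2^meta$bit_depth - 1
  for (f in seq_len(meta$n_frames)) {
    gx <- exp(-(axes$x - sx[f])^2 / (2 * psf_sigma_um^2))
    gy <- exp(-(axes$y - sy[f])^2 / (2 * psf_sigma_um^2))
    lambda <- bg_photons + amp * outer(gy, gx)
    frames[, , f] <- pmin(rpois(length(lambda), lambda), maxval)
  }
  truth <- structure(list(
    kind = "spot", angle_trace = NULL,
    tracks = list(track(times, sx, sy, track_id = "spot", source = "spot")),
    params = list(cell_length_um = cell_length_um,
                  cell_width_um = cell_width_um,
                  belt_speed_um_s = belt_speed_um_s,
                  psf_sigma_um = psf_sigma_um, photon_level = photon_level,
                  bg_photons = bg_photons, mode = mode,
                  osc_segment_um = osc_segment_um, s0 = s0, seed = seed,
                  perimeter_um = path$perimeter)
  ), class = "ground_truth")
  list(video = video_stack(meta, frames), truth = truth)
}
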