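# TIRF spot detection and conveyor-belt trajectory shape classification.

# Separable Gaussian blur via banded convolution matrices; edges use a
# truncated, renormalized kernel.
blur_matrix <- function(n, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-h:h, sd = sigma)
  m <- matrix(0, n, n)
  for (j in -h:h) {
    i <- seq_len(n)
    ok <- i + j >= 1L & i + j <= n
    m[cbind(i[ok], (i + j)[ok])] <- k[j + h + 1L]
  }
  m / rowSums(m)
}

gaussian_blur <- function(img, sigma_px) {
  blur_matrix(nrow(img), sigma_px) %*% img %*% t(blur_matrix(ncol(img), sigma_px))
}

#' Detect diffraction-limited spots in one frame
#'
#' Band-pass by difference of Gaussians (sigma and 3*sigma), candidate
#' maxima above `median + snr_threshold * MAD` of the band-passed image,
#' 8-neighborhood local maxima, and subpixel localization by
#' intensity-weighted centroid in a window of about `4*sigma + 1` pixels.
#' Candidates must additionally carry the integrated band-passed mass of a
#' PSF-sized object (at least `snr_threshold * MAD * 4*pi*sigma_px^2`, the
#' mass of a just-detectable Gaussian spot), which rejects single
#' correlated-noise spikes that clear the peak threshold. Saturated frames
#' (any pixel at the bit-depth ceiling) are flagged in the `saturated`
#' attribute of the result.
#'
#' @param frame integer intensity matrix (one video frame).
#' @param meta the [video_meta()] carrying pixel size and bit depth.
#' @param psf_sigma_um expected PSF standard deviation (um).
#' @param snr_threshold detection threshold in MAD units (default 5).
#' @return data.frame with `x_um`, `y_um`, `intensity`, `snr` (possibly
#'   zero rows).
#' @export
detect_spots <- function(frame, meta, psf_sigma_um = 0.15, snr_threshold = 5) {
  stopifnot(inherits(meta, "video_meta"))
  sig <- psf_sigma_um / meta$pixel_size_um
  img <- matrix(as.numeric(frame), nrow(frame), ncol(frame))
  dog <- gaussian_blur(img, sig) - gaussian_blur(img, 3 * sig)
  med <- median(dog); s <- mad(dog)
  if (s == 0) s <- .Machine$double.eps
  thr <- med + snr_threshold * s
  nr <- nrow(dog); nc <- ncol(dog)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dog
  is_max <- dog > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & dog >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  peaks <- which(is_max, arr.ind = TRUE)
  axes <- px_axes(meta)
  w <- max(2L, round(2 * sig))
  out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                    intensity = numeric(0), snr = numeric(0))
  bg <- median(img)
  for (k in seq_len(nrow(peaks))) {
    r0 <- peaks[k, 1]; c0 <- peaks[k, 2]
    rr <- max(1L, r0 - w):min(nr, r0 + w)
    cc <- max(1L, c0 - w):min(nc, c0 + w)
    wt <- pmax(dog[rr, cc, drop = FALSE], 0)
    if (sum(wt) < snr_threshold * s * 4 * pi * sig^2) next
    xs <- sum(t(t(wt) * axes$x[cc])) / sum(wt)
    ys <- sum(wt * axes$y[rr]) / sum(wt)
    out[nrow(out) + 1L, ] <- c(xs, ys, sum(pmax(img[rr, cc] - bg, 0)),
                               (dog[r0, c0] - med) / s)
  }
  attr(out, "saturated") <- any(frame >= 2^meta$bit_depth - 1)
  out
}

#' Detect spots across a whole video stack
#'
#' Applies [detect_spots()] per frame and returns a detection table ready
#' for [link_tracks()].
#'
#' @param video a `video_stack`.
#' @inheritParams detect_spots
#' @return data.frame with `frame`, `t_s`, `x_um`, `y_um`, `intensity`,
#'   `snr`.
#' @export
detect_spots_stack <- function(video, psf_sigma_um = 0.15, snr_threshold = 5) {
  stopifnot(inherits(video, "video_stack"))
  meta <- video$meta
  rows <- lapply(seq_len(meta$n_frames), function(f) {
    d <- detect_spots(video$frames[, , f], meta, psf_sigma_um, snr_threshold)
    if (!nrow(d)) return(NULL)
    cbind(frame = f - 1L, t_s = (f - 1L) * meta$frame_interval_s, d)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(frame = integer(0), t_s = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), intensity = numeric(0),
                      snr = numeric(0)))
  do.call(rbind, rows)
}

#' Mean spot speed along the belt
#'
#' Identical contract and implementation as [track_speed()] (shared
#' smoothing and gap handling); provided under the assay's own name.
#'
#' @inheritParams track_speed
#' @return mean speed in um/s.
#' @export
spot_speed <- function(track, smooth_window_frames = 5L) {
  track_speed(track, smooth_window_frames)
}

# 1D arc-length position along the dominant PCA axis (documented
# approximation of the belt coordinate for non-looped tracks)
principal_projection <- function(track) {
  xy <- cbind(track$x_um, track$y_um)
  xy <- sweep(xy, 2, colMeans(xy))
  v <- svd(xy, nu = 0, nv = 1)$v[, 1]
  drop(xy %*% v)
}

count_direction_reversals <- function(s, min_excursion_um = 0.15) {
  # sign changes of motion along s, ignoring sub-threshold jitter
  n <- 0L; dir <- 0; ref <- s[1]
  for (v in s[-1]) {
    d <- v - ref
    if (abs(d) >= min_excursion_um) {
      newdir <- sign(d)
      if (dir != 0 && newdir != dir) n <- n + 1L
      dir <- newdir
      ref <- v
    } else if (dir != 0 && sign(d) == dir && abs(d) > 0) {
      ref <- v   # keep tracking the running extreme
    }
  }
  n
}

#' Classify the shape of a belt trajectory
#'
#' `looped`: the track returns within `loop_closure_um` of a previously
#' visited point after traversing at least half the estimated cell
#' perimeter (closed conveyor belt looping around the poles).
#' `oscillatory`: at least `reversal_count_threshold` direction reversals
#' along the dominant PCA axis with confinement ratio (net displacement /
#' path length) below 0.2 (short back-and-forth trajectories of a
#' disrupted belt). Otherwise `extended`. The cell perimeter is estimated
#' from the track extents along its principal axes (stadium outline).
#'
#' @param track a track with at least 10 samples.
#' @param loop_closure_um closure tolerance (default 0.5 um).
#' @param reversal_count_threshold reversals needed for `oscillatory`.
#' @return a `shape_class` list: `label`, `confinement_ratio`,
#'   `n_direction_reversals`.
#' @export
classify_shape <- function(track, loop_closure_um = 0.5,
                           reversal_count_threshold = 3L) {
  if (nrow(track) < 10L) abort_param("need at least 10 samples to classify")
  xy <- cbind(track$x_um, track$y_um)
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr, nu = 0, nv = 2)
  proj <- ctr %*% sv$v
  ext <- apply(proj, 2, function(p) diff(range(p)))
  perimeter_est <- 2 * max(ext[1] - ext[2], 0) + pi * ext[2]
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  cum <- c(0, cumsum(steps))
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  confinement <- if (cum[length(cum)] > 0) net / cum[length(cum)] else 0
  s1 <- drop(ctr %*% sv$v[, 1])
  nrev <- count_direction_reversals(s1)

  # A loop needs (a) a revisit within loop_closure_um after at least half
  # the estimated perimeter of path, and (b) genuine transverse extent of
  # the connecting path (> loop_closure_um / 2) so a 1D back-and-forth
  # retrace does not count as a loop.
  looped <- FALSE
  n <- nrow(xy)
  for (j in seq_len(n)) {
    prior <- which(cum[j] - cum >= perimeter_est / 2)
    if (length(prior)) {
      d2 <- (xy[prior, 1] - xy[j, 1])^2 + (xy[prior, 2] - xy[j, 2])^2
      for (i in prior[d2 <= loop_closure_um^2]) {
        seg <- ctr[i:j, , drop = FALSE]
        seg <- sweep(seg, 2, colMeans(seg))
        minor <- min(apply(seg %*% svd(seg, nu = 0, nv = 2)$v, 2,
                           function(p) diff(range(p))))
        if (minor > loop_closure_um / 2) { looped <- TRUE; break }
      }
      if (looped) break
    }
  }
  label <- if (looped) "looped"
  else if (nrev >= reversal_count_threshold && confinement < 0.2) "oscillatory"
  else "extended"
  structure(list(label = label,
                 confinement_ratio = min(max(confinement, 0), 1),
                 n_direction_reversals = nrev),
            class = "shape_class")
}
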