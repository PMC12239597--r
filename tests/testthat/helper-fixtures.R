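# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_meta <- function(n_frames = 75L, shape = c(96L, 96L), bit_depth = 8L,
                      fps = 15) {
  video_meta(pixel_size_um = 0.1, frame_interval_s = 1 / fps,
             n_frames = n_frames, shape_px = shape, bit_depth = bit_depth)
}

# detections = ground-truth track positions + localization noise
noisy_detections <- function(tr, sd_um = 0.05, seed = 1L) {
  set.seed(seed)
  data.frame(frame = seq_len(nrow(tr)) - 1L, t_s = tr$t_s,
             x_um = tr$x_um + rnorm(nrow(tr), 0, sd_um),
             y_um = tr$y_um + rnorm(nrow(tr), 0, sd_um))
}

# straight run at constant speed with localization noise
straight_noisy_track <- function(speed, duration_s = 60, fps = 15,
                                 sd_um = 0.05, seed = 1L) {
  t <- seq(0, duration_s, by = 1 / fps)
  set.seed(seed)
  th <- runif(1, -pi, pi)
  track(t, speed * t * cos(th) + rnorm(length(t), 0, sd_um),
        speed * t * sin(th) + rnorm(length(t), 0, sd_um),
        track_id = seed, source = "cell")
}

longest_track <- function(tracks) tracks[[which.max(vapply(tracks, nrow, integer(1)))]]

# direct pairwise-count Mann-Whitney U (independent of the rank-sum code)
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# full-enumeration two-tailed Mann-Whitney p-value on the raw data
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) brute_u(pooled[ii], pooled[-ii]))
  u_obs <- brute_u(x, y)
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# brute-force minimum-cost assignment between <= 5 heads and detections
brute_assignment_cost <- function(heads, dets, max_jump) {
  n <- nrow(heads); m <- nrow(dets)
  d <- sqrt(outer(heads[, 1], dets[, 1], "-")^2 +
              outer(heads[, 2], dets[, 2], "-")^2)
  d[d > max_jump] <- NA
  k <- min(n, m)
  best <- Inf; best_links <- -1L
  # enumerate all injective partial assignments via recursion
  rec <- function(i, used, cost, links) {
    if (i > n) {
      if (links > best_links || (links == best_links && cost < best)) {
        best <<- cost; best_links <<- links
      }
      return()
    }
    rec(i + 1L, used, cost, links)          # head i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && !is.na(d[i, j])) {
        used[j] <- TRUE
        rec(i + 1L, used, cost + d[i, j], links + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0, 0L)
  list(cost = best, links = best_links)
}
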