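# Track container and CSV interchange.
#
# A track is a data.frame with columns t_s, x_um, y_um (and optionally
# intensity), plus attributes track_id and source. Micrometers and seconds
# everywhere; pixels exist only inside the imaging modules.

#' Construct a track
#'
#' @param t_s numeric vector of sample times (seconds), strictly increasing.
#' @param x_um,y_um numeric coordinates in micrometers.
#' @param intensity optional per-sample intensity.
#' @param track_id identifier (integer or character).
#' @param source one of `"cell"`, `"spot"`, `"simulated"`.
#' @return a `gearbelt_track` data.frame.
#' @export
#' @examples
#' tr <- track(t_s = 0:9 / 15, x_um = seq(0, 1.2, length.out = 10), y_um = rep(0, 10))
#' path_length(tr)
track <- function(t_s, x_um, y_um, intensity = NULL, track_id = 1L,
                  source = c("cell", "spot", "simulated")) {
  source <- match.arg(source)
  if (length(t_s) != length(x_um) || length(t_s) != length(y_um))
    abort_param("track coordinates and times must have equal length")
  if (length(t_s) >= 2L && any(diff(t_s) <= 0))
    abort_param("track times must be strictly increasing")
  df <- data.frame(t_s = as.numeric(t_s), x_um = as.numeric(x_um),
                   y_um = as.numeric(y_um))
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  structure(df, track_id = track_id, source = source,
            class = c("gearbelt_track", "data.frame"))
}

#' @export
print.gearbelt_track <- function(x, ...) {
  cat(sprintf("<track %s> %d samples over %.2f s (%s)\n",
              attr(x, "track_id"), nrow(x),
              if (nrow(x)) diff(range(x$t_s)) else 0, attr(x, "source")))
  invisible(x)
}

#' Total path length of a track
#'
#' Sum of Euclidean step lengths, in micrometers.
#'
#' @param track a track (see [track()]).
#' @return numeric scalar, micrometers.
#' @export
path_length <- function(track) {
  if (nrow(track) < 2L) return(0)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Write tracks to the shared Track CSV format
#'
#' Columns: `track_id, frame, t_s, x_um, y_um[, intensity]`, full float
#' precision, one header comment line carrying the schema version.
#'
#' @param tracks a single track or a list of tracks.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "gearbelt_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    df <- as.data.frame(tr)
    df$track_id <- attr(tr, "track_id")
    df$frame <- seq_len(nrow(df)) - 1L
    cols <- c("track_id", "frame", "t_s", "x_um", "y_um",
              intersect("intensity", names(df)))
    df[, cols]
  })
  has_int <- vapply(rows, function(d) "intensity" %in% names(d), logical(1))
  if (any(has_int) && !all(has_int))
    rows <- lapply(rows, function(d) { if (!"intensity" %in% names(d)) d$intensity <- NA_real_; d })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gearbelt track csv v1", con)
  write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from the shared Track CSV format
#'
#' @param path file written by [write_tracks_csv()] (or any CSV with the
#'   same columns; `#` lines are ignored).
#' @param source source tag applied to the returned tracks.
#' @return list of tracks, in order of first appearance of each `track_id`.
#' @export
read_tracks_csv <- function(path, source = "cell") {
  df <- read.csv(path, comment.char = "#")
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    abort_param("track CSV ", path, " missing columns: ",
                paste(setdiff(need, names(df)), collapse = ", "))
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    d <- df[df$track_id == id, , drop = FALSE]
    track(d$t_s, d$x_um, d$y_um,
          intensity = if ("intensity" %in% names(d) && !all(is.na(d$intensity))) d$intensity,
          track_id = id, source = source)
  })
}
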