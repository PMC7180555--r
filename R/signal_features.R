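# Signal preprocessing: smoothing, sliding-window segmentation, and the
# per-window statistical feature battery.

#' Segmentation configuration
#'
#' @param window_seconds Window length in seconds (common choices: 2 s at
#'   50 Hz, 5 s at 25 Hz).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`; 0.5 halves the stride.
#' @param smoothing_width Moving-average filter width in samples; positive
#'   odd integer.
#' @return An object of class `comeal_segmentation_config`.
#' @export
segmentation_config <- function(window_seconds = 2, overlap_fraction = 0.5,
                                smoothing_width = 5) {
  check_positive(window_seconds, "window_seconds")
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      is.na(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_config("overlap_fraction must lie in [0, 1)")
  }
  if (!is.numeric(smoothing_width) || length(smoothing_width) != 1L ||
      smoothing_width < 1 || smoothing_width %% 2 != 1) {
    stop_config("smoothing_width must be a positive odd integer")
  }
  structure(
    list(window_seconds = window_seconds,
         overlap_fraction = overlap_fraction,
         smoothing_width = as.integer(smoothing_width)),
    class = "comeal_segmentation_config"
  )
}

#' Centered moving average with truncated edges
#'
#' Per-channel centered moving mean of width `width`; edge windows are
#' truncated to the available samples (so a constant signal stays constant
#' and `width = 1` is the identity).
#'
#' @param signal Numeric vector or time-by-channels matrix.
#' @param width Positive odd integer, at most the signal length.
#' @return Smoothed signal, same shape as the input.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
moving_average <- function(signal, width) {
  if (!is.numeric(width) || length(width) != 1L || width < 1 ||
      width %% 2 != 1) {
    stop_input("width must be a positive odd integer")
  }
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, ncol = 1L) else as.matrix(signal)
  if (width > nrow(x)) stop_input("width exceeds signal length")
  out <- apply(x, 2L, function(col) {
    zoo::rollapply(col, width, mean, partial = TRUE, align = "center")
  })
  out <- matrix(out, nrow = nrow(x), ncol = ncol(x),
                dimnames = dimnames(x))
  if (vec) drop(out) else out
}

#' Segment a stream into overlapping windows
#'
#' Window length `W = round(window_seconds * sampling_hz)`, stride
#' `S = round(W * (1 - overlap_fraction))` (at least 1). Windows start at
#' sample offsets 0, S, 2S, ...; a trailing partial window is discarded.
#' Each window's label is the majority of its sample labels; windows whose
#' majority is tied are discarded (activity-boundary windows carry label
#' noise).
#'
#' @param stream A `comeal_stream`.
#' @param cfg A [segmentation_config()].
#' @return A list of windows, each a list with `samples` (W-by-channels
#'   matrix), `label`, `window_index` (position in the start-offset grid)
#'   and `start` (1-based sample index). Streams shorter than one window
#'   yield an empty list.
#' @export
segment <- function(stream, cfg) {
  if (!inherits(stream, "comeal_stream")) stop_input("not a comeal_stream")
  if (!inherits(cfg, "comeal_segmentation_config")) {
    stop_input("cfg must be a segmentation_config()")
  }
  n <- nrow(stream$samples)
  w <- round(cfg$window_seconds * stream$sampling_hz)
  if (w < 1) stop_config("window shorter than one sample")
  if (n < w) return(list())
  s <- max(1L, round(w * (1 - cfg$overlap_fraction)))
  starts <- seq(1L, n - w + 1L, by = s)
  out <- list()
  for (i in seq_along(starts)) {
    rows <- starts[i] + seq_len(w) - 1L
    labs <- stream$labels[rows]
    tab <- table(labs)
    top <- max(tab)
    if (sum(tab == top) > 1L) next   # tied majority: discard window
    out[[length(out) + 1L]] <- list(
      samples = stream$samples[rows, , drop = FALSE],
      label = names(tab)[which.max(tab)],
      window_index = i,
      start = starts[i]
    )
  }
  out
}

# Zero-crossing count of the mean-removed signal: sign changes between
# consecutive samples, exact zeros carrying no sign.
zero_crossings <- function(x) {
  s <- sign(x - mean(x))
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Extract the statistical feature vector of one window
#'
#' Per channel, in fixed order: mean, standard deviation, minimum, maximum,
#' median, root-mean-square, interquartile range, and the zero-crossing
#' count of the mean-removed channel. Channel blocks are concatenated
#' channel-major, so `q = 8 * channels`.
#'
#' @param window Numeric matrix (samples by channels) or vector (one
#'   channel); all values must be finite.
#' @return Named numeric vector `f1..fq`.
#' @export
#' @examples
#' extract_features(matrix(c(-1, 1, -1, 1), ncol = 1))
extract_features <- function(window) {
  x <- if (is.null(dim(window))) matrix(window, ncol = 1L) else as.matrix(window)
  if (nrow(x) == 0L) stop_input("window is empty")
  if (!all(is.finite(x))) stop_input("window contains non-finite values")
  feats <- unlist(lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    c(mean(v),
      if (length(v) > 1L) sd(v) else 0,
      min(v),
      max(v),
      median(v),
      sqrt(mean(v^2)),
      unname(quantile(v, 0.75) - quantile(v, 0.25)),
      zero_crossings(v))
  }))
  names(feats) <- paste0("f", seq_along(feats))
  feats
}

#' Full stream-to-features pipeline
#'
#' Smooths a stream with [moving_average()], segments it with [segment()],
#' and extracts per-window features with [extract_features()].
#'
#' @param stream A `comeal_stream`.
#' @param cfg A [segmentation_config()].
#' @return A feature table: columns `f1..fq`, `label`, `subject`,
#'   `location`, `window_index`. Zero rows if the stream is shorter than one
#'   window.
#' @export
stream_features <- function(stream, cfg = segmentation_config()) {
  smoothed <- stream
  smoothed$samples <- moving_average(stream$samples, cfg$smoothing_width)
  wins <- segment(smoothed, cfg)
  if (length(wins) == 0L) {
    return(data.frame(label = character(0), subject = character(0),
                      location = character(0), window_index = integer(0)))
  }
  feats <- do.call(rbind, lapply(wins, function(w) extract_features(w$samples)))
  out <- as.data.frame(feats)
  out$label <- vapply(wins, `[[`, "", "label")
  out$subject <- stream$subject_id
  out$location <- stream$location_id
  out$window_index <- vapply(wins, `[[`, 0L, "window_index")
  out
}

#' Feature tables for every stream of a world
#'
#' @param world A `comeal_world`.
#' @param cfg A [segmentation_config()].
#' @return One feature table covering all (subject, location) streams.
#' @export
world_features <- function(world, cfg = segmentation_config()) {
  if (!inherits(world, "comeal_world")) stop_input("not a comeal_world")
  out <- do.call(rbind, lapply(world$streams, stream_features, cfg = cfg))
  rownames(out) <- NULL
  out
}
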