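# Synthetic multi-subject, multi-location sensor worlds.
#
# Every algorithm in the package is exercised on worlds produced here, so the
# generator is first-class code: deterministic given (config, seed), with
# inter-subject distribution shift and noise as explicit knobs.

#' World configuration for the synthetic sensor generator
#'
#' Describes a synthetic sensing study: how many subjects wear how many
#' sensors, which activity classes occur, at what sampling rate, and how
#' strongly subjects differ from one another.
#'
#' @param n_subjects Number of subjects (source and target contexts).
#' @param n_locations Number of body locations (sensors) per subject.
#' @param label_set Character vector of activity class ids, no duplicates,
#'   at least two.
#' @param sampling_hz Sampling frequency in Hz.
#' @param seconds_per_activity Duration of each activity bout, in seconds.
#' @param channels_per_location Number of signal channels per sensor
#'   (e.g. 3 for a tri-axial accelerometer).
#' @param subject_shift_scale Nonnegative scale of the per-subject affine
#'   distribution shift (0 = all subjects identical).
#' @param noise_scale Nonnegative scale of additive Gaussian sensor noise.
#' @param seed Integer root seed; all randomness flows from it through named
#'   substreams (world / split / experts).
#'
#' @return An object of class `comeal_world_config`.
#' @export
#' @examples
#' cfg <- world_config(n_subjects = 2, n_locations = 1,
#'                     label_set = c("walk", "sit"))
world_config <- function(n_subjects = 3,
                         n_locations = 1,
                         label_set = c("walk", "run", "sit", "stairs"),
                         sampling_hz = 50,
                         seconds_per_activity = 10,
                         channels_per_location = 3,
                         subject_shift_scale = 0.1,
                         noise_scale = 0.05,
                         seed = 1L) {
  check_positive(n_subjects, "n_subjects")
  check_positive(n_locations, "n_locations")
  check_positive(sampling_hz, "sampling_hz")
  check_positive(seconds_per_activity, "seconds_per_activity")
  check_positive(channels_per_location, "channels_per_location")
  check_nonnegative(subject_shift_scale, "subject_shift_scale")
  check_nonnegative(noise_scale, "noise_scale")
  label_set <- as.character(label_set)
  if (anyDuplicated(label_set)) stop_config("label_set has duplicate labels")
  if (length(label_set) < 2L) stop_config("label_set needs at least 2 labels")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_locations = as.integer(n_locations),
         label_set = label_set,
         sampling_hz = sampling_hz,
         seconds_per_activity = seconds_per_activity,
         channels_per_location = as.integer(channels_per_location),
         subject_shift_scale = subject_shift_scale,
         noise_scale = noise_scale,
         seed = as.integer(seed)),
    class = "comeal_world_config"
  )
}

#' @export
print.comeal_world_config <- function(x, ...) {
  cat("Synthetic world config:", x$n_subjects, "subjects x",
      x$n_locations, "locations,", length(x$label_set), "activities (",
      paste(x$label_set, collapse = ", "), ")\n")
  cat("  sampling:", x$sampling_hz, "Hz,", x$seconds_per_activity,
      "s/activity,", x$channels_per_location, "channels/location\n")
  cat("  subject shift:", x$subject_shift_scale,
      " noise:", x$noise_scale, " seed:", x$seed, "\n")
  invisible(x)
}

# Base waveform parameters per (label, location, channel): a sum of 2-3
# sinusoids with label-specific frequencies/amplitudes plus a DC offset,
# mimicking periodic locomotion signals.
base_waveform_params <- function(cfg) {
  local_seed(substream_seed(cfg$seed, "world-base"), {
    out <- list()
    for (loc in seq_len(cfg$n_locations)) {
      for (lab in cfg$label_set) {
        for (ch in seq_len(cfg$channels_per_location)) {
          n_sin <- sample(2:3, 1L)
          out[[paste(lab, loc, ch, sep = "|")]] <- list(
            freq = runif(n_sin, 0.5, 3.5),
            amp = runif(n_sin, 0.4, 1.6),
            phase = runif(n_sin, 0, 2 * pi),
            dc = runif(1, -1, 1)
          )
        }
      }
    }
    out
  })
}

eval_waveform <- function(params, t) {
  y <- rep(params$dc, length(t))
  for (i in seq_along(params$freq)) {
    y <- y + params$amp[i] * sin(2 * pi * params$freq[i] * t + params$phase[i])
  }
  y
}

#' Generate a synthetic sensor world of raw streams
#'
#' Produces one multi-channel stream per (subject, location). Each activity
#' bout is a base waveform per (label, location) — a sum of 2–3 sinusoids
#' plus a DC offset — transformed by a subject-specific affine shift (gain in
#' `[1 - s, 1 + s]`, offset `N(0, s^2)` with `s = subject_shift_scale`) and
#' additive Gaussian noise scaled by `noise_scale`. Every stream contains
#' every label, in `label_set` order. Deterministic given the config seed.
#'
#' @param cfg A [world_config()].
#' @return An object of class `comeal_world`: a list with `streams` (a list
#'   of `comeal_stream` objects named `s<i>_l<j>`) and `config`.
#' @export
#' @examples
#' w <- generate_world(world_config(n_subjects = 2, seconds_per_activity = 1))
#' names(w$streams)
generate_world <- function(cfg) {
  if (!inherits(cfg, "comeal_world_config")) {
    stop_config("cfg must be a world_config()")
  }
  n_seg <- round(cfg$seconds_per_activity * cfg$sampling_hz)
  if (n_seg < 1) stop_config("window shorter than one sample")
  k <- length(cfg$label_set)
  n_total <- n_seg * k
  ch <- cfg$channels_per_location
  base <- base_waveform_params(cfg)
  t_seg <- (seq_len(n_seg) - 1) / cfg$sampling_hz

  # Per-subject affine shift parameters; drawn unconditionally so streams for
  # different shift scales share the same underlying draws.
  shift <- local_seed(substream_seed(cfg$seed, "world-shift"), {
    s <- list()
    for (su in seq_len(cfg$n_subjects)) {
      for (loc in seq_len(cfg$n_locations)) {
        for (c1 in seq_len(ch)) {
          s[[paste(su, loc, c1, sep = "|")]] <- c(u = runif(1, -1, 1),
                                                  z = rnorm(1))
        }
      }
    }
    s
  })

  streams <- list()
  for (su in seq_len(cfg$n_subjects)) {
    for (loc in seq_len(cfg$n_locations)) {
      noise <- local_seed(
        substream_seed(cfg$seed, paste0("world-noise-", su, "-", loc)),
        matrix(rnorm(n_total * ch), n_total, ch) * cfg$noise_scale
      )
      samples <- matrix(0, n_total, ch)
      colnames(samples) <- paste0("ch", seq_len(ch))
      labels <- rep(cfg$label_set, each = n_seg)
      for (li in seq_len(k)) {
        rows <- (li - 1L) * n_seg + seq_len(n_seg)
        for (c1 in seq_len(ch)) {
          p <- base[[paste(cfg$label_set[li], loc, c1, sep = "|")]]
          sh <- shift[[paste(su, loc, c1, sep = "|")]]
          gain <- 1 + cfg$subject_shift_scale * sh[["u"]]
          offset <- cfg$subject_shift_scale * sh[["z"]]
          samples[rows, c1] <- gain * eval_waveform(p, t_seg) + offset
        }
      }
      samples <- samples + noise
      streams[[paste0("s", su, "_l", loc)]] <- structure(
        list(subject_id = paste0("s", su),
             location_id = paste0("l", loc),
             sampling_hz = cfg$sampling_hz,
             samples = samples,
             labels = labels),
        class = "comeal_stream"
      )
    }
  }
  structure(list(streams = streams, config = cfg), class = "comeal_world")
}

#' @export
print.comeal_stream <- function(x, ...) {
  cat("Sensor stream", x$subject_id, "/", x$location_id, ":",
      nrow(x$samples), "samples x", ncol(x$samples), "channels @",
      x$sampling_hz, "Hz;", length(unique(x$labels)), "activities\n")
  invisible(x)
}

#' @export
print.comeal_world <- function(x, ...) {
  cat("Synthetic sensor world:", length(x$streams), "streams\n")
  print(x$config)
  invisible(x)
}

#' Generate a synthetic world directly in feature space
#'
#' A feature-space shortcut past the signal-processing pipeline: each
#' (subject, location, label) contributes `n_per_class` draws from a
#' q-dimensional Gaussian whose class centers are mutually `class_sep` apart
#' (scaled orthonormal directions when `q >= k`), displaced by a
#' subject-specific shift vector `N(0, subject_shift_scale^2 I)`.
#' Deterministic given the config seed.
#'
#' @param cfg A [world_config()]; `sampling_hz` etc. are ignored here.
#' @param q Feature dimension (positive integer).
#' @param n_per_class Instances per (subject, location, label).
#' @param class_sep Euclidean distance between class centers (exact when
#'   `q >= k`).
#' @param feature_sd Within-class standard deviation per dimension.
#' @return A data frame with columns `f1..fq`, `label`, `subject`,
#'   `location`.
#' @export
#' @examples
#' tab <- generate_feature_world(world_config(n_subjects = 2), q = 4,
#'                               n_per_class = 5)
#' head(tab)
generate_feature_world <- function(cfg, q = 6, n_per_class = 50,
                                   class_sep = 4, feature_sd = 1) {
  if (!inherits(cfg, "comeal_world_config")) {
    stop_config("cfg must be a world_config()")
  }
  if (!is.numeric(q) || length(q) != 1L || q < 1) {
    stop_config("q must be a positive integer")
  }
  q <- as.integer(q)
  check_positive(n_per_class, "n_per_class")
  check_nonnegative(class_sep, "class_sep")
  check_positive(feature_sd, "feature_sd")
  k <- length(cfg$label_set)

  centers <- local_seed(substream_seed(cfg$seed, "feat-means"), {
    out <- list()
    for (loc in seq_len(cfg$n_locations)) {
      if (q >= k) {
        b <- qr.Q(qr(matrix(rnorm(q * k), q, k)))     # orthonormal columns
        m <- t(b) * class_sep / sqrt(2)               # pairwise dist = sep
      } else {
        m <- matrix(rnorm(k * q), k, q)
        m <- m / sqrt(rowSums(m^2)) * class_sep / sqrt(2)
      }
      rownames(m) <- cfg$label_set
      out[[loc]] <- m
    }
    out
  })

  shifts <- local_seed(substream_seed(cfg$seed, "feat-shift"), {
    s <- list()
    for (su in seq_len(cfg$n_subjects)) {
      for (loc in seq_len(cfg$n_locations)) {
        s[[paste(su, loc, sep = "|")]] <- rnorm(q) * cfg$subject_shift_scale
      }
    }
    s
  })

  rows <- list()
  for (su in seq_len(cfg$n_subjects)) {
    for (loc in seq_len(cfg$n_locations)) {
      x <- local_seed(
        substream_seed(cfg$seed, paste0("feat-noise-", su, "-", loc)),
        matrix(rnorm(n_per_class * k * q), n_per_class * k, q) * feature_sd
      )
      mu <- centers[[loc]][rep(seq_len(k), each = n_per_class), , drop = FALSE]
      x <- x + mu + matrix(shifts[[paste(su, loc, sep = "|")]],
                           nrow(x), q, byrow = TRUE)
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(q))
      df$label <- rep(cfg$label_set, each = n_per_class)
      df$subject <- paste0("s", su)
      df$location <- paste0("l", loc)
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified split into expert-initialization and evaluation pools
#'
#' Splits a labeled feature table by label: for each label, a seeded shuffle
#' assigns `floor(ratio * n_label)` instances to the first (initialization)
#' pool and the remainder to the second (evaluation) pool. The two pools are
#' disjoint and together exhaust the input.
#'
#' @param x A labeled feature table (must have a `label` column).
#' @param ratio Fraction in (0, 1) assigned to the initialization pool.
#' @param seed Integer seed for the per-label shuffles.
#' @return A list with elements `init` and `eval`, both data frames.
#' @export
split_expert_initialization <- function(x, ratio = 0.5, seed = 1L) {
  if (is.null(x) || nrow(x) == 0L) stop_config("input is empty")
  if (!"label" %in% names(x)) stop_config("input has no label column")
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio <= 0 || ratio >= 1) {
    stop_config("ratio must lie strictly between 0 and 1")
  }
  take <- local_seed(substream_seed(seed, "split"), {
    idx <- integer(0)
    for (lab in unique(x$label)) {
      rows <- which(x$label == lab)
      n1 <- floor(ratio * length(rows))
      if (n1 > 0) idx <- c(idx, sample(rows, n1))
    }
    idx
  })
  list(init = x[sort(take), , drop = FALSE],
       eval = x[setdiff(seq_len(nrow(x)), take), , drop = FALSE])
}

#' Write a sensor world to per-stream CSV files
#'
#' One file per (subject, location), named `<subject>_<location>.csv`, with
#' header `timestamp,ch1..chC,label`; timestamps in seconds.
#'
#' @param world A `comeal_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sensor_streams <- function(world, dir) {
  if (!inherits(world, "comeal_world")) stop_input("not a comeal_world")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in world$streams) {
    df <- data.frame(
      timestamp = (seq_len(nrow(st$samples)) - 1) / st$sampling_hz,
      st$samples,
      label = st$labels
    )
    path <- file.path(dir, paste0(st$subject_id, "_", st$location_id, ".csv"))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a sensor stream written by [write_sensor_streams()]
#'
#' @param path CSV path with header `timestamp,ch1..chC,label`.
#' @param subject_id,location_id Provenance ids to attach.
#' @param sampling_hz Sampling rate; inferred from timestamps when `NULL`.
#' @return A `comeal_stream`.
#' @export
read_sensor_stream <- function(path, subject_id = NA_character_,
                               location_id = NA_character_,
                               sampling_hz = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) == 0L) stop_input("no channel columns (ch1..chC) in ", path)
  if (is.null(sampling_hz)) {
    dt <- diff(df$timestamp[1:2])
    sampling_hz <- 1 / dt
  }
  structure(
    list(subject_id = subject_id, location_id = location_id,
         sampling_hz = sampling_hz,
         samples = as.matrix(df[, ch_cols, drop = FALSE]),
         labels = as.character(df$label)),
    class = "comeal_stream"
  )
}

#' Write / read a feature table in the package CSV dialect
#'
#' Header `f1..fq,label,subject,location`; values at full double precision
#' so tables round-trip losslessly.
#'
#' @param x A feature table.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(x, path) {
  fc <- feature_cols(x)
  keep <- c(fc, intersect(c("label", "subject", "location"), names(x)))
  out <- x[, keep, drop = FALSE]
  for (col in fc) out[[col]] <- sprintf("%.17g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in feature_cols(df)) df[[col]] <- as.numeric(df[[col]])
  df
}
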