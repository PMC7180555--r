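# Shared internal helpers: seed plumbing, feature-column handling, errors.

# Derive a deterministic 31-bit substream seed from a root seed and a stream
# name, so world generation, splitting and expert construction draw from
# independent but reproducible streams.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 2654435) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 69621 + h) %% 2147483646 + 1)
}

# Evaluate `code` with the global RNG set to `seed`, restoring the previous
# RNG state afterwards so library code never clobbers a caller's stream.
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Feature columns of a feature table
#'
#' `feature_cols()` returns the names of the `f1..fq` columns in numeric
#' order; `feature_matrix()` returns them as a numeric matrix.
#'
#' @param x A feature table (data frame with `f1..fq` columns).
#' @return A character vector of column names, or a numeric matrix.
#' @export
feature_cols <- function(x) {
  fc <- grep("^f[0-9]+$", names(x), value = TRUE)
  fc[order(as.integer(sub("^f", "", fc)))]
}

#' @rdname feature_cols
#' @export
feature_matrix <- function(x) {
  fc <- feature_cols(x)
  if (length(fc) == 0L) stop_input("no feature columns (f1..fq) found")
  as.matrix(x[, fc, drop = FALSE])
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("comeal_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("comeal_input_error", "error")))
}

stop_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("comeal_state_error", "error")))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_config(what, " must be a positive number")
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_config(what, " must be a nonnegative number")
  }
  invisible(x)
}

# Uncertainty thresholds are percentages in [0, 100]; values supplied in
# (0, 1] are read as fractions and rescaled. Returns a named vector over
# `label_set`.
normalize_threshold <- function(u_th, label_set) {
  if (!is.numeric(u_th) || any(is.na(u_th))) stop_config("u_th must be numeric")
  if (all(u_th <= 1)) u_th <- u_th * 100
  if (any(u_th < 0) || any(u_th > 100)) {
    stop_config("u_th must lie in [0, 1] (fraction) or [0, 100] (percent)")
  }
  if (length(u_th) == 1L) {
    u_th <- rep(u_th, length(label_set))
    names(u_th) <- label_set
  } else {
    if (is.null(names(u_th))) {
      if (length(u_th) != length(label_set)) {
        stop_config("vector u_th must be named or match the label set length")
      }
      names(u_th) <- label_set
    }
    if (!all(label_set %in% names(u_th))) {
      stop_config("u_th is missing thresholds for some labels")
    }
    u_th <- u_th[label_set]
  }
  u_th
}
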