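# The data-processing-unit learner: a random-forest wrapper exposing
# posterior probabilities, informativeness scores for query selection, and a
# per-label uncertainty vector.

#' Fit the learner on a labeled feature table
#'
#' Trains a probability random forest (10 trees by default) on the feature
#' columns `f1..fq` with `label` as the response. The model's label space is
#' the sorted set of labels present in the training data. A single-label
#' training set yields a degenerate model whose posterior is one-hot for
#' every input. At fit time the terminal-node class composition of every
#' tree is tabulated over the full training set, so leaf-purity
#' informativeness is a cheap lookup at query time.
#'
#' @param labeled Data frame with columns `f1..fq` and `label`; at least one
#'   instance per present label.
#' @param n_trees Number of trees in the forest.
#' @param seed Integer seed; refitting with identical data and seed gives
#'   identical predictions.
#' @return An object of class `comeal_learner`.
#' @export
fit_learner <- function(labeled, n_trees = 10, seed = 1L) {
  if (is.null(labeled) || nrow(labeled) == 0L) {
    stop(errorCondition("cannot train on an empty labeled set",
                        class = c("comeal_training_error", "error")))
  }
  if (!"label" %in% names(labeled)) stop_input("labeled set has no label column")
  fc <- feature_cols(labeled)
  label_space <- sort(unique(as.character(labeled$label)))
  model <- list(label_space = label_space, n_trees = as.integer(n_trees),
                seed = as.integer(seed), feature_names = fc)

  if (length(label_space) == 1L) {
    model$degenerate <- TRUE
    model$forest <- NULL
    class(model) <- "comeal_learner"
    return(model)
  }

  train <- labeled[, fc, drop = FALSE]
  train$.label <- factor(as.character(labeled$label), levels = label_space)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = train,
    num.trees = n_trees, probability = TRUE,
    seed = seed, num.threads = 1L
  )
  model$degenerate <- FALSE
  model$forest <- fit

  # Leaf composition over the full training set: per tree, the majority-class
  # fraction of each terminal node.
  tn <- ranger::predictions(stats::predict(
    fit, data = train[, fc, drop = FALSE],
    type = "terminalNodes", num.threads = 1L
  ))
  y <- as.character(train$.label)
  model$leaf_purity <- lapply(seq_len(ncol(tn)), function(t1) {
    vapply(split(y, tn[, t1]),
           function(lab) max(table(lab)) / length(lab), numeric(1))
  })
  class(model) <- "comeal_learner"
  model
}

#' @export
print.comeal_learner <- function(x, ...) {
  cat("Learner:", if (x$degenerate) "degenerate single-label model" else
    paste0("probability forest, ", x$n_trees, " trees"),
    "over labels {", paste(x$label_space, collapse = ", "), "}\n")
  invisible(x)
}

#' Posterior class probabilities
#'
#' @param model A [fit_learner()] model.
#' @param newdata Feature table (only `f1..fq` columns are used).
#' @return Matrix of probabilities, one row per instance, columns in the
#'   model's label space; each row sums to 1.
#' @export
predict_posterior <- function(model, newdata) {
  if (!inherits(model, "comeal_learner")) stop_state("model is not a comeal_learner")
  x <- newdata[, model$feature_names, drop = FALSE]
  if (model$degenerate) {
    p <- matrix(1, nrow(x), 1L, dimnames = list(NULL, model$label_space))
    return(p)
  }
  p <- ranger::predictions(stats::predict(model$forest, data = x,
                                          num.threads = 1L))
  p[, model$label_space, drop = FALSE]
}

#' Predicted labels (argmax posterior, ties to the lexicographically
#' smallest label)
#'
#' @inheritParams predict_posterior
#' @return Character vector of labels.
#' @export
predict_label <- function(model, newdata) {
  p <- predict_posterior(model, newdata)
  model$label_space[max.col(p, ties.method = "first")]
}

#' Shannon-entropy informativeness of a posterior
#'
#' The informativeness of an unlabeled instance is the entropy of the
#' learner's posterior over labels, `-sum(p * log(p))` in nats, with
#' `0 * log(0) = 0`; a uniform posterior is maximally informative and a
#' one-hot posterior scores 0.
#'
#' @param p Numeric probability vector; must be nonnegative and sum to 1
#'   (tolerance 1e-6).
#' @return Nonnegative entropy in nats.
#' @export
#' @examples
#' entropy_informativeness(rep(0.25, 4))  # log(4)
entropy_informativeness <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0)) {
    stop_input("posterior must be a nonnegative numeric vector")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop_input("posterior is not normalized (sum = ", format(sum(p)), ")")
  }
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

# Row-wise entropy of a posterior matrix (internal, assumes valid rows).
row_entropy <- function(p) {
  apply(p, 1L, function(r) {
    nz <- r[r > 0]
    -sum(nz * log(nz))
  })
}

# Mean leaf purity per instance across trees -> informativeness score.
purity_to_informativeness <- function(purity) {
  if (is.null(dim(purity))) purity <- matrix(purity, nrow = 1L)
  1 - rowMeans(purity)
}

# Per-instance, per-tree majority-class purity of the terminal node each
# instance falls into, looked up from the fit-time tabulation.
leaf_purity_matrix <- function(model, newdata) {
  x <- newdata[, model$feature_names, drop = FALSE]
  tn <- ranger::predictions(stats::predict(
    model$forest, data = x, type = "terminalNodes", num.threads = 1L
  ))
  out <- matrix(1, nrow(x), ncol(tn))
  for (t1 in seq_len(ncol(tn))) {
    pur <- model$leaf_purity[[t1]]
    hit <- as.character(tn[, t1])
    known <- hit %in% names(pur)
    out[known, t1] <- pur[hit[known]]
  }
  out
}

#' Leaf-purity informativeness
#'
#' Committee-style disagreement score from the forest itself: for each tree,
#' the purity of the terminal node an instance falls into is the fraction of
#' training samples of the majority class in that leaf; the score is
#' `1 - mean(purity)` across trees. 0 when every leaf is pure; bounded above
#' by `1 - 1/k` for k classes.
#'
#' @param x Feature table (one or more instances).
#' @param model A trained, non-degenerate [fit_learner()] model.
#' @return Numeric score per instance, in `[0, 1]`.
#' @export
leaf_purity_informativeness <- function(x, model) {
  if (!inherits(model, "comeal_learner")) stop_state("model is not a comeal_learner")
  if (model$degenerate) return(rep(0, nrow(x)))
  if (is.null(model$forest)) stop_state("model has no trained forest")
  purity_to_informativeness(leaf_purity_matrix(model, x))
}

min_max_normalize <- function(s) {
  rng <- range(s)
  if (rng[2] - rng[1] < .Machine$double.eps) return(rep(0.5, length(s)))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Select the most informative unlabeled instances
#'
#' Scores every instance in the pool under the chosen query strategy and
#' returns the indices of the top `K`, in descending score order with ties
#' broken by pool insertion order. The `hybrid` strategy is the equal-weight
#' mean of min-max-normalized entropy and leaf-purity scores over the pool;
#' `random` (the RAL baseline) scores instances by a seeded shuffle and
#' needs no model.
#'
#' @param K Number of instances to select (`K >= pool size` returns all).
#' @param pool Unlabeled feature table.
#' @param model A trained [fit_learner()] model (not needed for `random`).
#' @param strategy One of `"hybrid"`, `"entropy"`, `"leaf_purity"`,
#'   `"random"`.
#' @param seed Seed for the `random` strategy.
#' @return Integer vector of at most `K` pool row indices.
#' @export
get_informative_instances <- function(K, pool, model = NULL,
                                      strategy = c("hybrid", "entropy",
                                                   "leaf_purity", "random"),
                                      seed = 1L) {
  strategy <- match.arg(strategy)
  if (!is.numeric(K) || length(K) != 1L || K < 1) {
    stop_config("K must be a positive integer")
  }
  n <- nrow(pool)
  if (n == 0L) return(integer(0))
  if (strategy == "random") {
    scores <- local_seed(substream_seed(seed, "query-random"),
                         sample(seq_len(n)))
  } else {
    if (!inherits(model, "comeal_learner")) {
      stop_state("a trained model is required for strategy ", strategy)
    }
    p <- predict_posterior(model, pool)
    scores <- switch(strategy,
      entropy = row_entropy(p),
      leaf_purity = as.numeric(leaf_purity_informativeness(pool, model)),
      hybrid = {
        ent <- row_entropy(p)
        lp <- as.numeric(leaf_purity_informativeness(pool, model))
        (min_max_normalize(ent) + min_max_normalize(lp)) / 2
      })
  }
  ord <- order(-scores, seq_len(n))
  head(ord, min(as.integer(K), n))
}

# Core of the learner-uncertainty computation, factored out so it can be
# certified against hand-built posteriors: for each label, the complement of
# the mean top-posterior confidence over the instances predicted as that
# label, as a percentage; labels never predicted get 100.
uncertainty_from_posterior <- function(p, label_space,
                                       label_set = label_space) {
  pred <- label_space[max.col(p, ties.method = "first")]
  maxp <- p[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))]
  u <- vapply(label_set, function(lab) {
    idx <- pred == lab
    if (!any(idx)) return(100)
    100 * (1 - mean(maxp[idx]))
  }, numeric(1))
  names(u) <- label_set
  u
}

#' Per-label uncertainty vector of the learner
#'
#' For each label, uncertainty is `100 * (1 - mean top-posterior
#' probability)` over the pool instances the model predicts as that label;
#' labels with no predicted instances (including labels outside the model's
#' label space) get 100. Entries lie in `[0, 100]`, 0 meaning full
#' confidence.
#'
#' @param model A trained [fit_learner()] model.
#' @param pool Non-empty feature table to measure confidence over.
#' @param label_set Labels the vector must cover; defaults to the model's
#'   label space.
#' @return Named numeric vector of percentages.
#' @export
learner_uncertainty <- function(model, pool, label_set = model$label_space) {
  if (!inherits(model, "comeal_learner")) stop_state("model is not a comeal_learner")
  if (is.null(pool) || nrow(pool) == 0L) stop_input("pool is empty")
  p <- predict_posterior(model, pool)
  uncertainty_from_posterior(p, model$label_space, label_set)
}
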