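# The heterogeneous expert pool: perfect, imperfect and on-demand
# annotators, each with a per-label uncertainty vector and a
# confidence-proportional query cost, plus the collaborative knowledge
# updates (broadcast + uncertainty recomputation).

new_expert <- function(id, kind, label_set, uncertainty, base_cost,
                       updatable, model = NULL, train = NULL,
                       confident_labels = NULL, error_rate = NA_real_,
                       seed = 1L, answer_fun = NULL, unit_cost = NULL) {
  if (is.null(unit_cost)) {
    unit_cost <- if (updatable) {
      expert_cost_from_confidence(uncertainty, base_cost)
    } else {
      base_cost
    }
  }
  structure(
    list(id = id, kind = kind, label_set = label_set,
         uncertainty = uncertainty, base_cost = base_cost,
         unit_cost = unit_cost, updatable = updatable, model = model,
         train = train, confident_labels = confident_labels,
         error_rate = error_rate, seed = as.integer(seed),
         answer_fun = answer_fun),
    class = "comeal_expert"
  )
}

#' @export
print.comeal_expert <- function(x, ...) {
  cat(sprintf("Expert %s (%s): cost %.3f, mean uncertainty %.1f%%%s\n",
              x$id, x$kind, x$unit_cost, mean(x$uncertainty),
              if (!is.null(x$confident_labels))
                paste0(", confident on {",
                       paste(x$confident_labels, collapse = ", "), "}")
              else ""))
  invisible(x)
}

#' Query cost of an expert from its confidence
#'
#' An expert's cost is proportional to its confidence over the label set:
#' `base_cost * mean((100 - u) / 100)`. A fully confident expert (all
#' uncertainties 0) costs `base_cost`; a fully ignorant one costs 0.
#'
#' @param uncertainty Per-label uncertainty vector in `[0, 100]`.
#' @param base_cost Positive cost at full confidence.
#' @return Nonnegative cost.
#' @export
#' @examples
#' expert_cost_from_confidence(c(a = 20, b = 40), 10)  # 7
expert_cost_from_confidence <- function(uncertainty, base_cost) {
  if (any(uncertainty < 0) || any(uncertainty > 100)) {
    stop_input("uncertainty entries must lie in [0, 100]")
  }
  check_nonnegative(base_cost, "base_cost")
  base_cost * mean((100 - uncertainty) / 100)
}

# Per-label error rate of a set of predictions against ground truth, as an
# uncertainty vector: u_l = 100 * P(pred != l | truth = l). Labels without
# evaluation instances, or outside `known` (the predictor's label space),
# get 100.
uncertainty_from_predictions <- function(pred, truth, label_set,
                                         known = label_set) {
  u <- setNames(rep(100, length(label_set)), label_set)
  for (lab in intersect(label_set, known)) {
    idx <- truth == lab
    if (any(idx)) u[lab] <- 100 * mean(pred[idx] != lab)
  }
  u
}

uncertainty_from_eval <- function(model, eval_pool, label_set) {
  if (is.null(model)) {
    return(setNames(rep(100, length(label_set)), label_set))
  }
  uncertainty_from_predictions(predict_label(model, eval_pool),
                               as.character(eval_pool$label),
                               label_set, model$label_space)
}

# Per-label stratified subsample: floor(fraction * n_label) rows per label,
# chosen by a seeded shuffle. Labels whose floor is 0 drop out entirely.
stratified_fraction <- function(x, fraction, seed) {
  local_seed(substream_seed(seed, "expert-sample"), {
    idx <- integer(0)
    for (lab in unique(x$label)) {
      rows <- which(x$label == lab)
      n1 <- floor(fraction * length(rows))
      if (n1 > 0) idx <- c(idx, sample(rows, n1))
    }
    x[sort(idx), , drop = FALSE]
  })
}

#' Create a perfect expert
#'
#' Answers every query with the ground-truth label, flipped to a uniformly
#' random wrong label with probability `error_rate` (typically 1–10%). Its
#' uncertainty vector is `100 * error_rate` on every label, its cost is the
#' highest in the pool by construction, and it never updates.
#'
#' @param label_set Labels the expert covers.
#' @param error_rate Flip probability in `[0, 1]`.
#' @param base_cost Query cost (fixed; perfect experts do not update).
#' @param id Expert id.
#' @param seed Integer seed (kept for pool reproducibility bookkeeping).
#' @return A `comeal_expert` of kind `"perfect"`.
#' @export
make_perfect_expert <- function(label_set, error_rate = 0.05, base_cost = 10,
                                id = "perfect", seed = 1L) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1) {
    stop_config("error_rate must lie in [0, 1]")
  }
  u <- setNames(rep(100 * error_rate, length(label_set)), label_set)
  new_expert(id, "perfect", label_set, u, base_cost, updatable = FALSE,
             error_rate = error_rate, seed = seed, unit_cost = base_cost)
}

#' Create an imperfect expert
#'
#' Trains a random-forest annotator on a stratified `data_fraction` sample
#' of the expert-initialization pool; its per-label uncertainty is its
#' percentage error rate on the evaluation pool (labels absent from the
#' training sample get 100), and its cost follows
#' [expert_cost_from_confidence()]. Imperfect experts are updatable: they
#' retrain when labeled data is broadcast.
#'
#' @param init_pool Labeled expert-initialization table.
#' @param data_fraction Fraction in (0, 1] of `init_pool` used per label.
#' @param eval_pool Labeled evaluation table for uncertainty estimation.
#' @param base_cost Cost at full confidence.
#' @param id Expert id.
#' @param seed Integer seed for subsampling and forest training.
#' @return A `comeal_expert` of kind `"imperfect"`.
#' @export
make_imperfect_expert <- function(init_pool, data_fraction = 0.05, eval_pool,
                                  base_cost = 5, id = "imperfect", seed = 1L) {
  if (!is.numeric(data_fraction) || data_fraction <= 0 || data_fraction > 1) {
    stop_config("data_fraction must lie in (0, 1]")
  }
  label_set <- sort(unique(as.character(init_pool$label)))
  train <- stratified_fraction(init_pool, data_fraction, seed)
  model <- if (nrow(train) > 0L) fit_learner(train, seed = seed) else NULL
  u <- uncertainty_from_eval(model, eval_pool, label_set)
  new_expert(id, "imperfect", label_set, u, base_cost, updatable = TRUE,
             model = model, train = train, seed = seed)
}

#' Create an on-demand expert
#'
#' A cheap (zero-cost by default) annotator confident only on a subset of
#' labels: it trains on all initialization data for its confident labels
#' plus `n_other` instances per other label, and abstains whenever its
#' predicted label falls outside the confident subset. On-demand experts are
#' updatable.
#'
#' @param init_pool Labeled expert-initialization table.
#' @param confident_labels Non-empty proper subset of the label set.
#' @param n_other Instances per out-of-scope label included in training.
#' @param eval_pool Labeled evaluation table for uncertainty estimation.
#' @param base_cost Cost at full confidence (0 by default).
#' @param id Expert id.
#' @param seed Integer seed.
#' @return A `comeal_expert` of kind `"on_demand"`.
#' @export
make_on_demand_expert <- function(init_pool, confident_labels, n_other = 3,
                                  eval_pool, base_cost = 0, id = "ondemand",
                                  seed = 1L) {
  label_set <- sort(unique(as.character(init_pool$label)))
  confident_labels <- as.character(confident_labels)
  if (length(confident_labels) == 0L ||
      !all(confident_labels %in% label_set)) {
    stop_config("confident_labels must be a non-empty subset of the label set")
  }
  train_conf <- init_pool[init_pool$label %in% confident_labels, , drop = FALSE]
  others <- setdiff(label_set, confident_labels)
  train_other <- local_seed(substream_seed(seed, "ondemand-sample"), {
    idx <- integer(0)
    for (lab in others) {
      rows <- which(init_pool$label == lab)
      if (length(rows) > 0L) {
        idx <- c(idx, sample(rows, min(n_other, length(rows))))
      }
    }
    init_pool[sort(idx), , drop = FALSE]
  })
  train <- rbind(train_conf, train_other)
  model <- if (nrow(train) > 0L) fit_learner(train, seed = seed) else NULL
  u <- uncertainty_from_eval(model, eval_pool, label_set)
  new_expert(id, "on_demand", label_set, u, base_cost, updatable = TRUE,
             model = model, train = train,
             confident_labels = confident_labels, seed = seed)
}

#' Assemble an expert pool
#'
#' @param experts List of `comeal_expert` objects with unique ids.
#' @param label_set Labels every expert's uncertainty vector must cover.
#' @return A `comeal_expert_pool`.
#' @export
expert_pool <- function(experts, label_set) {
  ids <- vapply(experts, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_config("expert ids must be unique")
  for (e in experts) {
    if (!all(label_set %in% names(e$uncertainty))) {
      stop_config("expert ", e$id,
                  " has no uncertainty entry for some labels")
    }
  }
  names(experts) <- ids
  structure(list(experts = experts, label_set = as.character(label_set)),
            class = "comeal_expert_pool")
}

#' @export
print.comeal_expert_pool <- function(x, ...) {
  cat("Expert pool over {", paste(x$label_set, collapse = ", "), "}:\n")
  for (e in x$experts) print(e)
  invisible(x)
}

#' Ask one expert to label an instance
#'
#' Perfect experts return the ground truth (flipped with their error rate,
#' drawn from the session RNG); imperfect experts return their model's
#' prediction; on-demand experts return their prediction or `NA` (abstain)
#' when it falls outside their confident labels. A test stub with an
#' `answer_fun` component answers through it.
#'
#' @param expert A `comeal_expert`.
#' @param x One-row feature table.
#' @param true_label Hidden truth, used only by perfect experts.
#' @return A list with `label` (possibly `NA` for abstention) and `cost`
#'   (the expert's `unit_cost`, charged regardless of abstention).
#' @export
ask_expert <- function(expert, x, true_label = NULL) {
  ans <- if (!is.null(expert$answer_fun)) {
    expert$answer_fun(x, true_label)
  } else if (expert$kind == "perfect") {
    if (is.null(true_label)) stop_state("perfect expert needs the hidden truth")
    if (expert$error_rate > 0 && runif(1) < expert$error_rate) {
      wrong <- setdiff(expert$label_set, true_label)
      if (length(wrong) == 0L) true_label else
        wrong[sample.int(length(wrong), 1L)]
    } else {
      true_label
    }
  } else if (is.null(expert$model)) {
    NA_character_
  } else {
    pred <- predict_label(expert$model, x)
    if (expert$kind == "on_demand" && !pred %in% expert$confident_labels) {
      NA_character_
    } else {
      pred
    }
  }
  list(label = ans, cost = expert$unit_cost)
}

#' Broadcast newly labeled data to the expert pool
#'
#' The collaboration step: every updatable expert's training set is
#' augmented with the batch and its model retrained (with its own seed);
#' non-updatable (perfect) experts are unchanged. Uncertainty vectors are
#' not touched here — call [update_uncertainty_all()] afterwards.
#'
#' @param batch Labeled feature table (may be empty).
#' @param pool A `comeal_expert_pool`.
#' @return The updated pool.
#' @export
broadcast_labeled_data <- function(batch, pool) {
  if (is.null(batch) || nrow(batch) == 0L) return(pool)
  if (!all(batch$label %in% pool$label_set)) {
    stop_input("batch contains labels outside the pool's label set")
  }
  for (id in names(pool$experts)) {
    e <- pool$experts[[id]]
    if (!e$updatable) next
    fc <- feature_cols(batch)
    add <- batch[, c(fc, "label"), drop = FALSE]
    old <- if (is.null(e$train)) NULL else
      e$train[, c(feature_cols(e$train), "label"), drop = FALSE]
    e$train <- rbind(old, add)
    e$model <- fit_learner(e$train, seed = e$seed)
    pool$experts[[id]] <- e
  }
  pool
}

#' Recompute uncertainty vectors and costs for all updatable experts
#'
#' Each updatable expert's per-label uncertainty is recomputed as its
#' percentage error rate on the evaluation pool, and its cost as
#' [expert_cost_from_confidence()] of the new vector. Running it twice with
#' no data change is a fixed point.
#'
#' @param pool A `comeal_expert_pool`.
#' @param eval_pool Labeled evaluation table.
#' @return The updated pool.
#' @export
update_uncertainty_all <- function(pool, eval_pool) {
  for (id in names(pool$experts)) {
    e <- pool$experts[[id]]
    if (!e$updatable) next
    e$uncertainty <- uncertainty_from_eval(e$model, eval_pool, pool$label_set)
    e$unit_cost <- expert_cost_from_confidence(e$uncertainty, e$base_cost)
    pool$experts[[id]] <- e
  }
  pool
}

# Fixed-behavior expert stub for tests and the assignment oracle: answers
# through `answer_fun(x, true_label)` and carries an explicit uncertainty
# vector and cost.
make_stub_expert <- function(id, kind, label_set, uncertainty, unit_cost,
                             answer_fun) {
  new_expert(id, kind, label_set,
             setNames(uncertainty, label_set), base_cost = unit_cost,
             updatable = FALSE, answer_fun = answer_fun,
             unit_cost = unit_cost)
}
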