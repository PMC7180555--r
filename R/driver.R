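# The collaborative active-learning driver and its variants, plus the
# simple-transfer-learning baseline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration for the active-learning driver
#'
#' @param K Query batch size per round (default 10).
#' @param u_th Uncertainty threshold for expert selection: scalar or
#'   per-label vector, percent in `[0, 100]` or fraction in `(0, 1]`.
#' @param variant One of `"CAL"` (transfer + collaboration), `"CAL_star"`
#'   (CAL plus the prior-knowledge auto-labeling path), `"NCAL"` (no
#'   collaboration), `"RAL"` (random query baseline), `"STL"` (simple
#'   transfer baseline, no expert queries).
#' @param strategy Query strategy for the informative-instance selection
#'   (ignored for RAL/STL).
#' @param budget_fraction Fraction of the initial unlabeled pool that may be
#'   queried, in (0, 1].
#' @param scenario Optional scenario tag carried in results.
#' @param seed Integer root seed for the run.
#' @param n_trees Trees in the learner forest.
#' @param confidence_floor Posterior floor for the CAL* prior-knowledge
#'   path.
#' @param stop_uth Optional separate stopping threshold for the learner's
#'   uncertainty (defaults to `u_th`); set to 0 to always run to the query
#'   budget, as fixed-budget experiments do.
#' @return An object of class `comeal_run_config`.
#' @export
run_config <- function(K = 10, u_th = 0.2,
                       variant = c("CAL", "CAL_star", "NCAL", "RAL", "STL"),
                       strategy = c("hybrid", "entropy", "leaf_purity",
                                    "random"),
                       budget_fraction = 0.15, scenario = NULL, seed = 1L,
                       n_trees = 10, confidence_floor = 0.9,
                       stop_uth = NULL) {
  variant <- match.arg(variant)
  strategy <- match.arg(strategy)
  if (!is.numeric(K) || K < 1) stop_config("K must be a positive integer")
  if (!is.numeric(budget_fraction) || budget_fraction <= 0 ||
      budget_fraction > 1) {
    stop_config("budget_fraction must lie in (0, 1]")
  }
  structure(
    list(K = as.integer(K), u_th = u_th, variant = variant,
         strategy = strategy, budget_fraction = budget_fraction,
         scenario = scenario, seed = as.integer(seed),
         n_trees = as.integer(n_trees),
         confidence_floor = confidence_floor, stop_uth = stop_uth),
    class = "comeal_run_config"
  )
}

#' @export
print.comeal_run_config <- function(x, ...) {
  cat("Run config:", x$variant, "| strategy", x$strategy,
      "| K =", x$K, "| u_th =", paste(x$u_th, collapse = ","),
      "| budget =", x$budget_fraction,
      "| trees =", x$n_trees, "| seed =", x$seed, "\n")
  if (!is.null(x$stop_uth)) cat("  stopping threshold:", x$stop_uth, "\n")
  invisible(x)
}

eval_accuracy <- function(model, eval_pool) {
  mean(predict_label(model, eval_pool) == as.character(eval_pool$label))
}

#' Run the collaborative active-learning driver
#'
#' The full loop: transfer-initialize the learner from the related source
#' domains, optionally auto-label confidently predicted target data with a
#' prior model (CAL* only), then repeat — select the `K` most informative
#' unlabeled instances, annotate each through the expert pool (greedy
#' cost-minimizing selection), move them to the labeled side, broadcast the
#' new labels to the experts and refresh their uncertainties (CAL/CAL*
#' only), and retrain — until the learner's uncertainty is within the
#' stopping threshold on every label or the query budget is exhausted.
#'
#' @param related List of labeled source feature tables (may be empty).
#' @param x_l Target labeled table (possibly zero rows).
#' @param x_u Target unlabeled table (non-empty; no usable `label` column).
#' @param truth Hidden ground-truth labels for `x_u`, used only by perfect
#'   experts and never shown to the learner.
#' @param label_set Full label set of the experiment.
#' @param pool A `comeal_expert_pool` containing at least one perfect
#'   expert.
#' @param cfg A [run_config()].
#' @param eval_pool Labeled held-out table for accuracy tracking and expert
#'   uncertainty recomputation; never queried.
#' @param prior_model Optional prior [fit_learner()] model (CAL* only).
#' @return An object of class `comeal_run`: the final `model`, the
#'   `ledger`, per-round `accuracy`, `uncertainty` (rounds-by-labels
#'   matrix), `sizes` (labeled/unlabeled pool sizes per round),
#'   `n_queries`, and `expert_counts` by kind.
#' @export
run_driver <- function(related, x_l, x_u, truth, label_set, pool, cfg,
                       eval_pool, prior_model = NULL) {
  if (!inherits(cfg, "comeal_run_config")) stop_config("cfg must be a run_config()")
  if (!inherits(pool, "comeal_expert_pool") || length(pool$experts) == 0L) {
    stop_config("pool must be a non-empty comeal_expert_pool")
  }
  if (!any(vapply(pool$experts, `[[`, "", "kind") == "perfect")) {
    stop_config("pool must contain at least one perfect expert")
  }
  if (is.null(x_u) || nrow(x_u) == 0L) stop_config("x_u is empty")
  if (length(truth) != nrow(x_u)) stop_config("truth must match x_u rows")
  variant <- cfg$variant
  if (variant == "STL") stop_config("use run_stl_baseline() for the STL variant")

  local_seed(substream_seed(cfg$seed, "driver"), {
    fc <- feature_cols(x_u)
    u_th <- normalize_threshold(cfg$u_th, label_set)
    stop_uth <- normalize_threshold(cfg$stop_uth %||% cfg$u_th, label_set)
    model_seed <- substream_seed(cfg$seed, "learner")
    truth <- as.character(truth)
    ids <- paste0("u", seq_len(nrow(x_u)))

    x_l <- if (is.null(x_l) || nrow(x_l) == 0L) {
      empty <- x_u[0, fc, drop = FALSE]
      empty$label <- character(0)
      empty
    } else {
      x_l[, c(fc, "label"), drop = FALSE]
    }

    if (length(related) > 0L) {
      init <- initialize_learner(related, x_u, label_set,
                                 seed = substream_seed(cfg$seed, "init"))
      if (!is.null(init$data) && nrow(init$data) > 0L) {
        x_l <- rbind(x_l, init$data[, c(fc, "label"), drop = FALSE])
      }
    }

    if (variant == "CAL_star" && !is.null(prior_model)) {
      apk <- apply_prior_knowledge(prior_model, x_u, cfg$confidence_floor)
      if (length(apk$indices) > 0L) {
        x_l <- rbind(x_l, apk$labeled[, c(fc, "label"), drop = FALSE])
        x_u <- x_u[-apk$indices, , drop = FALSE]
        truth <- truth[-apk$indices]
        ids <- ids[-apk$indices]
      }
    }
    if (nrow(x_l) == 0L) {
      stop_config("no labeled data after initialization; ",
                  "supply related domains or a non-empty x_l")
    }

    n_u0 <- nrow(x_u)
    budget <- floor(cfg$budget_fraction * n_u0)
    model <- fit_learner(x_l, n_trees = cfg$n_trees, seed = model_seed)
    unc_pool <- function() if (nrow(x_u) > 0L) x_u else eval_pool
    unc <- learner_uncertainty(model, unc_pool(), label_set)

    accuracy <- eval_accuracy(model, eval_pool)
    unc_trace <- matrix(unc, 1L, length(label_set),
                        dimnames = list(NULL, label_set))
    sizes <- data.frame(round = 0L, n_labeled = nrow(x_l),
                        n_unlabeled = nrow(x_u))
    ledger <- new_cost_ledger()
    queries <- 0L; round <- 0L

    while (queries < budget && nrow(x_u) > 0L && !all(unc <= stop_uth)) {
      round <- round + 1L
      k_round <- min(cfg$K, budget - queries, nrow(x_u))
      strategy <- if (variant == "RAL") "random" else cfg$strategy
      idx <- get_informative_instances(
        k_round, x_u, model, strategy,
        seed = substream_seed(cfg$seed, paste0("round-", round))
      )
      sel <- x_u[idx, , drop = FALSE]
      post <- predict_posterior(model, sel)
      labels <- character(length(idx))
      for (i in seq_along(idx)) {
        semi <- model$label_space[which.max(post[i, ])]
        res <- annotate(sel[i, , drop = FALSE], pool, semi, u_th, ledger,
                        true_label = truth[idx[i]],
                        instance_id = ids[idx[i]], round = round)
        ledger <- res$ledger
        labels[i] <- res$label
      }
      batch <- sel[, fc, drop = FALSE]
      batch$label <- labels
      x_l <- rbind(x_l, batch)
      x_u <- x_u[-idx, , drop = FALSE]
      truth <- truth[-idx]
      ids <- ids[-idx]
      queries <- queries + length(idx)

      if (variant %in% c("CAL", "CAL_star")) {
        pool <- broadcast_labeled_data(batch, pool)
        pool <- update_uncertainty_all(pool, eval_pool)
      }
      model <- fit_learner(x_l, n_trees = cfg$n_trees, seed = model_seed)
      unc <- learner_uncertainty(model, unc_pool(), label_set)
      accuracy <- c(accuracy, eval_accuracy(model, eval_pool))
      unc_trace <- rbind(unc_trace, unc)
      sizes <- rbind(sizes, data.frame(round = round, n_labeled = nrow(x_l),
                                       n_unlabeled = nrow(x_u)))
    }

    structure(
      list(model = model, ledger = ledger, accuracy = accuracy,
           uncertainty = unc_trace, sizes = sizes, n_queries = queries,
           expert_counts = query_counts(ledger, "expert_kind"),
           pool = pool, cfg = cfg, variant = variant),
      class = "comeal_run"
    )
  })
}

#' @export
print.comeal_run <- function(x, ...) {
  cat("Active-learning run (", x$variant, "): ",
      length(x$accuracy) - 1L, " rounds, ", x$n_queries, " queries, ",
      "total cost ", format(round(total_cost(x$ledger), 3)), "\n", sep = "")
  cat("  accuracy: ", paste(sprintf("%.3f", x$accuracy), collapse = " -> "),
      "\n", sep = "")
  if (length(x$expert_counts)) {
    cat("  queries by expert kind:",
        paste(names(x$expert_counts), x$expert_counts, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simple transfer-learning baseline (STL)
#'
#' No expert queries: the target's unlabeled data is clustered once, source
#' domains are ranked by the cosine similarity of their class centers to
#' the nearest cluster centers, and each round adds the next most similar
#' source domain to the training set and retrains.
#'
#' @param related Non-empty list of labeled source feature tables.
#' @param x_u Unlabeled target table (used only for clustering).
#' @param label_set Full label set.
#' @param cfg A [run_config()] (only `seed` and `n_trees` are used).
#' @param eval_pool Labeled held-out table for accuracy tracking.
#' @param n_rounds Number of sources to add (defaults to all; the run ends
#'   when sources are exhausted).
#' @return A `comeal_run` with an empty ledger; `accuracy[r]` is the
#'   accuracy after adding the r-th most similar source.
#' @export
run_stl_baseline <- function(related, x_u, label_set, cfg, eval_pool,
                             n_rounds = length(related)) {
  if (length(related) == 0L) stop_config("related must be non-empty")
  if (!inherits(cfg, "comeal_run_config")) stop_config("cfg must be a run_config()")
  local_seed(substream_seed(cfg$seed, "stl"), {
    k <- length(label_set)
    km <- kmeans(feature_matrix(x_u), centers = min(k, nrow(unique(feature_matrix(x_u)))),
                 nstart = 10)
    centers <- km$centers
    if (is.null(names(related))) {
      names(related) <- paste0("source", seq_along(related))
    }
    sims <- vapply(related, function(db) {
      m <- feature_matrix(db)
      labs <- unique(as.character(db$label))
      mean(vapply(labs, function(l) {
        cen <- colMeans(m[db$label == l, , drop = FALSE])
        max(apply(centers, 1L, cosine_similarity, a = cen))
      }, numeric(1)))
    }, numeric(1))
    ord <- names(sort(sims, decreasing = TRUE))
    n_rounds <- min(n_rounds, length(ord))

    fc <- feature_cols(x_u)
    accuracy <- numeric(0)
    train <- NULL
    model <- NULL
    for (r in seq_len(n_rounds)) {
      db <- related[[ord[r]]][, c(fc, "label"), drop = FALSE]
      train <- rbind(train, db)
      model <- fit_learner(train, n_trees = cfg$n_trees,
                           seed = substream_seed(cfg$seed, "learner"))
      accuracy <- c(accuracy, eval_accuracy(model, eval_pool))
    }
    structure(
      list(model = model, ledger = new_cost_ledger(), accuracy = accuracy,
           uncertainty = NULL,
           sizes = data.frame(round = seq_len(n_rounds),
                              n_labeled = NA_integer_,
                              n_unlabeled = nrow(x_u)),
           n_queries = 0L, expert_counts = integer(0), pool = NULL,
           cfg = cfg, variant = "STL", source_order = ord),
      class = "comeal_run"
    )
  })
}
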