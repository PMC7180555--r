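# The three reconfiguration scenarios — context change (new subject),
# configuration change (new sensor), user-need change (new activities) —
# assembled from the synthetic feature-world generator, plus the default
# simulated expert pool.

#' Build the default simulated expert pool
#'
#' One perfect expert (highest cost, small error rate), `n_imperfect`
#' imperfect experts trained on stratified fractions of the
#' expert-initialization split, and `n_on_demand` zero-cost on-demand
#' experts each confident on a quarter of the label set (at least one
#' label), assigned round-robin.
#'
#' @param expert_init Labeled expert-initialization table.
#' @param eval_pool Labeled evaluation table.
#' @param label_set Full label set.
#' @param n_imperfect,n_on_demand Pool composition.
#' @param perfect_error Perfect-expert flip probability.
#' @param perfect_cost Perfect-expert cost (highest in the pool).
#' @param imperfect_base Base costs for the imperfect experts (recycled).
#' @param imperfect_fraction Training data fractions for the imperfect
#'   experts (recycled).
#' @param seed Integer seed.
#' @return A `comeal_expert_pool`.
#' @export
make_default_pool <- function(expert_init, eval_pool, label_set,
                              n_imperfect = 2, n_on_demand = 2,
                              perfect_error = 0.05, perfect_cost = 10,
                              imperfect_base = c(8, 6),
                              imperfect_fraction = c(0.05, 0.1),
                              seed = 1L) {
  experts <- list(make_perfect_expert(label_set, perfect_error, perfect_cost,
                                      id = "E1", seed = seed))
  for (j in seq_len(n_imperfect)) {
    experts[[length(experts) + 1L]] <- make_imperfect_expert(
      expert_init,
      data_fraction = imperfect_fraction[(j - 1L) %% length(imperfect_fraction) + 1L],
      eval_pool = eval_pool,
      base_cost = imperfect_base[(j - 1L) %% length(imperfect_base) + 1L],
      id = paste0("E", j + 1L),
      seed = substream_seed(seed, paste0("imperfect-", j))
    )
  }
  k <- length(label_set)
  # Overlapping confident subsets (about a quarter of the label set, at
  # least 2) so two on-demand experts can corroborate a phase-1 majority.
  size <- min(k - 1L, max(2L, floor(k / 4)))
  for (j in seq_len(n_on_demand)) {
    sel <- label_set[((j - 1L) + seq_len(size) - 1L) %% k + 1L]
    experts[[length(experts) + 1L]] <- make_on_demand_expert(
      expert_init, confident_labels = unique(sel), eval_pool = eval_pool,
      id = paste0("E", n_imperfect + 1L + j),
      seed = substream_seed(seed, paste0("ondemand-", j))
    )
  }
  expert_pool(experts, label_set)
}

# Split a target domain's table into the unlabeled query pool (one half)
# and a labeled half that is itself split 50/50 into expert initialization
# and evaluation.
split_target <- function(target, seed) {
  s1 <- split_expert_initialization(target, 0.5, seed = seed)
  s2 <- split_expert_initialization(s1$eval, 0.5,
                                    seed = substream_seed(seed, "target-eval"))
  list(x_u = s1$init, expert_init = s2$init, eval = s2$eval)
}

#' Build a reconfiguration scenario on a synthetic world
#'
#' Constructs the related source domains, the target pools, the hidden
#' truth and the simulated expert pool for one of the three change
#' scenarios:
#'
#' * `context_change` — leave-one-subject-out: the target subject's stream
#'   is the new context (unlabeled); every other subject is a related
#'   labeled source domain.
#' * `configuration_change` — a new sensor location is the target; other
#'   locations are related sources, and a prior model trained on a subset
#'   of labels at the new location is carried over (CAL* eligible).
#' * `user_need_change` — the last two labels are new activities: they
#'   appear in the target's hidden truth but in no related source and not
#'   in the prior model.
#'
#' The target domain's instances are split half into the unlabeled query
#' pool and half into labeled data, the latter split 50/50 into expert
#' initialization and evaluation.
#'
#' @param scenario One of `"context_change"`, `"configuration_change"`,
#'   `"user_need_change"`.
#' @param cfg A [world_config()] (feasible for the scenario: at least 2
#'   subjects for context change, 2 locations for configuration change, 4
#'   labels for user-need change).
#' @param q Feature dimension.
#' @param n_per_class Instances per (subject, location, label) in the
#'   target domain.
#' @param class_sep Class-center separation in feature space.
#' @param feature_sd Within-class standard deviation.
#' @param n_source_per_class Labeled instances per class kept from each
#'   related source domain (`NULL` keeps all). Related contexts typically
#'   contribute brief labeled calibration sessions while the target wears
#'   the device continuously, so the query budget is a meaningful share of
#'   the total supervision.
#' @param ... Passed to [make_default_pool()].
#' @return An object of class `comeal_scenario`: a list with `related`,
#'   `x_l`, `x_u`, `truth`, `expert_init`, `eval`, `pool`, `label_set`,
#'   `prior_model`, `scenario`.
#' @export
build_scenario <- function(scenario = c("context_change",
                                        "configuration_change",
                                        "user_need_change"),
                           cfg = world_config(), q = 6, n_per_class = 100,
                           class_sep = 3.5, feature_sd = 1,
                           n_source_per_class = 25, ...) {
  scenario <- match.arg(scenario)
  if (!inherits(cfg, "comeal_world_config")) {
    stop_config("cfg must be a world_config()")
  }
  label_set <- cfg$label_set
  k <- length(label_set)
  seed <- cfg$seed
  prior_model <- NULL

  if (scenario == "context_change") {
    if (cfg$n_subjects < 2L) stop_config("context change needs >= 2 subjects")
    tab <- generate_feature_world(cfg, q, n_per_class, class_sep, feature_sd)
    tab <- tab[tab$location == "l1", , drop = FALSE]
    target <- tab[tab$subject == "s1", , drop = FALSE]
    related <- split(tab[tab$subject != "s1", , drop = FALSE],
                     tab$subject[tab$subject != "s1"])
  } else if (scenario == "configuration_change") {
    if (cfg$n_locations < 2L) {
      stop_config("configuration change needs >= 2 locations")
    }
    tab <- generate_feature_world(cfg, q, n_per_class, class_sep, feature_sd)
    target_loc <- paste0("l", cfg$n_locations)
    target <- tab[tab$subject == "s1" & tab$location == target_loc, ,
                  drop = FALSE]
    rel <- tab[tab$location != target_loc, , drop = FALSE]
    related <- split(rel, paste(rel$subject, rel$location, sep = "_"))
  } else {
    if (k < 4L) stop_config("user-need change needs >= 4 labels (2 spare)")
    tab <- generate_feature_world(cfg, q, n_per_class, class_sep, feature_sd)
    tab <- tab[tab$location == "l1", , drop = FALSE]
    new_labels <- label_set[(k - 1L):k]
    target <- tab[tab$subject == "s1", , drop = FALSE]
    rel <- tab[tab$subject != "s1" & !(tab$label %in% new_labels), ,
               drop = FALSE]
    related <- split(rel, rel$subject)
  }

  if (!is.null(n_source_per_class)) {
    related <- lapply(seq_along(related), function(i) {
      db <- related[[i]]
      local_seed(substream_seed(seed, paste0("source-session-", i)), {
        idx <- unlist(lapply(split(seq_len(nrow(db)), db$label), function(r) {
          if (length(r) > n_source_per_class) sample(r, n_source_per_class)
          else r
        }))
        db[sort(idx), , drop = FALSE]
      })
    })
    names(related) <- if (scenario == "configuration_change") {
      vapply(related, function(db) paste(db$subject[1], db$location[1],
                                         sep = "_"), "")
    } else {
      vapply(related, function(db) db$subject[1], "")
    }
  }

  parts <- split_target(target, substream_seed(seed, "scenario-split"))
  truth <- as.character(parts$x_u$label)
  x_u <- parts$x_u[, feature_cols(parts$x_u), drop = FALSE]
  rownames(x_u) <- NULL

  if (scenario == "configuration_change") {
    prior_labels <- label_set[seq_len(ceiling(k / 2))]
    prior_train <- parts$expert_init[parts$expert_init$label %in% prior_labels, ,
                                     drop = FALSE]
    prior_model <- fit_learner(prior_train,
                               seed = substream_seed(seed, "prior"))
  } else if (scenario == "user_need_change") {
    old <- parts$expert_init[!(parts$expert_init$label %in%
                                 label_set[(k - 1L):k]), , drop = FALSE]
    prior_model <- fit_learner(old, seed = substream_seed(seed, "prior"))
  }

  pool <- make_default_pool(parts$expert_init, parts$eval, label_set,
                            seed = substream_seed(seed, "experts"), ...)
  x_l <- parts$x_u[0, c(feature_cols(parts$x_u), "label"), drop = FALSE]

  structure(
    list(scenario = scenario, related = related, x_l = x_l, x_u = x_u,
         truth = truth, expert_init = parts$expert_init, eval = parts$eval,
         pool = pool, label_set = label_set, prior_model = prior_model,
         world_config = cfg),
    class = "comeal_scenario"
  )
}

#' @export
print.comeal_scenario <- function(x, ...) {
  cat("Scenario", x$scenario, ":", length(x$related), "related domains,",
      nrow(x$x_u), "unlabeled target instances,",
      nrow(x$eval), "evaluation instances,",
      length(x$pool$experts), "experts\n")
  invisible(x)
}

#' Run a configured variant on a built scenario
#'
#' Thin dispatcher: STL goes to [run_stl_baseline()], everything else to
#' [run_driver()] (CAL* receives the scenario's prior model).
#'
#' @param scen A [build_scenario()] object.
#' @param cfg A [run_config()].
#' @return A `comeal_run`.
#' @export
run_scenario <- function(scen, cfg) {
  if (!inherits(scen, "comeal_scenario")) stop_config("scen must be a comeal_scenario")
  if (cfg$variant == "STL") {
    run_stl_baseline(scen$related, scen$x_u, scen$label_set, cfg, scen$eval)
  } else {
    run_driver(scen$related, scen$x_l, scen$x_u, scen$truth, scen$label_set,
               scen$pool, cfg, scen$eval,
               prior_model = if (cfg$variant == "CAL_star") scen$prior_model)
  }
}
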