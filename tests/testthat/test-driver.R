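test_that("scenario construction matches each reconfiguration case", {
  scen <- small_scenario(seed = 1)
  expect_length(scen$related, 2L)                 # leave-one-subject-out
  expect_equal(nrow(scen$x_u), length(scen$truth))
  expect_false("label" %in% names(scen$x_u))
  expect_true(any(vapply(scen$pool$experts, `[[`, "", "kind") == "perfect"))

  cfgc <- world_config(n_subjects = 2, n_locations = 2,
                       subject_shift_scale = 0.5, seed = 2)
  conf <- build_scenario("configuration_change", cfgc, q = 4,
                         n_per_class = 30, n_source_per_class = 15)
  expect_false(is.null(conf$prior_model))
  expect_lt(length(conf$prior_model$label_space), length(conf$label_set))

  un <- small_scenario(seed = 3, scenario = "user_need_change")
  new_labels <- un$label_set[3:4]
  for (db in un$related) expect_false(any(db$label %in% new_labels))
  expect_true(any(un$truth %in% new_labels))
  expect_false(any(new_labels %in% un$prior_model$label_space))
})

test_that("a prior model lowers initial uncertainty on its covered labels", {
  gaps <- sapply(1:10, function(s) {
    cfgc <- world_config(n_subjects = 2, n_locations = 2,
                         subject_shift_scale = 0.5, seed = s)
    conf <- build_scenario("configuration_change", cfgc, q = 4,
                           n_per_class = 30, n_source_per_class = 15)
    u <- learner_uncertainty(conf$prior_model, conf$x_u, conf$label_set)
    covered <- conf$prior_model$label_space
    mean(u[setdiff(conf$label_set, covered)]) - mean(u[covered])
  })
  expect_gt(mean(gaps), 0)
})

test_that("a vacuous threshold stops before any query", {
  scen <- small_scenario(seed = 4)
  r <- run_scenario(scen, run_config(variant = "CAL", u_th = 100,
                                     budget_fraction = 0.2, seed = 4))
  expect_equal(r$n_queries, 0L)
  expect_equal(nrow(r$ledger), 0L)
  expect_length(r$accuracy, 1L)
})

test_that("runs terminate at the budget and conserve instances", {
  scen <- small_scenario(seed = 5)
  cfg <- run_config(variant = "CAL", u_th = 0.3, budget_fraction = 1,
                    stop_uth = 0, seed = 5)
  r <- run_scenario(scen, cfg)
  expect_equal(r$sizes$n_unlabeled[nrow(r$sizes)], 0L)  # pool exhausted
  # conservation: labeled + unlabeled constant across rounds
  totals <- r$sizes$n_labeled + r$sizes$n_unlabeled
  expect_true(all(totals == totals[1]))
  expect_true(all(diff(r$sizes$n_labeled) > 0))
  expect_true(all(diff(r$sizes$n_unlabeled) < 0))
  # ledger conservation
  expect_equal(total_cost(r$ledger), sum(r$ledger$cost))
  # traces have matching lengths
  expect_length(r$accuracy, nrow(r$sizes))
  expect_equal(nrow(r$uncertainty), nrow(r$sizes))
})

test_that("identical configuration and seeds reproduce identical traces", {
  scen <- small_scenario(seed = 6)
  cfg <- run_config(variant = "CAL", u_th = 0.2, budget_fraction = 0.2,
                    stop_uth = 0, seed = 6)
  r1 <- run_scenario(scen, cfg)
  r2 <- run_scenario(scen, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$uncertainty, r2$uncertainty)
})

test_that("driver validates its inputs", {
  scen <- small_scenario(seed = 7)
  cfg <- run_config(variant = "CAL", seed = 7)
  no_perfect <- expert_pool(
    Filter(function(e) e$kind != "perfect", scen$pool$experts),
    scen$label_set
  )
  expect_error(run_driver(scen$related, scen$x_l, scen$x_u, scen$truth,
                          scen$label_set, no_perfect, cfg, scen$eval),
               class = "comeal_config_error")
  expect_error(run_driver(scen$related, scen$x_l, scen$x_u[0, ],
                          character(0), scen$label_set, scen$pool, cfg,
                          scen$eval),
               class = "comeal_config_error")
})

test_that("CAL_star auto-labels confident target data before querying", {
  cfgc <- world_config(n_subjects = 2, n_locations = 2,
                       subject_shift_scale = 0.3, seed = 8)
  conf <- build_scenario("configuration_change", cfgc, q = 4,
                         n_per_class = 40, class_sep = 6,
                         n_source_per_class = 15)
  star <- run_scenario(conf, run_config(variant = "CAL_star", u_th = 0.2,
                                        budget_fraction = 0.15,
                                        stop_uth = 0, seed = 8))
  plain <- run_scenario(conf, run_config(variant = "CAL", u_th = 0.2,
                                         budget_fraction = 0.15,
                                         stop_uth = 0, seed = 8))
  # the prior path moves confident instances out of the unlabeled pool
  expect_lt(star$sizes$n_unlabeled[1], plain$sizes$n_unlabeled[1])
})

test_that("STL adds sources in similarity order and exhausts them", {
  scen <- small_scenario(seed = 9)
  cfg <- run_config(variant = "STL", seed = 9)
  r <- run_stl_baseline(scen$related, scen$x_u, scen$label_set, cfg,
                        scen$eval)
  expect_length(r$accuracy, length(scen$related))
  expect_equal(r$n_queries, 0L)
  expect_equal(nrow(r$ledger), 0L)
  expect_setequal(r$source_order, names(scen$related))
})

test_that("matched-distribution sources keep STL accuracy non-decreasing", {
  deltas <- sapply(1:10, function(s) {
    cfg0 <- world_config(n_subjects = 4, n_locations = 1,
                         subject_shift_scale = 0, seed = s)
    ft <- generate_feature_world(cfg0, q = 4, n_per_class = 25,
                                 class_sep = 4)
    target <- ft[ft$subject == "s1", ]
    related <- split(ft[ft$subject != "s1", ],
                     ft$subject[ft$subject != "s1"])
    r <- run_stl_baseline(related, target[feature_cols(target)],
                          cfg0$label_set, run_config(variant = "STL",
                                                     seed = s), target)
    mean(diff(r$accuracy))
  })
  expect_gte(mean(deltas), 0)
})

test_that("a far-shifted source degrades STL when finally added", {
  drops <- sapply(1:10, function(s) {
    cfg0 <- world_config(n_subjects = 3, n_locations = 1,
                         subject_shift_scale = 0, seed = s)
    ft <- generate_feature_world(cfg0, q = 4, n_per_class = 25,
                                 class_sep = 4)
    target <- ft[ft$subject == "s1", ]
    good <- ft[ft$subject == "s2", ]
    bad <- ft[ft$subject == "s3", ]
    # a source whose activity patterns conflict with the target's: shifted
    # into the target's feature range with rotated labels
    bad[feature_cols(bad)] <- bad[feature_cols(bad)] + 2
    labs <- cfg0$label_set
    bad$label <- labs[match(bad$label, labs) %% length(labs) + 1]
    r <- run_stl_baseline(list(good = good, bad = bad),
                          target[feature_cols(target)], cfg0$label_set,
                          run_config(variant = "STL", seed = s), target)
    r$accuracy[which(r$source_order == "bad")] -
      r$accuracy[which(r$source_order == "good")]
  })
  expect_lte(mean(drops), 0)
})
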