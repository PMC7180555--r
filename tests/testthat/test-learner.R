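test_that("entropy informativeness matches direct evaluation", {
  expect_equal(entropy_informativeness(rep(0.25, 4)), log(4))
  expect_equal(entropy_informativeness(c(1, 0, 0)), 0)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(entropy_informativeness(p), -sum(p * log(p)))
  expect_equal(round(entropy_informativeness(p), 4), 1.0297)
  expect_error(entropy_informativeness(c(0.5, 0.3)),
               class = "comeal_input_error")
  expect_error(entropy_informativeness(c(-0.1, 1.1)),
               class = "comeal_input_error")
})

test_that("the uniform posterior uniquely maximizes entropy", {
  set.seed(3)
  k <- 5
  u_ent <- entropy_informativeness(rep(1 / k, k))
  for (i in 1:50) {
    p <- runif(k); p <- p / sum(p)
    if (max(abs(p - 1 / k)) > 1e-6) {
      expect_lt(entropy_informativeness(p), u_ent)
    }
  }
})

test_that("leaf purity converts and bounds correctly", {
  # hand-built stub: two trees with leaf purities 1.0 and 0.5
  expect_equal(as.numeric(comeal:::purity_to_informativeness(c(1.0, 0.5))),
               0.25)
  expect_equal(as.numeric(comeal:::purity_to_informativeness(
    rbind(c(1, 1), c(0.5, 0.7)))), c(0, 0.4))

  # a forest on well-separated data has (near-)pure leaves; purity is
  # tabulated over the full training set, so out-of-bag strays keep the
  # score slightly above an exact 0
  tab <- separable_tables(seed = 5, class_sep = 12)
  model <- fit_learner(tab, seed = 1)
  expect_lt(max(as.numeric(leaf_purity_informativeness(tab, model))), 0.05)

  # a genuinely mixed region scores higher than a pure one
  mixed <- data.frame(f1 = c(rep(0, 20), rep(10, 20), rep(5, 20)),
                      f2 = 0,
                      label = c(rep("a", 20), rep("b", 20),
                                rep(c("a", "b"), 10)))
  mm <- fit_learner(mixed, seed = 1)
  probe <- data.frame(f1 = c(0, 5), f2 = 0)
  s_mix <- as.numeric(leaf_purity_informativeness(probe, mm))
  expect_gt(s_mix[2], s_mix[1])

  # scores never exceed 1 - 1/k
  noisy <- expert_world(seed = 6, class_sep = 0.5, k = 3)
  m2 <- fit_learner(noisy, seed = 2)
  s <- as.numeric(leaf_purity_informativeness(noisy, m2))
  expect_true(all(s >= 0 & s <= 1 - 1 / 3 + 1e-12))
})

test_that("fitting is deterministic and handles degenerate label sets", {
  tab <- expert_world(seed = 3)
  m1 <- fit_learner(tab, seed = 7)
  m2 <- fit_learner(tab, seed = 7)
  expect_identical(predict_posterior(m1, tab), predict_posterior(m2, tab))
  expect_equal(rowSums(predict_posterior(m1, tab)), rep(1, nrow(tab)),
               tolerance = 1e-9)

  single <- tab[tab$label == "l1", ]
  md <- fit_learner(single, seed = 1)
  p <- predict_posterior(md, tab)
  expect_equal(dim(p), c(nrow(tab), 1L))
  expect_true(all(p == 1))

  expect_error(fit_learner(tab[0, ]), class = "comeal_training_error")

  sep <- separable_tables(seed = 9, class_sep = 10)
  ms <- fit_learner(sep, seed = 1)
  expect_equal(mean(predict_label(ms, sep) == sep$label), 1.0)
})

test_that("informative-instance selection respects K, forcing and ties", {
  tab <- separable_tables(seed = 2, n_per_class = 30, class_sep = 8)
  model <- fit_learner(tab, seed = 1)

  # saturation: K >= pool returns everything
  pool <- tab[1:7, ]
  expect_setequal(get_informative_instances(50, pool, model, "entropy"),
                  1:7)

  # forced maximizer: a midpoint between the class centers is most uncertain
  ca <- colMeans(feature_matrix(tab[tab$label == "a", ]))
  cb <- colMeans(feature_matrix(tab[tab$label == "b", ]))
  mid <- as.data.frame(rbind((ca + cb) / 2))
  names(mid) <- feature_cols(tab)
  pool2 <- rbind(tab[c(1:3, 31:33), feature_cols(tab)], mid)
  expect_equal(get_informative_instances(1, pool2, model, "entropy"),
               7L)

  # tied scores fall back to insertion order
  tied <- rbind(mid, mid, tab[1, feature_cols(tab)])
  expect_equal(get_informative_instances(2, tied, model, "entropy"), c(1L, 2L))

  expect_error(get_informative_instances(0, pool, model, "entropy"),
               class = "comeal_config_error")
})

test_that("entropy selection agrees with brute-force score sorting", {
  tab <- expert_world(seed = 8, n_per_class = 25, class_sep = 2, k = 3)
  model <- fit_learner(tab, seed = 4)
  pool <- tab[sample(nrow(tab), 40), ]
  p <- predict_posterior(model, pool)
  brute <- apply(p, 1, entropy_informativeness)
  ord <- order(-brute, seq_along(brute))
  expect_equal(get_informative_instances(10, pool, model, "entropy"),
               ord[1:10])
})

test_that("random selection is seeded and model-free", {
  pool <- expert_world(seed = 1, n_per_class = 10)
  s1 <- get_informative_instances(5, pool, strategy = "random", seed = 3)
  s2 <- get_informative_instances(5, pool, strategy = "random", seed = 3)
  s3 <- get_informative_instances(5, pool, strategy = "random", seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("learner uncertainty follows the confidence-complement rule", {
  # hand-built posteriors: two instances predicted l1 with max 0.6 and 0.8
  p <- rbind(c(0.6, 0.4), c(0.8, 0.2), c(0.1, 0.9))
  u <- comeal:::uncertainty_from_posterior(p, c("l1", "l2"))
  expect_equal(u[["l1"]], 30)         # 100 * (1 - 0.7)
  expect_equal(u[["l2"]], 100 * (1 - 0.9))

  # one-hot posteriors over all labels -> all zero
  ph <- rbind(c(1, 0), c(0, 1))
  expect_equal(unname(comeal:::uncertainty_from_posterior(ph, c("a", "b"))),
               c(0, 0))

  # a label never predicted gets 100 (also labels outside the model space)
  pn <- rbind(c(0.9, 0.1))
  u2 <- comeal:::uncertainty_from_posterior(pn, c("a", "b"), c("a", "b", "c"))
  expect_equal(unname(u2), c(10, 100, 100))

  tab <- expert_world(seed = 2)
  model <- fit_learner(tab, seed = 1)
  u3 <- learner_uncertainty(model, tab)
  expect_true(all(u3 >= 0 & u3 <= 100))
})

test_that("more labeled data does not raise learner uncertainty on average", {
  per_label <- sapply(1:10, function(seed) {
    tab <- expert_world(seed = seed, n_per_class = 60, class_sep = 3, k = 3)
    sp <- split_expert_initialization(tab, 0.5, seed = seed)
    idx_small <- unlist(lapply(split(seq_len(nrow(sp$init)), sp$init$label),
                               head, 8))
    m_small <- fit_learner(sp$init[idx_small, ], seed = seed)
    m_big <- fit_learner(sp$init, seed = seed)
    mean(learner_uncertainty(m_big, sp$eval)) -
      mean(learner_uncertainty(m_small, sp$eval))
  })
  expect_lte(mean(per_label), 0)
})
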