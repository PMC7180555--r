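# Stub pools (helper-stubs.R) with fixed uncertainties/costs/answers let
# the annotation routine be checked against exhaustive enumeration.

test_that("majority vote returns the mode and refuses ties", {
  expect_equal(majority_vote(c("a", "a", "b")), "a")
  expect_true(is.na(majority_vote(c("a", "b"))))
  expect_true(is.na(majority_vote(character(0))))
  expect_true(is.na(majority_vote(c(NA, NA))))
  expect_equal(majority_vote(c(NA, "c", NA)), "c")
})

test_that("a single perfect expert annotates with ground truth at its cost", {
  labs <- c("a", "b")
  pool <- expert_pool(list(make_perfect_expert(labs, 0, base_cost = 10)),
                      labs)
  res <- annotate(one_row(), pool, semi_label = "a", u_th = 0.2,
                  true_label = "b")
  expect_equal(res$label, "b")
  expect_equal(total_cost(res$ledger), 10)
  expect_equal(nrow(res$ledger), 1L)
})

test_that("a confident on-demand majority ends annotation at phase 1", {
  labs <- c("a", "b")
  pool <- stub_pool(list(
    list(kind = "on_demand", u = 5, cost = 0, returns = "b"),
    list(kind = "on_demand", u = 8, cost = 0, returns = "b"),
    list(kind = "perfect", u = 1, cost = 10, returns = "b")
  ), labs)
  res <- annotate(one_row(), pool, semi_label = "a", u_th = 0.1,
                  true_label = "b")
  expect_equal(res$label, "b")
  expect_equal(total_cost(res$ledger), 0)
  expect_true(all(res$ledger$expert_kind == "on_demand"))
})

test_that("phase 2 asks the cheapest expert among the confident set", {
  labs <- c("a", "b")
  # (u, cost) = (5, 10), (8, 4), (50, 1); threshold 10 -> cost-4 expert
  pool <- stub_pool(list(
    list(id = "X", kind = "perfect", u = 5, cost = 10, returns = "a"),
    list(id = "Y", kind = "imperfect", u = 8, cost = 4, returns = "a"),
    list(id = "Z", kind = "imperfect", u = 50, cost = 1, returns = "a")
  ), labs)
  res <- annotate(one_row(), pool, semi_label = "a", u_th = 10 / 100,
                  true_label = "a")
  expect_equal(res$ledger$expert_id, "Y")
  expect_equal(total_cost(res$ledger), 4)
})

test_that("annotation escalates when no expert can satisfy the threshold", {
  labs <- c("a", "b")
  pool <- stub_pool(list(
    list(kind = "imperfect", u = 50, cost = 1, returns = "a")
  ), labs)
  err <- tryCatch(
    annotate(one_row(), pool, semi_label = "a", u_th = 0.1,
             true_label = "a"),
    comeal_escalation_error = function(e) e
  )
  expect_s3_class(err, "comeal_escalation_error")
  expect_equal(err$label, "a")
})

test_that("semi-label revisions re-evaluate and eventually force a perfect expert", {
  labs <- c("a", "b")
  # the cheap expert keeps answering "b", on which it is not confident;
  # the loop must cap and fall back to the perfect expert
  pool <- stub_pool(list(
    list(id = "P", kind = "perfect", u = 1, cost = 10,
         answer = function(x, true_label) true_label),
    list(id = "C", kind = "imperfect", u = c(5, 90), cost = 1,
         returns = "b")
  ), labs)
  res <- annotate(one_row(), pool, semi_label = "a", u_th = 0.1,
                  true_label = "a")
  expect_equal(res$label, "a")
  expect_true("P" %in% res$ledger$expert_id)
})

test_that("ledger totals equal the sum of per-query charges", {
  labs <- c("a", "b")
  pool <- stub_pool(list(
    list(kind = "on_demand", u = 90, cost = 0.5, returns = "a"),
    list(kind = "perfect", u = 2, cost = 7, returns = "a")
  ), labs)
  led <- new_cost_ledger()
  for (i in 1:5) {
    res <- annotate(one_row(), pool, "a", 0.1, led, true_label = "a",
                    instance_id = paste0("x", i), round = i)
    led <- res$ledger
  }
  expect_equal(total_cost(led), sum(led$cost))
  expect_equal(nrow(led), 10L)                   # one on-demand + one perfect each
  expect_equal(total_cost(led), 5 * (0.5 + 7))
  expect_equal(unname(query_counts(led, "expert_kind")), c(5L, 5L))
})

test_that("the exact oracle picks per-instance minima and reports infeasibility", {
  # one instance, two feasible experts with costs 3 and 7
  sol <- exact_assignment_oracle(matrix(c(3, 7), 1), matrix(c(5, 5), 1), 10)
  expect_equal(sol$assignment, 1L)
  expect_equal(sol$total_cost, 3)

  # no feasible expert -> reported, not an error
  sol2 <- exact_assignment_oracle(matrix(c(3, 7), 1), matrix(c(50, 60), 1),
                                  10)
  expect_equal(sol2$infeasible, 1L)
  expect_true(is.na(sol2$assignment))
  expect_equal(sol2$total_cost, 0)

  expect_error(exact_assignment_oracle(matrix(0, 13, 2), matrix(0, 13, 2), 1),
               class = "comeal_config_error")
})

test_that("per-instance decomposition equals joint enumeration on random tables", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:4, 1); p <- sample(2:3, 1)
    costs <- matrix(runif(n * p, 1, 10), n, p)
    unc <- matrix(runif(n * p, 0, 100), n, p)
    th <- runif(1, 20, 90)
    sol <- exact_assignment_oracle(costs, unc, th)
    # joint enumeration over all expert assignments
    grids <- expand.grid(rep(list(seq_len(p)), n))
    feas_cost <- apply(grids, 1, function(a) {
      if (all(unc[cbind(seq_len(n), a)] <= th)) {
        sum(costs[cbind(seq_len(n), a)])
      } else NA_real_
    })
    if (all(!is.na(sol$assignment))) {
      expect_equal(sol$total_cost, min(feas_cost, na.rm = TRUE))
    } else {
      expect_true(all(is.na(feas_cost)))
    }
  }
})

test_that("greedy annotation matches the oracle when answers confirm semi-labels", {
  set.seed(21)
  labs <- c("a", "b", "c")
  for (rep in 1:20) {
    p <- sample(3:5, 1)
    u <- matrix(runif(p * 3, 0, 60), p, 3)
    u[1, ] <- runif(3, 0, 5)                      # a near-perfect anchor
    cost <- c(10, runif(p - 1, 1, 8))
    specs <- lapply(seq_len(p), function(j) {
      list(id = paste0("E", j),
           kind = if (j == 1) "perfect" else "imperfect",
           u = u[j, ], cost = cost[j],
           answer = local({jj <- j; function(x, true_label) attr(x, "semi")}))
    })
    pool <- stub_pool(specs, labs)
    semis <- sample(labs, 6, replace = TRUE)
    th <- 30

    tabs <- comeal:::assignment_tables(pool, semis)
    sol <- exact_assignment_oracle(tabs$costs, tabs$uncertainties, th)

    led <- new_cost_ledger()
    for (i in seq_along(semis)) {
      x <- one_row(); attr(x, "semi") <- semis[i]
      res <- annotate(x, pool, semis[i], th / 100, led,
                      true_label = semis[i], instance_id = paste0("x", i))
      led <- res$ledger
    }
    expect_equal(total_cost(led), sol$total_cost)
  }
})

test_that("raising the threshold never increases assignment cost", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(2:8, 1); p <- sample(2:6, 1)
    costs <- matrix(runif(n * p, 1, 10), n, p)
    unc <- matrix(runif(n * p, 0, 100), n, p)
    unc[, 1] <- 0                                # keep everything feasible
    t1 <- runif(1, 10, 50); t2 <- t1 + runif(1, 0, 40)
    c1 <- exact_assignment_oracle(costs, unc, t1)$total_cost
    c2 <- exact_assignment_oracle(costs, unc, t2)$total_cost
    expect_gte(c1, c2)
  }
})
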