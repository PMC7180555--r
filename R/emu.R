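# Expert management unit: the greedy cost-minimizing annotation routine,
# the cost ledger, and the exact small-instance assignment oracle that
# certifies the greedy.

#' Create an empty cost ledger
#'
#' The ledger is an append-only record of every expert charge: which expert
#' answered which query in which round, at what cost, returning which label,
#' and what the semi-label was when the expert was asked.
#'
#' @return A zero-row data frame of class `comeal_cost_ledger`.
#' @export
new_cost_ledger <- function() {
  structure(
    data.frame(round = integer(0), instance_id = character(0),
               expert_id = character(0), expert_kind = character(0),
               cost = numeric(0), returned_label = character(0),
               semi_label = character(0), stringsAsFactors = FALSE),
    class = c("comeal_cost_ledger", "data.frame")
  )
}

ledger_charge <- function(ledger, round, instance_id, expert, returned_label,
                          semi_label) {
  rec <- data.frame(round = as.integer(round),
                    instance_id = as.character(instance_id),
                    expert_id = expert$id, expert_kind = expert$kind,
                    cost = expert$unit_cost,
                    returned_label = as.character(returned_label),
                    semi_label = as.character(semi_label),
                    stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(ledger), rec),
            class = c("comeal_cost_ledger", "data.frame"))
}

#' Total cost recorded in a ledger
#'
#' @param ledger A `comeal_cost_ledger`.
#' @return Sum of all per-query charges.
#' @export
total_cost <- function(ledger) sum(ledger$cost)

#' Per-expert query counts from a ledger
#'
#' @param ledger A `comeal_cost_ledger`.
#' @param by Count by `"expert_id"` or `"expert_kind"`.
#' @return Named integer vector of query counts.
#' @export
query_counts <- function(ledger, by = c("expert_id", "expert_kind")) {
  by <- match.arg(by)
  if (nrow(ledger) == 0L) return(integer(0))
  tab <- table(ledger[[by]])
  setNames(as.integer(tab), names(tab))
}

#' Write a ledger as JSON-lines / summarise it as CSV
#'
#' @param ledger A `comeal_cost_ledger`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ledger_jsonl <- function(ledger, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ledger))) {
    writeLines(jsonlite::toJSON(as.list(ledger[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_ledger_jsonl
#' @export
write_ledger_summary <- function(ledger, path) {
  if (nrow(ledger) == 0L) {
    summary <- data.frame(expert_id = character(0), expert_kind = character(0),
                          n_queries = integer(0), cost = numeric(0))
  } else {
    summary <- aggregate(cost ~ expert_id + expert_kind, data = ledger, sum)
    counts <- aggregate(cost ~ expert_id, data = ledger, length)
    names(counts)[2] <- "n_queries"
    summary <- merge(summary, counts, by = "expert_id")
  }
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Majority vote over expert answers
#'
#' @param answers Character vector of labels (abstentions already removed,
#'   or present as `NA` and dropped here).
#' @return The modal label, or `NA` on a tie or when no answers remain.
#' @export
#' @examples
#' majority_vote(c("walk", "walk", "sit"))  # "walk"
#' majority_vote(c("walk", "sit"))          # NA
majority_vote <- function(answers) {
  answers <- answers[!is.na(answers)]
  if (length(answers) == 0L) return(NA_character_)
  tab <- table(answers)
  top <- max(tab)
  if (sum(tab == top) > 1L) return(NA_character_)
  names(tab)[which.max(tab)]
}

#' Annotate one instance through the expert pool
#'
#' The greedy two-phase expert-selection routine. Phase 1 queries every
#' on-demand expert (each charged its unit cost, usually 0); if their
#' non-abstaining answers have a majority label, the semi-label becomes that
#' label and the working uncertainty `u` becomes the minimum uncertainty on
#' it among the agreeing on-demand experts. Phase 2 then loops while `u`
#' exceeds the threshold for the current semi-label: among perfect and
#' imperfect experts whose uncertainty on the semi-label is within
#' threshold, the cheapest is asked (and charged); the semi-label becomes
#' its answer and `u` its uncertainty on that answer. If an answer keeps
#' revising the semi-label, after as many iterations as there are experts
#' the cheapest perfect expert is forced and its answer accepted.
#'
#' @param x One-row feature table (the query instance).
#' @param pool A `comeal_expert_pool`.
#' @param semi_label The learner's current most probable label for `x`.
#' @param u_th Uncertainty threshold: scalar or per-label vector, percent in
#'   `[0, 100]` or fraction in `(0, 1]`.
#' @param ledger Ledger to append charges to.
#' @param true_label Hidden ground truth (consumed by perfect experts).
#' @param instance_id Identifier recorded in the ledger.
#' @param round Query round recorded in the ledger.
#' @return A list with `label` (the final label) and `ledger`.
#' @export
annotate <- function(x, pool, semi_label, u_th, ledger = new_cost_ledger(),
                     true_label = NULL, instance_id = "x", round = 1L) {
  if (!inherits(pool, "comeal_expert_pool") || length(pool$experts) == 0L) {
    stop_config("pool must be a non-empty comeal_expert_pool")
  }
  u_th <- normalize_threshold(u_th, pool$label_set)
  u <- 100

  # Phase 1: query all on-demand experts.
  od <- Filter(function(e) e$kind == "on_demand", pool$experts)
  if (length(od) > 0L) {
    answers <- character(0)
    for (e in od) {
      ans <- ask_expert(e, x, true_label)
      ledger <- ledger_charge(ledger, round, instance_id, e,
                              ans$label, semi_label)
      answers[e$id] <- ans$label
    }
    winner <- majority_vote(answers)
    if (!is.na(winner)) {
      semi_label <- winner
      agree <- names(answers)[!is.na(answers) & answers == winner]
      u <- min(vapply(od[agree], function(e) e$uncertainty[[winner]],
                      numeric(1)))
    }
  }

  # Phase 2: cheapest confident perfect/imperfect expert until within
  # threshold.
  others <- Filter(function(e) e$kind %in% c("perfect", "imperfect"),
                   pool$experts)
  iter <- 0L
  max_iter <- length(pool$experts)
  while (u > u_th[[semi_label]]) {
    feasible <- Filter(function(e) e$uncertainty[[semi_label]] <= u_th[[semi_label]],
                       others)
    if (length(feasible) == 0L) {
      stop(errorCondition(
        paste0("no expert satisfies the uncertainty threshold for label '",
               semi_label, "'"),
        class = c("comeal_escalation_error", "error"), label = semi_label))
    }
    costs <- vapply(feasible, `[[`, numeric(1), "unit_cost")
    chosen <- feasible[[which.min(costs)]]   # ties: pool insertion order
    ans <- ask_expert(chosen, x, true_label)
    ledger <- ledger_charge(ledger, round, instance_id, chosen,
                            ans$label, semi_label)
    semi_label <- ans$label
    u <- chosen$uncertainty[[semi_label]]
    iter <- iter + 1L
    if (iter >= max_iter && u > u_th[[semi_label]]) {
      # Cap reached: force the cheapest perfect expert and accept its answer.
      perfect <- Filter(function(e) e$kind == "perfect", others)
      if (length(perfect) == 0L) {
        stop(errorCondition(
          paste0("annotation cannot settle for label '", semi_label,
                 "' and the pool has no perfect expert"),
          class = c("comeal_escalation_error", "error"), label = semi_label))
      }
      pcosts <- vapply(perfect, `[[`, numeric(1), "unit_cost")
      forced <- perfect[[which.min(pcosts)]]
      ans <- ask_expert(forced, x, true_label)
      ledger <- ledger_charge(ledger, round, instance_id, forced,
                              ans$label, semi_label)
      semi_label <- ans$label
      break
    }
  }
  list(label = semi_label, ledger = ledger)
}

#' Exact assignment oracle for small instances
#'
#' The expert-assignment subproblem — pick exactly one feasible expert per
#' selected instance to minimize total cost, an expert being feasible when
#' its uncertainty at the instance's semi-label is within threshold —
#' decomposes per instance because each instance is constrained
#' independently and costs are additive. This oracle exhaustively enumerates
#' each instance's feasible experts and returns the global minimum-cost
#' assignment; it certifies the greedy routine on instances of at most 12
#' queries by 8 experts.
#'
#' @param costs n-by-p matrix: `costs[i, j]` is the cost of asking expert j
#'   for instance i.
#' @param uncertainties n-by-p matrix: expert j's uncertainty (percent) at
#'   instance i's semi-label.
#' @param u_th Threshold per instance (scalar recycled), percent or
#'   fraction.
#' @return A list with `selected` (logical per instance, `TRUE` when
#'   feasible), `assignment` (chosen expert index per instance, `NA` when
#'   infeasible), `total_cost` (over feasible instances), and `infeasible`
#'   (indices with an empty feasible set).
#' @export
exact_assignment_oracle <- function(costs, uncertainties, u_th) {
  costs <- as.matrix(costs)
  uncertainties <- as.matrix(uncertainties)
  if (!all(dim(costs) == dim(uncertainties))) {
    stop_input("costs and uncertainties must have the same dimensions")
  }
  n <- nrow(costs); p <- ncol(costs)
  if (n > 12L || p > 8L) {
    stop_config("oracle is limited to at most 12 instances x 8 experts")
  }
  if (all(u_th <= 1)) u_th <- u_th * 100
  u_th <- rep_len(u_th, n)
  assignment <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    feas <- which(uncertainties[i, ] <= u_th[i])
    if (length(feas) == 0L) next
    assignment[i] <- feas[which.min(costs[i, feas])]
  }
  selected <- !is.na(assignment)
  list(selected = selected,
       assignment = assignment,
       total_cost = sum(costs[cbind(which(selected),
                                    assignment[selected])]),
       infeasible = which(!selected))
}

# Build the oracle's cost/uncertainty tables for the phase-2 experts of a
# pool at given semi-labels.
assignment_tables <- function(pool, semi_labels) {
  experts <- Filter(function(e) e$kind %in% c("perfect", "imperfect"),
                    pool$experts)
  n <- length(semi_labels); p <- length(experts)
  costs <- matrix(0, n, p, dimnames = list(NULL, names(experts)))
  unc <- matrix(0, n, p, dimnames = list(NULL, names(experts)))
  for (j in seq_len(p)) {
    costs[, j] <- experts[[j]]$unit_cost
    unc[, j] <- vapply(semi_labels,
                       function(l) experts[[j]]$uncertainty[[l]], numeric(1))
  }
  list(costs = costs, uncertainties = unc)
}
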