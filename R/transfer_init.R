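# Transfer-learning initialization: match k-means clusters of the unlabeled
# target data to labels, then pick for each label the most similar labeled
# source domain.

#' Cosine similarity between two vectors
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return `a . b / (|a| |b|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(4, 5, 6))  # 0.9746
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_input("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_input("cosine similarity of a zero vector")
  sum(a * b) / (na * nb)
}

# Greedy maximum-weight one-to-one matching on a similarity matrix
# (rows = labels, cols = clusters): repeatedly take the globally best
# remaining (label, cluster) pair.
greedy_matching <- function(sim) {
  match <- setNames(rep(NA_integer_, nrow(sim)), rownames(sim))
  rows <- seq_len(nrow(sim)); cols <- seq_len(ncol(sim))
  while (length(rows) > 0L && length(cols) > 0L) {
    sub <- sim[rows, cols, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    match[rows[best[1L]]] <- cols[best[2L]]
    rows <- rows[-best[1L]]
    cols <- cols[-best[2L]]
  }
  match
}

#' Initialize the learner from related labeled source domains
#'
#' Clusters the unlabeled target data into `k = |label_set|` groups
#' (k-means, 10 restarts, seeded), computes per-source per-label class
#' centers, assigns clusters to labels by greedy maximum-weight one-to-one
#' matching on cosine similarity, and for each label selects the source
#' domain whose class center is most similar to the label's matched cluster
#' center. The returned initialization set is the union of the selected
#' per-label source subsets — different labels may draw from different
#' sources. Labels present in no source are left without initialization
#' data (the active-learning loop must acquire them).
#'
#' @param related List of labeled source feature tables (one per source
#'   domain).
#' @param target_unlabeled Unlabeled target feature table with at least `k`
#'   distinct instances.
#' @param label_set Character vector of target labels.
#' @param seed Integer seed for the clustering.
#' @return A list with `data` (the initialization table, rows drawn from
#'   the sources) and `report` (a data frame with the chosen source and
#'   similarity per label).
#' @export
initialize_learner <- function(related, target_unlabeled, label_set,
                               seed = 1L) {
  if (length(related) == 0L) stop_config("no related source domains supplied")
  for (db in related) {
    if (!"label" %in% names(db) || anyNA(db$label)) {
      stop_config("every related dictionary must be fully labeled")
    }
  }
  k <- length(label_set)
  x <- feature_matrix(target_unlabeled)
  if (nrow(unique(x)) < k) {
    stop(errorCondition("fewer distinct target points than labels",
                        class = c("comeal_initialization_error", "error")))
  }
  km <- local_seed(substream_seed(seed, "transfer-kmeans"),
                   kmeans(x, centers = k, nstart = 10))
  cluster_centers <- km$centers

  # Per-source per-label class centers (feature means).
  if (is.null(names(related))) {
    names(related) <- paste0("source", seq_along(related))
  }
  source_centers <- lapply(related, function(db) {
    m <- feature_matrix(db)
    labs <- sort(unique(as.character(db$label)))
    cen <- t(vapply(labs, function(l) colMeans(m[db$label == l, , drop = FALSE]),
                    numeric(ncol(m))))
    rownames(cen) <- labs
    cen
  })

  # Label-cluster affinity: best similarity over sources carrying the label.
  avail <- intersect(label_set,
                     unique(unlist(lapply(source_centers, rownames))))
  if (length(avail) == 0L) stop_config("no source carries any target label")
  affinity <- matrix(-Inf, length(avail), k,
                     dimnames = list(avail, NULL))
  for (sc in source_centers) {
    for (lab in intersect(rownames(sc), avail)) {
      for (c1 in seq_len(k)) {
        s <- cosine_similarity(sc[lab, ], cluster_centers[c1, ])
        if (s > affinity[lab, c1]) affinity[lab, c1] <- s
      }
    }
  }
  match <- greedy_matching(affinity)

  # Per matched label, the most similar source.
  pieces <- list()
  report <- data.frame(label = character(0), cluster = integer(0),
                       source = character(0), similarity = numeric(0),
                       stringsAsFactors = FALSE)
  for (lab in names(match)) {
    cl <- match[[lab]]
    if (is.na(cl)) next
    sims <- vapply(names(source_centers), function(src) {
      sc <- source_centers[[src]]
      if (!lab %in% rownames(sc)) return(-Inf)
      cosine_similarity(sc[lab, ], cluster_centers[cl, ])
    }, numeric(1))
    best <- names(sims)[which.max(sims)]
    db <- related[[best]]
    pieces[[lab]] <- db[db$label == lab, , drop = FALSE]
    report <- rbind(report, data.frame(label = lab, cluster = cl,
                                       source = best,
                                       similarity = max(sims),
                                       stringsAsFactors = FALSE))
  }
  data <- do.call(rbind, pieces)
  rownames(data) <- NULL
  list(data = data, report = report)
}

#' Auto-label target data with a prior model
#'
#' The prior-knowledge path of the driver (the CAL* variant): target
#' instances whose maximum posterior under the prior model reaches
#' `confidence_floor` are moved to the labeled side with the model's
#' predicted label; the rest stay unlabeled.
#'
#' @param model A trained [fit_learner()] model carried over from the
#'   previous configuration.
#' @param target_unlabeled Unlabeled target feature table.
#' @param confidence_floor Minimum maximum-posterior probability in
#'   `[0, 1]`; default 0.9.
#' @return A list with `labeled` (auto-labeled rows, with a `label`
#'   column), `remaining` (the rest), and `indices` (row indices of the
#'   auto-labeled instances in the input).
#' @export
apply_prior_knowledge <- function(model, target_unlabeled,
                                  confidence_floor = 0.9) {
  if (!inherits(model, "comeal_learner")) stop_state("model is not a comeal_learner")
  if (nrow(target_unlabeled) == 0L) {
    return(list(labeled = target_unlabeled, remaining = target_unlabeled,
                indices = integer(0)))
  }
  p <- predict_posterior(model, target_unlabeled)
  maxp <- apply(p, 1L, max)
  keep <- which(maxp >= confidence_floor)
  labeled <- target_unlabeled[keep, , drop = FALSE]
  if (length(keep) > 0L) {
    labeled$label <- model$label_space[max.col(p[keep, , drop = FALSE],
                                               ties.method = "first")]
  } else {
    labeled$label <- character(0)
  }
  list(labeled = labeled,
       remaining = target_unlabeled[setdiff(seq_len(nrow(target_unlabeled)),
                                            keep), , drop = FALSE],
       indices = keep)
}
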