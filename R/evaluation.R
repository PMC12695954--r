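#' Predict the interaction type for a strain pair in an environment
#'
#' Scores the three candidate relations (negative, neutral, positive in the
#' queried environment) for the triple (sender, relation, receiver) and
#' returns the argmax. Under an `observed_only` relation vocabulary only
#' the types observed in that environment are candidates (at least one is
#' required). Ties are broken by canonical type order (negative first).
#'
#' @param model a trained `microkge_model`.
#' @param sender,receiver entity identifiers.
#' @param environment environment identifier.
#' @return list with `label` (the predicted type) and `scores` (named
#'   numeric vector over the candidate types; NA for unavailable types).
#' @export
classify_interaction <- function(model, sender, receiver, environment) {
  res <- classify_batch(model, sender, receiver, environment)
  list(label = res$labels[1L], scores = res$scores[1L, ])
}

# vectorized interaction-type classification; returns labels + score matrix
classify_batch <- function(model, senders, receivers, environments) {
  emb <- as_embeddings(model)
  n <- length(senders)
  check_that(length(receivers) == n && length(environments) == n,
             "senders, receivers, environments must have equal length")
  h <- entity_index(emb, senders)
  t <- entity_index(emb, receivers)
  types <- interaction_types()
  scores <- matrix(NA_real_, n, 3L, dimnames = list(NULL, types))
  for (j in seq_along(types)) {
    rel <- paste0(types[j], "@", environments)
    r <- match(rel, emb$relations)
    ok <- !is.na(r)
    if (any(ok)) scores[ok, j] <- score_batch(emb, h[ok], r[ok], t[ok])
  }
  if (any(rowSums(!is.na(scores)) == 0)) {
    bad <- unique(environments[rowSums(!is.na(scores)) == 0])
    stop("no candidate relation for environment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  masked <- scores
  masked[is.na(masked)] <- -Inf
  labels <- types[max.col(masked, ties.method = "first")]
  list(labels = labels, scores = scores)
}

#' Classification metrics from predicted and true interaction types
#'
#' Computes overall accuracy (correct / total), one-vs-rest precision,
#' recall and F1 per interaction type, macro-F1, and the 3x3 confusion
#' matrix (rows = truth, columns = prediction, canonical order). A
#' zero-denominator precision or recall is defined as 0 with a warning.
#'
#' @param predictions,truths equal-length vectors of interaction types.
#' @return list of class `"microkge_metrics"` with `accuracy`, `per_class`
#'   (data.frame: class, precision, recall, f1, support), `macro_f1`,
#'   `confusion` (3x3 integer matrix) and `n`.
#' @export
classification_metrics <- function(predictions, truths) {
  check_that(length(predictions) == length(truths) && length(truths) > 0,
             "predictions and truths must be non-empty and equal length")
  types <- interaction_types()
  pred <- factor(normalize_label(predictions), levels = types)
  true <- factor(normalize_label(truths), levels = types)
  confusion <- table(truth = true, prediction = pred)
  confusion <- matrix(as.integer(confusion), 3L, 3L,
                      dimnames = list(truth = types, prediction = types))
  total <- sum(confusion)
  accuracy <- sum(diag(confusion)) / total

  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      warning("zero denominator for ", what, " of class '", cls,
              "'; defining it as 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  per_class <- do.call(rbind, lapply(seq_along(types), function(i) {
    tp <- confusion[i, i]
    precision <- safe_div(tp, sum(confusion[, i]), "precision", types[i])
    recall <- safe_div(tp, sum(confusion[i, ]), "recall", types[i])
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class = types[i], precision = precision, recall = recall,
               f1 = f1, support = sum(confusion[i, ]),
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = accuracy, per_class = per_class,
                 macro_f1 = mean(per_class$f1), confusion = confusion,
                 n = total),
            class = "microkge_metrics")
}

#' @export
print.microkge_metrics <- function(x, ...) {
  cat("Classification over", x$n, "triples: accuracy",
      sprintf("%.3f", x$accuracy), "| macro-F1",
      sprintf("%.3f", x$macro_f1), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Classify every triple of an evaluation graph and score the predictions
#'
#' Convenience wrapper: each test triple (sender, (type, e), receiver)
#' becomes the query "which interaction type between this pair in e?", and
#' the predictions are compared with the recorded types.
#'
#' @param model trained `microkge_model`.
#' @param kg evaluation graph.
#' @return a `microkge_metrics` (see [classification_metrics()]).
#' @export
evaluate_classification <- function(model, kg) {
  check_that(nrow(kg$triples) > 0, "evaluation graph has no triples")
  pred <- classify_batch(model, kg$triples$head, kg$triples$tail,
                         kg$triples$environment)
  classification_metrics(pred$labels, kg$triples$type)
}

#' Raw rank of a true triple among entity substitutions
#'
#' The head-based rank compares the score of (h, r, t) with the scores of
#' (h', r, t) for every entity h' in the graph (including h itself); the
#' tail-based rank substitutes the tail. Ranking is raw (unfiltered): other
#' true triples are not removed from the candidate list, matching the
#' literal rank definition. Tied scores receive the mean rank of the tied
#' block, which avoids optimistic bias for untrained or degenerate
#' embeddings.
#'
#' @param model trained `microkge_model`.
#' @param head,relation,tail the true triple.
#' @param side `"head"` or `"tail"`: which slot is substituted.
#' @param filter_against optional `microkge_kg`; when given, candidate
#'   substitutions forming a triple observed there (other than the true
#'   one) are dropped before ranking (filtered ranking).
#' @return numeric rank >= 1.
#' @export
rank_triple <- function(model, head, relation, tail,
                        side = c("head", "tail"), filter_against = NULL) {
  side <- match.arg(side)
  emb <- as_embeddings(model)
  h <- entity_index(emb, head)
  r <- relation_index(emb, relation)
  t <- entity_index(emb, tail)
  n_ent <- length(emb$entities)
  cand <- seq_len(n_ent)
  true_idx <- if (side == "head") h else t
  if (!is.null(filter_against)) {
    obs <- filter_against$triples
    seen <- if (side == "head") {
      obs$relation == relation & obs$tail == tail
    } else {
      obs$head == head & obs$relation == relation
    }
    seen_ent <- match(if (side == "head") obs$head[seen] else obs$tail[seen],
                      emb$entities)
    cand <- union(setdiff(cand, seen_ent), true_idx)
  }
  scores <- if (side == "head") {
    score_batch(emb, cand, rep(r, length(cand)), rep(t, length(cand)))
  } else {
    score_batch(emb, rep(h, length(cand)), rep(r, length(cand)), cand)
  }
  rank(-scores, ties.method = "average")[match(true_idx, cand)]
}

#' Mean reciprocal rank and Hits@k over a test graph
#'
#' For a test set of N triples, 2N ranks are computed (head- and tail-side
#' per triple) and
#' \deqn{MRR = \frac{1}{2N}\sum \left(\frac{1}{rank^h} + \frac{1}{rank^t}\right),}
#' \deqn{Hits@k = \frac{|E^h| + |E^t|}{2N}}
#' with \eqn{E^h, E^t} the triples whose head/tail rank is at most k.
#'
#' @param model trained `microkge_model`.
#' @param test_kg non-empty evaluation graph.
#' @param ks integer cutoffs for Hits@k.
#' @param filter_against optional graph for filtered ranking (see
#'   [rank_triple()]); default NULL gives raw ranks.
#' @return list with `mrr`, `hits_at` (named numeric vector) and `ranks`
#'   (data.frame with head/tail ranks per test triple).
#' @export
mrr_hits <- function(model, test_kg, ks = c(1L, 3L, 10L),
                     filter_against = NULL) {
  tri <- test_kg$triples
  check_that(nrow(tri) > 0, "test graph has no triples")
  rank_h <- rank_t <- numeric(nrow(tri))
  for (i in seq_len(nrow(tri))) {
    rank_h[i] <- rank_triple(model, tri$head[i], tri$relation[i], tri$tail[i],
                             side = "head", filter_against = filter_against)
    rank_t[i] <- rank_triple(model, tri$head[i], tri$relation[i], tri$tail[i],
                             side = "tail", filter_against = filter_against)
  }
  n2 <- 2 * nrow(tri)
  mrr <- sum(1 / rank_h + 1 / rank_t) / n2
  hits <- vapply(ks, function(k) (sum(rank_h <= k) + sum(rank_t <= k)) / n2,
                 numeric(1))
  names(hits) <- paste0("hits@", ks)
  list(mrr = mrr, hits_at = hits,
       ranks = data.frame(head_rank = rank_h, tail_rank = rank_t))
}

# ---- null models ------------------------------------------------------

null_model_kinds <- function() {
  c("A_global_majority", "B_environment_majority", "C_receiver_majority",
    "D_sender_majority", "E_pair_majority")
}

majority_label <- function(labels) {
  counts <- table(factor(labels, levels = interaction_types()))
  interaction_types()[which.max(counts)]   # canonical tie-break
}

#' Fit a majority-class null model on a training graph
#'
#' Five increasingly conditioned majority baselines: (A) the global
#' majority class; (B) the majority within each environment; (C) within
#' each receiver strain; (D) within each sender strain; (E) within each
#' (sender, receiver) pair. A query whose stratum was never seen in
#' training falls back to the global majority; ties break in canonical
#' type order.
#'
#' @param kind one of `"A_global_majority"`, `"B_environment_majority"`,
#'   `"C_receiver_majority"`, `"D_sender_majority"`, `"E_pair_majority"`.
#' @param train_kg non-empty training graph.
#' @return object of class `"microkge_null_model"`.
#' @export
null_model <- function(kind = null_model_kinds(), train_kg) {
  kind <- match.arg(kind)
  tri <- train_kg$triples
  check_that(nrow(tri) > 0, "training graph has no triples")
  strata_key <- switch(kind,
    A_global_majority = rep("", nrow(tri)),
    B_environment_majority = tri$environment,
    C_receiver_majority = tri$tail,
    D_sender_majority = tri$head,
    E_pair_majority = paste(tri$head, tri$tail, sep = "\r"))
  lut <- vapply(split(tri$type, strata_key), majority_label, character(1))
  structure(list(kind = kind, lookup = lut,
                 global = majority_label(tri$type)),
            class = "microkge_null_model")
}

#' Predict with a null model
#'
#' @param kind null model kind (see [null_model()]), or a fitted
#'   `microkge_null_model` in which case `train_kg` is ignored.
#' @param train_kg training graph to fit on.
#' @param sender,receiver,environment the query (vectors allowed).
#' @return character vector of predicted interaction types.
#' @export
null_model_predict <- function(kind, train_kg = NULL, sender, receiver,
                               environment) {
  fit <- if (inherits(kind, "microkge_null_model")) kind
         else null_model(kind, train_kg)
  key <- switch(fit$kind,
    A_global_majority = rep("", length(sender)),
    B_environment_majority = as.character(environment),
    C_receiver_majority = as.character(receiver),
    D_sender_majority = as.character(sender),
    E_pair_majority = paste(sender, receiver, sep = "\r"))
  out <- unname(fit$lookup[key])
  out[is.na(out)] <- fit$global
  out
}

#' Shannon entropy and effective number of interaction types
#'
#' \deqn{H = -\sum_c p(c)\log_2 p(c)} over the three interaction-type
#' proportions (0 log 0 := 0), and the effective class number \eqn{2^H},
#' which ranges from 1 (one class dominates completely) to 3 (uniform).
#'
#' @param class_counts nonnegative counts, one per interaction type (length
#'   3, optionally named).
#' @return list with `H` (bits) and `effective_classes` (= 2^H).
#' @export
interaction_entropy <- function(class_counts) {
  check_that(is.numeric(class_counts) && length(class_counts) == 3 &&
               all(class_counts >= 0), "need 3 nonnegative counts")
  total <- sum(class_counts)
  check_that(total > 0, "all-zero counts: entropy undefined")
  p <- class_counts / total
  p <- p[p > 0]
  H <- -sum(p * log2(p))
  list(H = H, effective_classes = 2^H)
}
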