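#' Phylogenetic feature helpers
#'
#' Phylogenetic features are per-strain coordinates in a Euclidean feature
#' space (e.g. a PCA of 16S rRNA distances, computed upstream and consumed
#' here as a plain table).
#'
#' @param features data.frame with a `strain_id` column and numeric
#'   coordinate columns.
#' @return numeric matrix with strain ids as rownames.
#' @keywords internal
phylo_matrix <- function(features) {
  check_that(is.data.frame(features) && "strain_id" %in% names(features),
             "features must be a data.frame with a strain_id column")
  ids <- as.character(features$strain_id)
  check_that(!anyDuplicated(ids), "duplicate strain_id in features")
  m <- as.matrix(features[, setdiff(names(features), "strain_id"),
                          drop = FALSE])
  check_that(is.numeric(m) && all(is.finite(m)),
             "phylogenetic coordinates must be finite numerics")
  rownames(m) <- ids
  m
}

#' Euclidean distance between two strains in phylogenetic feature space
#'
#' @param features phylogenetic feature table (see [phylo_matrix()]).
#' @param a,b strain identifiers present in the table.
#' @return nonnegative distance.
#' @export
phylo_distance <- function(features, a, b) {
  m <- phylo_matrix(features)
  for (s in c(a, b)) {
    check_that(s %in% rownames(m), paste0("unknown strain: ", s))
  }
  sqrt(sum((m[a, ] - m[b, ])^2))
}

#' Synthetic embedding for a strain absent from the graph
#'
#' Embedding models cannot score entities they were not trained on. For a
#' new strain with known phylogenetic coordinates, a synthetic embedding is
#' built as a distance-weighted average of the embeddings of its k
#' phylogenetically nearest in-graph strains:
#' \deqn{v_{S_n} = \sum_{j=1}^k w_j v_{i_j},\qquad w_j = \frac{1}{1 + d_j}}
#' with the weights renormalized to sum to 1, making the synthetic
#' embedding a convex combination of its neighbours. For SimplE the
#' head-role and tail-role vectors are aggregated separately.
#'
#' @param model trained `microkge_model`.
#' @param features phylogenetic feature table covering the target and the
#'   in-graph strains.
#' @param target strain identifier not present in the model's entity set.
#' @param k number of nearest neighbours (ties broken by canonical strain
#'   order).
#' @param neighbors optional explicit neighbour ids (overrides the
#'   nearest-k selection; used e.g. for random-neighbour baselines). Their
#'   true phylogenetic distances still define the weights.
#' @return list with `roles` (named list of embedding vectors: `E` or
#'   `E_h`/`E_t`), `neighbors`, `distances`, `weights`.
#' @export
synthetic_embedding <- function(model, features, target, k = 5L,
                                neighbors = NULL) {
  emb <- as_embeddings(model)
  m <- phylo_matrix(features)
  check_that(target %in% rownames(m),
             paste0("target '", target, "' has no phylogenetic coordinates"))
  check_that(!(target %in% emb$entities),
             paste0("target '", target, "' is already in the graph"))
  pool <- intersect(emb$entities, rownames(m))
  if (is.null(neighbors)) {
    check_that(k >= 1 && k <= length(pool),
               paste0("k must be in [1, ", length(pool),
                      "] (in-graph strains with coordinates)"))
    d_all <- sqrt(colSums((t(m[pool, , drop = FALSE]) - m[target, ])^2))
    ord <- order(d_all, pool)          # ties by canonical strain order
    neighbors <- pool[ord[seq_len(k)]]
  } else {
    check_that(all(neighbors %in% pool),
               "explicit neighbors must be in-graph strains with coordinates")
  }
  d <- vapply(neighbors,
              function(s) sqrt(sum((m[s, ] - m[target, ])^2)), numeric(1))
  w <- 1 / (1 + d)
  w <- w / sum(w)

  idx <- entity_index(emb, neighbors)
  agg <- function(M) as.numeric(w %*% M[idx, , drop = FALSE])
  roles <- if (emb$model == "SimplE") {
    list(E_h = agg(emb$params$E_h), E_t = agg(emb$params$E_t))
  } else {
    list(E = agg(emb$params$E))
  }
  list(roles = roles, neighbors = neighbors, distances = unname(d),
       weights = unname(w))
}

# score triples where one side is an explicit role-vector set (`syn`) and
# the other an in-graph entity index; r_idx vectorized
score_with_synthetic <- function(emb, syn, partner_idx, r_idx,
                                 target_side = c("head", "tail")) {
  target_side <- match.arg(target_side)
  p <- emb$params
  R <- p$R[r_idx, , drop = FALSE]
  if (emb$model == "SimplE") {
    Ri <- p$R_inv[r_idx, , drop = FALSE]
    if (target_side == "head") {
      0.5 * (rowSums(rep_row(syn$roles$E_h, length(r_idx)) * R *
                       p$E_t[partner_idx, , drop = FALSE]) +
               rowSums(rep_row(syn$roles$E_t, length(r_idx)) * Ri *
                         p$E_h[partner_idx, , drop = FALSE]))
    } else {
      0.5 * (rowSums(p$E_h[partner_idx, , drop = FALSE] * R *
                       rep_row(syn$roles$E_t, length(r_idx))) +
               rowSums(p$E_t[partner_idx, , drop = FALSE] * Ri *
                         rep_row(syn$roles$E_h, length(r_idx))))
    }
  } else {
    tgt <- rep_row(syn$roles$E, length(r_idx))
    prt <- p$E[partner_idx, , drop = FALSE]
    H <- if (target_side == "head") tgt else prt
    T <- if (target_side == "head") prt else tgt
    if (emb$model == "TransE") {
      d <- H + R - T
      if (emb$norm_kind == "L2") -sqrt(rowSums(d^2)) else -rowSums(abs(d))
    } else {
      rowSums(H * R * T)
    }
  }
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Predict interaction types for an unseen strain
#'
#' Substitutes the phylogeny-weighted synthetic embedding of the target for
#' the queried side of each triple and classifies the interaction type as
#' in [classify_interaction()] (argmax over the candidate types, canonical
#' tie-break).
#'
#' @param model trained `microkge_model`.
#' @param features phylogenetic feature table.
#' @param target unseen strain identifier.
#' @param queries data.frame with columns `partner`, `environment`,
#'   `direction` (`"target_as_sender"` or `"target_as_receiver"`).
#' @param k neighbour count for [synthetic_embedding()].
#' @param neighbors optional explicit neighbour override.
#' @return character vector of predicted interaction types, one per query.
#' @export
predict_unseen <- function(model, features, target, queries, k = 5L,
                           neighbors = NULL) {
  check_that(all(c("partner", "environment", "direction") %in% names(queries)),
             "queries needs columns partner, environment, direction")
  check_that(all(queries$direction %in%
                   c("target_as_sender", "target_as_receiver")),
             "direction must be target_as_sender or target_as_receiver")
  emb <- as_embeddings(model)
  syn <- synthetic_embedding(model, features, target, k = k,
                             neighbors = neighbors)
  partner_idx <- entity_index(emb, queries$partner)
  types <- interaction_types()
  n <- nrow(queries)
  scores <- matrix(NA_real_, n, 3L, dimnames = list(NULL, types))
  for (j in seq_along(types)) {
    rel <- paste0(types[j], "@", queries$environment)
    r <- match(rel, emb$relations)
    for (side in c("head", "tail")) {
      sel <- !is.na(r) & (queries$direction ==
        if (side == "head") "target_as_sender" else "target_as_receiver")
      if (any(sel)) {
        scores[sel, j] <- score_with_synthetic(emb, syn, partner_idx[sel],
                                               r[sel], target_side = side)
      }
    }
  }
  if (any(rowSums(!is.na(scores)) == 0)) {
    stop("no candidate relation for some queried environments", call. = FALSE)
  }
  masked <- scores
  masked[is.na(masked)] <- -Inf
  types[max.col(masked, ties.method = "first")]
}

#' Environment embedding: concatenated relation vectors
#'
#' An environment e is represented by concatenating the learned vectors of
#' its three relations (negative, neutral, positive in e), in canonical
#' type order. For SimplE each block is the concatenation of the relation
#' and its inverse vector (6d total); single-relation models give 3d. An
#' environment lacking any of the three relations in the model's vocabulary
#' has no embedding and is excluded from environment-level analyses.
#'
#' @param model trained `microkge_model`.
#' @param environment environment identifier.
#' @return list of class `"microkge_env_embedding"` with `environment` and
#'   `vector`.
#' @export
environment_embedding <- function(model, environment) {
  emb <- as_embeddings(model)
  rel <- paste0(interaction_types(), "@", environment)
  idx <- match(rel, emb$relations)
  if (anyNA(idx)) {
    stop("incomplete environment '", environment, "': missing relation(s) ",
         paste(rel[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  blocks <- lapply(idx, function(i) {
    if (emb$model == "SimplE") c(emb$params$R[i, ], emb$params$R_inv[i, ])
    else emb$params$R[i, ]
  })
  structure(list(environment = environment,
                 vector = unlist(blocks, use.names = FALSE)),
            class = "microkge_env_embedding")
}

#' Distance between two environment embeddings
#'
#' Euclidean distance \eqn{\lVert v_1 - v_2\rVert_2} or cosine distance
#' \eqn{1 - \frac{v_1 \cdot v_2}{\lVert v_1\rVert_2 \lVert v_2\rVert_2}}.
#'
#' @param v1,v2 numeric vectors of equal length (or
#'   `microkge_env_embedding` objects).
#' @param metric `"euclidean"` or `"cosine"`.
#' @return nonnegative distance.
#' @export
environment_distance <- function(v1, v2, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (inherits(v1, "microkge_env_embedding")) v1 <- v1$vector
  if (inherits(v2, "microkge_env_embedding")) v2 <- v2$vector
  check_that(length(v1) == length(v2), "vectors must have equal length")
  if (metric == "euclidean") {
    sqrt(sum((v1 - v2)^2))
  } else {
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    check_that(n1 > 0 && n2 > 0, "cosine distance undefined for zero vectors")
    1 - sum(v1 * v2) / (n1 * n2)
  }
}

# environments of the model with all three relation types present
complete_environments <- function(model) {
  emb <- as_embeddings(model)
  envs <- unique(parse_relation_id(emb$relations)$environment)
  envs <- sort(envs)
  keep <- vapply(envs, function(e) {
    all(paste0(interaction_types(), "@", e) %in% emb$relations)
  }, logical(1))
  envs[keep]
}

#' Pairwise environment distance matrix
#'
#' Distances between the embeddings of all complete environments (those
#' with all three relation types in the vocabulary); exportable for
#' external clustering or dendrogram construction.
#'
#' @param model trained `microkge_model`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return symmetric numeric matrix with environment ids as dimnames.
#' @export
environment_distance_matrix <- function(model,
                                        metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  envs <- complete_environments(model)
  check_that(length(envs) >= 1, "no complete environments in the model")
  vecs <- lapply(envs, function(e) environment_embedding(model, e)$vector)
  n <- length(envs)
  out <- matrix(0, n, n, dimnames = list(envs, envs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) out[i, j] <- environment_distance(vecs[[i]], vecs[[j]], metric)
    }
  }
  out + t(out)
}

#' Transfer an observed interaction from the most similar environment
#'
#' Predicts the interaction between a strain pair in a query environment by
#' copying the observed interaction between the same pair in the most
#' similar other environment (by embedding distance). If the pair was not
#' observed in the most similar environment, the second most similar is
#' consulted, and so on down the list. An optional distance threshold
#' restricts the donors considered.
#'
#' @param model trained `microkge_model` (supplies environment embeddings).
#' @param reference_kg graph holding the candidate donor observations.
#' @param sender,receiver,environment the query.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param max_distance optional cap: donor environments farther than this
#'   from the query environment are skipped.
#' @return list with `label`, `used_environment`, `distance`.
#' @export
environment_rule_predict <- function(model, reference_kg, sender, receiver,
                                     environment,
                                     metric = c("euclidean", "cosine"),
                                     max_distance = NULL) {
  metric <- match.arg(metric)
  v_query <- environment_embedding(model, environment)$vector
  donors <- setdiff(complete_environments(model), environment)
  check_that(length(donors) > 0, "no candidate donor environments")
  d <- vapply(donors, function(e) {
    environment_distance(v_query, environment_embedding(model, e)$vector,
                         metric)
  }, numeric(1))
  ord <- order(d, donors)              # deterministic tie-break by name
  tri <- reference_kg$triples
  pair_rows <- tri$head == sender & tri$tail == receiver
  for (i in ord) {
    if (!is.null(max_distance) && d[i] > max_distance) next
    hit <- which(pair_rows & tri$environment == donors[i])
    if (length(hit) > 0) {
      return(list(label = tri$type[hit[1L]], used_environment = donors[i],
                  distance = unname(d[i])))
    }
  }
  stop("no donor observation for pair ", sender, " -> ", receiver,
       if (!is.null(max_distance)) " within max_distance", call. = FALSE)
}

#' Recommend candidate strains for a desired interaction
#'
#' Given a target strain, a desired interaction type and an environment,
#' scores every candidate strain c for the triple (c, (I, e), target) — or
#' (target, (I, e), c) when the effect direction is reversed — and ranks
#' candidates by descending score. The top-ranked candidate is the
#' recommended strain. Scores are additionally min-max normalized within
#' the candidate set for comparability (a constant set maps to all 1).
#'
#' @param model trained `microkge_model`.
#' @param target target strain (in the graph).
#' @param interaction desired interaction type.
#' @param environment environment identifier.
#' @param candidates non-empty candidate strains, excluding the target.
#' @param direction `"candidates_affect_target"` (candidates as senders) or
#'   `"target_affects_candidates"`.
#' @return list of class `"microkge_recommendation"` with `candidates`
#'   (descending by score), `scores`, `normalized_scores` and `s_rec`.
#' @export
recommend_strains <- function(model, target, interaction, environment,
                              candidates,
                              direction = c("candidates_affect_target",
                                            "target_affects_candidates")) {
  direction <- match.arg(direction)
  emb <- as_embeddings(model)
  check_that(length(candidates) > 0, "candidate list is empty")
  check_that(!(target %in% candidates), "target must not be a candidate")
  r <- relation_index(emb, relation_id(interaction, environment))
  c_idx <- entity_index(emb, candidates)
  t_idx <- entity_index(emb, target)
  scores <- if (direction == "candidates_affect_target") {
    score_batch(emb, c_idx, rep(r, length(c_idx)), rep(t_idx, length(c_idx)))
  } else {
    score_batch(emb, rep(t_idx, length(c_idx)), rep(r, length(c_idx)), c_idx)
  }
  ord <- order(-scores, candidates)    # deterministic tie-break by name
  rng <- range(scores)
  normalized <- if (rng[1] == rng[2]) rep(1, length(scores)) else
    (scores - rng[1]) / (rng[2] - rng[1])
  structure(list(candidates = as.character(candidates)[ord],
                 scores = scores[ord],
                 normalized_scores = normalized[ord],
                 s_rec = as.character(candidates)[ord[1L]]),
            class = "microkge_recommendation")
}

#' @export
print.microkge_recommendation <- function(x, ...) {
  cat("Recommended strain:", x$s_rec, "\n")
  print(data.frame(candidate = x$candidates, score = x$scores,
                   normalized = x$normalized_scores), row.names = FALSE)
  invisible(x)
}

#' Pairwise strain embedding distance matrix
#'
#' Euclidean distances between strain-level analysis vectors (see
#' [entity_vectors()]; SimplE concatenates head- and tail-role vectors).
#' Exportable for dendrogram construction in external tools.
#'
#' @param model trained model or embedding set.
#' @return symmetric matrix with strain ids as dimnames.
#' @export
strain_distance_matrix <- function(model) {
  as.matrix(stats::dist(entity_vectors(model)))
}
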