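#' Training configuration
#'
#' Collects the hyperparameters of mini-batch SGD embedding training.
#' Model/loss pairing follows the usual convention for these models: the
#' margin-based pairwise ranking loss for TransE, the pointwise logistic
#' loss for DistMult and SimplE; either can be overridden. Negative
#' sampling is classical head/tail corruption or interaction-based
#' corruption of the relation's type component (the environment is kept).
#'
#' @param model `"SimplE"`, `"TransE"` or `"DistMult"`.
#' @param dim embedding dimension.
#' @param learning_rate positive SGD step size.
#' @param batch_size positive batch size.
#' @param epochs nonnegative epoch count (0 = return the initialization).
#' @param margin positive margin gamma of the pairwise loss.
#' @param loss `"pairwise"` or `"logistic"`; default depends on `model`.
#' @param ns_strategy `"interaction_based"` or `"classical_head_tail"`.
#' @param negatives_per_positive positive count of negatives per positive.
#' @param l2_reg nonnegative weight-decay coefficient.
#' @param seed integer seed; initialization uses `seed`, the sampling
#'   stream uses `seed + 1` so both are independently reproducible.
#' @param transe_normalize re-normalize TransE entity vectors to unit L2
#'   norm after every SGD step (the original TransE recipe).
#' @param norm_kind TransE score norm, `"L2"` or `"L1"`.
#' @return list of class `"microkge_train_config"`.
#' @export
train_config <- function(model = c("SimplE", "TransE", "DistMult"),
                         dim = 32L, learning_rate = 0.05, batch_size = 128L,
                         epochs = 100L, margin = 1,
                         loss = NULL,
                         ns_strategy = c("interaction_based",
                                         "classical_head_tail"),
                         negatives_per_positive = 1L, l2_reg = 0,
                         seed = 1L, transe_normalize = TRUE,
                         norm_kind = c("L2", "L1")) {
  model <- match.arg(model)
  ns_strategy <- match.arg(ns_strategy)
  norm_kind <- match.arg(norm_kind)
  if (is.null(loss)) loss <- if (model == "TransE") "pairwise" else "logistic"
  loss <- match.arg(loss, c("pairwise", "logistic"))
  check_that(learning_rate > 0, "learning_rate must be positive")
  check_that(batch_size >= 1, "batch_size must be positive")
  check_that(epochs >= 0, "epochs must be nonnegative")
  check_that(negatives_per_positive >= 1,
             "negatives_per_positive must be positive")
  check_that(l2_reg >= 0, "l2_reg must be nonnegative")
  if (loss == "pairwise") {
    check_that(is.numeric(margin) && margin > 0,
               "pairwise loss requires a positive margin")
  }
  structure(list(model = model, dim = as.integer(dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), margin = margin, loss = loss,
                 ns_strategy = ns_strategy,
                 negatives_per_positive = as.integer(negatives_per_positive),
                 l2_reg = l2_reg, seed = as.integer(seed),
                 transe_normalize = isTRUE(transe_normalize),
                 norm_kind = norm_kind),
            class = "microkge_train_config")
}

#' Classical negative sampling: corrupt head or tail
#'
#' With probability 1/2 the head, otherwise the tail, is replaced by an
#' entity drawn uniformly from the graph's entities minus the replaced one.
#' The relation is kept. No filtering of accidental true triples is
#' performed — in a dense interaction graph some corruptions will coincide
#' with observed facts, which is accepted as in standard embedding training
#' pipelines.
#'
#' @param triple list or one-row data.frame with `head`, `type`,
#'   `environment`, `tail`.
#' @param kg the knowledge graph supplying the entity set.
#' @return a triple of the same shape, differing in exactly one of
#'   head/tail. Uses the current RNG state.
#' @export
corrupt_classical <- function(triple, kg) {
  ents <- kg$entities
  check_that(length(ents) >= 2, "classical corruption needs >= 2 entities")
  out <- as.list(triple)[c("head", "type", "environment", "tail")]
  side <- if (stats::runif(1) < 0.5) "head" else "tail"
  out[[side]] <- sample(setdiff(ents, out[[side]]), 1L)
  out
}

#' Interaction-based negative sampling: corrupt the interaction type
#'
#' Replaces the relation's interaction type with one of the other two
#' types, chosen uniformly, keeping head, tail and environment unchanged.
#' Because the interaction type is the quantity being predicted, these
#' corruptions are guaranteed false whenever each (pair, environment) cell
#' holds a single observed label.
#'
#' @param triple list or one-row data.frame with `head`, `type`,
#'   `environment`, `tail`.
#' @return corrupted triple. Uses the current RNG state.
#' @export
corrupt_interaction <- function(triple) {
  out <- as.list(triple)[c("head", "type", "environment", "tail")]
  alts <- setdiff(interaction_types(), normalize_label(out$type))
  out$type <- alts[sample.int(2L, 1L)]
  out
}

#' Pairwise margin ranking loss
#'
#' \deqn{\sum_i \max(0, \gamma - \varphi^+_i + \varphi^-_i)} over paired
#' positive/negative scores.
#'
#' @param pos_scores,neg_scores equal-length numeric vectors, paired.
#' @param margin positive margin gamma.
#' @return nonnegative total loss.
#' @export
pairwise_loss <- function(pos_scores, neg_scores, margin = 1) {
  check_that(length(pos_scores) == length(neg_scores),
             "pos_scores and neg_scores must be paired (equal length)")
  check_that(margin > 0, "margin must be positive")
  sum(pmax(0, margin - pos_scores + neg_scores))
}

#' Pointwise logistic loss
#'
#' \deqn{\sum_i \log(1 + \exp(-l_i \varphi_i))} with label +1 for observed
#' and -1 for corrupted triples. Evaluated overflow-safely for large
#' |score|.
#'
#' @param scores numeric vector of triple scores.
#' @param labels vector of +1 / -1, one per score.
#' @return nonnegative total loss.
#' @export
logistic_loss <- function(scores, labels) {
  check_that(length(scores) == length(labels), "scores/labels length mismatch")
  check_that(all(labels %in% c(-1, 1)), "labels must be +1 or -1")
  sum(softplus(-labels * scores))
}

# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# d/dphi of the logistic loss term, label l: -l * sigmoid(-l * phi)
logistic_dphi <- function(phi, l) -l * stats::plogis(-l * phi)

# ---- analytic gradients -----------------------------------------------

# accumulate per-row contributions `contrib` (m x d) into gradient matrix G
# at rows `idx` (duplicates summed)
accum <- function(G, idx, contrib) {
  s <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  G[rows, ] <- G[rows, , drop = FALSE] + s
  G
}

# gradient of sum(coef_i * phi(triple_i)) w.r.t. all parameters, added to gr
add_phi_grads <- function(gr, emb, idx, coef) {
  p <- emb$params
  h <- idx[, 1L]; r <- idx[, 2L]; t <- idx[, 3L]
  if (emb$model == "TransE") {
    diff <- p$E[h, , drop = FALSE] + p$R[r, , drop = FALSE] -
      p$E[t, , drop = FALSE]
    if (emb$norm_kind == "L2") {
      nrm <- sqrt(rowSums(diff^2))
      unit <- diff / pmax(nrm, 1e-12)
      unit[nrm == 0, ] <- 0
    } else {
      unit <- sign(diff)
    }
    g <- -coef * unit                       # dphi/dh = dphi/dr = -unit
    gr$E <- accum(gr$E, h, g)
    gr$R <- accum(gr$R, r, g)
    gr$E <- accum(gr$E, t, -g)
  } else if (emb$model == "DistMult") {
    H <- p$E[h, , drop = FALSE]; R <- p$R[r, , drop = FALSE]
    T <- p$E[t, , drop = FALSE]
    gr$E <- accum(gr$E, h, coef * R * T)
    gr$R <- accum(gr$R, r, coef * H * T)
    gr$E <- accum(gr$E, t, coef * H * R)
  } else {                                  # SimplE
    Hh <- p$E_h[h, , drop = FALSE]; Ht <- p$E_t[h, , drop = FALSE]
    Th <- p$E_h[t, , drop = FALSE]; Tt <- p$E_t[t, , drop = FALSE]
    R <- p$R[r, , drop = FALSE]; Ri <- p$R_inv[r, , drop = FALSE]
    half <- 0.5 * coef
    gr$E_h <- accum(gr$E_h, h, half * R * Tt)
    gr$E_t <- accum(gr$E_t, t, half * Hh * R)
    gr$R <- accum(gr$R, r, half * Hh * Tt)
    gr$E_t <- accum(gr$E_t, h, half * Ri * Th)
    gr$E_h <- accum(gr$E_h, t, half * Ht * Ri)
    gr$R_inv <- accum(gr$R_inv, r, half * Ht * Th)
  }
  gr
}

zero_grads <- function(emb) lapply(emb$params, function(m) m * 0)

# loss and full analytic gradient for one batch of positives `pos` and
# paired negatives `neg` (integer matrices with columns h, r, t; neg rows
# are grouped per positive: rep(each = negatives_per_positive))
kge_loss_grad <- function(emb, pos, neg, loss = c("logistic", "pairwise"),
                          margin = 1) {
  loss <- match.arg(loss)
  npos <- nrow(pos)
  npp <- nrow(neg) / npos
  check_that(npp == as.integer(npp), "neg rows must be a multiple of pos rows")
  pair <- rep(seq_len(npos), each = npp)
  phi_p <- score_batch(emb, pos[, 1L], pos[, 2L], pos[, 3L])
  phi_n <- score_batch(emb, neg[, 1L], neg[, 2L], neg[, 3L])
  gr <- zero_grads(emb)
  if (loss == "pairwise") {
    slack <- margin - phi_p[pair] + phi_n
    active <- slack > 0
    value <- sum(slack[active])
    coef_n <- as.numeric(active)
    coef_p <- -as.numeric(rowsum(coef_n, pair, reorder = TRUE))
    gr <- add_phi_grads(gr, emb, pos, coef_p)
    if (any(active)) {
      gr <- add_phi_grads(gr, emb, neg[active, , drop = FALSE],
                          coef_n[active])
    }
  } else {
    value <- sum(softplus(-phi_p)) + sum(softplus(phi_n))
    gr <- add_phi_grads(gr, emb, pos, logistic_dphi(phi_p, 1))
    gr <- add_phi_grads(gr, emb, neg, logistic_dphi(phi_n, -1))
  }
  list(loss = value, grads = gr)
}

# ---- negative generation (vectorized, index space) --------------------

# classical: corrupt head or tail with a uniform replacement != original
neg_classical <- function(pos, n_entities) {
  m <- nrow(pos)
  out <- pos
  repl <- sample.int(n_entities - 1L, m, replace = TRUE)
  heads <- stats::runif(m) < 0.5
  orig <- ifelse(heads, pos[, 1L], pos[, 3L])
  repl <- repl + (repl >= orig)
  out[heads, 1L] <- repl[heads]
  out[!heads, 3L] <- repl[!heads]
  out
}

# interaction-based: swap the relation for one of its two same-environment
# alternatives (alt_mat: n_relations x 2 of alternative relation indices)
neg_interaction <- function(pos, alt_mat) {
  m <- nrow(pos)
  col <- 1L + (stats::runif(m) < 0.5)
  out <- pos
  out[, 2L] <- alt_mat[cbind(pos[, 2L], col)]
  out
}

# map relation index -> two alternative indices with the other types, same
# environment; NA when the vocabulary lacks them
relation_alternatives <- function(relations) {
  key <- function(type, env) paste0(type, "@", env)
  idx_of <- stats::setNames(seq_len(nrow(relations)), relations$id)
  alt <- matrix(NA_integer_, nrow(relations), 2L)
  for (i in seq_len(nrow(relations))) {
    others <- setdiff(interaction_types(), relations$type[i])
    alt[i, ] <- idx_of[key(others, relations$environment[i])]
  }
  alt
}

#' Train a knowledge graph embedding model
#'
#' Mini-batch stochastic gradient descent with a constant learning rate.
#' Each epoch shuffles the training triples, forms positive batches,
#' generates paired negative batches with the configured sampler, and takes
#' one SGD step on the batch loss using analytic gradients. For TransE,
#' entity vectors are optionally re-normalized to unit L2 norm after every
#' step. The run is fully reproducible: initialization is seeded with
#' `config$seed` and the shuffling/sampling stream with `config$seed + 1`.
#'
#' @param train_kg non-empty `microkge_kg`. Interaction-based sampling
#'   requires `vocabulary_mode = "full_grid"` so that the two alternative
#'   (type, environment) relations always exist.
#' @param config a [train_config()].
#' @return object of class `"microkge_model"`: list with `embeddings`,
#'   `config`, `loss_history` (mean batch loss per epoch) and `kg` metadata
#'   (entity/relation/environment vocabularies).
#' @export
train_kge <- function(train_kg, config = train_config()) {
  check_that(inherits(train_kg, "microkge_kg"), "train_kg must be a microkge_kg")
  check_that(nrow(train_kg$triples) > 0, "training graph has no triples")
  if (config$ns_strategy == "interaction_based" &&
      train_kg$vocabulary_mode != "full_grid") {
    stop("interaction-based negative sampling requires a 'full_grid' ",
         "relation vocabulary; rebuild the graph with ",
         "build_kg(..., vocabulary_mode = \"full_grid\")", call. = FALSE)
  }

  emb <- init_embeddings(length(train_kg$entities), nrow(train_kg$relations),
                         model = config$model, dim = config$dim,
                         seed = config$seed, norm_kind = config$norm_kind,
                         entity_names = train_kg$entities,
                         relation_names = train_kg$relations$id)

  tri <- cbind(match(train_kg$triples$head, train_kg$entities),
               match(train_kg$triples$relation, train_kg$relations$id),
               match(train_kg$triples$tail, train_kg$entities))
  n <- nrow(tri)
  n_ent <- length(train_kg$entities)
  npp <- config$negatives_per_positive
  alt_mat <- if (config$ns_strategy == "interaction_based") {
    relation_alternatives(train_kg$relations)
  }
  lr <- config$learning_rate
  decay <- 1 - lr * config$l2_reg

  set.seed(config$seed + 1L)
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      rows <- perm[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
      pos <- tri[rows, , drop = FALSE]
      src <- pos[rep(seq_len(nrow(pos)), each = npp), , drop = FALSE]
      neg <- if (config$ns_strategy == "interaction_based") {
        neg_interaction(src, alt_mat)
      } else {
        neg_classical(src, n_ent)
      }
      lg <- kge_loss_grad(emb, pos, neg, loss = config$loss,
                          margin = config$margin)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             "; reduce the learning rate", call. = FALSE)
      }
      for (k in names(emb$params)) {
        emb$params[[k]] <- emb$params[[k]] - lr * lg$grads[[k]]
        if (decay < 1) emb$params[[k]] <- emb$params[[k]] * decay
      }
      if (config$model == "TransE" && config$transe_normalize) {
        emb$params$E <- emb$params$E / sqrt(rowSums(emb$params$E^2))
      }
      batch_losses[b] <- lg$loss
    }
    loss_history[epoch] <- mean(batch_losses)
  }

  structure(list(embeddings = emb, config = config,
                 loss_history = loss_history,
                 kg = list(entities = train_kg$entities,
                           relations = train_kg$relations,
                           environments = train_kg$environments,
                           vocabulary_mode = train_kg$vocabulary_mode)),
            class = "microkge_model")
}

#' @export
print.microkge_model <- function(x, ...) {
  cat("Trained ", x$config$model, " model (",
      x$config$ns_strategy, " negatives)\n",
      "  d = ", x$config$dim, ", epochs = ", x$config$epochs, sep = "")
  if (length(x$loss_history)) {
    cat(", final mean batch loss = ",
        signif(x$loss_history[length(x$loss_history)], 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Grid search over training hyperparameters
#'
#' Trains one model per point of the Cartesian grid and scores each by
#' interaction-type classification accuracy on the validation graph. Ties
#' are broken deterministically by enumeration order (first grid point
#' wins).
#'
#' @param train_kg,valid_kg training and validation graphs.
#' @param grid named list mapping [train_config()] field names to candidate
#'   vectors, e.g. `list(dim = c(16, 32), learning_rate = c(0.05, 0.1))`.
#' @param base_config config supplying all fields not in the grid.
#' @return list with `best_config`, `best_accuracy` and `table` (one row
#'   per grid point with its validation accuracy).
#' @export
grid_search <- function(train_kg, valid_kg, grid,
                        base_config = train_config()) {
  check_that(is.list(grid) && length(grid) > 0 && !is.null(names(grid)),
             "grid must be a non-empty named list")
  check_that(nrow(valid_kg$triples) > 0, "validation graph is empty")
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- numeric(nrow(points))
  configs <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    cfg <- base_config
    for (fld in names(points)) cfg[[fld]] <- points[[fld]][i]
    cfg <- do.call(train_config, unclass(cfg))
    configs[[i]] <- cfg
    model <- train_kge(train_kg, cfg)
    acc[i] <- evaluate_classification(model, valid_kg)$accuracy
  }
  best <- which.max(acc)
  table <- cbind(points, accuracy = acc)
  list(best_config = configs[[best]], best_accuracy = acc[best], table = table)
}
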