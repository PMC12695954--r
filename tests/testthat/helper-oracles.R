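# Independent brute-force oracles: naive re-implementations of the scoring,
# ranking and loss definitions used to cross-check the vectorized package
# code. Deliberately written as plain loops over raw parameter matrices.

oracle_score <- function(emb, head, relation, tail) {
  h <- match(head, emb$entities)
  r <- match(relation, emb$relations)
  t <- match(tail, emb$entities)
  p <- emb$params
  if (emb$model == "TransE") {
    d <- p$E[h, ] + p$R[r, ] - p$E[t, ]
    if (emb$norm_kind == "L2") -sqrt(sum(d * d)) else -sum(abs(d))
  } else if (emb$model == "DistMult") {
    s <- 0
    for (i in seq_len(emb$dim)) s <- s + p$E[h, i] * p$R[r, i] * p$E[t, i]
    s
  } else {
    s1 <- 0; s2 <- 0
    for (i in seq_len(emb$dim)) {
      s1 <- s1 + p$E_h[h, i] * p$R[r, i] * p$E_t[t, i]
      s2 <- s2 + p$E_t[h, i] * p$R_inv[r, i] * p$E_h[t, i]
    }
    (s1 + s2) / 2
  }
}

oracle_rank <- function(emb, head, relation, tail, side) {
  scores <- vapply(emb$entities, function(e) {
    if (side == "head") oracle_score(emb, e, relation, tail)
    else oracle_score(emb, head, relation, e)
  }, numeric(1))
  true_score <- if (side == "head") scores[[head]] else scores[[tail]]
  # mean rank of the tied block
  sum(scores > true_score) + (sum(scores == true_score) + 1) / 2
}

oracle_mrr_hits <- function(emb, triples, ks) {
  rr <- 0
  hits <- stats::setNames(numeric(length(ks)), paste0("hits@", ks))
  for (i in seq_len(nrow(triples))) {
    for (side in c("head", "tail")) {
      rk <- oracle_rank(emb, triples$head[i], triples$relation[i],
                        triples$tail[i], side)
      rr <- rr + 1 / rk
      hits <- hits + (rk <= ks)
    }
  }
  n2 <- 2 * nrow(triples)
  list(mrr = rr / n2, hits_at = hits / n2)
}

oracle_classify <- function(emb, sender, receiver, environment) {
  types <- interaction_types()
  scores <- rep(-Inf, 3)
  for (j in 1:3) {
    rel <- paste0(types[j], "@", environment)
    if (rel %in% emb$relations) {
      scores[j] <- oracle_score(emb, sender, rel, receiver)
    }
  }
  types[which.max(scores)]
}

# naive batch loss from oracle scores (pos/neg are index matrices as in
# microkge:::kge_loss_grad; negatives grouped per positive)
oracle_loss <- function(emb, pos, neg, loss, margin = 1) {
  sc <- function(m, i) oracle_score(emb, emb$entities[m[i, 1]],
                                    emb$relations[m[i, 2]],
                                    emb$entities[m[i, 3]])
  npp <- nrow(neg) / nrow(pos)
  total <- 0
  if (loss == "pairwise") {
    for (i in seq_len(nrow(neg))) {
      p <- ceiling(i / npp)
      total <- total + max(0, margin - sc(pos, p) + sc(neg, i))
    }
  } else {
    for (i in seq_len(nrow(pos))) total <- total + log(1 + exp(-sc(pos, i)))
    for (i in seq_len(nrow(neg))) total <- total + log(1 + exp(sc(neg, i)))
  }
  total
}

# central finite differences of oracle_loss w.r.t. every coordinate
numeric_grads <- function(emb, pos, neg, loss, margin = 1, eps = 1e-5) {
  lapply(stats::setNames(names(emb$params), names(emb$params)), function(k) {
    M <- emb$params[[k]]
    G <- M * 0
    for (i in seq_len(nrow(M))) {
      for (j in seq_len(ncol(M))) {
        up <- emb; up$params[[k]][i, j] <- M[i, j] + eps
        dn <- emb; dn$params[[k]][i, j] <- M[i, j] - eps
        G[i, j] <- (oracle_loss(up, pos, neg, loss, margin) -
                      oracle_loss(dn, pos, neg, loss, margin)) / (2 * eps)
      }
    }
    G
  })
}

# random embedding set over a small entity/relation vocabulary
random_embeddings <- function(model, n_ent = 5, n_env = 2, dim = 3,
                              seed = 1) {
  envs <- paste0("e", seq_len(n_env))
  rels <- as.vector(outer(interaction_types(), envs, paste, sep = "@"))
  emb <- init_embeddings(n_ent, length(rels), model = model, dim = dim,
                         seed = seed,
                         entity_names = paste0("s", seq_len(n_ent)),
                         relation_names = rels)
  # break the unit-norm TransE initialization so scores are generic
  set.seed(seed + 500)
  emb$params <- lapply(emb$params, function(m) {
    m + matrix(stats::rnorm(length(m), sd = 0.3), nrow(m), ncol(m))
  })
  emb
}

# small labeled interaction table over 3 strains x 2 environments
tiny_records <- function() {
  data.frame(
    sender      = c("A", "B", "C", "A"),
    receiver    = c("B", "A", "A", "C"),
    environment = c("glc", "glc", "lac", "lac"),
    label       = c("positive", "negative", "neutral", "positive"),
    stringsAsFactors = FALSE)
}
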