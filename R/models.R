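#' Initialize embeddings for a knowledge graph
#'
#' Allocates and randomly initializes the embedding parameters of one of the
#' three supported models. TransE and DistMult hold one d-vector per entity
#' and one per relation. SimplE holds two per entity (a head-role and a
#' tail-role vector) and two per relation (the relation and its inverse),
#' following its factorization of a triple score into a forward and an
#' inverse trilinear term.
#'
#' All coordinates are drawn i.i.d. uniform on \eqn{[-6/\sqrt d, +6/\sqrt d]}
#' (the initialization convention of the original translational-embedding
#' work); TransE entity vectors are additionally L2-normalized at
#' initialization.
#'
#' @param n_entities,n_relations positive counts, or a `microkge_kg` passed
#'   as `n_entities` (counts and names are then taken from the graph).
#' @param model `"TransE"`, `"DistMult"` or `"SimplE"`.
#' @param dim embedding dimension d.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param norm_kind `"L2"` or `"L1"` (TransE score norm).
#' @param entity_names,relation_names optional identifier vectors used for
#'   lookups; default `e1..en` / `r1..rm`.
#' @return An object of class `"microkge_embeddings"`: list with `model`,
#'   `dim`, `norm_kind`, `entities`, `relations` and `params` (named list of
#'   matrices: `E`, `R` for TransE/DistMult; `E_h`, `E_t`, `R`, `R_inv` for
#'   SimplE; one row per entity/relation).
#' @export
init_embeddings <- function(n_entities, n_relations = NULL,
                            model = c("SimplE", "TransE", "DistMult"),
                            dim = 32L, seed = 1L, norm_kind = c("L2", "L1"),
                            entity_names = NULL, relation_names = NULL) {
  model <- match.arg(model)
  norm_kind <- match.arg(norm_kind)
  if (inherits(n_entities, "microkge_kg")) {
    kg <- n_entities
    entity_names <- kg$entities
    relation_names <- kg$relations$id
    n_entities <- length(entity_names)
    n_relations <- length(relation_names)
  }
  check_that(is.numeric(dim) && length(dim) == 1 && dim >= 1,
             "dim must be a positive integer")
  check_that(n_entities >= 1 && n_relations >= 1,
             "entity and relation counts must be positive")
  dim <- as.integer(dim)
  if (is.null(entity_names)) entity_names <- paste0("e", seq_len(n_entities))
  if (is.null(relation_names)) relation_names <- paste0("r", seq_len(n_relations))

  set.seed(as.integer(seed))
  b <- 6 / sqrt(dim)
  rand_mat <- function(n) {
    matrix(stats::runif(n * dim, -b, b), nrow = n, ncol = dim)
  }
  params <- if (model == "SimplE") {
    list(E_h = rand_mat(n_entities), E_t = rand_mat(n_entities),
         R = rand_mat(n_relations), R_inv = rand_mat(n_relations))
  } else {
    E <- rand_mat(n_entities)
    if (model == "TransE") E <- E / sqrt(rowSums(E^2))
    list(E = E, R = rand_mat(n_relations))
  }
  structure(list(model = model, dim = dim, norm_kind = norm_kind,
                 entities = as.character(entity_names),
                 relations = as.character(relation_names),
                 params = params),
            class = "microkge_embeddings")
}

#' TransE score: negative norm of the translation residual
#'
#' \deqn{\varphi(h,r,t) = -\lVert h + r - t\rVert} under the L1 or L2 norm.
#' The score is never positive and is 0 exactly when the relation vector
#' translates the head onto the tail.
#'
#' @param h,r,t numeric vectors of equal length.
#' @param norm_kind `"L2"` (default) or `"L1"`.
#' @return a single numeric score, always <= 0.
#' @export
score_transe <- function(h, r, t, norm_kind = c("L2", "L1")) {
  norm_kind <- match.arg(norm_kind)
  check_that(length(h) == length(r) && length(r) == length(t),
             "h, r, t must have equal length")
  d <- h + r - t
  if (norm_kind == "L2") -sqrt(sum(d^2)) else -sum(abs(d))
}

#' DistMult score: trilinear product
#'
#' \deqn{\varphi(h,r,t) = \sum_i h_i r_i t_i.} Symmetric in head and tail,
#' which is DistMult's known limitation for asymmetric relations.
#'
#' @param h,r,t numeric vectors of equal length.
#' @return a single numeric score.
#' @export
score_distmult <- function(h, r, t) {
  check_that(length(h) == length(r) && length(r) == length(t),
             "h, r, t must have equal length")
  sum(h * r * t)
}

#' SimplE score: mean of forward and inverse trilinear terms
#'
#' \deqn{\varphi(h,r,t) = \tfrac12(\langle h_h, r, t_t\rangle +
#'   \langle h_t, r^{-1}, t_h\rangle)} where each entity carries a head-role
#' and a tail-role vector and each relation carries a forward and an inverse
#' vector.
#'
#' @param h_head,h_tail head-role and tail-role vectors of the head entity.
#' @param t_head,t_tail head-role and tail-role vectors of the tail entity.
#' @param r,r_inv relation and inverse-relation vectors.
#' @return a single numeric score.
#' @export
score_simple <- function(h_head, h_tail, t_head, t_tail, r, r_inv) {
  len <- lengths(list(h_head, h_tail, t_head, t_tail, r, r_inv))
  check_that(length(unique(len)) == 1, "all vectors must have equal length")
  0.5 * (sum(h_head * r * t_tail) + sum(h_tail * r_inv * t_head))
}

# vectorized scoring over integer index triples (rows of h/r/t indices)
score_batch <- function(emb, h_idx, r_idx, t_idx) {
  p <- emb$params
  switch(emb$model,
    TransE = {
      d <- p$E[h_idx, , drop = FALSE] + p$R[r_idx, , drop = FALSE] -
        p$E[t_idx, , drop = FALSE]
      if (emb$norm_kind == "L2") -sqrt(rowSums(d^2)) else -rowSums(abs(d))
    },
    DistMult = rowSums(p$E[h_idx, , drop = FALSE] *
                         p$R[r_idx, , drop = FALSE] *
                         p$E[t_idx, , drop = FALSE]),
    SimplE = 0.5 * (rowSums(p$E_h[h_idx, , drop = FALSE] *
                              p$R[r_idx, , drop = FALSE] *
                              p$E_t[t_idx, , drop = FALSE]) +
                      rowSums(p$E_t[h_idx, , drop = FALSE] *
                                p$R_inv[r_idx, , drop = FALSE] *
                                p$E_h[t_idx, , drop = FALSE])))
}

entity_index <- function(emb, ids) {
  idx <- match(as.character(ids), emb$entities)
  if (anyNA(idx)) {
    stop("unknown entity id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

relation_index <- function(emb, ids) {
  idx <- match(as.character(ids), emb$relations)
  if (anyNA(idx)) {
    stop("unknown relation id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Score one (head, relation, tail) triple under an embedding set
#'
#' Dispatches to the model-specific scoring rule, resolving identifiers
#' through the embedding set's entity and relation index maps.
#'
#' @param embeddings a `microkge_embeddings` (or a trained model, whose
#'   embeddings are used).
#' @param head,tail entity identifiers.
#' @param relation relation identifier (`"type@environment"`).
#' @return a single numeric score.
#' @export
score_triple <- function(embeddings, head, relation, tail) {
  emb <- as_embeddings(embeddings)
  h <- entity_index(emb, head)
  r <- relation_index(emb, relation)
  t <- entity_index(emb, tail)
  score_batch(emb, h, r, t)
}

as_embeddings <- function(x) {
  if (inherits(x, "microkge_model")) x$embeddings
  else if (inherits(x, "microkge_embeddings")) x
  else stop("expected a microkge_embeddings or microkge_model", call. = FALSE)
}

#' @export
print.microkge_embeddings <- function(x, ...) {
  cat(x$model, " embeddings: ", length(x$entities), " entities, ",
      length(x$relations), " relations, d = ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Strain-level analysis vectors
#'
#' Returns one vector per entity for external analyses (distance matrices,
#' clustering). For SimplE, the head-role and tail-role vectors are
#' concatenated into a single 2d representation per strain; other models
#' return their entity matrix unchanged.
#'
#' @param embeddings a `microkge_embeddings` or trained model.
#' @return numeric matrix, one row per entity, rownames = entity ids.
#' @export
entity_vectors <- function(embeddings) {
  emb <- as_embeddings(embeddings)
  m <- if (emb$model == "SimplE") cbind(emb$params$E_h, emb$params$E_t)
       else emb$params$E
  rownames(m) <- emb$entities
  m
}
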