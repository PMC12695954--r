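toy_phylo <- function() {
  data.frame(strain_id = c("s1", "s2", "s3", "s4", "T"),
             f1 = c(0, 3, 0, 1, 0), f2 = c(0, 4, 1, 1, 0),
             stringsAsFactors = FALSE)
}

test_that("phylogenetic distance is the plain Euclidean metric", {
  ph <- toy_phylo()
  expect_equal(phylo_distance(ph, "s1", "T"), 0)
  expect_equal(phylo_distance(ph, "s1", "s2"), 5)
  set.seed(2)
  for (i in 1:10) {
    ab <- sample(ph$strain_id, 2)
    expect_equal(phylo_distance(ph, ab[1], ab[2]),
                 phylo_distance(ph, ab[2], ab[1]))
  }
  expect_error(phylo_distance(ph, "s1", "zz"), "zz")
})

test_that("synthetic embeddings are normalized convex combinations", {
  emb <- random_embeddings("DistMult", n_ent = 4, dim = 3, seed = 10)
  ph <- toy_phylo()

  # k = 1: exactly the nearest neighbour's embedding (s1 at distance 0)
  syn1 <- synthetic_embedding(emb, ph, "T", k = 1)
  expect_equal(syn1$neighbors, "s1")
  expect_equal(syn1$roles$E, unname(emb$params$E[1, ]))

  # weights 1/(1+d) renormalized: d = (0, 1) -> (2/3, 1/3)
  syn2 <- synthetic_embedding(emb, ph, "T", k = 2)
  expect_equal(syn2$neighbors, c("s1", "s3"))
  expect_equal(syn2$weights, c(2 / 3, 1 / 3))
  expect_equal(syn2$roles$E,
               unname(2 / 3 * emb$params$E[1, ] + 1 / 3 * emb$params$E[3, ]))
  expect_true(all(syn2$weights > 0))
  expect_equal(sum(syn2$weights), 1)

  # equidistant neighbours average arithmetically
  ph_eq <- data.frame(strain_id = c("s1", "s2", "X"),
                      f1 = c(1, -1, 0), f2 = c(0, 0, 0))
  syn_eq <- synthetic_embedding(emb, ph_eq, "X", k = 2)
  expect_equal(syn_eq$roles$E,
               unname(colMeans(emb$params$E[1:2, ])))

  # convex hull: every coordinate within the neighbour-wise bounds
  syn4 <- synthetic_embedding(emb, ph, "T", k = 4)
  nb <- emb$params$E[match(syn4$neighbors, emb$entities), ]
  expect_true(all(syn4$roles$E <= apply(nb, 2, max) + 1e-12))
  expect_true(all(syn4$roles$E >= apply(nb, 2, min) - 1e-12))

  # SimplE aggregates the two roles separately
  sp <- random_embeddings("SimplE", n_ent = 4, dim = 3, seed = 11)
  syn_sp <- synthetic_embedding(sp, ph, "T", k = 1)
  expect_named(syn_sp$roles, c("E_h", "E_t"))
  expect_equal(syn_sp$roles$E_h, unname(sp$params$E_h[1, ]))

  expect_error(synthetic_embedding(emb, ph, "s1", k = 1), "already")
  expect_error(synthetic_embedding(emb, ph, "T", k = 10), "k must be")
})

test_that("a coordinate clone of an in-graph strain predicts like it", {
  ds <- generate_dataset(synthetic_config(n_strains = 6, n_environments = 4,
                                          env_groups = 2, noise_sd = 0,
                                          missing_fraction = 0, seed = 6))
  kg <- build_kg(ds$records, vocabulary_mode = "full_grid")
  model <- train_kge(kg, train_config(model = "SimplE", dim = 16,
                                      epochs = 30, seed = 6))
  clone <- ds$phylo[ds$phylo$strain_id == "S01", ]
  clone$strain_id <- "NEW"
  ph <- rbind(ds$phylo, clone)
  queries <- data.frame(partner = c("S02", "S03"),
                        environment = c("env01", "env02"),
                        direction = c("target_as_sender",
                                      "target_as_receiver"))
  pred_new <- predict_unseen(model, ph, "NEW", queries, k = 1)
  pred_ref <- c(
    classify_interaction(model, "S01", "S02", "env01")$label,
    classify_interaction(model, "S03", "S01", "env02")$label)
  expect_equal(pred_new, pred_ref)
})

test_that("environment embeddings concatenate relation vectors canonically", {
  rels <- paste0(interaction_types(), "@e")
  emb <- init_embeddings(2, 3, model = "DistMult", dim = 2, seed = 1,
                         entity_names = c("x", "y"), relation_names = rels)
  emb$params$R <- rbind(c(1, 2), c(3, 4), c(5, 6))
  ve <- environment_embedding(emb, "e")
  expect_equal(ve$vector, c(1, 2, 3, 4, 5, 6))
  expect_length(ve$vector, 3 * 2)

  # missing type -> incomplete environment error
  partial <- init_embeddings(2, 2, model = "DistMult", dim = 2, seed = 1,
                             entity_names = c("x", "y"),
                             relation_names = c("negative@e", "positive@e"))
  expect_error(environment_embedding(partial, "e"), "incomplete")

  # SimplE doubles each block with the inverse-relation vector
  sp <- random_embeddings("SimplE", n_ent = 2, n_env = 1, dim = 2, seed = 2)
  expect_length(environment_embedding(sp, "e1")$vector, 6 * 2)
})

test_that("environment distances satisfy the metric identities", {
  expect_equal(environment_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(environment_distance(c(1, 2), c(1, 2), metric = "cosine"), 0)
  expect_equal(environment_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(environment_distance(c(1, 0), c(0, 1), metric = "cosine"), 1)
  expect_equal(environment_distance(c(1, 2), -c(1, 2), metric = "cosine"), 2)
  expect_error(environment_distance(c(0, 0), c(1, 1), metric = "cosine"),
               "zero")
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    expect_lte(environment_distance(a, c),
               environment_distance(a, b) + environment_distance(b, c) + 1e-12)
    expect_equal(environment_distance(a, b, "cosine"),
                 environment_distance(b, a, "cosine"))
  }
})

test_that("the environment rule copies from the nearest donor with fallback", {
  # DistMult d=1; relation values chosen so environment embeddings are
  # ordered e_query ~ e_near < e_far
  envs <- c("eq", "enear", "efar")
  rels <- as.vector(outer(interaction_types(), envs, paste, sep = "@"))
  emb <- init_embeddings(3, length(rels), model = "DistMult", dim = 1,
                         seed = 1, entity_names = c("A", "B", "C"),
                         relation_names = rels)
  emb$params$R <- matrix(c(1, 1, 1,  1.1, 1.1, 1.1,  9, 9, 9), 9, 1)

  ref <- build_kg(data.frame(
    sender = c("A", "A", "B"), receiver = c("B", "B", "C"),
    environment = c("enear", "efar", "efar"),
    label = c("positive", "negative", "neutral")))

  res <- environment_rule_predict(emb, ref, "A", "B", "eq")
  expect_equal(res$label, "positive")
  expect_equal(res$used_environment, "enear")
  expect_equal(res$distance,
               environment_distance(environment_embedding(emb, "eq")$vector,
                                    environment_embedding(emb, "enear")$vector))

  # pair absent from the nearest donor: falls through to the next one
  res2 <- environment_rule_predict(emb, ref, "B", "C", "eq")
  expect_equal(res2$label, "neutral")
  expect_equal(res2$used_environment, "efar")

  # distance cap excludes the only donor containing the pair
  expect_error(environment_rule_predict(emb, ref, "B", "C", "eq",
                                        max_distance = 1),
               "no donor")
  expect_error(environment_rule_predict(emb, ref, "C", "A", "eq"),
               "no donor")
})

test_that("recommendation ranks candidates by score, permutation-invariantly", {
  rels <- paste0(interaction_types(), "@e")
  emb <- init_embeddings(3, 3, model = "DistMult", dim = 1, seed = 1,
                         entity_names = c("t", "c1", "c2"),
                         relation_names = rels)
  emb$params$E <- matrix(c(1, 3, 1), 3, 1)
  emb$params$R <- matrix(1, 3, 1)
  # scores for (ci, positive@e, t): c1 -> 3, c2 -> 1
  rec <- recommend_strains(emb, "t", "positive", "e", c("c1", "c2"))
  expect_equal(rec$candidates, c("c1", "c2"))
  expect_equal(rec$scores, c(3, 1))
  expect_equal(rec$normalized_scores, c(1, 0))
  expect_equal(rec$s_rec, "c1")
  expect_equal(rec$s_rec, rec$candidates[which.max(rec$scores)])

  # shuffling candidates changes neither the top pick nor any score
  rec_shuf <- recommend_strains(emb, "t", "positive", "e", c("c2", "c1"))
  expect_equal(rec_shuf$s_rec, rec$s_rec)
  expect_equal(rec_shuf$scores[match(rec$candidates, rec_shuf$candidates)],
               rec$scores)

  # reversed direction scores (t, r, ci) instead
  sp <- random_embeddings("SimplE", n_ent = 4, dim = 3, seed = 4)
  fwd <- recommend_strains(sp, "s1", "negative", "e1", c("s2", "s3", "s4"))
  rev <- recommend_strains(sp, "s1", "negative", "e1", c("s2", "s3", "s4"),
                           direction = "target_affects_candidates")
  for (cand in c("s2", "s3", "s4")) {
    expect_equal(fwd$scores[fwd$candidates == cand],
                 oracle_score(sp, cand, "negative@e1", "s1"))
    expect_equal(rev$scores[rev$candidates == cand],
                 oracle_score(sp, "s1", "negative@e1", cand))
  }

  expect_error(recommend_strains(emb, "t", "positive", "e", character(0)),
               "empty")
  expect_error(recommend_strains(emb, "t", "positive", "e", c("t", "c1")),
               "target")
})

test_that("distance matrices are symmetric with labelled axes", {
  sp <- random_embeddings("SimplE", n_ent = 4, n_env = 2, dim = 3, seed = 8)
  em <- environment_distance_matrix(sp)
  expect_equal(em, t(em))
  expect_equal(rownames(em), c("e1", "e2"))
  expect_true(all(diag(em) == 0))
  sm <- strain_distance_matrix(sp)
  expect_equal(dim(sm), c(4, 4))
  expect_equal(sm, t(sm))
})
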