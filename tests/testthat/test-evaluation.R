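# hand-set DistMult model over 2 entities / 1 environment where the
# positive relation dominates for (x, e, y)
toy_classifier <- function() {
  rels <- paste0(interaction_types(), "@e")
  emb <- init_embeddings(2, 3, model = "DistMult", dim = 1, seed = 1,
                         entity_names = c("x", "y"), relation_names = rels)
  emb$params$E <- matrix(c(1, 1), 2, 1)
  emb$params$R <- matrix(c(1, 1, 3), 3, 1)   # negative, neutral, positive
  emb
}

test_that("interaction classification is the relation-wise argmax", {
  emb <- toy_classifier()
  res <- classify_interaction(emb, "x", "y", "e")
  expect_equal(res$label, "positive")
  expect_equal(unname(res$scores), c(1, 1, 3))

  # all-tied scores fall back to the canonical first type
  emb$params$R <- matrix(1, 3, 1)
  expect_equal(classify_interaction(emb, "x", "y", "e")$label, "negative")
  expect_error(classify_interaction(emb, "x", "y", "nope"), "nope")
})

test_that("classification agrees with exhaustive rescoring on random models", {
  for (case in 1:25) {
    model <- sample(c("TransE", "DistMult", "SimplE"), 1)
    emb <- random_embeddings(model, n_ent = 5, n_env = 2, dim = 3,
                             seed = case)
    set.seed(case)
    s <- sample(emb$entities, 1)
    t <- sample(setdiff(emb$entities, s), 1)
    e <- sample(c("e1", "e2"), 1)
    expect_equal(classify_interaction(emb, s, t, e)$label,
                 oracle_classify(emb, s, t, e))
  }
})

test_that("classification metrics recover published-style recalls", {
  # confusion with 423 true negatives (396 correct) and 152 true neutrals
  # (136 correct); remainders spread over the other predicted classes
  truths <- c(rep("negative", 423), rep("neutral", 152))
  preds <- c(rep("negative", 396), rep("neutral", 20), rep("positive", 7),
             rep("neutral", 136), rep("negative", 10), rep("positive", 6))
  # no true positives in this set: the positive-class recall denominator
  # is legitimately zero and warned about
  m <- suppressWarnings(classification_metrics(preds, truths))
  expect_equal(m$per_class$recall[m$per_class$class == "negative"], 396 / 423)
  expect_equal(m$per_class$recall[m$per_class$class == "neutral"], 136 / 152)
  expect_equal(m$accuracy, (396 + 136) / 575)
  expect_equal(sum(m$confusion), 575)

  perfect <- suppressWarnings(classification_metrics(truths, truths))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1[perfect$per_class$support > 0] == 1))
})

test_that("accuracy equals one minus the misclassification rate exactly", {
  set.seed(4)
  truths <- sample(interaction_types(), 101, replace = TRUE)
  preds <- sample(interaction_types(), 101, replace = TRUE)
  m <- classification_metrics(preds, truths)
  expect_identical(m$accuracy, 1 - mean(preds != truths))
})

test_that("zero-denominator precision/recall is 0 with a warning", {
  w <- capture_warnings(
    m <- classification_metrics(c("negative", "negative"),
                                c("negative", "positive")))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(m$per_class$precision[m$per_class$class == "neutral"], 0)
})

test_that("ranks follow the raw definition with mean-rank ties", {
  emb <- toy_classifier()
  # distinct entity values: strict ordering
  emb$params$E <- matrix(c(2, 1), 2, 1)
  # (x, positive@e, y): head candidates scored h*3*1 -> x wins
  expect_equal(rank_triple(emb, "x", "positive@e", "y", side = "head"), 1)
  # tail candidates scored 2*3*t -> y (value 1) is second of two
  expect_equal(rank_triple(emb, "x", "positive@e", "y", side = "tail"), 2)

  # all candidates tied -> mean rank (n + 1) / 2
  emb$params$E <- matrix(c(1, 1), 2, 1)
  expect_equal(rank_triple(emb, "x", "positive@e", "y", side = "head"), 1.5)
})

test_that("ranking agrees with the enumeration oracle on random graphs", {
  for (case in 1:20) {
    model <- sample(c("TransE", "DistMult", "SimplE"), 1)
    emb <- random_embeddings(model, n_ent = 6, n_env = 2, dim = 3,
                             seed = 100 + case)
    set.seed(case)
    h <- sample(emb$entities, 1)
    t <- sample(setdiff(emb$entities, h), 1)
    r <- sample(emb$relations, 1)
    for (side in c("head", "tail")) {
      expect_equal(rank_triple(emb, h, r, t, side = side),
                   oracle_rank(emb, h, r, t, side))
    }
  }
})

test_that("MRR and Hits@k follow their definitions on a crafted model", {
  # SimplE d=1 with disjoint forward/inverse relations makes head and tail
  # ranks independently controllable via the two role matrices
  rels <- c("negative@e", "positive@e")
  emb <- init_embeddings(3, 2, model = "SimplE", dim = 1, seed = 1,
                         entity_names = c("A", "B", "C"),
                         relation_names = rels)
  emb$params$E_h <- matrix(c(1, 3, 2), 3, 1)   # B > C > A in head role
  emb$params$E_t <- matrix(c(3, 1, 2), 3, 1)   # A > C > B in tail role
  emb$params$R <- matrix(c(2, 0), 2, 1)        # negative@e: forward only
  emb$params$R_inv <- matrix(c(0, 2), 2, 1)    # positive@e: inverse only

  test_kg <- build_kg(data.frame(
    sender = c("B", "A"), receiver = c("C", "B"),
    environment = "e", label = c("negative", "positive")))
  res <- mrr_hits(emb, test_kg, ks = c(1, 2))
  # ranks: (B, negative@e, C): head 1, tail 2; (A, positive@e, B): 1, 1
  expect_equal(res$mrr, (1 + 1 / 2 + 1 + 1) / 4)
  expect_equal(unname(res$hits_at), c(3 / 4, 1))

  oracle <- oracle_mrr_hits(emb, test_kg$triples, ks = c(1, 2))
  expect_equal(res$mrr, oracle$mrr)

  # perfect model limit: every rank 1
  expect_equal(res$hits_at[["hits@2"]], 1)
  expect_error(mrr_hits(emb, build_kg(tiny_records()[0, ])), "triple")
})

test_that("Hits@k is nondecreasing in k and saturates at the entity count", {
  emb <- random_embeddings("SimplE", n_ent = 6, n_env = 2, dim = 3, seed = 31)
  set.seed(31)
  recs <- data.frame(sender = c("s1", "s2", "s3"),
                     receiver = c("s2", "s4", "s6"),
                     environment = "e1",
                     label = c("positive", "negative", "neutral"))
  kg <- build_kg(recs)
  res <- mrr_hits(emb, kg, ks = 1:6)
  expect_true(all(diff(res$hits_at) >= 0))
  expect_equal(res$hits_at[["hits@6"]], 1)
  expect_gt(res$mrr, 0)
  expect_lte(res$mrr, 1)
})

test_that("null models predict stratum majorities with global fallback", {
  recs <- data.frame(
    sender = c("A", "B", "C", "A", "A", "B", "C", "B", "C"),
    receiver = c("B", "C", "A", "C", "B", "C", "A", "A", "B"),
    environment = c(rep("e1", 4), rep("e2", 3), rep("e3", 2)),
    label = c(rep("negative", 4), "positive", "positive", "negative",
              "neutral", "neutral"))
  kg <- build_kg(recs)   # global: 5 negative, 2 positive, 2 neutral

  # A: global majority is negative everywhere
  expect_equal(null_model_predict("A_global_majority", kg,
                                  "A", "B", "e2"), "negative")
  # B: e1 is all negative
  fitB <- null_model("B_environment_majority", kg)
  expect_equal(null_model_predict(fitB, sender = "A", receiver = "B",
                                  environment = "e1"), "negative")
  # e3's stratum majority overrides the global one
  expect_equal(null_model_predict(fitB, sender = "A", receiver = "C",
                                  environment = "e3"), "neutral")
  # unseen stratum falls back to the global majority
  expect_equal(null_model_predict(fitB, sender = "A", receiver = "B",
                                  environment = "e9"), "negative")
  # E: unseen pair falls back too
  fitE <- null_model("E_pair_majority", kg)
  expect_equal(null_model_predict(fitE, sender = "Z", receiver = "Q",
                                  environment = "e1"), "negative")
})

test_that("null model A's accuracy equals the majority-class frequency", {
  ds <- generate_dataset(synthetic_config(n_strains = 8, n_environments = 5,
                                          env_groups = 2, seed = 12,
                                          missing_fraction = 0))
  kg <- build_kg(ds$records)
  sp <- split_kg(kg, seed = 12)
  fit <- null_model("A_global_majority", sp$train)
  maj <- names(which.max(table(sp$train$triples$type)))
  pred <- null_model_predict(fit, sender = sp$test$triples$head,
                             receiver = sp$test$triples$tail,
                             environment = sp$test$triples$environment)
  expect_true(all(pred == maj))
  expect_equal(mean(pred == sp$test$triples$type),
               mean(sp$test$triples$type == maj))
})

test_that("entropy and effective class number cover the three regimes", {
  u <- interaction_entropy(c(7, 7, 7))
  expect_equal(u$H, log2(3))
  expect_equal(u$effective_classes, 3)

  d <- interaction_entropy(c(9, 0, 0))
  expect_equal(d$H, 0)
  expect_equal(d$effective_classes, 1)

  two <- interaction_entropy(c(5, 5, 0))
  expect_equal(two$H, 1)
  expect_equal(two$effective_classes, 2)
  expect_error(interaction_entropy(c(0, 0, 0)), "zero")
})
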