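#' Leave-one-strain-out evaluation of unseen-strain prediction
#'
#' For each held-out strain, removes every triple containing it (either
#' role) from the graph, retrains the model on the remainder, builds the
#' strain's synthetic embedding from its phylogenetically nearest in-graph
#' neighbours (or from random neighbours, as a baseline), predicts the
#' held-out interactions and records the per-strain accuracy. This mirrors
#' the n-fold protocol in which the model is retrained once per held-out
#' strain.
#'
#' @param records labeled interaction table (see [build_kg()]).
#' @param phylo phylogenetic feature table.
#' @param config [train_config()] used for every retraining.
#' @param k neighbour count for the synthetic embedding.
#' @param strains strains to hold out (default: all strains in the graph).
#' @param neighbor_mode `"phylo"` (nearest by phylogenetic distance) or
#'   `"random"` (k neighbours sampled uniformly; their true distances still
#'   set the weights).
#' @param seed seed for the random-neighbour draws.
#' @return data.frame with columns `strain`, `n_queries`, `accuracy`.
#' @export
evaluate_unseen_strains <- function(records, phylo, config = train_config(),
                                    k = 5L, strains = NULL,
                                    neighbor_mode = c("phylo", "random"),
                                    seed = 1L) {
  neighbor_mode <- match.arg(neighbor_mode)
  all_strains <- sort(unique(c(records$sender, records$receiver)))
  if (is.null(strains)) strains <- all_strains
  set.seed(as.integer(seed))
  out <- lapply(strains, function(s) {
    keep <- records$sender != s & records$receiver != s
    # rebuild the graph without the strain so it is truly unseen (absent
    # from the entity vocabulary, not merely from the triples)
    train_kg <- build_kg(records[keep, , drop = FALSE],
                         vocabulary_mode = "full_grid")
    model <- train_kge(train_kg, config)
    test_kg <- build_kg(records[!keep, , drop = FALSE],
                        vocabulary_mode = "observed_only")
    tri <- test_kg$triples
    queries <- data.frame(
      partner = ifelse(tri$head == s, tri$tail, tri$head),
      environment = tri$environment,
      direction = ifelse(tri$head == s, "target_as_sender",
                         "target_as_receiver"),
      stringsAsFactors = FALSE)
    neighbors <- if (neighbor_mode == "random") {
      pool <- intersect(model$embeddings$entities,
                        as.character(phylo$strain_id))
      sample(pool, k)
    }
    pred <- predict_unseen(model, phylo, s, queries, k = k,
                           neighbors = neighbors)
    data.frame(strain = s, n_queries = nrow(tri),
               accuracy = mean(pred == tri$type), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate the environment-similarity transfer rule on held-out queries
#'
#' Applies [environment_rule_predict()] to each query, or — as a baseline —
#' copies the pair's observed interaction from a donor environment chosen
#' uniformly at random (resampled per query). Queries without any donor
#' observation (or none within `max_distance`) are returned unanswered.
#'
#' @param model trained `microkge_model`.
#' @param reference_kg graph holding the donor observations.
#' @param queries data.frame with columns `sender`, `receiver`,
#'   `environment` and optionally `truth`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param max_distance optional donor distance cap.
#' @param donor `"similarity"` (the rule) or `"random"` (baseline).
#' @param seed seed for the random-donor baseline.
#' @return `queries` with added columns `prediction`, `used_environment`,
#'   `distance`, `answered`.
#' @export
evaluate_environment_rule <- function(model, reference_kg, queries,
                                      metric = c("euclidean", "cosine"),
                                      max_distance = NULL,
                                      donor = c("similarity", "random"),
                                      seed = 1L) {
  metric <- match.arg(metric)
  donor <- match.arg(donor)
  check_that(all(c("sender", "receiver", "environment") %in% names(queries)),
             "queries needs columns sender, receiver, environment")
  set.seed(as.integer(seed))
  tri <- reference_kg$triples
  n <- nrow(queries)
  prediction <- used_env <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (donor == "similarity") {
      res <- tryCatch(
        environment_rule_predict(model, reference_kg, queries$sender[i],
                                 queries$receiver[i], queries$environment[i],
                                 metric = metric, max_distance = max_distance),
        error = function(e) NULL)
      if (!is.null(res)) {
        prediction[i] <- res$label
        used_env[i] <- res$used_environment
        distance[i] <- res$distance
      }
    } else {
      hit <- which(tri$head == queries$sender[i] &
                     tri$tail == queries$receiver[i] &
                     tri$environment != queries$environment[i])
      if (length(hit) > 0) {
        pick <- hit[sample.int(length(hit), 1L)]
        prediction[i] <- tri$type[pick]
        used_env[i] <- tri$environment[pick]
      }
    }
  }
  out <- queries
  out$prediction <- prediction
  out$used_environment <- used_env
  out$distance <- distance
  out$answered <- !is.na(prediction)
  out
}

#' One-call pipeline: simulate, split, train, evaluate
#'
#' Convenience wrapper running the full workflow on synthetic data:
#' generate a dataset, build the knowledge graph, split it 90/5/5, train
#' the configured model and report classification and ranking metrics on
#' the test split. Used by the command-line smoke path and the acceptance
#' script.
#'
#' @param synth_config a [synthetic_config()].
#' @param config a [train_config()].
#' @param fractions train/valid/test fractions.
#' @param ks Hits@k cutoffs.
#' @return list with `dataset`, `kg`, `splits`, `model`, `classification`
#'   (a `microkge_metrics`) and `ranking` (from [mrr_hits()]).
#' @export
run_pipeline <- function(synth_config = synthetic_config(),
                         config = train_config(),
                         fractions = c(0.9, 0.05, 0.05),
                         ks = c(1L, 3L, 10L)) {
  dataset <- generate_dataset(synth_config)
  vocab <- if (config$ns_strategy == "interaction_based") "full_grid"
           else "observed_only"
  kg <- build_kg(dataset$records, vocabulary_mode = vocab)
  splits <- split_kg(kg, fractions = fractions, mode = "random",
                     seed = config$seed)
  model <- train_kge(splits$train, config)
  list(dataset = dataset, kg = kg, splits = splits, model = model,
       classification = evaluate_classification(model, splits$test),
       ranking = mrr_hits(model, splits$test, ks = ks))
}
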