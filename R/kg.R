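#' Coculture effect of a competitor strain on a focus strain
#'
#' The effect of a competitor strain S2 on a focus strain S1 in one
#' carbon-source environment is the log ratio of the focus strain's growth
#' yield in coculture versus monoculture:
#' \deqn{E_{S_2 \to S_1} = \log\left(\frac{Coculture(S_1|S_2)}{Monoculture(S_1)}\right)}
#' A positive value means the competitor enhances growth of the focus
#' strain, a negative value means it inhibits it, and 0 means no detected
#' effect. The logarithm base only scales the effect and never changes its
#' sign, so it is inert for the discretized labels; the natural log is the
#' default.
#'
#' @param coculture_yield positive growth yield of the focus strain in
#'   coculture.
#' @param monoculture_yield positive growth yield of the focus strain alone.
#' @param base logarithm base (default `exp(1)`).
#' @return numeric effect value(s) on the log-ratio scale.
#' @examples
#' compute_effect(10, 10)        # 0: no effect
#' compute_effect(exp(1) * 5, 5) # 1: e-fold enhancement
#' @export
compute_effect <- function(coculture_yield, monoculture_yield, base = exp(1)) {
  check_that(all(is.finite(coculture_yield)) && all(coculture_yield > 0),
             "coculture_yield must be a positive finite number")
  check_that(all(is.finite(monoculture_yield)) && all(monoculture_yield > 0),
             "monoculture_yield must be a positive finite number")
  log(coculture_yield / monoculture_yield, base = base)
}

#' Discretize a continuous coculture effect into an interaction type
#'
#' Effects within `neutral_band` of zero map to "neutral", effects above the
#' band to "positive" and below to "negative". The default band of 0 maps
#' exactly-zero effects to neutral, matching the sign rule used to label the
#' source data; a nonzero band accommodates datasets whose neutral class was
#' delimited by a detection threshold rather than exact zero.
#'
#' @param effect finite numeric effect value(s).
#' @param neutral_band nonnegative half-width of the neutral band.
#' @return character vector of interaction types.
#' @examples
#' discretize_effect(0.8)          # "positive"
#' discretize_effect(-0.3, 0.5)    # "neutral"
#' @export
discretize_effect <- function(effect, neutral_band = 0) {
  check_that(is.numeric(effect) && all(is.finite(effect)),
             "effect must be finite (no NA/NaN/Inf)")
  check_that(is.numeric(neutral_band) && length(neutral_band) == 1 &&
               is.finite(neutral_band) && neutral_band >= 0,
             "neutral_band must be a nonnegative finite number")
  out <- rep("neutral", length(effect))
  out[effect > neutral_band] <- "positive"
  out[effect < -neutral_band] <- "negative"
  out
}

#' Build a knowledge graph from labeled interaction records
#'
#' Each labeled record (sender, receiver, environment, label) becomes one
#' triple (head = sender, relation = (label, environment), tail = receiver).
#' Entities are the strains occurring as sender or receiver; the relation
#' vocabulary is either exactly the observed (type, environment) pairs
#' (`"observed_only"`) or the full 3 x n_environments grid (`"full_grid"`).
#' Interaction-based negative sampling corrupts the type component of a
#' relation and may therefore reference unobserved combinations, so
#' `"full_grid"` is required for (and is the natural companion of) that
#' sampler.
#'
#' Duplicate records for the same (sender, environment, receiver) cell are
#' collapsed to one triple with a warning when their labels agree, and are
#' an error when the labels conflict.
#'
#' @param records data.frame with columns `sender`, `receiver`,
#'   `environment`, and `label` (or `effect`, which is discretized with
#'   `neutral_band`).
#' @param vocabulary_mode `"observed_only"` or `"full_grid"`.
#' @param neutral_band band used when labels must be derived from effects.
#' @return An object of class `"microkge_kg"`: a list with `entities`
#'   (character), `environments` (character), `relations` (data.frame with
#'   columns `id`, `type`, `environment`), `triples` (data.frame with
#'   columns `head`, `type`, `environment`, `tail`, `relation`) and
#'   `vocabulary_mode`.
#' @export
build_kg <- function(records,
                     vocabulary_mode = c("observed_only", "full_grid"),
                     neutral_band = 0) {
  vocabulary_mode <- match.arg(vocabulary_mode)
  check_that(is.data.frame(records), "records must be a data.frame")
  req <- c("sender", "receiver", "environment")
  miss <- setdiff(req, names(records))
  check_that(length(miss) == 0,
             paste0("records missing required column(s): ",
                    paste(miss, collapse = ", ")))

  if (nrow(records) == 0) {
    kg <- list(entities = character(0), environments = character(0),
               relations = data.frame(id = character(0), type = character(0),
                                      environment = character(0),
                                      stringsAsFactors = FALSE),
               triples = empty_triples(), vocabulary_mode = vocabulary_mode)
    class(kg) <- "microkge_kg"
    return(kg)
  }

  sender <- as.character(records$sender)
  receiver <- as.character(records$receiver)
  environment <- as.character(records$environment)
  check_that(!any(sender == receiver),
             "self-interactions (sender == receiver) are not representable")

  if (!is.null(records$label) && !all(is.na(records$label))) {
    label <- normalize_label(records$label)
    if (anyNA(label)) {
      need <- is.na(label)
      check_that(!is.null(records$effect) && !any(is.na(records$effect[need])),
                 "records without a label must carry an effect")
      label[need] <- discretize_effect(records$effect[need], neutral_band)
    }
  } else if (!is.null(records$effect)) {
    check_that(!any(is.na(records$effect)),
               "records without a label must carry an effect")
    label <- discretize_effect(records$effect, neutral_band)
  } else {
    stop("records must have a 'label' or an 'effect' column", call. = FALSE)
  }

  cell <- paste(sender, environment, receiver, sep = "\r")
  if (anyDuplicated(cell)) {
    lab_per_cell <- tapply(label, cell, function(x) length(unique(x)))
    conflict <- names(lab_per_cell)[lab_per_cell > 1]
    if (length(conflict) > 0) {
      stop("conflicting duplicate records (same cell, different labels): ",
           paste(gsub("\r", " -> ", utils::head(conflict, 5)), collapse = "; "),
           call. = FALSE)
    }
    warning(sum(duplicated(cell)),
            " duplicate record(s) with identical labels collapsed",
            call. = FALSE)
    keep <- !duplicated(cell)
    sender <- sender[keep]; receiver <- receiver[keep]
    environment <- environment[keep]; label <- label[keep]
  }

  entities <- sort(unique(c(sender, receiver)))
  environments <- sort(unique(environment))
  triples <- data.frame(head = sender, type = label,
                        environment = environment, tail = receiver,
                        relation = relation_id(label, environment),
                        stringsAsFactors = FALSE)
  relations <- relation_table(environments, triples, vocabulary_mode)

  kg <- list(entities = entities, environments = environments,
             relations = relations, triples = triples,
             vocabulary_mode = vocabulary_mode)
  class(kg) <- "microkge_kg"
  kg
}

empty_triples <- function() {
  data.frame(head = character(0), type = character(0),
             environment = character(0), tail = character(0),
             relation = character(0), stringsAsFactors = FALSE)
}

relation_table <- function(environments, triples, vocabulary_mode) {
  if (vocabulary_mode == "full_grid") {
    grid <- expand.grid(type = interaction_types(),
                        environment = environments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    grid <- unique(triples[, c("type", "environment")])
  }
  grid <- grid[order(grid$environment,
                     match(grid$type, interaction_types())), , drop = FALSE]
  rownames(grid) <- NULL
  data.frame(id = relation_id(grid$type, grid$environment),
             type = grid$type, environment = grid$environment,
             stringsAsFactors = FALSE)
}

# rebuild a KG around a subset of triples, keeping the parent vocabulary
subset_kg <- function(kg, idx) {
  out <- kg
  out$triples <- kg$triples[idx, , drop = FALSE]
  rownames(out$triples) <- NULL
  out
}

#' @export
print.microkge_kg <- function(x, ...) {
  n_obs <- length(unique(x$triples$relation))
  cat("Microbial interaction knowledge graph\n",
      "  entities:  ", length(x$entities), "\n",
      "  relations: ", nrow(x$relations), " (", x$vocabulary_mode,
      "; observed: ", n_obs, ")\n",
      "  triples:   ", nrow(x$triples), "\n", sep = "")
  invisible(x)
}

#' Split a knowledge graph into train / validation / test sets
#'
#' Three split protocols are supported. `"random"` is a uniform triple-level
#' split into the given fractions (90/5/5 by default), with set sizes fixed
#' by largest-remainder rounding so the fractions are recovered exactly when
#' the triple count allows it. `"holdout_receivers"` sends every triple whose
#' tail (receiver) is a held-out strain to the test set and splits the
#' remainder between train and validation; this removes all growth
#' observations *of* those strains while keeping their sender role visible.
#' `"holdout_strain"` sends every triple containing the strain in either role
#' to the test set — the unseen-strain protocol, under which the model has
#' no access to the strain at all.
#'
#' @param kg a `microkge_kg`.
#' @param fractions three nonnegative numbers summing to 1
#'   (train, validation, test). For holdout modes the third entry is ignored
#'   and the first two are renormalized over the non-held-out triples.
#' @param mode `"random"`, `"holdout_receivers"` or `"holdout_strain"`.
#' @param holdout_ids strains to hold out (required for holdout modes unless
#'   `holdout_n` is given, in which case that many strains are sampled).
#' @param holdout_n number of strains to sample as holdouts.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with elements `train`, `valid`, `test` (each a
#'   `microkge_kg` sharing the parent's entity and relation vocabulary) and
#'   `holdout_ids`.
#' @export
split_kg <- function(kg, fractions = c(0.9, 0.05, 0.05),
                     mode = c("random", "holdout_receivers", "holdout_strain"),
                     holdout_ids = NULL, holdout_n = NULL, seed = 1L) {
  mode <- match.arg(mode)
  check_that(inherits(kg, "microkge_kg"), "kg must be a microkge_kg")
  check_that(length(fractions) == 3 && all(fractions >= 0) &&
               abs(sum(fractions) - 1) <= 1e-9,
             "fractions must be three nonnegative numbers summing to 1")
  n <- nrow(kg$triples)
  set.seed(as.integer(seed))

  if (mode == "random") {
    sizes <- largest_remainder(n, fractions)
    lab <- sample(rep.int(c("train", "valid", "test"), sizes))
    res <- list(train = subset_kg(kg, lab == "train"),
                valid = subset_kg(kg, lab == "valid"),
                test = subset_kg(kg, lab == "test"),
                holdout_ids = character(0))
    return(res)
  }

  if (is.null(holdout_ids)) {
    check_that(!is.null(holdout_n), "holdout modes need holdout_ids or holdout_n")
    holdout_ids <- sample(kg$entities, holdout_n)
  }
  holdout_ids <- as.character(holdout_ids)
  unknown <- setdiff(holdout_ids, kg$entities)
  check_that(length(unknown) == 0,
             paste0("holdout id(s) not in graph: ",
                    paste(unknown, collapse = ", ")))

  in_test <- if (mode == "holdout_receivers") {
    kg$triples$tail %in% holdout_ids
  } else {
    kg$triples$head %in% holdout_ids | kg$triples$tail %in% holdout_ids
  }
  rest <- which(!in_test)
  f12 <- fractions[1:2]
  f12 <- if (sum(f12) == 0) c(1, 0) else f12 / sum(f12)
  sizes <- largest_remainder(length(rest), c(f12, 0))
  lab <- sample(rep.int(c("train", "valid"), sizes[1:2]))
  list(train = subset_kg(kg, rest[lab == "train"]),
       valid = subset_kg(kg, rest[lab == "valid"]),
       test = subset_kg(kg, which(in_test)),
       holdout_ids = holdout_ids)
}

# integer allocation of n into parts proportional to fractions,
# largest-remainder (Hamilton) method
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
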