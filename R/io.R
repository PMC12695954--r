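#' Read an interaction table
#'
#' The interaction CSV dialect: UTF-8, comma-separated, header required,
#' columns `sender`, `receiver`, `environment` (strings; `"@"` forbidden in
#' environment names) plus at least one of `effect` (decimal log-ratio) and
#' `label` (`negative|neutral|positive`, case-insensitive). Errors report
#' the offending row number.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping the required
#'   names to the file's actual column names, e.g.
#'   `c(sender = "S2", receiver = "S1")`.
#' @return data.frame of interaction records.
#' @export
read_interactions <- function(path, column_map = NULL) {
  check_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      pos <- match(column_map[[std]], names(df))
      check_that(!is.na(pos), paste0("mapped column not found: ",
                                     column_map[[std]]))
      names(df)[pos] <- std
    }
  }
  for (col in c("sender", "receiver", "environment")) {
    check_that(col %in% names(df),
               paste0("missing required column: ", col))
  }
  check_that(any(c("effect", "label") %in% names(df)),
             "need an 'effect' or 'label' column")
  check_that(!any(grepl("@", df$environment, fixed = TRUE)),
             "environment names must not contain '@'")
  out <- data.frame(sender = df$sender, receiver = df$receiver,
                    environment = df$environment, stringsAsFactors = FALSE)
  out$effect <- if ("effect" %in% names(df)) {
    suppressWarnings(as.numeric(df$effect))
  } else {
    NA_real_
  }
  out$label <- if ("label" %in% names(df)) {
    lab <- trimws(df$label)
    lab[lab == ""] <- NA_character_
    normalize_label(lab)
  } else {
    NA_character_
  }
  bad <- which(is.na(out$effect) & is.na(out$label))
  if (length(bad) > 0) {
    stop("row(s) with neither effect nor label: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  self <- which(out$sender == out$receiver)
  if (length(self) > 0) {
    stop("sender equals receiver at row(s): ",
         paste(utils::head(self, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write an interaction table
#'
#' Inverse of [read_interactions()]; numeric effects are written with full
#' precision (`%.17g`) so a write/read round trip is lossless.
#'
#' @param records interaction record data.frame.
#' @param path output path.
#' @export
write_interactions <- function(records, path) {
  out <- records
  if ("effect" %in% names(out)) {
    out$effect <- ifelse(is.na(out$effect), "",
                         sprintf("%.17g", as.numeric(out$effect)))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export knowledge graph triples as TSV
#'
#' One line per triple: `head <TAB> type@environment <TAB> tail`.
#'
#' @param kg a `microkge_kg`.
#' @param path output path.
#' @export
write_triples <- function(kg, path) {
  lines <- paste(kg$triples$head, kg$triples$relation, kg$triples$tail,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export / import embeddings as TSV
#'
#' Columns: `id`, `role` (`entity`, `entity_head`, `entity_tail`,
#' `relation`, `relation_inv`), `v1..v_d`. Coordinates are written with the
#' `%.17g` decimal format, which round-trips IEEE doubles exactly.
#'
#' @param embeddings a `microkge_embeddings` or trained model.
#' @param path output path.
#' @export
write_embeddings <- function(embeddings, path) {
  emb <- as_embeddings(embeddings)
  role_of <- c(E = "entity", E_h = "entity_head", E_t = "entity_tail",
               R = "relation", R_inv = "relation_inv")
  rows <- lapply(names(emb$params), function(k) {
    ids <- if (k %in% c("R", "R_inv")) emb$relations else emb$entities
    M <- emb$params[[k]]
    vapply(seq_len(nrow(M)), function(i) {
      paste(c(ids[i], role_of[[k]], sprintf("%.17g", M[i, ])),
            collapse = "\t")
    }, character(1))
  })
  header <- paste(c("id", "role", paste0("v", seq_len(emb$dim))),
                  collapse = "\t")
  writeLines(c(header, unlist(rows)), path)
  invisible(path)
}

#' @rdname write_embeddings
#' @param model,norm_kind model kind and TransE norm recorded alongside the
#'   coordinates (not stored in the TSV itself).
#' @export
read_embeddings <- function(path, model = c("SimplE", "TransE", "DistMult"),
                            norm_kind = c("L2", "L1")) {
  model <- match.arg(model)
  norm_kind <- match.arg(norm_kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  to_mat <- function(role) {
    sub <- df[df$role == role, , drop = FALSE]
    m <- as.matrix(sub[, vcols, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    list(ids = sub$id, m = m)
  }
  if (model == "SimplE") {
    eh <- to_mat("entity_head"); et <- to_mat("entity_tail")
    r <- to_mat("relation"); ri <- to_mat("relation_inv")
    params <- list(E_h = eh$m, E_t = et$m, R = r$m, R_inv = ri$m)
    entities <- eh$ids; relations <- r$ids
  } else {
    e <- to_mat("entity"); r <- to_mat("relation")
    params <- list(E = e$m, R = r$m)
    entities <- e$ids; relations <- r$ids
  }
  structure(list(model = model, dim = length(vcols), norm_kind = norm_kind,
                 entities = entities, relations = relations, params = params),
            class = "microkge_embeddings")
}

#' Save / load a trained model checkpoint
#'
#' A checkpoint is a directory of plain-text files: `embeddings.tsv`
#' (see [write_embeddings()]), `config.json`, `kg.json` (entity, relation
#' and environment vocabularies) and `loss_history.json`.
#'
#' @param model a `microkge_model`.
#' @param dir checkpoint directory (created if absent).
#' @return the directory path (`save_model`) or the restored model
#'   (`load_model`).
#' @export
save_model <- function(model, dir) {
  check_that(inherits(model, "microkge_model"), "model must be a microkge_model")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_embeddings(model$embeddings, file.path(dir, "embeddings.tsv"))
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(model$kg, file.path(dir, "kg.json"),
                       auto_unbox = FALSE, dataframe = "columns")
  jsonlite::write_json(model$loss_history, file.path(dir, "loss_history.json"),
                       digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(train_config, cfg)
  kg_meta <- jsonlite::read_json(file.path(dir, "kg.json"),
                                 simplifyVector = TRUE)
  kg_meta$relations <- as.data.frame(kg_meta$relations,
                                     stringsAsFactors = FALSE)
  emb <- read_embeddings(file.path(dir, "embeddings.tsv"),
                         model = config$model, norm_kind = config$norm_kind)
  loss_history <- unlist(jsonlite::read_json(
    file.path(dir, "loss_history.json"), simplifyVector = TRUE))
  if (is.null(loss_history)) loss_history <- numeric(0)
  structure(list(embeddings = emb, config = config,
                 loss_history = as.numeric(loss_history), kg = kg_meta),
            class = "microkge_model")
}

#' Export metrics as JSON and the confusion matrix as CSV
#'
#' @param metrics a `microkge_metrics`, optionally with ranking results
#'   attached.
#' @param path JSON output path.
#' @param ranking optional result of [mrr_hits()] merged into the JSON.
#' @export
write_metrics <- function(metrics, path, ranking = NULL) {
  payload <- list(accuracy = metrics$accuracy, macro_f1 = metrics$macro_f1,
                  per_class = metrics$per_class, n = metrics$n,
                  confusion = as.data.frame(as.table(metrics$confusion)))
  if (!is.null(ranking)) {
    payload$mrr <- ranking$mrr
    payload$hits_at <- as.list(ranking$hits_at)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_confusion <- function(metrics, path) {
  utils::write.csv(metrics$confusion, path, row.names = TRUE)
  invisible(path)
}

#' Write a labeled distance matrix as CSV
#'
#' @param m symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(m, path) {
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read a phylogenetic feature table
#'
#' CSV with a `strain_id` column and numeric coordinate columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phylo_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that("strain_id" %in% names(df), "missing required column: strain_id")
  phylo_matrix(df)   # validates
  df
}
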