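#' Canonical interaction-type vocabulary
#'
#' The three coculture interaction outcomes in their canonical order
#' (negative < neutral < positive). This ordering is used throughout the
#' package for deterministic tie-breaking and for serialization: the first
#' type in canonical order wins a tie, and environment embeddings
#' concatenate relation vectors in this order.
#'
#' @return Character vector `c("negative", "neutral", "positive")`.
#' @export
interaction_types <- function() c("negative", "neutral", "positive")

#' Normalize interaction-type labels
#'
#' Case-insensitive mapping of labels onto the canonical vocabulary.
#'
#' @param x character vector of labels.
#' @return character vector of canonical lower-case labels.
#' @keywords internal
normalize_label <- function(x) {
  lab <- tolower(trimws(as.character(x)))
  bad <- !is.na(lab) & !(lab %in% interaction_types())
  if (any(bad)) {
    stop("unknown interaction label(s): ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  }
  lab
}

#' Serialize a relation as "type@environment"
#'
#' @param type interaction type(s).
#' @param environment environment identifier(s); must not contain `"@"`.
#' @return character vector of relation identifiers.
#' @export
relation_id <- function(type, environment) {
  if (any(grepl("@", environment, fixed = TRUE))) {
    stop("environment names must not contain '@'", call. = FALSE)
  }
  paste0(normalize_label(type), "@", environment)
}

# split "type@env" back into its components
parse_relation_id <- function(rel) {
  pos <- regexpr("@", rel, fixed = TRUE)
  if (any(pos < 0)) stop("malformed relation id (expected 'type@environment')",
                         call. = FALSE)
  list(type = normalize_label(substr(rel, 1L, pos - 1L)),
       environment = substring(rel, pos + 1L))
}

# stop() with a consistent prefix naming the offending argument
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
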