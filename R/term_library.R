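#' @title PRO-CTCAE term library
#'
#' @description
#' The PRO-CTCAE item library describes symptomatic adverse events as *terms*,
#' each belonging to one organ-system domain and carrying up to three
#' *attribute* questions: presence (yes/no, scored 0--1), severity,
#' interference, frequency, or amount (each 5-level ordinal, scored 0--4).
#' A `term_library` is a validated data frame with one row per term and 0/1
#' flags for the five attribute kinds.
#'
#' @name term_library
NULL

#' Attribute kinds of a PRO-CTCAE term
#'
#' @return character vector of the five attribute kinds, in canonical order.
#' @export
attribute_kinds <- function() c("presence", "severity", "interference", "frequency", "amount")

#' Maximum ordinal level of an attribute kind
#'
#' Presence is binary (0/1); all other attributes are scored 0--4.
#'
#' @param kind attribute kind name.
#' @return integer maximum level.
#' @export
attribute_max_level <- function(kind) {
  if (!all(kind %in% attribute_kinds())) abort_validation(paste0("unknown attribute kind: ", paste(setdiff(kind, attribute_kinds()), collapse = ", ")))
  ifelse(kind == "presence", 1L, 4L)
}

#' Ordinal cut level for proportion scores
#'
#' Severity >= "moderate", interference/amount >= "somewhat" and frequency >=
#' "occasionally" all sit at level 2 of the 0--4 scale, as does the physician
#' impact cut (>= "moderate").
#'
#' @return integer scalar, 2.
#' @export
proportion_cut_level <- function() 2L

LIBRARY_COLUMNS <- c("term_id", "display_name", "domain", attribute_kinds())

#' Construct a validated term library
#'
#' @param df data frame with columns `term_id`, `display_name`, `domain` and
#'   the five attribute flags (0/1) named as in [attribute_kinds()].
#' @return a `term_library` object (validated data frame).
#' @details Validation enforces: unique term ids; non-empty attribute sets;
#'   at most 3 attributes per term; presence-only terms carry exactly the
#'   presence question (presence is never combined with an ordinal attribute
#'   in the instrument).
#' @export
term_library <- function(df) {
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0("term library is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[, LIBRARY_COLUMNS]
  if (nrow(df) == 0) abort_validation("term library has no terms")
  if (anyDuplicated(df$term_id)) {
    abort_validation(paste0("duplicate term_id: ", paste(unique(df$term_id[duplicated(df$term_id)]), collapse = ", ")))
  }
  flags <- as.matrix(df[, attribute_kinds()])
  storage.mode(flags) <- "integer"
  if (any(is.na(flags)) || !all(flags %in% c(0L, 1L))) {
    abort_validation("attribute flags must be 0 or 1")
  }
  n_attr <- rowSums(flags)
  if (any(n_attr == 0)) {
    abort_validation(paste0("term(s) with empty attribute set: ", paste(df$term_id[n_attr == 0], collapse = ", ")))
  }
  if (any(n_attr > 3)) {
    abort_validation(paste0("term(s) with more than 3 attributes: ", paste(df$term_id[n_attr > 3], collapse = ", ")))
  }
  if (any(flags[, "presence"] == 1L & n_attr > 1)) {
    abort_validation("presence-only terms must have exactly the presence attribute")
  }
  df[, attribute_kinds()] <- flags
  rownames(df) <- NULL
  class(df) <- c("term_library", "data.frame")
  df
}

#' Load a term library from a delimited file
#'
#' @param path CSV/TSV file with header
#'   `term_id,display_name,domain,presence,severity,interference,frequency,amount`.
#' @param sep field separator (default comma).
#' @return a validated [term_library].
#' @export
load_term_library <- function(path, sep = ",") {
  if (!file.exists(path)) abort_format(paste0("term library file not found: ", path))
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"", comment.char = "")
  missing_cols <- setdiff(LIBRARY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort_format(paste0("term library file is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (a in attribute_kinds()) {
    v <- suppressWarnings(as.integer(df[[a]]))
    if (any(is.na(v))) abort_validation(paste0("non-numeric attribute flag in column ", a))
    df[[a]] <- v
  }
  term_library(df)
}

#' Write a term library to CSV
#'
#' @param library a [term_library].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_term_library <- function(library, path) {
  stopifnot(inherits(library, "term_library"))
  utils::write.csv(as.data.frame(library), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shipped 80-term PRO-CTCAE library fixture
#'
#' A reconstruction of the adult PRO-CTCAE v1.0 item library (80 terms, 124
#' attribute questions, 14 organ-system domains) assembled from the public
#' instrument description; it is a package fixture, not the official
#' instrument file. The two depression terms and the two irregular
#' menstruation terms are distinct `term_id`s sharing a display stem, so the
#' library holds 80 terms for 78 symptomatic adverse events.
#'
#' @return a [term_library] with 80 terms.
#' @export
proctcae_library <- function() {
  load_term_library(system.file("extdata", "proctcae_item_library.csv", package = "proctailor"))
}

#' Shipped tailored 30-term core library fixture
#'
#' The condensed phase I core list: 30 terms, 58 attribute questions, spanning
#' 11 organ-system domains.
#'
#' @return a [term_library] with 30 terms.
#' @export
tailored_core_library <- function() {
  load_term_library(system.file("extdata", "tailored_core_library.csv", package = "proctailor"))
}

#' Attribute set of one term
#'
#' @param library a [term_library].
#' @param term_id term key.
#' @return character vector of attribute kinds the term asks about.
#' @export
term_attributes <- function(library, term_id) {
  stopifnot(inherits(library, "term_library"))
  row <- library[library$term_id == term_id, , drop = FALSE]
  if (nrow(row) == 0) abort_lookup(paste0("unknown term_id: ", term_id))
  attribute_kinds()[as.logical(unlist(row[1, attribute_kinds()]))]
}

#' Count attribute questions over a set of terms
#'
#' The maximum number of survey items a list of terms generates when
#' conditional branching is off: the sum of each term's attribute-set size.
#'
#' @param term_ids character vector of term keys (may be empty).
#' @param library a [term_library].
#' @return integer count.
#' @export
item_count <- function(term_ids, library) {
  stopifnot(inherits(library, "term_library"))
  if (length(term_ids) == 0) return(0L)
  unknown <- setdiff(term_ids, library$term_id)
  if (length(unknown) > 0) abort_lookup(paste0("unknown term_id: ", paste(unknown, collapse = ", ")))
  idx <- match(term_ids, library$term_id)
  sum(rowSums(as.matrix(library[idx, attribute_kinds()])))
}

#' Terms of one organ-system domain
#'
#' @param library a [term_library].
#' @param domain domain name.
#' @return character vector of term ids, in lexicographic order.
#' @export
domain_terms <- function(library, domain) {
  stopifnot(inherits(library, "term_library"))
  if (!domain %in% library$domain) abort_lookup(paste0("unknown domain: ", domain))
  sort(library$term_id[library$domain == domain])
}

#' Domain names of a term library
#'
#' @param library a [term_library].
#' @return sorted character vector of domain names.
#' @export
library_domains <- function(library) {
  stopifnot(inherits(library, "term_library"))
  sort(unique(library$domain))
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf("PRO-CTCAE term library: %d terms, %d items, %d domains\n",
              nrow(x), item_count(x$term_id, x), length(unique(x$domain))))
  NextMethod()
}
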