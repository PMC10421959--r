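#' @title Per-term prevalence and proportion scores
#'
#' @description
#' All scores are simple proportions over pooled survey administrations:
#'
#' * **prevalence** -- administrations reporting *any* attribute of the term
#'   above its null level, over administrations in which the term was
#'   presented;
#' * **attribute proportion scores** (severity, interference, frequency,
#'   amount) -- responses at or above the attribute's cut level (level 2:
#'   "moderate" / "somewhat" / "occasionally"), over responses above level 0,
#'   i.e. among symptomatic responses only;
#' * **impact proportion score** -- physician panel ratings of impact on
#'   tolerability at or above "moderate", over *all* ratings of the term
#'   (the denominator is the full panel, not a symptomatic subset).
#'
#' Undefined scores (denominator 0) are carried as explicit `NA` values with
#' their zero denominators, never silently as 0. Stored values are full
#' precision; [percent()] applies half-up display rounding.
#'
#' @name scoring
NULL

new_proportion_score <- function(numerator, denominator, not_asked = FALSE) {
  value <- if (denominator > 0) numerator / denominator else NA_real_
  structure(list(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 value = value, not_asked = not_asked),
            class = "proportion_score")
}

#' @export
print.proportion_score <- function(x, ...) {
  if (x$not_asked) {
    cat("proportion score: not asked\n")
  } else if (is.na(x$value)) {
    cat(sprintf("proportion score: undefined (0/%d)\n", x$denominator))
  } else {
    cat(sprintf("proportion score: %d/%d = %.1f%%\n", x$numerator, x$denominator, percent(x$value)))
  }
  invisible(x)
}

term_records <- function(pooled, term_id) {
  pooled$records[pooled$records$term_id == term_id, , drop = FALSE]
}

#' Prevalence of a term over pooled administrations
#'
#' An administration counts toward the numerator when any of the term's
#' answered attribute items is above its null level (for presence-only terms,
#' a "yes"). The denominator is the number of administrations in which any of
#' the term's items was presented (answered).
#'
#' @param pooled a `pooled_responses` object from [pool_timepoints()].
#' @param term_id term key.
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @return a `proportion_score`; undefined (flagged, not an error) when the
#'   term was never presented.
#' @export
prevalence <- function(pooled, term_id, library = pooled$library) {
  stopifnot(inherits(pooled, "pooled_responses"))
  if (!term_id %in% library$term_id) abort_lookup(paste0("unknown term_id: ", term_id))
  rec <- term_records(pooled, term_id)
  if (nrow(rec) == 0) return(new_proportion_score(0L, 0L))
  any_pos <- tapply(rec$level > 0L, rec$admin_id, any)
  new_proportion_score(sum(any_pos), length(any_pos))
}

#' Attribute proportion score of a term
#'
#' Among symptomatic responses for the attribute (level > 0), the proportion
#' at or above the cut level ([proportion_cut_level()], level 2).
#'
#' @param pooled a `pooled_responses` object.
#' @param term_id term key.
#' @param attribute one of severity, interference, frequency, amount.
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @return a `proportion_score`; flagged `not_asked` when the term has no such
#'   attribute question; undefined when no response is above level 0.
#' @export
attribute_proportion_score <- function(pooled, term_id, attribute, library = pooled$library) {
  high_end_proportion(pooled, term_id, attribute, proportion_cut_level(), library)
}

#' High-end proportion of a term's attribute
#'
#' Same denominator as [attribute_proportion_score()] (symptomatic responses)
#' but a caller-chosen numerator level, e.g. level 3 for the share rated at
#' least "severe"/"frequently"/"quite a bit". At `level = 2` this reduces to
#' the attribute proportion score.
#'
#' @param pooled a `pooled_responses` object.
#' @param term_id term key.
#' @param attribute one of severity, interference, frequency, amount.
#' @param level ordinal numerator cut (responses at/above it are counted).
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @return a `proportion_score`.
#' @export
high_end_proportion <- function(pooled, term_id, attribute, level, library = pooled$library) {
  stopifnot(inherits(pooled, "pooled_responses"))
  if (identical(attribute, "presence")) {
    abort_validation("proportion scores are defined for ordinal attributes, not presence")
  }
  if (!attribute %in% attribute_kinds()) abort_validation(paste0("unknown attribute: ", attribute))
  attrs <- term_attributes(library, term_id)
  if (!attribute %in% attrs) {
    return(new_proportion_score(0L, 0L, not_asked = TRUE))
  }
  rec <- term_records(pooled, term_id)
  rec <- rec[rec$attribute == attribute, , drop = FALSE]
  sympt <- rec$level > 0L
  new_proportion_score(sum(rec$level[sympt] >= level), sum(sympt))
}

#' Physician impact proportion score of a term
#'
#' The share of panel respondents rating the term's impact on tolerability at
#' or above "moderate" (level 2) among **all** respondents who rated the term.
#' With a 9-member panel every defined score is a multiple of 1/9.
#'
#' @param panel data frame with columns `respondent_id`, `term_id`, `impact`
#'   (ordinal 0--4).
#' @param term_id term key.
#' @return a `proportion_score`; undefined when no respondent rated the term.
#' @export
impact_proportion_score <- function(panel, term_id) {
  if (!all(c("respondent_id", "term_id", "impact") %in% names(panel))) {
    abort_format("panel table must have columns respondent_id, term_id, impact")
  }
  if (nrow(panel) == 0) abort_validation("physician panel is empty")
  ratings <- panel$impact[panel$term_id == term_id]
  new_proportion_score(sum(ratings >= proportion_cut_level()), length(ratings))
}

SCORE_METRICS <- c("prevalence", "severity", "interference", "frequency", "amount")

#' Full score table over a library
#'
#' Computes prevalence and the four attribute proportion scores for every
#' library term over the pooled responses. Rows are ordered by library order
#' then metric order, so the output is deterministic.
#'
#' @param pooled a `pooled_responses` object.
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @return a `score_table`: data frame with columns `term_id`, `metric`,
#'   `numerator`, `denominator`, `value` (NA when undefined) and `not_asked`.
#' @export
score_table <- function(pooled, library = pooled$library) {
  stopifnot(inherits(pooled, "pooled_responses"))
  rows <- lapply(library$term_id, function(tid) {
    attrs <- term_attributes(library, tid)
    prev <- prevalence(pooled, tid, library)
    out <- data.frame(term_id = tid, metric = SCORE_METRICS,
                      numerator = 0L, denominator = 0L,
                      value = NA_real_, not_asked = FALSE,
                      stringsAsFactors = FALSE)
    out[1, c("numerator", "denominator", "value")] <- list(prev$numerator, prev$denominator, prev$value)
    for (i in seq_along(SCORE_METRICS[-1])) {
      a <- SCORE_METRICS[i + 1]
      s <- if (a %in% attrs) attribute_proportion_score(pooled, tid, a, library) else new_proportion_score(0L, 0L, not_asked = TRUE)
      out[i + 1, c("numerator", "denominator", "value")] <- list(s$numerator, s$denominator, s$value)
      out$not_asked[i + 1] <- s$not_asked
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Build a score table from per-term metric values
#'
#' Constructs a `score_table` directly from given proportion values (e.g. the
#' values reported for the study cohort), bypassing raw responses. Values are
#' percents with one decimal; they are stored exactly as numerator/1000.
#' Metrics not listed default to clearly-passing values so that threshold
#' replays are driven only by the listed scores.
#'
#' @param values data frame with columns `metric`, `term_id`, `value_percent`.
#' @param library a [term_library].
#' @param default_prevalence fill-in prevalence for unlisted terms (default 0.35).
#' @param default_proportion fill-in attribute score for unlisted, asked
#'   attributes (default 0.55).
#' @return a `score_table`.
#' @export
score_table_from_values <- function(values, library,
                                    default_prevalence = 0.35,
                                    default_proportion = 0.55) {
  stopifnot(inherits(library, "term_library"))
  if (!all(c("metric", "term_id", "value_percent") %in% names(values))) {
    abort_format("values table must have columns metric, term_id, value_percent")
  }
  unknown <- setdiff(values$term_id, library$term_id)
  if (length(unknown) > 0) abort_lookup(paste0("unknown term_id: ", paste(unknown, collapse = ", ")))
  key <- paste(values$metric, values$term_id)
  lookup <- stats::setNames(values$value_percent, key)
  rows <- lapply(library$term_id, function(tid) {
    attrs <- term_attributes(library, tid)
    vals <- vapply(SCORE_METRICS, function(m) {
      v <- lookup[paste(m, tid)]
      if (!is.na(v)) return(v / 100)
      if (m == "prevalence") return(default_prevalence)
      if (m %in% attrs) default_proportion else NA_real_
    }, numeric(1))
    not_asked <- SCORE_METRICS != "prevalence" & !SCORE_METRICS %in% attrs
    data.frame(term_id = tid, metric = SCORE_METRICS,
               numerator = ifelse(not_asked, 0L, as.integer(round(vals * 1000))),
               denominator = ifelse(not_asked, 0L, 1000L),
               value = ifelse(not_asked, NA_real_, vals),
               not_asked = not_asked, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Extract one metric from a score table
#'
#' @param scores a `score_table`.
#' @param metric one of `prevalence`, `severity`, `interference`, `frequency`,
#'   `amount`.
#' @return the metric's rows, one per term.
#' @export
score_metric <- function(scores, metric) {
  if (!metric %in% SCORE_METRICS) abort_validation(paste0("unknown metric: ", metric))
  scores[scores$metric == metric, , drop = FALSE]
}

#' Write a score table to CSV
#'
#' @param scores a `score_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
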