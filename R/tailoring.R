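#' @title The tailoring pipeline
#'
#' @description
#' The survey is condensed in a fixed order of steps: (i) prevalence filter at
#' 5%; (ii)--(v) severity, interference, frequency and amount proportion-score
#' filters at 25%, each retaining (carried forward) terms that lack the step's
#' attribute question; (vi) one reliability-based removal per eligible domain;
#' (vii) physician impact filter at 25% followed by reintroduction of terms
#' the panel repeatedly flagged as relevant. Every step is recorded in an
#' auditable elimination ledger whose bookkeeping identity
#' `|library| - eliminated + reintroduced = |final|` is enforced before any
#' report is rendered.
#'
#' Thresholds are strict: a term is eliminated only when its score is defined
#' and strictly below the threshold, so a term sitting exactly at the
#' threshold is retained. Scores are computed once from the pooled data; only
#' the reliability step is evaluated on the then-current working set.
#'
#' @name tailoring
NULL

#' Tailoring configuration
#'
#' @param prevalence_threshold proportion below which terms are eliminated at
#'   the prevalence step (default 0.05).
#' @param proportion_score_threshold threshold for the four attribute
#'   proportion-score steps (default 0.25).
#' @param impact_threshold threshold for the physician impact step
#'   (default 0.25).
#' @param reintroduction_terms term ids to reintroduce after the physician
#'   step; each must have been eliminated at an earlier step.
#' @param reliability_policy `"absolute"` or `"signed"`, see
#'   [select_reliability_removals()].
#' @param composite composite item score entering alpha, see
#'   [composite_item_scores()].
#' @param complete_case pool only patients observed at every timepoint
#'   (default `FALSE`: administered surveys count as-is).
#' @return a `tailoring_config` list.
#' @export
tailoring_config <- function(prevalence_threshold = 0.05,
                             proportion_score_threshold = 0.25,
                             impact_threshold = 0.25,
                             reintroduction_terms = character(),
                             reliability_policy = "absolute",
                             composite = "max",
                             complete_case = FALSE) {
  thresholds <- c(prevalence_threshold, proportion_score_threshold, impact_threshold)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0) || any(thresholds >= 1)) {
    abort_config("thresholds must lie strictly between 0 and 1")
  }
  structure(list(prevalence_threshold = prevalence_threshold,
                 proportion_score_threshold = proportion_score_threshold,
                 impact_threshold = impact_threshold,
                 reintroduction_terms = as.character(reintroduction_terms),
                 reliability_policy = match.arg(reliability_policy, c("absolute", "signed")),
                 composite = match.arg(composite, c("max", "severity", "mean")),
                 complete_case = isTRUE(complete_case)),
            class = "tailoring_config")
}

#' Read a tailoring configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [tailoring_config()]; absent keys take the defaults.
#' @return a `tailoring_config`.
#' @export
read_tailoring_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(tailoring_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) abort_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  do.call(tailoring_config, raw)
}

new_ledger <- function(library) {
  structure(list(library_terms = library$term_id,
                 working = sort(library$term_id),
                 steps = list(),
                 reintroduced = character()),
            class = "elimination_ledger")
}

ledger_add_step <- function(ledger, name, metric, threshold,
                            eliminated, carried_forward = character(),
                            reintroduced = character()) {
  stopifnot(all(eliminated$term_id %in% ledger$working))
  already <- intersect(eliminated$term_id, ledger_eliminated(ledger))
  if (length(already) > 0) {
    abort_integrity(paste0("term(s) eliminated twice: ", paste(already, collapse = ", ")))
  }
  surviving <- sort(union(setdiff(ledger$working, eliminated$term_id), reintroduced))
  step <- list(name = name, metric = metric, threshold = threshold,
               eliminated = eliminated[order(eliminated$term_id), , drop = FALSE],
               carried_forward = sort(carried_forward),
               reintroduced = sort(reintroduced),
               surviving_count = length(surviving))
  ledger$steps <- c(ledger$steps, list(step))
  ledger$working <- surviving
  ledger$reintroduced <- sort(c(ledger$reintroduced, reintroduced))
  ledger
}

#' All terms eliminated so far in a ledger
#'
#' @param ledger an `elimination_ledger`.
#' @return character vector of term ids (order of elimination, then id).
#' @export
ledger_eliminated <- function(ledger) {
  unlist(lapply(ledger$steps, function(s) s$eliminated$term_id), use.names = FALSE)
}

#' Surviving term count after each ledger step
#'
#' @param ledger an `elimination_ledger`.
#' @return named integer vector, one entry per step.
#' @export
ledger_survivors <- function(ledger) {
  stats::setNames(vapply(ledger$steps, function(s) s$surviving_count, integer(1)),
                  vapply(ledger$steps, function(s) s$name, character(1)))
}

#' Check the ledger conservation identity
#'
#' `|library| - total eliminated + reintroduced = |final|`, eliminations
#' pairwise disjoint, and every reintroduced term previously eliminated.
#'
#' @param ledger an `elimination_ledger`.
#' @return `TRUE` invisibly; otherwise an integrity error.
#' @export
ledger_conservation <- function(ledger) {
  elim <- ledger_eliminated(ledger)
  if (anyDuplicated(elim)) abort_integrity("ledger eliminations are not disjoint")
  if (!all(ledger$reintroduced %in% elim)) {
    abort_integrity("ledger reintroduces term(s) never eliminated")
  }
  expected <- length(ledger$library_terms) - length(elim) + length(ledger$reintroduced)
  if (expected != length(ledger$working)) {
    abort_integrity(sprintf("ledger conservation violated: %d - %d + %d != %d",
                            length(ledger$library_terms), length(elim),
                            length(ledger$reintroduced), length(ledger$working)))
  }
  invisible(TRUE)
}

#' Apply one threshold elimination step
#'
#' A term in the working set is eliminated iff its score for `metric` is
#' defined and strictly below `threshold`. Terms lacking the metric's
#' attribute question are retained and flagged carried-forward, as is a term
#' whose asked attribute has an undefined (0/0) score. A term whose
#' *prevalence* is undefined was never presented and is eliminated with
#' reason `"not_administered"`.
#'
#' @param scores a `score_table`.
#' @param working_set character vector of term ids still in play.
#' @param metric one of the score-table metrics.
#' @param threshold elimination threshold in (0, 1).
#' @param carry_forward whether missing-attribute terms are carried forward
#'   (`TRUE` for the attribute steps; at the prevalence step there is nothing
#'   to carry).
#' @return list with `eliminated` (data frame `term_id`, `value`, `reason`),
#'   `retained` and `carried_forward` (character vectors).
#' @export
apply_threshold_filter <- function(scores, working_set, metric, threshold,
                                   carry_forward = metric != "prevalence") {
  rows <- score_metric(scores, metric)
  rows <- rows[rows$term_id %in% working_set, , drop = FALSE]
  missing_terms <- setdiff(working_set, rows$term_id)
  if (length(missing_terms) > 0) {
    abort_validation(paste0("score table lacks metric ", metric, " for: ",
                            paste(missing_terms, collapse = ", ")))
  }
  carried <- character()
  eliminated <- data.frame(term_id = character(), value = numeric(),
                           reason = character(), stringsAsFactors = FALSE)
  if (carry_forward) {
    carried <- rows$term_id[rows$not_asked | (is.na(rows$value) & !rows$not_asked)]
    rows <- rows[!rows$term_id %in% carried, , drop = FALSE]
  } else {
    undef <- rows$term_id[is.na(rows$value)]
    if (length(undef) > 0) {
      eliminated <- rbind(eliminated,
                          data.frame(term_id = undef, value = NA_real_,
                                     reason = "not_administered", stringsAsFactors = FALSE))
      rows <- rows[!rows$term_id %in% undef, , drop = FALSE]
    }
  }
  below <- rows$value < threshold
  if (any(below)) {
    eliminated <- rbind(eliminated,
                        data.frame(term_id = rows$term_id[below], value = rows$value[below],
                                   reason = "below_threshold", stringsAsFactors = FALSE))
  }
  retained <- sort(c(rows$term_id[!below], carried))
  list(eliminated = eliminated[order(eliminated$term_id), , drop = FALSE],
       retained = retained, carried_forward = sort(carried))
}

patient_threshold_steps <- function(scores, library, config) {
  ledger <- new_ledger(library)
  # step (i): prevalence at 5%
  f <- apply_threshold_filter(scores, ledger$working, "prevalence",
                              config$prevalence_threshold, carry_forward = FALSE)
  ledger <- ledger_add_step(ledger, "prevalence", "prevalence",
                            config$prevalence_threshold, f$eliminated)
  # steps (ii)-(v): attribute proportion scores at 25%, with carry-forward
  for (metric in c("severity", "interference", "frequency", "amount")) {
    f <- apply_threshold_filter(scores, ledger$working, metric,
                                config$proportion_score_threshold, carry_forward = TRUE)
    ledger <- ledger_add_step(ledger, metric, metric,
                              config$proportion_score_threshold,
                              f$eliminated, carried_forward = f$carried_forward)
  }
  ledger
}

reliability_step_from_removals <- function(ledger, removals) {
  elim <- data.frame(term_id = removals$term_id,
                     value = if (is.null(removals$percent_change)) rep(NA_real_, nrow(removals)) else removals$percent_change,
                     reason = rep("lowest_reliability_change", nrow(removals)),
                     stringsAsFactors = FALSE)
  ledger_add_step(ledger, "reliability", "loo_percent_change", NA_real_, elim)
}

#' Run the patient-data tailoring steps (i)--(vi)
#'
#' Pools the dataset, computes the score table once, applies the prevalence
#' and four attribute proportion-score filters, then performs the
#' leave-one-term-out reliability pruning on the remaining working set.
#'
#' @param dataset a `response_dataset`.
#' @param library the [term_library]; defaults to the dataset's.
#' @param config a [tailoring_config()].
#' @return list with `ledger` (through the reliability step), `working_set`,
#'   `scores` (the full `score_table`), and `reliability` (the
#'   [domain_reliability()] table the removals were chosen from).
#' @export
run_patient_steps <- function(dataset, library = dataset$library,
                              config = tailoring_config()) {
  pooled <- pool_timepoints(dataset, complete_case = config$complete_case)
  scores <- score_table(pooled, library)
  ledger <- patient_threshold_steps(scores, library, config)
  rel <- domain_reliability(pooled, library, working_terms = ledger$working,
                            composite = config$composite)
  removals <- select_reliability_removals(rel, policy = config$reliability_policy)
  ledger <- reliability_step_from_removals(ledger, removals)
  list(ledger = ledger, working_set = ledger$working, scores = scores, reliability = rel)
}

#' Run the physician refinement step (vii)
#'
#' Eliminates working-set terms whose impact proportion score is defined and
#' below the threshold, then reintroduces the configured terms. Terms no
#' panel member rated are retained and flagged carried-forward. Each
#' reintroduced term must exist in the library and have been eliminated at an
#' earlier step; its full attribute set is restored from the library.
#'
#' @param ledger the `elimination_ledger` from [run_patient_steps()].
#' @param panel physician panel data frame
#'   (`respondent_id`, `term_id`, `impact`).
#' @param library the [term_library].
#' @param config a [tailoring_config()].
#' @return list with the updated `ledger`, the `final_set` (sorted term ids),
#'   and `impact_scores` (per working-set term).
#' @export
run_physician_step <- function(ledger, panel, library, config = tailoring_config()) {
  stopifnot(inherits(ledger, "elimination_ledger"))
  working <- ledger$working
  scores <- lapply(working, function(tid) impact_proportion_score(panel, tid))
  impact <- data.frame(term_id = working,
                       numerator = vapply(scores, `[[`, integer(1), "numerator"),
                       denominator = vapply(scores, `[[`, integer(1), "denominator"),
                       value = vapply(scores, `[[`, numeric(1), "value"),
                       stringsAsFactors = FALSE)
  carried <- impact$term_id[is.na(impact$value)]
  below <- !is.na(impact$value) & impact$value < config$impact_threshold
  eliminated <- data.frame(term_id = impact$term_id[below], value = impact$value[below],
                           reason = rep("below_threshold", sum(below)), stringsAsFactors = FALSE)
  reintro <- sort(unique(config$reintroduction_terms))
  unknown <- setdiff(reintro, library$term_id)
  if (length(unknown) > 0) abort_lookup(paste0("reintroduction term(s) not in library: ", paste(unknown, collapse = ", ")))
  prior_elim <- c(ledger_eliminated(ledger), eliminated$term_id)
  never <- setdiff(reintro, prior_elim)
  if (length(never) > 0) {
    abort_validation(paste0("reintroduction term(s) never eliminated: ", paste(never, collapse = ", ")))
  }
  ledger <- ledger_add_step(ledger, "physician", "impact", config$impact_threshold,
                            eliminated, carried_forward = carried, reintroduced = reintro)
  list(ledger = ledger, final_set = ledger$working, impact_scores = impact)
}

#' Build the tailored survey and a human-readable report
#'
#' Refuses to render (integrity error) unless the ledger's conservation
#' identity holds.
#'
#' @param ledger a completed `elimination_ledger`.
#' @param library the [term_library].
#' @return a `tailored_survey`: list with `terms` (library rows of the final
#'   set, annotated with attribute superscripts in Fig.-2 style, e.g.
#'   `Fatigue [S,I]`), `term_ids`, `item_count`, `domains`, `n_domains`,
#'   `survivors` (per-step counts) and `report` (markdown lines).
#' @export
build_report <- function(ledger, library) {
  ledger_conservation(ledger)
  final <- sort(ledger$working)
  terms <- as.data.frame(library)[library$term_id %in% final, , drop = FALSE]
  terms <- terms[order(terms$domain, terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  initials <- c(presence = "P", severity = "S", interference = "I",
                frequency = "F", amount = "A")
  terms$annotation <- vapply(terms$term_id, function(tid) {
    a <- term_attributes(library, tid)
    paste0(terms$display_name[terms$term_id == tid], " [",
           paste(initials[a], collapse = ","), "]")
  }, character(1))
  n_items <- item_count(final, library)
  domains <- sort(unique(terms$domain))
  md <- c("# Tailored survey report", "",
          sprintf("Library: %d terms, %d items.", length(ledger$library_terms),
                  item_count(ledger$library_terms, library)),
          "", "## Elimination ledger", "")
  for (s in ledger$steps) {
    md <- c(md, sprintf("- **%s** (metric %s%s): eliminated %d%s%s -> %d surviving",
                        s$name, s$metric,
                        if (is.na(s$threshold)) "" else sprintf(", threshold %g", s$threshold),
                        nrow(s$eliminated),
                        if (length(s$carried_forward) > 0)
                          sprintf(", carried forward %d", length(s$carried_forward)) else "",
                        if (length(s$reintroduced) > 0)
                          sprintf(", reintroduced %d", length(s$reintroduced)) else "",
                        s$surviving_count))
  }
  md <- c(md, "", sprintf("## Final survey: %d terms, %d domains, up to %d items", length(final), length(domains), n_items), "",
          paste0("- ", terms$annotation))
  structure(list(terms = terms, term_ids = final, item_count = n_items,
                 domains = domains, n_domains = length(domains),
                 survivors = ledger_survivors(ledger), report = md),
            class = "tailored_survey")
}

#' Run the complete tailoring pipeline
#'
#' Patient-data steps (i)--(vi) followed by the physician refinement step and
#' report construction. Fully deterministic given the inputs.
#'
#' @param dataset a `response_dataset`.
#' @param panel physician panel data frame.
#' @param library the [term_library]; defaults to the dataset's.
#' @param config a [tailoring_config()].
#' @return list with `ledger`, `survey` (a `tailored_survey`), `scores`,
#'   `reliability` and `impact_scores`.
#' @export
tailor_survey <- function(dataset, panel, library = dataset$library,
                          config = tailoring_config()) {
  pat <- run_patient_steps(dataset, library, config)
  phys <- run_physician_step(pat$ledger, panel, library, config)
  survey <- build_report(phys$ledger, library)
  list(ledger = phys$ledger, survey = survey, scores = pat$scores,
       reliability = pat$reliability, impact_scores = phys$impact_scores)
}

ledger_as_list <- function(ledger) {
  list(library_terms = ledger$library_terms,
       steps = lapply(ledger$steps, function(s) {
         list(name = s$name, metric = s$metric, threshold = s$threshold,
              eliminated = s$eliminated, carried_forward = s$carried_forward,
              reintroduced = s$reintroduced, surviving_count = s$surviving_count)
       }),
       reintroduced = ledger$reintroduced,
       final = ledger$working)
}

#' Write an elimination ledger to JSON
#'
#' @param ledger an `elimination_ledger`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(ledger_as_list(ledger), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.elimination_ledger <- function(x, ...) {
  cat(sprintf("elimination ledger: %d library terms, %d steps, %d surviving\n",
              length(x$library_terms), length(x$steps), length(x$working)))
  for (s in x$steps) {
    cat(sprintf("  %-12s -%3d%s -> %d\n", s$name, nrow(s$eliminated),
                if (length(s$reintroduced) > 0) sprintf(" +%d", length(s$reintroduced)) else "",
                s$surviving_count))
  }
  invisible(x)
}

#' @export
print.tailored_survey <- function(x, ...) {
  cat(sprintf("tailored survey: %d terms, %d domains, up to %d items\n",
              length(x$term_ids), x$n_domains, x$item_count))
  invisible(x)
}
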