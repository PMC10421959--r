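#' @title Latent-factor survey response generator
#'
#' @description
#' Responses are generated per patient and retained timepoint from a Gaussian
#' latent-threshold (copula-style) model. For every organ-system domain a
#' standard-normal factor `z` is drawn for the administration; term `t` with
#' loading `lambda_t` is symptomatic when
#' `u = lambda_t z + sqrt(1 - lambda_t^2) e < qnorm(pi_t)` with `e` standard
#' normal, so the marginal symptomatic probability equals the configured
#' prevalence `pi_t` *exactly* while within-domain co-occurrence (and hence
#' Cronbach's alpha of the composite scores) is controlled by the loadings.
#' Given a symptomatic draw, ordinal attribute levels 1--4 come from the
#' term's conditional distributions; attributes of one term are comonotone by
#' default (a single uniform mapped through each attribute's quantile
#' function). Attrition is independent Bernoulli retention per timepoint.
#'
#' @name synthetic_data
NULL

default_attribute_levels <- function() c(0.45, 0.35, 0.15, 0.05)

#' Generator configuration
#'
#' @param library a [term_library]; the generator emits one row per attribute
#'   item of each term at each retained administration.
#' @param n_patients cohort size (study-like default 219).
#' @param retention per-timepoint completion probabilities; the study-like
#'   default (1, 191/219, 118/219) gives expected administration counts
#'   219/191/118.
#' @param prevalence per-term marginal symptomatic probability `pi_t`; either
#'   a single value or a named vector over term ids (default 0.35 each).
#' @param attribute_levels conditional level distributions given symptomatic:
#'   a single probability 4-vector over levels 1--4, or a named list
#'   `term -> attribute -> 4-vector` (unlisted entries take the shared
#'   default).
#' @param loading per-term domain-factor loading in \[0, 1); single value or
#'   named vector (default 0.45).
#' @param attribute_coupling `"comonotone"` (default) or `"independent"`.
#' @param seed integer seed driving the single RNG stream.
#' @return a `generator_config`.
#' @export
generator_config <- function(library,
                             n_patients = 219,
                             retention = c(baseline = 1, mid_cycle_1 = 191 / 219, mid_cycle_2 = 118 / 219),
                             prevalence = 0.35,
                             attribute_levels = default_attribute_levels(),
                             loading = 0.45,
                             attribute_coupling = c("comonotone", "independent"),
                             seed = 1L) {
  stopifnot(inherits(library, "term_library"))
  attribute_coupling <- match.arg(attribute_coupling)
  if (n_patients < 1) abort_config("n_patients must be >= 1")
  if (length(retention) < 1 || any(retention < 0 | retention > 1)) {
    abort_config("retention probabilities must lie in [0, 1]")
  }
  if (is.null(names(retention))) names(retention) <- DEFAULT_TIMEPOINTS[seq_along(retention)]
  prev <- expand_named(prevalence, library$term_id, "prevalence")
  if (any(prev < 0 | prev > 1)) abort_config("prevalence values must lie in [0, 1]")
  lam <- expand_named(loading, library$term_id, "loading")
  if (any(lam < 0 | lam >= 1)) abort_config("loadings must lie in [0, 1)")
  levels_by_term <- expand_levels(attribute_levels, library)
  structure(list(library = library, n_patients = as.integer(n_patients),
                 retention = retention, prevalence = prev,
                 attribute_levels = levels_by_term, loading = lam,
                 attribute_coupling = attribute_coupling, seed = as.integer(seed)),
            class = "generator_config")
}

expand_named <- function(x, ids, what) {
  if (length(x) == 1 && is.null(names(x))) return(stats::setNames(rep(as.numeric(x), length(ids)), ids))
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  unknown <- setdiff(names(x), ids)
  if (length(unknown) > 0) abort_config(paste0("unknown term in ", what, ": ", paste(unknown, collapse = ", ")))
  out[names(x)] <- as.numeric(x)
  if (anyNA(out)) abort_config(paste0(what, " must cover every term or be a single value"))
  out
}

check_level_probs <- function(p, where) {
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort_config(paste0("conditional level distribution must be 4 probabilities summing to 1 (", where, ")"))
  }
  p
}

expand_levels <- function(attribute_levels, library) {
  ordinal <- setdiff(attribute_kinds(), "presence")
  out <- list()
  shared <- if (is.numeric(attribute_levels)) check_level_probs(attribute_levels, "shared") else default_attribute_levels()
  for (tid in library$term_id) {
    attrs <- intersect(term_attributes(library, tid), ordinal)
    out[[tid]] <- stats::setNames(rep(list(shared), length(attrs)), attrs)
    if (is.list(attribute_levels) && !is.null(attribute_levels[[tid]])) {
      for (a in names(attribute_levels[[tid]])) {
        if (!a %in% attrs) abort_config(paste0("term ", tid, " has no attribute ", a))
        out[[tid]][[a]] <- check_level_probs(attribute_levels[[tid]][[a]], paste(tid, a))
      }
    }
  }
  out
}

sample_levels <- function(probs, u) {
  # map uniforms through the conditional quantile function over levels 1..4
  findInterval(u, cumsum(probs), left.open = TRUE) + 1L
}

#' Simulate a survey response dataset
#'
#' @param config a [generator_config()].
#' @return a validated `response_dataset`; identical config (including seed)
#'   gives an identical dataset.
#' @export
simulate_survey_data <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  library <- config$library
  withr::with_seed(config$seed, {
    tps <- names(config$retention)
    admins <- do.call(rbind, lapply(seq_along(tps), function(k) {
      keep <- stats::rbinom(config$n_patients, 1L, config$retention[k]) == 1L
      if (!any(keep)) return(NULL)
      data.frame(patient_id = sprintf("P%04d", which(keep)), timepoint = tps[k],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(admins) || nrow(admins) == 0) abort_config("retention produced no administrations")
    n_adm <- nrow(admins)
    doms <- library_domains(library)
    z <- matrix(stats::rnorm(n_adm * length(doms)), n_adm, length(doms),
                dimnames = list(NULL, doms))
    chunks <- vector("list", nrow(library))
    for (i in seq_len(nrow(library))) {
      tid <- library$term_id[i]
      lam <- config$loading[tid]
      u <- lam * z[, library$domain[i]] + sqrt(1 - lam^2) * stats::rnorm(n_adm)
      sympt <- u < stats::qnorm(config$prevalence[tid])
      attrs <- term_attributes(library, tid)
      if (identical(attrs, "presence")) {
        lv <- matrix(as.integer(sympt), ncol = 1, dimnames = list(NULL, "presence"))
      } else {
        lv <- matrix(0L, nrow = n_adm, ncol = length(attrs), dimnames = list(NULL, attrs))
        if (any(sympt)) {
          ns <- sum(sympt)
          v_shared <- stats::runif(ns)
          for (a in attrs) {
            v <- if (config$attribute_coupling == "comonotone") v_shared else stats::runif(ns)
            lv[sympt, a] <- sample_levels(config$attribute_levels[[tid]][[a]], v)
          }
        }
      }
      chunks[[i]] <- data.frame(
        patient_id = rep(admins$patient_id, length(attrs)),
        timepoint = rep(admins$timepoint, length(attrs)),
        term_id = tid,
        attribute = rep(attrs, each = n_adm),
        level = as.integer(lv),
        stringsAsFactors = FALSE)
    }
    responses <- do.call(rbind, chunks)
  })
  response_dataset(responses, library, timepoints = names(config$retention))
}

#' Closed-form expected score table of a generator configuration
#'
#' Prevalence equals the configured `pi_t` by construction; each attribute
#' proportion score equals the conditional mass at or above the cut level
#' (levels 2--4).
#'
#' @param config a [generator_config()].
#' @return data frame `term_id`, `metric`, `value` (NA for attributes the
#'   term does not ask).
#' @export
analytic_marginals <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  library <- config$library
  rows <- lapply(library$term_id, function(tid) {
    attrs <- term_attributes(library, tid)
    vals <- vapply(SCORE_METRICS, function(m) {
      if (m == "prevalence") return(unname(config$prevalence[tid]))
      if (!m %in% attrs) return(NA_real_)
      sum(config$attribute_levels[[tid]][[m]][proportion_cut_level():4])
    }, numeric(1))
    data.frame(term_id = tid, metric = SCORE_METRICS, value = vals,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Physician panel configuration
#'
#' @param terms character vector of term ids the panel rates.
#' @param n_respondents panel size (study-like default 9).
#' @param impact_levels per-term impact rating distribution over levels 0--4:
#'   a single 5-vector or a named list over terms.
#' @param seed integer seed.
#' @return a `panel_config`.
#' @export
panel_config <- function(terms, n_respondents = 9,
                         impact_levels = c(0.3, 0.3, 0.2, 0.15, 0.05),
                         seed = 1L) {
  if (length(terms) == 0) abort_config("panel needs at least one term")
  if (n_respondents < 1) abort_config("n_respondents must be >= 1")
  check5 <- function(p, where) {
    if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort_config(paste0("impact distribution must be 5 probabilities summing to 1 (", where, ")"))
    }
    p
  }
  dist <- if (is.numeric(impact_levels)) {
    stats::setNames(rep(list(check5(impact_levels, "shared")), length(terms)), terms)
  } else {
    out <- stats::setNames(rep(list(check5(c(0.3, 0.3, 0.2, 0.15, 0.05), "default")), length(terms)), terms)
    unknown <- setdiff(names(impact_levels), terms)
    if (length(unknown) > 0) abort_config(paste0("unknown term in impact_levels: ", paste(unknown, collapse = ", ")))
    for (tid in names(impact_levels)) out[[tid]] <- check5(impact_levels[[tid]], tid)
    out
  }
  structure(list(terms = terms, n_respondents = as.integer(n_respondents),
                 impact_levels = dist, seed = as.integer(seed)),
            class = "panel_config")
}

#' Simulate a physician impact-rating panel
#'
#' @param config a [panel_config()].
#' @return data frame `respondent_id`, `term_id`, `impact` (0--4), one row per
#'   respondent-term; seeded determinism.
#' @export
simulate_physician_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  withr::with_seed(config$seed, {
    rows <- lapply(config$terms, function(tid) {
      data.frame(respondent_id = sprintf("MD%02d", seq_len(config$n_respondents)),
                 term_id = tid,
                 impact = sample(0:4, config$n_respondents, replace = TRUE,
                                 prob = config$impact_levels[[tid]]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}
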