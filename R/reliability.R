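#' @title Domain reliability and leave-one-term-out pruning
#'
#' @description
#' Terms are grouped into organ-system domains; each domain's internal
#' consistency is Cronbach's alpha over per-term composite item scores
#' (administrations x terms). For every term, alpha is recomputed with that
#' term excluded; the term with the smallest (by default, smallest absolute)
#' percent change in domain reliability is the pruning candidate -- removing
#' it affects the domain's reliability least. Domains with two or fewer
#' remaining terms are never pruned.
#'
#' @name reliability
NULL

#' Composite item scores of a domain
#'
#' Builds the administrations-by-terms matrix entering alpha. The default
#' composite is the maximum level across the term's answered attribute items
#' in that administration (mirroring the "any attribute" prevalence logic);
#' presence-only terms contribute their 0/1. Alternatives: `severity` (the
#' severity item alone, or the presence item for presence-only terms) and
#' `mean` of answered attribute levels. An administration with no answered
#' item for a term yields a missing cell.
#'
#' @param pooled a `pooled_responses` object.
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @param domain organ-system domain name.
#' @param terms optional working subset of the domain's terms (default: all).
#' @param composite one of `"max"`, `"severity"`, `"mean"`.
#' @return numeric matrix, rownames = administration ids, colnames = term ids
#'   in lexicographic order.
#' @export
composite_item_scores <- function(pooled, library = pooled$library, domain,
                                  terms = NULL, composite = c("max", "severity", "mean")) {
  stopifnot(inherits(pooled, "pooled_responses"))
  composite <- match.arg(composite)
  dterms <- domain_terms(library, domain)
  if (!is.null(terms)) {
    bad <- setdiff(terms, dterms)
    if (length(bad) > 0) abort_lookup(paste0("term(s) not in domain ", domain, ": ", paste(bad, collapse = ", ")))
    dterms <- sort(terms)
  }
  rec <- pooled$records[pooled$records$term_id %in% dterms, , drop = FALSE]
  if (composite == "severity") {
    rec <- rec[rec$attribute %in% c("severity", "presence"), , drop = FALSE]
  }
  admins <- sort(unique(pooled$records$admin_id))
  m <- matrix(NA_real_, nrow = length(admins), ncol = length(dterms),
              dimnames = list(admins, dterms))
  if (nrow(rec) > 0) {
    f <- switch(composite, max = max, severity = max, mean = mean)
    agg <- tapply(rec$level, list(rec$admin_id, rec$term_id), f)
    m[rownames(agg), colnames(agg)] <- agg
  }
  m
}

#' Cronbach's alpha of an item-score matrix
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of row sums),
#' with sample variances (denominator n-1) after listwise deletion of rows
#' with any missing cell.
#'
#' @param m numeric matrix, rows = administrations, columns = items (terms).
#' @return alpha as a scalar, with attributes `k` (items) and `n` (complete
#'   rows); `NA` (flagged via attribute `reason`) when fewer than 2 columns,
#'   fewer than 2 complete rows, or zero total variance.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2) return(structure(NA_real_, k = k, n = 0L, reason = "fewer than 2 items"))
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) return(structure(NA_real_, k = k, n = n, reason = "fewer than 2 complete rows"))
  item_var <- apply(m, 2, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) return(structure(NA_real_, k = k, n = n, reason = "zero total variance"))
  structure(k / (k - 1) * (1 - sum(item_var) / total_var), k = k, n = n)
}

#' Leave-one-term-out change in domain reliability
#'
#' For each term of the matrix, recomputes alpha without that column (alpha2),
#' and reports the change `delta = alpha2 - alpha1` and the percent change
#' `100 * delta / alpha1`. A domain is eligible for pruning only with more
#' than 2 terms (so each leave-one-out alpha is itself defined on >= 2 items).
#'
#' @param m numeric matrix as from [composite_item_scores()].
#' @return data frame with columns `term_id`, `alpha_full`, `alpha_without`,
#'   `delta`, `percent_change`, `eligible`; terms in column order.
#' @export
loo_percent_change <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  eligible <- k > 2
  alpha1 <- as.numeric(cronbach_alpha(m))
  out <- data.frame(term_id = colnames(m) %||% paste0("item", seq_len(k)),
                    alpha_full = alpha1,
                    alpha_without = NA_real_, delta = NA_real_,
                    percent_change = NA_real_, eligible = eligible,
                    stringsAsFactors = FALSE)
  if (!eligible || is.na(alpha1)) return(out)
  for (j in seq_len(k)) {
    a2 <- as.numeric(cronbach_alpha(m[, -j, drop = FALSE]))
    out$alpha_without[j] <- a2
    out$delta[j] <- a2 - alpha1
    if (abs(alpha1) >= 1e-8) out$percent_change[j] <- 100 * (a2 - alpha1) / alpha1
  }
  out
}

#' Domain-by-domain reliability results over a working term set
#'
#' @param pooled a `pooled_responses` object.
#' @param library the [term_library]; defaults to the one carried by `pooled`.
#' @param working_terms character vector of terms still in play.
#' @param composite composite item-score type, see [composite_item_scores()].
#' @return data frame stacking [loo_percent_change()] results with a leading
#'   `domain` column; domains in lexicographic order.
#' @export
domain_reliability <- function(pooled, library = pooled$library, working_terms,
                               composite = "max") {
  doms <- library_domains(library)
  res <- lapply(doms, function(d) {
    terms <- intersect(domain_terms(library, d), working_terms)
    if (length(terms) == 0) return(NULL)
    m <- composite_item_scores(pooled, library, d, terms = terms, composite = composite)
    cbind(domain = d, loo_percent_change(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select one removable term per eligible domain
#'
#' Implements the pruning rule: in every domain with more than 2 remaining
#' terms, the term whose exclusion changes the domain's reliability least is
#' removed. Under the default `"absolute"` policy "least" is the smallest
#' |percent change|; the `"signed"` alternative takes the (algebraically)
#' smallest percent change. Ties break lexicographically by term id. Domains
#' whose full alpha is numerically zero (|alpha1| < 1e-8) are skipped with a
#' warning, as percent change is undefined there.
#'
#' @param results data frame from [domain_reliability()].
#' @param policy `"absolute"` (default) or `"signed"`.
#' @return data frame with one row per removal: `domain`, `term_id`,
#'   `percent_change`.
#' @export
select_reliability_removals <- function(results, policy = c("absolute", "signed")) {
  policy <- match.arg(policy)
  out <- data.frame(domain = character(), term_id = character(),
                    percent_change = numeric(), stringsAsFactors = FALSE)
  if (is.null(results) || nrow(results) == 0) return(out)
  for (d in sort(unique(results$domain))) {
    r <- results[results$domain == d & results$eligible, , drop = FALSE]
    if (nrow(r) == 0) next
    if (all(is.na(r$percent_change))) {
      warning(sprintf("domain %s skipped: percent change undefined (alpha ~ 0 or insufficient data)", d))
      next
    }
    key <- if (policy == "absolute") abs(r$percent_change) else r$percent_change
    r <- r[order(key, r$term_id), , drop = FALSE]
    out <- rbind(out, data.frame(domain = d, term_id = r$term_id[1],
                                 percent_change = r$percent_change[1],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write reliability results to CSV
#'
#' @param results data frame from [domain_reliability()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reliability <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
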